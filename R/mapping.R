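new_allosteric_map <- function(values, row_kind, row_positions, residue_ids,
                               provenance = list()) {
  stopifnot(is.matrix(values), nrow(values) == length(row_positions),
            ncol(values) == length(residue_ids))
  rownames(values) <- as.character(row_positions)
  colnames(values) <- residue_ids
  structure(
    list(values = values, row_kind = row_kind,
         row_positions = as.integer(row_positions),
         residue_ids = as.character(residue_ids),
         provenance = provenance),
    class = "allosteric_map"
  )
}

#' @export
print.allosteric_map <- function(x, ...) {
  cat(sprintf("<allosteric_map> %s, %d x %d (kcal/mol), %d missing row(s)\n",
              x$row_kind, nrow(x$values), ncol(x$values),
              sum(apply(x$values, 1L, function(r) all(is.na(r))))))
  invisible(x)
}

#' @export
dim.allosteric_map <- function(x) dim(x$values)

map_provenance <- function(structure, config, extra = list()) {
  c(list(
    package = "allokit",
    version = as.character(utils::packageVersion("allokit")),
    source = attr(structure, "source_path") %||% NA_character_,
    n_residues = nrow(structure),
    config = unclass(config)
  ), extra)
}

#' Allosteric Signalling Map (exhaustive mutation scan)
#'
#' For every position m along the chain, computes the per-residue allosteric
#' response to mutating m and stacks the profiles into an N x N matrix: rows
#' are perturbed positions, columns responding residues. By default each row
#' is the modulation range (down-to-up dynamic range); `row_kind = "up"` or
#' `"down"` select single-direction maps. Positions where the down mutation
#' would disconnect the contact network yield a row of `NA` with a warning
#' rather than failing the whole scan.
#'
#' @param structure A `calpha_structure` with at least `min_n` residues.
#' @param config An [allokit_config()].
#' @param row_kind `"range"` (default), `"up"` or `"down"`.
#' @param min_n Smallest chain length accepted (mode analysis on tiny chains
#'   is physically meaningless); default 10.
#' @return An `allosteric_map` object.
#' @examples
#' asm <- compute_asm(make_helix(15))
#' dim(asm)
#' @export
compute_asm <- function(structure, config = allokit_config(),
                        row_kind = c("range", "up", "down"), min_n = 10L) {
  row_kind <- match.arg(row_kind)
  config <- as_allokit_config(config)
  validate_calpha_structure(structure)
  n <- nrow(structure)
  if (n < min_n) {
    abort(sprintf("structure has %d residues; at least %d required", n, min_n),
          class = "allokit_validation_error")
  }
  network <- build_network(structure, cutoff = config$cutoff, k0 = config$k0)
  eps0 <- network_stiffness(network, config)
  values <- matrix(NA_real_, n, n)
  failed <- integer()
  for (m in seq_len(n)) {
    row <- tryCatch({
      if (row_kind == "range") {
        modulation_range(network, m, eps0 = eps0, config = config)$dh_range
      } else {
        pert <- if (row_kind == "up") {
          perturbation("up", m, alpha_up = config$alpha_up)
        } else {
          perturbation("down", m)
        }
        free_energy_profile(network, pert, eps0 = eps0, config = config)$dh
      }
    }, allokit_disconnected_error = function(e) {
      failed <<- c(failed, m)
      rep(NA_real_, n)
    })
    values[m, ] <- row
  }
  if (length(failed) > 0L) {
    warn(sprintf("down mutation disconnects the network at position(s) %s; rows set to NA",
                 paste(failed, collapse = ", ")))
  }
  kind <- switch(row_kind, range = "mutation_range", up = "up", down = "down")
  new_allosteric_map(values, kind, seq_len(n), network$residue_ids,
                     map_provenance(structure, config,
                                    list(map = "asm", row_kind = kind)))
}

#' Allosteric Probing Map (exhaustive probe scan)
#'
#' Simulates binding of a small probe to every consecutive three-residue
#' segment and stacks the modulation profiles into an (N-2) x N matrix: row s
#' is the response to a probe bound at segment (s, s+1, s+2).
#'
#' @inheritParams compute_asm
#' @return An `allosteric_map` with `row_kind = "probe"`.
#' @export
compute_apm <- function(structure, config = allokit_config(), min_n = 10L) {
  config <- as_allokit_config(config)
  validate_calpha_structure(structure)
  n <- nrow(structure)
  if (n < min_n) {
    abort(sprintf("structure has %d residues; at least %d required", n, min_n),
          class = "allokit_validation_error")
  }
  network <- build_network(structure, cutoff = config$cutoff, k0 = config$k0)
  eps0 <- network_stiffness(network, config)
  values <- matrix(NA_real_, n - 2L, n)
  for (s in seq_len(n - 2L)) {
    pert <- perturbation("probe", s, alpha_bind = config$alpha_bind)
    values[s, ] <- free_energy_profile(network, pert, eps0 = eps0,
                                       config = config)$dh
  }
  new_allosteric_map(values, "probe", seq_len(n - 2L), network$residue_ids,
                     map_provenance(structure, config, list(map = "apm")))
}

#' Mask proximal and weak signalling: the allosteric fingerprint
#'
#' Entries whose responding residue lies closer than `d_min` Angstrom to the
#' perturbed residue(s) of the row (minimum C-alpha distance; strictly less),
#' or whose modulation magnitude does not exceed `h_min` kcal/mol, are masked
#' so that the remaining map highlights genuine long-range communication.
#' `NA` entries (failed rows) are always masked.
#'
#' @param map An `allosteric_map`.
#' @param structure The `calpha_structure` the map was computed from.
#' @param d_min Proximity threshold, Angstrom (default 12).
#' @param h_min Weak-signal threshold, kcal/mol (default 0.1).
#' @return An `allosteric_fingerprint`: the map, the logical mask (`TRUE` =
#'   masked), the thresholds and the masked fraction.
#' @export
make_fingerprint <- function(map, structure, d_min = 12, h_min = 0.1) {
  stopifnot(inherits(map, "allosteric_map"))
  validate_calpha_structure(structure)
  if (is.na(d_min) || is.na(h_min) || d_min < 0 || h_min < 0) {
    abort("d_min and h_min must be non-negative", class = "allokit_validation_error")
  }
  n <- nrow(structure)
  if (ncol(map$values) != n) {
    abort("map and structure disagree on the number of residues",
          class = "allokit_validation_error")
  }
  dmat <- as.matrix(dist(structure_coords(structure)))
  probe <- identical(map$row_kind, "probe")
  prox <- t(vapply(map$row_positions, function(p) {
    set <- if (probe) p + 0:2 else p
    apply(dmat[set, , drop = FALSE], 2L, min)
  }, numeric(n)))
  mask <- (prox < d_min) | (abs(map$values) <= h_min) | is.na(map$values)
  structure(
    list(map = map, mask = mask, d_min = d_min, h_min = h_min,
         masked_fraction = mean(mask)),
    class = "allosteric_fingerprint"
  )
}

#' @export
print.allosteric_fingerprint <- function(x, ...) {
  cat(sprintf(
    "<allosteric_fingerprint> %d x %d, d_min %.1f A, h_min %.3g kcal/mol, %.1f%% masked\n",
    nrow(x$mask), ncol(x$mask), x$d_min, x$h_min, 100 * x$masked_fraction))
  invisible(x)
}

#' Zoom into a contiguous submatrix of a map
#'
#' Large maps (the full scan of a >1200-residue chain) are easier to inspect
#' region by region; `zoom_map` extracts a contiguous block while preserving
#' labels and provenance.
#'
#' @param map An `allosteric_map`.
#' @param rows,cols Contiguous 1-based index ranges (e.g. `1:800`); `NULL`
#'   keeps the full range.
#' @return An `allosteric_map` over the selected block; the zoom window is
#'   recorded in provenance.
#' @export
zoom_map <- function(map, rows = NULL, cols = NULL) {
  stopifnot(inherits(map, "allosteric_map"))
  rows <- if (is.null(rows)) seq_len(nrow(map$values)) else as.integer(rows)
  cols <- if (is.null(cols)) seq_len(ncol(map$values)) else as.integer(cols)
  check_range <- function(r, limit, what) {
    if (length(r) == 0L || any(r < 1L) || any(r > limit)) {
      abort(sprintf("%s range out of bounds 1..%d", what, limit),
            class = "allokit_range_error")
    }
    if (!all(diff(r) == 1L)) {
      abort(sprintf("%s range must be contiguous and ascending", what),
            class = "allokit_range_error")
    }
  }
  check_range(rows, nrow(map$values), "row")
  check_range(cols, ncol(map$values), "column")
  new_allosteric_map(
    map$values[rows, cols, drop = FALSE], map$row_kind,
    map$row_positions[rows], map$residue_ids[cols],
    c(map$provenance, list(zoom_rows = range(rows), zoom_cols = range(cols)))
  )
}

#' Write / read an allosteric map as TSV
#'
#' Tab-separated, UTF-8: a header row of residue labels, a leading `pos`
#' column of row labels, values in kcal/mol at 6 significant digits, missing
#' rows serialized as `NA`. A JSON sidecar (`<path>.json`) records row kind,
#' positions, labels and the full provenance; on read the sidecar, when
#' present, must agree with the file's labels.
#'
#' @param map An `allosteric_map`.
#' @param path Output TSV path.
#' @return `write_map`: `path` invisibly. `read_map`: an `allosteric_map`.
#' @export
write_map <- function(map, path) {
  stopifnot(inherits(map, "allosteric_map"))
  vals <- signif(map$values, 6L)
  df <- data.frame(pos = rownames(map$values), vals, check.names = FALSE,
                   stringsAsFactors = FALSE)
  readr::write_tsv(df, path, na = "NA")
  sidecar <- list(
    row_kind = map$row_kind,
    row_positions = map$row_positions,
    residue_ids = map$residue_ids,
    provenance = map$provenance
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "allokit_io_error")
  }
  df <- tryCatch(
    readr::read_tsv(path, col_types = readr::cols(
      pos = readr::col_character(), .default = readr::col_double()),
      na = "NA", progress = FALSE),
    error = function(e) {
      abort(sprintf("cannot parse %s as a map TSV: %s", path,
                    conditionMessage(e)),
            class = "allokit_format_error")
    }
  )
  probs <- readr::problems(df)
  if (nrow(probs) > 0L) {
    abort(sprintf("malformed map TSV %s at line %d: %s", path,
                  probs$row[1] + 1L, probs$expected[1]),
          class = "allokit_format_error")
  }
  if (!identical(names(df)[1], "pos")) {
    abort(sprintf("map TSV %s must have a leading 'pos' column", path),
          class = "allokit_format_error")
  }
  values <- as.matrix(df[, -1, drop = FALSE])
  residue_ids <- colnames(values)
  row_labels <- df$pos

  sidecar_path <- paste0(path, ".json")
  row_kind <- "mutation_range"
  provenance <- list()
  row_positions <- suppressWarnings(as.integer(row_labels))
  if (anyNA(row_positions)) row_positions <- seq_along(row_labels)
  if (file.exists(sidecar_path)) {
    side <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
    if (!identical(as.character(side$residue_ids), residue_ids) ||
        !identical(as.character(side$row_positions), row_labels)) {
      abort(sprintf("labels in %s do not match its sidecar (file order is authoritative)",
                    path),
            class = "allokit_format_error")
    }
    row_kind <- side$row_kind
    row_positions <- as.integer(side$row_positions)
    provenance <- side$provenance
  }
  new_allosteric_map(values, row_kind, row_positions, residue_ids, provenance)
}
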