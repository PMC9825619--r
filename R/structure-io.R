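#' @rdname read_structure
#' @format NULL
#' @name calpha_structure
NULL

STANDARD_AA <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL", "UNK"
)

new_calpha_structure <- function(df, source_path = NA_character_, model_id = 1L) {
  out <- as_tibble(df)
  attr(out, "source_path") <- source_path
  attr(out, "model_id") <- as.integer(model_id)
  class(out) <- c("calpha_structure", class(tibble()))
  validate_calpha_structure(out)
}

validate_calpha_structure <- function(x) {
  needed <- c("chain_id", "res_seq", "res_name", "x", "y", "z", "bfactor")
  if (!all(needed %in% names(x))) {
    abort(paste0("calpha_structure must have columns: ",
                 paste(needed, collapse = ", ")),
          class = "allokit_validation_error")
  }
  if (nrow(x) < 1L) {
    abort("structure contains zero C-alpha records",
          class = "allokit_empty_structure_error")
  }
  if (!all(is.finite(x$x) & is.finite(x$y) & is.finite(x$z))) {
    abort("non-finite coordinates in structure",
          class = "allokit_validation_error")
  }
  key <- paste(x$chain_id, x$res_seq)
  if (anyDuplicated(key)) {
    abort("duplicate (chain, residue number) pairs in structure",
          class = "allokit_validation_error")
  }
  for (ch in unique(x$chain_id)) {
    rs <- x$res_seq[x$chain_id == ch]
    if (is.unsorted(rs, strictly = TRUE)) {
      abort(sprintf("residue numbers not strictly ascending in chain %s", ch),
            class = "allokit_validation_error")
    }
  }
  x
}

#' C-alpha coordinates as a matrix
#'
#' @param structure A `calpha_structure` tibble.
#' @return An N x 3 numeric matrix of coordinates in Angstrom.
#' @export
structure_coords <- function(structure) {
  m <- cbind(structure$x, structure$y, structure$z)
  dimnames(m) <- list(residue_labels(structure), c("x", "y", "z"))
  m
}

residue_labels <- function(structure) {
  paste0(structure$chain_id, structure$res_seq)
}

#' Read a C-alpha structure from PDB or mmCIF
#'
#' Reads an AlphaFold-style model file (or any single-chain protein structure)
#' down to one record per residue with a C-alpha atom. The B-factor column is
#' carried through unchanged; in AlphaFold models it stores the per-residue
#' pLDDT confidence score.
#'
#' Alternate locations are resolved by keeping the highest-occupancy altloc
#' (ties broken by altloc identifier). Residues without a C-alpha atom are
#' skipped with a warning. Multi-model files default to the first model.
#'
#' @param path Path to a PDB or mmCIF file.
#' @param format `"auto"` (by extension), `"pdb"` or `"mmcif"`.
#' @param chain Chain identifier. May be omitted when the file has exactly one
#'   chain; required otherwise.
#' @param model Model number for multi-model files (default: first).
#'
#' @return A `calpha_structure`: a tibble with one row per residue and columns
#'   `chain_id`, `res_seq` (author numbering), `res_name`, `x`, `y`, `z`
#'   (Angstrom) and `bfactor`, plus `source_path` / `model_id` attributes.
#' @examples
#' pdb <- tempfile(fileext = ".pdb")
#' write_structure(make_helix(5), pdb)
#' read_structure(pdb)
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           chain = NULL, model = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "allokit_io_error")
  }
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  atoms <- switch(format,
    pdb = parse_pdb_atoms(path),
    mmcif = parse_mmcif_atoms(path)
  )
  atoms_to_structure(atoms, path, chain = chain, model = model)
}

# Raw atom table contract shared by both parsers: columns
# record, elety, alt, res_name, chain_id, res_seq, x, y, z, occ, b, model.
parse_pdb_atoms <- function(path) {
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) {
      abort(sprintf("cannot parse '%s' as PDB: %s", path, conditionMessage(e)),
            class = "allokit_format_error")
    }
  )
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0L) {
    abort(sprintf("no atom records found in %s", path),
          class = "allokit_format_error")
  }
  n_models <- max(1L, nrow(pdb$xyz))
  base <- tibble(
    record = at$type,
    elety = at$elety,
    alt = ifelse(is.na(at$alt), "", at$alt),
    res_name = at$resid,
    chain_id = ifelse(is.na(at$chain), "A", at$chain),
    res_seq = as.integer(at$resno),
    occ = ifelse(is.na(at$o), 1.0, at$o),
    b = as.numeric(at$b)
  )
  out <- vector("list", n_models)
  for (m in seq_len(n_models)) {
    xyz <- matrix(pdb$xyz[m, ], ncol = 3L, byrow = TRUE)
    out[[m]] <- mutate(base, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                       model = m)
  }
  bind_rows(out)
}

# Minimal name-mapped reader for the atom_site loop of an mmCIF file.
# Column order is taken from the loop header, never assumed.
parse_mmcif_atoms <- function(path) {
  lines <- readLines(path, warn = FALSE)
  loop_at <- which(trimws(lines) == "loop_")
  header <- character()
  data_rows <- character()
  row_lineno <- integer()
  for (la in loop_at) {
    i <- la + 1L
    tags <- character()
    while (i <= length(lines) && startsWith(trimws(lines[i]), "_")) {
      tags <- c(tags, trimws(lines[i]))
      i <- i + 1L
    }
    if (!any(startsWith(tags, "_atom_site."))) next
    header <- sub("^_atom_site\\.", "", tags)
    while (i <= length(lines)) {
      ln <- trimws(lines[i])
      if (ln == "" || startsWith(ln, "#") || startsWith(ln, "_") ||
          ln == "loop_" || startsWith(ln, "data_")) break
      data_rows <- c(data_rows, lines[i])
      row_lineno <- c(row_lineno, i)
      i <- i + 1L
    }
    break
  }
  if (length(header) == 0L) {
    abort(sprintf("no atom_site loop found in %s", path),
          class = "allokit_format_error")
  }
  need <- function(...) {
    for (cand in c(...)) if (cand %in% header) return(cand)
    abort(sprintf("atom_site loop in %s lacks required column %s",
                  path, c(...)[1]),
          class = "allokit_format_error")
  }
  col <- list(
    record = need("group_PDB"),
    elety = need("label_atom_id", "auth_atom_id"),
    alt = need("label_alt_id"),
    res_name = need("auth_comp_id", "label_comp_id"),
    chain_id = need("auth_asym_id", "label_asym_id"),
    res_seq = need("auth_seq_id", "label_seq_id"),
    x = need("Cartn_x"), y = need("Cartn_y"), z = need("Cartn_z"),
    b = need("B_iso_or_equiv")
  )
  occ_col <- if ("occupancy" %in% header) "occupancy" else NULL
  model_col <- if ("pdbx_PDB_model_num" %in% header) "pdbx_PDB_model_num" else NULL

  fields <- lapply(seq_along(data_rows), function(k) {
    f <- tryCatch(scan(text = data_rows[k], what = character(), quiet = TRUE),
                  error = function(e) NULL)
    if (is.null(f) || length(f) != length(header)) {
      abort(sprintf("malformed atom_site row at line %d of %s",
                    row_lineno[k], path),
            class = "allokit_format_error")
    }
    f
  })
  tab <- do.call(rbind, fields)
  colnames(tab) <- header
  get <- function(nm) if (is.null(nm)) NULL else tab[, nm]
  num <- function(v, what) {
    out <- suppressWarnings(as.numeric(v))
    if (anyNA(out)) {
      bad <- row_lineno[which(is.na(out))[1]]
      abort(sprintf("non-numeric %s in atom_site at line %d of %s",
                    what, bad, path),
            class = "allokit_format_error")
    }
    out
  }
  tibble(
    record = get(col$record),
    elety = get(col$elety),
    alt = ifelse(get(col$alt) %in% c(".", "?"), "", get(col$alt)),
    res_name = get(col$res_name),
    chain_id = get(col$chain_id),
    res_seq = as.integer(num(get(col$res_seq), "residue number")),
    x = num(get(col$x), "x coordinate"),
    y = num(get(col$y), "y coordinate"),
    z = num(get(col$z), "z coordinate"),
    occ = if (is.null(occ_col)) 1.0 else num(get(occ_col), "occupancy"),
    b = num(get(col$b), "B-factor"),
    model = if (is.null(model_col)) 1L
            else as.integer(num(get(model_col), "model number"))
  )
}

atoms_to_structure <- function(atoms, path, chain = NULL, model = NULL) {
  atoms <- filter(atoms, .data$record == "ATOM")
  if (nrow(atoms) == 0L) {
    abort(sprintf("no protein ATOM records in %s", path),
          class = "allokit_empty_structure_error")
  }
  models <- sort(unique(atoms$model))
  model_id <- if (is.null(model)) models[1] else as.integer(model)
  if (!model_id %in% models) {
    abort(sprintf("model %d not present in %s (available: %s)", model_id,
                  path, paste(models, collapse = ", ")),
          class = "allokit_lookup_error")
  }
  atoms <- filter(atoms, .data$model == model_id)

  chains <- sort(unique(atoms$chain_id))
  if (is.null(chain)) {
    if (length(chains) > 1L) {
      abort(sprintf("file has %d chains (%s); pass `chain` explicitly",
                    length(chains), paste(chains, collapse = ", ")),
            class = "allokit_lookup_error")
    }
    chain <- chains[1]
  } else if (!chain %in% chains) {
    abort(sprintf("chain '%s' not found in %s (available: %s)", chain, path,
                  paste(chains, collapse = ", ")),
          class = "allokit_lookup_error")
  }
  atoms <- filter(atoms, .data$chain_id == chain)

  n_res_total <- length(unique(atoms$res_seq))
  ca <- filter(atoms, .data$elety == "CA")
  if (nrow(ca) == 0L) {
    abort(sprintf("no C-alpha atoms in chain %s of %s", chain, path),
          class = "allokit_empty_structure_error")
  }
  n_skipped <- n_res_total - length(unique(ca$res_seq))
  if (n_skipped > 0L) {
    warn(sprintf("%d residue(s) without a C-alpha atom skipped", n_skipped))
  }

  # altloc: keep highest occupancy, ties by altloc identifier
  ca <- arrange(ca, .data$res_seq, dplyr::desc(.data$occ), .data$alt)
  ca <- ca[!duplicated(ca$res_seq), , drop = FALSE]

  res_name <- toupper(ca$res_name)
  res_name[!res_name %in% STANDARD_AA] <- "UNK"

  new_calpha_structure(
    tibble(
      chain_id = ca$chain_id,
      res_seq = ca$res_seq,
      res_name = res_name,
      x = ca$x, y = ca$y, z = ca$z,
      bfactor = ca$b
    ),
    source_path = path, model_id = model_id
  )
}

#' Extract the per-residue pLDDT profile from an AlphaFold-style model
#'
#' In AlphaFold model files the B-factor field stores pLDDT, the per-residue
#' prediction confidence on a 0-100 scale. Values outside that range mean the
#' file is not an AlphaFold-style model and raise a validation error.
#'
#' @param structure A `calpha_structure`.
#' @return A tibble with columns `res_index` (1..N), `res_seq` and `plddt`,
#'   carrying a `source` attribute.
#' @examples
#' extract_plddt(make_helix(5, plddt = 88))
#' @export
extract_plddt <- function(structure) {
  validate_calpha_structure(structure)
  b <- structure$bfactor
  bad <- which(!is.finite(b) | b < 0 | b > 100)
  if (length(bad) > 0L) {
    abort(sprintf(
      "B-factor outside [0, 100] at residue index %s: not an AlphaFold-style model",
      paste(head(bad, 5), collapse = ", ")),
      class = "allokit_validation_error")
  }
  out <- tibble(
    res_index = seq_len(nrow(structure)),
    res_seq = structure$res_seq,
    plddt = b
  )
  attr(out, "source") <- attr(structure, "source_path") %||% NA_character_
  class(out) <- c("plddt_profile", class(tibble()))
  out
}

#' Write a C-alpha structure to PDB or mmCIF
#'
#' Emits a minimal single-chain, C-alpha-only file. The `bfactor` column is
#' written to the B-factor field, mimicking how AlphaFold models store pLDDT.
#'
#' @param structure A `calpha_structure`.
#' @param path Output path.
#' @param format `"auto"` (by extension), `"pdb"` or `"mmcif"`.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  validate_calpha_structure(structure)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  if (format == "pdb") {
    lines <- sprintf(
      "ATOM  %5d  CA  %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
      seq_len(nrow(structure)), structure$res_name, structure$chain_id,
      structure$res_seq, structure$x, structure$y, structure$z,
      1.0, structure$bfactor
    )
    writeLines(c(lines, "END"), path)
  } else {
    hdr <- c(
      "data_allokit", "#", "loop_",
      paste0("_atom_site.", c(
        "group_PDB", "id", "type_symbol", "label_atom_id", "label_alt_id",
        "label_comp_id", "label_asym_id", "label_entity_id", "label_seq_id",
        "pdbx_PDB_ins_code", "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
        "B_iso_or_equiv", "auth_seq_id", "auth_asym_id", "pdbx_PDB_model_num"
      ))
    )
    rows <- sprintf(
      "ATOM %d C CA . %s %s 1 %d ? %.3f %.3f %.3f 1.00 %.2f %d %s 1",
      seq_len(nrow(structure)), structure$res_name, structure$chain_id,
      structure$res_seq, structure$x, structure$y, structure$z,
      structure$bfactor, structure$res_seq, structure$chain_id
    )
    writeLines(c(hdr, rows, "#"), path)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
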