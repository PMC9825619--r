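#' Tidy an allosteric map into long format
#'
#' @param x An `allosteric_map`.
#' @param ... Unused.
#' @return A tibble with one row per (perturbed position, responding residue)
#'   pair: `row_pos`, `residue`, `res_index`, `value` (kcal/mol).
#' @method tidy allosteric_map
#' @export
tidy.allosteric_map <- function(x, ...) {
  tibble(
    row_pos = rep(x$row_positions, times = ncol(x$values)),
    residue = rep(x$residue_ids, each = nrow(x$values)),
    res_index = rep(seq_along(x$residue_ids), each = nrow(x$values)),
    value = as.vector(x$values)
  )
}

#' One-line summary of an allosteric map
#'
#' @param x An `allosteric_map`.
#' @param ... Unused.
#' @return A one-row tibble: dimensions, row kind, missing-row count and the
#'   range of the modulation values.
#' @method glance allosteric_map
#' @export
glance.allosteric_map <- function(x, ...) {
  finite <- x$values[is.finite(x$values)]
  tibble(
    row_kind = x$row_kind,
    n_rows = nrow(x$values),
    n_residues = ncol(x$values),
    n_missing_rows = sum(apply(x$values, 1L, function(r) all(is.na(r)))),
    min_value = if (length(finite)) min(finite) else NA_real_,
    max_value = if (length(finite)) max(finite) else NA_real_
  )
}

#' @rdname tidy.allosteric_map
#' @method tidy allosteric_fingerprint
#' @export
tidy.allosteric_fingerprint <- function(x, ...) {
  mutate(tidy(x$map), masked = as.vector(x$mask))
}

#' @rdname glance.allosteric_map
#' @method glance allosteric_fingerprint
#' @export
glance.allosteric_fingerprint <- function(x, ...) {
  mutate(glance(x$map),
         d_min = x$d_min, h_min = x$h_min,
         masked_fraction = x$masked_fraction)
}
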