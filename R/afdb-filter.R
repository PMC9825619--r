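#' Quality-filter thresholds for predicted structure models
#'
#' Kingdom presets follow the published selection criteria for AlphaFold
#' models: prokaryotes require less than 10% low-confidence residues (LCRs)
#' and LCR runs shorter than 15 residues; eukaryotes, with their larger
#' disordered regions, allow up to (strictly below) 20% and runs below 25.
#' Both share the pLDDT < 70 LCR definition, the 20-residue N-terminal
#' signal-peptide check, the > 50-residue size gate and the > 100-residue
#' browse gate. Every field can be overridden.
#'
#' @param kingdom `"prokaryote"` or `"eukaryote"`; sets `max_lcr_perc` and
#'   `max_lcr_run` unless given explicitly.
#' @param lcr_cut pLDDT below which a residue is an LCR (strict `<`).
#' @param max_lcr_perc Maximal admissible LCR percentage (strict: a structure
#'   at exactly the threshold fails).
#' @param max_lcr_run Maximal admissible consecutive LCR run (strict).
#' @param nterm_window Length of the N-terminal window that must not be all
#'   LCR (signal-peptide proxy).
#' @param min_size Minimal chain length; a structure passes only if strictly
#'   larger.
#' @param browse_min Chain length above which (strictly) a passing structure
#'   is browse-eligible.
#' @return A `filter_thresholds` list.
#' @examples
#' filter_thresholds("eukaryote")
#' @export
filter_thresholds <- function(kingdom = c("prokaryote", "eukaryote"),
                              lcr_cut = 70,
                              max_lcr_perc = NULL,
                              max_lcr_run = NULL,
                              nterm_window = 20L,
                              min_size = 50L,
                              browse_min = 100L) {
  kingdom <- match.arg(kingdom)
  preset <- list(
    prokaryote = list(perc = 10, run = 15L),
    eukaryote = list(perc = 20, run = 25L)
  )[[kingdom]]
  max_lcr_perc <- max_lcr_perc %||% preset$perc
  max_lcr_run <- max_lcr_run %||% preset$run
  stopifnot(lcr_cut > 0, max_lcr_perc > 0, max_lcr_run > 0,
            nterm_window > 0, min_size > 0, browse_min > 0)
  structure(
    list(kingdom = kingdom, lcr_cut = lcr_cut,
         max_lcr_perc = max_lcr_perc, max_lcr_run = as.integer(max_lcr_run),
         nterm_window = as.integer(nterm_window),
         min_size = as.integer(min_size),
         browse_min = as.integer(browse_min)),
    class = "filter_thresholds"
  )
}

plddt_scores <- function(profile) {
  scores <- if (is.data.frame(profile)) profile$plddt else as.numeric(profile)
  if (is.null(scores) || length(scores) < 1L) {
    abort("pLDDT profile is empty (expect a numeric vector or a tibble with a plddt column)",
          class = "allokit_validation_error")
  }
  if (any(!is.finite(scores) | scores < 0 | scores > 100)) {
    abort("pLDDT scores must lie in [0, 100]",
          class = "allokit_validation_error")
  }
  scores
}

#' Low-confidence residue mask
#'
#' A residue is a low-confidence residue (LCR) when its pLDDT score is
#' strictly below `lcr_cut` (default 70, matching the published convention;
#' a residue at exactly 70.0 is confident).
#'
#' @param profile Numeric pLDDT vector or a tibble with a `plddt` column
#'   (as returned by [extract_plddt()] or [make_plddt_profile()]).
#' @param lcr_cut The cut, default 70.
#' @return Logical vector, `TRUE` = LCR.
#' @examples
#' lcr_mask(c(71, 70, 69))
#' @export
lcr_mask <- function(profile, lcr_cut = 70) {
  plddt_scores(profile) < lcr_cut
}

#' LCR fraction and longest run
#'
#' @param mask Logical LCR mask from [lcr_mask()].
#' @return A list with `lcr_perc` (percentage of LCRs, 0-100) and
#'   `lcr_length` (longest consecutive LCR run; 0 when there are none).
#' @examples
#' lcr_stats(c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE))
#' @export
lcr_stats <- function(mask) {
  stopifnot(is.logical(mask), length(mask) >= 1L, !anyNA(mask))
  r <- rle(mask)
  runs <- r$lengths[r$values]
  list(
    lcr_perc = 100 * sum(mask) / length(mask),
    lcr_length = if (length(runs)) max(runs) else 0L
  )
}

#' Apply the quality filter to one pLDDT profile
#'
#' Evaluates the four selection rules with the strict comparisons of the
#' published criteria: fail when the LCR percentage reaches the threshold
#' (`lcr_perc >= max_lcr_perc`), when the longest LCR run reaches its
#' threshold (`lcr_length >= max_lcr_run`), when the first
#' `min(nterm_window, N)` residues are all LCR (low-confidence signal
#' peptide), or when the chain is not strictly larger than `min_size`.
#' Browse eligibility additionally requires `N > browse_min`.
#'
#' @param profile Numeric pLDDT vector or tibble with a `plddt` column.
#' @param thresholds A [filter_thresholds()] object.
#' @return A one-row tibble: `n_residues`, `lcr_perc`, `lcr_length`,
#'   `nterm_all_lcr`, `passed`, `browse_eligible` and `failed_rules`
#'   (list-column of violated rule names; empty when passed).
#' @examples
#' apply_filter(rep(90, 60), filter_thresholds("prokaryote"))
#' @export
apply_filter <- function(profile, thresholds = filter_thresholds()) {
  stopifnot(inherits(thresholds, "filter_thresholds"))
  scores <- plddt_scores(profile)
  n <- length(scores)
  mask <- scores < thresholds$lcr_cut
  stats <- lcr_stats(mask)
  nterm <- all(mask[seq_len(min(thresholds$nterm_window, n))])

  failed <- character()
  if (stats$lcr_perc >= thresholds$max_lcr_perc) failed <- c(failed, "lcr_perc")
  if (stats$lcr_length >= thresholds$max_lcr_run) failed <- c(failed, "lcr_length")
  if (nterm) failed <- c(failed, "nterm_all_lcr")
  if (n <= thresholds$min_size) failed <- c(failed, "min_size")
  passed <- length(failed) == 0L

  tibble(
    n_residues = n,
    lcr_perc = stats$lcr_perc,
    lcr_length = as.integer(stats$lcr_length),
    nterm_all_lcr = nterm,
    passed = passed,
    browse_eligible = passed && n > thresholds$browse_min,
    failed_rules = list(failed)
  )
}

#' Filter a batch of structure files
#'
#' Reads each file, extracts its pLDDT profile and applies the quality
#' filter. Unreadable or invalid files produce an error row (`error` column)
#' instead of aborting the batch; duplicated paths are processed with a
#' warning.
#'
#' @param paths Character vector of PDB/mmCIF files.
#' @param thresholds A [filter_thresholds()].
#' @param output Optional TSV path; the report is written there with
#'   `failed_rules` collapsed to a comma-separated string.
#' @param chain Optional chain passed to [read_structure()].
#' @return A tibble, one row per input, with an `id` column (file basename)
#'   followed by the [apply_filter()] columns and `error`.
#' @export
filter_batch <- function(paths, thresholds = filter_thresholds(),
                         output = NULL, chain = NULL) {
  if (length(paths) < 1L) {
    abort("no input files given", class = "allokit_validation_error")
  }
  if (anyDuplicated(paths)) {
    warn("duplicate input paths; each occurrence is processed")
  }
  rows <- purrr::map(paths, function(p) {
    res <- tryCatch({
      s <- suppressWarnings(read_structure(p, chain = chain))
      rep <- apply_filter(extract_plddt(s), thresholds)
      mutate(rep, id = basename(p), error = NA_character_)
    }, error = function(e) {
      tibble(id = basename(p), n_residues = NA_integer_,
             lcr_perc = NA_real_, lcr_length = NA_integer_,
             nterm_all_lcr = NA, passed = NA, browse_eligible = NA,
             failed_rules = list(character()),
             error = conditionMessage(e))
    })
    select(res, "id", dplyr::everything())
  })
  report <- bind_rows(rows)
  if (!is.null(output)) {
    out <- mutate(report, failed_rules = purrr::map_chr(
      .data$failed_rules, paste, collapse = ","))
    readr::write_tsv(out, output, na = "NA")
  }
  report
}
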