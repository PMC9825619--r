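#' Heatmap of an allosteric map
#'
#' Diverging heatmap of the modulation values: rows are perturbed positions,
#' columns responding residues, red/blue for positive/negative signalling
#' (destabilizing/stabilizing response).
#'
#' @param object An `allosteric_map`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot allosteric_map
#' @export
autoplot.allosteric_map <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = .data$res_index, y = .data$row_pos, fill = .data$value)) +
    geom_raster() +
    scale_fill_gradient2(low = "#2166AC", mid = "white", high = "#B2182B",
                         na.value = "grey80",
                         name = expression(Delta * h ~ "(kcal/mol)")) +
    labs(x = "responding residue",
         y = switch(object$row_kind,
                    probe = "probe segment start",
                    "mutated position")) +
    coord_cartesian(expand = FALSE) +
    theme_minimal()
}

#' Heatmap of an allosteric fingerprint
#'
#' As [autoplot.allosteric_map()], with proximal/weak entries over-painted in
#' the blue-green masking colour so only long-range, strong communication
#' remains visible.
#'
#' @param object An `allosteric_fingerprint`.
#' @param mask_colour Colour of masked cells.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot allosteric_fingerprint
#' @export
autoplot.allosteric_fingerprint <- function(object, mask_colour = "#1F9E89",
                                            ...) {
  df <- tidy(object)
  p <- autoplot(object$map)
  p + geom_raster(data = filter(df, .data$masked), fill = mask_colour)
}

#' Per-residue profile plot
#'
#' Line plot of a free-energy (`dg`/`dh`), modulation-range or pLDDT profile
#' against residue index.
#'
#' @param profile A `fe_profile`, `modulation_range` or `plddt_profile`
#'   tibble.
#' @return A ggplot object.
#' @export
plot_profile <- function(profile) {
  if (inherits(profile, "plddt_profile") || "plddt" %in% names(profile)) {
    return(
      ggplot(profile, aes(x = .data$res_index, y = .data$plddt)) +
        geom_hline(yintercept = 70, linetype = "dashed", colour = "grey40") +
        geom_line() +
        labs(x = "residue", y = "pLDDT") +
        theme_minimal()
    )
  }
  ycol <- if ("dh_range" %in% names(profile)) "dh_range" else "dh"
  ggplot(profile, aes(x = .data$res_index, y = .data[[ycol]])) +
    geom_hline(yintercept = 0, colour = "grey60") +
    geom_line() +
    labs(x = "residue",
         y = if (ycol == "dh_range") "modulation range (kcal/mol)"
             else "allosteric modulation (kcal/mol)") +
    theme_minimal()
}
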