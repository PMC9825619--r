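#' Model configuration
#'
#' Bundles every tunable of the elastic-network / free-energy engine in one
#' validated list, recorded verbatim in the provenance of every map.
#'
#' @param cutoff Contact cutoff in Angstrom for the C-alpha elastic network.
#' @param k0 Uniform spring constant of native contacts (model units).
#' @param alpha_up Spring-scaling factor applied to all contacts of an
#'   UP-mutated residue (stiffening; models substitution by a bulky side chain).
#' @param alpha_bind Spring-scaling factor for probe binding; also the spring
#'   constant multiplier for contacts the probe adds within its segment.
#' @param kBT Thermal energy in kcal/mol. The default 0.593 corresponds to
#'   T of about 298 K; it only ever sets the output scale of the free energies.
#' @param rigid_tol Relative eigenvalue tolerance below which a normal mode is
#'   treated as a rigid-body motion and dropped (fraction of the largest
#'   eigenvalue).
#' @param neighbors Which residues j enter the local stiffness sum for residue
#'   i: `"contacts"` (edge-incident neighbours in the network, the default) or
#'   `"all"` (every other residue; cutoff-independent alternative reading).
#' @param eps_floor Smallest admissible per-mode stiffness before the log
#'   ratio; entries below it are floored (and counted) to avoid -Inf.
#' @param mode_weighting If `TRUE`, eigenvectors are scaled by 1/sqrt(lambda)
#'   before the stiffness sum. Off by default: the free-energy formula uses
#'   eigenvectors only.
#'
#' @return A named list with class `"allokit_config"`.
#' @examples
#' cfg <- allokit_config(cutoff = 8)
#' cfg$cutoff
#' @export
allokit_config <- function(cutoff = 10.0,
                           k0 = 1.0,
                           alpha_up = 2.0,
                           alpha_bind = 2.0,
                           kBT = 0.593,
                           rigid_tol = 1e-8,
                           neighbors = c("contacts", "all"),
                           eps_floor = 1e-12,
                           mode_weighting = FALSE) {
  neighbors <- match.arg(neighbors)
  stopifnot(
    is.numeric(cutoff), length(cutoff) == 1L, cutoff > 0,
    is.numeric(k0), k0 > 0,
    is.numeric(alpha_up), alpha_up > 0,
    is.numeric(alpha_bind), alpha_bind > 0,
    is.numeric(kBT), kBT > 0,
    is.numeric(rigid_tol), rigid_tol > 0,
    is.numeric(eps_floor), eps_floor > 0,
    is.logical(mode_weighting)
  )
  structure(
    list(
      cutoff = cutoff, k0 = k0, alpha_up = alpha_up, alpha_bind = alpha_bind,
      kBT = kBT, rigid_tol = rigid_tol, neighbors = neighbors,
      eps_floor = eps_floor, mode_weighting = mode_weighting
    ),
    class = "allokit_config"
  )
}

#' @export
print.allokit_config <- function(x, ...) {
  cat("<allokit_config>\n")
  for (nm in names(x)) cat(sprintf("  %-14s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

as_allokit_config <- function(config) {
  if (inherits(config, "allokit_config")) return(config)
  if (is.list(config)) return(do.call(allokit_config, config))
  abort("`config` must be an allokit_config or a named list of its fields.",
        class = "allokit_config_error")
}
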