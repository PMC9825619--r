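#' Declare a perturbation
#'
#' A perturbation is applied to the native elastic network before the
#' free-energy comparison. Three kinds are supported:
#' \describe{
#'   \item{up}{generic substitution by a bulky residue at one position:
#'     all contacts of that residue are stiffened by `alpha_up`.}
#'   \item{down}{generic substitution by the smallest (Gly-like) residue:
#'     all contacts of that residue are removed, except the sequential
#'     backbone contacts to its chain neighbours (Gly still has a backbone).}
#'   \item{probe}{binding of a small probe to a three-residue segment:
#'     contacts of the three residues are stiffened by `alpha_bind`, and the
#'     three pairwise contacts within the segment are added (at
#'     `k0 * alpha_bind`) if absent.}
#' }
#'
#' @param kind `"up"`, `"down"` or `"probe"`.
#' @param positions 1-based residue index (length 1 for up/down) or the
#'   segment start (the probe covers `start`, `start + 1`, `start + 2`).
#' @param alpha_up,alpha_bind Scaling factors; defaults from [allokit_config()].
#' @return A `perturbation` object.
#' @examples
#' perturbation("up", 5)
#' perturbation("probe", 1)
#' @export
perturbation <- function(kind = c("up", "down", "probe"), positions,
                         alpha_up = 2.0, alpha_bind = 2.0) {
  kind <- match.arg(kind)
  positions <- as.integer(positions)
  if (kind %in% c("up", "down")) {
    stopifnot(length(positions) == 1L)
  } else {
    if (length(positions) == 1L) positions <- positions + 0:2
    if (length(positions) != 3L || !all(diff(positions) == 1L)) {
      abort("probe positions must be three consecutive residues",
            class = "allokit_validation_error")
    }
  }
  if (any(positions < 1L)) {
    abort("positions are 1-based residue indices",
          class = "allokit_validation_error")
  }
  structure(list(kind = kind, positions = positions,
                 alpha_up = alpha_up, alpha_bind = alpha_bind),
            class = "perturbation")
}

#' @export
print.perturbation <- function(x, ...) {
  cat(sprintf("<perturbation> %s at %s\n", x$kind,
              paste(x$positions, collapse = ",")))
  invisible(x)
}

#' Apply a perturbation to an elastic network
#'
#' Returns a new network; the native network is never modified. Contacts a
#' probe introduces beyond the build cutoff are flagged `added`. A down
#' mutation that would disconnect the contact graph raises an error naming
#' the isolated residues.
#'
#' @param network Native `elastic_network`.
#' @param pert A [perturbation()].
#' @return A perturbed `elastic_network`.
#' @export
apply_perturbation <- function(network, pert) {
  validate_network(network)
  stopifnot(inherits(pert, "perturbation"))
  n <- network$n
  pos <- pert$positions
  if (any(pos > n) || (pert$kind == "probe" && max(pos) > n)) {
    abort(sprintf("perturbation positions out of range 1..%d", n),
          class = "allokit_validation_error")
  }
  edges <- network$edges
  out <- network
  if (pert$kind == "up") {
    hit <- edges$i == pos | edges$j == pos
    edges$k[hit] <- edges$k[hit] * pert$alpha_up
  } else if (pert$kind == "down") {
    incident <- edges$i == pos | edges$j == pos
    sequential <- (edges$i == pos - 1L & edges$j == pos) |
      (edges$i == pos & edges$j == pos + 1L)
    drop <- incident & !sequential
    edges <- edges[!drop, , drop = FALSE]
    out$edges <- edges
    if (!network_connected(out)) {
      memb <- network_components(out)
      main <- as.integer(names(which.max(table(memb))))
      isolated <- which(memb != main)
      abort(sprintf("down mutation at %d disconnects residue(s) %s", pos,
                    paste(head(isolated, 8), collapse = ", ")),
            class = "allokit_disconnected_error")
    }
  } else {
    hit <- edges$i %in% pos | edges$j %in% pos
    edges$k[hit] <- edges$k[hit] * pert$alpha_bind
    triple <- utils::combn(sort(pos), 2L)
    for (c_ in seq_len(ncol(triple))) {
      a <- triple[1, c_]; b <- triple[2, c_]
      if (!any(edges$i == a & edges$j == b)) {
        edges <- bind_rows(edges, tibble(
          i = a, j = b, k = network$k0 * pert$alpha_bind, added = TRUE))
      }
    }
    edges <- arrange(edges, .data$i, .data$j)
  }
  out$edges <- edges
  out
}

#' Per-residue free-energy response between two networks
#'
#' Computes \eqn{\Delta g_i = \tfrac{1}{2} k_B T \sum_\mu
#' \ln(\varepsilon^{(P)}_{\mu,i} / \varepsilon^{(0)}_{\mu,i})}: the change in
#' the per-residue configurational free energy between the native (0) and
#' perturbed (P) ensembles, which depends only on the local stiffnesses
#' because the Gaussian-integral prefactors cancel in the ratio. The
#' allosteric modulation `dh` subtracts the chain mean, removing background
#' signalling. Retained modes of the two states are paired by ascending
#' eigenvalue rank and must be equal in number.
#'
#' @param native,perturbed `elastic_network` objects with identical residues.
#' @param eps0 Optional precomputed native `local_stiffness` (saves one
#'   eigendecomposition in scans).
#' @param config An [allokit_config()].
#' @return A `fe_profile` tibble with columns `res_index`, `residue`, `dg`,
#'   `dh` (kcal/mol); attributes record the configuration.
#' @export
free_energy_from_networks <- function(native, perturbed, eps0 = NULL,
                                      config = allokit_config()) {
  config <- as_allokit_config(config)
  validate_network(native)
  validate_network(perturbed)
  if (native$n != perturbed$n) {
    abort("native and perturbed networks differ in size",
          class = "allokit_validation_error")
  }
  n <- native$n
  if (networks_equal(native, perturbed)) {
    dg <- numeric(n)                     # exact zero, no eigen needed
  } else {
    if (!network_connected(perturbed)) {
      abort("perturbed network is disconnected",
            class = "allokit_disconnected_error")
    }
    if (is.null(eps0)) eps0 <- network_stiffness(native, config)
    epsP <- network_stiffness(perturbed, config)
    e0 <- eps0$eps
    eP <- epsP$eps
    # A down mutation can leave a residue held by too few springs to resist
    # every direction, adding exact-zero modes that the rigid cut removes.
    # Pair the states from the stiff end: the excess softest modes of the
    # larger set are excluded so mode mu always meets its rank partner.
    if (nrow(e0) != nrow(eP)) {
      excess <- abs(nrow(e0) - nrow(eP))
      if (excess > 6L) {
        abort(sprintf(
          "retained mode counts differ by %d (%d native, %d perturbed): networks are structurally incompatible",
          excess, nrow(e0), nrow(eP)),
          class = "allokit_mode_mismatch_error")
      }
      inform(sprintf(
        "retained mode counts differ (%d native, %d perturbed); %d softest mode(s) of the larger state excluded from pairing",
        nrow(e0), nrow(eP), excess))
      if (nrow(e0) > nrow(eP)) {
        e0 <- e0[-seq_len(excess), , drop = FALSE]
      } else {
        eP <- eP[-seq_len(excess), , drop = FALSE]
      }
    }
    e0 <- floor_eps(e0, config$eps_floor)
    eP <- floor_eps(eP, config$eps_floor)
    dg <- unname(0.5 * config$kBT * colSums(log(eP / e0)))
  }
  dh <- dg - mean(dg)
  out <- tibble(
    res_index = seq_len(n),
    residue = native$residue_ids %||% as.character(seq_len(n)),
    dg = dg, dh = dh
  )
  attr(out, "config") <- config
  class(out) <- c("fe_profile", class(tibble()))
  out
}

floor_eps <- function(eps, floor_val) {
  n_floored <- sum(eps < floor_val)
  if (n_floored > 0L) {
    inform(sprintf("%d stiffness entr%s floored to %g before the log ratio",
                   n_floored, if (n_floored == 1L) "y" else "ies", floor_val))
    eps[eps < floor_val] <- floor_val
  }
  eps
}

# Native or perturbed network -> local stiffness (with modes), quietly
# suppressing the degenerate-pair message which is informational only.
network_stiffness <- function(network, config) {
  H <- build_hessian(network)
  modes <- withCallingHandlers(
    compute_modes(H, rigid_tol = config$rigid_tol, network = network),
    message = function(m) invokeRestart("muffleMessage")
  )
  local_stiffness(modes, network, neighbors = config$neighbors,
                  mode_weighting = config$mode_weighting)
}

#' Free-energy profile of a declared perturbation
#'
#' Applies `pert` to `network` and evaluates [free_energy_from_networks()].
#' An identity perturbation (e.g. up with `alpha_up = 1`) short-circuits to an
#' exactly zero profile.
#'
#' @inheritParams free_energy_from_networks
#' @param network Native `elastic_network`.
#' @param pert A [perturbation()].
#' @return A `fe_profile` tibble (see [free_energy_from_networks()]); the
#'   `perturbation` attribute records the applied perturbation.
#' @examples
#' net <- build_network(make_helix(20))
#' prof <- free_energy_profile(net, perturbation("up", 10))
#' mean(prof$dh)
#' @export
free_energy_profile <- function(network, pert, eps0 = NULL,
                                config = allokit_config()) {
  perturbed <- apply_perturbation(network, pert)
  out <- free_energy_from_networks(network, perturbed, eps0 = eps0,
                                   config = config)
  attr(out, "perturbation") <- pert
  out
}

#' Allosteric modulation range of a position
#'
#' The modulation range \eqn{\Delta h^{(m\downarrow\uparrow)}_i =
#' \Delta h^{(m\uparrow)}_i - \Delta h^{(m\downarrow)}_i} measures the
#' maximal signalling strength from position m to every residue i, i.e. the
#' dynamic range attainable by mutating m between the smallest and bulkiest
#' residue. The opposite substitution direction is its exact negative and is
#' returned by `direction = "up_down"`.
#'
#' @inheritParams free_energy_profile
#' @param position 1-based residue index m to mutate.
#' @param direction `"down_up"` (default) or `"up_down"` (the exact negative).
#' @return A `modulation_range` tibble with columns `res_index`, `residue`,
#'   `dh_range` (kcal/mol); attributes `position` and `direction`.
#' @export
modulation_range <- function(network, position, eps0 = NULL,
                             config = allokit_config(),
                             direction = c("down_up", "up_down")) {
  direction <- match.arg(direction)
  config <- as_allokit_config(config)
  if (is.null(eps0)) eps0 <- network_stiffness(network, config)
  up <- free_energy_profile(
    network, perturbation("up", position, alpha_up = config$alpha_up),
    eps0 = eps0, config = config)
  down <- free_energy_profile(
    network, perturbation("down", position),
    eps0 = eps0, config = config)
  dh_range <- up$dh - down$dh
  if (direction == "up_down") dh_range <- -dh_range
  out <- tibble(res_index = up$res_index, residue = up$residue,
                dh_range = dh_range)
  attr(out, "position") <- as.integer(position)
  attr(out, "direction") <- direction
  attr(out, "config") <- config
  class(out) <- c("modulation_range", class(tibble()))
  out
}

#' Mutation response profile of a structure
#'
#' Structure-first convenience wrapper: builds the elastic network at the
#' configured cutoff and returns the per-residue allosteric response to an
#' up mutation, a down mutation, or the full modulation range at `position`.
#'
#' @param structure A `calpha_structure`.
#' @param position 1-based residue index to mutate.
#' @param direction `"range"` (default), `"up"` or `"down"`.
#' @param config An [allokit_config()].
#' @return A tibble: `fe_profile` for `"up"`/`"down"`, `modulation_range`
#'   for `"range"`.
#' @examples
#' mutation_profile(make_helix(20), 10)
#' @export
mutation_profile <- function(structure, position,
                             direction = c("range", "up", "down"),
                             config = allokit_config()) {
  direction <- match.arg(direction)
  config <- as_allokit_config(config)
  network <- build_network(structure, cutoff = config$cutoff, k0 = config$k0)
  if (direction == "range") {
    modulation_range(network, position, config = config)
  } else {
    pert <- if (direction == "up") {
      perturbation("up", position, alpha_up = config$alpha_up)
    } else {
      perturbation("down", position)
    }
    free_energy_profile(network, pert, config = config)
  }
}

#' Probe-binding response profile of a structure
#'
#' Simulates binding of a small probe to the three-residue segment starting
#' at `start` and returns the per-residue allosteric modulation.
#'
#' @param structure A `calpha_structure`.
#' @param start 1-based segment start; the probe covers start..start+2.
#' @param config An [allokit_config()].
#' @return A `fe_profile` tibble.
#' @export
probe_profile <- function(structure, start, config = allokit_config()) {
  config <- as_allokit_config(config)
  network <- build_network(structure, cutoff = config$cutoff, k0 = config$k0)
  free_energy_profile(
    network, perturbation("probe", start, alpha_bind = config$alpha_bind),
    config = config)
}
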