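#' Synthetic alpha-helical C-alpha trace
#'
#' Places residue t (0-based) at
#' (radius cos(t.twist), radius sin(t.twist), t.rise) using canonical
#' alpha-helix C-alpha geometry: 1.5 Angstrom rise and 100 degrees twist per
#' residue on a 2.3 Angstrom radius, giving the familiar ~3.6 residues per
#' turn and a constant consecutive C-alpha distance.
#'
#' @param n Number of residues (>= 2).
#' @param rise Rise per residue, Angstrom.
#' @param twist Twist per residue, degrees.
#' @param radius Helix radius, Angstrom.
#' @param chain Chain identifier.
#' @param plddt B-factor/pLDDT value(s): scalar or length-n vector.
#' @return A `calpha_structure` tibble.
#' @examples
#' make_helix(10)
#' @export
make_helix <- function(n, rise = 1.5, twist = 100, radius = 2.3,
                       chain = "A", plddt = 90) {
  if (n < 2L) {
    abort("a helix needs at least 2 residues", class = "allokit_validation_error")
  }
  t <- seq_len(n) - 1L
  ang <- t * twist * pi / 180
  new_calpha_structure(
    tibble(
      chain_id = chain,
      res_seq = seq_len(n),
      res_name = "ALA",
      x = radius * cos(ang),
      y = radius * sin(ang),
      z = t * rise,
      bfactor = rep_len(plddt, n)
    ),
    source_path = "synthetic:helix"
  )
}

compact_cluster <- function(n, spacing = 3.8) {
  # seeded random walk folded into a compact ball: dense enough that the
  # default 10 A cutoff connects it, sparse enough to avoid coincident beads
  radius <- max(4, spacing * 0.6 * n^(1 / 3) * 1.6)
  pts <- matrix(NA_real_, n, 3L)
  pts[1L, ] <- c(0, 0, 0)
  for (i in seq_len(n)[-1L]) {
    attempts <- 0L
    repeat {
      attempts <- attempts + 1L
      dir <- rnorm(3L)
      cand <- pts[i - 1L, ] + spacing * dir / sqrt(sum(dir^2))
      ok <- sqrt(sum(cand^2)) <= radius &&
        (i <= 2L || min(sqrt(rowSums(sweep(pts[seq_len(i - 2L), , drop = FALSE],
                                           2L, cand)^2))) >= 2.5)
      if (ok || attempts > 500L) {  # cap guarantees termination
        pts[i, ] <- cand
        break
      }
    }
  }
  pts
}

#' Synthetic two-domain structure with an extended linker
#'
#' A testbed for long-range signalling: two compact seeded random-coil
#' domains joined by an extended linker along x, guaranteed to give a
#' connected elastic network at the default 10 Angstrom cutoff (regenerated
#' internally up to a retry cap otherwise).
#'
#' @param n1,n2 Domain sizes (each >= 5).
#' @param linker_len Number of linker residues.
#' @param separation Distance between domain centres, Angstrom; default
#'   spreads the linker at 3.8 Angstrom per step.
#' @param seed Integer seed; same seed, same structure.
#' @param plddt B-factor/pLDDT value(s).
#' @return A `calpha_structure` tibble.
#' @examples
#' make_two_domain(10, 10, 4, seed = 7)
#' @export
make_two_domain <- function(n1, n2, linker_len = 4L,
                            separation = 3.8 * (linker_len + 1),
                            seed = 1L, plddt = 90) {
  if (n1 < 5L || n2 < 5L) {
    abort("each domain needs at least 5 residues",
          class = "allokit_validation_error")
  }
  build_once <- function(s) {
    withr::with_seed(s, {
      d1 <- compact_cluster(n1)
      d2 <- compact_cluster(n2)
    })
    d1 <- sweep(d1, 2L, colMeans(d1))
    d2 <- sweep(d2, 2L, colMeans(d2))
    d2[, 1] <- d2[, 1] + separation
    lx <- seq(0, separation, length.out = linker_len + 2L)
    linker <- cbind(lx[-c(1L, linker_len + 2L)], 0, 0)
    rbind(d1, linker, d2)
  }
  n <- n1 + linker_len + n2
  for (try in 0:19) {
    pts <- build_once(seed + try * 10007L)
    st <- new_calpha_structure(
      tibble(chain_id = "A", res_seq = seq_len(n), res_name = "ALA",
             x = pts[, 1], y = pts[, 2], z = pts[, 3],
             bfactor = rep_len(plddt, n)),
      source_path = "synthetic:two_domain"
    )
    net <- tryCatch(build_network(st), error = function(e) NULL)
    if (!is.null(net) && network_connected(net)) return(st)
  }
  abort("could not generate a connected two-domain structure; widen the cutoff or shorten the linker",
        class = "allokit_geometry_error")
}

#' Synthetic random-coil C-alpha trace
#'
#' Seeded self-avoiding-ish random walk with 3.8 Angstrom steps folded into a
#' compact ball; generic (non-symmetric) geometry useful for oracle tests.
#'
#' @param n Number of residues (>= 2).
#' @param seed Integer seed.
#' @param plddt B-factor/pLDDT value(s).
#' @return A `calpha_structure` tibble.
#' @export
make_random_coil <- function(n, seed = 1L, plddt = 90) {
  if (n < 2L) {
    abort("need at least 2 residues", class = "allokit_validation_error")
  }
  pts <- withr::with_seed(seed, compact_cluster(n))
  new_calpha_structure(
    tibble(chain_id = "A", res_seq = seq_len(n), res_name = "ALA",
           x = pts[, 1], y = pts[, 2], z = pts[, 3],
           bfactor = rep_len(plddt, n)),
    source_path = "synthetic:random_coil"
  )
}

#' Synthetic pLDDT profile
#'
#' Constant background score with rectangular overridden segments; later
#' segments win on overlap. Drives exhaustive truth tables for the quality
#' filter without any real model files.
#'
#' @param n Profile length.
#' @param segments List of `c(start, length, score)` triplets (1-based start).
#' @param background Background score.
#' @return A `plddt_profile` tibble with `res_index` and `plddt` columns.
#' @examples
#' make_plddt_profile(100, list(c(1, 20, 50)), background = 90)
#' @export
make_plddt_profile <- function(n, segments = list(), background = 90) {
  stopifnot(n >= 1L)
  check_score <- function(s) {
    if (!is.finite(s) || s < 0 || s > 100) {
      abort(sprintf("pLDDT score %s outside [0, 100]", format(s)),
            class = "allokit_validation_error")
    }
  }
  check_score(background)
  scores <- rep(as.numeric(background), n)
  for (seg in segments) {
    if (length(seg) != 3L) {
      abort("each segment must be c(start, length, score)",
            class = "allokit_validation_error")
    }
    start <- as.integer(seg[1]); len <- as.integer(seg[2]); sc <- seg[3]
    check_score(sc)
    if (start < 1L || len < 1L || start + len - 1L > n) {
      abort(sprintf("segment (%d, %d) out of bounds for n = %d", start, len, n),
            class = "allokit_validation_error")
    }
    scores[start:(start + len - 1L)] <- sc
  }
  out <- tibble(res_index = seq_len(n), plddt = scores)
  attr(out, "source") <- "synthetic:plddt"
  class(out) <- c("plddt_profile", class(tibble()))
  out
}
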