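#' Build a C-alpha elastic network
#'
#' Connects every pair of C-alpha atoms closer than `cutoff` Angstrom with a
#' harmonic spring of constant `k0`. This is the coarse-grained harmonic model
#' all downstream free-energy calculations operate on.
#'
#' @param structure A `calpha_structure` tibble.
#' @param cutoff Contact cutoff, Angstrom.
#' @param k0 Uniform spring constant (model units).
#' @return An `elastic_network` object: coordinates, an edge table
#'   (`i`, `j` 1-based residue indices with `i < j`, spring constant `k`,
#'   and an `added` flag for contacts introduced by a perturbation),
#'   the cutoff and residue labels.
#' @examples
#' net <- build_network(make_helix(10))
#' nrow(net$edges)
#' @export
build_network <- function(structure, cutoff = 10.0, k0 = 1.0) {
  validate_calpha_structure(structure)
  stopifnot(cutoff > 0, k0 > 0)
  coords <- structure_coords(structure)
  n <- nrow(coords)
  if (n < 2L) {
    abort("need at least 2 residues to build an elastic network",
          class = "allokit_validation_error")
  }
  d <- as.matrix(dist(coords))
  coincident <- which(d == 0 & upper.tri(d), arr.ind = TRUE)
  if (nrow(coincident) > 0L) {
    abort(sprintf("coincident C-alpha coordinates for residues %d and %d",
                  coincident[1, 1], coincident[1, 2]),
          class = "allokit_geometry_error")
  }
  idx <- which(d > 0 & d <= cutoff & upper.tri(d), arr.ind = TRUE)
  edges <- tibble(
    i = as.integer(idx[, 1]), j = as.integer(idx[, 2]),
    k = rep(k0, nrow(idx)), added = rep(FALSE, nrow(idx))
  )
  edges <- arrange(edges, .data$i, .data$j)
  structure(
    list(coords = coords, edges = edges, cutoff = cutoff, k0 = k0,
         n = n, residue_ids = rownames(coords)),
    class = "elastic_network"
  )
}

#' @export
print.elastic_network <- function(x, ...) {
  cat(sprintf("<elastic_network> %d residues, %d contacts (cutoff %.1f A)\n",
              x$n, nrow(x$edges), x$cutoff))
  invisible(x)
}

validate_network <- function(network) {
  e <- network$edges
  stopifnot(inherits(network, "elastic_network"),
            all(e$i < e$j), all(e$k > 0),
            all(e$i >= 1L), all(e$j <= network$n))
  invisible(network)
}

network_connected <- function(network) {
  g <- igraph::graph_from_edgelist(as.matrix(network$edges[, c("i", "j")]),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, network$n - igraph::vcount(g)))
  igraph::is_connected(g)
}

network_components <- function(network) {
  g <- igraph::graph_from_edgelist(as.matrix(network$edges[, c("i", "j")]),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, network$n - igraph::vcount(g)))
  igraph::components(g)$membership
}

networks_equal <- function(a, b) {
  identical(dim(a$coords), dim(b$coords)) &&
    isTRUE(all.equal(a$coords, b$coords, tolerance = 0)) &&
    nrow(a$edges) == nrow(b$edges) &&
    all(a$edges$i == b$edges$i) && all(a$edges$j == b$edges$j) &&
    all(a$edges$k == b$edges$k)
}

#' Assemble the anisotropic Hessian of an elastic network
#'
#' For each contact (i, j) the off-diagonal 3x3 block is
#' \eqn{-(k_{ij}/d_{ij}^2)\, r_{ij} r_{ij}^T} with \eqn{r_{ij}} the bond
#' vector; diagonal blocks make every block row sum to zero, so the matrix is
#' symmetric positive semidefinite and translation-invariant by construction.
#'
#' @param network An `elastic_network`.
#' @return A 3N x 3N symmetric numeric matrix.
#' @export
build_hessian <- function(network) {
  validate_network(network)
  n <- network$n
  H <- matrix(0, 3L * n, 3L * n)
  co <- network$coords
  for (e in seq_len(nrow(network$edges))) {
    i <- network$edges$i[e]; j <- network$edges$j[e]
    k <- network$edges$k[e]
    r <- co[j, ] - co[i, ]
    d2 <- sum(r * r)
    blk <- (k / d2) * tcrossprod(r)
    ii <- (3L * (i - 1L) + 1L):(3L * i)
    jj <- (3L * (j - 1L) + 1L):(3L * j)
    H[ii, jj] <- H[ii, jj] - blk
    H[jj, ii] <- H[jj, ii] - blk
    H[ii, ii] <- H[ii, ii] + blk
    H[jj, jj] <- H[jj, jj] + blk
  }
  H
}

#' Normal modes of an elastic network Hessian
#'
#' Full symmetric eigendecomposition with eigenvalues in ascending order.
#' Modes with eigenvalue below `rigid_tol` times the largest eigenvalue are
#' rigid-body motions and are dropped; a connected, non-collinear network has
#' exactly six. If more are found and the underlying contact graph is
#' disconnected, an error names the components; a connected but geometrically
#' degenerate network (e.g. collinear beads, or an under-constrained residue
#' after a down mutation) only emits a message.
#'
#' @param hessian 3N x 3N symmetric matrix from [build_hessian()].
#' @param rigid_tol Relative tolerance for the rigid-mode cut.
#' @param network Optional `elastic_network`, used to diagnose disconnection.
#' @return A `normal_modes` object: ascending retained `values`, orthonormal
#'   `vectors` (3N x M), `n_rigid_dropped`, and the full pre-drop spectrum.
#' @export
compute_modes <- function(hessian, rigid_tol = 1e-8, network = NULL) {
  stopifnot(is.matrix(hessian), nrow(hessian) == ncol(hessian),
            nrow(hessian) %% 3L == 0L)
  if (max(abs(hessian - t(hessian))) > 1e-10 * max(1, max(abs(hessian)))) {
    abort("hessian is not symmetric", class = "allokit_validation_error")
  }
  es <- eigen((hessian + t(hessian)) / 2, symmetric = TRUE)
  values <- rev(es$values)
  vectors <- es$vectors[, rev(seq_along(es$values)), drop = FALSE]
  tol_abs <- rigid_tol * max(abs(values), .Machine$double.eps)
  rigid <- values < tol_abs
  n_rigid <- sum(rigid)
  if (n_rigid > 6L) {
    if (!is.null(network) && !network_connected(network)) {
      memb <- network_components(network)
      parts <- split(seq_along(memb), memb)
      abort(sprintf(
        "network is disconnected into %d components (sizes %s): %s",
        length(parts), paste(lengths(parts), collapse = ", "),
        paste(vapply(parts, function(p)
          paste0("{", paste(head(p, 4), collapse = ","),
                 if (length(p) > 4) ",..." else "", "}"), ""),
          collapse = " ")),
        class = "allokit_disconnected_error")
    }
    inform(sprintf(
      "%d near-zero modes on a connected network (expected 6): degenerate or under-constrained geometry",
      n_rigid))
  } else if (n_rigid < 6L) {
    warn(sprintf("only %d near-zero modes found (expected 6): possible numerical issue",
                 n_rigid))
  }
  keep <- which(!rigid)
  lam <- values[keep]
  if (length(lam) > 1L) {
    gaps <- diff(lam) / pmax(abs(lam[-length(lam)]), .Machine$double.eps)
    if (any(gaps < 1e-6)) {
      inform(sprintf(
        "%d near-degenerate eigenvalue pair(s): per-mode stiffness is basis-dependent there",
        sum(gaps < 1e-6)))
    }
  }
  structure(
    list(values = lam, vectors = vectors[, keep, drop = FALSE],
         n_rigid_dropped = n_rigid, all_values = values,
         all_vectors = vectors, rigid_tol = rigid_tol),
    class = "normal_modes"
  )
}

#' @export
print.normal_modes <- function(x, ...) {
  cat(sprintf("<normal_modes> %d retained modes, %d rigid dropped\n",
              length(x$values), x$n_rigid_dropped))
  invisible(x)
}

#' Per-mode, per-residue local stiffness
#'
#' For each retained mode \eqn{\mu} and residue i computes the elastic-work
#' coefficient \eqn{\varepsilon_{\mu,i} = \sum_j |e_{\mu,i} - e_{\mu,j}|^2},
#' where \eqn{e_{\mu,i}} is the mode's 3-vector at residue i and j runs over
#' the residue's contact neighbours in the network (or over all residues with
#' `neighbors = "all"`). Rigid translations give identically zero stiffness.
#'
#' @param modes A `normal_modes` object.
#' @param network The `elastic_network` the modes were computed on.
#' @param neighbors `"contacts"` (default) or `"all"`.
#' @param mode_weighting Scale eigenvectors by 1/sqrt(eigenvalue) first
#'   (off by default; the free-energy formula is eigenvector-only).
#' @return A `local_stiffness` object with an M x N matrix `eps` (modes by
#'   residues) and the retained `mode_ids`.
#' @export
local_stiffness <- function(modes, network,
                            neighbors = c("contacts", "all"),
                            mode_weighting = FALSE) {
  neighbors <- match.arg(neighbors)
  stopifnot(inherits(modes, "normal_modes"))
  validate_network(network)
  if (nrow(modes$vectors) != 3L * network$n) {
    abort("modes and network disagree on the number of residues",
          class = "allokit_validation_error")
  }
  vec <- modes$vectors
  if (mode_weighting) {
    vec <- sweep(vec, 2L, sqrt(pmax(modes$values, .Machine$double.eps)), "/")
  }
  eps <- stiffness_from_vectors(vec, network, neighbors)
  structure(
    list(eps = eps, mode_ids = seq_along(modes$values), neighbors = neighbors),
    class = "local_stiffness"
  )
}

#' Stiffness matrix from arbitrary displacement vectors
#'
#' Workhorse behind [local_stiffness()], exposed so that candidate mode
#' vectors (e.g. pure translations, before the rigid-mode drop) can be
#' checked directly.
#'
#' @param vectors 3N x M matrix; column mu holds residue 3-vectors stacked.
#' @param network An `elastic_network` with N residues.
#' @param neighbors `"contacts"` or `"all"`.
#' @return M x N numeric matrix of stiffness values.
#' @export
stiffness_from_vectors <- function(vectors, network,
                                   neighbors = c("contacts", "all")) {
  neighbors <- match.arg(neighbors)
  n <- network$n
  m <- ncol(vectors)
  stopifnot(nrow(vectors) == 3L * n)
  # N x M component matrices
  vx <- vectors[seq(1L, 3L * n, by = 3L), , drop = FALSE]
  vy <- vectors[seq(2L, 3L * n, by = 3L), , drop = FALSE]
  vz <- vectors[seq(3L, 3L * n, by = 3L), , drop = FALSE]
  if (neighbors == "all") {
    # sum_j |e_i - e_j|^2 = N |e_i|^2 - 2 e_i . S + sum_j |e_j|^2  (closed form)
    sq <- vx^2 + vy^2 + vz^2              # N x M, |e_i|^2 per component sum
    tot <- colSums(sq)                    # M
    sx <- colSums(vx); sy <- colSums(vy); sz <- colSums(vz)
    dot <- sweep(vx, 2L, sx, "*") + sweep(vy, 2L, sy, "*") +
      sweep(vz, 2L, sz, "*")
    eps_nm <- n * sq - 2 * dot + matrix(tot, n, m, byrow = TRUE)
  } else {
    ei <- network$edges$i
    ej <- network$edges$j
    d2 <- (vx[ei, , drop = FALSE] - vx[ej, , drop = FALSE])^2 +
      (vy[ei, , drop = FALSE] - vy[ej, , drop = FALSE])^2 +
      (vz[ei, , drop = FALSE] - vz[ej, , drop = FALSE])^2
    agg <- rowsum(rbind(d2, d2), group = c(ei, ej))
    eps_nm <- matrix(0, n, m)
    eps_nm[as.integer(rownames(agg)), ] <- agg
  }
  eps <- t(eps_nm)
  eps[eps < 0] <- 0  # roundoff guard; entries are sums of squares
  dimnames(eps) <- list(NULL, network$residue_ids)
  eps
}
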