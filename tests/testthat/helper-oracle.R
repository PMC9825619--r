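# Independent brute-force implementation of the free-energy pipeline, written
# literally from the definitions (explicit loops, no shared code with the
# package internals). Used as the oracle for the vectorized implementation.

oracle_hessian <- function(coords, edges_i, edges_j, k) {
  n <- nrow(coords)
  H <- matrix(0, 3 * n, 3 * n)
  for (e in seq_along(edges_i)) {
    i <- edges_i[e]; j <- edges_j[e]
    r <- coords[j, ] - coords[i, ]
    d2 <- sum(r^2)
    blk <- (k[e] / d2) * outer(r, r)
    for (a in 1:3) for (b in 1:3) {
      H[3 * (i - 1) + a, 3 * (j - 1) + b] <- H[3 * (i - 1) + a, 3 * (j - 1) + b] - blk[a, b]
      H[3 * (j - 1) + a, 3 * (i - 1) + b] <- H[3 * (j - 1) + a, 3 * (i - 1) + b] - blk[a, b]
      H[3 * (i - 1) + a, 3 * (i - 1) + b] <- H[3 * (i - 1) + a, 3 * (i - 1) + b] + blk[a, b]
      H[3 * (j - 1) + a, 3 * (j - 1) + b] <- H[3 * (j - 1) + a, 3 * (j - 1) + b] + blk[a, b]
    }
  }
  H
}

# eigensystem, ascending, rigid modes (eigenvalue < tol * max) removed
oracle_modes <- function(H, rigid_tol = 1e-8) {
  es <- eigen(H, symmetric = TRUE)
  ord <- order(es$values)
  vals <- es$values[ord]
  vecs <- es$vectors[, ord, drop = FALSE]
  keep <- vals >= rigid_tol * max(abs(vals))
  list(values = vals[keep], vectors = vecs[, keep, drop = FALSE],
       n_dropped = sum(!keep))
}

# eps[mu, i] = sum over contact neighbours j of |e_mu,i - e_mu,j|^2,
# literal double loop
oracle_eps <- function(vectors, n, edges_i, edges_j, all_pairs = FALSE) {
  m <- ncol(vectors)
  eps <- matrix(0, m, n)
  neighbour_sets <- vector("list", n)
  if (all_pairs) {
    for (i in seq_len(n)) neighbour_sets[[i]] <- setdiff(seq_len(n), i)
  } else {
    for (e in seq_along(edges_i)) {
      neighbour_sets[[edges_i[e]]] <- c(neighbour_sets[[edges_i[e]]], edges_j[e])
      neighbour_sets[[edges_j[e]]] <- c(neighbour_sets[[edges_j[e]]], edges_i[e])
    }
  }
  for (mu in seq_len(m)) {
    for (i in seq_len(n)) {
      ei <- vectors[(3 * (i - 1) + 1):(3 * i), mu]
      s <- 0
      for (j in neighbour_sets[[i]]) {
        ej <- vectors[(3 * (j - 1) + 1):(3 * j), mu]
        s <- s + sum((ei - ej)^2)
      }
      eps[mu, i] <- s
    }
  }
  eps
}

# full chain: network edge list -> dg per residue, rank-paired modes
oracle_dg <- function(coords, e0_i, e0_j, k0, eP_i, eP_j, kP,
                      kBT = 0.593, rigid_tol = 1e-8, eps_floor = 1e-12) {
  n <- nrow(coords)
  m0 <- oracle_modes(oracle_hessian(coords, e0_i, e0_j, k0), rigid_tol)
  mP <- oracle_modes(oracle_hessian(coords, eP_i, eP_j, kP), rigid_tol)
  eps0 <- oracle_eps(m0$vectors, n, e0_i, e0_j)
  epsP <- oracle_eps(mP$vectors, n, eP_i, eP_j)
  n0 <- nrow(eps0); nP <- nrow(epsP)
  if (n0 > nP) eps0 <- eps0[(n0 - nP + 1):n0, , drop = FALSE]
  if (nP > n0) epsP <- epsP[(nP - n0 + 1):nP, , drop = FALSE]
  eps0[eps0 < eps_floor] <- eps_floor
  epsP[epsP < eps_floor] <- eps_floor
  dg <- numeric(n)
  for (i in seq_len(n)) {
    dg[i] <- 0.5 * kBT * sum(log(epsP[, i] / eps0[, i]))
  }
  dg
}

# random connected non-collinear toy: n points, all pairs connected
random_toy_coords <- function(n, seed) {
  withr::with_seed(seed, matrix(runif(3 * n, 0, 8), n, 3))
}

full_edges <- function(n) {
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  list(i = idx[, 1], j = idx[, 2])
}

random_rotation <- function(seed) {
  withr::with_seed(seed, {
    q <- rnorm(4)
  })
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(
    a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
    2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
    2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2
  ), 3, 3, byrow = TRUE)
}

transform_structure <- function(structure, rotation, translation = c(0, 0, 0)) {
  xyz <- structure_coords(structure) %*% t(rotation)
  out <- structure
  out$x <- xyz[, 1] + translation[1]
  out$y <- xyz[, 2] + translation[2]
  out$z <- xyz[, 3] + translation[3]
  out
}
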