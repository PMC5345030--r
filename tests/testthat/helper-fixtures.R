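# Shared fixtures and independent oracles for the test suite.

# A small, non-degenerate chiral point set (no symmetry planes).
chiral_points <- function() {
  matrix(
    c(
      0, 0, 0,
      6, 0, 0,
      6, 6, 0,
      2, 6, 5,
      -1, 2, 7
    ),
    ncol = 3, byrow = TRUE
  )
}

random_rotation <- function() {
  # uniform random rotation from a normalised quaternion
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]
  x <- q[2]
  y <- q[3]
  z <- q[4]
  matrix(
    c(
      1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
      2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
      2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
    ),
    nrow = 3, byrow = TRUE
  )
}

# Independent superposition-RMSD oracle: random-restart numerical
# optimisation over Euler angles (never uses the package's Kabsch path).
rmsd_oracle <- function(A, B, n_starts = 40) {
  A <- sweep(A, 2, colMeans(A))
  B <- sweep(B, 2, colMeans(B))
  rot <- function(ang) {
    cx <- cos(ang[1])
    sx <- sin(ang[1])
    cy <- cos(ang[2])
    sy <- sin(ang[2])
    cz <- cos(ang[3])
    sz <- sin(ang[3])
    Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, 3, byrow = TRUE)
    Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, 3, byrow = TRUE)
    Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, 3, byrow = TRUE)
    Rz %*% Ry %*% Rx
  }
  obj <- function(ang) sqrt(mean(rowSums((A %*% t(rot(ang)) - B)^2)))
  best <- Inf
  for (s in seq_len(n_starts)) {
    start <- stats::runif(3, -pi, pi)
    fit <- stats::optim(start, obj, method = "Nelder-Mead",
      control = list(maxit = 2000, reltol = 1e-14)
    )
    fit <- stats::optim(fit$par, obj, method = "BFGS",
      control = list(maxit = 500, reltol = 1e-14)
    )
    best <- min(best, fit$value)
  }
  best
}

# Exhaustive maximum non-crossing subset size (for <= ~12 pairs).
max_nested_oracle <- function(pairs) {
  P <- nrow(pairs)
  if (P == 0) {
    return(0L)
  }
  best <- 0L
  for (mask in 0:(2^P - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(P) - 1)) > 0)
    if (length(sel) <= best) next
    ok <- TRUE
    if (length(sel) > 1) {
      for (a in seq_along(sel)) {
        for (b in seq_along(sel)) {
          if (a >= b) next
          i1 <- pairs$i[sel[a]]
          j1 <- pairs$j[sel[a]]
          i2 <- pairs$i[sel[b]]
          j2 <- pairs$j[sel[b]]
          if ((i1 < i2 && i2 < j1 && j1 < j2) ||
            (i2 < i1 && i1 < j2 && j2 < j1)) {
            ok <- FALSE
            break
          }
        }
        if (!ok) break
      }
    }
    if (ok) best <- length(sel)
  }
  best
}

# Random valid base-pair set (each residue in at most one pair).
random_pairs <- function(n_pairs, L = 30) {
  res <- sample.int(L, 2 * n_pairs)
  base_pairs(res[seq_len(n_pairs)], res[n_pairs + seq_len(n_pairs)])
}

# Short-run engine config for unit tests.
quick_config <- function(...) {
  args <- list(cycles = 200, replicates = 2, seed = 42)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}
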