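# Independent oracles and small fixture helpers shared across the suite.

# Rodrigues rotation matrix about a unit axis.
rotation_matrix <- function(axis, theta) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -u[3], u[2],
                u[3], 0, -u[1],
                -u[2], u[1], 0), 3, byrow = TRUE)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * K %*% K
}

random_rotation <- function() {
  ax <- stats::rnorm(3)
  rotation_matrix(ax, stats::runif(1, 0, pi))
}

# Quadratic-scan contact oracle.
brute_force_contacts <- function(a, b, cutoff) {
  hits <- list()
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      d <- sqrt((a$x[i] - b$x[j])^2 + (a$y[i] - b$y[j])^2 +
                  (a$z[i] - b$z[j])^2)
      if (d <= cutoff) hits[[length(hits) + 1]] <- c(i, j, d)
    }
  }
  if (length(hits) == 0) {
    return(data.frame(idx_a = integer(), idx_b = integer(),
                      distance = numeric()))
  }
  m <- do.call(rbind, hits)
  out <- data.frame(idx_a = m[, 1], idx_b = m[, 2], distance = m[, 3])
  out[order(out$distance), ]
}

# Two-sided exact p by hypergeometric enumeration (dhyper), independent of
# the log-factorial implementation under test.
enumerate_exact_p <- function(m) {
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ]); c1 <- sum(m[, 1]); n <- sum(m)
  if (r1 == 0 || r2 == 0 || c1 == 0 || sum(m[, 2]) == 0) return(1)
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, r1, r2, c1)
  obs <- stats::dhyper(m[1, 1], r1, r2, c1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Nearest-canonical-rotamer assignment (centres -60 / +60 / 180 with
# circular distance); agrees with the bin partition except exactly at edges.
nearest_canonical_rotamer <- function(chi) {
  centres <- c("gauche-" = -60, "gauche+" = 60, "trans" = 180)
  circ <- function(a, b) {
    d <- abs(a - b) %% 360
    pmin(d, 360 - d)
  }
  d <- matrix(vapply(centres, function(cn) circ(chi, cn),
                     numeric(length(chi))), ncol = length(centres))
  names(centres)[max.col(-d, ties.method = "first")]
}

random_cloud <- function(n = 20) matrix(stats::rnorm(3 * n, sd = 3), ncol = 3)
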