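# Independent brute-force oracles used to cross-check the package's
# implementations. These deliberately use naive loops / enumeration, not the
# code paths under test.

# Weighted antitonic (nonincreasing) least-squares fit by pool-adjacent
# violators; applied to the raw ECDF slopes this yields the Grenander
# (concave-majorant) density.
pava_grenander_oracle <- function(pvalues) {
  n <- length(pvalues)
  x <- unique(c(0, sort(unique(pvalues)), 1))
  cdf <- vapply(x, function(t) sum(pvalues <= t) / n, numeric(1))
  cdf[1] <- 0
  w <- diff(x)
  s <- diff(cdf) / w
  # pool adjacent violators for a nonincreasing fit
  val <- as.list(s); wt <- as.list(w)
  i <- 1L
  while (i < length(val)) {
    if (val[[i]] < val[[i + 1L]] - 1e-12) {
      merged_w <- wt[[i]] + wt[[i + 1L]]
      merged_v <- (val[[i]] * wt[[i]] + val[[i + 1L]] * wt[[i + 1L]]) / merged_w
      val[[i]] <- merged_v; wt[[i]] <- merged_w
      val[[i + 1L]] <- NULL; wt[[i + 1L]] <- NULL
      if (i > 1L) i <- i - 1L
    } else i <- i + 1L
  }
  # expand back to per-interval slopes
  out <- numeric(0)
  breaks <- numeric(0)
  pos <- 0
  for (k in seq_along(val)) {
    out <- c(out, val[[k]])
    pos <- pos + wt[[k]]
    breaks <- c(breaks, pos)
  }
  list(knots = c(0, breaks), density = out)
}

# evaluate an oracle fit's step density at points t (left-continuous)
pava_density_at <- function(fit, t) {
  idx <- findInterval(t, fit$knots, left.open = TRUE, all.inside = TRUE)
  fit$density[idx]
}

# Exhaustive topology oracle for small graphs (n <= 8): strength by explicit
# summation, Zhang-Horvath clustering by looping over ordered neighbour
# pairs, path strength by enumerating every simple path.
brute_force_indices <- function(W) {
  n <- nrow(W)
  strength <- numeric(n)
  for (i in seq_len(n)) for (j in seq_len(n)) strength[i] <- strength[i] + W[i, j]
  Wh <- W / max(W)
  clustering <- numeric(n)
  for (i in seq_len(n)) {
    num <- 0; den <- 0
    for (j in seq_len(n)) for (k in seq_len(n)) {
      if (j != k && j != i && k != i) {
        num <- num + Wh[i, j] * Wh[j, k] * Wh[k, i]
        den <- den + Wh[i, j] * Wh[i, k]
      }
    }
    clustering[i] <- if (den > 0) num / den else 0
  }
  dist_mat <- matrix(NA_real_, n, n)
  all_paths_dist <- function(i, j, visited, acc) {
    # returns minimal summed 1/w over simple paths i -> j
    best <- Inf
    for (k in seq_len(n)) {
      if (W[i, k] > 0 && !visited[k]) {
        d <- acc + 1 / W[i, k]
        if (k == j) best <- min(best, d)
        else {
          visited[k] <- TRUE
          best <- min(best, all_paths_dist(k, j, visited, d))
          visited[k] <- FALSE
        }
      }
    }
    best
  }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    visited <- rep(FALSE, n); visited[i] <- TRUE
    d <- all_paths_dist(i, j, visited, 0)
    dist_mat[i, j] <- dist_mat[j, i] <- if (is.finite(d)) d else NA_real_
  }
  L <- 1 / dist_mat
  conn <- upper.tri(L) & !is.na(L)
  list(strength = strength, clustering = clustering, path = L,
       density = sum(W[upper.tri(W)] > 0) / (n * (n - 1) / 2),
       global = c(strength = mean(strength), clustering = mean(clustering),
                  path_length = if (any(conn)) mean(L[conn]) else NA_real_))
}

# Exact two-sided Mann-Whitney p by enumerating all group assignments of the
# pooled sample (tie-free data only).
mw_exact_oracle <- function(a, b) {
  pooled <- c(a, b)
  n_a <- length(a)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  mu <- n_a * length(b) / 2
  combos <- utils::combn(length(pooled), n_a)
  us <- apply(combos, 2, function(idx)
    sum(rank(pooled)[idx]) - n_a * (n_a + 1) / 2)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# Partial Spearman oracle: regress the ranks of x and y on the covariate
# ranks, correlate the residuals.
spearman_partial_oracle <- function(x, y, z) {
  rx <- rank(x); ry <- rank(y); rz <- rank(z)
  ex <- stats::residuals(stats::lm(rx ~ rz))
  ey <- stats::residuals(stats::lm(ry ~ rz))
  stats::cor(ex, ey)
}

# random symmetric nonnegative weight matrix with given density
random_weight_matrix <- function(n, density = 0.6, max_w = 1) {
  W <- matrix(0, n, n)
  ut <- which(upper.tri(W))
  on <- stats::runif(length(ut)) < density
  W[ut[on]] <- stats::runif(sum(on), 0.05, max_w)
  W + t(W)
}
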