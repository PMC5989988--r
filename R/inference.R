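#' Mann-Whitney rank test
#'
#' Two-sided Mann-Whitney U via [stats::wilcox.test()]. The U statistic uses
#' rank sums with midranks for ties. The p-value is computed by exact
#' enumeration when the smaller sample has at most 8 observations and the
#' pooled data are tie-free (reproducible small-sample behaviour for a
#' 9-versus-40 design); otherwise the normal approximation with tie and
#' continuity corrections is used.
#'
#' @param a,b nonempty numeric samples.
#' @return List with `U` (statistic for sample `a`) and `p` (two-sided).
#' @export
mann_whitney <- function(a, b) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) == 0L || length(b) == 0L)
    stop("both samples must be nonempty")
  pooled <- c(a, b)
  if (length(unique(pooled)) == 1L)  # fully tied: no evidence either way
    return(list(U = length(a) * length(b) / 2, p = 1, exact = FALSE))
  ties <- anyDuplicated(pooled) > 0L
  use_exact <- min(length(a), length(b)) <= 8L && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = use_exact, correct = TRUE,
                       alternative = "two.sided"))
  p <- wt$p.value
  if (is.na(p)) p <- 1
  list(U = unname(wt$statistic), p = min(1, p), exact = use_exact)
}

#' Residualize node-level values on graph density
#'
#' Local indices carry a global-connectivity component: subjects with denser
#' graphs have systematically larger node values. Before group testing, each
#' node-level index is regressed (ordinary least squares, all subjects
#' pooled) on the subject's graph density, and the residual plus the grand
#' mean is analysed in place of the raw value. If density has no variance
#' the values are returned unchanged.
#'
#' @param values numeric vector, one value per subject.
#' @param densities numeric vector of the subjects' graph densities (same
#'   length).
#' @return Adjusted values (residual + grand mean).
#' @export
density_adjust <- function(values, densities) {
  if (length(values) != length(densities))
    stop("values and densities must have equal length")
  if (length(values) < 3L)
    stop("density adjustment needs at least 3 subjects")
  ok <- is.finite(values) & is.finite(densities)
  if (stats::var(densities[ok]) == 0) return(values)
  fit <- stats::lm(values[ok] ~ densities[ok])
  out <- rep(NA_real_, length(values))
  out[ok] <- unname(stats::residuals(fit)) + mean(values[ok])
  out
}

#' Grenander estimate of the p-value density
#'
#' The nonincreasing density estimate on `[0, 1]`: the left derivative of
#' the least concave majorant (LCM) of the empirical CDF of the p-values.
#' Computed as the upper convex hull of the ECDF knots (including the
#' anchors (0,0) and (1,1)), whose segment slopes are automatically
#' nonincreasing and integrate to 1.
#'
#' @param pvalues numeric vector in `[0, 1]`, n >= 1.
#' @return An object of class `grenander_fit`: list with `knots` (x of the
#'   LCM vertices, starting at 0 and ending at 1), `cdf` (LCM values at the
#'   knots) and `density` (slope on each inter-knot interval).
#' @export
grenander_density <- function(pvalues) {
  if (length(pvalues) == 0L) stop("need at least one p-value")
  if (any(!is.finite(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stop("p-values must lie in [0, 1]")
  n <- length(pvalues)
  p_sorted <- sort(unique(pvalues))
  x <- unique(c(0, p_sorted, 1))
  ecdf_vals <- vapply(x, function(t) sum(pvalues <= t) / n, numeric(1))
  ecdf_vals[1] <- 0  # the ECDF's LCM is anchored at (0, 0)
  hull <- upper_hull(x, ecdf_vals)
  slopes <- diff(hull$y) / diff(hull$x)
  structure(list(knots = hull$x, cdf = hull$y, density = slopes,
                 n = n),
            class = "grenander_fit")
}

# Upper convex hull of points sorted by x (Andrew's monotone chain, upper
# side): keeps the vertices of the least concave majorant.
#' @keywords internal
upper_hull <- function(x, y) {
  keep <- integer(0)
  for (i in seq_along(x)) {
    while (length(keep) >= 2L) {
      a <- keep[length(keep) - 1L]; b <- keep[length(keep)]
      # drop b if it lies below the chord a--i (non-concave corner)
      cross <- (x[b] - x[a]) * (y[i] - y[a]) - (y[b] - y[a]) * (x[i] - x[a])
      if (cross >= -1e-15) keep <- keep[-length(keep)] else break
    }
    keep <- c(keep, i)
  }
  list(x = x[keep], y = y[keep])
}

#' Evaluate the Grenander fit
#'
#' @param fit a `grenander_fit`.
#' @param t evaluation points in `[0, 1]`.
#' @return `grenander_cdf()`: the concave-majorant CDF at `t`;
#'   `grenander_pdf()`: the step density at `t` (left-continuous).
#' @export
grenander_cdf <- function(fit, t) {
  stats::approx(fit$knots, fit$cdf, xout = t, rule = 2)$y
}

#' @rdname grenander_cdf
#' @export
grenander_pdf <- function(fit, t) {
  idx <- findInterval(t, fit$knots, left.open = TRUE, all.inside = TRUE)
  fit$density[idx]
}

#' False-nondiscovery multiple-comparison adjustment
#'
#' Tail-area adjustment driven by the Grenander fit of the p-value
#' distribution:
#' 1. fit the nonincreasing density (least concave majorant of the ECDF);
#' 2. estimate the null proportion `eta0` as the fit's terminal (flat-tail)
#'    slope, clipped to `[0, 1]`;
#' 3. adjust each p-value `t` by the tail-area ratio
#'    `q(t) = min(1, eta0 * t / F(t))` with `F` the concave-majorant CDF;
#' 4. enforce monotonicity of the adjusted values in the raw p-values.
#'
#' The complementary false-nondiscovery quantity at each threshold is
#' `FNDR(t) = (1 - eta0) * (1 - F1(t)) / (1 - F(t))` with
#' `F1 = (F - eta0 * t) / (1 - eta0)` the alternative CDF; it is reported as
#' 0 when `eta0 = 1` (no alternative component).
#'
#' @param pvalues raw p-values in `[0, 1]`.
#' @param method `"grenander"` (default) or `"BH"` for classical
#'   Benjamini-Hochberg on the raw p-values (comparison mode).
#' @return List with `p_adjusted`, `eta0`, `fndr` (all aligned with the
#'   input order) and the `grenander_fit` (NULL for BH).
#' @export
fnr_adjust <- function(pvalues, method = c("grenander", "BH")) {
  method <- match.arg(method)
  if (length(pvalues) == 0L) stop("need at least one p-value")
  if (method == "BH") {
    return(list(p_adjusted = stats::p.adjust(pvalues, "BH"),
                eta0 = NA_real_, fndr = rep(NA_real_, length(pvalues)),
                fit = NULL))
  }
  fit <- grenander_density(pvalues)
  # flat-tail step value: the density's last positive step (the trailing
  # zero step that exists whenever max(p) < 1 carries no information)
  tail_step <- fit$density[max(which(fit$density > 0))]
  eta0 <- min(1, max(0, tail_step))
  Ft <- grenander_cdf(fit, pvalues)
  q <- ifelse(Ft > 0, pmin(1, eta0 * pvalues / Ft), eta0)
  # monotone nondecreasing in raw p: running max in sort order
  ord <- order(pvalues)
  q[ord] <- cummax(q[ord])
  if (eta0 < 1) {
    F1 <- pmin(1, pmax(0, (Ft - eta0 * pvalues) / (1 - eta0)))
    fndr <- ifelse(1 - Ft > 0,
                   (1 - eta0) * (1 - F1) / (1 - Ft), 0)
    fndr <- pmin(1, pmax(0, fndr))
  } else {
    fndr <- rep(0, length(pvalues))
  }
  list(p_adjusted = q, eta0 = eta0, fndr = fndr, fit = fit)
}

#' Group comparisons of topology indices
#'
#' For `scope = "global"`, runs a Mann-Whitney test per global index and
#' group pair on the raw per-subject global values. For `scope = "local"`,
#' each node-level index is first residualised on graph density across all
#' subjects pooled ([density_adjust()]), then tested per node, and the
#' resulting family of N node p-values is adjusted with [fnr_adjust()]
#' within each (index, group pair) family.
#'
#' @param profiles named list of `topology_profile`s, one per subject (names
#'   are subject ids).
#' @param cohort data.frame with columns `subject` and `group` (and
#'   whatever else); every profiled subject must appear.
#' @param scope `"global"` or `"local"`.
#' @param indices which indices to test (default strength, clustering,
#'   path_length; global scope adds density and, when present in profiles,
#'   small_worldness is the caller's business).
#' @param correction passed to [fnr_adjust()] (`"grenander"` or `"BH"`).
#' @return A data.frame: index, node, group_a, group_b, n_a, n_b, U, p_raw,
#'   density_adjusted, p_adjusted, direction (sign of median difference
#'   a - b).
#' @export
compare_groups <- function(profiles, cohort,
                           scope = c("global", "local"),
                           indices = c("strength", "clustering",
                                       "path_length"),
                           correction = c("grenander", "BH")) {
  scope <- match.arg(scope)
  correction <- match.arg(correction)
  subj <- cohort$subject
  if (!all(subj %in% names(profiles)))
    stop("profiles missing for subjects: ",
         paste(setdiff(subj, names(profiles)), collapse = ", "))
  profiles <- profiles[subj]
  groups <- unique(as.character(cohort$group))
  if (length(groups) < 2L) stop("need at least 2 groups")
  counts <- table(as.character(cohort$group))
  if (any(counts < 2L))
    stop("group(s) with fewer than 2 subjects: ",
         paste(names(counts)[counts < 2L], collapse = ", "))
  pairs <- utils::combn(groups, 2L, simplify = FALSE)
  densities <- vapply(profiles, function(p) p$global[["density"]], numeric(1))

  if (scope == "global") {
    idx_global <- union(indices, "density")
    rows <- list()
    for (ix in idx_global) {
      vals <- vapply(profiles, function(p)
        if (ix %in% names(p$global)) p$global[[ix]] else NA_real_, numeric(1))
      for (pr in pairs) {
        a <- vals[cohort$group == pr[1]]
        b <- vals[cohort$group == pr[2]]
        mw <- mann_whitney(a, b)
        rows[[length(rows) + 1L]] <- data.frame(
          index = ix, node = "global", group_a = pr[1], group_b = pr[2],
          n_a = length(a), n_b = length(b), U = mw$U, p_raw = mw$p,
          density_adjusted = FALSE, p_adjusted = mw$p,
          direction = sign(stats::median(a, na.rm = TRUE) -
                           stats::median(b, na.rm = TRUE)),
          stringsAsFactors = FALSE)
      }
    }
    return(do.call(rbind, rows))
  }

  node_names <- profiles[[1]]$node$node
  rows <- list()
  for (ix in indices) {
    # subjects x nodes matrix of raw node values
    M <- vapply(profiles, function(p) p$node[[ix]],
                numeric(length(node_names)))
    M <- t(M)
    adj <- apply(M, 2L, density_adjust, densities = densities)
    for (pr in pairs) {
      ia <- cohort$group == pr[1]
      ib <- cohort$group == pr[2]
      fam <- lapply(seq_along(node_names), function(k) {
        mw <- mann_whitney(adj[ia, k], adj[ib, k])
        c(U = mw$U, p = mw$p,
          dir = sign(stats::median(adj[ia, k], na.rm = TRUE) -
                       stats::median(adj[ib, k], na.rm = TRUE)))
      })
      fam <- do.call(rbind, fam)
      padj <- fnr_adjust(fam[, "p"], method = correction)$p_adjusted
      rows[[length(rows) + 1L]] <- data.frame(
        index = ix, node = node_names, group_a = pr[1], group_b = pr[2],
        n_a = sum(ia), n_b = sum(ib), U = fam[, "U"], p_raw = fam[, "p"],
        density_adjusted = TRUE, p_adjusted = padj,
        direction = fam[, "dir"], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
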