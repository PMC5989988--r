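#' Spearman partial correlation
#'
#' Rank-transforms `x`, `y` and the covariate (midranks for ties) and
#' computes the first-order partial correlation on the ranks:
#' \deqn{r_{xy.z} = \frac{r_{xy} - r_{xz} r_{yz}}
#'   {\sqrt{(1 - r_{xz}^2)(1 - r_{yz}^2)}}}
#' This is Spearman's correlation between `x` and `y` with the monotone
#' association of each with the covariate removed.
#'
#' @param x,y numeric vectors of equal length n >= 4.
#' @param covariate numeric vector, same length, finite.
#' @return Partial rho in `[-1, 1]`; `NA` (with a warning) when `x` or `y`
#'   has zero rank variance.
#' @export
spearman_partial <- function(x, y, covariate) {
  n <- length(x)
  if (length(y) != n || length(covariate) != n)
    stop("x, y and covariate must have equal length")
  if (n < 4L) stop("partial correlation needs n >= 4")
  if (any(!is.finite(covariate))) stop("covariate must be finite")
  rx <- rank(x); ry <- rank(y); rz <- rank(covariate)
  if (stats::var(rx) == 0 || stats::var(ry) == 0) {
    warning("zero rank variance: partial correlation undefined")
    return(NA_real_)
  }
  r_xz <- if (stats::var(rz) == 0) 0 else stats::cor(rx, rz)
  r_yz <- if (stats::var(rz) == 0) 0 else stats::cor(ry, rz)
  if (abs(r_xz) >= 1 - 1e-12 || abs(r_yz) >= 1 - 1e-12)
    stop("degenerate covariate: perfectly rank-correlated with x or y")
  r_xy <- stats::cor(rx, ry)
  rho <- (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2))
  max(-1, min(1, rho))
}

#' Fisher z transform
#'
#' `z = atanh(rho)`: the variance-stabilising transform of a correlation.
#'
#' @param rho correlation(s) with `|rho| < 1`.
#' @return z score(s).
#' @export
fisher_z <- function(rho) {
  if (any(!is.na(rho) & abs(rho) >= 1))
    stop("Fisher z requires |rho| < 1")
  atanh(rho)
}

#' Test the difference between two independent correlations
#'
#' Compares correlations from two independent samples on the Fisher z scale:
#' \deqn{z = \frac{\mathrm{atanh}(r_1) - \mathrm{atanh}(r_2)}
#'   {\sqrt{1/(n_1 - 3) + 1/(n_2 - 3)}}}
#' with a two-sided p-value from the standard normal.
#'
#' @param r1,r2 correlations with `|r| < 1`.
#' @param n1,n2 sample sizes (each >= 4).
#' @return List with `z` and `p`.
#' @export
correlation_diff_test <- function(r1, n1, r2, n2) {
  if (n1 <= 3 || n2 <= 3) stop("both samples need n >= 4")
  if (abs(r1) >= 1 || abs(r2) >= 1) stop("correlations must satisfy |r| < 1")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Count strong correlations per node and index
#'
#' Tabulates, for each (node, network index) cell, how many cognitive
#' measures have `|rho|` above the threshold, per group. Undefined rho
#' (e.g. zero-variance measures) are excluded from counting and tallied.
#'
#' @param records data.frame of correlation records with columns `group`,
#'   `node`, `index`, `measure`, `rho`.
#' @param threshold absolute-rho threshold in `(0, 1)` (default 0.5).
#' @return List with `counts` (data.frame: group, node, index, n_strong),
#'   `total_evaluated` (named by group: nodes x indices x measures with
#'   defined rho), and `n_undefined` (excluded records per group).
#' @export
strong_correlation_counts <- function(records, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  defined <- !is.na(records$rho)
  counts <- stats::aggregate(
    strong ~ group + node + index,
    data = transform(records[defined, ],
                     strong = as.integer(abs(rho) > threshold)),
    FUN = sum)
  names(counts)[names(counts) == "strong"] <- "n_strong"
  list(counts = counts[order(counts$group, counts$node, counts$index), ],
       total_evaluated = tapply(defined, records$group, sum),
       n_undefined = tapply(!defined, records$group, sum))
}

#' Correlate network indices with cognition across a cohort
#'
#' Per group, computes Spearman partial correlations (controlling for the
#' named covariate) between each network index and each cognitive measure.
#' Controls are correlated with the three composites (working memory,
#' processing speed, memory); disease groups additionally with the motor
#' score (UPDRS III). `scope = "global"` uses the per-subject global index
#' values; `scope = "local"` the per-node values over `node_set`. Records
#' are flagged strong at `|z| > z_threshold` (global convention) and
#' `|rho| > r_threshold` (node-level convention).
#'
#' @param profiles named list of `topology_profile`s keyed by subject id.
#' @param cohort data.frame with columns `subject`, `group`, `education`,
#'   `age`, `updrs3`, `working_memory`, `processing_speed`, `memory`.
#' @param scope `"global"` or `"local"`.
#' @param covariate_name column of `cohort` to partial out (default
#'   `"education"`; `"age"` is the common alternative).
#' @param node_set character vector of node names for local scope (default
#'   all nodes in the profiles).
#' @param indices network indices to correlate.
#' @param r_threshold,z_threshold strong-correlation flags (defaults 0.50
#'   and 0.55).
#' @return A data.frame of correlation records: group, node, index, measure,
#'   covariate, n, rho, z, strong_r, strong_z, low_n.
#' @export
correlate_cohort <- function(profiles, cohort,
                             scope = c("global", "local"),
                             covariate_name = "education",
                             node_set = NULL,
                             indices = c("strength", "clustering",
                                         "path_length"),
                             r_threshold = 0.50, z_threshold = 0.55) {
  scope <- match.arg(scope)
  if (!covariate_name %in% names(cohort))
    stop("covariate not found in cohort: ", covariate_name)
  if (!all(cohort$subject %in% names(profiles)))
    stop("profiles missing for some subjects")
  profiles <- profiles[cohort$subject]
  measures_for <- function(group) {
    base <- c("working_memory", "processing_speed", "memory")
    if (grepl("control", group, ignore.case = TRUE)) base
    else c(base, "updrs3")
  }
  if (scope == "local") {
    all_nodes <- profiles[[1]]$node$node
    if (is.null(node_set)) node_set <- all_nodes
    if (!all(node_set %in% all_nodes))
      stop("node_set contains unknown nodes")
  }
  rows <- list()
  for (g in unique(as.character(cohort$group))) {
    in_g <- cohort$group == g
    n_g <- sum(in_g)
    low_n <- n_g < 5L
    if (low_n)
      warning(sprintf("group %s has n = %d < 5: correlations flagged low-n",
                      g, n_g))
    cov <- cohort[[covariate_name]][in_g]
    for (ms in measures_for(g)) {
      y <- cohort[[ms]][in_g]
      cells <- if (scope == "global") {
        lapply(indices, function(ix) list(
          node = "global", index = ix,
          x = vapply(profiles[in_g], function(p) p$global[[ix]], numeric(1))))
      } else {
        unlist(lapply(indices, function(ix) {
          lapply(node_set, function(nd) {
            k <- match(nd, profiles[[1]]$node$node)
            list(node = nd, index = ix,
                 x = vapply(profiles[in_g], function(p) p$node[[ix]][k],
                            numeric(1)))
          })
        }), recursive = FALSE)
      }
      for (cell in cells) {
        rho <- tryCatch(
          suppressWarnings(spearman_partial(cell$x, y, cov)),
          error = function(e) NA_real_)
        z <- if (is.na(rho) || abs(rho) >= 1) NA_real_ else fisher_z(rho)
        rows[[length(rows) + 1L]] <- data.frame(
          group = g, node = cell$node, index = cell$index, measure = ms,
          covariate = covariate_name, n = n_g, rho = rho, z = z,
          strong_r = !is.na(rho) && abs(rho) > r_threshold,
          strong_z = !is.na(z) && abs(z) > z_threshold,
          low_n = low_n, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
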