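#' Weighted connectome container
#'
#' @param W numeric N x N matrix: symmetric, nonnegative, zero diagonal,
#'   finite. Entries are the dimensionless edge weights (or an alternative
#'   weighting such as mean fractional anisotropy).
#' @param labels optional character vector of node labels (defaults to
#'   existing dimnames or `n1..nN`).
#' @param nodes optional data.frame of node metadata carried along.
#' @return An object of class `connectome` (the matrix, with attributes).
#' @export
connectome <- function(W, labels = NULL, nodes = NULL) {
  W <- as.matrix(W)
  n <- nrow(W)
  if (n < 2L || ncol(W) != n) stop("W must be square with N >= 2")
  if (!all(is.finite(W))) stop("W must be finite")
  if (any(W < 0)) stop("W must be nonnegative")
  if (max(abs(W - t(W))) > 1e-9 * max(1, max(abs(W))))
    stop("W must be symmetric")
  W <- (W + t(W)) / 2
  diag(W) <- 0
  if (is.null(labels)) labels <- rownames(W)
  if (is.null(labels)) labels <- paste0("n", seq_len(n))
  dimnames(W) <- list(labels, labels)
  structure(W, class = c("connectome", "matrix"), nodes = nodes)
}

#' @export
print.connectome <- function(x, ...) {
  cat(sprintf("connectome: %d nodes, %d edges, density %.4f\n",
              nrow(x), sum(x[upper.tri(x)] > 0), graph_density(x)))
  invisible(x)
}

# Resample a polyline so consecutive samples are at most `step` apart;
# original vertices are always kept.
#' @keywords internal
resample_polyline <- function(points, step) {
  segs <- lapply(seq_len(nrow(points) - 1L), function(k) {
    a <- points[k, ]; b <- points[k + 1L, ]
    len <- sqrt(sum((b - a)^2))
    n_sub <- max(1L, ceiling(len / step))
    tt <- seq(0, 1, length.out = n_sub + 1L)[-(n_sub + 1L)]
    outer(tt, b - a) + rep(a, each = length(tt))
  })
  rbind(do.call(rbind, segs), points[nrow(points), , drop = FALSE])
}

# Linear voxel keys traversed by a streamline, determined by point-in-voxel
# tests on the polyline resampled at 1/4 of the smallest voxel edge.
#' @keywords internal
streamline_voxel_keys <- function(grid, s, step = min(grid$voxel_edges) / 4) {
  pts <- resample_polyline(s$points, step)
  idx <- point_to_voxel(grid, pts)
  keep <- voxel_in_grid(grid, idx)
  unique(voxel_key(grid, idx[keep, , drop = FALSE]))
}

#' Assign streamlines to node pairs by endpoint containment
#'
#' A streamline is assigned to the unordered node pair `(i, j)`, `i != j`,
#' exactly when its first and last polyline points fall in the voxel masks of
#' nodes `i` and `j` (in either order). Streamlines with zero or one endpoint
#' in any node, or both endpoints in the same node (would-be self-loops), are
#' left unassigned; their counts are reported in the `dropped` attribute.
#'
#' @param t a [tractogram()].
#' @param parc a [parcellation()] on the same grid (disjoint voxel sets are
#'   enforced at construction).
#' @return A named list mapping `"i|j"` (i < j, node ids) to integer vectors
#'   of streamline indices, with attribute `dropped` = c(unassigned,
#'   self_loops).
#' @export
segment_tractogram <- function(t, parc) {
  check_same_grid(t$grid, parc$grid)
  n_nodes <- nrow(parc$nodes)
  lookup <- integer(0)
  for (i in seq_len(n_nodes))
    lookup[as.character(parc$voxel_keys[[i]])] <- parc$nodes$id[i]
  ends <- vapply(t$streamlines, function(s) {
    ep <- point_to_voxel(t$grid, s$points[c(1L, nrow(s$points)), ])
    inb <- voxel_in_grid(t$grid, ep)
    keys <- ifelse(inb, as.character(voxel_key(t$grid, ep)), NA_character_)
    c(node_of(lookup, keys[1]), node_of(lookup, keys[2]))
  }, integer(2))
  a <- pmin(ends[1, ], ends[2, ])
  b <- pmax(ends[1, ], ends[2, ])
  assigned <- a > 0L & a != b
  self_loops <- sum(a > 0L & a == b)
  pair_key <- paste0(a, "|", b)
  out <- split(which(assigned), pair_key[assigned])
  attr(out, "dropped") <- c(unassigned = sum(!assigned) - self_loops,
                            self_loops = self_loops)
  out
}

#' @keywords internal
node_of <- function(lookup, key) {
  if (is.na(key)) return(0L)
  v <- lookup[key]
  if (is.na(v)) 0L else unname(v)
}

#' @keywords internal
check_same_grid <- function(g1, g2) {
  if (!identical(g1$shape, g2$shape) ||
      max(abs(g1$voxel_edges - g2$voxel_edges)) > 1e-9)
    stop("tractogram and parcellation are defined on different grids")
  invisible(TRUE)
}

#' White-matter voxel occupancy of one edge
#'
#' For the candidate streamlines of a node pair, computes `R`: the union of
#' grid voxels their polylines traverse, minus the voxel masks of the two
#' nodes. `R` is the space occupied by the white-matter path; only
#' streamlines seeded inside `R` are retained for the edge weight
#' (see [characteristic_filter()]).
#'
#' @param t a [tractogram()].
#' @param parc a [parcellation()].
#' @param node_i,node_j node ids (i != j).
#' @param candidates integer indices into `t$streamlines` of the pair's
#'   candidate streamlines (from [segment_tractogram()]).
#' @return An object of class `edge_occupancy` with fields `node_pair`,
#'   `voxels` (sorted linear keys of R), `streamline_refs` (retained
#'   candidate indices) and `candidates`.
#' @export
edge_occupancy <- function(t, parc, node_i, node_j, candidates) {
  if (node_i == node_j) stop("edge occupancy needs two distinct nodes")
  pair <- sort(c(node_i, node_j))
  traversed <- unique(unlist(lapply(
    t$streamlines[candidates],
    function(s) streamline_voxel_keys(t$grid, s))))
  node_keys <- unlist(parc$voxel_keys[match(pair, parc$nodes$id)])
  R <- sort(setdiff(traversed, node_keys))
  occ <- structure(
    list(node_pair = pair, voxels = R, streamline_refs = integer(0),
         candidates = candidates),
    class = "edge_occupancy")
  retained <- candidates[vapply(t$streamlines[candidates], function(s)
    characteristic_filter(s, occ, parc) == 1L, logical(1))]
  occ$streamline_refs <- retained
  occ
}

#' Characteristic filter on seed provenance
#'
#' The indicator that keeps a candidate streamline only if it was seeded
#' inside the edge's white-matter voxel set `R`: streamlines that originate
#' within either node's mask, or in voxels not on the white-matter path, are
#' discarded. This is the strict seed-provenance control against spurious
#' streamlines.
#'
#' @param s a [streamline()].
#' @param occ an [edge_occupancy()] (its `voxels` field is `R`).
#' @param parc the [parcellation()] (used only for grid context).
#' @return 1L if the seed voxel is in `R`, else 0L.
#' @export
characteristic_filter <- function(s, occ, parc) {
  key <- voxel_key(parc$grid, s$seed_voxel)
  if (key %in% occ$voxels) 1L else 0L
}

#' Dimensionless edge weight
#'
#' The connection strength between nodes i and j:
#' \deqn{w(e_{ij}) = \frac{2}{A_i + A_j} \frac{V_{voxel}}{P_{voxel}}
#'   \sum_{f \in retained} \frac{1}{l(f)}}
#' summing over the streamlines retained by the characteristic filter. The
#' normalisation removes the bias of streamline length, seed density
#' (`P_voxel`), and image resolution (`V_voxel`); the weight is dimensionless
#' (mm^3 / (mm^2 * mm)) and invariant to a global rescaling of spatial units.
#'
#' @param t a [tractogram()] (supplies `V_voxel` and `P_voxel`).
#' @param occ an [edge_occupancy()] whose `streamline_refs` passed the
#'   characteristic filter.
#' @param node_i,node_j rows of the parcellation node table (need
#'   `surface_area_mm2`).
#' @return Nonnegative dimensionless weight; 0 when no streamline is
#'   retained.
#' @export
edge_weight <- function(t, occ, node_i, node_j) {
  a_sum <- node_i$surface_area_mm2 + node_j$surface_area_mm2
  if (!is.finite(a_sum) || a_sum <= 0)
    stop("invalid geometry: node surface areas must sum to a positive value")
  if (t$seeds_per_voxel <= 0)
    stop("invalid geometry: P_voxel must be positive")
  if (length(occ$streamline_refs) == 0L) return(0)
  inv_len <- vapply(t$streamlines[occ$streamline_refs],
                    function(s) 1 / streamline_arclength(s), numeric(1))
  (2 / a_sum) * (t$grid$voxel_volume / t$seeds_per_voxel) * sum(inv_len)
}

#' Build a weighted connectome from a tractogram
#'
#' Runs endpoint assignment, per-edge white-matter occupancy, the
#' characteristic seed filter, and the dimensionless edge weight for every
#' node pair. No threshold is applied: every pair with at least one retained
#' streamline keeps its (possibly weak) edge.
#'
#' @param t a [tractogram()].
#' @param parc a [parcellation()] on the same grid.
#' @param weighting `"dimensionless"` (default) or `"fa"` for mean fractional
#'   anisotropy over the edge's voxel set.
#' @param fa a [scalar_field()] of FA values, required when
#'   `weighting = "fa"`. Pairs whose occupancy is empty get weight 0.
#' @return A [connectome()] whose dimnames are the parcellation labels
#'   (prefixed by hemisphere when not "none").
#' @export
build_connectome <- function(t, parc,
                             weighting = c("dimensionless", "fa"),
                             fa = NULL) {
  weighting <- match.arg(weighting)
  if (weighting == "fa") {
    if (is.null(fa)) stop("FA weighting requires a scalar field `fa`")
    check_same_grid(t$grid, fa$grid)
  }
  check_same_grid(t$grid, parc$grid)
  n <- nrow(parc$nodes)
  W <- matrix(0, n, n)
  if (length(t$streamlines) == 0L) {
    warning("empty tractogram: returning an all-zero connectome")
  } else {
    assignment <- segment_tractogram(t, parc)
    for (key in names(assignment)) {
      pair <- as.integer(strsplit(key, "|", fixed = TRUE)[[1]])
      ri <- match(pair[1], parc$nodes$id)
      rj <- match(pair[2], parc$nodes$id)
      occ <- edge_occupancy(t, parc, pair[1], pair[2], assignment[[key]])
      w <- if (weighting == "dimensionless") {
        edge_weight(t, occ, parc$nodes[ri, ], parc$nodes[rj, ])
      } else {
        fa_edge_weight(occ, fa, absent_value = 0)
      }
      W[ri, rj] <- W[rj, ri] <- w
    }
  }
  connectome(W, labels = node_display_labels(parc$nodes), nodes = parc$nodes)
}

#' @keywords internal
node_display_labels <- function(nodes) {
  pre <- c(left = "Lf ", right = "Rt ", none = "")[nodes$hemisphere]
  paste0(pre, nodes$label)
}

#' Fractional-anisotropy edge weight
#'
#' Mean FA over the `M` voxels of the edge's white-matter set `R`; the
#' traditional comparison weighting. An edge with empty occupancy has no
#' defined FA weight.
#'
#' @param occ an [edge_occupancy()].
#' @param fa a [scalar_field()] on the same grid, values in `[0, 1]`.
#' @param absent_value value returned when `R` is empty; the default `NA`
#'   signals an undefined edge.
#' @return Mean FA in `[0, 1]`, or `absent_value`.
#' @export
fa_edge_weight <- function(occ, fa, absent_value = NA_real_) {
  if (length(occ$voxels) == 0L) return(absent_value)
  mean(field_at_keys(fa, occ$voxels))
}

#' Read/write connectome matrices
#'
#' `write_connectome_csv()` writes the N x N matrix with node labels as
#' header row and first column; `read_connectome_csv()` reads it back.
#' `write_edge_list()`/`read_edge_list()` use the sparse TSV alternative
#' `node_i <tab> node_j <tab> weight` (upper triangle, positive entries
#' only, with a labels header comment).
#'
#' @param x a [connectome()].
#' @param path file path.
#' @return The connectome (readers) or `path` invisibly (writers).
#' @export
write_connectome_csv <- function(x, path) {
  utils::write.csv(as.data.frame(unclass(x)), path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_connectome_csv
#' @export
read_connectome_csv <- function(path) {
  df <- utils::read.csv(path, row.names = 1L, check.names = FALSE)
  connectome(as.matrix(df), labels = rownames(df))
}

#' @rdname write_connectome_csv
#' @export
write_edge_list <- function(x, path) {
  labs <- rownames(x)
  up <- which(upper.tri(x) & x > 0, arr.ind = TRUE)
  df <- data.frame(node_i = labs[up[, 1]], node_j = labs[up[, 2]],
                   weight = x[up])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# nodes: %s", paste(labs, collapse = "\t")), con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_connectome_csv
#' @export
read_edge_list <- function(path) {
  first <- readLines(path, n = 1L)
  labs <- strsplit(sub("^# nodes: ", "", first), "\t", fixed = TRUE)[[1]]
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  n <- length(labs)
  W <- matrix(0, n, n, dimnames = list(labs, labs))
  i <- match(df$node_i, labs)
  j <- match(df$node_j, labs)
  if (anyNA(i) || anyNA(j)) stop("edge list refers to unknown node labels")
  W[cbind(i, j)] <- df$weight
  W[cbind(j, i)] <- df$weight
  connectome(W, labels = labs)
}
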