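#' Graph density
#'
#' Fraction of realised edges among all `N(N-1)/2` node pairs — the only
#' binary (nonweighted) index in the framework.
#'
#' @param x a [connectome()] or symmetric nonnegative matrix.
#' @return Density in `[0, 1]`.
#' @export
graph_density <- function(x) {
  n <- nrow(x)
  if (is.null(n) || n < 2L) stop("graph density needs at least 2 nodes")
  sum(x[upper.tri(x)] > 0) / (n * (n - 1) / 2)
}

#' Node strength
#'
#' Sum of the weights of all edges incident to each node: the node's
#' connectivity strength with the rest of the network.
#'
#' @param x a [connectome()].
#' @param i optional node index (or vector); default all nodes.
#' @return Numeric vector of strengths (named by node).
#' @export
node_strength <- function(x, i = NULL) {
  s <- rowSums(x)
  if (!is.null(i)) s <- s[i]
  s
}

#' Weighted clustering coefficient (Zhang-Horvath)
#'
#' Triangle-closure strength around each node, computed on weights
#' normalised by the graph maximum (`w_hat = w / max(w)` so `w_hat <= 1`):
#' \deqn{C_i = \frac{\sum_{j \ne k} \hat w_{ij}\hat w_{jk}\hat w_{ki}}
#'  {\left(\sum_j \hat w_{ij}\right)^2 - \sum_j \hat w_{ij}^2}}
#' `C_i` lies in `[0, 1]` and is 0 for nodes with fewer than two neighbours.
#'
#' @param x a [connectome()].
#' @param i optional node index/indices; default all.
#' @return Numeric vector of clustering coefficients.
#' @export
weighted_clustering <- function(x, i = NULL) {
  W <- unclass(x)
  mx <- max(W)
  if (mx <= 0) {
    warning("all-zero graph: clustering is 0 everywhere")
    cc <- rep(0, nrow(W))
  } else {
    Wh <- W / mx
    num <- diag(Wh %*% Wh %*% Wh)
    den <- rowSums(Wh)^2 - rowSums(Wh^2)
    cc <- ifelse(den > 0, num / den, 0)
  }
  names(cc) <- rownames(x)
  if (!is.null(i)) cc <- cc[i]
  cc
}

#' @keywords internal
connectome_igraph <- function(x) {
  g <- igraph::graph_from_adjacency_matrix(unclass(x), mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  # optimal routes minimise summed inverse weight
  igraph::E(g)$distance <- 1 / igraph::E(g)$weight
  g
}

#' Strength of the shortest path between two nodes
#'
#' Edges get length `d(e) = 1/w(e)`; the optimal route minimises the summed
#' length and the path strength is the reciprocal of that minimum,
#' `L(i,j) = 1 / D(i,j)`. Larger values mean stronger routes; for a pair
#' whose direct edge is optimal, `L(i,j) = w(i,j)`. Disconnected pairs have
#' no path strength (`NA`).
#'
#' @param x a [connectome()].
#' @param i,j distinct node indices.
#' @param as_distance if `TRUE`, return the raw minimal distance `D(i,j)`
#'   instead of its reciprocal.
#' @return Path strength (or distance), `NA` if no path exists.
#' @export
path_strength <- function(x, i, j, as_distance = FALSE) {
  if (i == j) stop("path strength is defined for distinct nodes")
  D <- path_strength_matrix(x, as_distance = as_distance)
  D[i, j]
}

#' All-pairs path strengths
#'
#' @param x a [connectome()].
#' @param as_distance return raw minimal distances instead of reciprocals.
#' @return N x N matrix; `NA` off-diagonal marks disconnected pairs, the
#'   diagonal is `NA` (undefined).
#' @export
path_strength_matrix <- function(x, as_distance = FALSE) {
  g <- connectome_igraph(x)
  D <- igraph::distances(g, weights = igraph::E(g)$distance,
                         algorithm = "dijkstra")
  D[is.infinite(D)] <- NA_real_
  out <- if (as_distance) D else 1 / D
  diag(out) <- NA_real_
  dimnames(out) <- dimnames(x)
  out
}

#' All weighted topology indices of one connectome
#'
#' Computes the per-node and global profile: node strength, Zhang-Horvath
#' clustering, mean path strength per node (over reachable partners), graph
#' density, and the global means. Global mean path length averages `L(i,j)`
#' over connected unordered pairs only; disconnected pairs are excluded (and
#' counted in `n_disconnected_pairs`).
#'
#' @param x a [connectome()].
#' @return An object of class `topology_profile`: list with `node` (a
#'   data.frame: node, strength, clustering, path_length) and `global`
#'   (named numeric: density, strength, clustering, path_length), plus
#'   bookkeeping fields.
#' @export
global_indices <- function(x) {
  s <- node_strength(x)
  cc <- weighted_clustering(x)
  L <- path_strength_matrix(x)
  conn <- upper.tri(L) & !is.na(L)
  node_L <- rowMeans(L, na.rm = TRUE)
  node_L[is.nan(node_L)] <- NA_real_
  n_pairs <- sum(upper.tri(L))
  structure(
    list(
      node = data.frame(node = rownames(x), strength = unname(s),
                        clustering = unname(cc),
                        path_length = unname(node_L),
                        stringsAsFactors = FALSE),
      global = c(density = graph_density(x),
                 strength = mean(s),
                 clustering = mean(cc),
                 path_length = if (any(conn)) mean(L[conn]) else NA_real_),
      n_disconnected_pairs = n_pairs - sum(conn)),
    class = "topology_profile")
}

#' @export
print.topology_profile <- function(x, ...) {
  cat("topology profile\n  global:\n")
  print(signif(x$global, 4))
  if (x$n_disconnected_pairs > 0)
    cat(sprintf("  (%d disconnected pairs excluded from path length)\n",
                x$n_disconnected_pairs))
  invisible(x)
}

#' Erdos-Renyi weighted null graph
#'
#' Random graph in which each unordered node pair is independently an edge
#' with probability `density`; edge weights are drawn uniformly with
#' replacement from `weight_pool` (typically the observed connectome's
#' positive weights, so the null matches the weight distribution as well as
#' the density).
#'
#' @param n_nodes number of nodes (>= 2).
#' @param density edge probability in `(0, 1]`.
#' @param weight_pool nonempty numeric vector of candidate weights (> 0).
#' @param seed optional integer seed for reproducibility.
#' @return A [connectome()].
#' @export
er_null <- function(n_nodes, density, weight_pool, seed = NULL) {
  if (!is.finite(density) || density <= 0 || density > 1)
    stop("density must be in (0, 1]")
  if (length(weight_pool) == 0L) stop("weight pool must be nonempty")
  if (!is.null(seed)) set.seed(seed)
  n_pairs <- n_nodes * (n_nodes - 1) / 2
  present <- stats::runif(n_pairs) < density
  w <- numeric(n_pairs)
  w[present] <- sample(weight_pool, sum(present), replace = TRUE)
  W <- matrix(0, n_nodes, n_nodes)
  W[upper.tri(W)] <- w
  connectome(W + t(W))
}

#' Small-worldness against an Erdos-Renyi ensemble
#'
#' \deqn{S = \frac{C_{obs} / C_{rand}}{L_{obs} / L_{rand}}}
#' where `C` is global mean clustering and `L` global mean path length, and
#' the null ensemble matches the observed node count, graph density and
#' weight pool. A small-world network has higher clustering than, and path
#' lengths similar to, its random counterpart (`S > 1`).
#'
#' @param x a [connectome()].
#' @param n_realizations ensemble size (default 20).
#' @param seed integer seed for the ensemble.
#' @return An object of class `small_worldness`: list with `S`, `C_obs`,
#'   `L_obs`, `C_rand`, `L_rand`, `n_realizations`, `seed`.
#' @export
small_worldness <- function(x, n_realizations = 20, seed = 1L) {
  if (n_realizations < 1L) stop("need at least one null realization")
  obs <- global_indices(x)
  pool <- x[upper.tri(x) & x > 0]
  if (length(pool) == 0L) stop("cannot build a null for an empty graph")
  set.seed(seed)
  null_seeds <- sample.int(.Machine$integer.max - 1L, n_realizations)
  ens <- vapply(null_seeds, function(s) {
    g <- global_indices(er_null(nrow(x), graph_density(x), pool, seed = s))
    g$global[c("clustering", "path_length")]
  }, numeric(2))
  C_rand <- mean(ens[1, ])
  L_rand <- mean(ens[2, ], na.rm = TRUE)
  if (!is.finite(C_rand) || C_rand <= 0)
    stop("degenerate null ensemble: zero clustering, small-worldness undefined")
  S <- (obs$global[["clustering"]] / C_rand) /
    (obs$global[["path_length"]] / L_rand)
  structure(list(S = S, C_obs = obs$global[["clustering"]],
                 L_obs = obs$global[["path_length"]],
                 C_rand = C_rand, L_rand = L_rand,
                 n_realizations = n_realizations, seed = seed),
            class = "small_worldness")
}

#' @export
print.small_worldness <- function(x, ...) {
  cat(sprintf("small-worldness S = %.3f (C %.3f/%.3f, L %.3f/%.3f, %d nulls)\n",
              x$S, x$C_obs, x$C_rand, x$L_obs, x$L_rand, x$n_realizations))
  invisible(x)
}

#' Write/read topology profiles as TSV
#'
#' One row per node plus one `global` row; columns node, strength,
#' clustering, path_length, density (density only on the global row).
#'
#' @param profile a `topology_profile` from [global_indices()].
#' @param path file path.
#' @return The profile (reader) or `path` invisibly (writer).
#' @export
write_topology_tsv <- function(profile, path) {
  sw <- if ("small_worldness" %in% names(profile$global))
    profile$global[["small_worldness"]] else NA_real_
  node <- cbind(profile$node, density = NA_real_,
                small_worldness = NA_real_)
  glob <- data.frame(node = "global",
                     strength = profile$global[["strength"]],
                     clustering = profile$global[["clustering"]],
                     path_length = profile$global[["path_length"]],
                     density = profile$global[["density"]],
                     small_worldness = sw)
  utils::write.table(rbind(node, glob), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_topology_tsv
#' @export
read_topology_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  gl <- df[df$node == "global", ]
  node <- df[df$node != "global",
             !names(df) %in% c("density", "small_worldness")]
  rownames(node) <- NULL
  glob <- c(density = gl$density, strength = gl$strength,
            clustering = gl$clustering, path_length = gl$path_length)
  if ("small_worldness" %in% names(gl) && !is.na(gl$small_worldness))
    glob <- c(glob, small_worldness = gl$small_worldness)
  structure(
    list(node = node, global = glob,
         n_disconnected_pairs = NA_integer_),
    class = "topology_profile")
}
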