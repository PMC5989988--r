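#' Specification of a synthetic tractography phantom
#'
#' Describes a fully ground-truthed phantom: cuboid nodes laid out on a
#' planar lattice inside a voxel grid, straight (or arc-lengthened) bundles
#' of identical streamlines between node pairs, uniform seeding along each
#' bundle corridor, and optional single-streamline spurious connections
#' between otherwise unconnected pairs.
#'
#' @param n_nodes number of nodes (>= 2).
#' @param bundles data.frame with columns `node_i`, `node_j`,
#'   `n_streamlines` and optionally `length_mm` (NA = straight
#'   center-to-center distance; larger values arc the bundle to the
#'   requested arc length). Default: 50-streamline bundles between all
#'   lattice-neighbour node pairs, each exactly `spacing_mm` long.
#' @param voxel_edge_mm voxel edge length (isotropic, default 2).
#' @param node_size_voxels node cuboid side in voxels (default 2).
#' @param spacing_mm lattice spacing between adjacent node centers
#'   (default 20).
#' @param seeds_per_voxel `P_voxel` (default 125, the uniform per-voxel seed
#'   count of the emulated tracking runs).
#' @param spurious_rate fraction of unconnected node pairs that receive one
#'   spurious single-streamline connection (default 0).
#' @param spurious_length_mm minimum arc length of spurious streamlines
#'   (default 40; false-positive streamlines are long, weak connections).
#' @param seed integer seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(n_nodes = 10,
                         bundles = NULL,
                         voxel_edge_mm = 2,
                         node_size_voxels = 2,
                         spacing_mm = 20,
                         seeds_per_voxel = 125,
                         spurious_rate = 0,
                         spurious_length_mm = 40,
                         seed = 1L) {
  if (n_nodes < 2L) stop("phantom needs at least 2 nodes")
  if (is.null(bundles)) {
    nb <- lattice_neighbors(n_nodes)
    bundles <- data.frame(node_i = nb[, 1], node_j = nb[, 2],
                          n_streamlines = 50L,
                          length_mm = NA_real_)
  }
  if (is.null(bundles$length_mm)) bundles$length_mm <- NA_real_
  if (any(bundles$n_streamlines < 0)) stop("streamline counts must be >= 0")
  if (any(bundles$node_i == bundles$node_j)) stop("bundles must join distinct nodes")
  if (seeds_per_voxel < 1L) stop("seeds_per_voxel (P_voxel) must be >= 1")
  if (spurious_rate < 0 || spurious_rate > 1)
    stop("spurious_rate must be in [0, 1]")
  structure(list(n_nodes = as.integer(n_nodes), bundles = bundles,
                 voxel_edge_mm = voxel_edge_mm,
                 node_size_voxels = as.integer(node_size_voxels),
                 spacing_mm = spacing_mm,
                 seeds_per_voxel = as.integer(seeds_per_voxel),
                 spurious_rate = spurious_rate,
                 spurious_length_mm = spurious_length_mm,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Adjacent (horizontal/vertical) pairs of the planar node lattice used by
# phantom_geometry; these pairs are exactly spacing_mm apart.
#' @keywords internal
lattice_neighbors <- function(n_nodes) {
  ncol_lat <- ceiling(sqrt(n_nodes))
  pos <- cbind(row = (seq_len(n_nodes) - 1L) %/% ncol_lat,
               col = (seq_len(n_nodes) - 1L) %% ncol_lat)
  pairs <- utils::combn(n_nodes, 2L)
  adj <- abs(pos[pairs[1, ], "row"] - pos[pairs[2, ], "row"]) +
    abs(pos[pairs[1, ], "col"] - pos[pairs[2, ], "col"]) == 1L
  t(pairs[, adj, drop = FALSE])
}

# Lattice layout: nodes on a ceil(sqrt(n)) x ... planar grid, cuboids aligned
# to voxel boundaries; returns grid, parcellation and node centers (mm).
#' @keywords internal
phantom_geometry <- function(spec) {
  e <- spec$voxel_edge_mm
  k <- spec$node_size_voxels
  n <- spec$n_nodes
  ncol_lat <- ceiling(sqrt(n))
  nrow_lat <- ceiling(n / ncol_lat)
  sp_vox <- ceiling(spec$spacing_mm / e)
  if (sp_vox <= k) stop("spacing too small: node cuboids would overlap")
  margin <- max(4L, k)  # room for arcs bulging outside the lattice
  extent_z <- 2L * margin + k + ceiling(spec$spurious_length_mm / e)
  grid <- voxel_grid(
    c(margin * 2L + (ncol_lat - 1L) * sp_vox + k,
      margin * 2L + (nrow_lat - 1L) * sp_vox + k,
      extent_z),
    e)
  z0 <- margin
  regions <- vector("list", n)
  centers <- matrix(0, n, 3L)
  for (id in seq_len(n)) {
    r <- (id - 1L) %/% ncol_lat
    cc <- (id - 1L) %% ncol_lat
    i0 <- margin + cc * sp_vox
    j0 <- margin + r * sp_vox
    vox <- as.matrix(expand.grid(i = i0:(i0 + k - 1L),
                                 j = j0:(j0 + k - 1L),
                                 k = z0:(z0 + k - 1L)))
    centers[id, ] <- (c(i0, j0, z0) + k / 2) * e
    regions[[id]] <- list(id = id, label = paste0("node", id),
                          hemisphere = "none",
                          surface_area_mm2 = 6 * (k * e)^2,
                          voxels = vox)
  }
  list(grid = grid, parcellation = parcellation(regions, grid),
       centers = centers)
}

# Polyline from a to b with arc length >= target: straight if target is NA
# or <= |b - a|, otherwise a 3-point tent raised along +z.
#' @keywords internal
arc_polyline <- function(a, b, target_length = NA_real_) {
  d <- sqrt(sum((b - a)^2))
  if (is.na(target_length) || target_length <= d)
    return(rbind(a, b))
  h <- sqrt((target_length / 2)^2 - (d / 2)^2)
  mid <- (a + b) / 2 + c(0, 0, h)
  rbind(a, mid, b)
}

#' Generate a phantom tractogram with known ground truth
#'
#' Builds the voxel grid, node parcellation and streamline bundles described
#' by a [phantom_spec()]. Every streamline of a bundle follows the same
#' center-to-center polyline (arc-lengthened when `length_mm` is set), so
#' closed-form edge weights are exactly predictable. Seeds are placed
#' deterministically by cycling over the bundle's corridor voxels (the
#' traversed voxels outside both node masks) and, within a voxel, over seed
#' indices `1..P_voxel` — so every emitted streamline passes the
#' characteristic filter. Spurious connections are single streamlines (arc
#' length >= `spurious_length_mm`) added between a random
#' `spurious_rate` fraction of the unconnected pairs.
#'
#' @param spec a [phantom_spec()].
#' @return List with `tractogram`, `parcellation`, `bundles` (ground-truth
#'   table with realised arc lengths), and `spurious` (data.frame of added
#'   pairs, possibly empty).
#' @export
make_phantom <- function(spec) {
  geo <- phantom_geometry(spec)
  set.seed(spec$seed)
  sls <- list()
  realized <- spec$bundles
  realized$arc_length_mm <- NA_real_
  for (bi in seq_len(nrow(spec$bundles))) {
    bnd <- spec$bundles[bi, ]
    pts <- arc_polyline(geo$centers[bnd$node_i, ], geo$centers[bnd$node_j, ],
                        bnd$length_mm)
    probe <- streamline(pts, c(0L, 0L, 0L))
    realized$arc_length_mm[bi] <- streamline_arclength(probe)
    corridor <- setdiff(
      streamline_voxel_keys(geo$grid, probe),
      unlist(geo$parcellation$voxel_keys[c(bnd$node_i, bnd$node_j)]))
    if (length(corridor) == 0L)
      stop("bundle corridor empty: nodes too close for a seedable path")
    n_s <- bnd$n_streamlines
    if (n_s > length(corridor) * spec$seeds_per_voxel)
      stop("bundle needs more seeds than corridor voxels x P_voxel")
    for (s_i in seq_len(n_s)) {
      vox_k <- corridor[(s_i - 1L) %% length(corridor) + 1L]
      seed_idx <- (s_i - 1L) %/% length(corridor) + 1L
      sls[[length(sls) + 1L]] <- streamline(
        pts, key_to_voxel(geo$grid, vox_k), seed_idx)
    }
  }
  # spurious single-streamline connections between unconnected pairs
  all_pairs <- utils::combn(spec$n_nodes, 2L)
  bundle_key <- paste(pmin(spec$bundles$node_i, spec$bundles$node_j),
                      pmax(spec$bundles$node_i, spec$bundles$node_j))
  unconn <- which(!(paste(all_pairs[1, ], all_pairs[2, ]) %in% bundle_key))
  n_spur <- round(spec$spurious_rate * length(unconn))
  spur_idx <- if (n_spur > 0) sample(unconn, n_spur) else integer(0)
  spurious <- data.frame(node_i = all_pairs[1, spur_idx],
                         node_j = all_pairs[2, spur_idx])
  if (n_spur > 0) {
    for (si in seq_len(n_spur)) {
      i <- spurious$node_i[si]; j <- spurious$node_j[si]
      pts <- arc_polyline(geo$centers[i, ], geo$centers[j, ],
                          spec$spurious_length_mm)
      probe <- streamline(pts, c(0L, 0L, 0L))
      corridor <- setdiff(
        streamline_voxel_keys(geo$grid, probe),
        unlist(geo$parcellation$voxel_keys[c(i, j)]))
      sls[[length(sls) + 1L]] <- streamline(
        pts, key_to_voxel(geo$grid, corridor[ceiling(length(corridor) / 2)]),
        1L)
    }
  }
  list(tractogram = tractogram(geo$grid, sls, spec$seeds_per_voxel),
       parcellation = geo$parcellation,
       bundles = realized,
       spurious = spurious)
}

#' Specification of a synthetic grouped cohort
#'
#' Describes the statistical structure of the emulated study population:
#' three groups (healthy controls and two disease phenotypes, the second
#' with memory impairment), a shared 82-node connectome support at the
#' target graph density with log-normal edge weights, per-group global
#' strength multipliers, an extra focal reduction on a designated node set,
#' per-subject noise, and cognitive composites tied to network strength and
#' education through a Gaussian copula.
#'
#' @param group_names character(3); defaults control / PD-Well / PD-MI.
#' @param group_sizes integer(3), default c(40, 31, 9).
#' @param n_nodes default 82.
#' @param density target graph density in (0, 1), default 0.40.
#' @param weight_meanlog,weight_sdlog log-normal edge-weight parameters
#'   (defaults log(0.05) and 1: nonnegative, right-skewed weights with a
#'   heavy top tail).
#' @param strength_multipliers per-group global mean-strength multipliers,
#'   default c(1, 0.9501, 0.8677) (a 4.99% and a 13.23% reduction).
#' @param focal_nodes node indices receiving the extra focal reduction;
#'   default the 27-node set of [pd_focal_nodes()] when `n_nodes` is 82,
#'   otherwise none.
#' @param focal_multipliers per-group multiplier on edges incident to focal
#'   nodes, default c(1, 1, 0.85); after the focal reduction each subject
#'   matrix is rescaled so the realised global multiplier stays equal to
#'   `strength_multipliers`, keeping focal and global effects separable.
#' @param subject_sdlog log-sd of the per-subject global scale factor
#'   (default 0.03). Kept deliberately small: the fixed edge support keeps
#'   graph density constant across subjects, so the density control that
#'   absorbs global connectivity differences in real cohorts has no handle
#'   on a large shared factor here.
#' @param node_sdlog log-sd of per-subject, per-node scale factors applied
#'   to a node's incident edges (default 0.10: the dominant, approximately
#'   node-independent part of between-subject variability).
#' @param edge_sdlog log-sd of per-subject, per-edge multiplicative noise
#'   (default 0.25).
#' @param strength_rho list of per-measure, per-group Spearman targets
#'   between the measure and the subject's global mean strength; defaults
#'   follow the study's global correlation table.
#' @param education_rho Spearman target between each composite and
#'   education (default 0.30).
#' @param demographics per-group means/sds for education, age, the three
#'   composites and the motor score; defaults follow the study's
#'   demographics table.
#' @param seed integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(group_names = c("control", "PD-Well", "PD-MI"),
                        group_sizes = c(40L, 31L, 9L),
                        n_nodes = 82L,
                        density = 0.40,
                        weight_meanlog = log(0.05),
                        weight_sdlog = 1,
                        strength_multipliers = c(1, 0.9501, 0.8677),
                        focal_nodes = NULL,
                        focal_multipliers = c(1, 1, 0.85),
                        subject_sdlog = 0.03,
                        node_sdlog = 0.10,
                        edge_sdlog = 0.25,
                        strength_rho = NULL,
                        education_rho = 0.30,
                        demographics = NULL,
                        seed = 1L) {
  if (length(group_names) != length(group_sizes))
    stop("group_names and group_sizes must align")
  if (any(group_sizes < 2L) || min(group_sizes) < 2L)
    stop("every group needs at least 2 subjects")
  if (density <= 0 || density >= 1) stop("density must be in (0, 1)")
  if (any(strength_multipliers <= 0 | strength_multipliers > 1))
    stop("strength multipliers must be in (0, 1]")
  if (is.null(focal_nodes) && n_nodes == 82L)
    focal_nodes <- focal_node_ids()
  if (is.null(focal_nodes)) focal_nodes <- integer(0)
  if (is.null(strength_rho))
    strength_rho <- list(
      working_memory   = c(0.221, -0.518, -0.304),
      processing_speed = c(0.021,  0.167, -0.533),
      memory           = c(0.226, -0.177,  0.115),
      updrs3           = c(NA,     0.008,  0.677))
  bad <- unlist(strength_rho)
  if (any(!is.na(bad) & abs(bad) >= 1))
    stop("correlation targets must lie in (-1, 1)")
  if (abs(education_rho) >= 1)
    stop("correlation targets must lie in (-1, 1)")
  if (is.null(demographics))
    demographics <- list(
      education        = cbind(mean = c(16.75, 16.8, 14.3),
                               sd = c(2.35, 2.91, 2.74)),
      age              = cbind(mean = c(68.18, 67.3, 69.4),
                               sd = c(4.64, 5.02, 6.77)),
      working_memory   = cbind(mean = c(1.15, 0.89, 0.27),
                               sd = c(0.55, 0.77, 0.57)),
      processing_speed = cbind(mean = c(0.16, -0.42, -0.68),
                               sd = c(0.47, 0.56, 0.76)),
      memory           = cbind(mean = c(0.00, -0.32, -1.76),
                               sd = c(1.00, 0.70, 0.20)),
      updrs3           = cbind(mean = c(NA, 18.2, 15.7),
                               sd = c(NA, 11.6, 7.25)))
  structure(list(group_names = group_names,
                 group_sizes = as.integer(group_sizes),
                 n_nodes = as.integer(n_nodes), density = density,
                 weight_meanlog = weight_meanlog, weight_sdlog = weight_sdlog,
                 strength_multipliers = strength_multipliers,
                 focal_nodes = focal_nodes,
                 focal_multipliers = focal_multipliers,
                 subject_sdlog = subject_sdlog, node_sdlog = node_sdlog,
                 edge_sdlog = edge_sdlog,
                 strength_rho = strength_rho, education_rho = education_rho,
                 demographics = demographics, seed = as.integer(seed)),
            class = "cohort_spec")
}

# Gaussian-copula coefficient hitting a Spearman target exactly in
# expectation for bivariate-normal latents.
#' @keywords internal
copula_coef <- function(rho_s) 2 * sin(pi * rho_s / 6)

# Within-group normal scores of a vector (midranks -> N(0,1) quantiles).
#' @keywords internal
normal_scores <- function(v) {
  stats::qnorm((rank(v) - 0.5) / length(v))
}

#' Generate a synthetic grouped cohort
#'
#' Draws one shared edge support at the target density with log-normal base
#' weights, then per subject: multiplies by the group's global strength
#' multiplier, the focal-node multiplier on edges incident to the focal set,
#' and three layers of log-normal noise (per-edge, per-node on incident
#' edges, and a small global subject factor);
#' each subject matrix is rescaled so the group's expected global reduction
#' equals the configured multiplier exactly. Cognitive composites, education,
#' age and the motor score are then generated per group, with each
#' composite's rank correlation to the subject's realised global mean
#' strength and to education injected through a Gaussian copula.
#'
#' @param spec a [cohort_spec()].
#' @return List with `connectomes` (named list of [connectome()]s) and
#'   `cohort` (data.frame: subject, group, education, age, updrs3,
#'   working_memory, processing_speed, memory).
#' @export
make_cohort <- function(spec) {
  set.seed(spec$seed)
  n <- spec$n_nodes
  n_pairs <- n * (n - 1) / 2
  support <- which(stats::runif(n_pairs) < spec$density)
  base_w <- stats::rlnorm(length(support), spec$weight_meanlog,
                          spec$weight_sdlog)
  base <- matrix(0, n, n)
  ut <- which(upper.tri(base))
  base[ut[support]] <- base_w
  base <- base + t(base)
  focal_scale <- function(mult) {
    s <- rep(1, n)
    s[spec$focal_nodes] <- sqrt(mult)  # sqrt so a focal-focal edge gets mult
    outer(s, s)
  }
  subjects <- character(0)
  groups <- character(0)
  connectomes <- list()
  mean_strength <- numeric(0)
  sid <- 0L
  for (g in seq_along(spec$group_names)) {
    F <- focal_scale(spec$focal_multipliers[g])
    expected <- base * F
    # rescale so the group's global strength multiplier is exact
    expected <- expected * (sum(base) / sum(expected)) *
      spec$strength_multipliers[g]
    for (k in seq_len(spec$group_sizes[g])) {
      sid <- sid + 1L
      subj <- sprintf("S%03d", sid)
      noise <- matrix(0, n, n)
      noise[ut] <- stats::rlnorm(n_pairs, 0, spec$edge_sdlog)
      noise <- noise + t(noise)
      node_f <- sqrt(stats::rlnorm(n, 0, spec$node_sdlog))
      W <- expected * noise * outer(node_f, node_f) *
        stats::rlnorm(1, 0, spec$subject_sdlog)
      cn <- connectome(W)
      connectomes[[subj]] <- cn
      subjects <- c(subjects, subj)
      groups <- c(groups, spec$group_names[g])
      mean_strength <- c(mean_strength, mean(node_strength(cn)))
    }
  }
  # cognition, demographics: per-group Gaussian copula against realised
  # global strength and education
  cohort <- data.frame(subject = subjects, group = groups,
                       education = NA_real_, age = NA_real_,
                       updrs3 = NA_real_, working_memory = NA_real_,
                       processing_speed = NA_real_, memory = NA_real_,
                       stringsAsFactors = FALSE)
  for (g in seq_along(spec$group_names)) {
    in_g <- cohort$group == spec$group_names[g]
    n_g <- sum(in_g)
    dg <- function(field) spec$demographics[[field]][g, ]
    edu <- stats::rnorm(n_g, dg("education")["mean"], dg("education")["sd"])
    cohort$education[in_g] <- edu
    cohort$age[in_g] <- stats::rnorm(n_g, dg("age")["mean"], dg("age")["sd"])
    z_s <- normal_scores(mean_strength[in_g])
    z_e <- normal_scores(edu)
    for (ms in c("working_memory", "processing_speed", "memory", "updrs3")) {
      rho_t <- spec$strength_rho[[ms]][g]
      if (is.na(rho_t) || all(is.na(dg(ms)))) next
      a <- copula_coef(rho_t)
      b <- if (ms == "updrs3") 0 else copula_coef(spec$education_rho)
      resid_var <- 1 - a^2 - b^2
      if (resid_var < 0) stop("correlation targets jointly too large")
      latent <- a * z_s + b * z_e +
        sqrt(resid_var) * stats::rnorm(n_g)
      val <- dg(ms)["mean"] + dg(ms)["sd"] * latent
      if (ms == "updrs3") val <- pmax(0, val)
      cohort[[ms]][in_g] <- val
    }
  }
  list(connectomes = connectomes, cohort = cohort)
}

#' Synthetic p-value mixtures
#'
#' `n * pi0` uniform null p-values plus `n * (1 - pi0)` alternative p-values
#' from one-sided normal tests with the given effect size
#' (`p = 1 - Phi(Z)`, `Z ~ N(effect, 1)`), shuffled.
#'
#' @param n total count.
#' @param pi0 null proportion in `[0, 1]`.
#' @param effect mean of the alternative test statistic.
#' @param seed integer seed.
#' @return Numeric vector of n p-values.
#' @export
make_pvalue_mixture <- function(n, pi0, effect = 3, seed = 1L) {
  if (pi0 < 0 || pi0 > 1) stop("pi0 must be in [0, 1]")
  set.seed(seed)
  n0 <- round(n * pi0)
  p <- c(stats::runif(n0),
         stats::pnorm(stats::rnorm(n - n0, mean = effect),
                      lower.tail = FALSE))
  sample(p)
}

#' Read/write generator specs as YAML
#'
#' @param spec a [phantom_spec()] or [cohort_spec()].
#' @param path YAML file path.
#' @return The spec (reader) or `path` invisibly (writer).
#' @export
write_spec_yaml <- function(spec, path) {
  kind <- class(spec)[1]
  payload <- unclass(spec)
  if (kind == "phantom_spec") payload$bundles <- as.list(payload$bundles)
  if (kind == "cohort_spec")
    payload$demographics <- lapply(payload$demographics, function(m)
      list(mean = unname(m[, "mean"]), sd = unname(m[, "sd"])))
  yaml::write_yaml(list(kind = kind, spec = payload), path, precision = 15)
  invisible(path)
}

#' @rdname write_spec_yaml
#' @export
read_spec_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  sp <- raw$spec
  if (raw$kind == "phantom_spec") {
    sp$bundles <- as.data.frame(sp$bundles)
    do.call(phantom_spec, sp[setdiff(names(sp), character(0))])
  } else if (raw$kind == "cohort_spec") {
    sp$demographics <- lapply(sp$demographics, function(d)
      cbind(mean = unlist(d$mean), sd = unlist(d$sd)))
    sp$strength_rho <- lapply(sp$strength_rho, unlist)
    do.call(cohort_spec, sp)
  } else stop("unknown spec kind: ", raw$kind)
}
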