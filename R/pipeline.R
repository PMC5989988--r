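#' Configuration of a full analysis run
#'
#' @param covariate_name covariate partialled out of the cognition
#'   correlations (`"education"`, default, or `"age"`).
#' @param r_threshold node-level strong-correlation threshold on `|rho|`
#'   (default 0.50).
#' @param z_threshold global strong-correlation threshold on `|z|`
#'   (default 0.55).
#' @param alpha significance level for group comparisons (default 0.05).
#' @param null_ensemble_size Erdos-Renyi realisations for small-worldness
#'   (default 20).
#' @param correction multiple-comparison mode for local families
#'   (`"grenander"`, default, or `"BH"`).
#' @param local_node_source `"significant"` (default: local correlations run
#'   on the nodes whose strength differs significantly between the first
#'   and last group after correction) or `"all"`.
#' @param seed integer seed (drives the small-world ensembles).
#' @return An object of class `run_config`.
#' @export
run_config <- function(covariate_name = "education",
                       r_threshold = 0.50, z_threshold = 0.55,
                       alpha = 0.05, null_ensemble_size = 20,
                       correction = c("grenander", "BH"),
                       local_node_source = c("significant", "all"),
                       seed = 1L) {
  stopifnot(r_threshold > 0, r_threshold < 1,
            z_threshold > 0, alpha > 0, alpha < 1)
  structure(list(covariate_name = covariate_name,
                 r_threshold = r_threshold, z_threshold = z_threshold,
                 alpha = alpha, null_ensemble_size = null_ensemble_size,
                 correction = match.arg(correction),
                 local_node_source = match.arg(local_node_source),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Topology profiles for a set of subjects
#'
#' @param connectomes named list of [connectome()]s keyed by subject id.
#' @param small_world compute small-worldness per subject (slower; default
#'   TRUE).
#' @param n_realizations,seed ensemble parameters for [small_worldness()].
#' @return Named list of `topology_profile`s; when `small_world` is TRUE
#'   each profile's `global` gains a `small_worldness` entry.
#' @export
profile_subjects <- function(connectomes, small_world = TRUE,
                             n_realizations = 20, seed = 1L) {
  out <- vector("list", length(connectomes))
  names(out) <- names(connectomes)
  for (i in seq_along(connectomes)) {
    prof <- global_indices(connectomes[[i]])
    if (small_world) {
      sw <- small_worldness(connectomes[[i]], n_realizations,
                            seed = seed + i)
      prof$global <- c(prof$global, small_worldness = sw$S)
    }
    out[[i]] <- prof
  }
  out
}

#' Run the full study workflow
#'
#' From per-subject connectomes and a cohort table to all result tables:
#' per-subject topology profiles (with small-worldness), global group
#' comparisons (raw Mann-Whitney), local group comparisons (density-adjusted
#' Mann-Whitney with the Grenander false-nondiscovery correction per
#' (index, group-pair) family), cognition correlation records (global and
#' over the significant-node set) and the strong-correlation count
#' matrices. Deterministic for a fixed config.
#'
#' @param connectomes named list of [connectome()]s keyed by subject id.
#' @param cohort cohort data.frame (see [make_cohort()] for the columns).
#' @param config a [run_config()].
#' @param output_dir optional directory; when given, all tables are written
#'   as TSV plus a machine-readable JSON manifest.
#' @return List with `profiles`, `global_comparisons`, `local_comparisons`,
#'   `significant_nodes`, `global_correlations`, `local_correlations`,
#'   `correlation_counts` and `config`.
#' @export
run_full_analysis <- function(connectomes, cohort, config = run_config(),
                              output_dir = NULL) {
  missing_conn <- setdiff(cohort$subject, names(connectomes))
  extra_conn <- setdiff(names(connectomes), cohort$subject)
  if (length(missing_conn) || length(extra_conn))
    stop("subject mismatch between connectomes and cohort table; missing: [",
         paste(missing_conn, collapse = ", "), "], unmatched: [",
         paste(extra_conn, collapse = ", "), "]")
  message(sprintf("profiling %d subjects", length(connectomes)))
  profiles <- profile_subjects(connectomes,
                               n_realizations = config$null_ensemble_size,
                               seed = config$seed)
  glob <- compare_groups(profiles, cohort, scope = "global",
                         indices = c("strength", "clustering", "path_length",
                                     "small_worldness"))
  loc <- compare_groups(profiles, cohort, scope = "local",
                        correction = config$correction)
  message(sprintf("ran %d global and %d local comparisons",
                  nrow(glob), nrow(loc)))
  # significant node set: strength differences between the first and last
  # groups after correction
  g_first <- unique(as.character(cohort$group))[1]
  g_last <- utils::tail(unique(as.character(cohort$group)), 1)
  sig <- loc$index == "strength" & loc$p_adjusted < config$alpha &
    ((loc$group_a == g_first & loc$group_b == g_last) |
       (loc$group_a == g_last & loc$group_b == g_first))
  sig_nodes <- unique(loc$node[sig])
  node_set <- if (config$local_node_source == "all" ||
                  length(sig_nodes) == 0L) NULL else sig_nodes
  gcor <- correlate_cohort(profiles, cohort, scope = "global",
                           covariate_name = config$covariate_name,
                           indices = c("strength", "clustering",
                                       "path_length", "small_worldness"),
                           r_threshold = config$r_threshold,
                           z_threshold = config$z_threshold)
  lcor <- suppressWarnings(
    correlate_cohort(profiles, cohort, scope = "local",
                     covariate_name = config$covariate_name,
                     node_set = node_set,
                     r_threshold = config$r_threshold,
                     z_threshold = config$z_threshold))
  counts <- strong_correlation_counts(lcor, threshold = config$r_threshold)
  result <- list(profiles = profiles, global_comparisons = glob,
                 local_comparisons = loc, significant_nodes = sig_nodes,
                 global_correlations = gcor, local_correlations = lcor,
                 correlation_counts = counts, config = config)
  if (!is.null(output_dir)) write_result_bundle(result, cohort, output_dir)
  result
}

#' @keywords internal
write_result_bundle <- function(result, cohort, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  prof_dir <- file.path(output_dir, "profiles")
  dir.create(prof_dir, showWarnings = FALSE)
  for (s in names(result$profiles))
    write_topology_tsv(result$profiles[[s]],
                       file.path(prof_dir, paste0(s, ".tsv")))
  tsv <- function(df, name)
    utils::write.table(df, file.path(output_dir, name), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  tsv(result$global_comparisons, "global_comparisons.tsv")
  tsv(result$local_comparisons, "local_comparisons.tsv")
  tsv(result$global_correlations, "global_correlations.tsv")
  tsv(result$local_correlations, "local_correlations.tsv")
  tsv(result$correlation_counts$counts, "correlation_counts.tsv")
  manifest <- list(
    package_version = as.character(utils::packageVersion("streamnet")),
    config = unclass(result$config),
    n_subjects = nrow(cohort),
    groups = as.list(table(cohort$group)),
    significant_nodes = result$significant_nodes)
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(output_dir)
}
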