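#' The 27-node focal set with reduced connectivity
#'
#' Labels (with hemisphere) of the 27 regions where node strength is focally
#' reduced in the memory-impaired disease phenotype: bilateral putamen,
#' caudal middle frontal, inferior parietal, postcentral, posterior
#' cingulate, precentral and precuneus, plus nine further left-hemisphere and
#' four further right-hemisphere regions. Used as the default focal set by
#' [cohort_spec()] and as the node set for local cognition correlations.
#'
#' @return A data.frame with columns `label` and `hemisphere` (27 rows).
#' @export
pd_focal_nodes <- function() {
  bilateral <- c("putamen", "caudal middle frontal", "inferior parietal",
                 "postcentral", "posterior cingulate", "precentral",
                 "precuneus")
  left_only <- c("pallidum", "entorhinal", "isthmus cingulate",
                 "middle temporal", "pars opercularis", "bankssts",
                 "supramarginal", "rostral middle frontal",
                 "superior temporal")
  right_only <- c("lateral occipital", "rostral anterior cingulate",
                  "rostral middle frontal", "superior parietal")
  data.frame(
    label = c(bilateral, left_only, bilateral, right_only),
    hemisphere = rep(c("left", "right"),
                     c(length(bilateral) + length(left_only),
                       length(bilateral) + length(right_only))),
    stringsAsFactors = FALSE)
}

#' @keywords internal
focal_node_ids <- function(nodes = dk82_nodes()) {
  focal <- pd_focal_nodes()
  idx <- match(paste(focal$hemisphere, focal$label),
               paste(nodes$hemisphere, nodes$label))
  if (anyNA(idx)) stop("focal node labels not found in the node table")
  nodes$id[idx]
}
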