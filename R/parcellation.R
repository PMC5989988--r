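#' Node parcellation
#'
#' A parcellation is the list of gray-matter regions that become connectome
#' nodes: each region carries an id, a label, a hemisphere, its surface area
#' `A_i` (mm^2, used by the edge-weight normalisation) and the set of grid
#' voxels it occupies. Region voxel sets must be pairwise disjoint.
#'
#' @param regions a list where each element has fields `id`, `label`,
#'   `hemisphere` ("left", "right" or "none"), `surface_area_mm2` (> 0) and
#'   `voxels` (matrix of 0-based voxel indices, n x 3).
#' @param grid the [voxel_grid()] the voxel indices refer to.
#' @return An object of class `parcellation`: a list with `nodes`
#'   (data.frame of metadata), `voxel_keys` (list of linear voxel keys per
#'   node) and `grid`.
#' @export
parcellation <- function(regions, grid) {
  ids <- vapply(regions, function(r) as.integer(r$id), integer(1))
  if (anyDuplicated(ids)) stop("node ids must be unique")
  labels <- vapply(regions, function(r) as.character(r$label), character(1))
  hemis <- vapply(regions, function(r) as.character(r$hemisphere), character(1))
  if (!all(hemis %in% c("left", "right", "none")))
    stop("hemisphere must be 'left', 'right' or 'none'")
  areas <- vapply(regions, function(r) as.numeric(r$surface_area_mm2),
                  numeric(1))
  if (any(!is.finite(areas)) || any(areas <= 0))
    stop("surface areas must be positive and finite")
  keys <- lapply(regions, function(r) {
    v <- r$voxels
    if (is.null(dim(v))) v <- matrix(v, ncol = 3L, byrow = TRUE)
    v <- matrix(as.integer(v), ncol = 3L)
    if (nrow(v) == 0L) stop("every node needs at least one voxel")
    if (!all(voxel_in_grid(grid, v))) stop("node voxels outside the grid")
    sort(unique(voxel_key(grid, v)))
  })
  all_keys <- unlist(keys)
  if (anyDuplicated(all_keys))
    stop("node voxel sets overlap; parcellation voxel sets must be disjoint")
  ord <- order(ids)
  structure(
    list(nodes = data.frame(id = ids[ord], label = labels[ord],
                            hemisphere = hemis[ord],
                            surface_area_mm2 = areas[ord],
                            stringsAsFactors = FALSE),
         voxel_keys = keys[ord],
         grid = grid),
    class = "parcellation")
}

#' @export
print.parcellation <- function(x, ...) {
  cat(sprintf("parcellation: %d nodes, %d voxels total\n",
              nrow(x$nodes), length(unlist(x$voxel_keys))))
  invisible(x)
}

#' Read a parcellation from JSON
#'
#' The file is a JSON array of objects
#' `{id, label, hemisphere, surface_area_mm2, voxels: [[i,j,k], ...]}` with
#' 0-based voxel indices.
#'
#' @param path JSON file path.
#' @param grid the [voxel_grid()] the voxel indices refer to.
#' @return A [parcellation()].
#' @export
read_parcellation <- function(path, grid) {
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                            simplifyMatrix = TRUE)
  parcellation(lapply(raw, function(r) {
    r$voxels <- do.call(rbind, lapply(r$voxels, as.integer))
    r
  }), grid)
}

#' Write a parcellation to JSON
#'
#' @param p a [parcellation()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_parcellation <- function(p, path) {
  regions <- lapply(seq_len(nrow(p$nodes)), function(i) {
    vox <- key_to_voxel(p$grid, p$voxel_keys[[i]])
    list(id = p$nodes$id[i], label = p$nodes$label[i],
         hemisphere = p$nodes$hemisphere[i],
         surface_area_mm2 = p$nodes$surface_area_mm2[i],
         voxels = lapply(seq_len(nrow(vox)), function(k) unname(vox[k, ])))
  })
  jsonlite::write_json(regions, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' The 82-region cortical + subcortical node set
#'
#' Returns the standard 82-node parcellation labelling used throughout the
#' analyses: 34 Desikan-Killiany cortical regions plus 7 subcortical
#' structures per hemisphere. Only the labels and hemispheres are fixed
#' anatomy; voxel memberships and surface areas come from each subject's
#' segmentation and are not part of this table.
#'
#' @return A data.frame with columns `id`, `label`, `hemisphere` (82 rows,
#'   left hemisphere first).
#' @export
dk82_nodes <- function() {
  path <- system.file("extdata", "dk82_nodes.csv", package = "streamnet",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
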