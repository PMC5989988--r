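#' Streamlines and tractograms
#'
#' A streamline is an ordered 3-D polyline (mm coordinates) produced by fiber
#' tracking, together with the provenance of its seed: the 0-based grid index
#' of the voxel containing the seed point, and the index of that seed within
#' the voxel (tracking runs place `P_voxel` seeds in every seeded voxel).
#'
#' @param points numeric matrix, n x 3, ordered polyline vertices in mm
#'   (n >= 2).
#' @param seed_voxel integer vector of length 3, 0-based voxel index of the
#'   seed point.
#' @param seed_index integer in `[1, P_voxel]`, which of the voxel's seeds
#'   started this streamline.
#' @return An object of class `streamline`.
#' @export
streamline <- function(points, seed_voxel, seed_index = 1L) {
  points <- as.matrix(points)
  if (nrow(points) < 2L)
    stop("degenerate streamline: fewer than 2 points")
  if (ncol(points) != 3L) stop("streamline points must be n x 3")
  if (!all(is.finite(points))) stop("streamline points must be finite")
  structure(
    list(points = unname(points),
         seed_voxel = as.integer(seed_voxel),
         seed_index = as.integer(seed_index)),
    class = "streamline")
}

#' Arc length of a streamline
#'
#' Sum of Euclidean segment lengths along the polyline, in mm.
#'
#' @param s a [streamline()].
#' @return Positive scalar length in mm.
#' @examples
#' s <- streamline(rbind(c(0, 0, 0), c(3, 0, 0), c(3, 4, 0)), c(0, 0, 0))
#' streamline_arclength(s)  # 7
#' @export
streamline_arclength <- function(s) {
  p <- s$points
  if (nrow(p) < 2L) stop("degenerate streamline: fewer than 2 points")
  d <- diff(p)
  len <- sum(sqrt(rowSums(d * d)))
  if (len <= 0) stop("degenerate streamline: zero arc length")
  len
}

#' Assemble a tractogram
#'
#' @param grid a [voxel_grid()].
#' @param streamlines list of [streamline()] objects.
#' @param seeds_per_voxel `P_voxel`, the number of seed points placed in each
#'   seeded voxel (>= 1). The edge-weight normalisation divides by this count
#'   so connectome weights do not depend on the seeding paradigm.
#' @return An object of class `tractogram`.
#' @export
tractogram <- function(grid, streamlines, seeds_per_voxel) {
  seeds_per_voxel <- as.integer(seeds_per_voxel)
  if (is.na(seeds_per_voxel) || seeds_per_voxel < 1L)
    stop("`seeds_per_voxel` (P_voxel) must be >= 1")
  for (s in streamlines) {
    if (!inherits(s, "streamline")) stop("all elements must be streamlines")
    if (!voxel_in_grid(grid, s$seed_voxel))
      stop("streamline seed voxel outside the grid")
    if (s$seed_index < 1L || s$seed_index > seeds_per_voxel)
      stop("streamline seed_index outside [1, P_voxel]")
  }
  structure(
    list(grid = grid, streamlines = streamlines,
         seeds_per_voxel = seeds_per_voxel),
    class = "tractogram")
}

#' @export
print.tractogram <- function(x, ...) {
  cat(sprintf("tractogram: %d streamlines, P_voxel = %d\n",
              length(x$streamlines), x$seeds_per_voxel))
  print(x$grid)
  invisible(x)
}

#' Write a tractogram in the native line-delimited format
#'
#' One streamline per line:
#' `seed_i seed_j seed_k <tab> seed_index <tab> x1,y1,z1; x2,y2,z2; ...`
#' preceded by a `#`-header carrying the grid shape, voxel edges (mm) and
#' `P_voxel`. Voxel indices are 0-based; a point belongs to voxel
#' `floor(coord/edge)` (half-open boxes).
#'
#' @param t a [tractogram()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tractogram <- function(t, path) {
  header <- c(
    "# streamnet tractogram v1",
    "# coordinates: mm; voxel indices 0-based; voxel = floor(coord/edge), half-open boxes",
    sprintf("# grid_shape: %s", paste(t$grid$shape, collapse = " ")),
    sprintf("# voxel_edges_mm: %s",
            paste(format(t$grid$voxel_edges, digits = 17), collapse = " ")),
    sprintf("# seeds_per_voxel: %d", t$seeds_per_voxel))
  body <- vapply(t$streamlines, function(s) {
    pts <- apply(s$points, 1L, function(p)
      paste(format(p, digits = 17, trim = TRUE), collapse = ","))
    paste(paste(s$seed_voxel, collapse = " "), s$seed_index,
          paste(pts, collapse = "; "), sep = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a tractogram from the native line-delimited format
#'
#' @param path file written by [write_tractogram()].
#' @return A [tractogram()].
#' @export
read_tractogram <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) {
    ln <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    if (length(ln) != 1L) stop("tractogram header missing field: ", key)
    strsplit(sub(paste0("^# ", key, ": *"), "", ln), " +")[[1]]
  }
  grid <- voxel_grid(as.integer(get("grid_shape")),
                     as.numeric(get("voxel_edges_mm")))
  p_voxel <- as.integer(get("seeds_per_voxel"))
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  sls <- lapply(body, function(ln) {
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(fields) != 3L) stop("malformed streamline record: ", ln)
    seed <- as.integer(strsplit(fields[1], " +")[[1]])
    pts <- do.call(rbind, lapply(
      strsplit(fields[3], ";", fixed = TRUE)[[1]],
      function(pt) as.numeric(strsplit(trimws(pt), ",", fixed = TRUE)[[1]])))
    streamline(pts, seed, as.integer(fields[2]))
  })
  tractogram(grid, sls, p_voxel)
}

#' Read a TrackVis TRK streamline file
#'
#' Minimal adapter for the TrackVis TRK format (version 2, little-endian):
#' reads the 1000-byte header for dimensions, voxel sizes and streamline
#' count, then the point blocks. TRK stores points in voxel-scaled mm
#' ("voxmm") coordinates, which match this package's mm convention when the
#' vox_to_ras transform is the identity scaling. Seed provenance is not part
#' of TRK; the seed voxel is taken as the voxel containing the first point,
#' with `seed_index = 1`.
#'
#' @param path path to a `.trk` file.
#' @param seeds_per_voxel value of `P_voxel` used by the tracking run; TRK
#'   does not record it, so it must be supplied (default 1).
#' @return A [tractogram()].
#' @export
read_trk <- function(path, seeds_per_voxel = 1L) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 5L))
  readBin(con, "raw", 1L)  # id_string padding byte
  if (magic != "TRACK") stop("not a TRK file (bad magic)")
  dim3 <- readBin(con, "integer", 3L, size = 2L, endian = "little")
  voxel_size <- readBin(con, "numeric", 3L, size = 4L, endian = "little")
  seek(con, 36L)  # origin (12) skipped
  n_scalars <- readBin(con, "integer", 1L, size = 2L, endian = "little")
  seek(con, 238L)  # scalar names (200) skipped
  n_properties <- readBin(con, "integer", 1L, size = 2L, endian = "little")
  seek(con, 988L)
  n_count <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  version <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  hdr_size <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (hdr_size != 1000L) stop("unsupported TRK header size: ", hdr_size)
  grid <- voxel_grid(dim3, voxel_size)
  sls <- vector("list", max(n_count, 0L))
  i <- 0L
  repeat {
    n_pts <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (length(n_pts) == 0L) break
    block <- readBin(con, "numeric", n_pts * (3L + n_scalars), size = 4L,
                     endian = "little")
    if (n_properties > 0L)
      readBin(con, "numeric", n_properties, size = 4L, endian = "little")
    pts <- matrix(block, ncol = 3L + n_scalars, byrow = TRUE)[, 1:3,
                                                              drop = FALSE]
    i <- i + 1L
    sls[[i]] <- streamline(pts, point_to_voxel(grid, pts[1L, ]))
  }
  tractogram(grid, sls[seq_len(i)], seeds_per_voxel)
}
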