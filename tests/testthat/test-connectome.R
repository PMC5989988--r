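# Small hand-built scene: two 2x2x2-voxel nodes on a 1 mm grid joined by a
# straight corridor along x, used by several tests below.
two_node_scene <- function(edge = 1, p_voxel = 1L, n_streamlines = 1L,
                           area = 100) {
  g <- voxel_grid(c(30, 6, 6), edge)
  mk_node <- function(id, i0) list(
    id = id, label = paste0("node", id), hemisphere = "none",
    surface_area_mm2 = area,
    voxels = as.matrix(expand.grid(i = i0:(i0 + 1L), j = 2:3, k = 2:3)))
  parc <- parcellation(list(mk_node(1L, 1L), mk_node(2L, 12L)), g)
  # straight polyline from inside node 1 to inside node 2, 10*edge mm long
  a <- c(2.5, 3.5, 3.5) * edge
  b <- c(12.5, 3.5, 3.5) * edge
  mid_voxel <- point_to_voxel(g, (a + b) / 2)[1, ]
  sls <- replicate(n_streamlines,
                   streamline(rbind(a, b), mid_voxel, 1L),
                   simplify = FALSE)
  list(grid = g, parc = parc,
       tract = tractogram(g, sls, p_voxel), a = a, b = b)
}

test_that("segmentation assigns streamlines by endpoint containment", {
  sc <- two_node_scene()
  seg <- segment_tractogram(sc$tract, sc$parc)
  expect_named(seg, "1|2")
  expect_equal(seg[["1|2"]], 1L, ignore_attr = TRUE)

  # both endpoints in node 1 -> unassigned self-loop; dangling end -> unassigned
  g <- sc$grid
  loops <- list(
    streamline(rbind(c(2.5, 2.5, 2.5), c(1.5, 3.5, 3.5)),
               point_to_voxel(g, c(2.5, 3, 3))[1, ], 1L),
    streamline(rbind(c(2.5, 3.5, 3.5), c(25, 3, 3)),
               point_to_voxel(g, c(8, 3, 3))[1, ], 1L))
  t2 <- tractogram(g, loops, 1L)
  seg2 <- segment_tractogram(t2, sc$parc)
  expect_length(seg2, 0L)
  expect_equal(unname(attr(seg2, "dropped")), c(1L, 1L))
})

test_that("phantom bundles are recovered with exact sizes", {
  sp <- phantom_spec(n_nodes = 3,
                     bundles = data.frame(node_i = c(1, 2), node_j = c(2, 3),
                                          n_streamlines = c(20L, 20L),
                                          length_mm = NA_real_),
                     seeds_per_voxel = 25)
  ph <- make_phantom(sp)
  seg <- segment_tractogram(ph$tractogram, ph$parcellation)
  expect_setequal(names(seg), c("1|2", "2|3"))
  expect_equal(lengths(seg)[["1|2"]], 20L)
  expect_equal(lengths(seg)[["2|3"]], 20L)
})

test_that("characteristic filter keeps only corridor-seeded streamlines", {
  sc <- two_node_scene()
  seg <- segment_tractogram(sc$tract, sc$parc)
  occ <- edge_occupancy(sc$tract, sc$parc, 1L, 2L, seg[["1|2"]])
  # corridor-seeded: retained
  expect_equal(characteristic_filter(sc$tract$streamlines[[1]], occ, sc$parc), 1L)
  # seeded inside node 1's mask: eliminated
  s_node <- streamline(sc$tract$streamlines[[1]]$points, c(2L, 2L, 2L), 1L)
  expect_equal(characteristic_filter(s_node, occ, sc$parc), 0L)
  # seeded off the white-matter path: eliminated
  s_off <- streamline(sc$tract$streamlines[[1]]$points, c(25L, 5L, 5L), 1L)
  expect_equal(characteristic_filter(s_off, occ, sc$parc), 0L)
  # R never contains node voxels
  node_keys <- unlist(sc$parc$voxel_keys)
  expect_length(intersect(occ$voxels, node_keys), 0L)
})

test_that("edge weight matches its closed form", {
  # one retained streamline, l = 10 mm, A = 100 mm^2 each, V = 1, P = 1
  sc <- two_node_scene()
  seg <- segment_tractogram(sc$tract, sc$parc)
  occ <- edge_occupancy(sc$tract, sc$parc, 1L, 2L, seg[["1|2"]])
  w <- edge_weight(sc$tract, occ, sc$parc$nodes[1, ], sc$parc$nodes[2, ])
  expect_equal(w, (2 / 200) * (1 / 1) * (1 / 10))

  # no retained streamlines -> 0
  occ0 <- occ
  occ0$streamline_refs <- integer(0)
  expect_equal(edge_weight(sc$tract, occ0, sc$parc$nodes[1, ],
                           sc$parc$nodes[2, ]), 0)

  # 50 streamlines, l = 20 mm, A = 400 each, V = 8, P = 125:
  # (2/800) * (8/125) * (50/20) = 4e-4, cross-checked by per-streamline
  # accumulation
  sp <- phantom_spec(n_nodes = 2,
                     bundles = data.frame(node_i = 1, node_j = 2,
                                          n_streamlines = 50L,
                                          length_mm = NA_real_),
                     voxel_edge_mm = 2, node_size_voxels = 2,
                     spacing_mm = 20, seeds_per_voxel = 125)
  ph <- make_phantom(sp)
  # node cuboids are 4 mm cubes -> A = 6 * 16 = 96; rescale metadata to the
  # worked example's A = 400 to test the normalisation arithmetic
  ph$parcellation$nodes$surface_area_mm2 <- 400
  seg <- segment_tractogram(ph$tractogram, ph$parcellation)
  occ <- edge_occupancy(ph$tractogram, ph$parcellation, 1L, 2L, seg[["1|2"]])
  w <- edge_weight(ph$tractogram, occ,
                   ph$parcellation$nodes[1, ], ph$parcellation$nodes[2, ])
  expect_equal(w, 4e-4)
  acc <- 0
  for (k in occ$streamline_refs)
    acc <- acc + (2 / 800) * (8 / 125) /
      streamline_arclength(ph$tractogram$streamlines[[k]])
  expect_equal(w, acc)

  bad_nodes <- data.frame(surface_area_mm2 = 0)
  expect_error(edge_weight(sc$tract, occ, bad_nodes, bad_nodes),
               "invalid geometry")
})

test_that("connectome construction is symmetric, diagonal-free, thresholdless", {
  sp <- phantom_spec(n_nodes = 4, seeds_per_voxel = 25, seed = 3)
  ph <- make_phantom(sp)
  cn <- build_connectome(ph$tractogram, ph$parcellation)
  expect_true(isSymmetric(unclass(cn)))
  expect_equal(unname(diag(cn)), rep(0, 4))
  expect_true(all(cn >= 0))
  # support equals the ground-truth bundle list
  got <- which(upper.tri(cn) & cn > 0, arr.ind = TRUE)
  expect_equal(nrow(got), nrow(ph$bundles))

  # empty tractogram -> all-zero matrix with a warning
  t0 <- tractogram(ph$tractogram$grid, list(), 25L)
  expect_warning(cn0 <- build_connectome(t0, ph$parcellation), "empty")
  expect_equal(sum(cn0), 0)

  # grid mismatch is refused
  other <- voxel_grid(ph$tractogram$grid$shape, 3)
  t_bad <- tractogram(other, ph$tractogram$streamlines, 25L)
  expect_error(build_connectome(t_bad, ph$parcellation), "different grids")
})

test_that("node relabeling conjugates the weight matrix", {
  sp <- phantom_spec(n_nodes = 5, seeds_per_voxel = 10, seed = 2)
  ph <- make_phantom(sp)
  cn <- build_connectome(ph$tractogram, ph$parcellation)
  perm <- c(3L, 1L, 5L, 2L, 4L)
  # relabel node ids by perm and rebuild
  parc2 <- ph$parcellation
  parc2$nodes$id <- perm
  ord <- order(parc2$nodes$id)
  parc2$nodes <- parc2$nodes[ord, ]
  parc2$voxel_keys <- parc2$voxel_keys[ord]
  cn2 <- build_connectome(ph$tractogram, parc2)
  expect_equal(unclass(cn2)[perm, perm], unclass(cn), ignore_attr = TRUE)
})

test_that("edge weights are invariant to P_voxel under proportional re-seeding", {
  mk <- function(p_voxel, n_s) {
    sp <- phantom_spec(n_nodes = 4, seeds_per_voxel = p_voxel,
                       bundles = data.frame(
                         node_i = c(1, 2, 3), node_j = c(2, 3, 4),
                         n_streamlines = n_s, length_mm = NA_real_))
    ph <- make_phantom(sp)
    build_connectome(ph$tractogram, ph$parcellation)
  }
  c1 <- mk(25L, 50L)
  c2 <- mk(50L, 100L)
  expect_equal(unclass(c1), unclass(c2), tolerance = 1e-12)
})

test_that("edge weights are dimensionless: global unit rescaling is a no-op", {
  mk <- function(s) {
    sp <- phantom_spec(n_nodes = 4, voxel_edge_mm = 2 * s,
                       spacing_mm = 20 * s, spurious_length_mm = 40 * s,
                       seeds_per_voxel = 25)
    ph <- make_phantom(sp)
    build_connectome(ph$tractogram, ph$parcellation)
  }
  expect_equal(as.vector(mk(1)), as.vector(mk(10)), tolerance = 1e-12)
  expect_equal(as.vector(mk(1)), as.vector(mk(0.1)), tolerance = 1e-12)
})

test_that("adding a retained streamline strictly increases the edge weight", {
  base <- two_node_scene(n_streamlines = 3L)
  more <- two_node_scene(n_streamlines = 4L)
  w_of <- function(sc) {
    seg <- segment_tractogram(sc$tract, sc$parc)
    occ <- edge_occupancy(sc$tract, sc$parc, 1L, 2L, seg[["1|2"]])
    edge_weight(sc$tract, occ, sc$parc$nodes[1, ], sc$parc$nodes[2, ])
  }
  expect_gt(w_of(more), w_of(base))
})

test_that("FA weighting averages the field over the edge voxels", {
  sc <- two_node_scene()
  seg <- segment_tractogram(sc$tract, sc$parc)
  occ <- edge_occupancy(sc$tract, sc$parc, 1L, 2L, seg[["1|2"]])
  fa_const <- scalar_field(sc$grid, 0.5)
  expect_equal(fa_edge_weight(occ, fa_const), 0.5)

  # two-voxel occupancy with FA 0.2 and 0.6 -> mean 0.4
  vals <- array(0, dim = sc$grid$shape)
  occ2 <- occ
  occ2$voxels <- occ$voxels[1:2]
  vals[occ2$voxels[1]] <- 0.2
  vals[occ2$voxels[2]] <- 0.6
  expect_equal(fa_edge_weight(occ2, scalar_field(sc$grid, vals)), 0.4)

  # empty occupancy -> undefined edge
  occ0 <- occ
  occ0$voxels <- integer(0)
  expect_true(is.na(fa_edge_weight(occ0, fa_const)))

  # FA outside [0, 1] is rejected at field construction
  expect_error(scalar_field(sc$grid, 1.2), "outside")

  # uniform field: every edge of a phantom connectome gets the same weight
  sp <- phantom_spec(n_nodes = 4, seeds_per_voxel = 10)
  ph <- make_phantom(sp)
  fa <- scalar_field(ph$tractogram$grid, 0.5)
  cn <- build_connectome(ph$tractogram, ph$parcellation, weighting = "fa",
                         fa = fa)
  expect_true(all(cn[cn > 0] == 0.5))
})

test_that("connectome CSV and edge-list formats round-trip", {
  set.seed(4)
  W <- random_weight_matrix(6)
  cn <- connectome(W, labels = paste0("region", 1:6))
  f_csv <- withr::local_tempfile(fileext = ".csv")
  f_tsv <- withr::local_tempfile(fileext = ".tsv")
  write_connectome_csv(cn, f_csv)
  back <- read_connectome_csv(f_csv)
  expect_equal(unclass(back), unclass(cn), tolerance = 1e-12)
  write_edge_list(cn, f_tsv)
  back2 <- read_edge_list(f_tsv)
  expect_equal(unclass(back2), unclass(cn), tolerance = 1e-12)
})

test_that("parcellation JSON round-trips and rejects overlap", {
  g <- voxel_grid(c(10, 10, 10), 2)
  r1 <- list(id = 1, label = "a", hemisphere = "left",
             surface_area_mm2 = 50, voxels = rbind(c(0, 0, 0), c(1, 0, 0)))
  r2 <- list(id = 2, label = "b", hemisphere = "right",
             surface_area_mm2 = 60, voxels = rbind(c(5, 5, 5)))
  p <- parcellation(list(r1, r2), g)
  f <- withr::local_tempfile(fileext = ".json")
  write_parcellation(p, f)
  p2 <- read_parcellation(f, g)
  expect_equal(p2$nodes, p$nodes)
  expect_equal(p2$voxel_keys, p$voxel_keys)

  r3 <- list(id = 3, label = "c", hemisphere = "none",
             surface_area_mm2 = 10, voxels = rbind(c(1, 0, 0)))
  expect_error(parcellation(list(r1, r3), g), "overlap")
})

test_that("the shipped 82-node table has the expected structure", {
  nodes <- dk82_nodes()
  expect_equal(nrow(nodes), 82L)
  expect_equal(sum(nodes$hemisphere == "left"), 41L)
  focal <- pd_focal_nodes()
  expect_equal(nrow(focal), 27L)
  ids <- focal_node_ids(nodes)
  expect_length(unique(ids), 27L)
  expect_true(all(ids %in% nodes$id))
})
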