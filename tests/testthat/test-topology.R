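test_that("graph density counts realised edge fractions", {
  n <- 5
  full <- connectome(matrix(1, n, n) - diag(n))
  expect_equal(graph_density(full), 1)
  empty <- connectome(matrix(0, n, n))
  expect_equal(graph_density(empty), 0)
  expect_error(graph_density(matrix(0, 1, 1)), "at least 2")

  # 82 nodes with exactly 1328 positive pairs: 1328/3321 = 0.39988
  W <- matrix(0, 82, 82)
  ut <- which(upper.tri(W))
  W[ut[seq_len(1328)]] <- 1
  cn <- connectome(W + t(W))
  expect_equal(graph_density(cn), 1328 / 3321)
  expect_equal(round(graph_density(cn), 4), 0.3999)
})

test_that("node strength equals explicit row summation", {
  W <- matrix(0, 4, 4)
  W[1, 2] <- W[2, 1] <- 0.1
  W[1, 3] <- W[3, 1] <- 0.2
  W[1, 4] <- W[4, 1] <- 0.3
  cn <- connectome(W)
  expect_equal(unname(node_strength(cn, 1)), 0.6)
  # isolated node
  W2 <- matrix(0, 3, 3); W2[1, 2] <- W2[2, 1] <- 1
  expect_equal(unname(node_strength(connectome(W2), 3)), 0)
  # random matrix vs independent elementwise oracle
  set.seed(11)
  W3 <- random_weight_matrix(10)
  s_oracle <- vapply(1:10, function(i) sum(vapply(1:10, function(j)
    W3[i, j], numeric(1))), numeric(1))
  expect_equal(unname(node_strength(connectome(W3))), s_oracle)
})

test_that("weighted clustering matches brute-force triple enumeration", {
  tri_equal <- connectome(rbind(c(0, 1, 1), c(1, 0, 1), c(1, 1, 0)) * 0.7)
  expect_equal(unname(weighted_clustering(tri_equal)), rep(1, 3))

  tri <- matrix(0, 3, 3)
  tri[1, 2] <- tri[2, 1] <- 1
  tri[1, 3] <- tri[3, 1] <- 1
  tri[2, 3] <- tri[3, 2] <- 0.5
  expect_equal(unname(weighted_clustering(connectome(tri), 1)), 0.5)

  star <- matrix(0, 4, 4)
  star[1, 2:4] <- star[2:4, 1] <- 0.8
  expect_equal(unname(weighted_clustering(connectome(star), 1)), 0)

  set.seed(21)
  for (rep in 1:5) {
    W <- random_weight_matrix(7)
    expect_equal(unname(weighted_clustering(connectome(W))),
                 brute_force_indices(W)$clustering)
  }
  expect_warning(cc0 <- weighted_clustering(connectome(matrix(0, 3, 3))),
                 "all-zero")
  expect_equal(unname(cc0), rep(0, 3))
})

test_that("path strength is the reciprocal optimal inverse-weight distance", {
  # direct edge only
  W <- matrix(0, 3, 3); W[1, 2] <- W[2, 1] <- 0.4
  expect_equal(path_strength(connectome(W), 1, 2), 0.4)
  # chain i-k-j with both weights 0.5 -> D = 4, L = 0.25
  Wc <- matrix(0, 3, 3)
  Wc[1, 2] <- Wc[2, 1] <- 0.5
  Wc[2, 3] <- Wc[3, 2] <- 0.5
  expect_equal(path_strength(connectome(Wc), 1, 3), 0.25)
  expect_equal(path_strength(connectome(Wc), 1, 3, as_distance = TRUE), 4)
  # disconnected components
  Wd <- matrix(0, 4, 4)
  Wd[1, 2] <- Wd[2, 1] <- 1
  Wd[3, 4] <- Wd[4, 3] <- 1
  expect_true(is.na(path_strength(connectome(Wd), 1, 3)))
  expect_error(path_strength(connectome(Wd), 2, 2), "distinct")
  # indirect route can beat a weak direct edge
  Wi <- matrix(0, 3, 3)
  Wi[1, 3] <- Wi[3, 1] <- 0.05
  Wi[1, 2] <- Wi[2, 1] <- 1
  Wi[2, 3] <- Wi[3, 2] <- 1
  expect_equal(path_strength(connectome(Wi), 1, 3), 0.5)
})

test_that("path strengths agree with exhaustive path enumeration", {
  set.seed(31)
  for (rep in 1:5) {
    W <- random_weight_matrix(6, density = 0.5)
    got <- path_strength_matrix(connectome(W))
    want <- brute_force_indices(W)$path
    expect_equal(unname(got), unname(want))
  }
})

test_that("global indices match the exhaustive oracle and are label-invariant", {
  # two-node single-edge graph
  W2 <- matrix(c(0, 0.2, 0.2, 0), 2, 2)
  prof2 <- global_indices(connectome(W2))
  expect_equal(unname(prof2$global["strength"]), 0.2)
  expect_equal(unname(prof2$global["path_length"]), 0.2)

  set.seed(41)
  for (rep in 1:3) {
    W <- random_weight_matrix(8, density = 0.5)
    prof <- global_indices(connectome(W))
    oracle <- brute_force_indices(W)
    expect_equal(unname(prof$global["strength"]), oracle$global[["strength"]])
    expect_equal(unname(prof$global["clustering"]),
                 oracle$global[["clustering"]])
    expect_equal(unname(prof$global["path_length"]),
                 oracle$global[["path_length"]])
    expect_equal(unname(prof$global["density"]), oracle$density)
    # node relabeling leaves global values unchanged
    perm <- sample(8)
    prof_p <- global_indices(connectome(W[perm, perm]))
    expect_equal(prof_p$global, prof$global)
  }
})

test_that("uniform weights reduce to the binary framework", {
  set.seed(51)
  A <- matrix(0, 7, 7)
  ut <- which(upper.tri(A))
  A[ut[runif(length(ut)) < 0.6]] <- 1
  A <- A + t(A)
  cn <- connectome(A)
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  # clustering equals the binary (transitivity) coefficient
  expect_equal(unname(weighted_clustering(cn)),
               ifelse(is.na(igraph::transitivity(g, type = "local")), 0,
                      igraph::transitivity(g, type = "local")))
  # path strength ranking equals inverse hop count
  D <- path_strength_matrix(cn, as_distance = TRUE)
  H <- igraph::distances(g)
  H[is.infinite(H)] <- NA
  diag(H) <- NA  # self-distances are undefined in the profile convention
  expect_equal(unname(D), unname(H))
})

test_that("strength and path strength scale with the weights; clustering and density do not", {
  set.seed(61)
  W <- random_weight_matrix(8)
  cn <- connectome(W)
  cnk <- connectome(3.7 * W)
  expect_equal(node_strength(cnk), 3.7 * node_strength(cn))
  expect_equal(path_strength_matrix(cnk), 3.7 * path_strength_matrix(cn))
  expect_equal(weighted_clustering(cnk), weighted_clustering(cn))
  expect_equal(graph_density(cnk), graph_density(cn))
})

test_that("raising one edge weight never lowers strengths or path strengths", {
  set.seed(71)
  W <- random_weight_matrix(7, density = 0.5)
  pos <- which(upper.tri(W) & W > 0)
  pick <- pos[3]
  W2 <- W
  W2[pick] <- W2[pick] * 2
  W2[lower.tri(W2)] <- t(W2)[lower.tri(W2)]
  s1 <- node_strength(connectome(W)); s2 <- node_strength(connectome(W2))
  expect_true(all(s2 >= s1 - 1e-12))
  L1 <- path_strength_matrix(connectome(W))
  L2 <- path_strength_matrix(connectome(W2))
  expect_true(all(L2 >= L1 - 1e-12, na.rm = TRUE))
})

test_that("ER nulls hit their density and are seed-reproducible", {
  full <- er_null(10, 1, weight_pool = c(0.5, 1), seed = 1)
  expect_equal(graph_density(full), 1)
  pool <- runif(50)
  a <- er_null(30, 0.4, weight_pool = pool, seed = 9)
  b <- er_null(30, 0.4, weight_pool = pool, seed = 9)
  expect_identical(unclass(a), unclass(b))
  expect_error(er_null(10, 1.5, 1), "density")
  expect_error(er_null(10, 0.4, numeric(0)), "nonempty")

  # binomial expectation on the emulated 82-node, 40%-density networks
  n_pairs <- 82 * 81 / 2
  counts <- vapply(1:500, function(s)
    sum(er_null(82, 0.4, 1, seed = s)[upper.tri(matrix(0, 82, 82))] > 0),
    numeric(1))
  se <- sqrt(500 * 0.4 * 0.6 * n_pairs) / 500
  expect_lt(abs(mean(counts) - 0.4 * n_pairs), 3 * se)
})

test_that("small-worldness is calibrated on its own null family and detects lattices", {
  # an ER graph with a mild weight pool scores ~1 against its own ensemble
  pool <- runif(600, 0.5, 1.5)
  er <- er_null(40, 0.35, pool, seed = 2)
  sw <- small_worldness(er, n_realizations = 25, seed = 5)
  expect_gt(sw$S, 0.8)
  expect_lt(sw$S, 1.25)

  # a weighted ring lattice (dense local triangles) is strongly small-world
  n <- 30
  W <- matrix(0, n, n)
  for (i in seq_len(n)) for (d in 1:3) {
    j <- ((i - 1 + d) %% n) + 1
    W[i, j] <- W[j, i] <- 1
  }
  sw_lat <- small_worldness(connectome(W), n_realizations = 20, seed = 7)
  expect_gt(sw_lat$S, 1)

  # determinism under a fixed seed
  sw2 <- small_worldness(er, n_realizations = 25, seed = 5)
  expect_identical(sw$S, sw2$S)
})

test_that("topology profiles round-trip through TSV", {
  set.seed(81)
  prof <- global_indices(connectome(random_weight_matrix(6)))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_topology_tsv(prof, f)
  back <- read_topology_tsv(f)
  expect_equal(back$node$strength, prof$node$strength, tolerance = 1e-12)
  expect_equal(back$global, prof$global, tolerance = 1e-12)
})
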