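test_that("density counts match the brute-force definition", {
  # degenerate cases
  same <- matrix(1, 40, 3)
  expect_equal(estimate_density(same, 0.5), rep(40L, 40))
  expect_equal(estimate_density(matrix(rnorm(5), 1, 5), 1), 1L)
  expect_error(estimate_density(same, 0), "radius")
  # seeded random cloud vs O(N^2) oracle, both metrics
  set.seed(11)
  x <- matrix(rnorm(50 * 5), 50, 5)
  for (metric in c("L1", "L2")) {
    # radius strictly between realized distances (the median of an odd
    # pair count IS a realized distance, a knife-edge for <=)
    r <- 1.01 * median(dist(x, method = if (metric == "L2") "euclidean"
                            else "manhattan"))
    expect_equal(estimate_density(x, r, metric),
                 oracle_density(x, r, metric))
  }
})

test_that("radius selection follows its definition and scales with the data", {
  two <- rbind(c(0, 0), c(3, 4))
  expect_equal(choose_radius(two, radius_alpha = 5, metric = "L2"), 25)
  expect_equal(choose_radius(two, radius_alpha = 5, metric = "L1"), 35)
  set.seed(5)
  x <- matrix(rnorm(100 * 4), 100, 4)
  r <- choose_radius(x, radius_alpha = 5, density_subsample = 40,
                     metric = "L1", seed = 3)
  # direct replay of the definition with the same substream
  set.seed(spectree:::stage_seed(3, "radius"))
  sub <- x[sort(sample.int(100, 40)), ]
  dm <- as.matrix(dist(sub, method = "manhattan")); diag(dm) <- Inf
  expect_equal(r, 5 * median(apply(dm, 1, min)))
  expect_equal(choose_radius(2.5 * x, radius_alpha = 5,
                             density_subsample = 40, seed = 3), 2.5 * r)
  # all-coincident subsample falls back to the smallest nonzero distance
  y <- rbind(matrix(1, 30, 2), c(1, 1.25))
  expect_equal(choose_radius(y, radius_alpha = 1, density_subsample = 5,
                             seed = 1), 0.25)
  expect_error(choose_radius(matrix(1, 10, 2), seed = 1), "coincide")
})

test_that("density downsampling implements the outlier/target rule", {
  # uniform density: everything kept
  same <- matrix(1, 25, 2)
  dens <- estimate_density(same, 1)
  expect_equal(density_downsample(same, dens, downsample_params(), seed = 1),
               1:25)
  # planted dense + sparse blobs
  set.seed(21)
  dense <- matrix(rnorm(1000 * 4, sd = 0.05), 1000, 4)
  sparse <- matrix(rnorm(30 * 4, sd = 8) + 40, 30, 4)
  x <- rbind(dense, sparse)
  dens <- estimate_density(x, 1, "L2")
  prm <- downsample_params()
  kept <- density_downsample(x, dens, prm, seed = 6)
  od <- quantile(dens, 0.01, names = FALSE)
  td <- quantile(dens, 0.03, names = FALSE)
  expect_true(all(dens[kept] >= od))
  # seeded replay of the keep rule
  set.seed(spectree:::stage_seed(6, "downsample"))
  u <- runif(length(dens))
  replay <- which(dens >= od & (dens <= td | u <= td / dens))
  expect_identical(kept, replay)
  # dense-blob retention within 3 binomial SEs of td / median dense density
  p_keep <- td / median(dens[1:1000])
  n_dense <- sum(kept <= 1000)
  se <- sqrt(1000 * p_keep * (1 - p_keep))
  expect_lt(abs(n_dense - 1000 * p_keep), 3 * se + 3)
  # max_kept thinning is honoured and sorted
  prm2 <- downsample_params(max_kept = 10)
  kept2 <- density_downsample(x, dens, prm2, seed = 6)
  expect_length(kept2, 10)
  expect_identical(kept2, sort(kept2))
})

test_that("downsampling flattens the density distribution", {
  set.seed(31)
  x <- rbind(matrix(rnorm(2000 * 3, sd = 0.3), 2000, 3),
             matrix(rnorm(200 * 3, sd = 3), 200, 3))
  r <- choose_radius(x, seed = 2)
  dens <- estimate_density(x, r)
  kept <- density_downsample(x, dens, downsample_params(), seed = 2)
  dens_after <- estimate_density(x[kept, ], r)
  cv <- function(v) sd(v) / mean(v)
  expect_lt(cv(dens_after), cv(dens))
})

test_that("k-means clustering recovers planted blobs exactly", {
  set.seed(41)
  blob <- function(cx) matrix(rnorm(60 * 4, sd = 0.2), 60, 4) + cx
  x <- rbind(blob(0), blob(10), blob(-10))
  truth <- rep(1:3, each = 60)
  cl <- cluster_nodes(x, 3, "kmeans", seed = 1)
  expect_equal(length(unique(paste(cl$labels, truth))), 3)
  # no point is closer to a foreign centroid
  d2 <- as.matrix(dist(rbind(x, cl$centroids)))[1:180, 181:183]
  expect_equal(max.col(-d2), cl$labels)
  # k = M: every point its own cluster, zero within-cluster SS
  y <- matrix(rnorm(8 * 3), 8, 3)
  expect_equal(cluster_nodes(y, 8, seed = 1)$wss, 0)
  expect_error(cluster_nodes(y, 9, seed = 1), "fewer points")
  # agglomerative route returns k centroids too
  ag <- cluster_nodes(x, 3, "agglomerative", seed = 1)
  expect_equal(dim(ag$centroids), c(3, 4))
  expect_equal(length(unique(paste(ag$labels, truth))), 3)
})

test_that("MST matches exhaustive enumeration and is permutation-stable", {
  expect_equal(nrow(build_mst(matrix(rnorm(3), 1, 3))), 0)
  e2 <- build_mst(rbind(c(0, 0), c(1, 1)), "L2")
  expect_equal(e2$from, 1L)
  expect_equal(e2$to, 2L)
  expect_equal(e2$weight, sqrt(2))
  set.seed(51)
  for (rep_i in 1:5) {
    cen <- matrix(rnorm(5 * 3), 5, 3)
    for (metric in c("L1", "L2")) {
      edges <- build_mst(cen, metric)
      D <- as.matrix(dist(cen, method = if (metric == "L2") "euclidean"
                          else "manhattan"))
      expect_equal(sum(edges$weight), oracle_mst_weight(D))
      expect_equal(nrow(edges), 4)
      # total weight invariant under row permutation
      perm <- sample(5)
      expect_equal(sum(build_mst(cen[perm, ], metric)$weight),
                   sum(edges$weight))
    }
  }
})

test_that("tree layout is seeded, finite and shape-respecting", {
  path3 <- data.frame(from = c(1L, 2L), to = c(2L, 3L), weight = c(1, 1))
  a <- layout_tree(path3, 3, seed = 4)
  b <- layout_tree(path3, 3, seed = 4)
  expect_identical(a, b)
  # middle node of a 3-path lies between the endpoints along the layout's
  # principal axis
  pc <- prcomp(a)$x[, 1]
  expect_true(pc[2] > min(pc[c(1, 3)]) && pc[2] < max(pc[c(1, 3)]))
  # a large random tree stays finite and collision-free
  set.seed(9)
  k <- 300
  parents <- c(NA, vapply(2:k, function(i) sample.int(i - 1, 1), 1L))
  edges <- data.frame(from = pmin(parents[-1], 2:k),
                      to = pmax(parents[-1], 2:k), weight = 1)
  xy <- layout_tree(edges, k, seed = 2)
  expect_true(all(is.finite(xy)))
  expect_false(any(duplicated(xy)))
  expect_error(layout_tree(path3[1, ], 3, seed = 1), "spanning tree")
})

test_that("pixel assignment is an exhaustive nearest-centroid partition", {
  set.seed(61)
  k <- 6; C <- 12
  cen <- matrix(rnorm(k * C), k, C)
  pix <- rbind(cen[7 - 7 + 4, , drop = FALSE] + 0,   # exact centroid copy
               matrix(rnorm(19 * C), 19, C))
  cube <- toy_cube(pix, 4, 5)
  asg <- assign_pixels(cube, centroids = cen, metric = "L1")
  expect_equal(asg$node_id[1], 4L)
  expect_equal(sum(asg$counts), 20)
  # oracle scan
  for (i in 1:20) {
    d <- apply(cen, 1, function(cc) sum(abs(pix[i, ] - cc)))
    expect_equal(asg$node_id[i], which.min(d))
  }
  expect_error(assign_pixels(cube, mask = matrix(FALSE, 4, 5),
                             centroids = cen), "empty mask")
})

test_that("node mean spectra obey the law of total mean", {
  run <- small_run()
  nm <- node_mean_spectra(run$cube, run$assignment, run$tree$centroids)
  w <- run$assignment$counts / sum(run$assignment$counts)
  expect_equal(colSums(nm * w), cube_mean_spectrum(run$cube),
               tolerance = 1e-10)
  # toy three-pixel node
  pix <- rbind(c(1, 2), c(3, 4), c(5, 12))
  cube <- toy_cube(pix, 1, 3)
  asg <- assign_pixels(cube, centroids = rbind(c(2, 5)), metric = "L1")
  expect_equal(node_mean_spectra(cube, asg)[1, ], c(3, 6))
  # single-pixel node equals the pixel spectrum
  asg2 <- assign_pixels(cube, centroids = rbind(c(1, 2), c(4, 8)),
                        metric = "L1")
  one <- which(asg2$counts == 1)
  if (length(one))
    expect_equal(node_mean_spectra(cube, asg2)[one[1], ],
                 pix[asg2$node_id == one[1], ])
})

test_that("projection onto a tree is idempotent and offset-tolerant", {
  run <- small_run()
  again <- project_to_tree(run$cube, mask = NULL, run$tree, center = FALSE)
  expect_identical(again$node_id, run$assignment$node_id)
  # constant offset spectrum added to every pixel cancels under centering
  off <- sin(run$cube$axis$values / 200) * 0.05
  d <- dim(run$cube$data)
  shifted <- run$cube
  shifted$data <- run$cube$data + array(rep(off, each = d[1] * d[2]), d)
  cen_asg <- project_to_tree(shifted, mask = NULL, run$tree, center = TRUE)
  base_asg <- project_to_tree(run$cube, mask = NULL, run$tree,
                              center = TRUE)
  expect_identical(cen_asg$node_id, base_asg$node_id)
  # centered assignment equals a direct oracle on centered spectra
  pm <- spectree:::cube_pixel_matrix(shifted)
  sp <- sweep(pm$spectra, 2, colMeans(pm$spectra))
  cen <- sweep(run$tree$centroids, 2, run$tree$train_mean)
  take <- seq(1, length(pm$idx), length.out = 25)
  for (i in as.integer(take)) {
    d1 <- apply(cen, 1, function(cc) sum(abs(sp[i, ] - cc)))
    expect_equal(cen_asg$node_id[pm$idx[i]], which.min(d1))
  }
  # axis mismatch is a parameter error
  other <- toy_cube(matrix(1, 4, 10), 2, 2)
  expect_error(project_to_tree(other, mask = NULL, run$tree), "axis mismatch")
})
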