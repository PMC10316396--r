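test_that("section profile correlation matches the Pearson definition", {
  tab <- rbind(c(1, 2, 1.5, 8),
               c(4, 1, 2.0, 3),
               c(2, 2, 9.0, 1))
  cm <- section_profile_correlation(tab)
  expect_equal(dim(cm), c(4, 4))
  expect_equal(unclass(cm), t(unclass(cm)), ignore_attr = TRUE)
  expect_equal(diag(cm), rep(1, 4))
  for (s in 1:3) for (t in (s + 1):4)
    expect_equal(cm[s, t], oracle_pearson(tab[, s], tab[, t]))
  # duplicated column correlates at exactly 1
  cm2 <- section_profile_correlation(cbind(tab, tab[, 2]))
  expect_equal(cm2[2, 5], 1)
  # constant column is undefined, not zero
  cm3 <- section_profile_correlation(cbind(tab, c(7, 7, 7)))
  expect_true(all(is.na(cm3[5, 1:4])))
  expect_true(is.na(cm3[5, 5]))
})

test_that("dynamic-gene filter implements the inclusive 2-fold rule", {
  m <- rbind(const = rep(4, 5),
             exact2 = c(1, 1.3, 2, 1.7, 1.1),
             below = c(1, 1.2, 1.9, 1.4, 1.3),
             zero_min = c(0, 1, 2, 1, 0.5))
  kept <- dynamic_gene_filter(m, fold = 2)
  expect_identical(rownames(kept), c("exact2", "zero_min"))
  # seeded random table equals a direct replay of the rule
  set.seed(77)
  rt <- matrix(rexp(40 * 6), 40, 6)
  kept2 <- dynamic_gene_filter(rt, fold = 2)
  eps <- 1e-6 * max(rt)
  replay <- which(apply(rt, 1, max) / pmax(apply(rt, 1, min), eps) >= 2)
  expect_equal(nrow(kept2), length(replay))
  expect_equal(unname(kept2), unname(rt[replay, , drop = FALSE]))
})

test_that("node clustermap ordering agrees with an average-linkage oracle", {
  set.seed(13)
  prof <- rbind(c(1, 2, 3, 4, 5, 6),
                c(2, 4, 6, 8, 10, 12) + rnorm(6, 0, 0.01),
                c(6, 5, 4, 3, 2, 1),
                c(1, 5, 1, 5, 1, 5),
                c(5, 1, 5, 1, 5, 1),
                c(3, 3, 3.3, 3, 3.1, 2.7))
  counts <- matrix(round(prof * 10), 6, 6)
  freq <- structure(list(counts = counts,
                         fractions = sweep(counts, 2, colSums(counts), "/"),
                         section_sizes = colSums(counts),
                         dropped_sections = integer(), k = 6L, S = 6L),
                    class = "node_frequency_table")
  cm <- node_clustermap(freq)
  # oracle agglomeration on the same correlation-row distances
  D <- as.matrix(dist(cm$corr))
  orc <- oracle_average_linkage(D)
  hc <- hclust(dist(cm$corr), method = "average")
  expect_equal(sort(hc$height), sort(orc$heights))
  # every oracle merge set is contiguous in the emitted leaf ordering
  pos <- match(seq_len(6), cm$order)
  for (ms in orc$merges)
    expect_equal(diff(range(pos[ms])), length(ms) - 1)
  # z-score rows standardize exactly
  expect_equal(unname(rowMeans(cm$zscores)), rep(0, 6), tolerance = 1e-12)
  expect_equal(unname(apply(cm$zscores, 1, sd)), rep(1, 6),
               tolerance = 1e-12)
  # variance divisor option changes the scale, not the ordering
  cmv <- node_clustermap(freq, zscore_divisor = "var")
  expect_equal(cmv$order, cm$order)
  expect_false(isTRUE(all.equal(cmv$zscores, cm$zscores)))
})

test_that("identical node profiles merge first and correlate at 1", {
  counts <- rbind(c(10, 20, 30), c(1, 2, 3), c(30, 10, 5), c(9, 28, 40))
  freq <- structure(list(counts = counts,
                         fractions = sweep(counts, 2, colSums(counts), "/"),
                         section_sizes = colSums(counts),
                         dropped_sections = integer(), k = 4L, S = 3L),
                    class = "node_frequency_table")
  cm <- node_clustermap(freq)
  expect_equal(cm$corr[1, 2], 1)
  expect_equal(abs(match(1, cm$order) - match(2, cm$order)), 1)
  expect_error(node_clustermap(structure(list(counts = counts[, 1:2],
                                              fractions = freq$fractions[, 1:2],
                                              dropped_sections = integer(),
                                              k = 4L, S = 2L),
                                         class = "node_frequency_table")),
               "3 non-empty")
})

test_that("gene-node correlations follow the Pearson formula", {
  fr <- rbind(c(0.5, 0.4, 0.3, 0.2),
              c(0.2, 0.3, 0.4, 0.5),
              c(0.25, 0.25, 0.25, 0.25),
              c(0.05, 0.05, 0.05, 0.1))
  freq <- structure(list(counts = round(fr * 100),
                         fractions = fr, section_sizes = rep(100L, 4),
                         dropped_sections = integer(), k = 4L, S = 4L),
                    class = "node_frequency_table")
  g <- c(3, 5, 6, 10)
  r <- gene_node_correlation(g, freq)
  for (n in c(1, 2, 4)) expect_equal(r[n], oracle_pearson(g, fr[n, ]))
  expect_true(is.na(r[3]))  # constant node profile
  expect_equal(gene_node_correlation(fr[2, ], freq)[2], 1)
  expect_true(all(is.na(gene_node_correlation(rep(4, 4), freq))))
  expect_error(gene_node_correlation(c(1, 2), freq), "length")
})

test_that("top-node selection obeys the descending/tie rule", {
  r <- c(0.5, 0.9, NA, 0.9, 0.1, NA, 0.7)
  expect_equal(top_gene_nodes(r, 3), c(2L, 4L, 7L))  # tie 2 vs 4 -> lower id
  expect_equal(top_gene_nodes(r, 10), c(2L, 4L, 7L, 1L, 5L))
  expect_warning(out <- top_gene_nodes(rep(NA_real_, 4), 2), "no defined")
  expect_length(out, 0)
  # seeded vector with a tie exactly at the selection boundary
  set.seed(19)
  rv <- round(runif(30), 1)
  top <- top_gene_nodes(rv, 10)
  ord <- order(-rv, seq_along(rv))
  expect_equal(top, ord[1:10])
})

test_that("pixel highlighting is an exact membership mask", {
  node_id <- matrix(c(1L, 2L, 3L, 1L, NA, 2L), 2, 3)
  asg <- structure(list(node_id = node_id, counts = c(2L, 2L, 1L), k = 3L),
                   class = "pixel_assignment")
  expect_equal(highlight_gene_pixels(integer(), asg),
               matrix(FALSE, 2, 3))
  m <- highlight_gene_pixels(c(1L, 3L), asg)
  expect_equal(sum(m), asg$counts[1] + asg$counts[3])
  expect_equal(m, matrix(node_id %in% c(1L, 3L), 2, 3))
  expect_error(highlight_gene_pixels(9L, asg), "unknown node")
})

test_that("correlation histograms bin defined values only", {
  h <- correlation_histogram(rep(0.5, 7), bins = 4)
  expect_equal(h$counts, c(0, 0, 0, 7))
  expect_equal(h$undefined, 0)
  set.seed(23)
  rv <- c(runif(200, -1, 1), NA, NA)
  h2 <- correlation_histogram(rv, bins = 10)
  expect_equal(sum(h2$counts), 200)
  expect_equal(h2$undefined, 2)
  edges <- seq(-1, 1, length.out = 11)
  oracle <- table(cut(rv[1:200], edges, include.lowest = TRUE))
  expect_equal(h2$counts, as.integer(oracle))
})

test_that("Pearson machinery is invariant to positive affine rescaling", {
  set.seed(29)
  tab <- matrix(rexp(8 * 5), 8, 5)
  cm <- section_profile_correlation(tab)
  cm2 <- section_profile_correlation(3.7 * tab + 2)
  expect_equal(unclass(cm), unclass(cm2), tolerance = 1e-12)
  fr <- sweep(tab, 2, colSums(tab), "/")
  freq <- structure(list(counts = tab, fractions = fr,
                         section_sizes = colSums(tab),
                         dropped_sections = integer(), k = 8L, S = 5L),
                    class = "node_frequency_table")
  g <- runif(5)
  expect_equal(gene_node_correlation(g, freq),
               gene_node_correlation(10 * g + 4, freq), tolerance = 1e-12)
})
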