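test_that("Euclidean distances match hand arithmetic at both levels", {
  prof <- rbind(c(1L, 1L, 0L), c(0L, 1L, 1L))
  colnames(prof) <- c("M_1", "M_2", "M_3")
  m <- bulk_matrix(prof, c("A", "B"), c(1L, 1L), 1L)
  d <- pairwise_distances(m)
  expect_equal(as.numeric(d), sqrt(2))
  expect_equal(attr(d, "level"), "bulk")

  # identical rows are at distance zero; all-ones vs all-zeros scales as sqrt(M)
  z <- rbind(a = rep(1L, 278), b = rep(1L, 278), c = rep(0L, 278))
  colnames(z) <- sprintf("M_%03d", 1:278)
  d2 <- pairwise_distances(accession_matrix(z, 1L))
  dm <- as.matrix(d2)
  expect_equal(dm["a", "b"], 0)
  expect_equal(dm["a", "c"], sqrt(278))
  expect_equal(attr(d2, "level"), "accession")

  expect_error(pairwise_distances(
    accession_matrix(z[1, , drop = FALSE], 1L)), "at least 2")
})

test_that("within/between statistics match brute-force pair enumeration", {
  # 2 accessions x 2 bulks with hand-set profiles; enumerate all 6 pairs
  profiles <- rbind(c(1, 0, 0), c(1, 1, 0), c(0, 0, 1), c(0, 1, 1))
  colnames(profiles) <- c("M_1", "M_2", "M_3")
  m <- bulk_matrix(profiles, c("A", "A", "B", "B"), c(1L, 2L, 1L, 2L), 2L)
  wb <- within_between_stats(m)

  d <- as.matrix(dist(profiles))
  within <- c(d[1, 2], d[3, 4])
  between <- c(d[1, 3], d[1, 4], d[2, 3], d[2, 4])
  expect_equal(wb$mean_within, mean(within))
  expect_equal(wb$mean_between, mean(between))
  expect_equal(wb$median_between, median(between))
  expect_equal(wb$ratio_between_over_within, mean(between) / mean(within))
  expect_equal(wb$n_within_pairs, 2L)
  expect_equal(wb$n_between_pairs, 4L)
  tt <- t.test(between, within)
  expect_equal(wb$t_statistic, unname(tt$statistic))
  expect_equal(wb$p_value, tt$p.value)
})

test_that("pair counts follow N B(B-1)/2 and B^2 N(N-1)/2 for uniform B", {
  sim <- simulate_collection(sim_config(n_accessions = 8L, n_markers = 4L,
                                        seed = 5))
  wb <- within_between_stats(sim$bulks)
  N <- 8; B <- 3
  expect_equal(wb$n_within_pairs, N * B * (B - 1) / 2)
  expect_equal(wb$n_between_pairs, B^2 * N * (N - 1) / 2)
})

test_that("degenerate bulk configurations are reported, not crashed", {
  # identical bulks within accessions, differing between
  prof <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1))
  colnames(prof) <- c("M_1", "M_2")
  m <- bulk_matrix(prof, c("A", "A", "B", "B"), c(1L, 2L, 1L, 2L), 2L)
  wb <- within_between_stats(m)
  expect_equal(wb$mean_within, 0)
  expect_gt(wb$mean_between, 0)

  # all bulks identical everywhere: t undefined, flagged
  prof2 <- matrix(1, 4, 2, dimnames = list(NULL, c("M_1", "M_2")))
  m2 <- bulk_matrix(prof2, c("A", "A", "B", "B"), c(1L, 2L, 1L, 2L), 2L)
  wb2 <- within_between_stats(m2)
  expect_equal(wb2$mean_within, 0)
  expect_equal(wb2$mean_between, 0)
  expect_true(is.na(wb2$t_statistic))
  expect_match(wb2$note, "undefined")

  # single-bulk accessions have no within pairs
  m3 <- bulk_matrix(prof[c(1, 3), ], c("A", "B"), c(1L, 1L), 1L)
  expect_error(within_between_stats(m3), "within")
})

test_that("UPGMA reproduces the worked 3-leaf tree and its cophenetic matrix", {
  d <- as.dist(matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
                      dimnames = list(c("A", "B", "C"), c("A", "B", "C"))))
  tree <- upgma(d)
  expect_equal(ape::write.tree(tree), "((A:1,B:1):1,C:2);")
  cop <- cophenetic(tree)
  expect_equal(cop["A", "B"], 2)
  expect_equal(cop["A", "C"], 4)
  expect_equal(cop["B", "C"], 4)

  # two leaves: a cherry at half their distance
  d2 <- as.dist(matrix(c(0, 3, 3, 0), 2, dimnames = list(c("x", "y"),
                                                         c("x", "y"))))
  t2 <- upgma(d2)
  expect_equal(sort(t2$tip.label), c("x", "y"))
  expect_equal(unname(t2$edge.length), c(1.5, 1.5))
})

test_that("UPGMA trees are ultrametric and agree with hclust on random input", {
  set.seed(99)
  for (rep in 1:10) {
    n <- sample(4:12, 1)
    x <- matrix(rnorm(n * 5), n)
    rownames(x) <- paste0("t", seq_len(n))
    d <- dist(x)
    tree <- upgma(d)
    # ultrametric: all root-to-leaf path lengths equal
    depths <- ape::node.depth.edgelength(tree)[seq_len(n)]
    expect_lt(max(depths) - min(depths), 1e-9)
    # independent implementation: hclust average linkage cophenetics
    hc <- hclust(d, method = "average")
    cop_hc <- as.matrix(cophenetic(hc))
    cop <- as.matrix(cophenetic(tree))[rownames(cop_hc), colnames(cop_hc)]
    expect_equal(cop, cop_hc, tolerance = 1e-9)
  }
})

test_that("UPGMA cophenetics are invariant to input permutation", {
  set.seed(17)
  x <- matrix(sample(0:3, 8 * 6, TRUE), 8)
  rownames(x) <- paste0("t", 1:8)
  d <- dist(x)
  cop1 <- as.matrix(cophenetic(upgma(d)))
  p <- sample(8)
  cop2 <- as.matrix(cophenetic(upgma(dist(x[p, ]))))
  expect_equal(cop2[rownames(cop1), colnames(cop1)], cop1, tolerance = 1e-12)
})

test_that("newick export round-trips through ape", {
  fx <- make_fixture("F2")
  tree <- upgma(pairwise_distances(fx$accessions))
  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tree, path)
  back <- ape::read.tree(path)
  expect_setequal(back$tip.label, rownames(fx$accessions$z))
  expect_equal(as.matrix(cophenetic(back))[rownames(fx$accessions$z),
                                           rownames(fx$accessions$z)],
               as.matrix(cophenetic(tree))[rownames(fx$accessions$z),
                                           rownames(fx$accessions$z)],
               tolerance = 1e-6)
})

test_that("jackknife sensitivity is zero for constant and duplicated columns", {
  set.seed(23)
  z <- matrix(sample(0:3, 6 * 4, TRUE), 6)
  rownames(z) <- paste0("a", 1:6)
  z <- cbind(z, 2L, z[, 1])   # a constant column and a duplicate of column 1
  colnames(z) <- sprintf("M_%d", seq_len(ncol(z)))
  a <- accession_matrix(z, 3L)
  jk <- jackknife_columns(a)
  expect_equal(nrow(jk), ncol(z))
  expect_equal(jk$sensitivity[5], 0, tolerance = 1e-12)        # constant
  expect_equal(jk$sensitivity[6], jk$sensitivity[1], tolerance = 1e-12)
  expect_true(all(jk$sensitivity >= -1e-12, na.rm = TRUE))
})

test_that("jackknife at M = 2 matches direct single-column reconstruction", {
  z <- rbind(a = c(0L, 3L), b = c(1L, 1L), c = c(3L, 0L), d = c(2L, 2L))
  colnames(z) <- c("M_1", "M_2")
  a <- accession_matrix(z, 3L)
  jk <- jackknife_columns(a)
  full <- cophenetic(upgma(pairwise_distances(a)))
  for (j in 1:2) {
    red <- accession_matrix(z[, -j, drop = FALSE], 3L)
    cop <- cophenetic(upgma(pairwise_distances(red)))
    ord <- rownames(full)
    expected <- 1 - cor(full[lower.tri(full)],
                        cop[ord, ord][lower.tri(full)])
    expect_equal(jk$sensitivity[j], expected, tolerance = 1e-12)
  }
})

test_that("haversine distances and the Mantel correlation behave as constructed", {
  # quarter meridian: (0,0) to (90N,0) is 6371 * pi / 2 km
  z <- rbind(a = c(0L, 1L), b = c(1L, 0L))
  colnames(z) <- c("M_1", "M_2")
  meta <- data.frame(accession = c("a", "b"), lat = c(0, 90), lon = c(0, 0))
  d <- pairwise_distances(accession_matrix(z, 1L))
  res <- geo_genetic_correlation(meta, d, permutations = 0L)
  expect_true(is.na(res$r) || !is.null(res$r))  # r over a single pair is NA-prone
  gm <- geosphere::distHaversine(c(0, 0), c(0, 90), r = 6371000) / 1000
  expect_equal(gm, 6371 * pi / 2, tolerance = 1e-9)

  # genetic distance proportional to geographic: r = 1, small Mantel p
  set.seed(31)
  n <- 12
  meta2 <- data.frame(accession = sprintf("A%02d", 1:n),
                      lat = runif(n, 18, 21), lon = runif(n, -99, -97))
  gd <- geosphere::distm(cbind(meta2$lon, meta2$lat),
                         fun = function(p, q)
                           geosphere::distHaversine(p, q, r = 6371000)) / 1000
  fake <- as.dist(gd * 0.01)
  attr(fake, "Labels") <- meta2$accession
  res2 <- geo_genetic_correlation(meta2, fake, permutations = 199L, seed = 9)
  expect_equal(res2$r, 1, tolerance = 1e-12)
  expect_lte(res2$mantel_p, 2 / (199 + 1))

  # all accessions at one point: geographic distances all zero
  meta3 <- data.frame(accession = c("a", "b"), lat = c(19, 19),
                      lon = c(-98, -98))
  res3 <- geo_genetic_correlation(meta3, d, permutations = 0L)
  expect_true(is.na(res3$r))
  expect_match(res3$note, "constant")

  expect_error(geo_genetic_correlation(meta3[1, ], d), "no metadata")
})
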