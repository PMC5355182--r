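make_group_matrix <- function(z_in, z_out, label = "M_1") {
  z <- matrix(c(z_in, z_out), ncol = 1,
              dimnames = list(sprintf("a%02d", seq_len(length(z_in) +
                                                         length(z_out))),
                              label))
  accession_matrix(z, 3L)
}

test_that("group t-tests match the textbook Welch formula and handle degeneracy", {
  set.seed(13)
  z_in <- sample(0:3, 12, TRUE); z_out <- sample(0:3, 20, TRUE)
  a <- make_group_matrix(z_in, z_out)
  groups <- rep(c("g", "h"), c(12, 20))
  res <- group_allele_ttests(a, groups, min_size = 10L)
  row <- res[res$group == "g", ]
  expect_equal(row$mean_in_group, mean(z_in))
  expect_equal(row$mean_in_others, mean(z_out))
  expect_equal(row$t_statistic, welch_oracle(z_in, z_out), tolerance = 1e-12)
  expect_equal(row$p_value, t.test(z_in, z_out)$p.value)
  expect_equal(row$direction, if (mean(z_in) > mean(z_out)) "+" else "-")

  # fully separated constant groups: the zero-standard-error Welch limit
  a2 <- make_group_matrix(rep(3L, 10), rep(0L, 10))
  res2 <- group_allele_ttests(a2, rep(c("g", "h"), each = 10), min_size = 10L)
  g2 <- res2[res2$group == "g", ]
  expect_equal(g2$mean_in_group, 3)
  expect_equal(g2$mean_in_others, 0)
  expect_equal(g2$direction, "+")
  expect_equal(g2$p_value, 0)
  expect_true(is.infinite(g2$t_statistic) && g2$t_statistic > 0)

  # a column constant across all accessions is never significant
  z3 <- cbind(a2$z, M_2 = 2L)
  res3 <- group_allele_ttests(accession_matrix(z3, 3L),
                              rep(c("g", "h"), each = 10), min_size = 10L)
  const <- res3[res3$column == "M_2", ]
  expect_true(all(const$p_value == 1))
  expect_false(any(const$significant))
  expect_match(const$note[1], "constant")
})

test_that("groups below the minimum size are excluded", {
  a <- make_group_matrix(sample(0:3, 9, TRUE), sample(0:3, 15, TRUE))
  groups <- rep(c("small", "big"), c(9, 15))
  res <- group_allele_ttests(a, groups, min_size = 10L)
  expect_false("small" %in% res$group)
  expect_true("big" %in% res$group)
})

test_that("BH q-values follow hand arithmetic and are monotone/nested", {
  # three groups x one informative column engineered to give chosen p's is
  # fiddly; check the family correction directly on the assembled table
  expect_equal(p.adjust(c(0.01, 0.02, 0.03), method = "BH"),
               c(0.03, 0.03, 0.03))

  set.seed(29)
  sim <- simulate_collection(sim_config(n_accessions = 60L, n_markers = 5L,
                                        n_races = 3L, seed = 29))
  a <- collapse_bulks(sim$bulks)
  res <- group_allele_ttests(a, sim$metadata$race1, min_size = 10L)
  tested <- res[res$tested, ]
  expect_true(all(tested$fdr_q >= tested$p_value - 1e-15))
  ord <- order(tested$p_value)
  expect_true(all(diff(tested$fdr_q[ord]) >= -1e-12))
  # significance sets nest across q levels
  s1 <- tested$fdr_q <= 0.01
  s2 <- tested$fdr_q <= 0.05
  expect_true(all(s2[s1]))
})

test_that("the G-statistic matches closed forms and the information identity", {
  expect_equal(rareset:::g_statistic(matrix(c(10, 0, 0, 10), 2)),
               40 * log(2), tolerance = 1e-12)
  # exactly proportional margins are independent: G = 0
  expect_equal(rareset:::g_statistic(matrix(c(6, 3, 4, 2), 2)), 0,
               tolerance = 1e-12)
  set.seed(37)
  for (rep in 1:20) {
    tab <- matrix(rpois(4, 8) + 1, 2)
    expect_equal(rareset:::g_statistic(tab), mutual_information_g(tab),
                 tolerance = 1e-10)
  }
})

test_that("G-test contingency analysis flags separation and skips degenerate margins", {
  a <- make_group_matrix(c(rep(3L, 10)), rep(0L, 10))
  groups <- rep(c("g", "h"), each = 10)
  res <- group_allele_gtests(a, groups, min_size = 10L)
  g <- res[res$group == "g", ]
  expect_equal(g$G_statistic, 40 * log(2), tolerance = 1e-12)
  expect_lt(g$p_value, 1e-6)
  expect_equal(g$direction, "+")

  # all accessions present the allele: degenerate margin, skipped
  a2 <- make_group_matrix(rep(3L, 10), rep(2L, 10))
  res2 <- group_allele_gtests(a2, groups, min_size = 10L)
  expect_false(any(res2$tested))
  expect_match(res2$note[1], "degenerate")

  # multi-level z tables remain available
  res3 <- group_allele_gtests(a, groups, min_size = 10L, levels = "z")
  expect_equal(res3$df[res3$group == "g"], 1L)  # z takes two levels here
})

test_that("partitioning a 2xk table never makes component G exceed the total", {
  set.seed(41)
  for (rep in 1:20) {
    tab <- matrix(rpois(8, 6) + 1, 2)  # 2 x 4
    total <- rareset:::g_statistic(tab)
    parts <- sum(vapply(seq_len(ncol(tab)), function(j)
      rareset:::g_statistic(cbind(tab[, j], rowSums(tab) - tab[, j])),
      numeric(1)))
    # each column-vs-rest component is a coarsening: sum bounded by k-1 times
    # total is not guaranteed, but no single component may exceed the total
    comp_max <- max(vapply(seq_len(ncol(tab)), function(j)
      rareset:::g_statistic(cbind(tab[, j], rowSums(tab) - tab[, j])),
      numeric(1)))
    expect_lte(comp_max, total + 1e-9)
  }
})

test_that("t and G tests agree on direction for well-separated groups", {
  set.seed(43)
  hits <- 0; total <- 0
  for (rep in 1:20) {
    z_in <- pmin(3L, pmax(0L, round(rnorm(15, 2.5, 0.5))))
    z_out <- pmin(3L, pmax(0L, round(rnorm(25, 0.5, 0.5))))
    a <- make_group_matrix(z_in, z_out)
    groups <- rep(c("g", "h"), c(15, 25))
    rt <- group_allele_ttests(a, groups, min_size = 10L)
    rg <- group_allele_gtests(a, groups, min_size = 10L)
    both <- merge(rt[rt$tested, c("group", "column", "direction")],
                  rg[rg$tested, c("group", "column", "direction")],
                  by = c("group", "column"))
    total <- total + nrow(both)
    hits <- hits + sum(both$direction.x == both$direction.y)
  }
  expect_gte(hits / total, 0.95)
})

test_that("a noiseless linear altitude signal is recovered exactly", {
  set.seed(47)
  a <- rand_accession_matrix(40, 6)
  masl <- 1000 + 100 * a$z[, 3]
  # a zero-residual fit makes summary.lm grumble; exactness is the point here
  fit <- suppressWarnings(masl_regression(a, masl))
  expect_equal(fit$terms, colnames(a$z)[3])
  cf <- coef(fit)
  expect_equal(unname(cf["(Intercept)"]), 1000, tolerance = 1e-9)
  expect_equal(unname(cf[colnames(a$z)[3]]), 100, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_equal(unname(predict(fit)), unname(masl), tolerance = 1e-9)
})

test_that("pure-noise altitude selects no terms under BIC in most replicates", {
  set.seed(53)
  zero_terms <- 0
  for (rep in 1:20) {
    a <- rand_accession_matrix(40, 8)
    masl <- rnorm(40, 2000, 300)
    fit <- masl_regression(a, masl)
    if (length(fit$terms) == 0) zero_terms <- zero_terms + 1
  }
  expect_gt(zero_terms, 10)
})

test_that("two planted coefficients are recovered in sign and magnitude", {
  set.seed(59)
  a <- rand_accession_matrix(200, 10)
  beta <- c(200, -150)
  masl <- 1500 + beta[1] * a$z[, 2] + beta[2] * a$z[, 7] + rnorm(200, 0, 50)
  fit <- masl_regression(a, masl)
  expect_setequal(intersect(fit$terms, colnames(a$z)[c(2, 7)]),
                  colnames(a$z)[c(2, 7)])
  cf <- coef(fit)
  expect_equal(unname(cf[colnames(a$z)[2]]), 200, tolerance = 0.2)
  expect_equal(unname(cf[colnames(a$z)[7]]), -150, tolerance = 0.2)
})

test_that("collinear candidate columns are skipped with a note", {
  set.seed(61)
  z <- matrix(sample(0:3, 30 * 3, TRUE), 30)
  z <- cbind(z, z[, 1])  # exact duplicate of an informative column
  rownames(z) <- sprintf("a%02d", 1:30)
  colnames(z) <- sprintf("M_%d", 1:4)
  a <- accession_matrix(z, 3L)
  masl <- 1000 + 120 * z[, 1] + rnorm(30, 0, 10)
  fit <- masl_regression(a, masl)
  picked <- intersect(fit$terms, c("M_1", "M_4"))
  expect_equal(length(picked), 1L)  # only one of the twin columns enters
  expect_true(setdiff(c("M_1", "M_4"), picked) %in% fit$skipped)
})
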