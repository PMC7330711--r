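test_that("pooled t test matches the base-R oracle and handles edge cases", {
  set.seed(1)
  for (k in 1:10) {
    a <- rnorm(5 + k)
    b <- rnorm(4 + k, mean = 0.5)
    got <- ttest_ind_pooled(a, b)
    want <- t.test(a, b, var.equal = TRUE)
    expect_equal(got$t, unname(want$statistic), tolerance = 1e-12)
    expect_equal(got$p, want$p.value, tolerance = 1e-12)
    expect_equal(got$df, unname(want$parameter))
  }

  same <- ttest_ind_pooled(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  # hand-computed worked example
  got <- ttest_ind_pooled(c(1, 2, 3), c(1, 2, 3, 4))
  sp2 <- (2 * 1 + 3 * (5 / 3)) / 5
  expect_equal(got$t, -0.5 / sqrt(sp2 * (1 / 3 + 1 / 4)), tolerance = 1e-12)

  expect_error(ttest_ind_pooled(c(1, 1, 1), c(1, 1)), "pooled variance")
  expect_error(ttest_ind_pooled(1, c(1, 2)), "at least 2")
  expect_error(ttest_ind_pooled(c(1, NA, 2), c(1, 2)), "finite")
})

test_that("summary-statistic t is zero under equal groups and antisymmetric", {
  set.seed(2)
  for (k in 1:20) {
    m <- rnorm(1); s <- runif(1, 0.5, 3); n <- sample(3:40, 1)
    expect_equal(ttest_from_summary(m, s, n, m, s, n)$t, 0)
    m2 <- rnorm(1); s2 <- runif(1, 0.5, 3); n2 <- sample(3:40, 1)
    expect_equal(ttest_from_summary(m, s, n, m2, s2, n2)$t,
                 -ttest_from_summary(m2, s2, n2, m, s, n)$t,
                 tolerance = 1e-12)
  }

  # agrees with the raw-data statistic through the sample summaries
  a <- rnorm(12); b <- rnorm(9, 1)
  expect_equal(ttest_from_summary(mean(a), sd(a), 12, mean(b), sd(b), 9)$t,
               ttest_ind_pooled(a, b)$t, tolerance = 1e-12)
  expect_error(ttest_from_summary(1, 0, 5, 2, 0, 5), "SDs are zero")
})

test_that("Spearman correlation uses average ranks and the t approximation", {
  expect_equal(spearman_rank(1:8, (1:8)^3)$rho, 1)
  expect_equal(spearman_rank(1:8, -(1:8)^3)$rho, -1)
  expect_equal(spearman_rank(1:8, (1:8)^3)$p, 0)

  # ties, n = 8: brute-force average-rank formula
  x <- c(1, 2, 2, 3, 4, 4, 4, 5)
  y <- c(2, 1, 3, 3, 5, 4, 6, 7)
  got <- spearman_rank(x, y)
  rx <- rank(x); ry <- rank(y)
  want_rho <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(got$rho, want_rho, tolerance = 1e-12)
  # cross-check against the independent base implementation
  expect_equal(got$rho, unname(cor.test(x, y, method = "spearman",
                                        exact = FALSE)$estimate),
               tolerance = 1e-12)
  expect_equal(got$p, cor.test(x, y, method = "spearman",
                               exact = FALSE)$p.value, tolerance = 1e-10)

  expect_error(spearman_rank(rep(1, 5), 1:5), "constant")
  expect_error(spearman_rank(1:2, 2:1), "at least 3")
})

test_that("Spearman is invariant under strictly monotone transforms", {
  set.seed(3)
  for (k in 1:15) {
    x <- rnorm(12)
    y <- rnorm(12)
    base <- spearman_rank(x, y)$rho
    expect_equal(spearman_rank(exp(x), y)$rho, base, tolerance = 1e-12)
    expect_equal(spearman_rank(x, y^3 + 5 * y)$rho, base,
                 tolerance = 1e-12)
  }
})

mock_counts <- function(vals) {
  # build a community_edge_counts whose left-LM intra count is `vals` and
  # everything else 0
  cn <- community_names()
  pn <- community_pair_names()
  structure(list(intra = stats::setNames(c(0, 0, vals, rep(0, 11))[1:14],
                                         cn),
                 inter = stats::setNames(rep(0L, 91), pn),
                 unassigned_touching = 0L, total_edges = as.integer(vals),
                 band = band_spec("high_beta"), density = 0.15),
            class = "community_edge_counts")
}

test_that("edgewise comparison reduces to the pooled t test per measure", {
  vals <- c(3, 4, 5, 2, 9, 8, 10, 7)
  groups <- rep(c("HC", "BD"), each = 4)
  counts <- lapply(vals, mock_counts)
  comp <- edgewise_group_comparison(counts, groups)
  expect_equal(nrow(comp), 105L)
  row <- comp[comp$measure == "intra:LM_L", ]
  want <- ttest_ind_pooled(vals[1:4], vals[5:8])
  expect_equal(row$t, want$t, tolerance = 1e-12)
  expect_equal(row$p, want$p, tolerance = 1e-12)
  expect_equal(row$t_patient_minus_control, -want$t, tolerance = 1e-12)
  expect_true(row$sig05)

  # all-zero measures have undefined t, flagged rather than infinite
  zrow <- comp[comp$measure == "intra:FPN_L", ]
  expect_true(zrow$undefined)
  expect_true(is.na(zrow$t))

  # significance flags nest
  expect_true(all(comp$sig05[comp$sig01], na.rm = TRUE))

  expect_error(edgewise_group_comparison(counts, rep("HC", 8)),
               "absent")
})

test_that("symptom correlations run within the patient group only", {
  vals <- c(1, 2, 3, 4, 2, 4, 6, 8, 10)
  groups <- c(rep("HC", 4), rep("BD", 5))
  counts <- lapply(vals, mock_counts)
  scores <- data.frame(subject_id = sprintf("s%d", 1:9), group = groups,
                       bdi = c(5, 5, 5, 5, 3, 6, 9, 12, 15),
                       hamd = c(NA, NA, NA, NA, 2, 3, 5, 7, 8))
  out <- symptom_correlations(counts, scores, "intra:LM_L",
                              scales = c("bdi", "hamd"))
  expect_equal(nrow(out), 2L)
  expect_equal(out$n, c(5L, 5L))
  expect_equal(out$rho[out$scale == "bdi"], 1)   # monotone in the count

  expect_error(symptom_correlations(counts[1:5], scores[1:5, ],
                                    "intra:LM_L"), "fewer than 3")
  scores$bdi[groups == "BD"] <- 7
  expect_error(symptom_correlations(counts, scores, "intra:LM_L",
                                    scales = "bdi"), "constant")
})

test_that("null edgewise p-values are approximately uniform", {
  comp <- null_study()
  p <- comp$p[!comp$undefined]
  expect_gte(length(p), 600L)
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_lt(unname(ks$statistic), 0.1)
})
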