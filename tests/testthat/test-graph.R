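sym_rand <- function(n, seed) {
  set.seed(seed)
  C <- matrix(rnorm(n * n), n)
  C <- (C + t(C)) / 2
  diag(C) <- NA_real_
  C
}

test_that("proportional thresholding keeps exactly the strongest pairs", {
  C <- matrix(0, 5, 5)
  vals <- c(10, 9, 8, 7, 6, 5, 4, 3, 2, 1)
  C[upper.tri(C)] <- vals
  C <- C + t(C)
  diag(C) <- NA_real_
  A <- threshold_proportional(C, 0.2)     # floor(0.2 * 10) = 2 edges
  expect_equal(attr(A, "n_edges"), 2L)
  # upper.tri fills column-wise: entries 10 and 9 sit at (1,2) and (1,3)
  expect_equal(A[1, 2], 1L)
  expect_equal(A[1, 3], 1L)
  expect_equal(sum(A), 4L)                # symmetric storage

  Afull <- threshold_proportional(C, 1.0)
  expect_equal(attr(Afull, "n_edges"), 10L)
  expect_true(all(Afull[upper.tri(Afull)] == 1L))
})

test_that("edge count follows the floor convention across densities", {
  dens <- seq(0.05, 0.30, by = 0.05)
  for (seed in 1:20) {
    C <- sym_rand(20, seed)
    for (d in dens) {
      A <- threshold_proportional(C, d)
      expect_identical(attr(A, "n_edges"), as.integer(floor(d * 190)))
      expect_identical(sum(A) / 2, floor(d * 190))
      expect_true(all(diag(A) == 0))
    }
  }
  # 446 ROIs at 15%: floor(0.15 * 99235) edges under this convention
  A446 <- threshold_proportional(sym_rand(446, 99), 0.15)
  expect_identical(attr(A446, "n_edges"), 14885L)
})

test_that("ties break deterministically by value then indices", {
  C <- matrix(0.5, 4, 4)
  diag(C) <- NA_real_
  A1 <- threshold_proportional(C, 1 / 3)   # floor(2) of 6 all-tied pairs
  A2 <- threshold_proportional(C, 1 / 3)
  expect_identical(A1, A2)
  expect_equal(attr(A1, "n_edges"), 2L)
  expect_equal(A1[1, 2], 1L)               # first by (row, col) order
  expect_equal(A1[1, 3], 1L)
  expect_error(threshold_proportional(C, 0), "density")
  expect_error(threshold_proportional(matrix(NA_real_, 3, 3), 0.5),
               "all off-diagonal")
})

test_that("partition table loading validates and maps to communities", {
  tf <- tempfile(fileext = ".tsv")
  df <- data.frame(roi_label = sprintf("roi_%d", 1:6),
                   network = rep(c("FPN", "LM", "DMN"), each = 2),
                   hemisphere = rep(c("L", "R"), 3))
  write.table(df, tf, sep = "\t", quote = FALSE, row.names = FALSE)
  p <- load_partition(tf, df$roi_label)
  expect_equal(sort(as.integer(table(p))), rep(1L, 6))
  expect_equal(unname(p["roi_1"]), "FPN_L")
  expect_equal(unname(p["roi_4"]), "LM_R")

  # missing label -> unassigned with a warning
  expect_warning(p2 <- load_partition(tf, c(df$roi_label, "roi_99")),
                 "unassigned")
  expect_equal(unname(p2["roi_99"]), "unassigned")

  # duplicates and unknown networks are hard errors naming the culprit
  write.table(rbind(df, df[1, ]), tf, sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_error(load_partition(tf, df$roi_label), "roi_1")
  df$network[2] <- "BOGUS"
  write.table(df, tf, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_partition(tf, df$roi_label), "BOGUS")
})

test_that("community edge counts obey closed forms and conservation", {
  labels <- sprintf("r%d", 1:5)
  part <- structure(c("FPN_L", "FPN_L", "FPN_L", "LM_R", "LM_R"),
                    names = labels, class = "network_partition")
  A <- matrix(1L, 5, 5, dimnames = list(labels, labels))
  diag(A) <- 0L
  cc <- community_edge_counts(A, part)
  expect_equal(unname(cc$intra["FPN_L"]), 3L)   # C(3,2)
  expect_equal(unname(cc$intra["LM_R"]), 1L)    # C(2,2)
  expect_equal(unname(cc$inter["FPN_L:LM_R"]), 6L)
  expect_equal(cc$total_edges, 10L)

  A0 <- matrix(0L, 5, 5, dimnames = list(labels, labels))
  cc0 <- community_edge_counts(A0, part)
  expect_equal(cc0$total_edges, 0L)
  expect_true(all(cc0$intra == 0) && all(cc0$inter == 0))

  # conservation on random graphs, with some unassigned ROIs
  labels20 <- sprintf("r%d", 1:20)
  part20 <- make_default_partition(labels20)
  part20[c(3, 11)] <- "unassigned"
  for (seed in 1:200) {
    C <- sym_rand(20, seed)
    dimnames(C) <- list(labels20, labels20)
    A <- threshold_proportional(C, 0.2)
    cc <- community_edge_counts(A, part20)
    expect_identical(sum(cc$intra) + sum(cc$inter) + cc$unassigned_touching,
                     cc$total_edges)
  }
})

test_that("relabeling ROIs permutes counts consistently", {
  labels <- sprintf("r%d", 1:20)
  part <- make_default_partition(labels)
  C <- sym_rand(20, 42)
  dimnames(C) <- list(labels, labels)
  cc <- community_edge_counts(threshold_proportional(C, 0.25), part)

  set.seed(9)
  perm <- sample(20)
  Cp <- C[perm, perm]
  partp <- part[perm]
  class(partp) <- "network_partition"
  ccp <- community_edge_counts(threshold_proportional(Cp, 0.25), partp)
  expect_equal(cc$intra, ccp$intra)
  expect_equal(cc$inter, ccp$inter)
})

test_that("density sweep is monotone and consistent with single calls", {
  labels <- sprintf("r%d", 1:14)
  part <- make_default_partition(labels)
  C <- sym_rand(14, 8)
  dimnames(C) <- list(labels, labels)
  sweep_out <- density_sweep(C, part)
  mv <- vapply(sweep_out, measure_vector, numeric(105))
  expect_true(all(diff(t(mv)) >= 0))      # every count nondecreasing

  single <- community_edge_counts(threshold_proportional(C, 0.15), part)
  expect_equal(sweep_out[["0.15"]]$intra, single$intra)
  expect_equal(sweep_out[["0.15"]]$inter, single$inter)
})

test_that("hand-enumerated toy sweep matches brute force", {
  n <- 10
  labels <- sprintf("r%d", 1:n)
  part <- structure(rep(c("FPN_L", "LM_L"), each = 5), names = labels,
                    class = "network_partition")
  C <- sym_rand(n, 77)
  dimnames(C) <- list(labels, labels)
  for (d in c(0.1, 0.3)) {
    k <- floor(d * n * (n - 1) / 2)
    ut <- which(upper.tri(C), arr.ind = TRUE)
    ord <- order(-C[ut])
    keep <- ut[ord[seq_len(k)], , drop = FALSE]
    brute <- c(FPN_L = 0L, LM_L = 0L, inter = 0L)
    for (e in seq_len(nrow(keep))) {
      ci <- unname(part[keep[e, 1]]); cj <- unname(part[keep[e, 2]])
      if (ci == cj) brute[ci] <- brute[ci] + 1L else
        brute["inter"] <- brute["inter"] + 1L
    }
    cc <- community_edge_counts(threshold_proportional(C, d), part)
    expect_identical(unname(cc$intra["FPN_L"]), brute[["FPN_L"]])
    expect_identical(unname(cc$intra["LM_L"]), brute[["LM_L"]])
    expect_identical(unname(cc$inter["FPN_L:LM_L"]), brute[["inter"]])
  }
})
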