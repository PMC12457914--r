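# A small verdict table + feature table with hand-set cutoffs, used to build
# landscapes without running the full selection pipeline.
toy_landscape <- function(values, labels, K = 2) {
  n <- length(labels)
  tab <- tibble::tibble(nut_id = sprintf("n%02d", seq_len(n)), ct = "toy",
                        kernel_status = labels)
  for (f in names(values)) tab[[f]] <- values[[f]]
  verdicts <- tibble::tibble(
    feature_1 = names(values), feature_2 = NA_character_,
    cutoff_1 = 0.5, cutoff_2 = NA_real_,
    category = "1", blank = 0L, filled = 0L, statistic = "odds",
    overlap = 0, tau = 0.1, is_major = TRUE, M = 0L
  )
  build_landscape(verdicts, tab, K = K)
}

test_that("membership matrices encode categorized codes against the verdict cutoffs", {
  vals <- list(f1 = c(0.9, 0.9, 0.1, 0.1), f2 = c(0.1, 0.1, 0.9, 0.9))
  L <- toy_landscape(vals, c("blank", "blank", "filled", "filled"))
  expect_equal(dim(L$matrix), c(2, 4))
  expect_equal(unname(L$matrix["f1=1", ]), c(1, 1, 0, 0))
  expect_equal(unname(L$matrix["f2=1", ]), c(0, 0, 1, 1))
  # matrix content is binary; reordering by the trees is a pure permutation
  expect_setequal(unique(as.vector(L$matrix)), c(0, 1))
  expect_setequal(L$col_tree$labels, colnames(L$matrix))
})

test_that("zero major categories is an error suggesting a larger tau", {
  verdicts <- tibble::tibble(
    feature_1 = "f1", feature_2 = NA_character_, cutoff_1 = 0.5,
    cutoff_2 = NA_real_, category = "1", blank = 0L, filled = 0L,
    statistic = "odds", overlap = 0.5, tau = 0.1, is_major = FALSE, M = 0L
  )
  tab <- tibble::tibble(nut_id = "a", ct = "x", kernel_status = "filled", f1 = 0.2)
  expect_error(category_membership(verdicts, tab), "tau")
})

test_that("identical nuts are mutual nearest neighbours at distance zero", {
  vals <- list(f1 = c(0.9, 0.9, 0.9, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1, 0.9),
               f2 = c(0.9, 0.9, 0.9, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1))
  L <- toy_landscape(vals, rep("filled", 11), K = 2)
  prof <- L$knn[L$knn$nut_id == "n01", ]
  expect_equal(prof$distance, c(0, 0))
  expect_equal(prof$neighbour_id, c("n02", "n03"))
})

test_that("knn profiles equal the exhaustive all-pairs oracle", {
  set.seed(21)
  m <- matrix(rbinom(20 * 12, 1, 0.4), nrow = 12,
              dimnames = list(paste0("cat", 1:12), sprintf("n%02d", 1:20)))
  got <- knn_profile(m, K = 5)
  want <- oracle_knn(m, K = 5)
  expect_equal(got$neighbour_id, want$neighbour_id)
  expect_equal(got$distance, want$distance)
  # per-nut distances are non-decreasing in rank
  for (id in unique(got$nut_id)) {
    expect_true(all(diff(got$distance[got$nut_id == id]) >= 0))
  }
  expect_error(knn_profile(m, K = 20), "smaller")
})

test_that("a planted two-block matrix splits exactly at the 2-branch Ward-D2 cut", {
  tabs <- ct_regime_landscapes()
  L <- tabs$landscapes$CT3
  blocks <- stats::cutree(L$col_tree, k = 2)
  # the cut must coincide with the generator's latent block sign exactly
  s <- tabs$signs$CT3
  split_tbl <- table(blocks, s)
  expect_equal(nrow(split_tbl), 2)
  expect_true(all(apply(split_tbl, 1, min) == 0))
  expect_true(all(apply(split_tbl, 1, max) > 0))
})

test_that("branch blank rates conserve the global blank fraction at any cut", {
  tabs <- ct_regime_landscapes()
  L <- tabs$landscapes$CT3
  global <- mean(L$labels == "blank")
  for (k in 2:6) {
    br <- branch_blank_rates(L, n_branches = k)
    expect_equal(attr(br, "overall"), global)
    expect_equal(sum(br$size), 90)
    expect_equal(sum(br$n_blank), 21)
  }
  # all-filled landscape: every branch rate is zero
  vals <- list(f1 = runif(12), f2 = runif(12))
  L0 <- toy_landscape(vals, rep("filled", 12), K = 2)
  br0 <- branch_blank_rates(L0, n_branches = 3)
  expect_equal(br0$rate, rep(0, nrow(br0)))
})

test_that("landscape tidiers and plots expose the matrix faithfully", {
  vals <- list(f1 = c(0.9, 0.1, 0.9, 0.1), f2 = c(0.1, 0.9, 0.9, 0.1))
  L <- toy_landscape(vals, c("blank", "filled", "filled", "filled"))
  td <- tidy(L)
  expect_equal(nrow(td), 8)
  expect_equal(sum(td$member), sum(L$matrix))
  gl <- glance(L)
  expect_equal(gl$n_nuts, 4)
  expect_equal(gl$n_blank, 1)
  expect_s3_class(autoplot(L), "ggplot")
})
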