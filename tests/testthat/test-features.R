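test_that("region partition sizes follow the ceiling rule", {
  p <- region_partition(sample(100), 30)
  expect_length(p$closest, 30)
  expect_length(p$farthest, 30)
  # n = 7, k = 30: ceiling(2.1) = 3
  p7 <- region_partition(sample(7), 30)
  expect_length(p7$closest, 3)
  expect_length(p7$farthest, 3)
  expect_error(region_partition(integer(0), 30), "empty")
})

test_that("closest-k and farthest-(100-k) cover the pixel set", {
  set.seed(11)
  for (n in c(7, 50, 90, 101)) {
    ranks <- sample(n)
    for (k in c(30, 50, 70)) {
      a <- region_partition(ranks, k)$closest
      b <- region_partition(ranks, 100 - k)$farthest
      expect_setequal(c(a, b), seq_len(n))
      # overlap is exactly the ceiling excess: one shared boundary pixel
      # when k% of n is not integral, none otherwise
      excess <- ceiling(k / 100 * n) + ceiling((100 - k) / 100 * n) - n
      expect_length(intersect(a, b), excess)
    }
  }
})

test_that("colour proportions form a probability vector and match direct counting", {
  pal <- demo_palette()
  set.seed(4)
  codes <- sample(1:8, 200, replace = TRUE)
  v <- colour_proportions(codes, pal)
  expect_equal(sum(v), 1)
  expect_equal(unname(v), as.vector(tabulate(codes, 8) / 200))
  # single colour
  expect_equal(unname(colour_proportions(rep(8L, 10), pal)), c(rep(0, 7), 1))
  # 50/50 mix
  expect_equal(unname(colour_proportions(rep(c(1L, 2L), 25), pal)),
               c(0.5, 0.5, rep(0, 6)))
  # all background: flagged zero vector
  z <- colour_proportions(rep(background_id(pal), 5), pal)
  expect_equal(as.numeric(z), rep(0, 8))
  expect_true(attr(z, "all_background"))
})

test_that("a nut's feature vector is 56 region-wise probability vectors", {
  pal <- demo_palette()
  set.seed(6)
  shape <- synth_nut_pixels(c(0, 0), a = 45, b = 27, theta = 0.5, prot_len = 13)
  k <- sample(1:8, nrow(shape), replace = TRUE)
  px <- tibble::tibble(
    x = shape$x, y = shape$y,
    r = pal$r[k], g = pal$g[k], b = pal$b[k]
  )
  fv <- feature_vector(px, pal)
  expect_length(fv, 56)
  expect_named(fv, feature_names())
  expect_true(all(fv >= 0 & fv <= 1))
  for (rg in c("full", "tip_closest_30", "tip_farthest_70")) {
    expect_equal(sum(fv[sprintf("%s_c%d", rg, 1:8)]), 1)
  }
  # deterministic
  expect_identical(feature_vector(px, pal), fv)
  # uniform single-colour nut: every region is the same unit vector
  px1 <- px
  px1$r <- pal$r[3]; px1$g <- pal$g[3]; px1$b <- pal$b[3]
  fv1 <- feature_vector(px1, pal)
  expect_equal(unname(fv1[sprintf("full_c%d", 1:8)]),
               c(0, 0, 1, rep(0, 5)))
  expect_equal(unname(fv1), rep(c(0, 0, 1, rep(0, 5)), 7))
})

test_that("feature vectors agree with per-region recomputation", {
  pal <- demo_palette()
  set.seed(13)
  shape <- synth_nut_pixels(c(0, 0), a = 40, b = 24, theta = -1, prot_len = 12)
  k <- sample(1:8, nrow(shape), replace = TRUE)
  px <- tibble::tibble(x = shape$x, y = shape$y,
                       r = pal$r[k], g = pal$g[k], b = pal$b[k])
  fv <- feature_vector(px, pal)
  # oracle: classify, rank by tip distance, count subsets directly
  codes <- oracle_classify(px, pal)
  tp <- locate_tip(px)
  d <- tp$pixels$distance
  o <- order(d, seq_along(d))
  n <- length(d)
  m <- ceiling(0.3 * n)
  closest30 <- codes[o[1:m]]
  expect_equal(unname(fv[sprintf("tip_closest_30_c%d", 1:8)]),
               as.vector(tabulate(closest30, 8) / m))
  farthest50 <- codes[o[(n - ceiling(0.5 * n) + 1):n]]
  expect_equal(unname(fv[sprintf("tip_farthest_50_c%d", 1:8)]),
               as.vector(tabulate(farthest50, 8) / ceiling(0.5 * n)))
})

test_that("variability filter drops flat features and honours the >= rule", {
  tab <- make_feature_table(n = 20, n_blank = 5, seed = 8)
  tab$full_c1 <- 0.5                                  # constant: must go
  tab$full_c2 <- rep(c(0.49, 0.51), 10)               # sd 0.01026: stays
  tab$full_c3 <- rep(c(0.492, 0.508), 10)             # sd 0.00821: goes
  out <- variability_filter(tab)
  kept <- feature_columns(out)
  expect_false("full_c1" %in% kept)
  expect_true("full_c2" %in% kept)
  expect_false("full_c3" %in% kept)
  # hand-computed SDs: sd = d * sqrt(n/(n-1)) for +/- d around the mean
  expect_equal(0.01 * sqrt(20 / 19), sd(tab$full_c2), tolerance = 1e-12)
  # retention at a threshold equal to a column's own SD (>=, not >)
  out2 <- variability_filter(tab, min_sd = sd(tab$full_c2))
  expect_true("full_c2" %in% feature_columns(out2))
  rep_tbl <- retention_report(out)
  expect_equal(nrow(rep_tbl), 7)
  expect_equal(names(rep_tbl), c("region", paste0("c", 1:8)))
})

test_that("median categorization assigns ties to code 0", {
  tab <- tibble::tibble(nut_id = letters[1:4], ct = "x",
                        kernel_status = c("blank", "filled", "filled", "filled"),
                        f = c(0.1, 0.2, 0.3, 0.4))
  cf <- categorize(tab, "f")
  expect_equal(cf$cutoff, 0.25)
  expect_equal(cf$codes, c(0L, 0L, 1L, 1L))
  # a value exactly at an explicit cutoff goes to code 0
  cf2 <- categorize(tab, "f", cutoff = 0.3)
  expect_equal(cf2$codes, c(0L, 0L, 0L, 1L))
  tab$g <- 0.2
  expect_error(categorize(tab, "g"), "identical")
})

test_that("order-2 pairing counts", {
  expect_equal(nrow(pair_features(feature_names())), 1540)
  expect_equal(nrow(pair_features(c("a", "b"))), 1)
  expect_equal(nrow(pair_features(letters[1:10])), 45)
})
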