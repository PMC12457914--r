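# Exact values below were frozen from direct -sum(p log p) / ratio arithmetic
# on the published contingency-table counts.

test_that("row entropies (natural log) are exact on the published tables", {
  expect_equal(row_entropy(c(0, 46)), 0)
  expect_equal(row_entropy(c(9, 35)), 0.5066395578, tolerance = 1e-9)
  expect_equal(row_entropy(c(9, 81)), 0.3250829734, tolerance = 1e-9)
  expect_equal(row_entropy(c(1, 44)), 0.1065659588, tolerance = 1e-9)
  expect_equal(row_entropy(c(8, 37)), 0.4680070431, tolerance = 1e-9)
  expect_equal(row_entropy(c(9, 36)), 0.5004024235, tolerance = 1e-9)
  expect_equal(row_entropy(c(10, 80)), 0.3488320958, tolerance = 1e-9)
  expect_equal(row_entropy(c(19, 26)), 0.6809991433, tolerance = 1e-9)
  expect_equal(row_entropy(c(2, 43)), 0.1818202823, tolerance = 1e-9)
  expect_equal(row_entropy(c(21, 69)), 0.5432727813, tolerance = 1e-9)
  # two-column entropies live in [0, log 2]
  set.seed(1)
  for (i in 1:20) {
    cts <- rpois(2, 20)
    if (sum(cts) == 0) next
    e <- row_entropy(cts)
    expect_gte(e, 0)
    expect_lte(e, log(2) + 1e-12)
  }
  expect_error(row_entropy(c(0, 0)), "positive")
})

test_that("blank odds reproduce the published ratios and handle zero denominators", {
  expect_equal(row_odds(c(19, 26)), 19 / 26)
  expect_equal(row_odds(c(2, 43)), 2 / 43)
  expect_equal(row_odds(c(21, 69)), 21 / 69)
  expect_equal(row_odds(c(0, 46)), 0)
  expect_equal(row_odds(c(5, 0)), Inf)
})

test_that("contingency tables are assembled with entropies, odds and baselines", {
  cat_codes <- c(rep("0", 46), rep("1", 44))
  labels <- c(rep("filled", 46), rep("blank", 9), rep("filled", 35))
  tab <- make_table(cat_codes, labels)
  expect_equal(unname(tab$counts), matrix(c(0, 9, 46, 35), ncol = 2))
  expect_equal(unname(tab$row_entropy), c(0, row_entropy(c(9, 35))))
  expect_equal(tab$baseline_entropy, row_entropy(c(9, 81)))
  expect_equal(tab$baseline_odds, 9 / 81)
  expect_error(make_table(cat_codes, replace(labels, 1, "cracked")), "blank")
  # single-category feature collapses to the column sums
  tab1 <- make_table(rep("0", 90), c(rep("blank", 21), rep("filled", 69)))
  expect_equal(unname(tab1$counts[1, ]), c(21, 69))
  # tidiers
  td <- tidy(tab)
  expect_equal(td$blank, c(0, 9))
  gl <- glance(tab)
  expect_equal(gl$n, 90)
  expect_equal(gl$baseline_odds, 1 / 9)
})

test_that("both ensembles preserve column sums and their means converge", {
  tab <- as_ceda_table(ct_fixtures()$T2)
  ens <- simulate_ensembles(tab, M = 1000, seed = 30)
  for (arr in list(ens$alternative, ens$null)) {
    expect_true(all(apply(arr, 3, colSums) == c(9, 81)))
  }
  # alternative keeps structural zeros: observed blank proportion of row 0 is 0
  expect_true(all(ens$alternative[1, 1, ] == 0))
  # null blank column row-0 mean ~ Binomial(9, 46/90) within 3 SE
  m <- mean(ens$null[1, 1, ])
  p <- 46 / 90
  se <- sqrt(9 * p * (1 - p) / 1000)
  expect_lt(abs(m - 9 * p), 3 * se)
  # alternative filled column row-1 mean ~ Binomial(81, 35/81) within 3 SE
  m2 <- mean(ens$alternative[2, 2, ])
  p2 <- 35 / 81
  se2 <- sqrt(81 * p2 * (1 - p2) / 1000)
  expect_lt(abs(m2 - 81 * p2), 3 * se2)
  # reproducible from the seed
  ens2 <- simulate_ensembles(tab, M = 1000, seed = 30)
  expect_identical(ens$alternative, ens2$alternative)
  expect_error(simulate_ensembles(tab, M = 0, seed = 1), "M")
})

test_that("overlap area is a symmetric, affine-invariant measure on [0, 1]", {
  set.seed(5)
  a <- rnorm(500)
  b <- rnorm(500, 3)
  expect_equal(overlap_area(a, a), 1)
  expect_equal(overlap_area(a, a + 100), 0)
  o <- overlap_area(a, b)
  expect_gte(o, 0)
  expect_lte(o, 1)
  expect_equal(o, overlap_area(b, a))
  expect_equal(overlap_area(2 * a - 7, 2 * b - 7), o)
  # point masses: identical -> 1, distinct -> 0
  expect_equal(overlap_area(rep(1, 10), rep(1, 10)), 1)
  expect_equal(overlap_area(rep(1, 10), rep(2, 10)), 0)
  # infinite odds are routed to a shared overflow bin
  expect_equal(overlap_area(c(rep(1, 9), Inf), c(rep(50, 9), Inf)), 0.1)
})

test_that("category assessment flags planted associations and spares noise", {
  # a strongly associated synthetic feature is declared major at tau = 0.1
  tab <- make_feature_table(
    n = 90, n_blank = 45,
    planted = list(list(feature = "full_c1",
                        p_high_blank = 10 / 11, p_high_filled = 1 / 11)),
    seed = 14
  )
  cf <- categorize(tab, "full_c1")
  ct <- make_table(as.character(cf$codes), tab$kernel_status)
  v <- lapply(1:2, function(r)
    assess_category(ct, r, statistic = "odds", M = 1000, seed = 40 + r, tau = 0.1))
  expect_true(all(vapply(v, function(x) x$is_major, logical(1))))
  # independent noise features are usually not major
  set.seed(60)
  n_major <- 0L
  n_total <- 0L
  for (s in 1:10) {
    noise <- make_feature_table(n = 90, n_blank = 45, seed = 100 + s)
    cf <- categorize(noise, "tip_closest_50_c4")
    ctn <- make_table(as.character(cf$codes), noise$kernel_status)
    for (r in 1:2) {
      n_total <- n_total + 1L
      n_major <- n_major + assess_category(ctn, r, statistic = "odds",
                                           M = 500, seed = NULL,
                                           tau = 0.1)$is_major
    }
  }
  expect_lte(n_major / n_total, 0.15)
})

test_that("the whole selection pipeline is reproducible at a fixed seed", {
  tab <- make_feature_table(n = 60, n_blank = 15, seed = 3)
  sub <- tab[, c("nut_id", "ct", "kernel_status",
                 sprintf("full_c%d", 1:4))]
  v1 <- select_major(sub, order = 1, M = 200, seed = 77, tau = 0.1)
  v2 <- select_major(sub, order = 1, M = 200, seed = 77, tau = 0.1)
  expect_identical(v1, v2)
  # order 2 assesses the joint cells of every pair
  v2o <- select_major(sub, order = 2, M = 50, seed = 78, tau = 0.1)
  expect_setequal(unique(paste(v2o$feature_1, v2o$feature_2)),
                  with(pair_features(sprintf("full_c%d", 1:4)),
                       paste(feature_1, feature_2)))
  expect_true(all(v2o$category %in% c("00", "01", "10", "11")))
  expect_true(all(v2o$blank + v2o$filled > 0))
})
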