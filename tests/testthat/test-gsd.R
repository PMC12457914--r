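random_landscape <- function(n_cat, n_nut, seed, labels = NULL) {
  set.seed(seed)
  m <- matrix(rbinom(n_cat * n_nut, 1, 0.45), nrow = n_cat,
              dimnames = list(paste0("cat", seq_len(n_cat)),
                              sprintf("n%02d", seq_len(n_nut))))
  if (is.null(labels)) labels <- rep("filled", n_nut)
  structure(
    list(matrix = m,
         row_tree = stats::hclust(stats::dist(m), "ward.D2"),
         col_tree = stats::hclust(stats::dist(t(m)), "ward.D2"),
         knn = NULL, labels = stats::setNames(labels, colnames(m)),
         K = 10, ct_label = "rand"),
    class = "landscape"
  )
}

test_that("candidate neighbours match an exhaustive distance scan", {
  L <- random_landscape(15, 40, seed = 31)
  set.seed(32)
  for (i in 1:5) {
    x <- rbinom(15, 1, 0.5)
    got <- candidate_neighbours(x, L, K = 10)
    d <- sqrt(colSums((L$matrix - x)^2))
    o <- order(d, colnames(L$matrix))[1:10]
    expect_equal(got$nut_id, colnames(L$matrix)[o])
    expect_equal(got$distance, unname(d[o]))
  }
  # a query equal to a reference puts that reference first at distance 0
  got <- candidate_neighbours(L$matrix[, 7], L, K = 3)
  expect_equal(got$nut_id[1], colnames(L$matrix)[7])
  expect_equal(got$distance[1], 0)
  expect_error(candidate_neighbours(rbinom(3, 1, 0.5), L), "categories")
})

test_that("odds_g equals the brute-force neighbourhood enumeration", {
  for (s in 1:6) {
    L <- random_landscape(12, 30, seed = 100 + s)
    set.seed(200 + s)
    x <- rbinom(12, 1, 0.5)
    got <- odds_g(x, L, K = 10)
    want <- oracle_odds_g(x, L$matrix, K = 10)
    expect_equal(as.numeric(got), want$odds_g)
    expect_equal(attr(got, "votes"), want$votes)
    expect_gte(as.numeric(got), 0)
    expect_lte(as.numeric(got), 1)
  }
})

test_that("a reference nut evaluated against its own landscape scores at least 1/K", {
  L <- random_landscape(12, 30, seed = 55)
  for (i in c(1, 10, 30)) {
    g <- odds_g(L$matrix[, i], L, K = 10)
    expect_gte(as.numeric(g), 1 / 10)
  }
})

test_that("the printed worked example yields zero votes and OddsG 0", {
  fx <- nn_fixture()
  out <- admission_votes(fx$nn, fx$query)
  expect_equal(out$votes, 0L)
  expect_equal(out$odds_g, 0)
  # sanity of the fixture itself: every query distance exceeds every
  # candidate radius
  expect_true(all(fx$query > apply(fx$nn, 2, max)))
  # a query inside the radii is admitted
  out2 <- admission_votes(fx$nn, rep(4, 10))
  expect_equal(out2$votes, 10L)
  expect_true(is.na(out2$odds_g))
})

test_that("stage classification matches the six published patterns", {
  expect_equal(as.character(classify_stage(c(0, 0, 0))$stage), "before-CT1")
  expect_equal(as.character(classify_stage(c(1, 0, 0))$stage), "at-CT1")
  expect_equal(as.character(classify_stage(c(0.5, 0.5, 0))$stage), "between-CT1-CT2")
  expect_equal(as.character(classify_stage(c(0, 1, 0))$stage), "at-CT2")
  expect_equal(as.character(classify_stage(c(0, 0.5, 0.5))$stage), "between-CT2-CT3")
  expect_equal(as.character(classify_stage(c(0, 0, 1))$stage), "at-CT3")
  # total and deterministic on a grid
  g <- seq(0, 1, by = 0.25)
  for (a in g) for (b in g) for (c in g) {
    s1 <- classify_stage(c(a, b, c))
    s2 <- classify_stage(c(a, b, c))
    expect_identical(s1$stage, s2$stage)
    expect_false(is.na(s1$stage))
  }
})

test_that("cloned reference batches classify to their own time point", {
  rg <- ct_regime_landscapes()
  for (src in c("CT1", "CT2", "CT3")) {
    queries <- lapply(c("CT1", "CT2", "CT3"), function(ct)
      category_membership(rg$verdicts[[ct]], rg$tables[[src]]))
    bs <- batch_stage(queries, rg$landscapes, K = 10)
    expect_equal(bs$batch_stage, paste0("at-", src))
    expect_gte(mean(as.character(bs$nuts$stage) == paste0("at-", src)), 0.9)
  }
})

test_that("all-zero landscape vectors fall before CT1", {
  rg <- ct_regime_landscapes()
  queries <- lapply(rg$landscapes, function(L)
    matrix(0L, nrow(L$matrix), 3, dimnames = list(NULL, paste0("q", 1:3))))
  bs <- batch_stage(queries, rg$landscapes, K = 10)
  expect_equal(bs$batch_stage, "before-CT1")
  expect_true(all(bs$nuts$odds_g1 == 0))
})

test_that("blank prevalence recovers planted branch rates and flags outliers", {
  rg <- ct_regime_landscapes()
  L <- rg$landscapes$CT3
  br <- branch_blank_rates(L, n_branches = 2)
  # queries cloned from the references recover their own branch rates exactly
  res <- blank_prevalence(L$matrix, L, K = 10, n_branches = 2)
  expect_equal(res$n_outliers, 0)
  grp <- attr(br, "membership")
  expect_equal(res$annotations$rate,
               unname(br$rate[match(grp[res$annotations$neighbour_id], br$branch)]))
  # queries cloned from an all-filled branch annotate 0 throughout
  filled_branch <- names(grp)[grp == br$branch[br$rate == 0][1]]
  res0 <- blank_prevalence(L$matrix[, filled_branch[1:5]], L, K = 10,
                           n_branches = 2)
  expect_equal(res0$annotations$rate, rep(0, 5))
  expect_equal(res0$estimate, 0)
  # queries admitted by no reference (e.g. empty colour landscapes, far from
  # every block) are outliers, excluded from the estimate
  zero <- matrix(0L, nrow(L$matrix), 5,
                 dimnames = list(rownames(L$matrix), paste0("q", 1:5)))
  res2 <- blank_prevalence(zero, L, K = 10, n_branches = 2)
  expect_equal(res2$n_outliers, 5)
  expect_true(all(res2$annotations$outlier))
  expect_true(is.na(res2$estimate))
})
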