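# Three synthetic colour regimes standing in for the three critical time
# points. Per-regime blank counts follow the study design (9, 10, 21 blanks
# out of 90). Each regime carries a latent contrast axis loading on a
# stage-specific colour (tip/hull colour 8 early, colour 1 mid, colour 5
# late; one feature per region), so each stage has its own tightly
# co-varying block system aligned with kernel status — the structure the
# growth-stage algorithm relies on.

ct_regime_table <- function(ct, seed) {
  colour <- switch(ct, CT1 = 8, CT2 = 1, CT3 = 5)
  n_blank <- switch(ct, CT1 = 9, CT2 = 10, CT3 = 21)
  regions <- c("full", "tip_closest_30", "tip_closest_50", "tip_closest_70",
               "tip_farthest_30", "tip_farthest_50", "tip_farthest_70")
  make_feature_table(
    n = 90, n_blank = n_blank,
    latent = list(features = sprintf("%s_c%d", regions, colour),
                  p_pos_blank = 0.97),
    seed = seed, ct = ct
  )
}

# Full per-regime pipeline: variability filter, order-1 major-category
# selection, landscape assembly. Computed once per test run.
ct_regime_landscapes <- local({
  cache <- NULL
  function(seed = 20, M = 500, tau = 0.2, K = 10) {
    if (!is.null(cache)) return(cache)
    cts <- c("CT1", "CT2", "CT3")
    raw <- lapply(seq_along(cts), function(i) ct_regime_table(cts[i], seed = seed + i))
    tables <- lapply(raw, variability_filter)
    names(tables) <- cts
    signs <- lapply(raw, function(t) attr(t, "latent")$block_sign)
    names(signs) <- cts
    verdicts <- lapply(seq_along(cts), function(i) {
      lat <- attr(raw[[i]], "latent")$features
      sub <- tables[[i]][, c("nut_id", "ct", "kernel_status",
                             intersect(lat, names(tables[[i]])))]
      select_major(sub, order = 1, statistic = "odds", M = M,
                   seed = seed + 10 + i, tau = tau)
    })
    names(verdicts) <- cts
    landscapes <- lapply(cts, function(ct) {
      build_landscape(verdicts[[ct]], tables[[ct]], K = K, ct_label = ct)
    })
    names(landscapes) <- cts
    cache <<- list(tables = tables, verdicts = verdicts,
                   landscapes = landscapes, signs = signs)
    cache
  }
})
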