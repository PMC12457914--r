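# Independent brute-force oracles and small fixture builders used across the
# suite. Oracles are deliberately plain-loop implementations, kept separate
# from the package's vectorised paths.

# Exhaustive nearest-centroid scan (ties to the lower cluster id).
oracle_classify <- function(pixels, palette) {
  cent <- cbind(palette$r, palette$g, palette$b)
  vapply(seq_len(nrow(pixels)), function(i) {
    d <- sqrt(rowSums(sweep(cent, 2, c(pixels$r[i], pixels$g[i], pixels$b[i]))^2))
    palette$id[which.min(d)]
  }, numeric(1))
}

# All-pairs K nearest neighbours of binary column vectors.
oracle_knn <- function(m, K) {
  ids <- colnames(m)
  out <- list()
  for (i in seq_along(ids)) {
    d <- vapply(seq_along(ids), function(j) sqrt(sum((m[, i] - m[, j])^2)), numeric(1))
    d <- d[-i]; nb <- ids[-i]
    o <- order(d, nb)[seq_len(K)]
    out[[i]] <- data.frame(nut_id = ids[i], rank = seq_len(K),
                           neighbour_id = nb[o], distance = d[o])
  }
  do.call(rbind, out)
}

# Plain-loop neighbourhood-vote score: enumerate every reference
# neighbourhood, apply the admission test, take the best intersection share.
oracle_odds_g <- function(x, m, K) {
  ids <- colnames(m)
  dq <- vapply(seq_along(ids), function(j) sqrt(sum((x - m[, j])^2)), numeric(1))
  candi <- ids[order(dq, ids)[seq_len(K)]]
  best <- 0; votes <- 0
  for (z in candi) {
    j <- match(z, ids)
    dz <- vapply(seq_along(ids), function(k) sqrt(sum((m[, j] - m[, k])^2)), numeric(1))
    o <- order(dz[-j], ids[-j])[seq_len(K)]
    nz <- ids[-j][o]
    rz <- dz[-j][o][K]
    if (dq[j] <= rz) {
      votes <- votes + 1
      best <- max(best, length(intersect(nz, candi)) / K)
    }
  }
  list(odds_g = best, votes = votes)
}

# Filled axis-aligned rectangle of pixels, optionally rotated about its centre.
rect_pixels <- function(w = 100, h = 40, theta = 0) {
  g <- expand.grid(x = seq_len(w) - 1, y = seq_len(h) - 1)
  cx <- mean(g$x); cy <- mean(g$y)
  if (theta != 0) {
    x <- cx + (g$x - cx) * cos(theta) - (g$y - cy) * sin(theta)
    y <- cy + (g$x - cx) * sin(theta) + (g$y - cy) * cos(theta)
    g <- data.frame(x = x, y = y)
  }
  tibble::tibble(x = g$x, y = g$y)
}

# Reference nuts whose pixels are noisy draws from a known palette, for
# palette-recovery tests.
palette_reference_nuts <- function(palette, n_nuts = 10, n_px = 1500,
                                   noise = 3, seed = 1) {
  set.seed(seed)
  k_all <- nrow(palette)
  tibble::tibble(
    nut_id = sprintf("ref-%d", seq_len(n_nuts)),
    pixels = lapply(seq_len(n_nuts), function(i) {
      k <- sample(seq_len(k_all), n_px, replace = TRUE)
      tibble::tibble(
        x = 0L, y = 0L,
        r = pmin(pmax(palette$r[k] + stats::rnorm(n_px, 0, noise), 0), 255),
        g = pmin(pmax(palette$g[k] + stats::rnorm(n_px, 0, noise), 0), 255),
        b = pmin(pmax(palette$b[k] + stats::rnorm(n_px, 0, noise), 0), 255)
      )
    })
  )
}
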