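# Synthetic plates, nuts and feature tables with known ground truth, so that
# every stage of the pipeline is testable without the original photographs.

#' A deterministic demonstration palette
#'
#' Eight hull-like major colours spanning the green-yellow to red range seen
#' across late pistachio development, plus a black background cluster.
#' Ordered by descending luminance like a built palette; the last usable
#' colour (deep red) is the one the generator over-expresses near the tip of
#' blank nuts.
#'
#' @return a `hull_palette` with 9 clusters.
#' @export
demo_palette <- function() {
  cent <- tibble::tribble(
    ~r, ~g, ~b,
    215, 210, 155,   # pale straw
    205, 190, 120,   # light yellow
    220, 165, 150,   # pink blush
    175, 185, 110,   # yellow-green
    150, 170, 100,   # green
    200, 120, 105,   # light red
    140, 140, 80,    # olive
    170, 60, 50,     # deep red (tip colour of blanks)
    12, 12, 12       # background black
  )
  palette_from_centroids(cent)
}

#' Pixel ensemble of a synthetic nut shape
#'
#' An axis-aligned-then-rotated filled ellipse with a tapering wedge
#' protrusion (the tip) appended on one end of the long axis. Used by the
#' plate generator and by geometry tests; the apex position is recorded so
#' tip detection can be scored against ground truth.
#'
#' @param centre length-2 centre (x, y).
#' @param a,b ellipse semi-axes in pixels (`a >= b`).
#' @param theta orientation of the long axis, radians.
#' @param prot_len protrusion length beyond the ellipse end (pixels).
#' @param prot_width half-width of the protrusion base as a fraction of `b`
#'   (default 0.45).
#' @return tibble of integer `x`, `y` pixels; attribute `apex` holds the
#'   protrusion apex (x, y).
#' @export
synth_nut_pixels <- function(centre, a = 55, b = 32, theta = 0,
                             prot_len = 14, prot_width = 0.45) {
  stopifnot(a >= b, prot_len > 0)
  u <- c(cos(theta), sin(theta))
  reach <- ceiling(a + prot_len) + 1
  gx <- seq(floor(centre[1]) - reach, ceiling(centre[1]) + reach)
  gy <- seq(floor(centre[2]) - reach, ceiling(centre[2]) + reach)
  g <- expand.grid(x = gx, y = gy)
  dx <- g$x - centre[1]; dy <- g$y - centre[2]
  s <- dx * u[1] + dy * u[2]            # along long axis
  t <- -dx * u[2] + dy * u[1]           # perpendicular
  in_ellipse <- (s / a)^2 + (t / b)^2 <= 1
  # wedge from 0.8 a to a + prot_len, width tapering linearly to 0 at the apex
  s0 <- 0.8 * a; s1 <- a + prot_len
  w <- prot_width * b * pmax(1 - (s - s0) / (s1 - s0), 0)
  in_wedge <- s >= s0 & s <= s1 & abs(t) <= w
  px <- g[in_ellipse | in_wedge, ]
  apex_xy <- round(centre + s1 * u)
  out <- tibble::tibble(x = as.integer(px$x), y = as.integer(px$y))
  attr(out, "apex") <- c(x = apex_xy[1], y = apex_xy[2])
  out
}

# Zone mixture weights over the usable colours for one nut. Radial mixture
# keyed to tip distance: zone 1 = tip-nearest third, 3 = farthest. Blank nuts
# get `blank_effect` extra weight on the designated red colour in zone 1.
.nut_mixtures <- function(n_major, red_id, blank, blank_effect) {
  base <- stats::rgamma(n_major, shape = 2)
  base <- base / sum(base)
  zones <- rbind(base, base, base)
  if (blank && blank_effect > 0) {
    zones[1, ] <- zones[1, ] * (1 - blank_effect)
    zones[1, red_id] <- zones[1, red_id] + blank_effect
    zones[2, ] <- zones[2, ] * (1 - blank_effect / 3)
    zones[2, red_id] <- zones[2, red_id] + blank_effect / 3
  }
  zones
}

#' Generate a synthetic plate with ground truth
#'
#' Renders `n_nuts` non-overlapping elliptical nuts with protruding tips on a
#' near-white plate. Nut colours are drawn per pixel from per-zone mixtures
#' over the palette's major colours, where the zones are terciles of the
#' distance to the tip apex — so the tip-closest/farthest feature contrast is
#' controllable. Blank nuts over-express the darkest red major colour near
#' the tip (`blank_effect`), emulating the red tip colouration associated
#' with kernel-less nuts. This emulates, rather than reproduces, real hull
#' colouring.
#'
#' @param n_nuts nuts on the plate (default 30, the study's plate size).
#' @param width,height canvas size in pixels.
#' @param palette a `hull_palette` (default [demo_palette()]).
#' @param seed integer seed (required; the generator is seed-deterministic).
#' @param kernel_status optional character vector of `"blank"`/`"filled"` per
#'   nut (in placement order); default all filled.
#' @param blank_effect extra near-tip weight on the red colour for blank nuts
#'   (default 0.35).
#' @param colour_noise per-channel Gaussian RGB noise SD (default 4).
#' @param background RGB of the plate background (slightly warm white by
#'   default so white balancing has work to do).
#' @param plate_id,ct metadata for the resulting `plate_image`.
#' @return list with `plate` (a `plate_image`) and `truth` — a tibble with
#'   one row per nut: `ordinal` (top-to-bottom, left-to-right centroid
#'   order), `centre_x`, `centre_y`, `theta`, `a`, `b`, `tip_x`, `tip_y`,
#'   `kernel_status`, `area_px`.
#' @export
make_plate <- function(n_nuts = 30, width = 1200, height = 900,
                       palette = demo_palette(), seed = 1,
                       kernel_status = NULL, blank_effect = 0.35,
                       colour_noise = 4, background = c(250, 248, 244),
                       plate_id = "synth", ct = "unknown") {
  set.seed(seed)
  if (is.null(kernel_status)) kernel_status <- rep("filled", n_nuts)
  stopifnot(length(kernel_status) == n_nuts)
  .assert_kernel_labels(kernel_status)

  # grid placement guarantees non-overlap; fail loudly if nuts cannot fit
  n_col <- ceiling(sqrt(n_nuts * width / height))
  n_row <- ceiling(n_nuts / n_col)
  cell_w <- (width - 40) / n_col
  cell_h <- (height - 40) / n_row
  a_max <- min(cell_w, cell_h) / 2 - 18
  if (a_max < 25) stop("cannot place ", n_nuts, " nuts without overlap on a ",
                       width, "x", height, " canvas", call. = FALSE)

  img <- array(0, dim = c(height, width, 3))
  for (c in 1:3) img[, , c] <- background[c]

  n_major <- sum(!palette$is_background)
  red_id <- max(palette$id[!palette$is_background])
  cent <- cbind(palette$r, palette$g, palette$b)

  rows <- vector("list", n_nuts)
  for (i in seq_len(n_nuts)) {
    gr <- (i - 1) %/% n_col; gc <- (i - 1) %% n_col
    cx <- 20 + (gc + 0.5) * cell_w + stats::runif(1, -8, 8)
    cy <- 20 + (gr + 0.5) * cell_h + stats::runif(1, -8, 8)
    a <- stats::runif(1, 0.75 * a_max, 0.92 * a_max)
    b <- a * stats::runif(1, 0.52, 0.62)
    theta <- stats::runif(1, -pi, pi)
    prot <- stats::runif(1, 0.28, 0.38) * a
    shape <- synth_nut_pixels(c(cx, cy), a = a, b = b, theta = theta,
                              prot_len = prot, prot_width = 0.5)
    apex <- attr(shape, "apex")
    mix <- .nut_mixtures(n_major, red_id, kernel_status[i] == "blank",
                         blank_effect)
    d_tip <- sqrt((shape$x - apex["x"])^2 + (shape$y - apex["y"])^2)
    zone <- findInterval(d_tip, stats::quantile(d_tip, c(1 / 3, 2 / 3)),
                         rightmost.closed = FALSE) + 1L
    np <- nrow(shape)
    code <- integer(np)
    for (z in 1:3) {
      sel <- zone == z
      if (any(sel)) code[sel] <- sample.int(n_major, sum(sel), replace = TRUE,
                                            prob = mix[z, ])
    }
    rgb <- cent[code, , drop = FALSE] +
      matrix(stats::rnorm(3 * np, 0, colour_noise), ncol = 3)
    rgb <- pmin(pmax(rgb, 0), 255)
    ri <- shape$y + 1L; ci <- shape$x + 1L
    for (c in 1:3) img[cbind(ri, ci, c)] <- rgb[, c]
    rows[[i]] <- tibble::tibble(
      centre_x = cx, centre_y = cy,
      centroid_x = mean(shape$x), centroid_y = mean(shape$y),
      theta = theta, a = a, b = b,
      tip_x = unname(apex["x"]), tip_y = unname(apex["y"]),
      kernel_status = kernel_status[i], area_px = np
    )
  }
  truth <- dplyr::bind_rows(rows)
  # same ordering key as segment_plate: rendered-pixel centroid, row-major
  truth <- truth[order(truth$centroid_y, truth$centroid_x), ]
  truth$ordinal <- seq_len(n_nuts)
  truth <- truth[, c("ordinal", setdiff(names(truth), "ordinal"))]
  list(plate = plate_image(img, plate_id = plate_id, ct = ct), truth = truth)
}

#' Generate a feature table with planted associations
#'
#' Builds an `n`-nut feature table in the canonical 56-column layout where
#' every region's colour proportions form a probability vector, and a chosen
#' set of features carries a planted association with kernel status: the
#' feature's value falls in a `high` range with probability `p_high_blank`
#' for blank nuts and `p_high_filled` for filled nuts, and in a `low` range
#' otherwise. All other features are exchangeable noise, independent of the
#' response.
#'
#' In addition to (or instead of) individually planted features, a *latent
#' contrast axis* can be requested: each nut gets a signed latent score
#' `u = s * |N(shift, shift_sd)|` whose sign `s` is kernel-biased (blanks
#' are positive with probability `p_pos_blank`; the filled-nut probability is
#' set so the two sign blocks are balanced) and a stage-specific set of
#' features loads on it with signs `loadings`. This emulates the dominant
#' co-varying colour contrast of a developmental stage: nuts split into two
#' tight colour blocks aligned with kernel status, and the *set* of features
#' carrying the contrast changes from stage to stage.
#'
#' @param n nuts (default 90, the per-time-point study size).
#' @param n_blank blank nuts among them (default 21, the CT3 design).
#' @param planted `NULL` for pure noise, or a list of planted specs — each a
#'   list with `feature` (column name), `p_high_blank`, `p_high_filled`, and
#'   optionally `low`, `high` (value ranges; defaults `c(0.05, 0.35)` and
#'   `c(0.55, 0.85)`).
#' @param latent `NULL`, or a list with `features` (character; at most one
#'   per region), and optionally `loadings` (signs, default alternating),
#'   `p_pos_blank` (default 0.95), `shift` (default 0.25), `shift_sd`
#'   (default 0.08), `noise` (default 0.05).
#' @param noise_sd Gaussian jitter added to planted values before clipping
#'   (default 0.02).
#' @param seed integer seed (required).
#' @param ct label stored in the `ct` column.
#' @return a feature table tibble (`nut_id`, `ct`, `kernel_status` + 56
#'   features); attributes `"planted"` and `"latent"` record the specs (the
#'   latent record includes the per-nut block sign `s`).
#' @export
make_feature_table <- function(n = 90, n_blank = 21, planted = NULL,
                               latent = NULL, noise_sd = 0.02, seed = 1,
                               ct = "synthetic") {
  set.seed(seed)
  status <- sample(c(rep("blank", n_blank), rep("filled", n - n_blank)))
  fnames <- feature_names()
  n_major <- 8L

  # per-nut, per-region Dirichlet(2) proportion vectors
  vals <- matrix(0, nrow = n, ncol = length(fnames),
                 dimnames = list(NULL, fnames))
  for (rg in .region_names) {
    w <- matrix(stats::rgamma(n * n_major, shape = 2), nrow = n)
    w <- w / rowSums(w)
    vals[, sprintf("%s_c%d", rg, seq_len(n_major))] <- w
  }

  rescale_into <- function(vals, f, v) {
    rg <- sub("_c\\d+$", "", f)
    sibs <- setdiff(sprintf("%s_c%d", rg, seq_len(n_major)), f)
    scale <- (1 - v) / rowSums(vals[, sibs, drop = FALSE])
    vals[, sibs] <- vals[, sibs] * scale
    vals[, f] <- v
    vals
  }

  s <- NULL
  if (!is.null(latent)) {
    lf <- latent$features
    if (anyDuplicated(sub("_c\\d+$", "", lf))) {
      stop("latent features must lie in distinct regions", call. = FALSE)
    }
    loadings <- latent$loadings %||% rep_len(c(1, -1), length(lf))
    p_pos_blank <- latent$p_pos_blank %||% 0.95
    shift <- latent$shift %||% 0.25
    shift_sd <- latent$shift_sd %||% 0.08
    lnoise <- latent$noise %||% 0.05
    # balance the sign blocks while keeping the kernel bias
    p_pos_filled <- max(min((n / 2 - p_pos_blank * n_blank) / (n - n_blank), 1), 0)
    p_pos <- ifelse(status == "blank", p_pos_blank, p_pos_filled)
    s <- ifelse(stats::runif(n) < p_pos, 1, -1)
    # bimodal with a guaranteed gap: |u| >= shift, so the two colour blocks
    # never blur into each other at the median cutoff
    u <- s * (shift + abs(stats::rnorm(n, 0, shift_sd)))
    for (j in seq_along(lf)) {
      v <- pmin(pmax(0.5 + loadings[j] * u + stats::rnorm(n, 0, lnoise),
                     0.01), 0.99)
      vals <- rescale_into(vals, lf[j], v)
    }
    latent$block_sign <- s
  }

  for (sp in planted) {
    f <- sp$feature
    if (!f %in% fnames) stop("unknown planted feature: ", f, call. = FALSE)
    low <- sp$low %||% c(0.05, 0.35)
    high <- sp$high %||% c(0.55, 0.85)
    p_high <- ifelse(status == "blank", sp$p_high_blank, sp$p_high_filled)
    in_high <- stats::runif(n) < p_high
    v <- ifelse(in_high, stats::runif(n, high[1], high[2]),
                stats::runif(n, low[1], low[2]))
    v <- pmin(pmax(v + stats::rnorm(n, 0, noise_sd), 0.001), 0.999)
    vals <- rescale_into(vals, f, v)
  }

  out <- tibble::as_tibble(cbind(
    tibble::tibble(nut_id = sprintf("synth-%d", seq_len(n)), ct = ct,
                   kernel_status = status),
    vals
  ))
  attr(out, "planted") <- planted
  attr(out, "latent") <- latent
  out
}
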