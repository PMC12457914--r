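# Feature-defining protocol: 7 tip-anchored regions x 8 major-colour
# proportions = 56 features per nut, variability filtering, median
# categorization, and order-2 pairing.

.region_names <- c("full",
                   "tip_closest_30", "tip_closest_50", "tip_closest_70",
                   "tip_farthest_30", "tip_farthest_50", "tip_farthest_70")

#' Canonical names of the 56 colour-proportion features
#'
#' Fixed column order: the `full` hull first, then tip-closest-30/50/70 and
#' tip-farthest-30/50/70; within each region, major colours 1..8. Here k in
#' tip-closest-k / tip-farthest-k is the percentage of the nut's
#' non-background pixels nearest to / farthest from the tip.
#'
#' @param n_colours number of major colours (default 8).
#' @return character vector of length `7 * n_colours`.
#' @export
feature_names <- function(n_colours = 8) {
  as.vector(t(outer(.region_names, seq_len(n_colours),
                    function(r, c) sprintf("%s_c%d", r, c))))
}

#' Partition pixels into tip-closest and tip-farthest sets
#'
#' Given the tip-distance ranks of the non-background pixels of a nut
#' (background excluded *before* the percentages are taken), the closest set
#' holds the `ceiling(k/100 * n)` lowest-ranked pixels and the farthest set
#' the same number of highest-ranked pixels. Because ranks are a strict
#' permutation, closest-k and farthest-(100-k) jointly cover the pixel set;
#' when both ceilings round up (k% of n not integral) the two sets share
#' exactly one boundary pixel, otherwise they are disjoint.
#'
#' @param ranks integer ranks `1..n` (from [locate_tip()], restricted to
#'   non-background pixels and re-ranked).
#' @param k percentage in (0, 100).
#' @return list with integer index vectors `closest` and `farthest`.
#' @export
region_partition <- function(ranks, k) {
  n <- length(ranks)
  if (n == 0) stop("empty pixel ensemble", call. = FALSE)
  m <- ceiling(k / 100 * n)
  list(closest = which(ranks <= m), farthest = which(ranks > n - m))
}

#' Colour proportions of a pixel subset
#'
#' Fraction of pixels classified to each of the 8 major colours, computed
#' after excluding background-classified pixels; the result is a probability
#' vector over colours 1..8 whenever at least one non-background pixel
#' remains, and a flagged zero vector otherwise.
#'
#' @param codes integer colour codes (from [classify_pixels()]).
#' @param palette the `hull_palette` the codes refer to.
#' @return named numeric vector of length 8 (attribute `all_background` set
#'   when the subset had no usable pixels).
#' @export
colour_proportions <- function(codes, palette) {
  n_major <- sum(!palette$is_background)
  keep <- codes != background_id(palette)
  codes <- codes[keep]
  out <- if (length(codes) == 0) {
    structure(numeric(n_major), all_background = TRUE)
  } else {
    tabulate(codes, n_major) / length(codes)
  }
  names(out) <- paste0("c", seq_len(n_major))
  out
}

#' 56-feature vector of one nut
#'
#' Classifies the nut's pixels against the palette, excludes background,
#' locates the tip on the full pixel ensemble, re-ranks the non-background
#' pixels by distance to the tip, and concatenates the 8 colour proportions
#' of the 7 regions in the canonical [feature_names()] order.
#'
#' @param pixels the nut's pixel tibble (`x`, `y`, `r`, `g`, `b`).
#' @param palette a `hull_palette`.
#' @param method pixel classification mode, see [classify_pixels()].
#' @return named numeric vector of length 56, each value in \[0, 1\].
#' @export
feature_vector <- function(pixels, palette, method = "centroid") {
  codes <- classify_pixels(pixels, palette, method = method)
  tip <- locate_tip(pixels)
  keep <- codes != background_id(palette)
  if (!any(keep)) stop("all pixels classified as background", call. = FALSE)
  d <- tip$pixels$distance[keep]
  codes <- codes[keep]
  rk <- integer(length(d))
  rk[order(d, seq_along(d))] <- seq_along(d)

  vecs <- vector("list", length(.region_names))
  names(vecs) <- .region_names
  vecs[["full"]] <- colour_proportions(codes, palette)
  for (k in c(30, 50, 70)) {
    part <- region_partition(rk, k)
    vecs[[sprintf("tip_closest_%d", k)]] <- colour_proportions(codes[part$closest], palette)
    vecs[[sprintf("tip_farthest_%d", k)]] <- colour_proportions(codes[part$farthest], palette)
  }
  out <- unlist(vecs)
  names(out) <- feature_names(sum(!palette$is_background))
  out
}

#' Feature table for a set of nuts
#'
#' @param nuts tibble of nut records (columns `nut_id`, `kernel_status`,
#'   optionally `ct`, and a `pixels` list-column).
#' @param palette a `hull_palette`.
#' @param method pixel classification mode.
#' @return tibble: `nut_id`, `ct`, `kernel_status`, then the 56 features.
#' @export
nut_features <- function(nuts, palette, method = "centroid") {
  fv <- purrr::map(nuts$pixels, feature_vector, palette = palette, method = method)
  tibble::as_tibble(cbind(
    tibble::tibble(
      nut_id = nuts$nut_id,
      ct = if ("ct" %in% names(nuts)) nuts$ct else NA_character_,
      kernel_status = if ("kernel_status" %in% names(nuts)) nuts$kernel_status else "unknown"
    ),
    do.call(rbind, fv)
  ))
}

#' Drop features with negligible variability
#'
#' Removes feature columns whose sample standard deviation falls below
#' `min_sd` (default 0.01) — features that are constant or nearly so, which
#' typically flag the absence of a major colour at that time point. The
#' retention pattern (region x colour) is attached as attribute `"retention"`
#' and can be laid out with [retention_report()].
#'
#' @param table a feature table.
#' @param min_sd retention threshold on the sample SD (kept when `sd >= min_sd`).
#' @return the filtered feature table.
#' @export
variability_filter <- function(table, min_sd = 0.01) {
  stopifnot(nrow(table) >= 2)
  feats <- feature_columns(table)
  sds <- vapply(table[feats], stats::sd, numeric(1))
  keep <- sds >= min_sd
  out <- table[, c(intersect(.meta_cols, names(table)), feats[keep])]
  attr(out, "retention") <- tibble::tibble(
    feature = feats, sd = unname(sds), retained = unname(keep)
  )
  out
}

#' Region-by-colour retention layout
#'
#' Pivots the retention record of [variability_filter()] into the region x
#' colour grid used to report which colour signals stay informative.
#'
#' @param filtered output of [variability_filter()].
#' @return tibble with a `region` column and one logical column per colour.
#' @export
retention_report <- function(filtered) {
  ret <- attr(filtered, "retention")
  if (is.null(ret)) stop("no retention record; run variability_filter() first", call. = FALSE)
  ret$region <- sub("_c\\d+$", "", ret$feature)
  ret$colour <- sub("^.*_c", "c", ret$feature)
  tidyr::pivot_wider(ret[, c("region", "colour", "retained")],
                     names_from = "colour", values_from = "retained")
}

#' Categorize a feature into two bins
#'
#' Splits a feature's range at a cutoff (its median by default) into binary
#' codes: 0 for values at or below the cutoff, 1 above. The equality case is
#' assigned to code 0 by convention (the split is described only as
#' smaller/larger than the median).
#'
#' @param table a feature table.
#' @param feature feature column name.
#' @param cutoff `"median"` or a numeric threshold.
#' @return list of class `categorized_feature`: `feature`, `cutoff`,
#'   `codes` (integer 0/1 per nut).
#' @export
categorize <- function(table, feature, cutoff = "median") {
  x <- table[[feature]]
  if (is.null(x)) stop("unknown feature: ", feature, call. = FALSE)
  if (length(unique(x)) < 2) {
    stop("cannot categorize '", feature, "': all values identical", call. = FALSE)
  }
  cut_val <- if (identical(cutoff, "median")) stats::median(x) else as.numeric(cutoff)
  structure(
    list(feature = feature, cutoff = cut_val, codes = as.integer(x > cut_val)),
    class = "categorized_feature"
  )
}

#' All unordered feature pairs (order-2 variables)
#'
#' The 56 single features generate `choose(56, 2) = 1540` order-2 variables;
#' each pair's categories are the joint cells of the two binary codes.
#'
#' @param features character vector of feature names (length >= 2).
#' @return tibble with columns `feature_1`, `feature_2`, one row per pair.
#' @export
pair_features <- function(features) {
  stopifnot(length(features) >= 2)
  idx <- utils::combn(length(features), 2)
  tibble::tibble(feature_1 = features[idx[1, ]], feature_2 = features[idx[2, ]])
}
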