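# Reference spectrum of major hull colours: hierarchical clustering of pooled
# RGB pixels from reference nuts, and nearest-profile pixel classification.

#' Build the major-colour palette from reference nuts
#'
#' Pools RGB pixels from a set of reference nuts (the study design uses 10
#' nuts chosen to span both kernel states and developmental stages), clusters
#' them hierarchically (Euclidean distance, Ward-D2 linkage) and cuts the tree
#' into `n_clusters` colour profiles. The cluster with the lowest centroid
#' luminance is flagged as the black background/edge cluster; the remaining
#' clusters are the usable major colours, re-indexed 1..(n_clusters-1) by
#' descending luminance so that colour codes are stable across runs. The
#' background cluster receives the last id.
#'
#' Clustering all pixels of the reference nuts is quadratic in memory, so a
#' fixed-seed subsample per nut is clustered and centroids summarise the
#' branches; a sample of branch members is retained for the nearest-member
#' classification mode.
#'
#' @param reference nut records: a tibble with a `pixels` list-column of
#'   per-nut pixel tibbles holding `r`, `g`, `b` in \[0, 255\].
#' @param n_clusters total colour profiles including background (default 9:
#'   8 major colours + black).
#' @param subsample_per_nut pixels drawn per nut before clustering
#'   (default 2000).
#' @param seed integer seed for the subsample (required for reproducibility).
#' @param member_sample_size branch members retained per cluster (default 200).
#' @return object of class `hull_palette`: a tibble with columns `id`,
#'   `r`, `g`, `b` (centroids), `luminance`, `is_background`, `size` and a
#'   `members` list-column; attributes record the reference nut ids and seed.
#' @export
build_palette <- function(reference, n_clusters = 9, subsample_per_nut = 2000,
                          seed = 1, member_sample_size = 200) {
  stopifnot(nrow(reference) >= 2, "pixels" %in% names(reference))
  set.seed(seed)
  pool <- purrr::map_dfr(reference$pixels, function(px) {
    n <- nrow(px)
    take <- if (n > subsample_per_nut) sample.int(n, subsample_per_nut) else seq_len(n)
    px[take, c("r", "g", "b")]
  })
  if (nrow(pool) < n_clusters) stop("fewer pooled pixels than clusters", call. = FALSE)
  if (nrow(dplyr::distinct(pool)) < n_clusters) {
    stop("fewer distinct colours than requested clusters", call. = FALSE)
  }
  hc <- stats::hclust(stats::dist(pool), method = "ward.D2")
  grp <- stats::cutree(hc, k = n_clusters)
  cent <- dplyr::summarise(dplyr::group_by(cbind(pool, .grp = grp), .data$.grp),
                           r = mean(.data$r), g = mean(.data$g), b = mean(.data$b),
                           size = dplyr::n(), .groups = "drop")
  cent$luminance <- .luminance(cent$r, cent$g, cent$b)
  bg <- which.min(cent$luminance)
  ord <- c(setdiff(order(cent$luminance, decreasing = TRUE), bg), bg)
  cent <- cent[ord, ]
  cent$id <- seq_len(nrow(cent))
  cent$is_background <- cent$id == nrow(cent)
  members <- lapply(cent$.grp, function(g) {
    m <- pool[grp == g, , drop = FALSE]
    if (nrow(m) > member_sample_size) m <- m[sample.int(nrow(m), member_sample_size), ]
    as.matrix(m)
  })
  out <- tibble::tibble(
    id = cent$id, r = cent$r, g = cent$g, b = cent$b,
    luminance = cent$luminance, is_background = cent$is_background,
    size = cent$size, members = members
  )
  attr(out, "reference_ids") <- reference$nut_id
  attr(out, "seed") <- seed
  class(out) <- c("hull_palette", class(out))
  out
}

#' Assemble a palette from known centroids
#'
#' Constructor used by the synthetic generator and by tests: given centroid
#' colours (last row or `is_background` marking the black cluster), orders the
#' usable colours by descending luminance and builds a valid `hull_palette`.
#'
#' @param centroids data frame or matrix with columns `r`, `g`, `b`.
#' @param background index of the background (black) row; default: the row
#'   with minimum luminance.
#' @return a `hull_palette`.
#' @export
palette_from_centroids <- function(centroids, background = NULL) {
  cent <- tibble::as_tibble(as.data.frame(centroids))[, c("r", "g", "b")]
  cent$luminance <- .luminance(cent$r, cent$g, cent$b)
  if (is.null(background)) background <- which.min(cent$luminance)
  ord <- c(setdiff(order(cent$luminance, decreasing = TRUE), background), background)
  cent <- cent[ord, ]
  cent$id <- seq_len(nrow(cent))
  cent$is_background <- cent$id == nrow(cent)
  cent$size <- NA_integer_
  cent$members <- lapply(seq_len(nrow(cent)),
                         function(i) matrix(unlist(cent[i, c("r", "g", "b")]),
                                            nrow = 1, dimnames = list(NULL, c("r", "g", "b"))))
  out <- cent[, c("id", "r", "g", "b", "luminance", "is_background", "size", "members")]
  class(out) <- c("hull_palette", class(out))
  out
}

#' Id of the background cluster
#' @param palette a `hull_palette`.
#' @return integer id of the black background cluster.
#' @export
background_id <- function(palette) palette$id[palette$is_background]

#' Classify pixels against the palette
#'
#' Assigns each pixel the id of the nearest colour profile by Euclidean
#' distance in RGB. The default compares against cluster centroids;
#' `method = "member"` compares against the stored branch-member samples
#' (nearest member wins), reflecting the view of a major colour as a branch
#' of RGB coordinates rather than a single point. Equidistant ties go to the
#' lower cluster id. Pixels assigned to the background cluster should be
#' excluded from colour-proportion features ([colour_proportions()] does so).
#'
#' @param pixels data frame with columns `r`, `g`, `b`.
#' @param palette a `hull_palette`.
#' @param method `"centroid"` (default) or `"member"`.
#' @return integer vector of cluster ids (background pixels carry
#'   [background_id()]).
#' @export
classify_pixels <- function(pixels, palette, method = c("centroid", "member")) {
  method <- match.arg(method)
  px <- cbind(pixels$r, pixels$g, pixels$b)
  if (method == "centroid") {
    cent <- cbind(palette$r, palette$g, palette$b)
    # squared distances, n x k
    d2 <- outer(rowSums(px^2), rep(1, nrow(cent))) -
      2 * px %*% t(cent) +
      outer(rep(1, nrow(px)), rowSums(cent^2))
    palette$id[max.col(-d2, ties.method = "first")]
  } else {
    all_members <- do.call(rbind, palette$members)
    owner <- rep(palette$id, vapply(palette$members, nrow, 1L))
    d2 <- outer(rowSums(px^2), rep(1, nrow(all_members))) -
      2 * px %*% t(all_members) +
      outer(rep(1, nrow(px)), rowSums(all_members^2))
    # ties to the lower cluster id: members are ordered by id
    owner[max.col(-d2, ties.method = "first")]
  }
}
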