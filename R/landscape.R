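# Topological colour landscape: binary nut x major-category membership,
# Ward-D2 dendrograms on both axes, and K-nearest-neighbour distance profiles.

#' Binary membership of nuts in major feature categories
#'
#' For each major verdict (a categorized feature — or joint feature pair —
#' and a category code), a nut is a member (1) when its own categorized code
#' equals that category, using the cutoffs recorded in the verdicts.
#'
#' @param verdicts verdict tibble from [select_major()] (only rows with
#'   `is_major = TRUE` are used).
#' @param table the feature table the verdicts were computed from (or a query
#'   table with the same feature columns).
#' @return binary matrix, rows = major categories (named
#'   `feature[:feature]=category`), columns = nut ids. Each column is the
#'   nut's individual colour landscape.
#' @export
category_membership <- function(verdicts, table) {
  maj <- verdicts[verdicts$is_major, , drop = FALSE]
  if (nrow(maj) == 0) {
    stop("zero major categories; consider a larger tau", call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(maj)), function(i) {
    c1 <- as.integer(table[[maj$feature_1[i]]] > maj$cutoff_1[i])
    code <- if (is.na(maj$feature_2[i])) {
      as.character(c1)
    } else {
      paste0(c1, as.integer(table[[maj$feature_2[i]]] > maj$cutoff_2[i]))
    }
    as.integer(code == maj$category[i])
  })
  m <- do.call(rbind, rows)
  rownames(m) <- paste0(
    ifelse(is.na(maj$feature_2), maj$feature_1,
           paste0(maj$feature_1, ":", maj$feature_2)),
    "=", maj$category
  )
  colnames(m) <- table$nut_id
  m
}

#' Build a topological colour landscape
#'
#' Assembles the binary nut x major-category matrix, clusters both axes with
#' Euclidean distance and Ward-D2 linkage, and computes each nut's K-nearest-
#' neighbour distance profile. The column dendrogram defines the
#' neighbourhood system (the "topology") on the nuts used by the growth-stage
#' algorithm.
#'
#' @param verdicts major-category verdicts ([select_major()]).
#' @param table the feature table (must carry `nut_id` and `kernel_status`).
#' @param K neighbours per nut for the distance profiles (default 10).
#' @param ct_label optional critical-time-point label for the landscape.
#' @return object of class `landscape`: list with `matrix` (categories x
#'   nuts), `row_tree`, `col_tree` (hclust, `NULL` when an axis has < 2
#'   elements), `knn` (tibble), `labels` (kernel status per nut), `ct_label`.
#' @export
build_landscape <- function(verdicts, table, K = 10, ct_label = NA_character_) {
  m <- category_membership(verdicts, table)
  row_tree <- if (nrow(m) >= 2) stats::hclust(stats::dist(m), method = "ward.D2") else NULL
  col_tree <- if (ncol(m) >= 2) stats::hclust(stats::dist(t(m)), method = "ward.D2") else NULL
  L <- structure(
    list(matrix = m, row_tree = row_tree, col_tree = col_tree,
         knn = NULL, labels = stats::setNames(table$kernel_status, table$nut_id),
         K = K, ct_label = ct_label),
    class = "landscape"
  )
  if (ncol(m) > K) L$knn <- knn_profile(L, K = K)
  L
}

#' @export
print.landscape <- function(x, ...) {
  cat(sprintf("Colour landscape%s: %d major categories x %d nuts (%d blank)\n",
              if (is.na(x$ct_label)) "" else paste0(" [", x$ct_label, "]"),
              nrow(x$matrix), ncol(x$matrix), sum(x$labels == "blank")))
  invisible(x)
}

#' K-nearest-neighbour distance profiles
#'
#' For every nut, the K smallest Euclidean distances from its binary landscape
#' column to the other nuts' columns, in ascending order (distance ties broken
#' by nut id). These ranked profiles carry the local geometric information
#' that the growth-stage algorithm compares against a query nut.
#'
#' @param landscape a `landscape` (or a bare binary matrix, categories x nuts).
#' @param K profile length (default 10; must be < number of nuts).
#' @return tibble: `nut_id`, `rank`, `neighbour_id`, `distance`.
#' @export
knn_profile <- function(landscape, K = 10) {
  m <- if (inherits(landscape, "landscape")) landscape$matrix else landscape
  n <- ncol(m)
  if (K >= n) stop("K must be smaller than the number of nuts", call. = FALSE)
  D <- as.matrix(stats::dist(t(m)))
  ids <- colnames(m)
  purrr::map_dfr(seq_len(n), function(i) {
    d <- D[i, -i]
    nb <- ids[-i]
    o <- order(d, nb)[seq_len(K)]
    tibble::tibble(nut_id = ids[i], rank = seq_len(K),
                   neighbour_id = nb[o], distance = unname(d[o]))
  })
}

#' Branch-specific blank rates at a dendrogram cut
#'
#' Cuts the landscape's column dendrogram into branches and reports each
#' branch's blank fraction and size, plus the size-weighted overall rate. The
#' weighted overall rate equals the global blank fraction at any cut (a
#' conservation identity used as a self-check).
#'
#' @param landscape a `landscape` with kernel labels.
#' @param n_branches number of branches to cut into (exclusive with `height`).
#' @param height cut height on the Ward-D2 tree.
#' @return tibble: `branch`, `size`, `n_blank`, `rate`; attribute
#'   `overall` holds the size-weighted mean rate.
#' @export
branch_blank_rates <- function(landscape, n_branches = NULL, height = NULL) {
  stopifnot(inherits(landscape, "landscape"))
  if (is.null(landscape$col_tree)) stop("landscape has no column tree", call. = FALSE)
  if (is.null(n_branches) && is.null(height)) n_branches <- 2
  grp <- if (!is.null(n_branches)) {
    stats::cutree(landscape$col_tree, k = n_branches)
  } else {
    stats::cutree(landscape$col_tree, h = height)
  }
  blank <- landscape$labels[names(grp)] == "blank"
  out <- tibble::tibble(branch = as.integer(names(table(grp))),
                        size = as.integer(table(grp)),
                        n_blank = as.integer(tapply(blank, grp, sum)),
                        rate = as.numeric(tapply(blank, grp, mean)))
  if (all(out$size == 1)) warning("cut produced only singleton branches")
  attr(out, "overall") <- sum(out$size / sum(out$size) * out$rate)
  attr(out, "membership") <- grp
  out
}
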