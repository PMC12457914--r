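# Broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a contingency table
#'
#' One row per feature category with its counts, conditional natural-log
#' entropy and blank odds.
#'
#' @param x a `ceda_table`.
#' @param ... unused.
#' @return tibble: `category`, `blank`, `filled`, `row_sum`, `entropy`,
#'   `odds`.
#' @export
tidy.ceda_table <- function(x, ...) {
  tibble::tibble(
    category = rownames(x$counts),
    blank = unname(x$counts[, 1]), filled = unname(x$counts[, 2]),
    row_sum = unname(rowSums(x$counts)),
    entropy = unname(x$row_entropy), odds = unname(x$row_odds)
  )
}

#' Glance at a contingency table
#'
#' @param x a `ceda_table`.
#' @param ... unused.
#' @return one-row tibble with the totals and the baseline (column-sum)
#'   entropy and odds.
#' @export
glance.ceda_table <- function(x, ...) {
  cs <- unname(colSums(x$counts))
  tibble::tibble(
    n = sum(cs), n_blank = cs[[1]], n_filled = cs[[2]],
    n_categories = nrow(x$counts),
    baseline_entropy = x$baseline_entropy, baseline_odds = x$baseline_odds
  )
}

#' Tidy a colour landscape
#'
#' @param x a `landscape`.
#' @param ... unused.
#' @return long tibble: `category`, `nut_id`, `member` (0/1),
#'   `kernel_status`.
#' @export
tidy.landscape <- function(x, ...) {
  m <- x$matrix
  tibble::tibble(
    category = rep(rownames(m), times = ncol(m)),
    nut_id = rep(colnames(m), each = nrow(m)),
    member = as.integer(m),
    kernel_status = rep(unname(x$labels[colnames(m)]), each = nrow(m))
  )
}

#' Glance at a colour landscape
#'
#' @param x a `landscape`.
#' @param ... unused.
#' @return one-row tibble: category and nut counts, blank count, matrix fill.
#' @export
glance.landscape <- function(x, ...) {
  tibble::tibble(
    ct_label = x$ct_label,
    n_categories = nrow(x$matrix), n_nuts = ncol(x$matrix),
    n_blank = sum(x$labels == "blank"),
    fill = mean(x$matrix)
  )
}

#' Heatmap of a colour landscape
#'
#' Block heatmap of the binary nut x category matrix with both axes ordered
#' by their Ward-D2 dendrograms, nuts annotated by kernel status along the
#' x axis, mirroring the block-structured heatmaps used to read branch
#' composition.
#'
#' @param object a `landscape`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.landscape <- function(object, ...) {
  d <- tidy(object)
  # mark blank nuts in the axis labels ("id *") so branch composition can be
  # read off the reordered columns
  lab_of <- function(id) ifelse(object$labels[id] == "blank",
                                paste0(id, " *"), id)
  d$nut_id <- lab_of(d$nut_id)
  if (!is.null(object$col_tree)) {
    d$nut_id <- factor(d$nut_id,
                       levels = lab_of(object$col_tree$labels[object$col_tree$order]))
  }
  if (!is.null(object$row_tree)) {
    d$category <- factor(d$category, levels = object$row_tree$labels[object$row_tree$order])
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$nut_id, y = .data$category,
                                  fill = factor(.data$member))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(`0` = "grey95", `1` = "grey15"),
                               name = "member") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(
      angle = 90, vjust = 0.5, hjust = 1, size = 6)) +
    ggplot2::labs(x = "nut (* = blank kernel)", y = "major feature category")
}

#' Alternative-vs-null distributions behind a verdict
#'
#' Overlaid histograms of the row statistic under the alternative and null
#' ensembles; the shared area is the overlap reported in the verdict. Needs
#' `keep_samples = TRUE` in [assess_category()].
#'
#' @param object a `ceda_verdict` carrying samples.
#' @param bins histogram bins (cosmetic; the verdict's overlap uses its own
#'   shared grid).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.ceda_verdict <- function(object, bins = 50, ...) {
  s <- attr(object, "samples")
  if (is.null(s)) stop("no samples stored; rerun assess_category(keep_samples = TRUE)",
                       call. = FALSE)
  s <- s[is.finite(s$value), ]
  ggplot2::ggplot(s, ggplot2::aes(x = .data$value, fill = .data$ensemble)) +
    ggplot2::geom_histogram(alpha = 0.55, position = "identity", bins = bins) +
    ggplot2::labs(
      title = sprintf("category %s: overlap %.4f (%s)",
                      object$category, object$overlap, object$statistic),
      x = object$statistic, y = "count") +
    ggplot2::theme_minimal()
}

#' Ranked K-nearest-neighbour distance profiles
#'
#' One line per nut: its K ranked distances within the landscape, blank nuts
#' highlighted. Tight, low profiles indicate nuts deep inside dense branches.
#'
#' @param landscape a `landscape` with a `knn` profile table.
#' @return a ggplot object.
#' @export
plot_knn_profiles <- function(landscape) {
  stopifnot(inherits(landscape, "landscape"))
  if (is.null(landscape$knn)) stop("landscape has no knn profiles", call. = FALSE)
  d <- landscape$knn
  d$kernel_status <- unname(landscape$labels[d$nut_id])
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rank, y = .data$distance,
                                  group = .data$nut_id,
                                  colour = .data$kernel_status)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::scale_colour_manual(values = c(blank = "firebrick", filled = "grey40")) +
    ggplot2::labs(x = "neighbour rank", y = "Euclidean distance") +
    ggplot2::theme_minimal()
}
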