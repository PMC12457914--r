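# Categorical exploratory data analysis (CEDA) core: contingency tables of
# categorized colour features against kernel status, row entropies and odds,
# alternative/null multinomial ensembles, and overlap-area screening of
# feature categories.

#' Cross-tabulate a categorized feature against kernel status
#'
#' Builds the 2-column contingency table of a categorized feature versus the
#' binary kernel response (blank vs filled), together with per-row natural-log
#' entropies and blank odds and the baseline (column-sum) statistics. The
#' association of a feature category with kernel status is read row by row:
#' a row whose conditional blank/filled distribution departs from the
#' column-sum (marginal) distribution carries associative information.
#'
#' @param category per-nut category codes (character or integer; e.g. the
#'   `codes` of [categorize()], or joint codes for feature pairs).
#' @param labels per-nut kernel status, `"blank"` or `"filled"`, aligned with
#'   `category`.
#' @return an object of class `ceda_table`: a list with `counts` (rows =
#'   categories, columns = blank/filled), `row_entropy`, `row_odds`,
#'   `baseline_entropy`, `baseline_odds`. Use [tidy()][tidy.ceda_table] for a
#'   tibble view.
#' @seealso [row_entropy()], [row_odds()], [assess_category()]
#' @export
make_table <- function(category, labels) {
  .assert_kernel_labels(labels)
  stopifnot(length(category) == length(labels))
  lab <- factor(labels, levels = c("blank", "filled"))
  counts <- table(factor(category), lab)
  counts <- matrix(as.integer(counts), nrow = nrow(counts),
                   dimnames = list(rownames(counts), c("blank", "filled")))
  as_ceda_table(counts)
}

#' Construct a `ceda_table` from a printed counts matrix
#'
#' @param counts integer matrix with columns `(blank, filled)`; rows are
#'   feature categories. Useful for re-analysing published tables.
#' @return a `ceda_table`; see [make_table()].
#' @export
as_ceda_table <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(ncol(counts) == 2, all(counts >= 0), all(counts == round(counts)))
  colnames(counts) <- c("blank", "filled")
  if (is.null(rownames(counts))) rownames(counts) <- as.character(seq_len(nrow(counts)) - 1L)
  structure(
    list(
      counts = counts,
      row_entropy = apply(counts, 1, row_entropy),
      row_odds = apply(counts, 1, row_odds),
      baseline_entropy = row_entropy(colSums(counts)),
      baseline_odds = row_odds(colSums(counts))
    ),
    class = "ceda_table"
  )
}

#' @export
print.ceda_table <- function(x, ...) {
  cat("Contingency table (feature category x kernel status)\n")
  m <- cbind(x$counts, row_sum = rowSums(x$counts),
             entropy = round(x$row_entropy, 5), odds = round(x$row_odds, 5))
  print(m)
  cat(sprintf("col-sums: %d %d | baseline entropy %.5f, baseline odds %.5f\n",
              colSums(x$counts)[1], colSums(x$counts)[2],
              x$baseline_entropy, x$baseline_odds))
  invisible(x)
}

#' Natural-log Shannon entropy of a contingency-table row
#'
#' Entropy (in nats) of the conditional blank/filled distribution of a row,
#' with the convention `0 * log(0) = 0`. For two columns the value lies in
#' `[0, log(2)]`.
#'
#' @param counts non-negative numeric vector of counts with positive sum.
#' @return entropy in nats.
#' @examples
#' row_entropy(c(9, 35))   # 0.50664
#' row_entropy(c(0, 46))   # 0
#' @export
row_entropy <- function(counts) {
  s <- sum(counts)
  if (s <= 0) stop("row sum must be positive", call. = FALSE)
  p <- counts / s
  p <- p[p > 0]
  -sum(p * log(p))
}

# Entropy with the zero-row convention used inside simulated ensembles:
# an empty simulated row carries no distribution, score 0.
.entropy0 <- function(b, f) {
  s <- b + f
  out <- numeric(length(s))
  ok <- s > 0
  pb <- b[ok] / s[ok]
  pf <- f[ok] / s[ok]
  tb <- ifelse(pb > 0, pb * log(pb), 0)
  tf <- ifelse(pf > 0, pf * log(pf), 0)
  out[ok] <- -(tb + tf)
  out
}

#' Blank odds of a contingency-table row
#'
#' The ratio `blank / filled` for a row (or for the column sums, giving the
#' marginal odds of blank). A zero filled count yields `Inf`, which downstream
#' overlap computations route to a dedicated overflow bin.
#'
#' @param counts length-2 vector `(blank, filled)` with positive sum.
#' @return non-negative real, possibly `Inf`.
#' @examples
#' row_odds(c(19, 26))  # 0.73077
#' row_odds(c(21, 69))  # 0.30435 (marginal)
#' @export
row_odds <- function(counts) {
  if (sum(counts) <= 0) stop("row sum must be positive", call. = FALSE)
  if (counts[2] == 0) return(Inf)
  unname(counts[1] / counts[2])
}

.odds0 <- function(b, f) {
  out <- b / f            # Inf when f == 0, NaN when 0/0
  out
}

#' Simulate alternative and null contingency-table ensembles
#'
#' Column-wise multinomial resampling of an observed contingency table. In the
#' *alternative* ensemble each column (blank; filled) is redrawn as a
#' multinomial with its observed total and its observed within-column row
#' proportions, capturing the sampling variability of the observed pattern.
#' In the *null* ensemble each column is redrawn with the marginal row
#' proportions (row sums / total), enforcing independence between feature
#' category and kernel status. Both ensembles preserve the observed column
#' sums exactly.
#'
#' @param table a `ceda_table`.
#' @param M number of simulated tables per ensemble (default 1000).
#' @param seed integer seed; `NULL` leaves the RNG stream untouched (used when
#'   a caller manages one stream across many tables).
#' @return list with elements `alternative` and `null`, each an
#'   `nrow x 2 x M` array of counts, plus `M` and `seed`.
#' @export
simulate_ensembles <- function(table, M = 1000, seed = NULL) {
  stopifnot(inherits(table, "ceda_table"))
  counts <- table$counts
  if (nrow(counts) < 2) stop("need at least 2 rows to simulate", call. = FALSE)
  cs <- colSums(counts)
  if (any(cs == 0)) stop("both column sums must be positive", call. = FALSE)
  if (M < 1) stop("M must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  draw <- function(probs) {
    arr <- array(0L, dim = c(nrow(counts), 2, M),
                 dimnames = list(rownames(counts), c("blank", "filled"), NULL))
    for (j in 1:2) arr[, j, ] <- stats::rmultinom(M, size = cs[j], prob = probs[, j])
    arr
  }
  p_alt <- sweep(counts, 2, cs, "/")
  p_null <- matrix(rep(rowSums(counts) / sum(counts), 2), ncol = 2)
  list(alternative = draw(p_alt), null = draw(p_null), M = M, seed = seed)
}

# Row statistic (entropy in nats or blank odds) across one simulated ensemble.
.ensemble_row_stat <- function(arr, row, statistic = c("odds", "entropy")) {
  statistic <- match.arg(statistic)
  b <- arr[row, 1, ]
  f <- arr[row, 2, ]
  if (statistic == "entropy") .entropy0(b, f) else .odds0(b, f)
}

#' Overlap area of two empirical distributions
#'
#' Histograms both samples on a shared equal-width grid spanning their joint
#' finite range and returns the intersection mass
#' `sum_b min(freq_a[b], freq_b[b])`, with each sample's frequencies
#' normalized to 1. Non-finite values (infinite odds from zero filled counts)
#' are routed to a common overflow bin. The overlap is interpreted as the
#' minimum sum of Type-I and Type-II errors of deciding between the two
#' distributions: identical samples give 1, disjoint supports give 0.
#'
#' @param sample_a,sample_b numeric vectors (nonempty).
#' @param bins number of shared equal-width bins (default 50).
#' @return overlap in `[0, 1]`.
#' @export
overlap_area <- function(sample_a, sample_b, bins = 50) {
  stopifnot(length(sample_a) > 0, length(sample_b) > 0, bins >= 1)
  fin_a <- sample_a[is.finite(sample_a)]
  fin_b <- sample_b[is.finite(sample_b)]
  over_a <- 1 - length(fin_a) / length(sample_a)
  over_b <- 1 - length(fin_b) / length(sample_b)
  overlap <- min(over_a, over_b)          # shared overflow bin
  if (length(fin_a) == 0 || length(fin_b) == 0) return(overlap)
  lo <- min(fin_a, fin_b)
  hi <- max(fin_a, fin_b)
  if (hi == lo) {
    # single shared point mass
    return(overlap + min(length(fin_a) / length(sample_a),
                         length(fin_b) / length(sample_b)))
  }
  idx <- function(x) pmin(pmax(ceiling((x - lo) / (hi - lo) * bins), 1L), bins)
  fa <- tabulate(idx(fin_a), bins) / length(sample_a)
  fb <- tabulate(idx(fin_b), bins) / length(sample_b)
  overlap + sum(pmin(fa, fb))
}

#' Ensemble-based significance of one feature category
#'
#' Simulates the alternative and null ensembles of a contingency table,
#' computes the chosen row statistic (blank odds by default; entropy
#' retained as an alternative) across each ensemble, and measures the overlap
#' of the two distributions. The category is declared *major* when the
#' overlap — the minimum sum of Type-I and Type-II errors — does not exceed
#' the threshold `tau`.
#'
#' @param table a `ceda_table`.
#' @param row row index or row name of the category under assessment.
#' @param statistic `"odds"` (default) or `"entropy"`.
#' @param M ensemble size (default 1000).
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @param tau overlap threshold for declaring the category major (default 0.1).
#' @param bins shared histogram bins for the overlap (default 50).
#' @param keep_samples keep the simulated statistic samples (for plotting
#'   with [autoplot.ceda_verdict()]).
#' @return one-row tibble of class `ceda_verdict`: category, statistic,
#'   `overlap`, `tau`, `is_major`, `M`.
#' @export
assess_category <- function(table, row, statistic = c("odds", "entropy"),
                            M = 1000, seed = NULL, tau = 0.1, bins = 50,
                            keep_samples = FALSE) {
  statistic <- match.arg(statistic)
  ens <- simulate_ensembles(table, M = M, seed = seed)
  if (is.character(row)) row <- match(row, rownames(table$counts))
  a <- .ensemble_row_stat(ens$alternative, row, statistic)
  n <- .ensemble_row_stat(ens$null, row, statistic)
  ov <- overlap_area(a, n, bins = bins)
  out <- tibble::tibble(
    category = rownames(table$counts)[row],
    statistic = statistic,
    overlap = ov,
    tau = tau,
    is_major = ov <= tau,
    M = M
  )
  if (keep_samples) {
    attr(out, "samples") <- tibble::tibble(
      ensemble = rep(c("alternative", "null"), each = M),
      value = c(a, n)
    )
  }
  class(out) <- c("ceda_verdict", class(out))
  out
}

#' Screen all feature categories of a feature table
#'
#' The selection pipeline: every retained feature (order 1) or feature pair
#' (order 2) is categorized — binary median split by default for single
#' features, joint cells of the two binary codes for pairs — cross-tabulated
#' against kernel status, and every non-empty category row is assessed with
#' [assess_category()]. One RNG stream seeded once drives all ensembles, so
#' the whole selection is reproducible bit-for-bit from `seed`.
#'
#' @param table a feature table (after [variability_filter()]), with a
#'   `kernel_status` column.
#' @param order 1 for single-feature categories, 2 for all unordered feature
#'   pairs (joint 2x2 cells).
#' @param statistic,M,tau,bins passed to [assess_category()].
#' @param seed integer seed for the single stream (required).
#' @param cutoff `"median"` or a named numeric vector of per-feature cutoffs.
#' @return tibble of verdicts with columns `feature_1`, `feature_2`,
#'   `cutoff_1`, `cutoff_2`, `category`, `blank`, `filled`, `statistic`,
#'   `overlap`, `tau`, `is_major`, `M`.
#' @export
select_major <- function(table, order = 1, statistic = c("odds", "entropy"),
                         M = 1000, seed = 1, tau = 0.1, bins = 50,
                         cutoff = "median") {
  statistic <- match.arg(statistic)
  stopifnot(order %in% c(1, 2), "kernel_status" %in% names(table))
  feats <- feature_columns(table)
  labels <- table$kernel_status
  set.seed(seed)

  cut_of <- function(f) {
    if (identical(cutoff, "median")) stats::median(table[[f]]) else cutoff[[f]]
  }
  cats <- lapply(feats, function(f) categorize(table, f, cutoff = cut_of(f)))
  names(cats) <- feats

  assess_rows <- function(category, f1, f2, c1, c2) {
    tab <- make_table(category, labels)
    keep <- rowSums(tab$counts) > 0
    purrr::map_dfr(which(keep), function(r) {
      v <- assess_category(tab, r, statistic = statistic, M = M, seed = NULL,
                           tau = tau, bins = bins)
      tibble::tibble(
        feature_1 = f1, feature_2 = f2, cutoff_1 = c1, cutoff_2 = c2,
        category = v$category,
        blank = tab$counts[r, 1], filled = tab$counts[r, 2],
        statistic = v$statistic, overlap = v$overlap, tau = v$tau,
        is_major = v$is_major, M = v$M
      )
    })
  }

  if (order == 1) {
    out <- purrr::map_dfr(feats, function(f) {
      cf <- cats[[f]]
      assess_rows(as.character(cf$codes), f, NA_character_, cf$cutoff, NA_real_)
    })
  } else {
    pairs <- pair_features(feats)
    out <- purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
      f1 <- pairs$feature_1[i]; f2 <- pairs$feature_2[i]
      joint <- paste0(cats[[f1]]$codes, cats[[f2]]$codes)
      assess_rows(joint, f1, f2, cats[[f1]]$cutoff, cats[[f2]]$cutoff)
    })
  }
  out
}
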