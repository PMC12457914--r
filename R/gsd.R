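# Growth-stage determining (GSD) algorithm: nearest-candidate-neighbour
# admission votes per critical time point, the OddsG triplet, stage
# classification, and the blank-prevalence protocol.

# Per-reference neighbourhood system: each reference nut's K nearest
# neighbours and its radius (K-th NN distance).
.reference_neighbourhoods <- function(landscape, K) {
  m <- landscape$matrix
  ids <- colnames(m)
  D <- as.matrix(stats::dist(t(m)))
  nbhd <- lapply(seq_along(ids), function(i) {
    d <- D[i, -i]
    nb <- ids[-i]
    o <- order(d, nb)[seq_len(K)]
    list(members = nb[o], radius = d[o][K])
  })
  names(nbhd) <- ids
  nbhd
}

#' K nearest candidate neighbours of a query nut
#'
#' Projects nothing: the query vector must already live in the landscape's
#' category space (see [category_membership()] applied to the query's feature
#' table with the landscape's verdicts). Returns the K reference nuts closest
#' in Euclidean distance, ascending, ties broken by nut id.
#'
#' @param x binary query vector (length = number of landscape categories).
#' @param landscape a `landscape`.
#' @param K number of candidates (default 10).
#' @return tibble: `rank`, `nut_id`, `distance`.
#' @export
candidate_neighbours <- function(x, landscape, K = 10) {
  m <- landscape$matrix
  if (length(x) != nrow(m)) {
    stop("query vector length ", length(x), " does not match the landscape's ",
         nrow(m), " categories", call. = FALSE)
  }
  d <- sqrt(colSums((m - x)^2))
  o <- order(d, colnames(m))[seq_len(min(K, ncol(m)))]
  tibble::tibble(rank = seq_along(o), nut_id = colnames(m)[o],
                 distance = unname(d[o]))
}

#' Neighbourhood-support score (OddsG) of a query at one time point
#'
#' Each of the query's K nearest candidate neighbours casts a vote when it
#' would *admit* the query into its own neighbourhood: the query's distance to
#' the candidate must not exceed the candidate's K-th nearest-neighbour
#' distance (its neighbourhood radius). With zero votes the query lies outside
#' the landscape's topology and OddsG is 0; otherwise OddsG is the maximum,
#' over admitting candidates z, of `|N[z] intersect CandiG| / K` — how fully an
#' admitting candidate's own neighbourhood is shared with the query's
#' candidate set.
#'
#' @inheritParams candidate_neighbours
#' @return the OddsG score in \[0, 1\], with attributes `votes` (admitting
#'   candidates) and `candidates` (the [candidate_neighbours()] tibble).
#' @export
odds_g <- function(x, landscape, K = 10) {
  candi <- candidate_neighbours(x, landscape, K)
  nbhd <- .reference_neighbourhoods(landscape, K)
  admits <- vapply(seq_len(nrow(candi)), function(k) {
    candi$distance[k] <= nbhd[[candi$nut_id[k]]]$radius
  }, logical(1))
  score <- 0
  if (any(admits)) {
    score <- max(vapply(candi$nut_id[admits], function(z) {
      length(intersect(nbhd[[z]]$members, candi$nut_id)) / K
    }, numeric(1)))
  }
  structure(score, votes = sum(admits), candidates = candi)
}

#' Admission votes from printed neighbour-distance profiles
#'
#' The tabular form of the vote test: given each candidate's ranked
#' nearest-neighbour distances (columns) and the query's distance to each
#' candidate, a candidate votes for the query when the query's distance does
#' not exceed the candidate's K-th (largest listed) neighbour distance. Zero
#' votes mean the query is an outlier with respect to this landscape and its
#' OddsG score is 0; with votes present the score additionally needs the full
#' neighbourhood system (use [odds_g()]), so it is reported as `NA`.
#'
#' @param nn_distances K x K numeric matrix; column k holds candidate k's K
#'   ranked nearest-neighbour distances.
#' @param query_distances length-K vector of the query's distances to the K
#'   candidates.
#' @return list with `votes` (integer) and `odds_g` (0 when `votes == 0`,
#'   otherwise `NA`).
#' @export
admission_votes <- function(nn_distances, query_distances) {
  nn_distances <- as.matrix(nn_distances)
  stopifnot(ncol(nn_distances) == length(query_distances))
  radius <- apply(nn_distances, 2, max)
  votes <- sum(query_distances <= radius)
  list(votes = as.integer(votes),
       odds_g = if (votes == 0) 0 else NA_real_)
}

.stage_levels <- c("before-CT1", "at-CT1", "between-CT1-CT2",
                   "at-CT2", "between-CT2-CT3", "at-CT3")

#' Classify a growth stage from an OddsG triplet
#'
#' Matches `(OddsG1, OddsG2, OddsG3)` against the six stage patterns:
#' `(0,0,0)` before-CT1, `(1,0,0)` at-CT1, `(d,1-d,0)` between CT1 and CT2,
#' `(0,1,0)` at-CT2, `(0,d,1-d)` between CT2 and CT3, `(0,0,1)` at-CT3. The
#' two transitional patterns are treated as segments with the mixing fraction
#' d restricted to `[tol, 1-tol]`; the triplet is assigned the pattern at
#' minimum Euclidean distance. The tolerance also drives the discrete 0/1/d
#' coding used to flag ambiguity (two or more patterns matching equally).
#'
#' @param triplet numeric length-3 vector in \[0, 1\]^3.
#' @param tol tolerance for treating a score as 0 (<= tol) or 1 (>= 1 - tol);
#'   default 0.2.
#' @return one-row tibble: `stage` (factor over the six stages), `ambiguous`,
#'   `distance` (to the matched pattern).
#' @export
classify_stage <- function(triplet, tol = 0.2) {
  stopifnot(length(triplet) == 3, all(triplet >= 0), all(triplet <= 1))
  g <- as.numeric(triplet)
  seg_dist <- function(a, b, lo = tol, hi = 1 - tol) {
    # distance from g to {pattern(t) : t in [lo, hi]} where the pattern puts
    # t in slot a, (1 - t) in slot b and 0 elsewhere
    t_star <- (g[a] - g[b] + 1) / 2
    t_star <- min(max(t_star, lo), hi)
    p <- c(0, 0, 0); p[a] <- t_star; p[b] <- 1 - t_star
    sqrt(sum((g - p)^2))
  }
  point_dist <- function(p) sqrt(sum((g - p)^2))
  d <- c(
    point_dist(c(0, 0, 0)),
    point_dist(c(1, 0, 0)),
    seg_dist(1, 2),
    point_dist(c(0, 1, 0)),
    seg_dist(2, 3),
    point_dist(c(0, 0, 1))
  )
  best <- which(d <= min(d) + 1e-9)
  tibble::tibble(
    stage = factor(.stage_levels[best[1]], levels = .stage_levels),
    ambiguous = length(best) > 1,
    distance = min(d)
  )
}

#' Stage a batch of query nuts
#'
#' Computes each query nut's OddsG triplet against the three critical-time-
#' point landscapes, classifies each nut's stage, and returns the batch stage
#' as the majority vote together with the vote distribution.
#'
#' @param queries list of three binary matrices (categories x nuts), the
#'   queries' colour-landscape vectors in each landscape's category space, in
#'   CT1, CT2, CT3 order; all three must share column (nut) ids.
#' @param landscapes list of the three `landscape` objects (CT1, CT2, CT3).
#' @param K candidates / neighbourhood size (default 10).
#' @param tol stage-pattern tolerance (default 0.2).
#' @return list of class `gsd_batch`: `nuts` (per-nut tibble with the triplet,
#'   stage, ambiguity), `batch_stage`, `votes` (stage counts).
#' @export
batch_stage <- function(queries, landscapes, K = 10, tol = 0.2) {
  stopifnot(length(queries) == 3, length(landscapes) == 3)
  ids <- colnames(queries[[1]])
  if (length(ids) == 0) stop("empty batch", call. = FALSE)
  trip <- vapply(seq_along(ids), function(i) {
    vapply(1:3, function(ct) {
      as.numeric(odds_g(queries[[ct]][, i], landscapes[[ct]], K = K))
    }, numeric(1))
  }, numeric(3))
  st <- purrr::map_dfr(seq_along(ids), function(i) classify_stage(trip[, i], tol = tol))
  nuts <- tibble::tibble(
    nut_id = ids,
    odds_g1 = trip[1, ], odds_g2 = trip[2, ], odds_g3 = trip[3, ],
    stage = st$stage, ambiguous = st$ambiguous
  )
  votes <- table(nuts$stage)
  structure(
    list(nuts = nuts,
         batch_stage = names(votes)[which.max(votes)],
         votes = tibble::tibble(stage = names(votes), n = as.integer(votes))),
    class = "gsd_batch"
  )
}

#' @export
print.gsd_batch <- function(x, ...) {
  cat("GSD batch of", nrow(x$nuts), "nuts; batch stage:", x$batch_stage, "\n")
  print(x$votes)
  invisible(x)
}

#' Blank-prevalence protocol
#'
#' Annotates each query nut with the branch-specific blank rate of its nearest
#' *admitting* reference neighbour (a candidate that would take the query into
#' its own K-neighbourhood), at a chosen cut of the landscape's column
#' dendrogram. Queries admitted by no candidate are flagged as outliers and
#' excluded from the estimate. The returned estimate is the mean of the
#' annotated rates — each query weighted equally, so branches are weighted by
#' how many queries they attract.
#'
#' @param queries binary matrix (categories x query nuts) in the landscape's
#'   category space.
#' @param landscape the reference `landscape` (kernel labels required).
#' @param K neighbourhood size (default 10).
#' @param n_branches,height dendrogram cut, see [branch_blank_rates()].
#' @return list of class `blank_prevalence`: `annotations` (tibble: `nut_id`,
#'   `neighbour_id`, `branch`, `rate`, `outlier`), `estimate` (mean annotated
#'   rate), `histogram` (rate counts), `branch_rates`.
#' @export
blank_prevalence <- function(queries, landscape, K = 10,
                             n_branches = NULL, height = NULL) {
  rates <- branch_blank_rates(landscape, n_branches = n_branches, height = height)
  grp <- attr(rates, "membership")
  nbhd <- .reference_neighbourhoods(landscape, K)
  ann <- purrr::map_dfr(seq_len(ncol(queries)), function(i) {
    candi <- candidate_neighbours(queries[, i], landscape, K)
    admits <- vapply(seq_len(nrow(candi)), function(k) {
      candi$distance[k] <= nbhd[[candi$nut_id[k]]]$radius
    }, logical(1))
    if (!any(admits)) {
      return(tibble::tibble(nut_id = colnames(queries)[i],
                            neighbour_id = NA_character_,
                            branch = NA_integer_, rate = NA_real_,
                            outlier = TRUE))
    }
    z <- candi$nut_id[which(admits)[1]]   # nearest admitting neighbour
    b <- grp[[z]]
    tibble::tibble(nut_id = colnames(queries)[i], neighbour_id = z,
                   branch = as.integer(b),
                   rate = rates$rate[rates$branch == b],
                   outlier = FALSE)
  })
  kept <- ann$rate[!ann$outlier]
  structure(
    list(annotations = ann,
         estimate = if (length(kept)) mean(kept) else NA_real_,
         histogram = if (length(kept)) table(round(kept, 6)) else table(numeric(0)),
         branch_rates = rates,
         n_outliers = sum(ann$outlier)),
    class = "blank_prevalence"
  )
}

#' @export
print.blank_prevalence <- function(x, ...) {
  cat(sprintf("Blank prevalence estimate: %.4f (%d annotated, %d outliers)\n",
              x$estimate, sum(!x$annotations$outlier), x$n_outliers))
  invisible(x)
}
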