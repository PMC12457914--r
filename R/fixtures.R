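# Published worked-example tables shipped as plain-text fixtures: the four
# printed contingency tables of categorized colour features vs kernel status
# (one per worked example across the three critical time points) and the
# nearest-neighbour distance table of the growth-stage worked example.

#' Printed contingency-table fixtures
#'
#' The four published 2x2 contingency tables of categorized hull-colour
#' features against kernel status: `T2` (CT1, tip-closest-50 colour 8,
#' median split), `T3` (CT1, tip-closest-70 colour 8), `T4` (CT2,
#' tip-closest-30 colour 1) and `T5` (CT3, full-hull colour 1, median split).
#' Column sums are the per-time-point response margins: 9/81 blank/filled at
#' CT1, 10/80 at CT2, 21/69 at CT3.
#'
#' @return named list of 2x2 integer matrices (rows: categories `0`, `1`;
#'   columns: `blank`, `filled`). Pass one to [as_ceda_table()] to attach
#'   entropies and odds.
#' @examples
#' as_ceda_table(ct_fixtures()$T5)
#' @export
ct_fixtures <- function() {
  path <- system.file("extdata", "contingency_tables.csv", package = "hullscape")
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- lapply(split(d, d$table), function(t) {
    m <- as.matrix(t[, c("blank", "filled")])
    rownames(m) <- as.character(t$category)
    storage.mode(m) <- "integer"
    m
  })
  out[c("T2", "T3", "T4", "T5")]
}

#' Printed nearest-neighbour profile fixture
#'
#' The growth-stage worked example: a CT2 nut queried against the CT3 colour
#' landscape. Ten candidate neighbours (columns) each list their own 10
#' ranked nearest-neighbour distances; the `query` row gives the query nut's
#' distance to each candidate. Every query distance exceeds every candidate's
#' 10th-neighbour distance, so the query collects zero admission votes — it
#' is an outlier with respect to the CT3 landscape and its OddsG score is 0
#' (see [admission_votes()]).
#'
#' @return list with `nn` (10x10 numeric matrix, rows = neighbour rank,
#'   columns = candidate ids) and `query` (named length-10 vector of the
#'   query's candidate distances).
#' @examples
#' fx <- nn_fixture()
#' admission_votes(fx$nn, fx$query)
#' @export
nn_fixture <- function() {
  path <- system.file("extdata", "nn_profiles_table6.csv", package = "hullscape")
  d <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1])
  rownames(m) <- d$row
  list(nn = m[rownames(m) != "query", , drop = FALSE],
       query = m["query", ])
}
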