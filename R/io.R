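# Serialization of the reference palette (JSON) and of colour landscapes
# (TSV matrix, Newick dendrograms, K-NN profile table).

#' Write a palette to JSON
#'
#' Serializes centroids, luminances, background flag, the stored branch
#' member samples and the build provenance (reference nut ids, subsample
#' seed) so a palette can be rebuilt bit-identically elsewhere.
#'
#' @param palette a `hull_palette`.
#' @param path output JSON path.
#' @export
write_palette <- function(palette, path) {
  obj <- list(
    clusters = lapply(seq_len(nrow(palette)), function(i) list(
      id = palette$id[i],
      centroid = c(palette$r[i], palette$g[i], palette$b[i]),
      luminance = palette$luminance[i],
      is_background = palette$is_background[i],
      size = palette$size[i],
      members = palette$members[[i]]
    )),
    reference_ids = attr(palette, "reference_ids"),
    seed = attr(palette, "seed")
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a palette from JSON
#'
#' @param path JSON path written by [write_palette()].
#' @return a `hull_palette`.
#' @export
read_palette <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cl <- obj$clusters
  out <- tibble::tibble(
    id = as.integer(cl$id),
    r = vapply(cl$centroid, `[`, numeric(1), 1),
    g = vapply(cl$centroid, `[`, numeric(1), 2),
    b = vapply(cl$centroid, `[`, numeric(1), 3),
    luminance = cl$luminance,
    is_background = cl$is_background,
    size = suppressWarnings(as.integer(cl$size)),
    members = lapply(cl$members, function(m) {
      m <- as.matrix(m)
      colnames(m) <- c("r", "g", "b")
      m
    })
  )
  attr(out, "reference_ids") <- obj$reference_ids
  attr(out, "seed") <- obj$seed
  class(out) <- c("hull_palette", class(out))
  out
}

#' Write a landscape to disk
#'
#' Canonical text outputs: the binary membership matrix as TSV (rows =
#' categories, columns = nut ids), both Ward-D2 dendrograms as Newick with
#' branch lengths taken from the merge heights, and the K-NN profile table
#' as TSV. The heatmap rendering ([autoplot.landscape()]) is a by-product of
#' these.
#'
#' @param landscape a `landscape`.
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_landscape <- function(landscape, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- landscape$matrix
  utils::write.table(
    data.frame(category = rownames(m), m, check.names = FALSE),
    file.path(dir, "matrix.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  if (!is.null(landscape$row_tree)) {
    ape::write.tree(ape::as.phylo(landscape$row_tree),
                    file.path(dir, "row_tree.nwk"))
  }
  if (!is.null(landscape$col_tree)) {
    ape::write.tree(ape::as.phylo(landscape$col_tree),
                    file.path(dir, "col_tree.nwk"))
  }
  if (!is.null(landscape$knn)) {
    utils::write.table(landscape$knn, file.path(dir, "knn.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(
    data.frame(nut_id = names(landscape$labels),
               kernel_status = unname(landscape$labels)),
    file.path(dir, "labels.tsv"), sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(dir)
}

#' Read a landscape written by [write_landscape()]
#'
#' Trees are re-fit from the matrix (Ward-D2 on Euclidean distances), which
#' reproduces the written Newick topologies; the Newick files are the
#' interchange format for other tools.
#'
#' @param dir directory written by [write_landscape()].
#' @param K neighbours for the profile table (default 10).
#' @return a `landscape`.
#' @export
read_landscape <- function(dir, K = 10) {
  d <- utils::read.delim(file.path(dir, "matrix.tsv"), check.names = FALSE)
  m <- as.matrix(d[, -1])
  rownames(m) <- d$category
  labs <- utils::read.delim(file.path(dir, "labels.tsv"))
  L <- structure(
    list(
      matrix = m,
      row_tree = if (nrow(m) >= 2) stats::hclust(stats::dist(m), "ward.D2") else NULL,
      col_tree = if (ncol(m) >= 2) stats::hclust(stats::dist(t(m)), "ward.D2") else NULL,
      knn = NULL,
      labels = stats::setNames(labs$kernel_status, labs$nut_id),
      K = K, ct_label = NA_character_
    ),
    class = "landscape"
  )
  if (ncol(m) > K) L$knn <- knn_profile(L, K = K)
  L
}
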