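# Internal helpers shared across modules.

# BT.601 luma; used consistently wherever a single brightness scalar is needed
# (background detection, palette ordering). Any monotone combination would do.
.luminance <- function(r, g, b) 0.299 * r + 0.587 * g + 0.114 * b

# Metadata columns of a feature table; everything else is a feature column.
.meta_cols <- c("nut_id", "ct", "kernel_status")

#' Feature columns of a feature table
#'
#' @param table a feature table (tibble with `nut_id`, `ct`, `kernel_status`
#'   metadata columns followed by feature columns).
#' @return character vector of feature column names, in table order.
#' @export
feature_columns <- function(table) {
  setdiff(names(table), .meta_cols)
}

.assert_kernel_labels <- function(labels) {
  bad <- setdiff(unique(labels), c("blank", "filled"))
  if (length(bad) > 0) {
    stop("kernel labels must be 'blank' or 'filled'; found: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(labels)
}
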