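# Plate imaging: white balance by chromatic adaptation, adaptive-threshold
# segmentation into labelled per-nut pixel ensembles, and kernel-status
# annotation from the paired open-plate image.

#' Construct a plate image
#'
#' @param pixels numeric `H x W x 3` array of 8-bit RGB values in \[0, 255\].
#' @param plate_id plate identifier used to form nut ids.
#' @param ct critical time point label (`"CT1"`, `"CT2"`, `"CT3"` or
#'   `"unknown"`).
#' @return object of class `plate_image`.
#' @export
plate_image <- function(pixels, plate_id = "plate", ct = "unknown") {
  stopifnot(length(dim(pixels)) == 3, dim(pixels)[3] == 3,
            all(pixels >= 0), all(pixels <= 255))
  structure(list(pixels = pixels, plate_id = plate_id, ct = ct, gains = NULL),
            class = "plate_image")
}

#' Read a plate photograph from PNG
#'
#' @param path PNG file path.
#' @inheritParams plate_image
#' @return a `plate_image`.
#' @export
read_plate <- function(path, plate_id = sub("\\.png$", "", basename(path)),
                       ct = "unknown") {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2) a <- array(rep(a, 3), dim = c(dim(a), 3))
  if (dim(a)[3] > 3) a <- a[, , 1:3, drop = FALSE]
  plate_image(a * 255, plate_id = plate_id, ct = ct)
}

#' Write a plate image to PNG
#' @param plate a `plate_image`.
#' @param path output PNG path.
#' @export
write_plate <- function(plate, path) {
  png::writePNG(plate$pixels / 255, target = path)
  invisible(path)
}

#' White-balance a plate by diagonal chromatic adaptation
#'
#' Estimates the white point as the mean RGB of the brightest-quartile pixels
#' (the plate's white background dominates a plate photograph) and applies
#' von-Kries diagonal gains that map the estimate to neutral grey at its own
#' luminance-preserving level (the mean of its three channels). A plate with
#' no near-white background — brightest-quartile luminance below
#' `luminance_floor`, or fewer than 5% of pixels above the floor — is
#' rejected with a diagnostic.
#'
#' @param plate a `plate_image`.
#' @param luminance_floor minimum luminance (0-255) a pixel must reach to
#'   count as near-white background (default 180).
#' @return the corrected `plate_image`, with the per-channel gain vector in
#'   `$gains`.
#' @export
white_balance <- function(plate, luminance_floor = 180) {
  px <- plate$pixels
  lum <- .luminance(px[, , 1], px[, , 2], px[, , 3])
  thr <- stats::quantile(lum, 0.75)
  if (thr < luminance_floor || mean(lum >= luminance_floor) < 0.05) {
    stop("no near-white background region found (brightest-quartile ",
         "luminance ", round(thr, 1), " below floor ", luminance_floor, ")",
         call. = FALSE)
  }
  bright <- lum >= thr
  white <- vapply(1:3, function(c) mean(px[, , c][bright]), numeric(1))
  gains <- mean(white) / white
  for (c in 1:3) px[, , c] <- pmin(pmax(px[, , c] * gains[c], 0), 255)
  out <- plate
  out$pixels <- px
  out$gains <- gains
  out
}

# Local mean over an odd square block via an integral image; windows are
# clipped at the borders and divided by their actual area.
.local_mean <- function(mat, block) {
  stopifnot(block %% 2 == 1)
  h <- (block - 1) / 2
  H <- nrow(mat); W <- ncol(mat)
  I <- matrix(0, H + 1, W + 1)
  I[2:(H + 1), 2:(W + 1)] <- t(apply(apply(mat, 2, cumsum), 1, cumsum))
  r1 <- pmax(seq_len(H) - h, 1); r2 <- pmin(seq_len(H) + h, H)
  c1 <- pmax(seq_len(W) - h, 1); c2 <- pmin(seq_len(W) + h, W)
  s <- I[r2 + 1, c2 + 1] - I[r1, c2 + 1] - I[r2 + 1, c1] + I[r1, c1]
  s / outer(r2 - r1 + 1, c2 - c1 + 1)
}

# Connected-component labelling of a logical mask (EBImage's bwlabel; label
# numbering is irrelevant downstream, nuts are re-ordered by centroid).
# Holes are filled first: a nut record holds every pixel inside its contour,
# and near-uniform nut interiors can fall above the local-mean threshold when
# the averaging window fits wholly inside the nut.
.label_components <- function(mask) {
  storage.mode(mask) <- "double"
  m <- EBImage::bwlabel(EBImage::fillHull(mask))
  matrix(as.integer(m), nrow = nrow(mask))
}

#' Segment a white-balanced plate into nut records
#'
#' Adaptive thresholding on the luminance channel — a pixel is foreground
#' when its luminance falls below the local mean over `block_size` minus
#' `offset` — followed by connected-component labelling. Components touching
#' the image border are discarded (plate edges, cropped nuts), as are specks
#' below `min_area_frac` of the image area. Surviving nuts are labelled
#' `1..N` top-to-bottom by centroid row, ties broken left-to-right by
#' centroid column, matching the plate layout convention.
#'
#' @param plate a (white-balanced) `plate_image`.
#' @param block_size odd local-mean window in pixels (default 51).
#' @param offset threshold offset C subtracted from the local mean (default 5).
#' @param min_area_frac minimum component area as a fraction of the image
#'   area (default 5e-4).
#' @return tibble with one row per nut: `nut_id`, `plate_id`, `ct`,
#'   `ordinal`, `centroid_x`, `centroid_y`, `area_px`, `kernel_status`
#'   (`"unknown"`), and a `pixels` list-column of per-nut tibbles
#'   (`x`, `y` 0-based image coordinates; `r`, `g`, `b`). Zero detections
#'   return an empty tibble with a warning.
#' @export
segment_plate <- function(plate, block_size = 51, offset = 5,
                          min_area_frac = 5e-4) {
  px <- plate$pixels
  H <- dim(px)[1]; W <- dim(px)[2]
  lum <- .luminance(px[, , 1], px[, , 2], px[, , 3])
  # a pixel is nut material when it is below the local mean AND clearly
  # darker than the white plate itself; the second clause suppresses the
  # bright-background halo that a local mean develops next to dark objects
  bg_lum <- stats::median(lum[lum >= stats::quantile(lum, 0.75)])
  mask <- (lum < .local_mean(lum, block_size) - offset) &
    (lum < bg_lum - 3 * offset)
  lab <- .label_components(mask)
  border <- unique(c(lab[1, ], lab[H, ], lab[, 1], lab[, W]))
  lab[lab %in% border] <- 0L
  min_area <- min_area_frac * H * W
  keep <- which(tabulate(lab) >= min_area)
  if (length(keep) == 0) {
    warning("no nuts detected on plate ", plate$plate_id)
    return(tibble::tibble(nut_id = character(), plate_id = character(),
                          ct = character(), ordinal = integer(),
                          centroid_x = numeric(), centroid_y = numeric(),
                          area_px = integer(), kernel_status = character(),
                          pixels = list()))
  }
  idx <- which(lab %in% keep)
  row <- (idx - 1) %% H + 1
  col <- (idx - 1) %/% H + 1
  comp <- lab[idx]
  cy <- tapply(row, comp, mean) - 1   # 0-based
  cx <- tapply(col, comp, mean) - 1
  ord <- order(cy, cx)
  out <- purrr::map_dfr(seq_along(ord), function(i) {
    k <- as.integer(names(cy))[ord[i]]
    sel <- comp == k
    ri <- row[sel]; ci <- col[sel]
    tibble::tibble(
      nut_id = paste0(plate$plate_id, "-", i),
      plate_id = plate$plate_id, ct = plate$ct, ordinal = i,
      centroid_x = unname(cx[as.character(k)]),
      centroid_y = unname(cy[as.character(k)]),
      area_px = sum(sel), kernel_status = "unknown",
      pixels = list(tibble::tibble(
        x = ci - 1L, y = ri - 1L,
        r = px[cbind(ri, ci, 1)],
        g = px[cbind(ri, ci, 2)],
        b = px[cbind(ri, ci, 3)]
      ))
    )
  })
  out
}

#' Annotate kernel status from the paired open-plate labels
#'
#' Each plate is photographed whole and cut open at matching positions; the
#' blank/filled call made on the open plate is copied onto the whole-nut
#' record with the same ordinal.
#'
#' @param whole nut records from [segment_plate()] on the whole-nut plate.
#' @param open_labels character vector of `"blank"` / `"filled"` in open-plate
#'   ordinal order (one per nut).
#' @param open optional nut records from the open plate, used to cross-check
#'   the detection counts.
#' @return `whole` with `kernel_status` filled in.
#' @export
annotate_kernel_status <- function(whole, open_labels, open = NULL) {
  .assert_kernel_labels(open_labels)
  n <- nrow(whole)
  if (!is.null(open) && nrow(open) != n) {
    stop("whole/open plate mismatch: ", n, " vs ", nrow(open), " nuts; ",
         "unmatched ordinals: ",
         paste(setdiff(seq_len(max(n, nrow(open))),
                       seq_len(min(n, nrow(open)))), collapse = ", "),
         call. = FALSE)
  }
  if (length(open_labels) != n) {
    stop("label/plate mismatch: ", n, " nuts vs ", length(open_labels),
         " labels; unmatched ordinals: ",
         paste(setdiff(seq_len(max(n, length(open_labels))),
                       seq_len(min(n, length(open_labels)))), collapse = ", "),
         call. = FALSE)
  }
  whole$kernel_status <- open_labels[whole$ordinal]
  whole
}

#' Write the per-nut manifest as TSV
#'
#' @param nuts nut records ([segment_plate()] output).
#' @param path output TSV path.
#' @export
write_nut_manifest <- function(nuts, path) {
  utils::write.table(
    nuts[, c("nut_id", "plate_id", "ct", "ordinal", "centroid_x",
             "centroid_y", "area_px", "kernel_status")],
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
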