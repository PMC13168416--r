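#' Labeled tumor mask
#'
#' A labeled tumor mask is an integer matrix: 0 = background, k > 0 = lesion
#' id. Coordinates are 0-based `(row, col)` with pixel centers at integer
#' coordinates. Each positive label must form a single 8-connected
#' component.
#'
#' @name labeled-mask
NULL

# 8-connected component labeling. EBImage::bwlabel is 4-connected; diagonal
# label pairs are merged with union-find afterwards.
label_components <- function(binary) {
  stopifnot(is.matrix(binary))
  lab <- EBImage::imageData(EBImage::bwlabel(binary * 1L))
  k <- max(lab)
  if (k <= 1L) return(matrix(as.integer(lab), nrow(lab), ncol(lab)))
  parent <- seq_len(k)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  union_ <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
    invisible(NULL)
  }
  nr <- nrow(lab); nc <- ncol(lab)
  # diagonal neighbor pairs with two distinct positive labels
  a <- lab[-nr, -nc]; b <- lab[-1, -1]
  idx <- which(a > 0 & b > 0 & a != b)
  for (i in idx) union_(a[i], b[i])
  a <- lab[-nr, -1]; b <- lab[-1, -nc]
  idx <- which(a > 0 & b > 0 & a != b)
  for (i in idx) union_(a[i], b[i])
  roots <- vapply(seq_len(k), find, integer(1))
  dense <- match(roots, sort(unique(roots)))
  out <- matrix(0L, nr, nc)
  pos <- lab > 0
  out[pos] <- dense[lab[pos]]
  out
}

#' Identify lesions in a mask and filter by a minimum area
#'
#' Validates/relabels a raster into 8-connected lesions, drops components
#' smaller than `min_area_um2` (the DAPI-dense lesion floor, 130 um2 by
#' default) and reports areas in both pixels and square micrometres under
#' the active calibration. Dropped components are reported via a message.
#'
#' @param mask integer matrix, 0 background; positive values mark tumor
#'   pixels (a binary mask is accepted and labeled).
#' @param cal a [calibration()] object.
#' @param min_area_um2 lesion area floor in um2 (>= 0).
#' @param relabel if `TRUE` (default) connected components are recomputed;
#'   if `FALSE` the existing positive labels are trusted.
#' @return a list with `labels` (integer matrix of surviving lesion ids,
#'   relabeled 1..n) and `lesions`, a data.frame with one row per lesion:
#'   `id`, `area_px`, `area_um2`, `centroid_row`, `centroid_col` (0-based).
#' @export
label_tumors <- function(mask, cal = calibration(), min_area_um2 = 130,
                         relabel = TRUE) {
  if (!is.matrix(mask) || !(is.numeric(mask) || is.logical(mask)))
    stop("mask must be a numeric matrix")
  if (any(mask < 0) || any(mask != round(mask)))
    stop("mask must contain non-negative integers")
  stopifnot(min_area_um2 >= 0)
  lab <- if (relabel) label_components(mask > 0) else {
    storage.mode(mask) <- "integer"
    mask
  }
  k <- max(lab)
  empty <- list(labels = matrix(0L, nrow(mask), ncol(mask)),
                lesions = data.frame(id = integer(), area_px = numeric(),
                                     area_um2 = numeric(),
                                     centroid_row = numeric(),
                                     centroid_col = numeric()))
  if (k == 0L) return(empty)
  area_px <- tabulate(lab[lab > 0], nbins = k)
  area_um2 <- px_to_um2(area_px, cal)
  keep <- which(area_um2 >= min_area_um2)
  dropped <- setdiff(seq_len(k), keep)
  if (length(dropped))
    message(length(dropped), " component(s) below the ", min_area_um2,
            " um2 floor dropped (areas: ",
            paste(signif(area_um2[dropped], 4), collapse = ", "), " um2)")
  if (!length(keep)) return(empty)
  new_id <- integer(k)
  new_id[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(lab), ncol(lab))
  pos <- lab > 0L
  out[pos] <- new_id[lab[pos]]
  idx <- which(out > 0, arr.ind = TRUE)
  ids <- out[out > 0]
  centroid_row <- tapply(idx[, 1] - 1, ids, mean)
  centroid_col <- tapply(idx[, 2] - 1, ids, mean)
  list(labels = out,
       lesions = data.frame(id = seq_along(keep),
                            area_px = area_px[keep],
                            area_um2 = area_um2[keep],
                            centroid_row = as.numeric(centroid_row),
                            centroid_col = as.numeric(centroid_col)))
}

#' Read/write labeled masks
#'
#' Masks are written as 16-bit single-channel TIFF (primary format) or 8-bit
#' PNG (accepted for up to 255 lesions). Pixel values are lesion ids.
#'
#' @param mask integer matrix of lesion ids.
#' @param path file path ending in `.tif`, `.tiff` or `.png`.
#' @export
write_mask <- function(mask, path) {
  stopifnot(is.matrix(mask), all(mask >= 0))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    if (max(mask) > 65535) stop("more than 65535 labels; cannot write 16-bit TIFF")
    tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16L)
  } else if (ext == "png") {
    if (max(mask) > 255) stop("more than 255 labels; use TIFF")
    png::writePNG(mask / 255, path)
  } else stop("unsupported mask format: .", ext)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) tiff::readTIFF(path) * 65535
         else if (ext == "png") png::readPNG(path) * 255
         else stop("unsupported mask format: .", ext)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  m <- round(img)
  storage.mode(m) <- "integer"
  m
}
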