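#' Lesion size-class bins
#'
#' A set of named, non-overlapping `[low, high]` bins plus a "major"
#' threshold. Two published presets ship with the package:
#'
#' * `"methods_px"`: small 70-1300 px, medium 2000-4000 px, large
#'   6000-10000 px, major above 338,511.7 um2 (the full frame area).
#' * `"results_um2"`: small 130-418, medium 643-1287, large 1931-3219 um2,
#'   major above 338,511.7 um2.
#'
#' The two presets are *not* mutually consistent under any single pixel
#' calibration; they are carried verbatim as alternative conventions and no
#' reconciliation is attempted. Areas falling in the gaps between bins are
#' "unclassified".
#'
#' @param bins named list of `c(low, high)` bounds.
#' @param unit `"px"` or `"um2"`: the unit of the bin bounds.
#' @param major_threshold_um2 areas strictly above this (in um2) are "major".
#' @return a `tam_size_bins` object.
#' @export
size_class_bins <- function(bins, unit = c("px", "um2"),
                            major_threshold_um2 = 338511.7) {
  unit <- match.arg(unit)
  stopifnot(is.list(bins), length(bins) >= 1L, !is.null(names(bins)))
  b <- t(vapply(bins, function(x) {
    stopifnot(is.numeric(x), length(x) == 2L, x[1] <= x[2], x[1] >= 0)
    as.numeric(x)
  }, numeric(2)))
  ord <- order(b[, 1])
  b <- b[ord, , drop = FALSE]
  if (nrow(b) > 1L && any(b[-1L, 1L] <= b[-nrow(b), 2L]))
    stop("size-class bins overlap: ", paste(rownames(b), collapse = ", "))
  structure(list(bins = b, unit = unit,
                 major_threshold_um2 = major_threshold_um2),
            class = "tam_size_bins")
}

#' @rdname size_class_bins
#' @param preset `"methods_px"` or `"results_um2"`.
#' @export
size_bins_preset <- function(preset = c("methods_px", "results_um2")) {
  preset <- match.arg(preset)
  switch(preset,
    methods_px = size_class_bins(
      list(small = c(70, 1300), medium = c(2000, 4000),
           large = c(6000, 10000)),
      unit = "px"),
    results_um2 = size_class_bins(
      list(small = c(130, 418), medium = c(643, 1287),
           large = c(1931, 3219)),
      unit = "um2")
  )
}

#' Assign a lesion to a size class
#'
#' "major" takes precedence (area above the major threshold, in um2); then
#' the unique containing bin; areas in inter-bin gaps return
#' `"unclassified"`.
#'
#' @param area_px,area_um2 lesion area in pixels and square micrometres
#'   (both supplied so either bin unit can be served).
#' @param bins a [size_class_bins()] object.
#' @return character vector of class labels.
#' @export
assign_size_class <- function(area_px, area_um2, bins = size_bins_preset()) {
  stopifnot(inherits(bins, "tam_size_bins"),
            length(area_px) == length(area_um2),
            all(area_px >= 0), all(area_um2 >= 0))
  area <- if (bins$unit == "px") area_px else area_um2
  out <- rep("unclassified", length(area))
  b <- bins$bins
  for (i in seq_len(nrow(b))) {
    out[area >= b[i, 1] & area <= b[i, 2]] <- rownames(b)[i]
  }
  out[area_um2 > bins$major_threshold_um2] <- "major"
  out
}
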