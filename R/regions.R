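# Euclidean distance transforms. distmap() returns, for every non-zero
# pixel, the exact Euclidean distance (pixel centers, center-to-center) to
# the nearest zero pixel; zero pixels get 0.
edt <- function(binary) {
  if (all(binary > 0)) {
    # no opposite phase anywhere: distances are infinite
    return(matrix(Inf, nrow(binary), ncol(binary)))
  }
  m <- EBImage::imageData(EBImage::distmap(binary * 1, metric = "euclidean"))
  matrix(as.numeric(m), nrow(binary), ncol(binary))
}

# The lesion border layer: foreground pixels with at least one opposite-
# phase 4-neighbor (pixels beyond the frame count as foreground, so a
# lesion clipped by the frame has no border along the frame edge).
border_layer <- function(binary) {
  nr <- nrow(binary); nc <- ncol(binary)
  pad <- matrix(TRUE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- binary
  binary & !(pad[1:nr, 2:(nc + 1)] & pad[3:(nr + 2), 2:(nc + 1)] &
             pad[2:(nr + 1), 1:nc] & pad[2:(nr + 1), 3:(nc + 2)])
}

# Exact Euclidean distance (pixel centers) from every pixel to the nearest
# border-layer pixel of `binary`; border pixels themselves get 0. The
# periphery band is the Euclidean dilation of this layer by band_width/2.
border_distance <- function(binary) {
  bord <- border_layer(binary)
  if (!any(bord)) return(matrix(Inf, nrow(binary), ncol(binary)))
  edt(!bord)
}

#' Decompose one lesion into periphery band and interior
#'
#' The periphery is a `band_width_px`-wide band centered on the lesion
#' border and extending equally inward and outward: all pixels within
#' Euclidean distance band_width/2 (center-to-center) of the lesion's
#' border layer (lesion pixels touching background). The inner band is the
#' lesion part of that dilation, the outer band its background part; the
#' interior is the lesion minus the inner band; for lesions narrower than
#' the band it is empty (with a warning). For a rasterized disc the total
#' band area matches the analytic annulus to well under the pixelation
#' error.
#'
#' @param labels integer matrix of lesion ids (see [label_tumors()]).
#' @param lesion_id id of the lesion to decompose.
#' @param band_width_px full band width in pixels (default 7, i.e. 3.5 px
#'   on each side of the border).
#' @return list of logical matrices `periphery_inner`, `periphery_outer`,
#'   `interior`.
#' @export
decompose_periphery_interior <- function(labels, lesion_id, band_width_px = 7) {
  stopifnot(is.matrix(labels), band_width_px > 0)
  les <- labels == lesion_id
  if (!any(les)) stop("lesion id ", lesion_id, " not present in mask")
  half <- band_width_px / 2
  d <- border_distance(les)
  inner <- les & d <= half
  outer <- (labels == 0L) & d <= half
  interior <- les & !inner
  if (!any(interior))
    warning("band width ", band_width_px,
            " px swallows lesion ", lesion_id, ": empty interior")
  list(periphery_inner = inner, periphery_outer = outer, interior = interior)
}

#' Intertumoral region and tumor-free area
#'
#' The intertumoral region is the background at center-to-center Euclidean
#' distance >= `buffer_um` (converted via the linear pixel size) from every
#' lesion pixel; the buffer excludes cells potentially at a tumor border.
#' The tumor-free area is the frame area minus the summed lesion areas -
#' the buffer is *not* subtracted from the denominator, matching how
#' between-tumor densities are normalized.
#'
#' @param labels integer matrix of lesion ids, already floor-filtered.
#' @param cal a [calibration()] object.
#' @param buffer_um exclusion distance in micrometres (>= 0).
#' @param frame_area_um2 total frame area; default = frame pixels converted
#'   under `cal`.
#' @return list with `intertumoral_mask` (logical matrix) and
#'   `tumor_free_area_um2`.
#' @export
intertumoral_region <- function(labels, cal = calibration(), buffer_um = 4,
                                frame_area_um2 = NULL) {
  stopifnot(is.matrix(labels))
  if (buffer_um < 0) stop("buffer_um must be >= 0")
  if (is.null(frame_area_um2))
    frame_area_um2 <- px_to_um2(length(labels), cal)
  buffer_px <- um_to_px(buffer_um, cal)
  d <- edt(labels == 0)           # background distance to any lesion pixel
  inter <- (labels == 0) & d >= buffer_px
  lesion_px <- sum(labels > 0)
  list(intertumoral_mask = inter,
       tumor_free_area_um2 = frame_area_um2 - px_to_um2(lesion_px, cal))
}

# 8-boundary foreground pixels (0-based coords): foreground pixels with at
# least one non-foreground 8-neighbor or on the frame edge. The nearest
# foreground pixel to any background point is always among these.
boundary_pixels <- function(binary) {
  nr <- nrow(binary); nc <- ncol(binary)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- binary
  all_nb <- matrix(TRUE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    all_nb <- all_nb & pad[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
  }
  which(binary & !all_nb, arr.ind = TRUE) - 1L
}

#' Distance from points to the nearest lesion
#'
#' Exact Euclidean distance (in micrometres) from arbitrary, possibly
#' sub-pixel, points to the nearest lesion pixel center; 0 for points whose
#' containing pixel lies inside a lesion. Points are 0-based `(row, col)`
#' with pixel centers at integer coordinates.
#'
#' @param labels integer matrix of lesion ids.
#' @param points two-column matrix (row, col) of 0-based coordinates.
#' @param cal a [calibration()] object.
#' @return numeric vector of distances in micrometres.
#' @export
distance_to_nearest_lesion <- function(labels, points, cal = calibration()) {
  stopifnot(is.matrix(labels))
  points <- matrix(as.numeric(points), ncol = 2)
  nr <- nrow(labels); nc <- ncol(labels)
  if (any(points[, 1] < -0.5 | points[, 1] > nr - 0.5 |
          points[, 2] < -0.5 | points[, 2] > nc - 0.5))
    stop("point outside frame")
  n <- nrow(points)
  out <- rep(Inf, n)
  if (!any(labels > 0)) return(out)
  pr <- pmin(pmax(as.integer(round(points[, 1])), 0L), nr - 1L)
  pc <- pmin(pmax(as.integer(round(points[, 2])), 0L), nc - 1L)
  inside <- labels[cbind(pr + 1L, pc + 1L)] > 0
  out[inside] <- 0
  todo <- which(!inside)
  if (!length(todo)) return(out)
  bd <- boundary_pixels(labels > 0)
  # chunk over points to bound the |points| x |boundary| workspace
  step <- max(1L, floor(2e6 / nrow(bd)))
  for (s in seq(1L, length(todo), by = step)) {
    ii <- todo[s:min(s + step - 1L, length(todo))]
    d2 <- outer(points[ii, 1], bd[, 1], "-")^2 +
          outer(points[ii, 2], bd[, 2], "-")^2
    out[ii] <- sqrt(apply(d2, 1, min))
  }
  px_to_um(out, cal)
}

#' Full region partition of a labeled mask
#'
#' Runs the periphery/interior decomposition for every lesion (on padded
#' bounding-box crops) and the intertumoral computation once, resolving
#' overlapping outer bands: outer-band pixels claimed by several lesions
#' are assigned to the nearest lesion border (ties to the lower id), so
#' per-lesion densities never double count.
#'
#' @param labels integer matrix of lesion ids (floor-filtered).
#' @param cal a [calibration()] object.
#' @param band_width_px full periphery band width (default 7).
#' @param buffer_um intertumoral exclusion buffer (default 4).
#' @param frame_area_um2 optional frame area override.
#' @return a `tam_region_partition`: list with
#'   `region` (character matrix: "interior", "periphery_inner",
#'   "periphery_outer", "intertumoral", "buffer", "background"),
#'   `lesion_of` (integer matrix: owning lesion id for interior/periphery
#'   pixels, else 0), `tumor_free_area_um2`, `intertumoral_mask`, `areas`
#'   (per-lesion px areas of interior/inner/outer) and the parameters used.
#' @export
region_partition <- function(labels, cal = calibration(), band_width_px = 7,
                             buffer_um = 4, frame_area_um2 = NULL) {
  stopifnot(is.matrix(labels))
  nr <- nrow(labels); nc <- ncol(labels)
  ids <- setdiff(sort(unique(as.vector(labels))), 0L)
  half <- band_width_px / 2
  region <- matrix("background", nr, nc)
  lesion_of <- matrix(0L, nr, nc)
  region[labels > 0] <- "interior"
  lesion_of[labels > 0] <- labels[labels > 0]
  pad <- ceiling(half) + 2L
  best_d <- matrix(Inf, nr, nc)
  for (id in ids) {
    w <- which(labels == id, arr.ind = TRUE)
    r0 <- max(1L, min(w[, 1]) - pad); r1 <- min(nr, max(w[, 1]) + pad)
    c0 <- max(1L, min(w[, 2]) - pad); c1 <- min(nc, max(w[, 2]) + pad)
    sub <- labels[r0:r1, c0:c1]
    d_sub <- border_distance(sub == id)
    in_band <- which(sub == id & d_sub <= half, arr.ind = TRUE)
    if (nrow(in_band)) {
      gi <- cbind(in_band[, 1] + r0 - 1L, in_band[, 2] + c0 - 1L)
      region[gi] <- "periphery_inner"
    }
    out_band <- which(sub == 0L & d_sub <= half &
                        d_sub < best_d[r0:r1, c0:c1], arr.ind = TRUE)
    if (nrow(out_band)) {
      gi <- cbind(out_band[, 1] + r0 - 1L, out_band[, 2] + c0 - 1L)
      best_d[gi] <- d_sub[out_band]
      region[gi] <- "periphery_outer"
      lesion_of[gi] <- id
    }
  }
  it <- intertumoral_region(labels, cal, buffer_um, frame_area_um2)
  inter <- it$intertumoral_mask & region == "background"
  region[inter] <- "intertumoral"
  region[region == "background"] <- "buffer"
  areas <- do.call(rbind, lapply(ids, function(id) {
    data.frame(id = id,
               interior_px = sum(region == "interior" & lesion_of == id),
               inner_px = sum(region == "periphery_inner" & lesion_of == id),
               outer_px = sum(region == "periphery_outer" & lesion_of == id))
  }))
  structure(list(region = region, lesion_of = lesion_of,
                 tumor_free_area_um2 = it$tumor_free_area_um2,
                 intertumoral_mask = it$intertumoral_mask,
                 areas = areas, cal = cal, band_width_px = band_width_px,
                 buffer_um = buffer_um),
            class = "tam_region_partition")
}
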