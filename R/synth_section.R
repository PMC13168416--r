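#' Tumor specification for the section generator
#'
#' @param shape `"disc"`, `"ellipse"` or `"blob"` (a disc with a smooth
#'   sinusoidal radial perturbation).
#' @param center_px `c(row, col)` center, 0-based.
#' @param radii_px radius (disc/blob) or `c(r_row, r_col)` (ellipse).
#' @param target_size_class optional expected size class (`"small"`,
#'   `"medium"`, `"large"`, `"major"`, `"none"`); when named, the rendered
#'   component's area is validated against the active size bins.
#' @param blob_amp,blob_k,blob_phase blob perturbation: relative amplitude,
#'   angular frequency and phase.
#' @return a `tam_tumor_spec`.
#' @export
tumor_spec <- function(shape = c("disc", "ellipse", "blob"), center_px,
                       radii_px, target_size_class = "none",
                       blob_amp = 0.15, blob_k = 5, blob_phase = 0) {
  shape <- match.arg(shape)
  stopifnot(length(center_px) == 2L, all(radii_px > 0),
            target_size_class %in% c("small", "medium", "large", "major",
                                     "none"))
  structure(list(shape = shape, center_px = as.numeric(center_px),
                 radii_px = as.numeric(radii_px),
                 target_size_class = target_size_class,
                 blob_amp = blob_amp, blob_k = blob_k,
                 blob_phase = blob_phase),
            class = "tam_tumor_spec")
}

render_tumor <- function(ts, nr, nc) {
  r <- matrix(0:(nr - 1), nr, nc)
  c_ <- matrix(0:(nc - 1), nr, nc, byrow = TRUE)
  dr <- r - ts$center_px[1]; dc <- c_ - ts$center_px[2]
  m <- switch(ts$shape,
    disc = (dr^2 + dc^2) <= ts$radii_px[1]^2,
    ellipse = {
      rr <- if (length(ts$radii_px) == 2L) ts$radii_px else rep(ts$radii_px, 2)
      (dr / rr[1])^2 + (dc / rr[2])^2 <= 1
    },
    blob = {
      theta <- atan2(dc, dr)
      rad <- ts$radii_px[1] *
        (1 + ts$blob_amp * sin(ts$blob_k * theta + ts$blob_phase))
      (dr^2 + dc^2) <= rad^2
    })
  m
}

#' Default programmed intensities (cells per 0.01 mm2)
#'
#' Two canned intensity matrices define the study conditions of the
#' synthetic cohort, mirroring the measured trend structure: in microtumor
#' sections MG dominate with a strong peripheral peak, MDM are sparse; in
#' major-tumor sections MDM dominate the interior so the MG/MDM ratio
#' inverts. Rows are TAM classes, columns region kinds.
#'
#' @return numeric matrix with rownames `MG`, `MDM` and colnames
#'   `nontumor`, `periphery`, `interior`.
#' @export
default_intensity_microtumor <- function() {
  m <- rbind(MG = c(nontumor = 8, periphery = 45, interior = 12),
             MDM = c(nontumor = 1.5, periphery = 8, interior = 5))
  m
}

#' @rdname default_intensity_microtumor
#' @export
default_intensity_major <- function() {
  rbind(MG = c(nontumor = 8, periphery = 25, interior = 15),
        MDM = c(nontumor = 1.5, periphery = 20, interior = 45))
}

#' Section specification for the synthetic generator
#'
#' Defines one imaged field: frame geometry, tumors, and the programmed
#' ground truth (region-specific expected densities, Ki-67 and CD206
#' probabilities) under a mouse model and compartment. Defaults reproduce
#' the published imaging conditions: a 338,511.7 um2 field at 1024 x 1024
#' pixels.
#'
#' @param frame_shape_px `c(rows, cols)`.
#' @param pixel_size_um linear pixel size.
#' @param frame_area_um2 stated frame area; must agree with
#'   `frame_shape_px * pixel_size_um^2` to within 1%.
#' @param tumors list of [tumor_spec()] objects.
#' @param intensity matrix (class x region) of expected cells per 0.01 mm2.
#' @param ki67_prob matrix (class x region) of Ki-67 probabilities.
#' @param cd206_prob named vector of CD206 probabilities per class.
#' @param mouse_model,compartment classification context (see
#'   [classify_cells()]).
#' @param bins size bins used to validate tumor target classes; the
#'   synthetic study scales the operational major threshold down to
#'   100,000 um2 because no in-frame lesion can exceed one full frame.
#' @param band_width_px,buffer_um geometry parameters for the placement
#'   regions.
#' @param seed integer RNG seed.
#' @return a `tam_section_spec`.
#' @export
section_spec <- function(frame_shape_px = c(1024, 1024),
                         pixel_size_um = 0.5681818,
                         frame_area_um2 = 338511.7,
                         tumors = list(),
                         intensity = default_intensity_microtumor(),
                         ki67_prob = NULL,
                         cd206_prob = c(MG = 0.1, MDM = 0.78,
                                        BAM_candidate = 0.75),
                         mouse_model = "cx3cr1creer",
                         compartment = "parenchyma",
                         bins = size_class_bins(
                           list(small = c(70, 1300), medium = c(2000, 4000),
                                large = c(6000, 10000)), unit = "px",
                           major_threshold_um2 = 1e5),
                         band_width_px = 7, buffer_um = 4, seed = 1L) {
  if (is.null(ki67_prob)) {
    ki67_prob <- matrix(0.01, nrow(intensity), ncol(intensity),
                        dimnames = dimnames(intensity))
    if ("MG" %in% rownames(ki67_prob)) {
      ki67_prob["MG", ] <- 0.25
      if ("nontumor" %in% colnames(ki67_prob))
        ki67_prob["MG", "nontumor"] <- 0.02
    }
  }
  stopifnot(all(intensity >= 0), all(ki67_prob >= 0 & ki67_prob <= 1),
            all(cd206_prob >= 0 & cd206_prob <= 1),
            identical(dim(intensity), dim(ki67_prob)))
  if (!mouse_model %in% tam_models) stop("unknown mouse model")
  implied <- prod(frame_shape_px) * pixel_size_um^2
  if (abs(implied - frame_area_um2) / frame_area_um2 > 0.01)
    stop("frame_area_um2 inconsistent with frame shape and pixel size (",
         signif(implied, 6), " vs ", frame_area_um2, ")")
  structure(list(frame_shape_px = as.integer(frame_shape_px),
                 pixel_size_um = pixel_size_um,
                 frame_area_um2 = frame_area_um2, tumors = tumors,
                 intensity = intensity, ki67_prob = ki67_prob,
                 cd206_prob = cd206_prob, mouse_model = mouse_model,
                 compartment = compartment, bins = bins,
                 band_width_px = band_width_px, buffer_um = buffer_um,
                 seed = as.integer(seed)),
            class = "tam_section_spec")
}

#' Generate a synthetic section: labeled mask + cell table
#'
#' Renders the tumors, decomposes the frame into placement regions
#' (interior, full periphery band, intertumoral), and scatters cells as a
#' homogeneous Poisson process per (class, region): expected count =
#' intensity x region area / 0.01 mm2, positions uniform over region
#' pixels with sub-pixel jitter, so region membership holds by
#' construction. Marker flags invert the mouse model's classification rule;
#' Ki-67/CD206 are Bernoulli with the programmed probabilities. Ground
#' truth is stored in reserved columns (`true_class`, `true_region`) that
#' the analysis pipeline never reads.
#'
#' @param spec a [section_spec()].
#' @return list with `mask` (labeled integer matrix), `cells` (data.frame),
#'   `partition` (the [region_partition()] used for placement), `cal`,
#'   `lesions`, and `spec`.
#' @export
make_section <- function(spec) {
  stopifnot(inherits(spec, "tam_section_spec"))
  set.seed(spec$seed)
  nr <- spec$frame_shape_px[1]; nc <- spec$frame_shape_px[2]
  cal <- calibration(spec$pixel_size_um)
  labels <- matrix(0L, nr, nc)
  for (i in seq_along(spec$tumors)) {
    m <- render_tumor(spec$tumors[[i]], nr, nc)
    clash <- labels > 0 & m
    if (any(clash)) {
      other <- sort(unique(labels[clash]))
      stop("tumor specs ", paste(other, collapse = ","), " and ", i,
           " overlap/merge into one component")
    }
    labels[m] <- i
  }
  # touching (but not overlapping) renders would still merge under
  # 8-connectivity: verify component count
  if (length(spec$tumors) &&
      max(label_components(labels > 0)) != length(spec$tumors)) {
    stop("adjacent tumor specs merge into one connected component")
  }
  # validate target size classes
  if (length(spec$tumors)) {
    area_px <- tabulate(labels[labels > 0], nbins = length(spec$tumors))
    area_um2 <- px_to_um2(area_px, cal)
    got <- assign_size_class(area_px, area_um2, spec$bins)
    for (i in seq_along(spec$tumors)) {
      tgt <- spec$tumors[[i]]$target_size_class
      if (tgt != "none" && got[i] != tgt)
        stop("tumor spec ", i, " targeted size class '", tgt,
             "' but rendered as '", got[i], "' (", area_px[i], " px)")
    }
  }
  part <- region_partition(labels, cal, spec$band_width_px, spec$buffer_um,
                           spec$frame_area_um2)
  region_masks <- list(
    nontumor = part$region == "intertumoral",
    periphery = part$region %in% c("periphery_inner", "periphery_outer"),
    interior = part$region == "interior")
  cells <- list()
  for (cl in rownames(spec$intensity)) {
    for (rk in colnames(spec$intensity)) {
      mask_rk <- region_masks[[rk]]
      npx <- sum(mask_rk)
      if (npx == 0) next
      area_um2 <- px_to_um2(npx, cal)
      lambda <- spec$intensity[cl, rk] * area_um2 / 1e4
      if (lambda == 0) next
      if (lambda > npx)
        stop("intensity for (", cl, ", ", rk, ") exceeds one cell per pixel")
      n <- stats::rpois(1, lambda)
      if (n == 0) next
      idx <- which(mask_rk)
      pick <- idx[sample.int(length(idx), n, replace = TRUE)]
      prow <- (pick - 1L) %% nr
      pcol <- (pick - 1L) %/% nr
      jr <- stats::runif(n, -0.499, 0.499)
      jc <- stats::runif(n, -0.499, 0.499)
      mk <- markers_for_class(cl, spec$mouse_model, spec$compartment)
      cells[[length(cells) + 1L]] <- data.frame(
        x_px = pcol + jc, y_px = prow + jr,
        tdT = unname(mk["tdT"]), GFP = unname(mk["GFP"]),
        Iba1 = unname(mk["Iba1"]),
        Ki67 = stats::runif(n) < spec$ki67_prob[cl, rk],
        CD206 = stats::runif(n) < spec$cd206_prob[[cl]],
        true_class = cl, true_region = rk,
        stringsAsFactors = FALSE)
    }
  }
  cells <- if (length(cells)) do.call(rbind, cells) else
    data.frame(x_px = numeric(), y_px = numeric(), tdT = logical(),
               GFP = logical(), Iba1 = logical(), Ki67 = logical(),
               CD206 = logical(), true_class = character(),
               true_region = character(), stringsAsFactors = FALSE)
  rownames(cells) <- NULL
  cells$mouse_model <- rep(spec$mouse_model, nrow(cells))
  lesions <- label_tumors(labels, cal, min_area_um2 = 0, relabel = FALSE)
  list(mask = labels, cells = cells, partition = part, cal = cal,
       lesions = lesions$lesions, spec = spec)
}

#' Render marker channels as Gaussian spots
#'
#' Optional visual fixture: one channel per marker, a unit-height Gaussian
#' spot at each positive cell's coordinates. Deterministic given inputs and
#' linear in the cell table.
#'
#' @param dim_px `c(rows, cols)` of the raster.
#' @param cells cell table with `x_px`, `y_px` and logical marker columns.
#' @param markers marker columns to render.
#' @param sigma_px Gaussian spot sd in pixels.
#' @param halfwidth_px stamp half-width in pixels.
#' @return 3-D array `rows x cols x markers`.
#' @export
render_channels <- function(dim_px, cells,
                            markers = c("tdT", "GFP", "Iba1"),
                            sigma_px = 2, halfwidth_px = 6) {
  nr <- dim_px[1]; nc <- dim_px[2]
  if (nrow(cells) &&
      (any(cells$y_px < -0.5 | cells$y_px > nr - 0.5) ||
       any(cells$x_px < -0.5 | cells$x_px > nc - 0.5)))
    stop("cells outside frame")
  out <- array(0, c(nr, nc, length(markers)),
               dimnames = list(NULL, NULL, markers))
  h <- halfwidth_px
  for (k in seq_along(markers)) {
    pos <- which(as.logical(cells[[markers[k]]]))
    ch <- matrix(0, nr, nc)
    for (i in pos) {
      r0 <- cells$y_px[i]; c0 <- cells$x_px[i]
      rr <- max(0, floor(r0 - h)):min(nr - 1, ceiling(r0 + h))
      cc <- max(0, floor(c0 - h)):min(nc - 1, ceiling(c0 + h))
      g <- exp(-outer((rr - r0)^2, (cc - c0)^2, "+") / (2 * sigma_px^2))
      ch[rr + 1, cc + 1] <- ch[rr + 1, cc + 1] + g
    }
    out[, , k] <- ch
  }
  out
}
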