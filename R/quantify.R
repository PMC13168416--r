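#' Density records
#'
#' All densities in the package are reported as cells per 0.01 mm2
#' (= 10,000 um2), the unit used for every density figure. A density record
#' row carries the raw count and area so records can be pooled exactly.
#'
#' @name density-records
NULL

density_per_0p01mm2 <- function(count, area_um2) count / (area_um2 / 1e4)

new_density_record <- function(mouse_id, section_id, region_kind, size_class,
                               tam_class, count, area_um2,
                               normalizer = NA_character_) {
  if (any(area_um2 <= 0)) stop("zero-area region in density record")
  data.frame(mouse_id = mouse_id, section_id = section_id,
             region_kind = region_kind, size_class = size_class,
             tam_class = tam_class, count = count, area_um2 = area_um2,
             density_per_0p01mm2 = density_per_0p01mm2(count, area_um2),
             normalizer = normalizer, stringsAsFactors = FALSE)
}

# cells -> containing pixel (1-based matrix indices), membership by mask
# rasterization: no sub-pixel adjudication at region borders.
cell_pixels <- function(cells, dim_mask) {
  r <- as.integer(round(cells$y_px)) + 1L
  c <- as.integer(round(cells$x_px)) + 1L
  if (any(r < 1L | r > dim_mask[1] | c < 1L | c > dim_mask[2]))
    stop("cell coordinates outside frame")
  cbind(r, c)
}

#' Cell density inside a region
#'
#' Counts classified cells by point-in-region membership and divides by the
#' region area, in cells per 0.01 mm2.
#'
#' @param cells classified cell table (needs `x_px`, `y_px`, `class`).
#' @param region_mask logical matrix, or `NULL` when `area_um2` and a
#'   precomputed `count` are supplied.
#' @param cal a [calibration()] object.
#' @param tam_class class to count.
#' @param mouse_id,section_id,region_kind,size_class record metadata.
#' @return one-row density record data.frame.
#' @export
region_density <- function(cells, region_mask, cal = calibration(),
                           tam_class = "MG", mouse_id = NA, section_id = NA,
                           region_kind = "region", size_class = NA) {
  area_px <- sum(region_mask)
  if (area_px == 0) stop("zero-area region: ", region_kind)
  sel <- cells[cells$class == tam_class, , drop = FALSE]
  n <- if (nrow(sel)) sum(region_mask[cell_pixels(sel, dim(region_mask))])
       else 0L
  new_density_record(mouse_id, section_id, region_kind, size_class,
                     tam_class, n, px_to_um2(area_px, cal))
}

#' Between-tumor (intertumoral) density
#'
#' Counts only cells inside the intertumoral mask (background at >= the
#' buffer distance from every lesion) but divides by the *tumor-free* area
#' (frame minus lesions, buffer not subtracted), exactly the published
#' normalization.
#'
#' @param cells classified cell table.
#' @param partition a [region_partition()] (buffer 4 um) or a list with
#'   `intertumoral_mask` and `tumor_free_area_um2`.
#' @param tam_class class to count (MDM for the between-tumor analysis).
#' @inheritParams region_density
#' @return one-row density record.
#' @export
between_tumor_density <- function(cells, partition, tam_class = "MDM",
                                  mouse_id = NA, section_id = NA) {
  mask <- if (!is.null(partition$intertumoral_mask)) partition$intertumoral_mask
          else stop("partition lacks intertumoral_mask")
  sel <- cells[cells$class == tam_class, , drop = FALSE]
  n <- if (nrow(sel)) sum(mask[cell_pixels(sel, dim(mask))]) else 0L
  new_density_record(mouse_id, section_id, "between", NA, tam_class, n,
                     partition$tumor_free_area_um2)
}

#' Border-compartment (leptomeninges / choroid plexus) density
#'
#' Density of reporter-positive cells in a border compartment, normalized
#' either to the tumor area or - in naive brains - to the CP area. The
#' normalizer provenance is recorded in the output.
#'
#' @param cells classified cell table.
#' @param region_mask logical matrix of the compartment (lesion or CP).
#' @param normalizer `"tumor_area"` or `"cp_area"`.
#' @param tam_class class to count (default BAM candidates).
#' @inheritParams region_density
#' @return one-row density record with a `normalizer` column.
#' @export
border_region_density <- function(cells, region_mask,
                                  normalizer = c("tumor_area", "cp_area"),
                                  cal = calibration(),
                                  tam_class = "BAM_candidate",
                                  mouse_id = NA, section_id = NA,
                                  region_kind = "cp") {
  normalizer <- match.arg(normalizer)
  if (sum(region_mask) == 0) {
    if (normalizer == "tumor_area")
      stop("tumor_area normalizer requested but no tumor region present")
    stop("zero-area region: ", region_kind)
  }
  rec <- region_density(cells, region_mask, cal, tam_class, mouse_id,
                        section_id, region_kind)
  rec$normalizer <- normalizer
  rec
}

#' Composition fractions and MG/MDM ratio
#'
#' Fractions of each class out of total Iba1+ (classified) cells, and the
#' MG/MDM count ratio, computed per mouse. A zero MDM count yields an
#' undefined (NA) ratio with a warning so it is excluded from ratio
#' statistics rather than silently infinite.
#'
#' @param counts named numeric vector of per-class counts (e.g.
#'   `c(MG = 10, MDM = 5)`).
#' @return list with `fractions` (summing to 1 over included classes, NA if
#'   all-zero) and `ratio` (MG/MDM).
#' @export
composition_and_ratio <- function(counts) {
  stopifnot(all(counts >= 0), !is.null(names(counts)))
  tot <- sum(counts)
  fractions <- if (tot == 0) {
    warning("all-zero counts: fractions undefined")
    counts * NA_real_
  } else counts / tot
  mg <- if ("MG" %in% names(counts)) counts[["MG"]] else NA_real_
  mdm <- if ("MDM" %in% names(counts)) counts[["MDM"]] else NA_real_
  ratio <- if (!is.na(mdm) && mdm == 0) {
    if (tot > 0) warning("MDM count is zero: MG/MDM ratio undefined")
    NA_real_
  } else mg / mdm
  list(fractions = fractions, ratio = ratio)
}

#' Proliferating fraction (Ki-67)
#'
#' Percentage of reporter-positive cells co-expressing Ki-67, within an
#' arbitrary scope (a region, a contact class, or a whole compartment).
#'
#' @param cells cell table with logical `tdT` and `Ki67` columns.
#' @param scope logical vector selecting the cells in scope (default all).
#' @param reporter column whose positives form the denominator (default
#'   `"tdT"`).
#' @return percentage (0-100), NA with a warning when the denominator is
#'   empty.
#' @export
proliferation_fraction <- function(cells, scope = rep(TRUE, nrow(cells)),
                                   reporter = "tdT") {
  if (!"Ki67" %in% names(cells)) stop("cell table lacks Ki67 column")
  pos <- as.logical(cells[[reporter]]) & scope
  if (!sum(pos)) {
    warning("no ", reporter, "+ cells in scope: proliferation fraction undefined")
    return(NA_real_)
  }
  100 * sum(pos & as.logical(cells$Ki67)) / sum(pos)
}

#' CD206 co-expression fractions
#'
#' The four (reporter x CD206) fractions of total Iba1+ cells:
#' tdT+/CD206+, tdT+/CD206-, tdT-/CD206+, tdT-/CD206-. They sum to 1 over
#' Iba1+ cells.
#'
#' @param cells cell table with logical `tdT`, `Iba1`, `CD206` columns.
#' @return named numeric vector of the four fractions (NA with a warning if
#'   there are no Iba1+ cells).
#' @export
cd206_coexpression <- function(cells) {
  need <- c("tdT", "Iba1", "CD206")
  miss <- setdiff(need, names(cells))
  if (length(miss)) stop("cell table lacks column(s): ",
                         paste(miss, collapse = ", "))
  iba <- as.logical(cells$Iba1)
  out <- c(tdTpos_CD206pos = NA_real_, tdTpos_CD206neg = NA_real_,
           tdTneg_CD206pos = NA_real_, tdTneg_CD206neg = NA_real_)
  if (!sum(iba)) {
    warning("no Iba1+ cells: CD206 fractions undefined")
    return(out)
  }
  tdT <- as.logical(cells$tdT)[iba]
  cd206 <- as.logical(cells$CD206)[iba]
  n <- sum(iba)
  c(tdTpos_CD206pos = sum(tdT & cd206) / n,
    tdTpos_CD206neg = sum(tdT & !cd206) / n,
    tdTneg_CD206pos = sum(!tdT & cd206) / n,
    tdTneg_CD206neg = sum(!tdT & !cd206) / n)
}

#' Aggregate section-level density records per mouse
#'
#' Per (mouse, region, size class, TAM class): pooled count over pooled
#' area (ratio of sums across that mouse's sections), which is unbiased
#' under unequal region areas; `method = "mean_of_ratios"` averages section
#' densities instead. The between-mouse SEM belongs downstream.
#'
#' @param records density-record data.frame (rbind of section records).
#' @param method `"ratio_of_sums"` (default) or `"mean_of_ratios"`.
#' @return data.frame keyed by (mouse_id, region_kind, size_class,
#'   tam_class) with pooled `count`, `area_um2`, `density_per_0p01mm2`.
#' @export
per_mouse_aggregate <- function(records,
                                method = c("ratio_of_sums",
                                           "mean_of_ratios")) {
  method <- match.arg(method)
  key_full <- do.call(paste, c(records[c("mouse_id", "section_id",
                                         "region_kind", "size_class",
                                         "tam_class")], sep = "\r"))
  if (anyDuplicated(key_full))
    stop("duplicate (mouse, section, region, class) keys in records")
  grp <- records[c("mouse_id", "region_kind", "size_class", "tam_class")]
  key <- do.call(paste, c(grp, sep = "\r"))
  first <- !duplicated(key)
  out <- grp[first, , drop = FALSE]
  out$count <- as.numeric(tapply(records$count, key, sum)[key[first]])
  out$area_um2 <- as.numeric(tapply(records$area_um2, key, sum)[key[first]])
  out$density_per_0p01mm2 <- if (method == "ratio_of_sums")
    density_per_0p01mm2(out$count, out$area_um2)
  else
    as.numeric(tapply(records$density_per_0p01mm2, key, mean)[key[first]])
  rownames(out) <- NULL
  out
}

#' Quantify one section end to end
#'
#' Computes per-lesion and section-level density records for every TAM
#' class present: interior, periphery (inner + assigned outer band),
#' whole-tumor (interior + full band, the published denominator convention)
#' per lesion with its size class, plus nontumor (intertumoral) densities
#' and the between-tumor record.
#'
#' @param mask integer matrix of lesion ids or a [label_tumors()] result.
#' @param cells classified cell table (see [classify_cells()]).
#' @param cal a [calibration()] object.
#' @param bins a [size_class_bins()] object for lesion size classes.
#' @param band_width_px,buffer_um geometry parameters.
#' @param classes TAM classes to tabulate (default MG and MDM).
#' @param mouse_id,section_id record metadata.
#' @param frame_area_um2 optional frame-area override.
#' @return list with `records` (density records, one row per lesion x
#'   region x class plus section-level rows), `partition`, `lesions`.
#' @export
quantify_section <- function(mask, cells, cal = calibration(),
                             bins = size_bins_preset(), band_width_px = 7,
                             buffer_um = 4, classes = c("MG", "MDM"),
                             mouse_id = NA, section_id = NA,
                             frame_area_um2 = NULL) {
  lt <- if (is.list(mask) && !is.null(mask$labels)) mask
        else label_tumors(mask, cal)
  labels <- lt$labels
  lesions <- lt$lesions
  part <- region_partition(labels, cal, band_width_px, buffer_um,
                           frame_area_um2)
  lesions$size_class <- assign_size_class(lesions$area_px, lesions$area_um2,
                                          bins)
  lrecs <- list()
  if (nrow(lesions)) {
    pix <- cell_pixels(cells, dim(labels))
    cls <- cells$class
    reg <- part$region[pix]
    owner <- part$lesion_of[pix]
    for (i in seq_len(nrow(lesions))) {
      id <- lesions$id[i]
      a <- part$areas[part$areas$id == id, ]
      for (cl in classes) {
        n_int <- sum(owner == id & cls == cl & reg == "interior")
        n_band <- sum(owner == id & cls == cl &
                      reg %in% c("periphery_inner", "periphery_outer"))
        r <- data.frame(
          lesion_id = id,
          region_kind = c("interior", "periphery", "whole_tumor"),
          size_class = lesions$size_class[i], tam_class = cl,
          count = c(n_int, n_band, n_int + n_band),
          area_px = c(a$interior_px, a$inner_px + a$outer_px,
                      a$interior_px + a$inner_px + a$outer_px),
          stringsAsFactors = FALSE)
        lrecs[[length(lrecs) + 1L]] <- r
      }
    }
  }
  lesion_records <- if (length(lrecs)) do.call(rbind, lrecs) else NULL
  if (!is.null(lesion_records)) {
    lesion_records$area_um2 <- px_to_um2(lesion_records$area_px, cal)
    lesion_records$density_per_0p01mm2 <- ifelse(
      lesion_records$area_um2 > 0,
      density_per_0p01mm2(lesion_records$count, lesion_records$area_um2),
      NA_real_)
    lesion_records$mouse_id <- mouse_id
    lesion_records$section_id <- section_id
  }
  # section-level records: lesion counts/areas pooled per size class
  recs <- list()
  if (!is.null(lesion_records)) {
    keep <- lesion_records$area_px > 0
    lr <- lesion_records[keep, , drop = FALSE]
    key <- paste(lr$region_kind, lr$size_class, lr$tam_class, sep = "\r")
    first <- !duplicated(key)
    recs[[1L]] <- new_density_record(
      mouse_id, section_id, lr$region_kind[first], lr$size_class[first],
      lr$tam_class[first],
      as.numeric(tapply(lr$count, key, sum)[key[first]]),
      px_to_um2(as.numeric(tapply(lr$area_px, key, sum)[key[first]]), cal))
  }
  for (cl in classes) {
    recs[[length(recs) + 1L]] <- region_density(
      cells, part$intertumoral_mask, cal, cl, mouse_id, section_id,
      region_kind = "nontumor")
    recs[[length(recs) + 1L]] <- between_tumor_density(
      cells, part, cl, mouse_id, section_id)
  }
  records <- do.call(rbind, recs)
  rownames(records) <- NULL
  list(records = records, lesion_records = lesion_records,
       partition = part, lesions = lesions)
}
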