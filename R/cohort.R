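#' Synthetic imaging cohort
#'
#' Builds the study-condition cohort: `n_mice` mice with
#' `sections_per_mouse` sections each - by default two microtumor sections
#' (three small, two medium, two large lesions under the MG-dominant
#' intensity set) and one major-tumor section (a near-frame-filling blob
#' under the MDM-dominant set). Every section gets its own derived seed, so
#' the cohort is reproducible from the master seed.
#'
#' @param n_mice number of mice (default 8).
#' @param sections_per_mouse sections per mouse (default 3; the last one is
#'   the major-tumor section when >= 2).
#' @param seed master seed (small integer).
#' @param mouse_model,compartment classification context.
#' @param intensity_micro,intensity_major programmed intensity matrices.
#' @return list of section entries: each with `mouse_id`, `section_id`,
#'   `scenario` (`"micro"`/`"major"`) and the [make_section()] output.
#' @export
make_cohort <- function(n_mice = 8, sections_per_mouse = 3, seed = 1,
                        mouse_model = "cx3cr1creer",
                        compartment = "parenchyma",
                        intensity_micro = default_intensity_microtumor(),
                        intensity_major = default_intensity_major()) {
  stopifnot(n_mice >= 1, sections_per_mouse >= 1)
  micro_tumors <- list(
    tumor_spec("disc", c(150, 150), 16, "small"),
    tumor_spec("disc", c(150, 500), 16, "small"),
    tumor_spec("disc", c(150, 850), 16, "small"),
    tumor_spec("disc", c(512, 200), 31, "medium"),
    tumor_spec("disc", c(512, 824), 31, "medium"),
    tumor_spec("disc", c(860, 300), 50, "large"),
    tumor_spec("disc", c(860, 724), 50, "large"))
  major_tumors <- list(
    tumor_spec("blob", c(511.5, 511.5), 430, "major", blob_amp = 0.1,
               blob_k = 7))
  out <- list()
  for (m in seq_len(n_mice)) {
    for (s in seq_len(sections_per_mouse)) {
      major <- sections_per_mouse >= 2 && s == sections_per_mouse
      spec <- section_spec(
        tumors = if (major) major_tumors else micro_tumors,
        intensity = if (major) intensity_major else intensity_micro,
        mouse_model = mouse_model, compartment = compartment,
        seed = seed * 10000L + m * 100L + s)
      out[[length(out) + 1L]] <- list(
        mouse_id = sprintf("m%02d", m), section_id = sprintf("s%d", s),
        scenario = if (major) "major" else "micro",
        section = make_section(spec))
    }
  }
  out
}

#' Quantify a synthetic cohort end to end
#'
#' Classifies each section's cells from their marker columns (the
#' ground-truth columns are never read), quantifies every section, and
#' aggregates per mouse (ratio of sums). Microtumor-section lesion records
#' are additionally pooled across size classes per (region, class), since
#' the programmed intensities are keyed by region and class only.
#'
#' @param cohort a [make_cohort()] result.
#' @param bins size bins (default: the synthetic study's Methods pixel bins
#'   with the scaled-down major threshold).
#' @return list: `records` (all section-level records), `per_mouse`
#'   (aggregates), `recovery` (per scenario x region x class: mean density
#'   across mice, pooled count/area, programmed value), `ratios` (per-mouse
#'   MG/MDM ratios by scenario).
#' @export
quantify_cohort <- function(cohort, bins = NULL) {
  first <- cohort[[1]]$section
  if (is.null(bins)) bins <- first$spec$bins
  cal <- first$cal
  recs <- list()
  for (entry in cohort) {
    sec <- entry$section
    cells <- classify_cells(sec$cells, sec$spec$mouse_model,
                            sec$spec$compartment)
    q <- quantify_section(
      list(labels = sec$mask,
           lesions = label_tumors(sec$mask, cal, 0, relabel = FALSE)$lesions),
      cells, cal, bins, sec$spec$band_width_px, sec$spec$buffer_um,
      classes = intersect(rownames(sec$spec$intensity), tam_classes),
      mouse_id = entry$mouse_id, section_id = entry$section_id,
      frame_area_um2 = sec$spec$frame_area_um2)
    r <- q$records
    r$scenario <- entry$scenario
    recs[[length(recs) + 1L]] <- r
  }
  records <- do.call(rbind, recs)
  per_mouse <- per_mouse_aggregate(
    records[records$region_kind != "between", ])
  # recovery per scenario x region x class, pooled over size classes
  rec_rows <- list()
  for (scen in unique(records$scenario)) {
    rs <- records[records$scenario == scen, ]
    spec_int <- cohort[[which(vapply(cohort, `[[`, "", "scenario") ==
                                scen)[1]]]$section$spec$intensity
    for (cl in unique(rs$tam_class)) {
      for (rk in c("nontumor", "periphery", "interior")) {
        sub <- rs[rs$tam_class == cl & rs$region_kind == rk, ]
        if (!nrow(sub)) next
        # per-mouse pooled densities, then mean across mice
        pm <- per_mouse_density(sub)
        tot_count <- sum(sub$count); tot_area <- sum(sub$area_um2)
        rec_rows[[length(rec_rows) + 1L]] <- data.frame(
          scenario = scen, region_kind = rk, tam_class = cl,
          mean_density = mean(pm), sem_density = stats::sd(pm) / sqrt(length(pm)),
          pooled_count = tot_count, pooled_area_um2 = tot_area,
          pooled_density = density_per_0p01mm2(tot_count, tot_area),
          programmed = spec_int[cl, rk],
          stringsAsFactors = FALSE)
      }
    }
  }
  recovery <- do.call(rbind, rec_rows)
  # per-mouse MG/MDM ratio over whole-tumor counts, by scenario
  ratios <- list()
  wt <- records[records$region_kind == "whole_tumor", ]
  for (scen in unique(wt$scenario)) {
    for (m in unique(wt$mouse_id)) {
      sub <- wt[wt$scenario == scen & wt$mouse_id == m, ]
      if (!nrow(sub)) next
      counts <- tapply(sub$count, sub$tam_class, sum)
      cr <- suppressWarnings(composition_and_ratio(
        stats::setNames(as.numeric(counts), names(counts))))
      ratios[[length(ratios) + 1L]] <- data.frame(
        scenario = scen, mouse_id = m, ratio = cr$ratio,
        stringsAsFactors = FALSE)
    }
  }
  list(records = records, per_mouse = per_mouse, recovery = recovery,
       ratios = do.call(rbind, ratios))
}

# pooled density per mouse from a record subset
per_mouse_density <- function(records) {
  key <- records$mouse_id
  cnt <- tapply(records$count, key, sum)
  ar <- tapply(records$area_um2, key, sum)
  density_per_0p01mm2(as.numeric(cnt), as.numeric(ar))
}
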