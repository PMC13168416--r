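#' Run configuration
#'
#' A nested key/value (YAML) configuration drives the workflow runners.
#' Unknown keys are rejected; the fully resolved configuration and its
#' hash are embedded in every output for provenance.
#'
#' @param path YAML file path, or `NULL` for defaults.
#' @param overrides named list merged over the file values (nested lists
#'   merge by key).
#' @return a `tam_run_config` list.
#' @export
run_config <- function(path = NULL, overrides = list()) {
  defaults <- list(
    calibration = list(pixel_size_um = 0.5681818,
                       area_mode = "linear_squared"),
    size_bins = list(preset = "methods_px", major_threshold_um2 = 1e5),
    geometry = list(band_width_px = 7, buffer_um = 4, min_area_um2 = 130),
    model = list(mouse_model = "cx3cr1creer", compartment = "parenchyma"),
    cohort = list(n_mice = 8, sections_per_mouse = 3),
    flow = list(n_events = 50000),
    stats = list(transform = "cbrt", fdr_q = 0.05),
    seed = 1L,
    out_dir = "results")
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  merge_cfg <- function(base, new, where = "") {
    unknown <- setdiff(names(new), names(base))
    if (length(unknown))
      stop("unknown config key(s)", if (nzchar(where)) paste0(" in ", where),
           ": ", paste(unknown, collapse = ", "))
    for (k in names(new)) {
      base[[k]] <- if (is.list(base[[k]]) && is.list(new[[k]]))
        merge_cfg(base[[k]], new[[k]], k)
      else new[[k]]
    }
    base
  }
  cfg <- merge_cfg(defaults, user)
  cfg <- merge_cfg(cfg, overrides)
  structure(cfg, class = "tam_run_config")
}

#' Configuration hash
#'
#' MD5 of the canonical (deparsed) configuration; embedded in every
#' artifact so outputs can be traced to the exact parameters that made
#' them. The output directory is excluded: it does not affect the data,
#' so identical parameters + seed hash identically wherever they run.
#'
#' @param config a [run_config()].
#' @return hex string.
#' @export
config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(cfg), f)
  unname(tools::md5sum(f))
}

#' Write a provenance-stamped CSV
#'
#' Comma-separated, UTF-8, mandatory header, "." decimal; a leading
#' comment line carries the config hash. Density columns are written at
#' full precision with a display-rounded companion column.
#'
#' @param df data.frame.
#' @param path output path.
#' @param hash config hash string.
#' @export
write_csv_prov <- function(df, path, hash = "unhashed") {
  num <- names(df)[startsWith(names(df), "density")]
  for (nm in num) df[[paste0(nm, "_display")]] <- round(df[[nm]], 2)
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# config_hash: ", hash), con)
  utils::write.table(df, con, sep = ",", dec = ".", row.names = FALSE,
                     qmethod = "double")
  invisible(path)
}

#' @rdname write_csv_prov
#' @export
read_csv_prov <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Workflow runners
#'
#' Thin, deterministic drivers tying the stages together:
#' `run_simulate()` generates the imaging cohort and flow-event tables and
#' writes masks (16-bit TIFF), cell tables and event tables;
#' `run_quantify()` classifies and quantifies the cohort and writes tidy
#' density records plus a JSON summary keyed by figure-panel analogue;
#' `run_gate()` gates the flow sample and writes fraction/FMI tables;
#' `run_stats()` runs the transform + ANOVA + two-stage FDR layer over the
#' per-mouse densities. `run_all()` chains the four. All outputs embed the
#' config hash; identical config + seed reproduce identical artifacts.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return each runner returns its in-memory results invisibly-ish (a
#'   list), after writing artifacts.
#' @export
run_simulate <- function(config = run_config(), out_dir = config$out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  h <- config_hash(config)
  cohort <- make_cohort(config$cohort$n_mice,
                        config$cohort$sections_per_mouse,
                        seed = config$seed,
                        mouse_model = config$model$mouse_model,
                        compartment = config$model$compartment)
  cells <- list()
  for (entry in cohort) {
    base <- paste0(entry$mouse_id, "_", entry$section_id)
    write_mask(entry$section$mask, file.path(out_dir, paste0("mask_", base,
                                                             ".tiff")))
    cc <- entry$section$cells
    cc$mouse_id <- entry$mouse_id
    cc$section_id <- entry$section_id
    cells[[length(cells) + 1L]] <- cc
  }
  write_csv_prov(do.call(rbind, cells), file.path(out_dir, "cells.csv"), h)
  fspec <- flow_spec(n_events = config$flow$n_events,
                     seed = config$seed)
  events <- make_flow_events(fspec)
  write_csv_prov(events, file.path(out_dir, "flow_events.csv"), h)
  fmo <- list()
  for (ch in c("CD11b", "CD45", "GFP", "F4_80", "CD38")) {
    fmo[[ch]] <- make_flow_events(fspec, fmo_channel = ch)
    write_csv_prov(fmo[[ch]],
                   file.path(out_dir, paste0("flow_fmo_", ch, ".csv")), h)
  }
  list(cohort = cohort, flow = list(spec = fspec, events = events,
                                    fmo = fmo), hash = h)
}

#' @rdname run_simulate
#' @param sim a [run_simulate()] result (regenerated if NULL).
#' @export
run_quantify <- function(config = run_config(), sim = NULL,
                         out_dir = config$out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  h <- config_hash(config)
  if (is.null(sim)) sim <- run_simulate(config, out_dir)
  qc <- quantify_cohort(sim$cohort)
  write_csv_prov(qc$records, file.path(out_dir, "density_records.csv"), h)
  write_csv_prov(qc$per_mouse, file.path(out_dir, "per_mouse.csv"), h)
  summary <- list(
    config_hash = h,
    fig2B_like = qc$recovery,
    fig2C_like = qc$ratios,
    n_mice = config$cohort$n_mice)
  jsonlite::write_json(summary, file.path(out_dir, "quantify_summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  qc
}

#' @rdname run_simulate
#' @export
run_gate <- function(config = run_config(), sim = NULL,
                     out_dir = config$out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  h <- config_hash(config)
  if (is.null(sim)) sim <- run_simulate(config, out_dir)
  g <- gate_sample(sim$flow$events, gate_config(), fmo = sim$flow$fmo)
  write_csv_prov(g$fractions, file.path(out_dir, "gate_fractions.csv"), h)
  write_csv_prov(g$subpop_fractions,
                 file.path(out_dir, "gate_subpop_fractions.csv"), h)
  if (!is.null(g$fmi))
    write_csv_prov(g$fmi, file.path(out_dir, "gate_fmi.csv"), h)
  g
}

#' @rdname run_simulate
#' @param quantified a [run_quantify()] result (regenerated if NULL).
#' @export
run_stats <- function(config = run_config(), quantified = NULL,
                      out_dir = config$out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  h <- config_hash(config)
  if (is.null(quantified)) quantified <- run_quantify(config, NULL, out_dir)
  pm <- quantified$per_mouse
  pm <- pm[pm$region_kind %in% c("nontumor", "periphery", "interior") &
             pm$tam_class %in% c("MG", "MDM"), ]
  res <- anova_contrasts(pm, "density_per_0p01mm2",
                         c("region_kind", "tam_class"),
                         transform = config$stats$transform)
  fdr <- bky_fdr(res$contrasts$p, config$stats$fdr_q)
  out <- res$contrasts
  out$q_adjusted <- fdr$adjusted
  out$significant <- fdr$reject
  write_csv_prov(out, file.path(out_dir, "stats_contrasts.csv"), h)
  list(contrasts = out, anova = res$anova, fdr = fdr)
}

#' @rdname run_simulate
#' @export
run_all <- function(config = run_config(), out_dir = config$out_dir) {
  sim <- run_simulate(config, out_dir)
  qc <- run_quantify(config, sim, out_dir)
  g <- run_gate(config, sim, out_dir)
  st <- run_stats(config, qc, out_dir)
  list(sim = sim, quantify = qc, gate = g, stats = st)
}
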