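#' Gate configuration
#'
#' All gates are rectangular on raw intensities (no compensation, no
#' biexponential transform): positivity thresholds per channel plus tiered
#' CD45 and CD11b cuts for the subpopulation gates. Numeric cuts are not
#' part of the published scheme and live entirely in configuration; the
#' defaults are the valley midpoints (geometric means between adjacent
#' population medians) of the synthetic generator's default mixture.
#'
#' The lower CD11b tier of the MG (Q3) subgate is annotated "low" in the
#' published median table but "int" in the gating figure; both labelings
#' are accepted via `q3_cd11b_tier`:
#' `"low"` (default) places Q3 i/ii below the low/int cut, `"int"` places
#' them in the same int band as Q2.
#'
#' @param cd11b_pos,cd45_pos,tdt_pos,gfp_pos,ly6c_pos,ly6g_pos positivity
#'   thresholds.
#' @param cd45_low_int,cd45_int_hi CD45 tier cuts (low < int < hi).
#' @param cd11b_low_int,cd11b_int_hi CD11b tier cuts.
#' @param q3_cd11b_tier `"low"` or `"int"`.
#' @param q3_cd45_floor if `TRUE`, subpopulation i of Q3 also requires CD45
#'   above the low/int cut (the "int" reading); default `FALSE` (the "low"
#'   reading: any CD45 below the int/hi cut).
#' @return a `tam_gate_config`.
#' @export
gate_config <- function(cd11b_pos = 1000, cd45_pos = 1000,
                        tdt_pos = 3873, gfp_pos = 5648,
                        ly6c_pos = 1732, ly6g_pos = 1549,
                        cd45_low_int = 42500, cd45_int_hi = 101193,
                        cd11b_low_int = 134975, cd11b_int_hi = 374874,
                        q3_cd11b_tier = c("low", "int"),
                        q3_cd45_floor = FALSE) {
  q3_cd11b_tier <- match.arg(q3_cd11b_tier)
  if (!(cd45_low_int < cd45_int_hi))
    stop("CD45 cuts must be ordered low < int < hi")
  if (!(cd11b_low_int < cd11b_int_hi))
    stop("CD11b cuts must be ordered low < int < hi")
  structure(list(cd11b_pos = cd11b_pos, cd45_pos = cd45_pos,
                 tdt_pos = tdt_pos, gfp_pos = gfp_pos,
                 ly6c_pos = ly6c_pos, ly6g_pos = ly6g_pos,
                 cd45_low_int = cd45_low_int, cd45_int_hi = cd45_int_hi,
                 cd11b_low_int = cd11b_low_int,
                 cd11b_int_hi = cd11b_int_hi,
                 q3_cd11b_tier = q3_cd11b_tier,
                 q3_cd45_floor = q3_cd45_floor),
            class = "tam_gate_config")
}

check_channels <- function(events, need) {
  miss <- setdiff(need, names(events))
  if (length(miss)) stop("event table lacks channel(s): ",
                         paste(miss, collapse = ", "))
  invisible(TRUE)
}

#' Quadrant gate on tdT x GFP within CD11b+
#'
#' Within CD11b+ events: Q1 = tdT+/GFP-, Q2 = tdT+/GFP+ (MDM),
#' Q3 = tdT-/GFP+ (MG), Q4 = tdT-/GFP-. CD11b- events get NA. The four
#' quadrants partition CD11b+ events exactly.
#'
#' @param events flow-event data.frame (needs `CD11b`, `tdT`, `GFP`).
#' @param config a [gate_config()].
#' @return character vector of quadrant labels (NA outside CD11b+).
#' @export
gate_quadrants <- function(events, config = gate_config()) {
  check_channels(events, c("CD11b", "tdT", "GFP"))
  myeloid <- events$CD11b >= config$cd11b_pos
  tdt <- events$tdT >= config$tdt_pos
  gfp <- events$GFP >= config$gfp_pos
  q <- ifelse(tdt & !gfp, "Q1",
       ifelse(tdt & gfp, "Q2",
       ifelse(!tdt & gfp, "Q3", "Q4")))
  q[!myeloid] <- NA_character_
  q
}

#' CD45 x CD11b subpopulation gate within a quadrant population
#'
#' Subpopulations: i = CD45 int / CD11b lower tier, ii = CD45 hi / CD11b
#' lower tier, iii = CD45 hi / CD11b hi. The lower CD11b tier is the int
#' band for the MDM quadrant (Q2) and - by default - the low band for the
#' MG quadrant (Q3). Events matching no tier combination are `"none"`.
#'
#' @param events flow-event data.frame (needs `CD45`, `CD11b`).
#' @param population `"Q2"` or `"Q3"`: selects the lower-tier convention.
#' @param config a [gate_config()].
#' @return character vector in `c("i","ii","iii","none")`.
#' @export
subgate_cd45_cd11b <- function(events, population = c("Q2", "Q3"),
                               config = gate_config()) {
  population <- match.arg(population)
  check_channels(events, c("CD45", "CD11b"))
  cd45 <- events$CD45; cd11b <- events$CD11b
  cd45_hi <- cd45 >= config$cd45_int_hi
  lower_tier <- if (population == "Q2" || config$q3_cd11b_tier == "int")
    cd11b >= config$cd11b_low_int & cd11b < config$cd11b_int_hi
  else
    cd11b < config$cd11b_low_int
  cd11b_hi <- cd11b >= config$cd11b_int_hi
  cd45_i_floor <- if (population == "Q2" || config$q3_cd45_floor)
    cd45 >= config$cd45_low_int else TRUE
  out <- rep("none", nrow(events))
  out[!cd45_hi & cd45_i_floor & lower_tier] <- "i"
  out[cd45_hi & lower_tier] <- "ii"
  out[cd45_hi & cd11b_hi] <- "iii"
  out
}

#' Neutrophil gate
#'
#' Fraction of CD11b+ events that are CD11b+ CD45+ tdT+ GFP- Ly6C+ Ly6G+.
#'
#' @param events flow-event data.frame.
#' @param config a [gate_config()].
#' @return list with `fraction` (of CD11b+ events) and `n`.
#' @export
neutrophil_gate <- function(events, config = gate_config()) {
  check_channels(events, c("CD11b", "CD45", "tdT", "GFP", "Ly6C", "Ly6G"))
  myeloid <- events$CD11b >= config$cd11b_pos
  neut <- myeloid & events$CD45 >= config$cd45_pos &
    events$tdT >= config$tdt_pos & events$GFP < config$gfp_pos &
    events$Ly6C >= config$ly6c_pos & events$Ly6G >= config$ly6g_pos
  list(fraction = sum(neut) / sum(myeloid), n = sum(neut))
}

#' FMO-subtracted fluorescence median intensity (FMI)
#'
#' `median(signal channel) - median(FMO channel)`. Negative values are
#' reported as-is with a warning.
#'
#' @param signal_events,fmo_events event data.frames.
#' @param channel channel name.
#' @return numeric FMI.
#' @export
fmi <- function(signal_events, fmo_events, channel) {
  check_channels(signal_events, channel)
  if (is.null(fmo_events) || nrow(fmo_events) == 0)
    stop("empty FMO event set for channel ", channel)
  check_channels(fmo_events, channel)
  if (nrow(signal_events) == 0) stop("empty signal event set")
  out <- stats::median(signal_events[[channel]]) -
    stats::median(fmo_events[[channel]])
  if (out < 0) warning("negative FMI for ", channel)
  out
}

#' Gate one sample end to end
#'
#' Applies the quadrant gate, the CD45 x CD11b subgates within Q2 and Q3,
#' and the neutrophil gate; computes the population fraction table (Q2 and
#' Q3 as fractions of CD11b+/GFP+ events, the published denominator) and,
#' when FMO tables are supplied, per-(population, channel) FMI values.
#'
#' @param events flow-event data.frame.
#' @param config a [gate_config()].
#' @param fmo named list of FMO event tables, one per channel.
#' @param fmi_channels channels for the FMI table.
#' @return list with `quadrant`, `subpop` (per-event labels), `fractions`
#'   (data.frame), `neutrophil`, and `fmi` (data.frame or NULL).
#' @export
gate_sample <- function(events, config = gate_config(), fmo = list(),
                        fmi_channels = c("CD11b", "CD45", "GFP", "F4_80",
                                         "CD38")) {
  quad <- gate_quadrants(events, config)
  sub <- rep(NA_character_, nrow(events))
  for (p in c("Q2", "Q3")) {
    in_p <- !is.na(quad) & quad == p
    if (any(in_p))
      sub[in_p] <- subgate_cd45_cd11b(events[in_p, , drop = FALSE], p, config)
  }
  gfp_pos <- events$GFP >= config$gfp_pos
  denom <- sum(events$CD11b >= config$cd11b_pos & gfp_pos)
  frac <- data.frame(
    population = c("Q2", "Q3"),
    fraction_of_cd11b_gfp = c(sum(quad == "Q2", na.rm = TRUE),
                              sum(quad == "Q3", na.rm = TRUE)) / denom)
  subfrac <- do.call(rbind, lapply(c("Q2", "Q3"), function(p) {
    in_p <- !is.na(quad) & quad == p
    n <- sum(in_p)
    data.frame(population = p, subpop = c("i", "ii", "iii"),
               fraction_of_population = if (n == 0) rep(NA_real_, 3) else
                 c(sum(sub[in_p] == "i"), sum(sub[in_p] == "ii"),
                   sum(sub[in_p] == "iii")) / n)
  }))
  fmi_tab <- NULL
  if (length(fmo)) {
    rows <- list()
    for (p in c("Q2", "Q3")) for (s in c("i", "ii", "iii")) {
      in_ps <- !is.na(quad) & quad == p & sub == s
      if (!any(in_ps)) next
      for (ch in intersect(fmi_channels, names(fmo))) {
        rows[[length(rows) + 1L]] <- data.frame(
          population = p, subpop = s, channel = ch,
          fmi = fmi(events[in_ps, , drop = FALSE], fmo[[ch]], ch))
      }
    }
    fmi_tab <- if (length(rows)) do.call(rbind, rows) else NULL
  }
  list(quadrant = quad, subpop = sub, fractions = frac,
       subpop_fractions = subfrac,
       neutrophil = neutrophil_gate(events, config), fmi = fmi_tab)
}
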