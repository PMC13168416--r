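#' Default flow-event mixture: populations, weights, channel medians
#'
#' The synthetic flow model draws each event from the lognormal cluster of
#' its population. Default channel medians are patterned on the published
#' per-subpopulation median intensities of the lung-carcinoma condition
#' (CD11b / CD45 / Cx3cr1-GFP / F4/80 / CD38), completed with invented but
#' internally consistent tdT, Ly6C and Ly6G levels: tdT-positive
#' populations (MDM subsets and neutrophils) at 5e4 vs. 300 background,
#' neutrophils (Q1) Ly6C/Ly6G-high. Default weights put 40% of CD11b+
#' events in the MDM quadrant (Q2) and 55% in the MG quadrant (Q3), with
#' the published within-quadrant subpopulation splits, plus 3% neutrophils
#' (Q1) and 2% double-negatives (Q4).
#'
#' @return `default_flow_medians()`: population x channel matrix;
#'   `default_flow_weights()`: named vector summing to 1;
#'   `default_fmo_background()`: named background medians per channel.
#' @export
default_flow_medians <- function() {
  ch <- c("CD11b", "CD45", "GFP", "tdT", "Ly6C", "Ly6G", "F4_80", "CD38")
  m <- rbind(
    Q1    = c(200000, 150000,    200, 50000, 20000, 30000,  800,  500),
    Q2i   = c(274836,  84354, 241178, 50000,   150,    80, 1829, 1006),
    Q2ii  = c(184832, 170208, 159418, 50000,   150,    80, 1960, 2514),
    Q2iii = c(819400, 225284, 986876, 50000,   150,    80, 6192, 3526),
    Q3i   = c( 98554,  21413, 833200,   300,   150,    80,  689,  337),
    Q3ii  = c( 87032, 121399, 220206,   300,   150,    80,  984, 1714),
    Q3iii = c(511333, 141892, 1042506,  300,   150,    80, 3361, 2265),
    Q4    = c(150000,  50000,    200,   300,   150,    80,  500,  300))
  colnames(m) <- ch
  m
}

#' @rdname default_flow_medians
#' @export
default_flow_weights <- function() {
  w <- c(Q1 = 0.03,
         Q2i = 0.40 * 0.6786, Q2ii = 0.40 * 0.0139, Q2iii = 0.40 * 0.3106,
         Q3i = 0.55 * 0.6530, Q3ii = 0.55 * 0.1671, Q3iii = 0.55 * 0.1776,
         Q4 = 0.02)
  w / sum(w)
}

#' @rdname default_flow_medians
#' @export
default_fmo_background <- function() {
  c(CD11b = 500, CD45 = 300, GFP = 200, tdT = 300, Ly6C = 150, Ly6G = 80,
    F4_80 = 120, CD38 = 100)
}

#' Flow-event generator specification
#'
#' @param n_events number of events (> 0).
#' @param weights named population fractions (>= 0, sum 1).
#' @param channel_medians population x channel median matrix (> 0).
#' @param dispersion lognormal sd on the log scale: scalar or named per
#'   channel. The default 0.035 keeps every population >= 5 log-sd from the
#'   default gate cuts (idealized, well-separated clusters; realism is out
#'   of scope).
#' @param fmo_background named per-channel background medians used for FMO
#'   draws.
#' @param seed integer RNG seed.
#' @return a `tam_flow_spec`.
#' @export
flow_spec <- function(n_events = 50000,
                      weights = default_flow_weights(),
                      channel_medians = default_flow_medians(),
                      dispersion = 0.035,
                      fmo_background = default_fmo_background(),
                      seed = 1L) {
  if (n_events <= 0) stop("n_events must be positive")
  stopifnot(all(weights >= 0), abs(sum(weights) - 1) < 1e-8,
            all(channel_medians > 0),
            all(rownames(channel_medians) %in% names(weights) |
                names(weights) %in% rownames(channel_medians)))
  stopifnot(all(names(weights) %in% rownames(channel_medians)))
  structure(list(n_events = as.integer(n_events), weights = weights,
                 channel_medians = channel_medians,
                 dispersion = dispersion, fmo_background = fmo_background,
                 seed = as.integer(seed)),
            class = "tam_flow_spec")
}

draw_lognormal <- function(median, sdlog, n) {
  if (sdlog == 0) rep(median, n) else median * exp(stats::rnorm(n, 0, sdlog))
}

#' Generate synthetic flow-cytometry events
#'
#' Each event's population is sampled from the mixture weights; channel
#' intensities are lognormal around the population's medians (so the
#' population median of each channel equals the programmed value). The true
#' population label is retained in `true_pop`. With `fmo_channel` set, the
#' named channel is replaced by a background draw, producing a paired FMO
#' control table.
#'
#' @param spec a [flow_spec()].
#' @param fmo_channel optional channel name for an FMO table.
#' @return data.frame of per-event channel intensities plus `true_pop` and
#'   `fmo_channel` (NA for signal tables).
#' @export
make_flow_events <- function(spec, fmo_channel = NULL) {
  stopifnot(inherits(spec, "tam_flow_spec"))
  set.seed(spec$seed + if (is.null(fmo_channel)) 0L
           else match(fmo_channel, colnames(spec$channel_medians)))
  n <- spec$n_events
  pops <- names(spec$weights)
  lab <- sample(pops, n, replace = TRUE, prob = spec$weights)
  chans <- colnames(spec$channel_medians)
  disp <- if (length(spec$dispersion) == 1L)
    stats::setNames(rep(spec$dispersion, length(chans)), chans)
  else spec$dispersion[chans]
  out <- data.frame(row.names = seq_len(n))
  for (ch in chans) {
    med <- spec$channel_medians[lab, ch]
    v <- if (disp[[ch]] == 0) med else med * exp(stats::rnorm(n, 0, disp[[ch]]))
    out[[ch]] <- v
  }
  if (!is.null(fmo_channel)) {
    if (!fmo_channel %in% chans) stop("unknown channel: ", fmo_channel)
    out[[fmo_channel]] <- draw_lognormal(
      spec$fmo_background[[fmo_channel]],
      disp[[fmo_channel]], n)
  }
  out$true_pop <- lab
  out$fmo_channel <- if (is.null(fmo_channel)) NA_character_ else fmo_channel
  out
}
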