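#' Variance-stabilizing transforms
#'
#' Element-wise `sqrt`, signed cube root (defined for negatives), `log`, or
#' identity. `log` of non-positive values errors unless a positive
#' `offset` is supplied (then `log(x + offset)`).
#'
#' @param x numeric vector.
#' @param kind `"none"`, `"sqrt"`, `"cbrt"` or `"log"`.
#' @param offset additive offset for the log transform (default 0: error
#'   on non-positive values).
#' @return transformed numeric vector.
#' @export
apply_transform <- function(x, kind = c("none", "sqrt", "cbrt", "log"),
                            offset = 0) {
  kind <- match.arg(kind)
  switch(kind,
    none = x,
    sqrt = {
      if (any(x < 0, na.rm = TRUE)) stop("sqrt transform of negative values")
      sqrt(x)
    },
    cbrt = sign(x) * abs(x)^(1 / 3),
    log = {
      if (any(x + offset <= 0, na.rm = TRUE))
        stop("log transform of non-positive values; supply a positive offset")
      log(x + offset)
    })
}

#' Factorial ANOVA with post-hoc linear contrasts
#'
#' Least-squares fit of the full factorial model (all interactions by
#' default) on the transformed response; each contrast of cell means is
#' tested against the pooled residual variance (two-sided t), or with a
#' Welch/Satterthwaite variance when `welch = TRUE`.
#'
#' @param data data.frame holding response and factors.
#' @param response name of the response column.
#' @param factors character vector of 1-3 factor column names.
#' @param transform passed to [apply_transform()].
#' @param contrasts named list of contrast weight vectors over the design
#'   cells (each summing to 0), or `"pairwise"` (default) for all pairwise
#'   cell-mean differences. Cells are labeled by the `:`-joined factor
#'   levels, in the order of `sort(unique(...))`; weights may also be
#'   supplied as named vectors over cell labels.
#' @param interactions include interaction terms (default `TRUE`).
#' @param welch use per-cell variances (Welch) instead of pooled MSE.
#' @param offset log-transform offset.
#' @return list of class `tam_anova`: `contrasts` data.frame (estimate,
#'   se, t, df, p per contrast), `anova` table of the fitted model, `fit`,
#'   `cells` (cell means/sizes).
#' @export
anova_contrasts <- function(data, response, factors,
                            transform = "none", contrasts = "pairwise",
                            interactions = TRUE, welch = FALSE,
                            offset = 0) {
  stopifnot(length(factors) >= 1L, length(factors) <= 3L,
            response %in% names(data), all(factors %in% names(data)))
  y <- apply_transform(data[[response]], transform, offset)
  fl <- lapply(data[factors], function(f) factor(f))
  cell <- factor(do.call(paste, c(fl, sep = ":")))
  ok <- stats::complete.cases(y, cell)
  y <- y[ok]; cell <- droplevels(cell[ok])
  fl <- lapply(fl, function(f) droplevels(f[ok]))
  levs <- levels(cell)
  if (length(levs) < 2L) stop("need >= 2 design cells")
  n_i <- as.vector(table(cell))
  if (max(n_i) < 2L) stop("need >= 2 observations in some cell")
  # check for aliased (empty) cells of the full factorial
  full <- do.call(expand.grid, lapply(fl, levels))
  full_lab <- do.call(paste, c(full, sep = ":"))
  missing_cells <- setdiff(full_lab, levs)
  if (length(missing_cells))
    stop("singular design; empty cell(s): ",
         paste(missing_cells, collapse = ", "))
  df_fit <- data.frame(y = y, fl)
  form <- stats::as.formula(paste(
    "y ~", paste(factors, collapse = if (interactions) " * " else " + ")))
  names(df_fit) <- c("y", factors)
  fit <- stats::lm(form, data = df_fit)
  mse <- sum(stats::residuals(fit)^2) / fit$df.residual
  means <- tapply(y, cell, mean)
  vars <- tapply(y, cell, stats::var)
  if (identical(contrasts, "pairwise")) {
    cmb <- utils::combn(length(levs), 2)
    contrasts <- lapply(seq_len(ncol(cmb)), function(j) {
      w <- numeric(length(levs))
      w[cmb[1, j]] <- 1; w[cmb[2, j]] <- -1
      w
    })
    names(contrasts) <- apply(cmb, 2, function(ij)
      paste(levs[ij[1]], "-", levs[ij[2]]))
  }
  rows <- lapply(names(contrasts), function(nm) {
    w <- contrasts[[nm]]
    if (!is.null(names(w))) {
      full_w <- numeric(length(levs))
      if (!all(names(w) %in% levs))
        stop("contrast '", nm, "' names unknown cells")
      full_w[match(names(w), levs)] <- w
      w <- full_w
    }
    if (length(w) != length(levs))
      stop("contrast '", nm, "' has wrong length")
    if (abs(sum(w)) > 1e-8) stop("contrast '", nm, "' does not sum to zero")
    est <- sum(w * means)
    if (welch) {
      se2_terms <- w^2 * vars / n_i
      se <- sqrt(sum(se2_terms))
      df <- sum(se2_terms)^2 / sum(se2_terms^2 / (n_i - 1))
    } else {
      se <- sqrt(mse * sum(w^2 / n_i))
      df <- fit$df.residual
    }
    tval <- est / se
    data.frame(contrast = nm, estimate = est, se = se, t = tval, df = df,
               p = 2 * stats::pt(-abs(tval), df),
               stringsAsFactors = FALSE)
  })
  structure(list(contrasts = do.call(rbind, rows),
                 anova = stats::anova(fit), fit = fit,
                 cells = data.frame(cell = levs, n = n_i,
                                    mean = as.numeric(means),
                                    var = as.numeric(vars))),
            class = "tam_anova")
}

# one Benjamini-Hochberg pass at level `level`: number of rejections and
# the rejection indicator
bh_reject <- function(p, level) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= (seq_len(m) / m) * level)
  r <- if (length(k)) max(k) else 0L
  rej <- logical(m)
  if (r > 0) rej[o[seq_len(r)]] <- TRUE
  list(r = r, reject = rej)
}

#' Two-stage Benjamini-Krieger-Yekutieli FDR
#'
#' Stage 1: BH at `q' = q/(1+q)` estimates the number of true nulls
#' `m - r1`. If no hypotheses are rejected, stop (reject none); if all
#' are, reject all. Otherwise stage 2 runs BH at level `q' * m/(m - r1)`.
#' Decisions are invariant to permutation of the p-vector.
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return list: `reject` (logical), `adjusted` (values comparable to `q`:
#'   `adjusted <= q` iff rejected, capped at 1), `r1` (stage-1 rejections),
#'   `q_prime`, `stage2_level`.
#' @export
bky_fdr <- function(pvalues, q = 0.05) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(pvalues)
  qp <- q / (1 + q)
  s1 <- bh_reject(pvalues, qp)
  r1 <- s1$r
  bh_adj <- stats::p.adjust(pvalues, method = "BH")
  if (r1 == 0L) {
    return(list(reject = logical(m), adjusted = rep(1, m), r1 = 0L,
                q_prime = qp, stage2_level = NA_real_))
  }
  if (r1 == m) {
    return(list(reject = rep(TRUE, m),
                adjusted = pmin(1, bh_adj / (qp / q)), r1 = m,
                q_prime = qp, stage2_level = qp))
  }
  level2 <- qp * m / (m - r1)
  s2 <- bh_reject(pvalues, level2)
  adjusted <- pmin(1, bh_adj * (m - r1) / m * (1 + q))
  list(reject = s2$reject, adjusted = adjusted, r1 = r1, q_prime = qp,
       stage2_level = level2)
}

#' Spearman rank correlation (tie-aware, small-n exact)
#'
#' Pearson correlation of mid-ranks. For n <= 8 the two-sided p-value is
#' computed by exhaustive enumeration of all permutations of one rank
#' vector (valid under ties); for larger n the t-approximation
#' `t = rho * sqrt((n-2)/(1-rho^2))` is used.
#'
#' @param x,y numeric vectors (n >= 3).
#' @return list with `rho`, `p`, `method`; `rho` is NA (with a warning)
#'   for constant input.
#' @export
spearman_rank <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) stop("need n >= 3")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    warning("constant vector: Spearman rho undefined")
    return(list(rho = NA_real_, p = NA_real_, method = "undefined"))
  }
  rho <- stats::cor(rx, ry)
  if (n <= 8) {
    pm <- permutations_of(n)
    mx <- rx - mean(rx); my <- ry - mean(ry)
    denom <- sqrt(sum(mx^2) * sum(my^2))
    rhos <- as.vector(matrix(my[pm], nrow(pm)) %*% mx) / denom
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    return(list(rho = rho, p = p, method = "exact_permutation"))
  }
  tval <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * stats::pt(-abs(tval), n - 2),
       method = "t_approximation")
}

# all permutations of 1..n as an n! x n matrix
permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  for (i in seq_len(n)) {
    rows <- (i - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1L] <- i
    rest <- seq_len(n)[-i]
    out[rows, -1L] <- matrix(rest[sub], nrow(sub))
  }
  out
}

#' Mann-Whitney U test (tie-aware, small-sample exact)
#'
#' U is computed from mid-ranks. Two-sided p-values: for n1*n2 <= 400,
#' exact - via the closed-form null distribution ([stats::pwilcox]) when
#' there are no ties, or by exhaustive enumeration of group assignments
#' when there are ties and the enumeration is feasible; otherwise the
#' tie-corrected normal approximation.
#'
#' @param x,y numeric samples (non-empty).
#' @return list with `U` (statistic for the first sample), `p`, `method`.
#' @export
mann_whitney_u <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0) stop("both samples must be non-empty")
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- any(duplicated(pooled))
  if (n1 * n2 <= 400) {
    if (!ties) {
      lo <- min(U, n1 * n2 - U)
      p <- min(1, stats::pwilcox(lo, n1, n2) +
                 (1 - stats::pwilcox(n1 * n2 - lo - 1, n1, n2)))
      # symmetric null: P(U' <= lo) + P(U' >= hi)
      return(list(U = U, p = p, method = "exact_pwilcox"))
    }
    if (choose(n1 + n2, n1) <= 2e5) {
      sel <- utils::combn(n1 + n2, n1)
      rsums <- colSums(matrix(r[sel], n1))
      Us <- rsums - n1 * (n1 + 1) / 2
      p <- mean(abs(Us - mu) >= abs(U - mu) - 1e-9)
      return(list(U = U, p = p, method = "exact_enumeration"))
    }
  }
  # tie-corrected normal approximation
  nt <- table(pooled)
  n <- n1 + n2
  tie_term <- sum(nt^3 - nt) / (n * (n - 1))
  sigma <- sqrt(n1 * n2 / 12 * (n + 1 - tie_term))
  if (sigma == 0) return(list(U = U, p = 1, method = "degenerate"))
  z <- (U - mu) / sigma
  list(U = U, p = 2 * stats::pnorm(-abs(z)), method = "normal_approximation")
}
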