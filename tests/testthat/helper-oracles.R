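# Independent brute-force oracles. Deliberately dumb: explicit loops and
# exhaustive scans, no shared code with the package internals.

# border pixels of a binary mask: foreground with a background 4-neighbor
# (frame edge does not count as background), by explicit per-pixel checks
oracle_border <- function(fg) {
  nr <- nrow(fg); nc <- ncol(fg)
  out <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!fg[i, j]) next
    if ((i > 1 && !fg[i - 1, j]) || (i < nr && !fg[i + 1, j]) ||
        (j > 1 && !fg[i, j - 1]) || (j < nc && !fg[i, j + 1]))
      out[i, j] <- TRUE
  }
  out
}

# exact distance field from every pixel center to a point set (1-based
# matrix coords), by pmin accumulation over the set
oracle_distance_field <- function(pts, nr, nc) {
  rowm <- matrix(seq_len(nr), nr, nc)
  colm <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  d2 <- matrix(Inf, nr, nc)
  for (k in seq_len(nrow(pts))) {
    d2 <- pmin(d2, (rowm - pts[k, 1])^2 + (colm - pts[k, 2])^2)
  }
  sqrt(d2)
}

# brute-force periphery/interior/intertumoral decomposition of one labeled
# mask under the package's stated definitions
oracle_partition <- function(labels, band_width_px = 7, buffer_px) {
  nr <- nrow(labels); nc <- ncol(labels)
  half <- band_width_px / 2
  ids <- setdiff(sort(unique(as.vector(labels))), 0L)
  inner <- outer_band <- matrix(FALSE, nr, nc)
  outer_owner <- matrix(0L, nr, nc)
  outer_best <- matrix(Inf, nr, nc)
  interior <- labels > 0
  for (id in ids) {
    fg <- labels == id
    bord <- which(oracle_border(fg), arr.ind = TRUE)
    d <- oracle_distance_field(bord, nr, nc)
    inner <- inner | (fg & d <= half)
    interior <- interior & !(fg & d <= half)
    claim <- (labels == 0) & d <= half & d < outer_best
    outer_best[claim] <- d[claim]
    outer_owner[claim] <- id
    outer_band <- outer_band | claim
  }
  fgpts <- which(labels > 0, arr.ind = TRUE)
  dall <- if (nrow(fgpts)) oracle_distance_field(fgpts, nr, nc)
          else matrix(Inf, nr, nc)
  intertumoral <- (labels == 0) & dall >= buffer_px
  list(inner = inner, outer = outer_band, interior = interior,
       outer_owner = outer_owner, intertumoral = intertumoral)
}

# exact min distance (px) from one sub-pixel point to all lesion pixels
oracle_point_distance <- function(labels, row0, col0) {
  w <- which(labels > 0, arr.ind = TRUE)
  if (!nrow(w)) return(Inf)
  min(sqrt((w[, 1] - 1 - row0)^2 + (w[, 2] - 1 - col0)^2))
}

# random labeled mask of non-touching discs for property tests
random_disc_mask <- function(nr, nc, n_lesions, rmin = 4, rmax = 12) {
  labels <- matrix(0L, nr, nc)
  rowm <- matrix(0:(nr - 1), nr, nc)
  colm <- matrix(0:(nc - 1), nr, nc, byrow = TRUE)
  placed <- 0L
  guard <- 0L
  while (placed < n_lesions && guard < 200L) {
    guard <- guard + 1L
    r <- runif(1, rmin, rmax)
    cr <- runif(1, r + 1, nr - r - 2)
    cc <- runif(1, r + 1, nc - r - 2)
    disc <- (rowm - cr)^2 + (colm - cc)^2 <= r^2
    # keep discs separated so components stay distinct
    grow <- (rowm - cr)^2 + (colm - cc)^2 <= (r + 2)^2
    if (any(labels[grow] > 0)) next
    placed <- placed + 1L
    labels[disc] <- placed
  }
  labels
}

# step-by-step two-stage FDR reference, written independently:
# literal stage-wise BH with explicit sorting and scanning
oracle_bky <- function(p, q = 0.05) {
  m <- length(p)
  qp <- q / (1 + q)
  bh_pass <- function(pv, level) {
    ord <- order(pv)
    crit <- level * seq_len(m) / m
    below <- pv[ord] <= crit
    k <- 0
    for (i in seq_len(m)) if (below[i]) k <- i
    rej <- rep(FALSE, m)
    if (k > 0) rej[ord[1:k]] <- TRUE
    rej
  }
  r1 <- sum(bh_pass(p, qp))
  if (r1 == 0) return(rep(FALSE, m))
  if (r1 == m) return(rep(TRUE, m))
  bh_pass(p, qp * m / (m - r1))
}

# exhaustive two-sided Mann-Whitney p-value over all group assignments
oracle_mw_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  sel <- utils::combn(n1 + n2, n1)
  count <- 0L
  for (j in seq_len(ncol(sel))) {
    U <- sum(r[sel[, j]]) - n1 * (n1 + 1) / 2
    if (abs(U - mu) >= abs(U_obs - mu) - 1e-9) count <- count + 1L
  }
  count / ncol(sel)
}

# exhaustive two-sided Spearman permutation p-value (tie-aware);
# permutations generated by iterative insertion
oracle_spearman_p <- function(x, y) {
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  rho_obs <- cor(rx, ry)
  perm <- matrix(1L, 1, 1)
  for (k in 2:n) {
    blocks <- vector("list", k)
    for (pos in seq_len(k)) {
      left <- if (pos > 1) perm[, seq_len(pos - 1), drop = FALSE] else NULL
      right <- if (pos <= k - 1) perm[, pos:(k - 1), drop = FALSE] else NULL
      blocks[[pos]] <- cbind(left, matrix(k, nrow(perm), 1), right)
    }
    perm <- do.call(rbind, blocks)
  }
  rhos <- vapply(seq_len(nrow(perm)), function(i) cor(rx, ry[perm[i, ]]),
                 numeric(1))
  mean(abs(rhos) >= abs(rho_obs) - 1e-12)
}
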