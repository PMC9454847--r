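# Shared fixtures and independent brute-force oracles for the test suite.
# Oracles are deliberately naive (double loops) and independent of the
# package's vectorised implementations.

BASE_SEED <- 20220824  # offsets derived from this fix all stochastic blocks

# Build a cell data frame from coordinates; markers consistent with phenotype,
# optional state overrides (named list marker -> 0/1 vector).
make_cells <- function(x, y, phenotype = "OTHER", states = list()) {
  n <- length(x)
  df <- data.frame(x = x, y = y,
                   phenotype = rep(phenotype, length.out = n),
                   stringsAsFactors = FALSE)
  for (mk in TME_MARKERS) df[[mk]] <- 0L
  lineage <- list(
    TCELL_HELPER = c("CD3"), TCELL_CTL = c("CD3", "CD8"),
    TCELL_TREG = c("CD3", "FoxP3"), APC = c("CD163"),
    EPITHELIAL = c("PanCK"), OTHER = character(0)
  )
  for (i in seq_len(n)) {
    for (mk in lineage[[df$phenotype[i]]]) df[[mk]][i] <- 1L
  }
  for (mk in names(states)) df[[mk]] <- as.integer(states[[mk]])
  df
}

# O(n^2) nearest-neighbor oracle.
bf_nn <- function(ref, target, exclude_self = FALSE) {
  out <- numeric(nrow(ref))
  for (i in seq_len(nrow(ref))) {
    best <- Inf
    for (j in seq_len(nrow(target))) {
      if (exclude_self && i == j) next
      d <- sqrt((ref$x[i] - target$x[j])^2 + (ref$y[i] - target$y[j])^2)
      if (d < best) best <- d
    }
    out[i] <- best
  }
  out
}

# O(n^2) engagement oracle.
bf_engagement <- function(ref, target, radius = 40, exclude_self = FALSE) {
  counts <- integer(nrow(ref))
  for (i in seq_len(nrow(ref))) {
    for (j in seq_len(nrow(target))) {
      if (exclude_self && i == j) next
      d <- sqrt((ref$x[i] - target$x[j])^2 + (ref$y[i] - target$y[j])^2)
      if (d <= radius) counts[i] <- counts[i] + 1L
    }
  }
  engaged <- counts >= 1L
  list(engaged_pct = 100 * mean(engaged),
       mean_contacts = if (any(engaged)) mean(counts[engaged]) else NA_real_)
}

# Uniform points in a disc for ad-hoc patterns (independent of the package's
# polar sampler).
disc_points <- function(n, R = 300, cx = 0, cy = 0) {
  x <- numeric(0); y <- numeric(0)
  while (length(x) < n) {
    cand_x <- runif(2 * n, -R, R); cand_y <- runif(2 * n, -R, R)
    keep <- cand_x^2 + cand_y^2 <= R^2
    x <- c(x, cand_x[keep]); y <- c(y, cand_y[keep])
  }
  data.frame(x = cx + x[seq_len(n)], y = cy + y[seq_len(n)])
}

# Minimal valid cell-table CSV written to a temp file; returns the path.
write_tiny_cell_csv <- function(path = tempfile(fileext = ".csv"),
                                n = 5, core_id = "C1", patient_id = "P1",
                                hladr = 10, drop_col = NULL, mutate = NULL) {
  df <- data.frame(
    cell_id = paste0("c", seq_len(n)), core_id = core_id,
    patient_id = patient_id,
    x_um = seq(0, by = 10, length.out = n), y_um = rep(0, n),
    stringsAsFactors = FALSE
  )
  for (mk in TME_MARKERS) df[[mk]] <- 0L
  df$CD3[1] <- 1L
  df$hladr_area_pct <- hladr
  if (!is.null(mutate)) df <- mutate(df)
  if (!is.null(drop_col)) df <- df[, setdiff(names(df), drop_col)]
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# Hand-rolled BH step-up: q_(i) = min_{j >= i} p_(j) * m / j, input order.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- pmin(ps * m / seq_len(m), 1)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[ord] <- q
  out
}

# Two-sided Fisher p by full hypergeometric enumeration (probability order).
fisher_oracle <- function(tab) {
  a <- tab[1, 1]
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
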