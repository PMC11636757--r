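# Independent brute-force implementations used as oracles. These are
# deliberately written as plain step-by-step loops, sharing no code
# with the package internals.

# Entropy-weighted index pipeline: returns entropy, weights and (when
# a standards list is given) per-sample scores.
oracle_ewqi <- function(X, S = NULL, ph_col = NULL) {
  m <- nrow(X); n <- ncol(X)
  Y <- matrix(0, m, n)
  for (j in 1:n) {
    mn <- min(X[, j]); mx <- max(X[, j])
    if (mx > mn) Y[, j] <- (X[, j] - mn) / (mx - mn)
  }
  e <- numeric(n)
  for (j in 1:n) {
    tot <- sum(Y[, j])
    if (tot == 0) { e[j] <- 1; next }
    P <- Y[, j] / tot
    acc <- 0
    for (i in 1:m) if (P[i] > 0) acc <- acc + P[i] * log(P[i])
    e[j] <- -acc / log(m)
    if (all(abs(P - P[1]) < 1e-15)) e[j] <- 1
  }
  w <- (1 - e) / sum(1 - e)
  out <- list(entropy = e, weights = w)
  if (!is.null(S)) {
    q <- matrix(0, m, n)
    for (j in 1:n) {
      for (i in 1:m) {
        if (!is.null(ph_col) && j == ph_col) {
          v <- X[i, j]
          q[i, j] <- if (v > 7) 100 * (v - 7) / 1.5
                     else if (v < 7) 100 * (v - 7) / -0.5
                     else 0
        } else {
          q[i, j] <- 100 * X[i, j] / S[j]
        }
      }
    }
    sc <- numeric(m)
    for (i in 1:m) sc[i] <- sum(w * q[i, ])
    out$score <- sc
  }
  out
}

# Naive double-loop IDW raster over cell centres, top row northernmost.
oracle_idw_raster <- function(x, y, z, bbox, cellsize, p = 2,
                              eps = 1e-9) {
  nc <- max(1, ceiling((bbox[2] - bbox[1]) / cellsize))
  nr <- max(1, ceiling((bbox[4] - bbox[3]) / cellsize))
  out <- matrix(NA_real_, nr, nc)
  for (i in 1:nr) {
    for (j in 1:nc) {
      cx <- bbox[1] + (j - 0.5) * cellsize
      cy <- bbox[3] + (nr - i + 0.5) * cellsize
      num <- 0; den <- 0; hit <- NA
      for (k in seq_along(x)) {
        d <- sqrt((x[k] - cx)^2 + (y[k] - cy)^2)
        if (d < eps) { hit <- z[k]; break }
        num <- num + z[k] / d^p
        den <- den + 1 / d^p
      }
      out[i, j] <- if (!is.na(hit)) hit else num / den
    }
  }
  out
}

# Textbook two-pass Pearson correlation.
oracle_pearson <- function(a, b) {
  ma <- mean(a); mb <- mean(b)
  num <- sum((a - ma) * (b - mb))
  num / sqrt(sum((a - ma)^2) * sum((b - mb)^2))
}

# A balanced reference water built from equivalent weights: every ion
# at `eq` meq/L on both sides.
balanced_sample <- function(eq = 2) {
  data.frame(Ca = eq * 40.078 / 2, Na = eq * 22.98977,
             HCO3 = eq * 61.016, Cl = eq * 35.4527)
}
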