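#' Min-max normalisation of the evaluation matrix
#'
#' Columns (parameters) are rescaled to `[0, 1]` by their in-matrix
#' range so that parameters with different units and magnitudes are
#' comparable. Constant columns carry no information; they are set to
#' zero and flagged degenerate.
#'
#' @param X Numeric matrix, samples in rows, parameters in columns,
#'   at least 2 rows, all finite.
#' @return List with `Y` (normalised matrix) and `degenerate` (logical
#'   per column).
#' @export
ewqi_normalize <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need at least 2 samples")
  if (any(!is.finite(X))) stop("non-finite values in evaluation matrix")
  rng <- apply(X, 2L, range)
  span <- rng[2, ] - rng[1, ]
  degenerate <- span == 0
  Y <- sweep(X, 2L, rng[1, ], "-")
  Y <- sweep(Y, 2L, ifelse(degenerate, 1, span), "/")
  Y[, degenerate] <- 0
  list(Y = Y, degenerate = degenerate)
}

#' Shannon entropy and entropy weights of parameters
#'
#' Each parameter's information entropy is computed from the column
#' proportions `P_ij = y_ij / sum_i y_ij` as
#' `e_j = -(1/ln m) sum_i P_ij ln P_ij` (with `0 ln 0 := 0`), and the
#' weight is its normalised information content
#' `w_j = (1 - e_j) / sum_j (1 - e_j)`. A parameter whose normalised
#' column is constant (including all-zero) is assigned `e_j = 1`, hence
#' weight 0: it cannot discriminate between samples.
#'
#' @param Y Normalised matrix from [ewqi_normalize()] (or any
#'   non-negative matrix).
#' @return List with `entropy` and `weights` (both named by column);
#'   weights sum to 1.
#' @export
entropy_weights <- function(Y) {
  Y <- as.matrix(Y)
  m <- nrow(Y)
  if (any(Y < 0)) stop("normalised matrix must be non-negative")
  colsum <- colSums(Y)
  e <- vapply(seq_len(ncol(Y)), function(j) {
    if (colsum[j] == 0) return(1)
    p <- Y[, j] / colsum[j]
    if (all(p == p[1])) return(1)  # uniform proportions: maximal entropy
    plogp <- ifelse(p > 0, p * log(p), 0)
    -sum(plogp) / log(m)
  }, numeric(1))
  names(e) <- colnames(Y)
  info <- 1 - e
  if (all(info <= 0)) {
    stop("all parameters degenerate: entropy weights undefined")
  }
  w <- info / sum(info)
  list(entropy = e, weights = w)
}

#' Quality rating of a measured value against its standard
#'
#' `q = 100 C / S` for ordinary parameters. pH is rated against its
#' band around neutrality: `q_pH = 100 (pH - 7) / (S_pH - 7)` with
#' `S_pH = 8.5` when pH > 7 and `S_pH = 6.5` when pH < 7, so the rating
#' is always non-negative and reaches 100 at either band edge; exactly
#' neutral water rates 0.
#'
#' @param x Measured values (vectorised).
#' @param parameter Parameter name (scalar), matched against the
#'   standards table; `"pH"` triggers the band rule.
#' @param standards A [who_standards()] object.
#' @return Numeric vector of ratings (>= 0).
#' @examples
#' quality_rating(61, "NO3")   # 122: above the 50 mg/L limit
#' quality_rating(c(6.5, 7, 8.5), "pH")
#' @export
quality_rating <- function(x, parameter, standards = who_standards()) {
  if (parameter == "pH") {
    upper <- standards$ph_band[2]
    lower <- standards$ph_band[1]
    q <- ifelse(x > 7, 100 * (x - 7) / (upper - 7),
         ifelse(x < 7, 100 * (x - 7) / (lower - 7), 0))
    return(q)
  }
  if (!parameter %in% names(standards$limits)) {
    stop("no standard registered for ", parameter)
  }
  s <- standards$limits[[parameter]]
  if (s == 0) stop("standard for ", parameter, " must be nonzero")
  100 * x / s
}

#' Entropy-weighted score from weights and ratings
#'
#' @param weights Parameter weights (summing to 1).
#' @param q Ratings: vector (one sample) or matrix (samples x
#'   parameters, columns aligned with `weights`).
#' @return Score per sample.
#' @export
ewqi_score <- function(weights, q) {
  if (is.matrix(q)) {
    if (ncol(q) != length(weights)) stop("dimension mismatch")
    drop(q %*% weights)
  } else {
    if (length(q) != length(weights)) stop("dimension mismatch")
    sum(weights * q)
  }
}

.ewqi_rank_labels <- c("I" = "excellent", "II" = "good",
                       "III" = "moderate", "IV" = "poor",
                       "V" = "extremely poor")

#' Classify an EWQI score into quality ranks I-V
#'
#' Default thresholds 25/50/100/150 delimit excellent (I, < 25), good
#' (II), moderate (III, marginally suitable for drinking), poor (IV,
#' not recommended) and extremely poor (V, >= 150); intervals are
#' left-closed (a score of exactly 100 is rank IV).
#'
#' @param score Numeric vector of scores (>= 0).
#' @param thresholds Strictly increasing vector of 4 cut points.
#' @return Ordered factor with levels `I < II < III < IV < V`; the
#'   `labels` attribute carries the verbal class per element.
#' @examples
#' classify_ewqi(c(83.27, 120.30))
#' @export
classify_ewqi <- function(score, thresholds = c(25, 50, 100, 150)) {
  if (any(diff(thresholds) <= 0)) {
    stop("thresholds must be strictly increasing")
  }
  idx <- findInterval(score, thresholds) + 1L   # left-closed bins
  rk <- factor(names(.ewqi_rank_labels)[idx],
               levels = names(.ewqi_rank_labels), ordered = TRUE)
  attr(rk, "labels") <- unname(.ewqi_rank_labels[idx])
  rk
}

#' Fit an entropy-weighted water quality index
#'
#' The EWQI scores a set of samples by (i) min-max normalising the
#' sample x parameter matrix, (ii) weighting each parameter by its
#' Shannon-entropy information content (a parameter that varies a lot
#' across samples gets more weight), (iii) rating each measured value
#' against its drinking-water standard (`q = 100 C/S`, with a band rule
#' for pH), and (iv) summing `EWQI_i = sum_j w_j q_ij`. Weights are a
#' property of the fitted run: seasons or well subsets should be fitted
#' separately, and [predict.ewqi()] scores new samples with the frozen
#' weights.
#'
#' @param data Data frame of samples containing the rated parameters
#'   (and optionally `well_id`, `season`).
#' @param parameters Character vector of parameters to rate (default
#'   the six-parameter drinking-water set `pH, TH, BOD, COD, Ca, NO3`).
#' @param standards A [who_standards()] object supplying permissible
#'   limits.
#' @param thresholds Rank cut points, see [classify_ewqi()].
#' @return An object of class `ewqi` with components `score`, `rank`,
#'   `label`, `weights`, `entropy`, `q` (ratings matrix), `X`, `Y`,
#'   `degenerate`, `parameters`, `standards`, `thresholds`, `wells`.
#' @examples
#' d <- data.frame(pH = c(7.2, 7.8, 7.5), TH = c(300, 500, 420),
#'                 BOD = c(6, 8, 7), COD = c(12, 15, 13),
#'                 Ca = c(60, 120, 90), NO3 = c(20, 55, 35))
#' fit <- ewqi(d)
#' fit$score
#' @export
ewqi <- function(data, parameters = c("pH", "TH", "BOD", "COD",
                                      "Ca", "NO3"),
                 standards = who_standards(),
                 thresholds = c(25, 50, 100, 150)) {
  data <- as.data.frame(data)
  missing_p <- setdiff(parameters, names(data))
  if (length(missing_p)) {
    stop("parameters absent from data: ", paste(missing_p, collapse = ", "))
  }
  X <- as.matrix(data[, parameters, drop = FALSE])
  if (nrow(X) < 2) stop("need at least 2 samples")
  nrm <- ewqi_normalize(X)
  ew <- entropy_weights(nrm$Y)
  q <- vapply(parameters, function(p) {
    quality_rating(data[[p]], p, standards)
  }, numeric(nrow(X)))
  q <- matrix(q, nrow = nrow(X),
              dimnames = list(NULL, parameters))
  score <- ewqi_score(ew$weights, q)
  rank <- classify_ewqi(score, thresholds)
  structure(list(
    score = score, rank = rank, label = attr(rank, "labels"),
    weights = ew$weights, entropy = ew$entropy, q = q,
    X = X, Y = nrm$Y, degenerate = nrm$degenerate,
    parameters = parameters, standards = standards,
    thresholds = thresholds,
    wells = if ("well_id" %in% names(data)) data$well_id
            else as.character(seq_len(nrow(X))),
    season = if ("season" %in% names(data)) data$season else NULL
  ), class = "ewqi")
}

#' @export
print.ewqi <- function(x, digits = 2, ...) {
  cat("Entropy-weighted water quality index (", length(x$score),
      " samples, ", length(x$parameters), " parameters)\n", sep = "")
  cat("Weights:\n")
  print(round(x$weights, 4))
  cat("Scores:\n")
  df <- data.frame(well = x$wells,
                   EWQI = round_half_up(x$score, digits),
                   rank = as.character(x$rank), class = x$label)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
summary.ewqi <- function(object, ...) {
  s <- object$score
  structure(list(
    n = length(s), parameters = object$parameters,
    entropy = object$entropy, weights = object$weights,
    score_range = range(s), score_mean = mean(s),
    rank_table = table(object$rank)
  ), class = "summary.ewqi")
}

#' @export
print.summary.ewqi <- function(x, ...) {
  cat("EWQI fit over", x$n, "samples\n")
  cat(sprintf("Score range %.2f - %.2f, mean %.2f\n",
              x$score_range[1], x$score_range[2], x$score_mean))
  cat("Rank counts:\n")
  print(x$rank_table)
  cat("Entropy weights:\n")
  print(round(rbind(entropy = x$entropy, weight = x$weights), 4))
  invisible(x)
}

#' Extract entropy weights from an EWQI fit
#'
#' @param object An `ewqi` object.
#' @param ... Unused.
#' @return Named weight vector (sums to 1).
#' @export
coef.ewqi <- function(object, ...) object$weights

#' @export
fitted.ewqi <- function(object, ...) object$score

#' Score new samples with frozen EWQI weights
#'
#' Applies the fitted run's entropy weights and standards to new
#' measurements. A sample identical to one of the fitted samples
#' receives exactly its fitted score.
#'
#' @param object An `ewqi` object.
#' @param newdata Data frame containing the fitted parameters.
#' @param ... Unused.
#' @return Data frame with `score`, `rank` and `class`.
#' @export
predict.ewqi <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  q <- vapply(object$parameters, function(p) {
    quality_rating(newdata[[p]], p, object$standards)
  }, numeric(nrow(newdata)))
  q <- matrix(q, nrow = nrow(newdata),
              dimnames = list(NULL, object$parameters))
  score <- ewqi_score(object$weights, q)
  rank <- classify_ewqi(score, object$thresholds)
  data.frame(score = score, rank = as.character(rank),
             class = attr(rank, "labels"), stringsAsFactors = FALSE)
}

#' Plot an EWQI fit
#'
#' Bar chart of per-well scores with the rank thresholds as guide
#' lines.
#'
#' @param x An `ewqi` object.
#' @param ... Passed to [graphics::barplot()].
#' @return Invisibly, the bar midpoints.
#' @export
plot.ewqi <- function(x, ...) {
  cols <- c(I = "#2c7bb6", II = "#abd9e9", III = "#ffffbf",
            IV = "#fdae61", V = "#d7191c")
  mids <- graphics::barplot(x$score, names.arg = x$wells, las = 2,
                            col = cols[as.character(x$rank)],
                            ylab = "EWQI", ...)
  graphics::abline(h = x$thresholds, lty = 3, col = "grey50")
  invisible(mids)
}
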