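# Association statistics: Spearman rank correlation (indicators vs
# immunohistochemistry scores) and the intraclass correlation coefficient
# for segmentation test-retest reproducibility.

# All permutations of 1..n as a matrix (rows = permutations), built by
# inserting n into every position of the (n-1)-permutations.
perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  p <- perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(pos) {
    cbind(p[, seq_len(pos - 1L), drop = FALSE], n,
          p[, seq_len(n - pos) + (pos - 1L), drop = FALSE])
  }))
}

#' Spearman rank correlation
#'
#' Average ranks for ties; rho is Pearson's correlation of the rank vectors.
#' The p-value uses the exact permutation distribution for n <= 9 and the
#' t-approximation on ranks otherwise (two-sided).
#'
#' @param x,y Equal-length finite numeric vectors, n >= 4.
#' @return List: `rho`, `p_value`, `n`, `method`; `rho` is `NA` with a
#'   `degenerate` flag when either vector has zero variance.
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  n <- length(x)
  if (n < 4) stopf("spearman needs n >= 4")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stopf("spearman: inputs must be finite")
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0)
    return(list(rho = NA_real_, p_value = NA_real_, n = n,
                method = "undefined", degenerate = TRUE))
  rho <- cor(rx, ry)
  if (n <= 9) {
    P <- perms(n)
    Yp <- matrix(ry[P], nrow = nrow(P))
    s <- as.numeric(Yp %*% rx)
    # only sum(rx * ry[perm]) varies across permutations
    mx <- mean(rx); my <- mean(ry)
    denom <- sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
    rho_perm <- (s - n * mx * my) / denom
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tt), df = n - 2)
    method <- "t approximation"
  }
  list(rho = rho, p_value = p, n = n, method = method, degenerate = FALSE)
}

#' Spearman correlation matrix of indicators vs scores
#'
#' @param indicators data.frame/matrix of indicator columns.
#' @param scores data.frame/matrix of score columns (e.g. p53, Ki67).
#' @return List: `rho` (indicators x scores matrix), `p_value` (same shape).
#' @export
spearman_matrix <- function(indicators, scores) {
  indicators <- as.data.frame(indicators)
  scores <- as.data.frame(scores)
  rho <- p <- matrix(NA_real_, ncol(indicators), ncol(scores),
                     dimnames = list(colnames(indicators), colnames(scores)))
  for (i in seq_len(ncol(indicators))) for (j in seq_len(ncol(scores))) {
    ok <- is.finite(indicators[[i]]) & is.finite(scores[[j]])
    if (sum(ok) >= 4) {
      s <- spearman(indicators[[i]][ok], scores[[j]][ok])
      rho[i, j] <- s$rho
      p[i, j] <- s$p_value
    }
  }
  list(rho = rho, p_value = p)
}

#' Intraclass correlation coefficient ICC(2,1)
#'
#' Two-way random effects, absolute agreement, single measurement, from the
#' ANOVA mean squares. Agreement above 0.90 is "excellent", above 0.75
#' "good", above 0.50 "moderate", otherwise "poor" (the usual reliability
#' guideline; reproducibility is accepted as good when ICC > 0.75).
#'
#' @param ratings Numeric matrix, subjects x raters (>= 2 each), finite.
#' @return List: `icc`, `classification`, mean squares (`msr`, `msc`,
#'   `mse`), `n`, `k`; `degenerate` flags zero between-subject variance.
#' @export
icc <- function(ratings) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 2 || k < 2) stopf("icc needs >= 2 subjects and >= 2 raters")
  if (any(!is.finite(ratings))) stopf("icc: ratings must be finite")
  grand <- mean(ratings)
  rowm <- rowMeans(ratings); colm <- colMeans(ratings)
  ssr <- k * sum((rowm - grand)^2)
  ssc <- n * sum((colm - grand)^2)
  sst <- sum((ratings - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  degenerate <- msr < 1e-12 * max(sst / (n * k), 1e-300) || denom <= 0
  val <- if (denom <= 0) NA_real_ else (msr - mse) / denom
  cls <- if (!is.finite(val)) NA_character_
    else if (val > 0.9) "excellent" else if (val > 0.75) "good"
    else if (val > 0.5) "moderate" else "poor"
  list(icc = val, classification = cls, msr = msr, msc = msc, mse = mse,
       n = n, k = k, degenerate = degenerate)
}
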