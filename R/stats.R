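#' Two-sided Wilcoxon rank-sum p-value
#'
#' Exact enumeration over all group assignments of the pooled midranks
#' when the pooled sample size is at most `exactLimit` (the enumeration
#' handles ties, unlike the classical exact distribution); otherwise a
#' normal approximation with tie correction and continuity correction.
#'
#' @param x,y numeric vectors with at least 2 observations each.
#' @param exactLimit largest pooled size for which all
#'   `choose(n + m, n)` rank splits are enumerated (default 12).
#' @return two-sided p-value in (0, 1].
#' @examples
#' wilcoxonRankSum(c(10, 11, 12), c(1, 2, 3))  # 0.1 by enumeration
#' @export
wilcoxonRankSum <- function(x, y, exactLimit = 12L) {
  if (length(x) < 2L || length(y) < 2L)
    stop("insufficient data: need at least 2 observations per group")
  n <- length(x); m <- length(y); N <- n + m
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n)])
  mu <- n * (N + 1) / 2
  if (N <= exactLimit) {
    cmb <- utils::combn(N, n)
    Ws <- colSums(matrix(r[cmb], nrow = n))
    mean(abs(Ws - mu) >= abs(W - mu) - 1e-9)
  } else {
    ties <- tabulate(match(r, unique(r)))
    sigma2 <- n * m / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sigma2 <= 0) return(1)
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
    min(1, 2 * stats::pnorm(-abs(z)))
  }
}

# Row-wise two-sided rank-sum p-values for a bins x samples matrix.
# Same branch rule as wilcoxonRankSum; the exact branch shares one
# enumeration of rank splits across all rows.
rowWilcoxonP <- function(mat, isTumor, exactLimit = 12L) {
  n <- sum(isTumor); m <- sum(!isTumor); N <- n + m
  if (n < 2L || m < 2L)
    stop("insufficient data: need at least 2 samples per group")
  if (nrow(mat) == 0L) return(numeric(0))
  mu <- n * (N + 1) / 2
  if (N <= exactLimit) {
    cmb <- utils::combn(N, n)
    apply(mat, 1L, function(v) {
      r <- rank(v)
      W <- sum(r[isTumor])
      Ws <- colSums(matrix(r[cmb], nrow = n))
      mean(abs(Ws - mu) >= abs(W - mu) - 1e-9)
    })
  } else {
    stats <- apply(mat, 1L, function(v) {
      r <- rank(v)
      ties <- tabulate(match(r, unique(r)))
      c(sum(r[isTumor]), sum(ties^3 - ties))
    })
    W <- stats[1L, ]; tieTerm <- stats[2L, ]
    sigma2 <- n * m / 12 * ((N + 1) - tieTerm / (N * (N - 1)))
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(pmax(sigma2, .Machine$double.eps))
    p <- pmin(1, 2 * stats::pnorm(-abs(z)))
    p[sigma2 <= 0] <- 1
    p
  }
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Classical step-up FDR adjustment: `q_(i) = min_{j >= i} m p_(j) / j`
#' over the p-values sorted ascending, capped at 1.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return q-values, same order as `p`.
#' @export
adjustBH <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  q <- pmin(1, cummin(m / (m:1) * p[o]))
  q[order(o)]
}

#' ROC curve and AUC by the Mann-Whitney identity
#'
#' AUC is the probability that a randomly chosen positive sample scores
#' above a randomly chosen negative one, ties counted as 1/2; computed
#' from the rank-sum of the positive class. ROC points are emitted at
#' every distinct score threshold (predict positive when score >=
#' threshold), bracketed by (0,0) and (1,1).
#'
#' @param scores numeric per-sample scores (higher = more positive-like).
#' @param labels logical or 0/1 vector, TRUE/1 = positive class.
#' @return list with `auc` and a `roc` data.frame of
#'   (threshold, tpr, fpr).
#' @examples
#' rocAuc(c(1, 2, 3, 4), c(0, 1, 0, 1))$auc  # 0.75
#' @export
rocAuc <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L)
    stop("both classes must be present")
  r <- rank(scores)
  auc <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(scores[labels] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[!labels] >= t), numeric(1))
  roc <- data.frame(threshold = c(Inf, thr), tpr = c(0, tpr), fpr = c(0, fpr))
  list(auc = auc, roc = roc)
}

# Sample odds ratio of a 2x2 table with Haldane-Anscombe 0.5 correction
# applied when any cell is zero; p-value from Fisher's exact test.
fisher2x2 <- function(tab, alternative = "two.sided") {
  stopifnot(all(dim(tab) == c(2L, 2L)))
  p <- stats::fisher.test(tab, alternative = alternative)$p.value
  t2 <- tab + if (any(tab == 0)) 0.5 else 0
  or <- (t2[1, 1] * t2[2, 2]) / (t2[1, 2] * t2[2, 1])
  list(oddsRatio = unname(or), pValue = p, table = tab)
}

# Per-row pooled-variance (Student) two-sample t-test, two-sided.
# Zero pooled variance: p = 1 when the group means agree, 0 otherwise.
rowStudentT <- function(mat, isTumor) {
  n1 <- sum(isTumor); n2 <- sum(!isTumor)
  if (n1 < 2L || n2 < 2L) stop("need >= 2 samples per group")
  x <- mat[, isTumor, drop = FALSE]; y <- mat[, !isTumor, drop = FALSE]
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- apply(x, 1L, stats::var); v2 <- apply(y, 1L, stats::var)
  df <- n1 + n2 - 2
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
  se <- sqrt(s2 * (1 / n1 + 1 / n2))
  t <- (m1 - m2) / se
  p <- 2 * stats::pt(-abs(t), df)
  zv <- se == 0
  t[zv] <- ifelse(m1[zv] == m2[zv], 0, sign(m1[zv] - m2[zv]) * Inf)
  p[zv] <- ifelse(m1[zv] == m2[zv], 1, 0)
  data.frame(t = t, p = p, meanTumor = m1, meanNormal = m2)
}
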