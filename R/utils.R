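`%||%` <- function(a, b) if (is.null(a)) b else a

#' Two-sample Wilcoxon rank-sum test
#'
#' Two-sided rank-sum test used throughout the differential-expression and
#' univariate-association machinery. For small samples (both groups no larger
#' than \code{exact_max}) the null distribution of the rank-sum statistic is
#' enumerated exhaustively over all assignments of the observed (tie-adjusted)
#' ranks, and the two-sided p value is twice the smaller tail probability,
#' capped at 1. For larger samples a normal approximation with tie correction
#' (no continuity correction) is used.
#'
#' @param x,y numeric vectors, the two groups.
#' @param exact_max largest per-group size for which the exact enumeration is
#'   used (default 10).
#' @return list with \code{statistic} (rank sum of \code{x}) and
#'   \code{p.value}. When all values in both groups are identical the p value
#'   is 1 by convention.
#' @export
rank_sum_test <- function(x, y, exact_max = 10) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 1L || length(y) < 1L)
    stop("rank_sum_test: both groups must be non-empty")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  if (length(unique(c(x, y))) == 1L)
    return(list(statistic = n1 * (n + 1) / 2, p.value = 1))
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)])
  if (n1 <= exact_max && n2 <= exact_max) {
    cmb <- utils::combn(n, n1)
    Ws <- colSums(matrix(r[cmb], nrow = n1))
    p_lo <- mean(Ws <= W + 1e-9)
    p_hi <- mean(Ws >= W - 1e-9)
    p <- min(1, 2 * min(p_lo, p_hi))
  } else {
    mu <- n1 * (n + 1) / 2
    tie_tab <- table(r)
    tie_cor <- sum(tie_tab^3 - tie_tab)
    sig2 <- n1 * n2 / 12 * ((n + 1) - tie_cor / (n * (n - 1)))
    if (sig2 <= 0) return(list(statistic = W, p.value = 1))
    p <- 2 * stats::pnorm(-abs(W - mu) / sqrt(sig2))
  }
  list(statistic = W, p.value = min(1, p))
}

# Internal: check that `x` is a single positive whole number.
is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}

stop_input <- function(...) stop(sprintf(...), call. = FALSE)
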