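#' Jarque-Bera test of residual normality
#'
#' Moment-based omnibus test combining sample skewness and excess kurtosis;
#' the statistic is asymptotically chi-squared with 2 degrees of freedom
#' under normality. Used as a model diagnostic for the Gaussian linear
#' models of [covariate_validation()].
#'
#' @param x numeric vector (e.g. model residuals); `NA`s are dropped.
#' @return list with `statistic`, `p.value`, `skewness`, `kurtosis`.
#' @export
#' @examples
#' jarque_bera(rnorm(200))$p.value
jarque_bera <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8L) stop("jarque_bera: need at least 8 finite observations")
  m <- mean(x)
  s2 <- mean((x - m)^2)
  skew <- mean((x - m)^3) / s2^1.5
  kurt <- mean((x - m)^4) / s2^2
  stat <- n / 6 * (skew^2 + (kurt - 3)^2 / 4)
  list(statistic = stat,
       p.value = stats::pchisq(stat, df = 2, lower.tail = FALSE),
       skewness = skew, kurtosis = kurt)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up false-discovery-rate control: for order statistics `p_(j)`,
#' `q_i = min over j >= rank(i) of m * p_(j) / j`, capped at 1. Matches the
#' classical BH procedure; `NA` p-values propagate as `NA` and do not count
#' toward `m`.
#'
#' @param p numeric vector of p-values in `[0, 1]` (`NA` allowed).
#' @return vector of q-values, same length and order as `p`.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
bh_adjust <- function(p) {
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  pv <- p[ok]
  if (any(pv < 0 | pv > 1)) stop("bh_adjust: p-values must lie in [0, 1]")
  m <- length(pv)
  if (m == 0L) return(q)
  o <- order(pv, decreasing = TRUE)
  ro <- order(o)
  q[ok] <- pmin(1, cummin(m / seq(m, 1) * pv[o]))[ro]
  q
}

#' Cliff's delta effect size
#'
#' Nonparametric dominance effect size in `[-1, 1]`: the difference between
#' the probability that a value drawn from `x` exceeds one drawn from `y`
#' and the converse, with ties contributing zero. `+1` means complete
#' dominance of `x`, `-1` complete dominance of `y`.
#'
#' @param x,y numeric vectors (non-empty).
#' @return scalar delta.
#' @export
#' @examples
#' cliffs_delta(c(1, 2, 3, 4), c(2, 3, 4, 5)) # -7/16
cliffs_delta <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0L || length(y) == 0L)
    stop("cliffs_delta: both samples must be non-empty")
  # rank-based O((n+m) log(n+m)) formulation of the all-pairs count
  r <- rank(c(x, y), ties.method = "average")
  nx <- length(x); ny <- length(y)
  rx <- sum(r[seq_len(nx)])
  # sum over pairs of sign(x_i - y_j) = 2*U - nx*ny with mid-rank U
  u <- rx - nx * (nx + 1) / 2
  (2 * u - nx * ny) / (nx * ny)
}

#' Adjusted Rand index between two partitions
#'
#' @param a,b label vectors of equal length.
#' @return ARI scalar (1 = identical partitions, ~0 expected at random).
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("partitions must have equal length")
  tab <- table(a, b)
  choose2 <- function(v) sum(v * (v - 1) / 2)
  sij <- choose2(as.vector(tab))
  si <- choose2(rowSums(tab))
  sj <- choose2(colSums(tab))
  n2 <- choose2(sum(tab))
  expected <- si * sj / n2
  denom <- (si + sj) / 2 - expected
  if (denom == 0) return(1)
  (sij - expected) / denom
}

# internal: check a features x samples abundance matrix
check_abundance <- function(x, what = "abundance matrix") {
  if (!is.matrix(x) || !is.numeric(x))
    stop(what, " must be a numeric matrix (features x samples)")
  if (anyNA(x) || any(!is.finite(x))) stop(what, " contains non-finite values")
  if (any(x < 0)) stop(what, " contains negative values")
  invisible(x)
}
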