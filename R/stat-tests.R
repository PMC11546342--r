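#' Benjamini-Hochberg step-up adjustment
#'
#' Standard step-up: with sorted p-values `p_(1) <= ... <= p_(m)`,
#' `q_(i) = min_{j >= i} (m / j) p_(j)`, clipped at 1 and returned in the
#' input order. Computed via [stats::p.adjust()].
#'
#' @param p numeric vector of p-values in `[0, 1]` (NAs propagate).
#' @return q-values in input order.
#' @export
benjamini_hochberg <- function(p) {
  if (length(p) && any(stats::na.omit(p) < 0 | stats::na.omit(p) > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' One-sided Wilcoxon rank-sum test with exact small-sample enumeration
#'
#' Tests whether values in `x` tend to exceed values in `y`
#' (`alternative = "greater"`). When both groups have at most `exact_max`
#' observations, the p-value is computed by full enumeration of all
#' `choose(n1 + n2, n1)` group assignments of the pooled values — exact
#' even under ties. Otherwise the normal approximation with tie
#' correction and continuity correction is used. All-tied data gives
#' p = 1.
#'
#' @param x,y numeric vectors (each length >= 1).
#' @param alternative `"greater"`, `"less"`, or `"two.sided"`.
#' @param exact_max largest per-group size for exact enumeration.
#' @return A list with `statistic` (rank-sum `W` of `x`, Mann-Whitney
#'   form), `p`, and `method` (`"exact"` or `"normal"`).
#' @export
wilcoxon_rank_sum <- function(x, y, alternative = c("greater", "less",
                                                    "two.sided"),
                              exact_max = 10L) {
  alternative <- match.arg(alternative)
  stopifnot(length(x) >= 1, length(y) >= 1)
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2  # Mann-Whitney U
  if (n1 <= exact_max && n2 <= exact_max) {
    idx <- utils::combn(n1 + n2, n1)
    w_all <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
    eps <- 1e-9
    p <- switch(alternative,
                greater = mean(w_all >= w_obs - eps),
                less = mean(w_all <= w_obs + eps),
                two.sided = {
                  mu <- n1 * n2 / 2
                  min(1, mean(abs(w_all - mu) >= abs(w_obs - mu) - eps))
                })
    list(statistic = w_obs, p = p, method = "exact")
  } else {
    mu <- n1 * n2 / 2
    n <- n1 + n2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * (n + 1 - tie_term)
    if (sigma2 <= 0) return(list(statistic = w_obs, p = 1, method = "normal"))
    z <- switch(alternative,
                greater = (w_obs - mu - 0.5) / sqrt(sigma2),
                less = (w_obs - mu + 0.5) / sqrt(sigma2),
                two.sided = (abs(w_obs - mu) - 0.5) / sqrt(sigma2))
    p <- switch(alternative,
                greater = stats::pnorm(z, lower.tail = FALSE),
                less = stats::pnorm(z),
                two.sided = 2 * stats::pnorm(z, lower.tail = FALSE))
    list(statistic = w_obs, p = min(1, p), method = "normal")
  }
}

# Cache of exact Spearman null distributions (sum of squared rank
# differences, by n) — the null law depends only on n when there are no
# ties.
.spearman_cache <- new.env(parent = emptyenv())

spearman_null_d2 <- function(n) {
  key <- as.character(n)
  if (!is.null(.spearman_cache[[key]])) return(.spearman_cache[[key]])
  perms <- permutations_int(n)
  d2 <- colSums((perms - seq_len(n))^2)
  .spearman_cache[[key]] <- d2
  d2
}

# All n! permutations of 1..n, one per column.
permutations_int <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_int(n - 1L)
  out <- matrix(0L, n, n * ncol(sub))
  col <- 0L
  for (k in seq_len(n)) {
    block <- rbind(rep(k, ncol(sub)), sub + (sub >= k))
    out[, col + seq_len(ncol(sub))] <- block
    col <- col + ncol(sub)
  }
  out
}

#' Spearman rank correlation with exact small-sample p-value
#'
#' Rho uses average ranks for ties. With `n <= exact_max` samples and no
#' ties in either variable, the two-sided p-value comes from full
#' enumeration of all `n!` rank permutations; otherwise from the
#' t-approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2`
#' degrees of freedom. Constant input yields `rho = NA`.
#'
#' @param x,y numeric vectors of equal length `n >= 3`.
#' @param exact_max largest n for exact enumeration (default 9).
#' @return A list with `rho`, `p`, `n`, `method`.
#' @export
spearman_correlation <- function(x, y, exact_max = 9L) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(rho = NA_real_, p = NA_real_, n = n, method = "degenerate"))
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  no_ties <- !anyDuplicated(x) && !anyDuplicated(y)
  if (n <= exact_max && no_ties) {
    d2_obs <- sum((rx - ry)^2)
    d2_null <- spearman_null_d2(n)
    # |rho| large <=> d2 far from its center n(n^2-1)/6
    center <- n * (n^2 - 1) / 6
    p <- mean(abs(d2_null - center) >= abs(d2_obs - center) - 1e-9)
    list(rho = rho, p = min(1, p), n = n, method = "exact")
  } else {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tstat), n - 2)
    }
    list(rho = rho, p = p, n = n, method = "t")
  }
}
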