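#' Mann-Whitney U test (exact small-sample behaviour)
#'
#' Rank-sum comparison of two independent samples. The U statistic is
#' computed from midranks (ties receive their average rank). When both
#' samples have at most `exact_cutoff` observations and the pooled sample
#' is tie-free, the p-value is exact, obtained by full enumeration of all
#' `choose(n_a + n_b, n_a)` assignments of the pooled ranks to group `a`;
#' otherwise the normal approximation with tie correction and continuity
#' correction is used.
#'
#' The reported statistic is `U_a`, the number of (a, b) pairs with
#' `a > b` (ties counting one half); `U_a + U_b = n_a * n_b` always.
#' One-sided alternatives follow the sample order: `"less"` tests whether
#' `a` tends to be smaller than `b` (small `U_a`), `"greater"` the reverse.
#'
#' @param a,b Numeric samples (non-empty).
#' @param sided `"two"` (default), `"greater"` or `"less"`.
#' @param exact_cutoff Largest per-group size for exact enumeration
#'   (default 8).
#' @return An `nprr_comparison` object: list with `statistic` (U_a),
#'   `p_value`, `method` (`"mann_whitney_exact"` or
#'   `"mann_whitney_normal"`), `n` (per-group sizes), `sided`, `stars`.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6), sided = "less")  # exact p = 0.05
#' @export
mann_whitney_u <- function(a, b, sided = c("two", "greater", "less"),
                           exact_cutoff = 8) {
  sided <- match.arg(sided)
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b) || anyNA(a) || anyNA(b)) {
    stop("Both samples must be non-empty and free of missing values.",
         call. = FALSE)
  }
  n_a <- length(a); n_b <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_a <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  has_ties <- anyDuplicated(pooled) > 0

  if (!has_ties && n_a <= exact_cutoff && n_b <= exact_cutoff) {
    p <- mw_exact_p(u_a, n_a, n_b, sided)
    method <- "mann_whitney_exact"
  } else {
    p <- mw_normal_p(u_a, r, n_a, n_b, sided)
    method <- "mann_whitney_normal"
  }
  new_comparison(statistic = u_a, statistic_name = "U",
                 p_value = p, method = method,
                 n = c(n_a = n_a, n_b = n_b), sided = sided)
}

# Exact null distribution of U by enumeration of all C(n_a + n_b, n_a)
# rank assignments (tie-free case). Cached per sample-size pair.
mw_null_cache <- new.env(parent = emptyenv())

mw_null_u <- function(n_a, n_b) {
  key <- paste(n_a, n_b, sep = "_")
  if (is.null(mw_null_cache[[key]])) {
    combos <- utils::combn(n_a + n_b, n_a)
    mw_null_cache[[key]] <- colSums(combos) - n_a * (n_a + 1) / 2
  }
  mw_null_cache[[key]]
}

mw_exact_p <- function(u_obs, n_a, n_b, sided) {
  u_all <- mw_null_u(n_a, n_b)
  total <- length(u_all)
  p_le <- sum(u_all <= u_obs + 1e-9) / total
  p_ge <- sum(u_all >= u_obs - 1e-9) / total
  switch(sided,
         less = p_le,
         greater = p_ge,
         two = min(1, 2 * min(p_le, p_ge)))
}

# Normal approximation with tie correction and continuity correction.
mw_normal_p <- function(u_obs, r, n_a, n_b, sided) {
  n <- n_a + n_b
  mu <- n_a * n_b / 2
  ties <- table(r)
  sigma2 <- n_a * n_b / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) {
    # all observations identical: no evidence either way
    return(1)
  }
  sigma <- sqrt(sigma2)
  z <- u_obs - mu
  cc <- switch(sided, two = sign(z) * 0.5, greater = 0.5, less = -0.5)
  z <- (z - cc) / sigma
  switch(sided,
         less = stats::pnorm(z),
         greater = stats::pnorm(z, lower.tail = FALSE),
         two = min(1, 2 * min(stats::pnorm(z),
                              stats::pnorm(z, lower.tail = FALSE))))
}

#' One-sample t test against a reference value
#'
#' Tests whether the mean of a sample differs from a specified value
#' (zero by default, as when normalised responses are compared to no
#' response): `t = (mean - mu0) / (sd / sqrt(n))` with `n - 1` degrees of
#' freedom.
#'
#' @param x Numeric sample with at least two values and positive variance.
#' @param mu0 Reference value (default 0).
#' @param sided `"two"` (default), `"greater"` or `"less"`.
#' @return An `nprr_comparison` object with the t statistic, `df`,
#'   `p_value` and `method = "one_sample_t"`.
#' @export
one_sample_t <- function(x, mu0 = 0, sided = c("two", "greater", "less")) {
  sided <- match.arg(sided)
  x <- as.numeric(x)
  if (length(x) < 2 || anyNA(x)) {
    stop("Need >= 2 non-missing observations.", call. = FALSE)
  }
  if (stats::sd(x) == 0) {
    stop("Degenerate sample: zero variance.", call. = FALSE)
  }
  alt <- switch(sided, two = "two.sided", greater = "greater", less = "less")
  ht <- stats::t.test(x, mu = mu0, alternative = alt)
  new_comparison(statistic = unname(ht$statistic), statistic_name = "t",
                 p_value = ht$p.value, method = "one_sample_t",
                 n = c(n = length(x)), sided = sided,
                 df = unname(ht$parameter), estimate = unname(ht$estimate),
                 mu0 = mu0)
}

new_comparison <- function(statistic, statistic_name, p_value, method, n,
                           sided, ...) {
  structure(
    list(statistic = statistic, statistic_name = statistic_name,
         p_value = p_value, method = method, n = n, sided = sided,
         stars = significance_stars(p_value), ...),
    class = "nprr_comparison"
  )
}

#' Significance stars
#'
#' Renders p-values with the conventional star notation: `*` for p < 0.05,
#' `**` for p < 0.01, `***` for p < 0.001, `****` for p < 0.0001 and
#' `"n.s."` otherwise.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Character vector of the same length.
#' @export
significance_stars <- function(p) {
  cut_pts <- c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf)
  labels <- c("****", "***", "**", "*", "n.s.")
  as.character(cut(p, cut_pts, labels = labels, right = FALSE))
}

#' @export
print.nprr_comparison <- function(x, ...) {
  cat(sprintf("<%s> %s = %.4g, p = %.4g %s (n = %s, %s-sided)\n",
              x$method, x$statistic_name, x$statistic, x$p_value, x$stars,
              paste(x$n, collapse = "/"), x$sided))
  invisible(x)
}

#' Tidy a comparison result
#'
#' @param x An `nprr_comparison` from [mann_whitney_u()] or
#'   [one_sample_t()].
#' @param ... Unused.
#' @return A one-row tibble with `method`, `statistic`, `p_value`,
#'   sample sizes, `sided` and `stars`.
#' @export
tidy.nprr_comparison <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    statistic = x$statistic,
    statistic_name = x$statistic_name,
    p_value = x$p_value,
    n = paste(x$n, collapse = "/"),
    sided = x$sided,
    stars = x$stars
  )
}

#' @rdname tidy.nprr_comparison
#' @export
glance.nprr_comparison <- function(x, ...) {
  tidy.nprr_comparison(x)
}
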