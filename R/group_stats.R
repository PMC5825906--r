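#' Mann-Whitney U test for two unpaired groups
#'
#' U is computed from rank sums with midranks for ties:
#' `U = R_a - n1 (n1 + 1) / 2` where `R_a` is the rank sum of the first
#' group, so `U(a, b) + U(b, a) = n1 * n2`. The two-sided p-value is exact
#' (full enumeration of the permutation null, via the exact U distribution)
#' when `n1 * n2 <= 400` and there are no ties, and otherwise uses the
#' normal approximation with tie correction and continuity correction.
#' Two-sided p is `min(1, 2 * one-sided)`.
#'
#' @param a,b numeric vectors (both non-empty).
#' @return a `group_comparison`: `n1`, `n2`, `U`, `p_two_sided`, `method`
#'   (`"exact"` or `"normal_approximation"`), and per-group `mean`/`sem`.
#' @export
mann_whitney <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) == 0L || length(b) == 0L)
    stop("both groups must be non-empty", call. = FALSE)
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- (n1 * n2 <= 400) && !ties
  p <- stats::wilcox.test(a, b, exact = exact, correct = TRUE)$p.value
  sa <- summarize_group(a); sb <- summarize_group(b)
  structure(list(n1 = n1, n2 = n2, U = U, p_two_sided = p,
                 method = if (exact) "exact" else "normal_approximation",
                 mean_a = sa[["mean"]], sem_a = sa[["sem"]],
                 mean_b = sb[["mean"]], sem_b = sb[["sem"]]),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    paste0("<group_comparison> n = %d vs %d, U = %g, p = %.4g (%s)\n",
           "  group A: %.4g +/- %.4g (mean +/- SEM)\n",
           "  group B: %.4g +/- %.4g\n"),
    x$n1, x$n2, x$U, x$p_two_sided, x$method,
    x$mean_a, x$sem_a, x$mean_b, x$sem_b))
  invisible(x)
}

#' Mean and standard error of the mean
#'
#' SEM is the sample standard deviation (n - 1 denominator) divided by
#' `sqrt(n)`; 0 for a single observation.
#'
#' @param x non-empty numeric vector.
#' @return named vector `c(mean, sem, n)`.
#' @export
summarize_group <- function(x) {
  x <- as.numeric(x)
  x <- x[!is.na(x)]
  if (length(x) == 0L) stop("group must be non-empty", call. = FALSE)
  n <- length(x)
  sem <- if (n == 1L) 0 else stats::sd(x) / sqrt(n)
  c(mean = mean(x), sem = sem, n = n)
}
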