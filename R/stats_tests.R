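## Common return shape for the test battery.
stat_test_result <- function(method, statistic, p_value, n, ...) {
  if (is.finite(p_value) && (p_value < 0 || p_value > 1)) {
    stop("internal error: p-value outside [0, 1]")
  }
  structure(c(list(method = method, statistic = statistic,
                   p_value = p_value, n = n), list(...)),
            class = "stat_test_result")
}

#' @export
print.stat_test_result <- function(x, ...) {
  cat(sprintf("<%s> statistic = %.4g, p = %.4g (n = %s)\n",
              x$method, x$statistic, x$p_value, paste(x$n, collapse = "/")))
  invisible(x)
}

#' Pearson chi-square test on a 2x2 contingency table
#'
#' Computes the Pearson chi-square statistic
#' `N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` on a 2x2 table of counts, with
#' 1 degree of freedom and a two-sided p-value.  The default applies no
#' continuity correction, which is the variant that reproduces the
#' demographic worked examples this package ships (e.g. a 4/6 vs 5/5 sex
#' split gives p = 0.653); Yates' correction is available as a flag.
#'
#' @param table 2x2 matrix of non-negative counts (rows = groups).
#' @param correct Apply Yates' continuity correction (default FALSE).
#' @return A `stat_test_result` with fields `statistic` (chi-square),
#'   `p_value`, `df`, `n`.
#' @export
chi_square_2x2 <- function(table, correct = FALSE) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2, 2))) stop("table must be 2x2")
  if (any(tab < 0)) stop("counts must be non-negative")
  rs <- rowSums(tab); cs <- colSums(tab); N <- sum(tab)
  if (any(rs == 0) || any(cs == 0)) stop("degenerate table: zero margin")
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  num <- abs(a * d - b * c)
  if (correct) num <- max(0, num - N / 2)
  stat <- N * num^2 / (rs[1] * rs[2] * cs[1] * cs[2])
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  stat_test_result(method = if (correct) "chi_square_yates" else "chi_square",
                   statistic = unname(stat), p_value = unname(p),
                   n = N, df = 1, correct = correct)
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison of two independent samples.  In
#' `"auto"` mode the exact null distribution is used when both samples have
#' at most 10 observations and there are no ties; otherwise the
#' tie-corrected normal approximation (no continuity correction) is used,
#' matching common statistical-package output at n = 10 per group.
#'
#' @param a,b Numeric samples.
#' @param mode `"auto"` (default), `"exact"`, or `"normal"`.
#' @return A `stat_test_result` with `statistic` = U for sample `a`,
#'   `p_value`, `n = c(length(a), length(b))`, `exact`, `tie_corrected`.
#' @export
mann_whitney <- function(a, b, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b)) stop("empty sample")
  if (any(!is.finite(c(a, b)))) stop("non-finite values")
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- switch(mode,
                  auto = length(a) <= 10 && length(b) <= 10 && !ties,
                  exact = TRUE,
                  normal = FALSE)
  if (exact && ties) stop("exact mode requires tie-free data")
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = FALSE)
  )
  stat_test_result(method = "mann_whitney",
                   statistic = unname(wt$statistic),
                   p_value = min(1, wt$p.value),
                   n = c(length(a), length(b)),
                   exact = exact, tie_corrected = !exact && ties)
}

#' Two-sided p-value for a Spearman coefficient via the t-approximation
#'
#' Converts a Spearman rank-correlation coefficient and sample size to a
#' two-sided p-value through `t = rho * sqrt((n - 2) / (1 - rho^2))` on
#' `n - 2` degrees of freedom.  This is the conversion that reproduces the
#' published qEEG worked examples (rho = 0.547, n = 20 gives p = 0.013).
#'
#' @param rho Spearman coefficient in `[-1, 1]`.
#' @param n Number of pairs (>= 4).
#' @return Two-sided p-value.
#' @export
spearman_p_from_rho <- function(rho, n) {
  if (abs(rho) > 1) stop("rho must be in [-1, 1]")
  if (n < 4) stop("need at least 4 pairs")
  if (abs(rho) >= 1) return(0)
  t <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * stats::pt(-abs(t), df = n - 2)
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Rho is the Pearson correlation of average ranks (ties allowed).  The
#' default p-value uses the t-approximation of [spearman_p_from_rho()];
#' `method = "exact"` enumerates all rank permutations (feasible for
#' n <= 8) and reports the fraction of permutations with `|rho|` at least
#' as large as observed.
#'
#' @param x,y Paired numeric vectors, n >= 4.
#' @param method `"t_approx"` (default) or `"exact"`.
#' @return A `stat_test_result` with `statistic` = rho, `p_value`, `n`.
#' @export
spearman_test <- function(x, y, method = c("t_approx", "exact")) {
  method <- match.arg(method)
  keep <- stats::complete.cases(x, y)
  x <- as.numeric(x[keep]); y <- as.numeric(y[keep])
  n <- length(x)
  if (n < 4) stop("need at least 4 complete pairs")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) stop("zero rank variance")
  rho <- stats::cor(rx, ry)
  p <- if (method == "t_approx") {
    spearman_p_from_rho(rho, n)
  } else {
    if (n > 8) stop("exact permutation p limited to n <= 8")
    perms <- permutations_of(n)
    obs <- abs(rho) - 1e-12
    mean(apply(perms, 1, function(pm) abs(stats::cor(rx, ry[pm])) >= obs))
  }
  stat_test_result(method = paste0("spearman_", method), statistic = rho,
                   p_value = p, n = n, rho = rho)
}

## All permutations of 1..n as a matrix (n! rows); recursion, small n only.
permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out[r + seq_len(nrow(sub)), ] <- cbind(k, matrix(rest[sub], nrow(sub)))
    r <- r + nrow(sub)
  }
  out
}

#' Independent two-sample t-tests at every frequency bin
#'
#' Compares the normalized power of two groups at each 0-50 Hz bin, per
#' channel, with a two-sided independent-samples t-test (pooled variance by
#' default, Welch as a flag).  Bins where both groups are constant are
#' flagged degenerate: the p-value is NA unless the constants are equal, in
#' which case t = 0 and p = 1.  An optional Benjamini-Hochberg adjusted
#' p-value column can be appended (an extension; the raw p-values are the
#' primary output).
#'
#' @param group_a,group_b Lists of `normalized_spectrum` (or
#'   `power_spectrum`) objects, one per participant; >= 2 per group.
#' @param var_equal Pooled-variance t-test (default TRUE); FALSE for Welch.
#' @param bh Append Benjamini-Hochberg adjusted p-values (default FALSE).
#' @return Data.frame: `channel`, `freq`, `mean_a`, `mean_b`, `t`, `df`,
#'   `p_value`, `degenerate` (+ `p_bh` if requested).
#' @export
per_frequency_ttest <- function(group_a, group_b, var_equal = TRUE, bh = FALSE) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("need at least 2 participants per group")
  }
  ra <- spectrum_values(group_a[[1]])
  rows <- list()
  for (ch in ra$labels) {
    ma <- vapply(group_a, function(sp) spectrum_values(sp)$values[ch, ],
                 numeric(length(ra$freqs)))
    mb <- vapply(group_b, function(sp) {
      s <- spectrum_values(sp)
      if (!identical(s$freqs, ra$freqs)) stop("frequency grids differ")
      s$values[ch, ]
    }, numeric(length(ra$freqs)))
    for (i in seq_along(ra$freqs)) {
      va <- ma[i, ]; vb <- mb[i, ]
      degenerate <- stats::var(va) == 0 && stats::var(vb) == 0
      if (degenerate) {
        tt <- if (mean(va) == mean(vb)) list(statistic = 0, parameter = NA_real_, p.value = 1)
              else list(statistic = NA_real_, parameter = NA_real_, p.value = NA_real_)
      } else {
        ht <- stats::t.test(va, vb, var.equal = var_equal)
        tt <- list(statistic = unname(ht$statistic),
                   parameter = unname(ht$parameter), p.value = ht$p.value)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        channel = ch, freq = ra$freqs[i], mean_a = mean(va), mean_b = mean(vb),
        t = tt$statistic, df = tt$parameter, p_value = tt$p.value,
        degenerate = degenerate, stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  if (bh) out$p_bh <- stats::p.adjust(out$p_value, method = "BH")
  out
}
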