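#' Forward stepwise linear regression with removal
#'
#' SPSS-style stepwise selection by ordinary least squares: at each step
#' the excluded candidate whose coefficient would have the smallest
#' p-value enters if that p-value is below `p_enter`; after each entry,
#' included predictors whose p-value has risen above `p_remove` are
#' removed (worst first).  With `p_enter = 1` and `p_remove = 1` the
#' procedure reproduces the full-entry OLS fit.
#'
#' Because published stepwise tables often print coefficients for *all*
#' candidates, the result carries both the selected model and the
#' full-entry model; the per-predictor table reports B, t, and p under
#' each.
#'
#' @param outcome Numeric response vector.
#' @param candidates Data.frame of candidate predictors (numeric columns).
#' @param p_enter Probability-of-F-to-enter threshold (default 0.05).
#' @param p_remove Probability-of-F-to-remove threshold (default 0.10).
#' @return An object of class `stepwise_fit`: list with `table`
#'   (per-predictor B/t/p for the full and selected models and a
#'   `selected` flag), `selected` (predictor names in the final model),
#'   `trace` (entry/removal order), `r_squared`, `r_squared_full`, and the
#'   two `lm` fits.
#' @export
stepwise_regression <- function(outcome, candidates, p_enter = 0.05,
                                p_remove = 0.10) {
  y <- as.numeric(outcome)
  X <- as.data.frame(candidates)
  if (!all(vapply(X, is.numeric, logical(1)))) {
    stop("all candidate columns must be numeric")
  }
  if (length(y) != nrow(X)) stop("outcome and candidates differ in length")
  keep <- stats::complete.cases(y, X)
  y <- y[keep]; X <- X[keep, , drop = FALSE]
  n <- length(y); p <- ncol(X)
  if (n <= p + 1) stop("need n > number of candidates + 1")
  qrX <- qr(cbind(1, as.matrix(X)))
  if (qrX$rank < p + 1) {
    pivot_dropped <- qrX$pivot[(qrX$rank + 1):(p + 1)] - 1L
    stop(sprintf("rank-deficient candidate matrix; offending column(s): %s",
                 paste(names(X)[pivot_dropped], collapse = ", ")))
  }
  dat <- cbind(.y = y, X)

  fit_with <- function(vars) {
    fml <- if (length(vars)) {
      stats::reformulate(sprintf("`%s`", vars), response = ".y")
    } else {
      .y ~ 1
    }
    stats::lm(fml, data = dat)
  }
  coef_p <- function(fit, var) {
    s <- summary(fit)$coefficients
    rn <- sub("^`|`$", "", rownames(s))
    s[match(var, rn), , drop = FALSE]
  }

  included <- character(0)
  trace <- list()
  max_steps <- 10L * (p + 1L)   # guards against enter/remove cycling
  repeat {
    if (length(trace) >= max_steps) break
    changed <- FALSE
    ## entry scan
    excluded <- setdiff(names(X), included)
    if (length(excluded)) {
      ps <- vapply(excluded, function(v) {
        fit <- fit_with(c(included, v))
        coef_p(fit, v)[1, 4]
      }, numeric(1))
      if (min(ps) < p_enter || (p_enter >= 1 && min(ps) <= 1)) {
        enter <- excluded[which.min(ps)]
        included <- c(included, enter)
        trace[[length(trace) + 1L]] <- list(action = "enter", variable = enter,
                                            p = unname(min(ps)))
        changed <- TRUE
      }
    }
    ## removal scan
    repeat {
      if (length(included) == 0) break
      fit <- fit_with(included)
      ps <- vapply(included, function(v) coef_p(fit, v)[1, 4], numeric(1))
      if (max(ps) > p_remove) {
        drop <- included[which.max(ps)]
        included <- setdiff(included, drop)
        trace[[length(trace) + 1L]] <- list(action = "remove", variable = drop,
                                            p = unname(max(ps)))
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }

  fit_sel <- fit_with(included)
  fit_full <- fit_with(names(X))
  tab <- data.frame(predictor = names(X),
                    B_full = NA_real_, t_full = NA_real_, p_full = NA_real_,
                    B_selected = NA_real_, t_selected = NA_real_,
                    p_selected = NA_real_,
                    selected = names(X) %in% included,
                    stringsAsFactors = FALSE)
  for (i in seq_len(p)) {
    cf <- coef_p(fit_full, names(X)[i])
    tab$B_full[i] <- cf[1, 1]; tab$t_full[i] <- cf[1, 3]; tab$p_full[i] <- cf[1, 4]
    if (tab$selected[i]) {
      cs <- coef_p(fit_sel, names(X)[i])
      tab$B_selected[i] <- cs[1, 1]; tab$t_selected[i] <- cs[1, 3]
      tab$p_selected[i] <- cs[1, 4]
    }
  }
  structure(
    list(table = tab, selected = included, trace = trace,
         r_squared = summary(fit_sel)$r.squared,
         r_squared_full = summary(fit_full)$r.squared,
         fit_selected = fit_sel, fit_full = fit_full,
         p_enter = p_enter, p_remove = p_remove, n = n),
    class = "stepwise_fit"
  )
}

#' @export
print.stepwise_fit <- function(x, ...) {
  cat(sprintf("<stepwise_fit> n = %d; selected: %s; R^2 = %.3f (full %.3f)\n",
              x$n,
              if (length(x$selected)) paste(x$selected, collapse = ", ") else "(none)",
              x$r_squared, x$r_squared_full))
  print(x$table, digits = 4)
  invisible(x)
}
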