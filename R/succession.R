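#' Fit the logistic succession model of stability vs restoration age
#'
#' Nonlinear least-squares fit of \eqn{D(t) = K / (1 + a e^{-r t})}: K is
#' the stability asymptote (D units), a the shape (initial deficit) and r
#' the succession rate (1/years). Initialisation runs a deterministic
#' multi-start grid (a in \{1, 5, 20, 100\}, r in \{0.1, 0.5, 1, 2\}, K in
#' \{max(D), 1\}) and keeps the converged fit with the smallest SSE.
#' Natural-reference sites have no restoration age and must be excluded by
#' the caller.
#'
#' @param ages restoration ages in years (>= 4 distinct values).
#' @param D stability scores in (0, 1\].
#' @return object of class `"logistic_fit"`: `K`, `a`, `r`, `R2`, `sse`,
#'   `fitted`, `residuals`, `n`, `converged`, `degenerate`, plus the data.
#' @export
fit_logistic <- function(ages, D) {
  stopifnot(length(ages) == length(D))
  if (length(unique(ages)) < 4L)
    stop("need >= 4 distinct ages", call. = FALSE)
  if (any(D <= 0) || any(D > 1))
    stop("D values must lie in (0, 1]", call. = FALSE)
  sst <- sum((D - mean(D))^2)
  if (sst == 0) {
    return(structure(list(K = mean(D), a = NA_real_, r = NA_real_,
                          R2 = 0, sse = 0, fitted = rep(mean(D), length(D)),
                          residuals = rep(0, length(D)), n = length(D),
                          converged = FALSE, degenerate = TRUE,
                          ages = ages, D = D), class = "logistic_fit"))
  }
  dat <- data.frame(t = ages, y = D)
  starts <- expand.grid(K = c(max(D), 1), a = c(1, 5, 20, 100),
                        r = c(0.1, 0.5, 1, 2))
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ K / (1 + a * exp(-r * t)), data = dat,
                        start = as.list(starts[s, ]),
                        lower = c(K = 1e-6, a = 1e-9, r = 1e-6),
                        upper = c(K = 1.5, a = 1e9, r = 50),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(stats::resid(fit)^2)
    if (is.null(best) || sse < best$sse - 1e-12) {
      best <- list(fit = fit, sse = sse)
    }
  }
  if (is.null(best))
    stop("logistic fit failed to converge from every start; ",
         "n = ", length(D), ", D range = [",
         signif(min(D), 3), ", ", signif(max(D), 3), "]", call. = FALSE)
  cf <- stats::coef(best$fit)
  structure(list(K = unname(cf["K"]), a = unname(cf["a"]),
                 r = unname(cf["r"]),
                 R2 = 1 - best$sse / sst, sse = best$sse,
                 fitted = stats::fitted(best$fit),
                 residuals = stats::resid(best$fit), n = length(D),
                 converged = TRUE, degenerate = FALSE,
                 ages = ages, D = D), class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  if (x$degenerate) {
    cat("Degenerate logistic fit: constant D =", signif(x$K, 4), "\n")
  } else {
    cat(sprintf("D(t) = %.4g / (1 + %.4g * exp(-%.4g t)); R2 = %.4f (n = %d)\n",
                x$K, x$a, x$r, x$R2, x$n))
  }
  invisible(x)
}

#' Significance of a logistic succession fit
#'
#' F-test of the three-parameter logistic model against the intercept-only
#' (constant-stability) model:
#' \eqn{F = ((SST - SSE)/2) / (SSE/(n - 3))}. A perfect fit (SSE = 0) is
#' reported at the numerical floor; a degenerate fit has no defined p.
#'
#' @param fit a `"logistic_fit"`.
#' @return list with `F`, `p`, `df` (c(2, n - 3)).
#' @export
logistic_significance <- function(fit) {
  stopifnot(inherits(fit, "logistic_fit"))
  if (fit$degenerate)
    return(list(F = NaN, p = NaN, df = c(2, fit$n - 3)))
  sst <- sum((fit$D - mean(fit$D))^2)
  df2 <- fit$n - 3
  if (df2 <= 0) stop("too few points for a significance test", call. = FALSE)
  if (fit$sse == 0)
    return(list(F = Inf, p = .Machine$double.xmin, df = c(2, df2)))
  f <- ((sst - fit$sse) / 2) / (fit$sse / df2)
  list(F = f, p = stats::pf(f, 2, df2, lower.tail = FALSE), df = c(2, df2))
}

#' Logistic succession fits per mine
#'
#' Fits the succession model to each mine's restoration sites (natural
#' references excluded: they have no restoration age).
#'
#' @param stability data.frame from [stability_pipeline()] (needs
#'   `mine_id`, `age`, `D`, `is_reference`).
#' @return data.frame per mine: `mine_id`, `K`, `a`, `r`, `R2`, `p`, `n`.
#' @export
succession_table <- function(stability) {
  need <- c("mine_id", "age", "D", "is_reference")
  stopifnot(all(need %in% names(stability)))
  ra <- stability[!stability$is_reference, ]
  out <- lapply(split(ra, ra$mine_id), function(d) {
    fit <- fit_logistic(d$age, d$D)
    sig <- logistic_significance(fit)
    data.frame(mine_id = d$mine_id[1], K = fit$K, a = fit$a, r = fit$r,
               R2 = fit$R2, p = sig$p, n = fit$n)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
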