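#' Fit pan- and core-genome growth models
#'
#' Fits the conventional pan-genome power law `P(k) = A_p * k^B_p + C_p`
#' to the median pan sizes and the exponential decay
#' `C(k) = A_c * exp(-B_c * k) + C_c` to the median core sizes, by
#' Levenberg-Marquardt least squares (`minpack.lm::nlsLM`).  Starting
#' values are deterministic (amplitude from the median range, pan exponent
#' from the log-log slope, core rate 0.5, offset from the last median)
#' with a fixed ladder of jittered restarts, so the fit is reproducible.
#' A constant curve short-circuits to the exact degenerate solution
#' (amplitude 0, offset = the constant).
#'
#' @param result A `rarefaction_result` (or list with `k`, `pan_median`,
#'   `core_median`).
#' @param n_restarts Number of deterministic jittered restarts (default 10).
#' @return Object of class `growth_model_fit`: list with `pan`
#'   (`A`, `B`, `C`, `rss`, `converged`) and `core` (same fields), plus
#'   `pan_fitted`/`core_fitted` over the observed k.
#' @export
fit_growth_models <- function(result, n_restarts = 10L) {
  k <- result$k
  if (length(k) < 4L) stop("need at least 4 subset sizes to fit", call. = FALSE)
  pan <- fit_one_growth(k, result$pan_median, model = "power", n_restarts)
  core <- fit_one_growth(k, result$core_median, model = "expdecay", n_restarts)
  structure(
    list(pan = pan$par, core = core$par,
         pan_fitted = pan$fitted, core_fitted = core$fitted, k = k),
    class = "growth_model_fit"
  )
}

growth_predict <- function(model, k, A, B, C) {
  if (model == "power") A * k^B + C else A * exp(-B * k) + C
}

fit_one_growth <- function(k, y, model, n_restarts) {
  rng <- diff(range(y))
  if (rng < .Machine$double.eps * max(1, abs(y[1L]))) {
    par <- list(A = 0, B = if (model == "power") 1 else 0.5, C = y[1L],
                rss = 0, converged = TRUE)
    return(list(par = par, fitted = rep(y[1L], length(k))))
  }
  # deterministic starts
  A0 <- if (model == "power") rng else max(rng, y[1L] - y[length(y)])
  B0 <- if (model == "power") {
    dy <- diff(y)
    slope <- tryCatch(
      stats::coef(stats::lm(log(pmax(dy, 1e-9)) ~ log(k[-1L])))[[2L]] + 1,
      error = function(e) 0.5)
    min(max(slope, 0.05), 1.5)
  } else 0.5
  C0 <- y[length(y)]
  # fixed jitter ladder: restart r scales (A, B) by deterministic factors
  jit <- c(1, 0.5, 2, 0.25, 4, 0.75, 1.5, 0.1, 3, 0.9)[seq_len(n_restarts)]
  best <- NULL
  dat <- data.frame(k = k, y = y)
  form <- if (model == "power") y ~ A * k^B + C else y ~ A * exp(-B * k) + C
  for (j in jit) {
    fit <- tryCatch(
      minpack.lm::nlsLM(form, data = dat,
                        start = list(A = A0 * j, B = B0 * j, C = C0),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12) {
      cf <- stats::coef(fit)
      best <- list(A = cf[["A"]], B = cf[["B"]], C = cf[["C"]], rss = rss,
                   converged = TRUE)
    }
  }
  if (is.null(best)) {
    # flagged fit: best attempt is the deterministic start itself
    best <- list(A = A0, B = B0, C = C0,
                 rss = sum((y - growth_predict(model, k, A0, B0, C0))^2),
                 converged = FALSE)
  }
  list(par = best,
       fitted = growth_predict(model, k, best$A, best$B, best$C))
}

#' @export
print.growth_model_fit <- function(x, ...) {
  cat("<growth_model_fit>\n")
  cat(sprintf("  pan : P(k) = %.4g * k^%.4g + %.4g   (RSS %.4g%s)\n",
              x$pan$A, x$pan$B, x$pan$C, x$pan$rss,
              if (x$pan$converged) "" else ", NOT converged"))
  cat(sprintf("  core: C(k) = %.4g * exp(-%.4g k) + %.4g   (RSS %.4g%s)\n",
              x$core$A, x$core$B, x$core$C, x$core$rss,
              if (x$core$converged) "" else ", NOT converged"))
  invisible(x)
}
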