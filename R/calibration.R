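#' Root mean square error
#'
#' `sqrt(mean((observed - simulated)^2))`, the standard crop-model
#' goodness-of-fit measure, in the units of the compared quantity.
#'
#' @param observed,simulated Numeric vectors of equal, nonzero length.
#' @return RMSE (>= 0).
#' @export
rmse <- function(observed, simulated) {
  if (length(observed) != length(simulated)) stop("length mismatch")
  if (length(observed) == 0L) stop("empty input")
  sqrt(mean((observed - simulated)^2))
}

#' Relative error of simulated versus observed values (percent)
#'
#' Default form is the root-mean-square relative deviation,
#' `100 * sqrt(mean(((observed - simulated)/simulated)^2))`; the
#' `"absolute"` form is the mean absolute relative deviation times 100.
#'
#' @param observed,simulated Numeric vectors of equal length; simulated
#'   values must be nonzero.
#' @param form `"rms"` (default) or `"absolute"`.
#' @return Relative error in percent.
#' @export
relative_error <- function(observed, simulated, form = c("rms", "absolute")) {
  form <- match.arg(form)
  if (length(observed) != length(simulated)) stop("length mismatch")
  if (any(simulated == 0)) stop("zero simulated value")
  r <- (observed - simulated) / simulated
  100 * switch(form, rms = sqrt(mean(r^2)), absolute = mean(abs(r)))
}

#' Fit the logistic potential-quality curve to observed data
#'
#' Least-squares fit of `q_max / (1 + exp(-k (t - t_m)))` to quality-vs-age
#' observations by bounded Levenberg-Marquardt, restarted from three
#' deterministic initial points (the optimizer keeps the best). Bounds:
#' `q_max` in (0, 2 max(value)], `k` in (0, 2], `t_m` in (0, 120].
#'
#' @param age Fruit ages, physiological days since squaring (>= 0).
#' @param value Observed quality values (> 0); at least 3 points spanning
#'   more than one distinct value.
#' @return List of class `logistic_fit`: `estimate` (named q_max, k, t_m),
#'   `se` (standard errors), `r_squared`, `rmse`, `fitted`, `n`, and the
#'   underlying `nls` object as `fit`.
#' @export
fit_logistic <- function(age, value) {
  if (length(age) != length(value)) stop("length mismatch")
  if (length(age) < 3L) stop("under-determined: need at least 3 points")
  if (any(age < 0)) stop("ages must be non-negative")
  if (any(value <= 0)) stop("values must be positive")
  if (length(unique(value)) < 2L) stop("degenerate constant series")
  dat <- data.frame(t = age, y = value)
  upper <- c(q_max = 2 * max(value), k = 2, t_m = 120)
  lower <- c(q_max = 1e-8, k = 1e-8, t_m = 1e-8)
  starts <- list(
    c(q_max = max(value), k = 0.1, t_m = stats::median(age)),
    c(q_max = 1.1 * max(value), k = 0.3, t_m = mean(age)),
    c(q_max = 1.5 * max(value), k = 0.05,
      t_m = unname(stats::quantile(age, 0.75))))
  best <- NULL
  errs <- character()
  for (st in starts) {
    st <- pmin(pmax(st, lower), upper)
    f <- tryCatch(
      minpack.lm::nlsLM(y ~ q_max / (1 + exp(-k * (t - t_m))), data = dat,
                        start = as.list(st), lower = lower, upper = upper,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) e)
    if (inherits(f, "error")) { errs <- c(errs, conditionMessage(f)); next }
    if (is.null(best) || stats::deviance(f) < stats::deviance(best)) best <- f
  }
  if (is.null(best))
    stop("logistic fit failed to converge from all starts: ",
         paste(unique(errs), collapse = "; "))
  est <- stats::coef(best)
  sm <- summary(best)
  fitted <- stats::fitted(best)
  ss_res <- sum((value - fitted)^2)
  ss_tot <- sum((value - mean(value))^2)
  structure(list(estimate = est, se = sm$coefficients[, "Std. Error"],
                 r_squared = 1 - ss_res / ss_tot,
                 rmse = rmse(value, fitted),
                 fitted = fitted, n = length(value), fit = best),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("Logistic potential-quality fit (n =", x$n, ")\n")
  for (p in names(x$estimate))
    cat(sprintf("  %-6s %8.4f  (SE %.4f)\n", p, x$estimate[[p]], x$se[[p]]))
  cat(sprintf("  R^2 = %.4f, RMSE = %.4f\n", x$r_squared, x$rmse))
  invisible(x)
}

#' Read an observed quality-vs-age series
#'
#' CSV with columns `age_pdays, index, value`: fruit age in physiological
#' days, the quality index name, and the observed value.
#'
#' @param path CSV path.
#' @return Data frame with those three columns.
#' @export
read_quality_series <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("age_pdays", "index", "value")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(x) == 0L) stop("no records in ", path)
  x
}

#' Calibrate the three quality indices from an observed series
#'
#' Fits the logistic potential curve separately to each index present in the
#' series and assembles a [quality_params] set (reduction-factor coefficients
#' keep their defaults; they are calibrated from multi-site temperature
#' experiments, not from quality-vs-age data).
#'
#' @param series Data frame from [read_quality_series()].
#' @param base Parameter set supplying values for indices absent from the
#'   series and all factor coefficients.
#' @return List with `params` (a [quality_params]) and `fits` (per-index
#'   `logistic_fit`s).
#' @export
calibrate_quality <- function(series, base = quality_params()) {
  idx <- intersect(c("length", "strength", "micronaire"), unique(series$index))
  if (length(idx) == 0L) stop("series contains no recognised quality index")
  fits <- lapply(stats::setNames(nm = idx), function(i) {
    s <- series[series$index == i, ]
    fit_logistic(s$age_pdays, s$value)
  })
  q_max <- base$q_max; k <- base$k; t_m <- base$t_m
  for (i in idx) {
    q_max[[i]] <- unname(fits[[i]]$estimate[["q_max"]])
    k[[i]] <- unname(fits[[i]]$estimate[["k"]])
    t_m[[i]] <- unname(fits[[i]]$estimate[["t_m"]])
  }
  list(params = quality_params(q_max = q_max, k = k, t_m = t_m,
                               length_mean_coef = base$length_mean_coef,
                               strength_mean_coef = base$strength_mean_coef,
                               strength_td_coef = base$strength_td_coef,
                               micronaire_tmin_coef = base$micronaire_tmin_coef),
       fits = fits)
}
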