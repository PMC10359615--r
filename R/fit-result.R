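#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL

new_apekin_fit <- function(model, params, se, residual_ss, converged,
                           warnings = character(), data = NULL,
                           predict_fun = NULL, extra = list()) {
  structure(
    c(
      list(
        model = model,
        params = params,
        se = se,
        residual_ss = residual_ss,
        converged = converged,
        warnings = warnings,
        data = data,
        predict_fun = predict_fun
      ),
      extra
    ),
    class = c(paste0("apekin_", model, "_fit"), "apekin_fit")
  )
}

#' @export
print.apekin_fit <- function(x, digits = 4, ...) {
  cat(sprintf("<apekin %s fit>%s\n", x$model,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  print(tidy(x), n = Inf)
  if (length(x$warnings)) {
    cat("warnings:", paste(x$warnings, collapse = "; "), "\n")
  }
  invisible(x)
}

#' Tidy a fitted apekin model
#'
#' @param x An `apekin_fit` object.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`.
#' @export
tidy.apekin_fit <- function(x, ...) {
  tibble::tibble(
    term = names(x$params),
    estimate = unname(unlist(x$params)),
    std.error = unname(x$se[names(x$params)])
  )
}

#' One-row model summary for a fitted apekin model
#'
#' @param x An `apekin_fit` object.
#' @param ... Unused.
#' @return A one-row tibble with `model`, `residual_ss`, `n`, `converged`
#'   and the collapsed warning string (empty if none).
#' @export
glance.apekin_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model,
    residual_ss = x$residual_ss,
    n = if (is.null(x$data)) NA_integer_ else nrow(x$data),
    converged = x$converged,
    warnings = paste(x$warnings, collapse = "; ")
  )
}

#' Observations with fitted values and residuals
#'
#' @param x An `apekin_fit` carrying its training data.
#' @param ... Unused.
#' @return The model data with `.fitted` and `.resid` columns appended.
#' @export
augment.apekin_fit <- function(x, ...) {
  if (is.null(x$data) || is.null(x$predict_fun)) {
    stop("fit carries no data to augment", call. = FALSE)
  }
  d <- tibble::as_tibble(x$data)
  d$.fitted <- x$predict_fun(d[[1]])
  d$.resid <- d[[2]] - d$.fitted
  d
}

#' @export
coef.apekin_fit <- function(object, ...) {
  unlist(object$params)
}

has_fit_warning <- function(fit, what) {
  any(grepl(what, fit$warnings, fixed = TRUE))
}

# Levenberg-Marquardt least squares on log-transformed (positive) parameters
# with jittered multi-start. `fn(par, x)` evaluates the model at the natural
# scale; residuals are unweighted (gel/plate quantification practice).
nls_positive <- function(x, y, fn, start, n_starts = 5, jitter_sd = 0.4,
                         seed = NULL) {
  start <- pmax(start, 1e-12)
  resid_fun <- function(lp) y - fn(exp(lp), x)
  one_fit <- function(lp0) {
    tryCatch(
      minpack.lm::nls.lm(
        par = lp0, fn = resid_fun,
        control = minpack.lm::nls.lm.control(maxiter = 400)
      ),
      error = function(e) NULL
    )
  }
  best <- one_fit(log(start))
  ok <- function(f) !is.null(f) && f$info %in% 1:4
  if (!ok(best)) {
    jitters <- withr::with_seed(
      if (is.null(seed)) 101L else as.integer(seed),
      replicate(n_starts, stats::rnorm(length(start), 0, jitter_sd),
                simplify = FALSE)
    )
    for (j in jitters) {
      cand <- one_fit(log(start) + j)
      if (ok(cand) && (!ok(best) || cand$deviance < best$deviance)) {
        best <- cand
      }
    }
  }
  if (is.null(best)) {
    return(list(converged = FALSE, par = start, se = rep(NA_real_, length(start)),
                deviance = NA_real_))
  }
  par <- exp(best$par)
  se <- tryCatch(
    {
      sm <- summary(best)
      # delta method: se on natural scale from se of log-parameter
      par * sm$coefficients[, "Std. Error"]
    },
    error = function(e) rep(NA_real_, length(par))
  )
  names(par) <- names(start)
  names(se) <- names(start)
  list(
    converged = best$info %in% 1:4,
    par = par,
    se = se,
    deviance = best$deviance
  )
}

# Wald-Wolfowitz runs test on residual signs (one-sided: fewer runs than
# expected under randomness indicates systematic lack of fit).
runs_test_pvalue <- function(resid) {
  s <- sign(resid)
  s <- s[s != 0]
  n1 <- sum(s > 0)
  n2 <- sum(s < 0)
  if (n1 == 0 || n2 == 0) return(0)
  runs <- 1 + sum(diff(s) != 0)
  n <- n1 + n2
  mu <- 2 * n1 * n2 / n + 1
  v <- 2 * n1 * n2 * (2 * n1 * n2 - n) / (n^2 * (n - 1))
  if (v <= 0) return(1)
  stats::pnorm((runs - mu) / sqrt(v))
}

check_timecourse <- function(data, regime = NULL) {
  data <- tibble::as_tibble(data)
  if (!all(c("time_s", "product_nM") %in% names(data))) {
    stop("time course needs columns time_s and product_nM", call. = FALSE)
  }
  if (any(data$time_s < 0) || any(data$product_nM < 0)) {
    stop("time course values must be non-negative", call. = FALSE)
  }
  if (length(unique(data$time_s)) < 6) {
    stop("need at least 6 distinct time points to fit", call. = FALSE)
  }
  reg <- attr(data, "design")$regime
  if (!is.null(regime) && !is.null(reg) && !identical(reg, regime)) {
    stop(sprintf("data regime is '%s', expected '%s'", reg, regime),
         call. = FALSE)
  }
  data
}
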