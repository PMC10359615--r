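#' Aggregate replicate measurements
#'
#' Mean, sample standard deviation and standard error of the mean across
#' independent replicates. Kinetic assays here report the average of at
#' least three independent experiments plus/minus standard error; two
#' replicates are accepted with a warning.
#'
#' @param values Numeric vector of replicate values, length >= 2.
#' @return A one-row tibble with `mean`, `sd`, `sem`, `n`.
#' @examples
#' aggregate_replicates(c(1, 2, 3))
#' @export
aggregate_replicates <- function(values) {
  n <- length(values)
  if (n < 2) stop("need at least 2 replicates", call. = FALSE)
  if (n == 2) {
    warning("only 2 replicates; at least 3 independent experiments are the norm",
            call. = FALSE)
  }
  s <- stats::sd(values)
  tibble::tibble(mean = mean(values), sd = s, sem = s / sqrt(n), n = n)
}

#' Fold change with first-order error propagation
#'
#' Central fold change as in [fold_change()], with a standard error from
#' first-order propagation of the ratio:
#' \eqn{se_{fold} = fold \sqrt{(se_{ref}/ref)^2 + (se_{val}/val)^2}.}
#'
#' @param ref,val Rates, s^-1 (> 0).
#' @param ref_se,val_se Their standard errors (>= 0).
#' @return A tibble with `fold`, `direction`, `fold_se`.
#' @examples
#' fold_change_with_error(129, 24, 10, 1)
#' @export
fold_change_with_error <- function(ref, ref_se, val, val_se) {
  check_nonneg(ref_se, "ref_se")
  check_nonneg(val_se, "val_se")
  fc <- fold_change(ref, val)
  fc$fold_se <- fc$fold * sqrt((ref_se / ref)^2 + (val_se / val)^2)
  fc
}
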