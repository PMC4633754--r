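#' Confirmation rate of assessed predictions
#'
#' The success statistic used when predictions are scored by expert
#' assessment or growth experiments: confirmed cases over assessed cases,
#' as a percentage by default.
#'
#' @param n_confirmed Number of predictions confirmed (assessed positive,
#'   grown, or verified in the literature).
#' @param n_assessed Total number assessed.
#' @param percent Return a percentage (default) rather than a fraction.
#' @return Numeric rate.
#' @examples
#' confirmation_rate(873, 1354)   # curator confirmation, ~64%
#' @export
confirmation_rate <- function(n_confirmed, n_assessed, percent = TRUE) {
  if (n_assessed <= 0 || n_confirmed < 0 || n_confirmed > n_assessed) {
    abort("Need 0 <= n_confirmed <= n_assessed with n_assessed > 0.")
  }
  rate <- n_confirmed / n_assessed
  if (percent) 100 * rate else rate
}
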