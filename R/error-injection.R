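# Controlled perturbation of calibration ages. The experiment's independent
# variable is an error level: at level p, each training age is multiplied by
# (1 + u) with u uniform on [-p/100, +p/100], so a sample's recorded age can
# move up to p% away from its true age in either direction, independently
# per sample. 100% is the admissible maximum: a larger level could produce
# negative ages.

#' Inject bounded relative error into an age vector
#'
#' Each age is independently perturbed to `age * (1 + u)` with
#' `u ~ Uniform(-percent/100, +percent/100)`. The perturbation never exceeds
#' `percent`% of the true age, and every perturbed age stays non-negative.
#' Only the stated bound constrains the perturbation; within it the uniform
#' law is the least-informative choice and is isolated here so an
#' alternative could be swapped in.
#'
#' @param ages Numeric vector of positive ages.
#' @param percent Error level in `[0, 100]`.
#' @param seed Integer seed for a reproducible draw (NULL draws from the
#'   current RNG stream, giving fresh independent noise per call).
#' @return Perturbed age vector, same length and names as `ages`.
#' @export
#' @examples
#' inject_age_error(c(10, 50), percent = 10, seed = 1)
inject_age_error <- function(ages, percent, seed = NULL) {
  if (!is.numeric(ages) || length(ages) == 0L || anyNA(ages)) {
    stop_data("`ages` must be a non-empty numeric vector without missing values.")
  }
  if (any(ages <= 0)) {
    stop_data("All ages must be positive; relative perturbation is undefined otherwise.")
  }
  if (!is.numeric(percent) || length(percent) != 1L || is.na(percent)) {
    stop_config("`percent` must be a single number.")
  }
  if (percent < 0 || percent > 100) {
    stop_config(sprintf(
      "Error level must be in [0, 100] (got %s); levels above 100%% would permit negative ages.",
      format(percent)))
  }
  check_seed(seed)
  if (percent == 0) return(ages)
  a <- percent / 100
  u <- with_seed_or_rng(seed, runif(length(ages), -a, a))
  ages * (1 + u)
}
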