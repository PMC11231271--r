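#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data abort warn inform %||%
#' @importFrom stats lm coef predict quantile sd cor rnorm runif rpois rexp
#'   t.test pt complete.cases
#' @importFrom utils head tail
NULL

# Deterministic substream seed: one master integer fans out into named
# streams so toggling one stage never shifts another's randomness.
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(name) * (seq_along(utf8ToInt(name)) + 31L))
  as.integer((abs(seed) * 48271 + h * 2654435.0) %% 2147483647)
}

# Round half away from zero at `digits` decimals (the convention that
# reproduces published 2-dp transport tables; base round() is half-to-even).
round_half_away <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# Population (n-denominator) standard deviation.
sd_pop <- function(x) {
  x <- x[!is.na(x)]
  sqrt(mean((x - mean(x))^2))
}

month_start <- function(date) lubridate::floor_date(date, "month")
week_start <- function(date) lubridate::floor_date(date, "week", week_start = 1)

days_elapsed <- function(date, origin = min(date)) as.numeric(date - origin)

# AR(1) noise vector, mean zero, innovation scaled so the marginal sd is
# `sd_marginal` regardless of rho.
ar1_noise <- function(n, rho, sd_marginal) {
  if (sd_marginal <= 0 || n == 0L) return(rep(0, n))
  innov_sd <- sd_marginal * sqrt(max(1 - rho^2, 1e-12))
  x <- numeric(n)
  x[1] <- rnorm(1, 0, sd_marginal)
  if (n > 1) for (i in 2:n) x[i] <- rho * x[i - 1] + rnorm(1, 0, innov_sd)
  x
}

# Shared validation: strictly increasing dates, no duplicates.
check_dates <- function(date, what = "table") {
  if (anyDuplicated(date)) {
    abort(sprintf("Duplicate dates in %s: %s", what,
                  paste(head(format(date[duplicated(date)]), 3), collapse = ", ")),
          class = "carbonsplit_integrity_error")
  }
  if (is.unsorted(date, strictly = TRUE)) {
    abort(sprintf("Dates in %s are not strictly increasing; refusing to reorder.", what),
          class = "carbonsplit_integrity_error")
  }
  invisible(date)
}

`%na0%` <- function(x, y) ifelse(is.na(x), y, x)
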