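#' Rescale a percentage indicator to the unit interval
#'
#' @param values numeric vector in \[0, 100\].
#' @return `values / 100`.
#' @export
scale_percentage <- function(values) {
  if (any(values < 0 | values > 100, na.rm = TRUE)) {
    stop("percentage values must lie in [0, 100]")
  }
  values / 100
}

#' 90% winsorization
#'
#' Clamps every value to the interval \[P5, P95\], where the percentiles are
#' computed from the data by linear interpolation between order statistics
#' (`stats::quantile` type 7, the project-wide convention). Limits the
#' influence of extreme values before rescaling an unbounded indicator.
#'
#' @param values numeric vector with at least 2 finite values.
#' @return Clamped vector, in the input order.
#' @export
winsorize_90 <- function(values) {
  if (sum(is.finite(values)) < 2L) {
    stop("winsorization needs at least 2 finite values")
  }
  q <- stats::quantile(values, c(0.05, 0.95), type = 7, names = FALSE,
                       na.rm = TRUE)
  pmin(pmax(values, q[1]), q[2])
}

#' Rescale an unbounded (already winsorized) indicator by its maximum
#'
#' Divides each value by the series maximum so the result lies in \[0, 1\]
#' and attains 1 at the maximum; when winsorization clipped the top of the
#' series, 1 corresponds to the 95th-percentile cap.
#'
#' @param values numeric vector with positive maximum.
#' @return `values / max(values)`.
#' @export
rescale_unbounded <- function(values) {
  m <- max(values, na.rm = TRUE)
  if (!is.finite(m) || m <= 0) {
    stop("cannot rescale a series whose maximum is not positive")
  }
  values / m
}

#' Transform a raw indicator onto the 0-1 integrity scale
#'
#' Dispatches on the indicator's scale kind: percentages are divided by 100;
#' already-unit indices (e.g. national watershed/catchment integrity
#' indices) are validated and passed through; unbounded indicators (e.g.
#' upstream road-crossing counts) are 90%-winsorized and then divided by
#' their post-winsorization maximum. Only unbounded series are winsorized.
#'
#' @param values numeric vector of raw indicator values.
#' @param scale_kind `"percentage"`, `"unbounded"` or `"already_unit"`.
#' @return Numeric vector in \[0, 1\].
#' @export
scale_indicator <- function(values,
                            scale_kind = c("percentage", "unbounded",
                                           "already_unit")) {
  scale_kind <- match.arg(scale_kind)
  switch(scale_kind,
         percentage = scale_percentage(values),
         unbounded = rescale_unbounded(winsorize_90(values)),
         already_unit = {
           if (any(values < 0 | values > 1, na.rm = TRUE)) {
             stop("already_unit values must lie in [0, 1]")
           }
           values
         })
}

#' Classify scaled indicator values as high or low integrity
#'
#' Splits the unit interval at `threshold`; a value exactly at the
#' threshold classifies as `high` (one fixed tie rule, applied identically
#' at every call site in the package, keeping good-integrity semantics for
#' protection screening).
#'
#' @param scaled_values numeric vector in \[0, 1\].
#' @param threshold split point (default 0.5).
#' @return Factor with levels `high`, `low`.
#' @export
classify_high_low <- function(scaled_values, threshold = 0.5) {
  if (any(scaled_values < 0 | scaled_values > 1, na.rm = TRUE)) {
    stop("scaled values must lie in [0, 1]")
  }
  factor(ifelse(scaled_values >= threshold, "high", "low"),
         levels = c("high", "low"))
}

#' Stressor view of an integrity value
#'
#' Integrity indices run 0-1 with 1 = high integrity; the equivalent
#' stressor representation is `1 - value`. Applying the function twice
#' returns the input.
#'
#' @param value numeric vector in \[0, 1\].
#' @return `1 - value`.
#' @export
stressor_from_integrity <- function(value) {
  if (any(value < 0 | value > 1, na.rm = TRUE)) {
    stop("integrity values must lie in [0, 1]")
  }
  1 - value
}

#' Build a scaled indicator series
#'
#' Bundles a named indicator's raw values with their unit-scaled form and
#' high/low class.
#'
#' @param name indicator name.
#' @param raw numeric vector of raw values.
#' @param scale_kind see [scale_indicator()].
#' @param threshold high/low split (default 0.5).
#' @return data.frame with columns `name`, `raw`, `scaled`, `klass`.
#' @export
indicator_series <- function(name, raw,
                             scale_kind = c("percentage", "unbounded",
                                            "already_unit"),
                             threshold = 0.5) {
  scale_kind <- match.arg(scale_kind)
  scaled <- scale_indicator(raw, scale_kind)
  data.frame(name = name, raw = raw, scaled = scaled,
             klass = classify_high_low(scaled, threshold))
}
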