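# Cohort-level SNAVF statistics.
#
# Raw SNAVF values are power ratios on an arbitrary absolute scale, so a
# cohort is balanced by its average before distributional comparison:
# the default rule maps v to (v - mean) / mean, giving a distribution with
# mean exactly 0 spanning negative to positive values and invariant to any
# positive rescaling of the inputs.

#' Normalize per-subject SNAVF values
#'
#' @param values positive SNAVF ratios, one per recording.
#' @param method \code{"relative"} (default): \code{(v - mean) / mean},
#'   dimensionless relative deviation from the cohort mean;
#'   \code{"zscore"}: \code{(v - mean) / sd}.
#' @return Numeric vector of normalized values with mean 0.
#' @examples
#' normalize_snavf(c(1, 2, 3))  # -0.5, 0, 0.5
#' @export
normalize_snavf <- function(values, method = c("relative", "zscore")) {
  method <- match.arg(method)
  if (length(values) == 0L) stop("values must be non-empty")
  if (any(values <= 0)) stop("SNAVF ratios must be positive")
  m <- mean(values)
  if (m == 0) stop("mean of values is zero")
  if (method == "relative") (values - m) / m else (values - m) / sd(values)
}

#' Quartile summary with half-median rule
#'
#' Quartiles split the sorted data into four equal parts: Q2 is the overall
#' median; Q1 is the median of the lower half and Q3 of the upper half, the
#' overall median being excluded from both halves when the count is odd
#' (Moore-McCabe convention, i.e. the middle number between the minimum and
#' the median); the fourth quartile is reported as the maximum value.
#'
#' @param values numeric vector, at least 4 values.
#' @return Named numeric vector \code{c(q1, q2, q3, q4_max)}.
#' @examples
#' quartile_summary(1:7)  # 2, 4, 6, 7
#' quartile_summary(1:4)  # 1.5, 2.5, 3.5, 4
#' @export
quartile_summary <- function(values) {
  n <- length(values)
  if (n < 4L) stop("quartile summary needs at least 4 values")
  s <- sort(values)
  half <- n %/% 2L
  lower <- s[seq_len(half)]
  upper <- s[(n - half + 1L):n]
  c(q1 = median(lower), q2 = median(s), q3 = median(upper), q4_max = s[n])
}

#' Cohort distribution summary of SNAVF values
#'
#' Normalizes the raw ratios (see \code{\link{normalize_snavf}}) and
#' summarizes the normalized distribution by its quartiles.
#'
#' @param values raw positive SNAVF ratios, at least 4.
#' @param method normalization rule, passed to \code{\link{normalize_snavf}}.
#' @return An object of class \code{cohort_summary}: list with
#'   \code{n_subjects}, \code{normalized_values}, \code{mean_raw},
#'   \code{median_norm}, \code{q1}, \code{q2}, \code{q3}, \code{q4_max}.
#' @export
cohort_summary <- function(values, method = "relative") {
  norm <- normalize_snavf(values, method)
  q <- quartile_summary(norm)
  structure(list(n_subjects = length(values), normalized_values = norm,
                 mean_raw = mean(values), median_norm = median(norm),
                 q1 = q[["q1"]], q2 = q[["q2"]], q3 = q[["q3"]],
                 q4_max = q[["q4_max"]]),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> %d recordings, raw mean SNAVF %.4g\n",
              x$n_subjects, x$mean_raw))
  cat(sprintf("  normalized quartiles: Q1 %.3g, Q2 %.3g, Q3 %.3g, max %.3g\n",
              x$q1, x$q2, x$q3, x$q4_max))
  invisible(x)
}

#' Back-calculate the raw cohort mean from a normalized maximum
#'
#' Under the relative-deviation rule, a raw maximum \code{raw_max} that
#' normalizes to \code{norm_max} implies a raw cohort mean of
#' \code{raw_max / (1 + norm_max)}. A sanity utility for checking reported
#' summary numbers for internal consistency; not a substitute for the data.
#'
#' @param raw_max maximum raw SNAVF in the cohort.
#' @param norm_max its normalized value.
#' @return The implied raw mean.
#' @examples
#' implied_mean_raw(0.18, 1.44)  # about 0.074
#' @export
implied_mean_raw <- function(raw_max, norm_max) raw_max / (1 + norm_max)
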