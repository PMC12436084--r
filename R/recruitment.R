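# Recruitment-through-calendar-time models. Time is measured in months
# (real-valued); the defining property of each model is that cumulative
# recruitment reaches n_max at tmax.

#' Uniform recruitment rate
#'
#' @param n_max Total sample size recruited over the trial.
#' @param tmax Total recruitment time (months).
#' @return Rate lambda = n_max / tmax (patients/month).
#' @examples
#' uniform_rate(800, 24)  # 33.33 patients/month
#' @export
uniform_rate <- function(n_max, tmax) {
  stopifnot_scalar(n_max, "n_max", positive = TRUE)
  stopifnot_scalar(tmax, "tmax", positive = TRUE)
  n_max / tmax
}

#' Linear recruitment slope
#'
#' Under linearly increasing recruitment the rate at (discrete) month t is
#' Delta * t, so cumulative recruitment over tmax months is
#' Delta * tmax * (tmax + 1) / 2; equating to n_max gives the slope.
#'
#' @inheritParams uniform_rate
#' @return Slope Delta = 2 n_max / (tmax (tmax + 1)) (patients/month^2).
#' @examples
#' linear_slope(336, 20)  # 1.6
#' @export
linear_slope <- function(n_max, tmax) {
  stopifnot_scalar(n_max, "n_max", positive = TRUE)
  stopifnot_scalar(tmax, "tmax", positive = TRUE)
  if (tmax < 1) stop("tmax must be at least 1 month", call. = FALSE)
  2 * n_max / (tmax * (tmax + 1))
}

#' Specify a recruitment model
#'
#' @param kind \code{"uniform"} (constant rate) or \code{"linear"} (rate
#'   increasing linearly in time, the extreme of the ramp-up patterns seen in
#'   multi-centre trials).
#' @inheritParams uniform_rate
#' @return An object of class \code{"recruitment_model"} with the rate
#'   (\code{lam}) or slope (\code{delta_slope}) filled in.
#' @export
recruitment_model <- function(kind = c("uniform", "linear"), n_max, tmax) {
  kind <- match.arg(kind)
  out <- list(kind = kind, n_max = n_max, tmax = tmax,
              lam = NA_real_, delta_slope = NA_real_)
  if (kind == "uniform") out$lam <- uniform_rate(n_max, tmax)
  else out$delta_slope <- linear_slope(n_max, tmax)
  structure(out, class = "recruitment_model")
}

#' @export
print.recruitment_model <- function(x, ...) {
  if (x$kind == "uniform")
    cat(sprintf("Uniform recruitment: lambda=%.4f patients/month (n_max=%.2f, tmax=%g)\n",
                x$lam, x$n_max, x$tmax))
  else
    cat(sprintf("Linear recruitment: Delta=%.4f patients/month^2 (n_max=%.2f, tmax=%g)\n",
                x$delta_slope, x$n_max, x$tmax))
  invisible(x)
}

#' Outcome-delay specification
#'
#' @param m0 Time from a participant's recruitment to observation of their
#'   primary outcome (months, >= 0).
#' @param tmax Total recruitment time (months).
#' @return An object of class \code{"delay_spec"}.
#' @export
delay_spec <- function(m0, tmax) {
  stopifnot_scalar(m0, "m0")
  stopifnot_scalar(tmax, "tmax", positive = TRUE)
  if (m0 < 0) stop("m0 must be >= 0", call. = FALSE)
  structure(list(m0 = m0, tmax = tmax), class = "delay_spec")
}

# Cumulative recruitment by (real) time t, evaluated on the model's
# untruncated accrual curve; the design-level caps, not this curve, enforce
# that totals never exceed n_max.
accrual <- function(model, t) {
  if (model$kind == "uniform") model$lam * t
  else model$delta_slope * t * (t + 1) / 2
}

#' Time to recruit a given cumulative sample size
#'
#' Inverts the model's cumulative accrual curve: uniform, t = n / lambda;
#' linear, the positive root of Delta t (t + 1) / 2 = n, i.e.
#' t = -1/2 + sqrt(1 + 8 n / Delta) / 2.
#'
#' @param model A \code{\link{recruitment_model}}.
#' @param n Cumulative number of participants (0 <= n).
#' @return Time in months (real-valued).
#' @examples
#' stage_time(recruitment_model("linear", 336, 20), 168)  # 14
#' @export
stage_time <- function(model, n) {
  stopifnot(all(n >= 0))
  if (model$kind == "uniform") n / model$lam
  else -0.5 + 0.5 * sqrt(1 + 8 * n / model$delta_slope)
}

#' Interim-analysis times under outcome delay
#'
#' Given the recruitment-completion times t_j of the stagewise cohorts, the
#' analysis clock follows the recursion (with t~_0 = 0): if the previous
#' analysis happened no later than t_j, the analysis waits the outcome delay
#' after recruitment completes (t~_j = t_j + m0); otherwise it happens m0
#' after the previous analysis, but is capped at tmax once waiting that long
#' would pass the end of recruitment. The clock is additionally kept
#' nondecreasing for the corner case where an uncapped analysis time already
#' exceeds tmax.
#'
#' @param stage_times Nondecreasing vector of recruitment-completion times.
#' @param m0 Outcome delay (months).
#' @param tmax Total recruitment time (months).
#' @return Vector of analysis times t~_j.
#' @export
analysis_times <- function(stage_times, m0, tmax) {
  if (any(diff(stage_times) < -1e-9))
    stop("stage_times must be nondecreasing", call. = FALSE)
  tt <- numeric(length(stage_times))
  prev <- 0
  for (j in seq_along(stage_times)) {
    v <- if (prev <= stage_times[j] + 1e-12) {
      stage_times[j] + m0
    } else if (prev + m0 < tmax) {
      prev + m0
    } else {
      tmax
    }
    v <- max(v, prev)
    tt[j] <- v
    prev <- v
  }
  tt
}
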