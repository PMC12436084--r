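# Pipeline participants and the delay-adjusted realized sample size.
#
# All quantities here are per outcome path (per omega): the stagewise
# cumulative sample sizes, recruitment and analysis times, the uncapped and
# capped pipeline counts, and n_delay(omega).

#' Maximum possible recruitment from a stage onwards
#'
#' nu_j: the further recruitment that would be needed if every arm present at
#' analysis j (including the control) continued to the planned end of the
#' trial. When all arms are present this equals n_max - n_{j-1}. Pipeline
#' counts are capped so the running total never exceeds n_{j-1} + nu_j.
#'
#' @param design A \code{\link{mams_design}}.
#' @param omega Per-arm stopping stages.
#' @param j Analysis index (1 <= j <= max(omega)).
#' @return nu_j (patients).
#' @export
max_possible_recruitment <- function(design, omega, j) {
  jmax <- max(omega)
  stopifnot(j >= 1, j <= jmax)
  present <- c(TRUE, omega >= j)  # control + experimental arms at analysis j
  sum(design$group_sizes[j:design$J, present, drop = FALSE])
}

#' Per-path recruitment and delay timeline
#'
#' Lays out, stage by stage along one outcome path: the cumulative sample
#' size n_j informing analysis j, its recruitment-completion time t_j, the
#' analysis time t~_j under delay, the maximum possible further recruitment
#' nu_j, and the uncapped and capped pipeline counts n~_j. Pipelines at
#' analysis j are the participants accrued on the recruitment curve between
#' max(t_j, t~_{j-1}) and t~_j; they are zero at the planned final stage J
#' and once the previous analysis time has reached tmax. The capped count
#' never lets total recruitment exceed n_{j-1} + nu_j.
#'
#' The delay-adjusted realized sample size is
#' n_delay(omega) = n_jmax + max(0, max_j (n_j + n~_j) - n_jmax),
#' which covers both the small-delay case (pipelines inflate the total only
#' if the trial stops early) and the large-delay case (only the largest
#' overshoot past n_jmax counts).
#'
#' @param design A \code{\link{mams_design}}.
#' @param omega Per-arm stopping stages.
#' @param model A \code{\link{recruitment_model}}.
#' @param delay A \code{\link{delay_spec}}.
#' @return A data.frame with one row per stage 1..jmax: \code{stage},
#'   \code{n_cum}, \code{t}, \code{t_tilde}, \code{nu}, \code{pipeline_raw},
#'   \code{pipeline}; the delay-adjusted total is attached as attribute
#'   \code{"n_delay"}.
#' @export
delay_timeline <- function(design, omega, model, delay) {
  J <- design$J
  jmax <- max(omega)
  gs <- design$group_sizes
  n_cum <- numeric(jmax)
  nu <- numeric(jmax)
  run <- 0
  for (j in seq_len(jmax)) {
    present <- c(TRUE, omega >= j)
    run <- run + sum(gs[j, present])
    n_cum[j] <- run
    nu[j] <- sum(gs[j:J, present, drop = FALSE])
  }
  t <- vapply(n_cum, function(n) stage_time(model, n), numeric(1))
  tt <- analysis_times(t, delay$m0, delay$tmax)
  prev_tt <- c(0, tt[-jmax])
  pipe_raw <- numeric(jmax)
  for (j in seq_len(jmax)) {
    if (j == jmax && jmax == J) {
      pipe_raw[j] <- 0             # no pipelines at the planned final analysis
    } else if (prev_tt[j] >= delay$tmax - 1e-12) {
      pipe_raw[j] <- 0             # everyone already recruited
    } else {
      s <- max(t[j], prev_tt[j])
      pipe_raw[j] <- max(0, accrual(model, tt[j]) - accrual(model, s))
    }
  }
  cap <- pmax(0, c(0, n_cum[-jmax]) + nu - n_cum)
  pipe <- pmin(pipe_raw, cap)
  out <- data.frame(stage = seq_len(jmax), n_cum = n_cum, t = t,
                    t_tilde = tt, nu = nu, pipeline_raw = pipe_raw,
                    pipeline = pipe)
  attr(out, "n_delay") <-
    n_cum[jmax] + max(0, max(n_cum + pipe) - n_cum[jmax])
  out
}

#' Pipeline participants at one interim analysis
#'
#' Expected number of participants recruited while the analysis-j outcomes
#' are awaited, along the outcome path \code{omega}. Under uniform
#' recruitment this is lambda * m0 (or lambda * (t~_j - t~_{j-1}) once the
#' analysis clock is capped at tmax); under linear recruitment it is
#' Delta * (m0 s + m0 (m0 + 1) / 2) with s the later of t_j and t~_{j-1}.
#'
#' @inheritParams delay_timeline
#' @param j Interim index.
#' @param capped If \code{TRUE} (default) the count is capped by the maximum
#'   possible recruitment (see \code{\link{max_possible_recruitment}}).
#' @return n~_j (patients, real-valued).
#' @examples
#' d <- mams_design(K = 3, J = 2, n = 42)
#' m <- recruitment_model("uniform", 336, 29)
#' pipeline_count(d, c(1, 1, 1), 1, m, delay_spec(6, 29))  # 69.52
#' @export
pipeline_count <- function(design, omega, j, model, delay, capped = TRUE) {
  tl <- delay_timeline(design, omega, model, delay)
  stopifnot(j >= 1, j <= nrow(tl))
  if (capped) tl$pipeline[j] else tl$pipeline_raw[j]
}

#' Cap a pipeline count by the maximum possible recruitment
#'
#' Applies the recruitment cap min(n~_j, n_{j-1} + nu_j - n_j) (clamped at
#' zero), which guarantees total recruitment through interim j never exceeds
#' the maximum n_{j-1} + nu_j needed by the arms still present.
#'
#' @param n_tilde Uncapped pipeline count.
#' @inheritParams max_possible_recruitment
#' @return Capped pipeline count.
#' @export
cap_pipeline <- function(n_tilde, design, omega, j) {
  stopifnot(n_tilde >= 0)
  jmax <- max(omega)
  gs <- design$group_sizes
  n_cum <- 0
  for (jj in seq_len(j)) n_cum <- n_cum + sum(gs[jj, c(TRUE, omega >= jj)])
  n_prev <- 0
  if (j > 1) for (jj in seq_len(j - 1)) n_prev <- n_prev + sum(gs[jj, c(TRUE, omega >= jj)])
  nu <- max_possible_recruitment(design, omega, j)
  min(n_tilde, max(0, n_prev + nu - n_cum))
}

#' Delay-adjusted realized sample size of an outcome path
#'
#' @inheritParams delay_timeline
#' @return n_delay(omega); satisfies
#'   n(omega) <= n_delay(omega) <= n_max.
#' @examples
#' d <- mams_design(K = 3, J = 4, n = 50)
#' m <- recruitment_model("uniform", 800, 24)
#' realized_sample_size_delay(d, c(1, 1, 3), m, delay_spec(12, 24))  # 600
#' @export
realized_sample_size_delay <- function(design, omega, model, delay) {
  attr(delay_timeline(design, omega, model, delay), "n_delay")
}

#' Expected sample size under outcome delay
#'
#' ESS_delay = sum over paths of n_delay(omega) * P(omega, psi): the expected
#' sample size with pipeline participants counted. Satisfies
#' ESS <= ESS_delay <= n_max.
#'
#' @inheritParams ess
#' @param model A \code{\link{recruitment_model}}.
#' @param delay A \code{\link{delay_spec}}.
#' @return Expected delay-adjusted sample size.
#' @export
ess_delay <- function(design, boundaries, tau, model, delay,
                      distribution = NULL) {
  if (is.null(distribution))
    distribution <- outcome_distribution(design, boundaries, tau)
  omega_mat <- attr(distribution, "omega")
  keys <- distribution$omega
  uk <- !duplicated(keys)
  nd <- vapply(which(uk), function(i)
    realized_sample_size_delay(design, omega_mat[i, ], model, delay),
    numeric(1))
  names(nd) <- keys[uk]
  sum(nd[keys] * distribution$prob)
}
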