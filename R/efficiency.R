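# Efficiency metrics relative to the matched single-stage multi-arm design.

#' Efficiency gain of a MAMS design over the single-stage design
#'
#' EG = (n_MA - ESS) / n_MA: the proportional reduction in expected sample
#' size relative to the K-arm single-stage design with the same familywise
#' error rate and conjunctive power. Negative values (a MAMS worse than the
#' single-stage design) are allowed.
#'
#' @param n_MA Sample size of the matched single-stage design.
#' @param ess Expected sample size of the MAMS design.
#' @return The efficiency gain (a proportion).
#' @export
efficiency_gain <- function(n_MA, ess) {
  stopifnot_scalar(n_MA, "n_MA", positive = TRUE)
  (n_MA - ess) / n_MA
}

#' Efficiency loss due to outcome delay
#'
#' EL = 100 * (EG - EG_delay) / EG: the percentage of the expected efficiency
#' gain destroyed by delay. Values above 100 are possible when delay makes
#' the MAMS design less efficient than the single-stage comparator. When the
#' delay-free gain is zero the loss is undefined and \code{NA} is returned.
#'
#' @param EG Efficiency gain without delay.
#' @param EG_delay Efficiency gain with delay.
#' @return Efficiency loss in percent, or \code{NA} if \code{EG} is 0.
#' @export
efficiency_loss <- function(EG, EG_delay) {
  if (abs(EG) < .Machine$double.eps * 100) return(NA_real_)
  100 * (EG - EG_delay) / EG
}

#' Efficiency report for one design/delay scenario
#'
#' Calibrates a MAMS design (boundaries to the familywise error rate, group
#' size to the conjunctive power at the global alternative), computes the
#' matched single-stage size, and evaluates ESS, ESS_delay and the
#' efficiency metrics under the given recruitment model and delay.
#'
#' @param J,K Stages and experimental arms.
#' @param m0 Outcome delay (months); may be a vector, producing one row per
#'   value (the expensive path integration is shared).
#' @param tmax Total recruitment time (months).
#' @param model Recruitment kind, \code{"uniform"} or \code{"linear"}.
#' @param spacing Spacing scheme name or numeric fractions.
#' @param shape Boundary shape (default the zero-futility O'Brien-Fleming
#'   design).
#' @param tau True-effect scenario: \code{"alternative"} (all arms at
#'   delta), \code{"null"}, or a numeric vector of length K.
#' @param alpha,power,delta,sigma Design targets, see
#'   \code{\link{mams_design}}.
#' @return A data.frame with one row per \code{m0}: scenario descriptors
#'   plus \code{n_max}, \code{n_MA}, \code{ESS}, \code{ESS_delay},
#'   \code{EG}, \code{EG_delay}, \code{EL}.
#' @export
efficiency_report <- function(J, K, m0, tmax, model = "uniform",
                              spacing = "I", shape = "fixed_futility_obf",
                              tau = "alternative", alpha = 0.05,
                              power = 0.8, delta = 0.5, sigma = 1) {
  base <- mams_design(K = K, J = J, n = 10, spacing = spacing, sigma = sigma,
                      delta = delta, alpha = alpha, power = power)
  fit <- calibrate_group_size(base, shape = shape)
  design <- fit$design
  tau_vec <- resolve_tau(tau, K, delta)
  dist <- outcome_distribution(design, fit$boundaries, tau_vec)
  n_max <- design_nmax(design)
  n_MA <- single_stage_size(design)
  ESS <- ess(design, fit$boundaries, tau_vec, distribution = dist)
  EG <- efficiency_gain(n_MA, ESS)
  rec <- recruitment_model(model, n_max, tmax)
  rows <- lapply(m0, function(m) {
    ESSd <- ess_delay(design, fit$boundaries, tau_vec, rec,
                      delay_spec(m, tmax), distribution = dist)
    EGd <- efficiency_gain(n_MA, ESSd)
    data.frame(J = J, K = K, m0 = m, tmax = tmax, model = model,
               spacing = if (is.character(spacing)) spacing else "custom",
               shape = shape, tau = paste(signif(tau_vec, 6), collapse = ","),
               n_max = n_max, n_MA = n_MA, ESS = ESS, ESS_delay = ESSd,
               EG = EG, EG_delay = EGd,
               EL = efficiency_loss(EG, EGd),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

resolve_tau <- function(tau, K, delta) {
  if (is.character(tau)) {
    switch(match.arg(tau, c("alternative", "null")),
           alternative = rep(delta, K),
           null = rep(0, K))
  } else {
    if (length(tau) == 1L) tau <- rep(tau, K)
    if (length(tau) != K) stop("tau must have length K", call. = FALSE)
    tau
  }
}

#' Scenario grid of efficiency losses
#'
#' Evaluates \code{\link{efficiency_report}} over the cartesian product of
#' stages, arms, delays, recruitment models and spacing schemes, re-using
#' calibrations and path distributions within each design cell. This is the
#' machinery behind delay-sensitivity summaries such as "EL against m0 for
#' each (J, K)".
#'
#' @param J,K Integer vectors of stages / experimental arms.
#' @param m0 Vector of delays (months).
#' @param tmax Total recruitment time (months).
#' @param models Character vector of recruitment kinds.
#' @param spacings Character vector of spacing scheme names.
#' @param shapes Character vector of boundary shapes.
#' @inheritParams efficiency_report
#' @param verbose Print one line per design cell as it completes.
#' @return A data.frame with one row per scenario combination.
#' @export
scenario_grid <- function(J = 2:4, K = 2:4, m0 = seq(0, 36, by = 6),
                          tmax = 36, models = c("uniform", "linear"),
                          spacings = "I", shapes = "fixed_futility_obf",
                          tau = "alternative", alpha = 0.05, power = 0.8,
                          delta = 0.5, sigma = 1, verbose = FALSE) {
  out <- list()
  for (shp in shapes) for (sp in spacings) for (jj in J) for (kk in K) {
    for (mod in models) {
      rep_jk <- tryCatch(
        efficiency_report(J = jj, K = kk, m0 = m0, tmax = tmax, model = mod,
                          spacing = sp, shape = shp, tau = tau,
                          alpha = alpha, power = power, delta = delta,
                          sigma = sigma),
        error = function(e) {
          warning(sprintf("scenario J=%d K=%d %s/%s/%s failed: %s",
                          jj, kk, mod, sp, shp, conditionMessage(e)),
                  call. = FALSE)
          NULL
        })
      if (!is.null(rep_jk)) out[[length(out) + 1L]] <- rep_jk
    }
    if (verbose)
      message(sprintf("scenario cell J=%d K=%d spacing=%s shape=%s done",
                      jj, kk, sp, shp))
  }
  do.call(rbind, out)
}
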