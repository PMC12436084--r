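# Error-rate evaluation and calibration of boundaries and group sizes.

#' Familywise error rate of a design
#'
#' Probability, under the global null (all true effects zero), that at least
#' one experimental arm ever crosses its efficacy boundary. Computed as one
#' minus the total probability of the no-rejection paths (every arm stopping
#' for futility at some stage), each a multivariate-normal box probability.
#' Futility bounds are binding.
#'
#' @param design A \code{\link{mams_design}}.
#' @param boundaries A \code{\link{shape_boundaries}} object.
#' @return The familywise error rate.
#' @export
fwer <- function(design, boundaries) {
  J <- design$J; K <- design$K
  omega <- as.matrix(expand.grid(rep(list(seq_len(J)), K),
                                 KEEP.OUT.ATTRS = FALSE))
  psi <- matrix(0L, nrow(omega), K)
  res <- path_prob_batch(design, boundaries, rep(0, K), omega, psi)
  max(0, min(1, 1 - sum(res$prob)))
}

#' Conjunctive power of a design
#'
#' Probability that all K null hypotheses are rejected when the true effects
#' are \code{tau}: the summed probability of every path on which each arm
#' exits through its efficacy boundary.
#'
#' @inheritParams fwer
#' @param tau True effects (scalar recycled to length K).
#' @return The conjunctive power.
#' @export
conjunctive_power <- function(design, boundaries, tau) {
  J <- design$J; K <- design$K
  if (length(tau) == 1L) tau <- rep(tau, K)
  omega <- as.matrix(expand.grid(rep(list(seq_len(J)), K),
                                 KEEP.OUT.ATTRS = FALSE))
  psi <- matrix(1L, nrow(omega), K)
  res <- path_prob_batch(design, boundaries, tau, omega, psi)
  max(0, min(1, sum(res$prob)))
}

#' Calibrate stopping boundaries to the familywise error rate
#'
#' Finds the scalar c of a one-parameter boundary shape such that the
#' familywise error rate under the global null equals the design's alpha.
#' The FWER is strictly decreasing in c, so a monotone root search
#' (\code{uniroot} with bracket extension) is used; results are memoised per
#' design signature.
#'
#' @inheritParams fwer
#' @param shape Boundary shape name, see \code{\link{shape_boundaries}}.
#' @param interval Initial bracket for c.
#' @return A calibrated \code{\link{shape_boundaries}} object.
#' @examples
#' d <- mams_design(K = 1, J = 1, n = 50)
#' calibrate_boundaries(d, "pocock")$e  # qnorm(0.95)
#' @export
calibrate_boundaries <- function(design, shape = "fixed_futility_obf",
                                 interval = c(0.5, 4)) {
  key <- paste0("bounds|", design_signature(design, shape))
  cache_get_or(key, function() {
    target <- design$alpha
    gfun <- function(cc)
      fwer(design, shape_boundaries(shape, design$spacing, cc)) - target
    root <- tryCatch(
      uniroot(gfun, interval = interval, extendInt = "downX", tol = 1e-6),
      error = function(e)
        stop(sprintf(
          "boundary calibration failed to bracket alpha=%.4g in [%.3g, %.3g]: %s",
          target, interval[1], interval[2], conditionMessage(e)),
          call. = FALSE)
    )
    shape_boundaries(shape, design$spacing, root$root)
  })
}

#' Calibrate the group size to the conjunctive power target
#'
#' With boundaries calibrated to the familywise error rate (the boundary
#' calibration is scale-invariant in the sample size, since the covariance of
#' the z statistics depends only on allocation ratios and spacing), finds the
#' smallest per-arm sample size achieving the conjunctive power target at the
#' global alternative (all effects equal to \code{delta}). The continuous
#' (real-valued) solution is kept in the returned design's group sizes;
#' integer-feasible stagewise sizes (ceilings of the cumulative sizes) are
#' reported separately, since rounding is a reporting-layer decision.
#'
#' @inheritParams fwer
#' @param shape Boundary shape name.
#' @param tau_alt Alternative used for power; defaults to the global
#'   alternative \code{rep(delta, K)}.
#' @param n_cap Upper bound on the per-arm total size in the root search.
#' @return A list with \code{design} (group sizes at the continuous
#'   solution), \code{boundaries}, \code{n_arm} (continuous per-arm total),
#'   \code{n_stage} (continuous per-arm per-stage size for equal increments),
#'   \code{n_cum_integer} (ceiling of cumulative per-arm sizes), and
#'   \code{power_achieved}.
#' @export
calibrate_group_size <- function(design, shape = "fixed_futility_obf",
                                 tau_alt = NULL, n_cap = 1e4) {
  if (is.null(tau_alt)) tau_alt <- rep(design$delta, design$K)
  key <- paste0("size|", design_signature(design, shape), "|",
                paste(signif(tau_alt, 12), collapse = ","))
  cache_get_or(key, function() {
    boundaries <- calibrate_boundaries(design, shape)
    target <- 1 - design$beta
    pfun <- function(n_arm)
      conjunctive_power(scale_design(design, n_arm), boundaries, tau_alt) -
        target
    root <- tryCatch(
      uniroot(pfun, interval = c(2, 500), extendInt = "upX", tol = 1e-4),
      error = function(e)
        stop("group-size calibration did not converge: ",
             conditionMessage(e), call. = FALSE)
    )
    if (root$root > n_cap)
      stop("group-size calibration exceeded the size cap", call. = FALSE)
    sized <- scale_design(design, root$root)
    list(design = sized,
         boundaries = boundaries,
         n_arm = root$root,
         n_stage = root$root / design$J,
         n_cum_integer = ceiling(cumsum(sized$group_sizes[, 2]) - 1e-9),
         power_achieved = conjunctive_power(sized, boundaries, tau_alt))
  })
}

#' Sample size of the matched single-stage multi-arm design
#'
#' Total sample size n_MA of the K-arm single-stage (no interim) design
#' calibrated to the same familywise error rate and conjunctive power targets
#' at the global alternative, using the same integration machinery with
#' J = 1. This is the comparator in the efficiency-gain metric.
#'
#' @param design A \code{\link{mams_design}} (its K, alpha, power, delta and
#'   sigma are used; stages and spacing are ignored).
#' @return Real-valued total sample size across the K+1 arms.
#' @export
single_stage_size <- function(design) {
  single <- mams_design(K = design$K, J = 1, n = 10,
                        sigma = design$sigma, delta = design$delta,
                        alpha = design$alpha, power = 1 - design$beta)
  fit <- calibrate_group_size(single, shape = "pocock")
  design_nmax(fit$design)
}
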