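# Enumeration of trial outcome paths (omega, psi) and their probabilities.
#
# With separate stopping rules each arm independently carries one of 2J
# labelled decisions: stop at an interim stage j < J for efficacy or
# futility, or reach the final stage and be rejected or not. A path is one
# decision per arm; there are (2J)^K paths in total.

#' Enumerate all consistent outcome paths of a MAMS trial
#'
#' @param J Number of stages.
#' @param K Number of experimental arms.
#' @return An object of class \code{"mams_outcomes"}: list with matrices
#'   \code{omega} (per-arm stopping stage) and \code{psi} (per-arm rejection
#'   indicator), each with (2J)^K rows and K columns, plus \code{jmax}
#'   (per-path realized number of stages) and \code{J}, \code{K}.
#' @examples
#' nrow(enumerate_outcomes(2, 2)$omega)  # 16
#' @export
enumerate_outcomes <- function(J, K) {
  stopifnot(J >= 1, K >= 1)
  labels <- cbind(omega = rep(seq_len(J), each = 2L),
                  psi   = rep(c(1L, 0L), J))
  idx <- as.matrix(expand.grid(rep(list(seq_len(2L * J)), K),
                               KEEP.OUT.ATTRS = FALSE))
  omega <- matrix(labels[idx, "omega"], ncol = K)
  psi <- matrix(labels[idx, "psi"], ncol = K)
  colnames(omega) <- colnames(psi) <- paste0("arm", seq_len(K))
  structure(list(omega = omega, psi = psi,
                 jmax = apply(omega, 1L, max), J = J, K = K),
            class = "mams_outcomes")
}

#' @export
print.mams_outcomes <- function(x, ...) {
  cat(sprintf("MAMS outcome space: J=%d, K=%d, %d paths\n",
              x$J, x$K, nrow(x$omega)))
  invisible(x)
}

#' Arm presence indicators along an outcome path
#'
#' Indicator matrix theta with theta[j, k] = 1 if arm k recruits in (is
#' present at) stage j of the path, i.e. if j <= omega_k; the control arm
#' recruits through the realized final stage jmax = max(omega).
#'
#' @param omega Per-arm stopping stages (length K).
#' @param J Total number of planned stages.
#' @return J x (K+1) 0/1 matrix, column 1 the control.
#' @export
arm_presence <- function(omega, J) {
  K <- length(omega)
  jmax <- max(omega)
  theta <- matrix(0L, J, K + 1L)
  theta[seq_len(jmax), 1L] <- 1L
  for (k in seq_len(K)) theta[seq_len(omega[k]), k + 1L] <- 1L
  dimnames(theta) <- list(paste0("stage", seq_len(J)),
                          c("control", paste0("arm", seq_len(K))))
  theta
}

#' Realized sample size of an outcome path
#'
#' Total number of participants whose outcomes inform the analyses along the
#' path: arm k recruits its planned stage-j group whenever j <= omega_k, and
#' the control recruits through jmax.
#'
#' @param design A \code{\link{mams_design}}.
#' @param omega Per-arm stopping stages.
#' @return n(omega), a single number.
#' @export
realized_sample_size <- function(design, omega) {
  gs <- design$group_sizes
  run <- 0
  # accumulate stagewise, in the same order as the delay timeline, so that
  # n(omega) and n_delay(omega) are bitwise equal when there are no pipelines
  for (j in seq_len(max(omega)))
    run <- run + sum(gs[j, c(TRUE, omega >= j)])
  run
}

# Integration box for one path: per arm k, stages j < omega_k constrained to
# the continuation region (f_j, e_j), the exit stage to (e, Inf) or (-Inf, f].
path_box <- function(design, boundaries, omega, psi) {
  J <- design$J
  cells <- integer(0); lo <- numeric(0); hi <- numeric(0)
  for (k in seq_along(omega)) {
    wk <- omega[k]
    if (wk > 1L) {
      js <- seq_len(wk - 1L)
      cells <- c(cells, cell_index(js, k, J))
      lo <- c(lo, boundaries$f[js]); hi <- c(hi, boundaries$e[js])
    }
    cells <- c(cells, cell_index(wk, k, J))
    if (psi[k] == 1L) {
      lo <- c(lo, boundaries$e[wk]); hi <- c(hi, Inf)
    } else {
      lo <- c(lo, -Inf); hi <- c(hi, boundaries$f[wk])
    }
  }
  list(cells = cells, lower = lo, upper = hi)
}

#' Probability of one outcome path
#'
#' Computes P(omega, psi | tau, e, f): the probability that, for every arm,
#' the z statistic stays strictly between the futility and efficacy bounds
#' before the arm's stopping stage and exits on the recorded side at it.
#' Evaluated as a box probability of the joint normal distribution of the
#' active (stage, arm) statistics via randomized quasi-Monte-Carlo
#' integration (with a fixed internal seed, so results are reproducible).
#'
#' @param design A \code{\link{mams_design}}.
#' @param boundaries A \code{\link{shape_boundaries}} object.
#' @param tau True effects (scalar or length K).
#' @param omega,psi One path: stopping stages and rejection indicators.
#' @return The probability, with attribute \code{"error"} carrying the
#'   integration error estimate and \code{"flagged"} set when the requested
#'   absolute tolerance was not met.
#' @export
outcome_probability <- function(design, boundaries, tau, omega, psi) {
  mu <- as.vector(z_mean(design, tau))      # arm-major flattening
  V <- z_covariance(design)
  path_probability(design, boundaries, mu, V, omega, psi)
}

# Worker used by the batched evaluators: takes precomputed mean/covariance.
path_probability <- function(design, boundaries, mu, V, omega, psi) {
  box <- path_box(design, boundaries, omega, psi)
  width <- box$upper - box$lower
  width[is.nan(width)] <- 0      # equal infinite bounds: empty interval
  if (any(width < 1e-12)) {
    out <- 0
    attr(out, "error") <- 0; attr(out, "flagged") <- FALSE
    return(out)
  }
  if (length(box$cells) == 1L) {
    m <- mu[box$cells]
    p <- pnorm(box$upper, mean = m) - pnorm(box$lower, mean = m)
    out <- max(p, 0)
    attr(out, "error") <- 0; attr(out, "flagged") <- FALSE
    return(out)
  }
  abseps <- mvn_abseps()
  p <- with_fixed_rng(
    mvtnorm::pmvnorm(lower = box$lower, upper = box$upper,
                     mean = mu[box$cells],
                     sigma = V[box$cells, box$cells, drop = FALSE],
                     algorithm = mvtnorm::GenzBretz(abseps = abseps,
                                                    maxpts = mvn_maxpts()))
  )
  out <- max(as.numeric(p), 0)
  err <- attr(p, "error")
  attr(out, "error") <- err
  attr(out, "flagged") <- isTRUE(err > abseps * 10)
  out
}

# Arms are exchangeable when their allocation, variance and true effect all
# coincide; path probabilities then depend only on the multiset of per-arm
# decisions, which cuts the number of distinct integrals substantially
# (e.g. 4096 paths -> 330 integrals for J=K=4).
is_exchangeable <- function(design, tau) {
  gs <- design$group_sizes[, -1, drop = FALSE]
  all(abs(gs - gs[, 1]) < 1e-12) &&
    all(abs(design$sigma[-1] - design$sigma[2]) < 1e-12) &&
    all(abs(tau - tau[1]) < 1e-12)
}

# Probabilities for a batch of paths given as matrices, with caching by
# decision multiset under exchangeability.
path_prob_batch <- function(design, boundaries, tau, omega, psi) {
  if (length(tau) == 1L) tau <- rep(tau, design$K)
  mu <- as.vector(z_mean(design, tau))
  V <- z_covariance(design)
  exch <- is_exchangeable(design, tau)
  cache <- new.env(parent = emptyenv())
  n <- nrow(omega)
  prob <- err <- numeric(n)
  flagged <- logical(n)
  for (i in seq_len(n)) {
    key <- if (exch) {
      paste(sort(paste0(omega[i, ], ".", psi[i, ])), collapse = ";")
    } else {
      paste(omega[i, ], psi[i, ], collapse = ";")
    }
    hit <- cache[[key]]
    if (is.null(hit)) {
      p <- path_probability(design, boundaries, mu, V, omega[i, ], psi[i, ])
      hit <- c(as.numeric(p), attr(p, "error"), as.numeric(attr(p, "flagged")))
      cache[[key]] <- hit
    }
    prob[i] <- hit[1]; err[i] <- hit[2]; flagged[i] <- hit[3] > 0
  }
  list(prob = prob, error = err, flagged = flagged)
}

#' Full outcome-path distribution of a design
#'
#' Enumerates every outcome path and computes its probability, realized
#' sample size and realized number of stages. The resulting table is the
#' basis of the expected sample size with and without delay, and can be
#' dumped for audit.
#'
#' @inheritParams outcome_probability
#' @param paths Optionally, a pre-built \code{\link{enumerate_outcomes}}
#'   object (e.g. to reuse across calls).
#' @return A data.frame with one row per path: \code{omega}, \code{psi}
#'   (comma-separated strings), \code{jmax}, \code{n_omega}, \code{prob},
#'   \code{error}. The omega/psi matrices are attached as attributes
#'   \code{"omega"} and \code{"psi"}.
#' @export
outcome_distribution <- function(design, boundaries, tau, paths = NULL) {
  if (is.null(paths)) paths <- enumerate_outcomes(design$J, design$K)
  res <- path_prob_batch(design, boundaries, tau, paths$omega, paths$psi)
  n_omega <- apply(paths$omega, 1L, function(om)
    realized_sample_size(design, om))
  out <- data.frame(
    omega = apply(paths$omega, 1L, paste, collapse = ","),
    psi = apply(paths$psi, 1L, paste, collapse = ","),
    jmax = paths$jmax,
    n_omega = n_omega,
    prob = res$prob,
    error = res$error,
    stringsAsFactors = FALSE
  )
  attr(out, "omega") <- paths$omega
  attr(out, "psi") <- paths$psi
  attr(out, "flagged") <- any(res$flagged)
  out
}

#' Expected sample size of a calibrated design
#'
#' ESS(tau, e, f) = sum over all outcome paths of n(omega) * P(omega, psi).
#'
#' @inheritParams outcome_probability
#' @param distribution Optionally a precomputed
#'   \code{\link{outcome_distribution}} table to reuse.
#' @return Expected sample size (patients).
#' @export
ess <- function(design, boundaries, tau, distribution = NULL) {
  if (is.null(distribution))
    distribution <- outcome_distribution(design, boundaries, tau)
  sum(distribution$n_omega * distribution$prob)
}
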