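# Independent Monte Carlo oracle. Trials are simulated from stagewise cohort
# outcome sums (exact sums of the individual normal responses), so the
# distribution of the simulated z statistics is constructed without touching
# the analytic mean/covariance machinery that the simulator validates.

#' Simulate MAMS trials with a recruitment clock
#'
#' Draws R replicate trials: per-arm per-stage cohort outcome sums, the
#' resulting cumulative z statistics, and the arm-wise conduct rules
#' (stop for efficacy when Z > e_j, for futility when Z <= f_j, forced
#' decision at stage J). When a recruitment model and delay are supplied the
#' per-replicate delay-adjusted sample size n_delay(omega) is also computed
#' by advancing the recruitment clock along the replicate's path.
#'
#' @param design A \code{\link{mams_design}} (group sizes are rounded to
#'   whole patients for outcome generation).
#' @param boundaries A \code{\link{shape_boundaries}} object.
#' @param tau True effects (scalar recycled to length K).
#' @param model Optional \code{\link{recruitment_model}}.
#' @param delay Optional \code{\link{delay_spec}}.
#' @param R Number of replicate trials.
#' @param seed Integer seed; the whole replicate stream is a deterministic
#'   function of it.
#' @return An object of class \code{"mams_sim"}: list with per-replicate
#'   matrices \code{omega}, \code{psi} and vectors \code{n}, \code{n_delay},
#'   plus a \code{summary} list holding empirical FWER-style any-rejection
#'   and all-rejection rates, ESS and ESS_delay with standard errors, path
#'   frequencies, \code{R} and \code{seed}.
#' @examples
#' d <- mams_design(K = 2, J = 2, n = 20)
#' b <- shape_boundaries("fixed_futility_obf", d$spacing, c = 2.3)
#' s <- simulate_mams(d, b, tau = 0.5, R = 2000, seed = 1)
#' s$summary$ess
#' @export
simulate_mams <- function(design, boundaries, tau, model = NULL,
                          delay = NULL, R = 10000, seed = 1) {
  J <- design$J; K <- design$K
  if (length(tau) == 1L) tau <- rep(tau, K)
  stopifnot(length(tau) == K, R >= 1)
  gs <- round(design$group_sizes)
  if (any(gs < 1))
    stop("simulation needs at least one patient per arm per stage",
         call. = FALSE)
  sig <- design$sigma
  mu <- c(0, tau)                      # control mean 0 without loss
  set.seed(as.integer(seed))

  # Cohort sums per (stage, arm): sum of n iid N(mu, sigma^2) outcomes.
  cums <- array(0, dim = c(R, J, K + 1L))   # cumulative sums
  cumn <- apply(gs, 2, cumsum)
  if (J == 1L) cumn <- matrix(cumn, nrow = 1L)
  for (a in seq_len(K + 1L)) {
    acc <- numeric(R)
    for (j in seq_len(J)) {
      acc <- acc + rnorm(R, mean = gs[j, a] * mu[a],
                         sd = sqrt(gs[j, a]) * sig[a])
      cums[, j, a] <- acc
    }
  }
  Z <- array(NA_real_, dim = c(R, J, K))
  for (k in seq_len(K)) for (j in seq_len(J)) {
    se <- sqrt(sig[k + 1]^2 / cumn[j, k + 1] + sig[1]^2 / cumn[j, 1])
    Z[, j, k] <- (cums[, j, k + 1] / cumn[j, k + 1] -
                    cums[, j, 1] / cumn[j, 1]) / se
  }

  omega <- matrix(0L, R, K)
  psi <- matrix(NA_integer_, R, K)
  active <- matrix(TRUE, R, K)
  for (j in seq_len(J)) {
    zj <- Z[, j, , drop = FALSE]
    dim(zj) <- c(R, K)
    if (j < J) {
      up <- active & zj > boundaries$e[j]
      dn <- active & zj <= boundaries$f[j]
    } else {
      up <- active & zj > boundaries$e[J]
      dn <- active & !up
    }
    psi[up] <- 1L; omega[up] <- j
    psi[dn] <- 0L; omega[dn] <- j
    active <- active & !(up | dn)
  }

  # Map the (few) distinct omega vectors to realized sizes.
  okey <- apply(omega, 1L, paste, collapse = ",")
  uidx <- which(!duplicated(okey))
  nmap <- vapply(uidx, function(i)
    realized_sample_size(design, omega[i, ]), numeric(1))
  names(nmap) <- okey[uidx]
  n <- unname(nmap[okey])
  n_delay <- rep(NA_real_, R)
  if (!is.null(model) && !is.null(delay)) {
    ndmap <- vapply(uidx, function(i)
      realized_sample_size_delay(design, omega[i, ], model, delay),
      numeric(1))
    names(ndmap) <- okey[uidx]
    n_delay <- unname(ndmap[okey])
  }

  any_rej <- rowSums(psi == 1L) > 0
  all_rej <- rowSums(psi == 1L) == K
  pkey <- paste(okey, apply(psi, 1L, paste, collapse = ","), sep = "|")
  freq <- sort(table(pkey) / R, decreasing = TRUE)
  se_of <- function(x) sd(x) / sqrt(R)
  summary <- list(
    R = R, seed = seed,
    p_any_reject = mean(any_rej),
    p_any_reject_se = se_of(any_rej),
    p_all_reject = mean(all_rej),
    p_all_reject_se = se_of(all_rej),
    ess = mean(n), ess_se = se_of(n),
    ess_delay = if (all(is.na(n_delay))) NA_real_ else mean(n_delay),
    ess_delay_se = if (all(is.na(n_delay))) NA_real_ else se_of(n_delay),
    path_freq = freq
  )
  structure(list(omega = omega, psi = psi, n = n, n_delay = n_delay,
                 summary = summary),
            class = "mams_sim")
}

#' @export
print.mams_sim <- function(x, ...) {
  s <- x$summary
  cat(sprintf("MAMS simulation: R=%d replicates (seed %s)\n", s$R,
              format(s$seed)))
  cat(sprintf("  P(any rejection)  %.4f (se %.4f)\n",
              s$p_any_reject, s$p_any_reject_se))
  cat(sprintf("  P(all rejections) %.4f (se %.4f)\n",
              s$p_all_reject, s$p_all_reject_se))
  cat(sprintf("  ESS        %.2f (se %.3f)\n", s$ess, s$ess_se))
  if (!is.na(s$ess_delay))
    cat(sprintf("  ESS_delay  %.2f (se %.3f)\n", s$ess_delay, s$ess_delay_se))
  invisible(x)
}

#' Empirical frequency of one outcome path in a simulation
#'
#' @param sim A \code{\link{simulate_mams}} result.
#' @param omega,psi The path.
#' @return List with the empirical frequency and its binomial standard error.
#' @export
sim_path_frequency <- function(sim, omega, psi) {
  key <- paste(paste(omega, collapse = ","), paste(psi, collapse = ","),
               sep = "|")
  R <- sim$summary$R
  p <- unname(sim$summary$path_freq[key])
  if (is.na(p) || length(p) == 0L) p <- 0
  list(freq = p, se = sqrt(p * (1 - p) / R))
}
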