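# Shared fixtures and independent oracles for the test suite.

# Small designs used throughout.
design_22 <- function(n = 20) mams_design(K = 2, J = 2, n = n)
design_33 <- function(n = 20) mams_design(K = 3, J = 3, n = n)
design_24_worked <- function() mams_design(K = 3, J = 4, n = 50)   # 4-stage, 3-arm, 50/arm/stage
design_tailor <- function() mams_design(K = 3, J = 2, n = 42)      # 2-stage dose-ranging layout

# Independent oracle for a single-arm (K=1) two-stage path probability,
# by one-dimensional quadrature over the stage-1 statistic and the exact
# conditional normal law of the stage-2 statistic given stage 1. Never
# touches the multivariate integration code path.
oracle_path_prob_2stage <- function(design, boundaries, tau, omega, psi) {
  stopifnot(design$K == 1L, design$J == 2L)
  mu <- z_mean(design, tau)               # 2 x 1
  rho <- z_covariance(design)[1, 2]
  e <- boundaries$e; f <- boundaries$f
  if (omega == 1L) {
    if (psi == 1L) return(1 - pnorm(e[1], mean = mu[1, 1]))
    return(pnorm(f[1], mean = mu[1, 1]))
  }
  cond_tail <- function(z1, upper) {
    cmean <- mu[2, 1] + rho * (z1 - mu[1, 1])
    csd <- sqrt(1 - rho^2)
    if (upper) 1 - pnorm(e[2], mean = cmean, sd = csd)
    else pnorm(f[2], mean = cmean, sd = csd)
  }
  integrand <- function(z1)
    dnorm(z1, mean = mu[1, 1]) * cond_tail(z1, upper = psi == 1L)
  integrate(integrand, lower = f[1], upper = e[1], rel.tol = 1e-10)$value
}

# Brute-force outcome-path enumeration for tiny J, K by cartesian product of
# the per-arm labelled decisions; used to validate enumerate_outcomes.
oracle_enumerate <- function(J, K) {
  one_arm <- list()
  for (j in seq_len(J)) for (p in c(1L, 0L))
    one_arm[[length(one_arm) + 1L]] <- c(j, p)
  grids <- rep(list(seq_along(one_arm)), K)
  combos <- expand.grid(grids, KEEP.OUT.ATTRS = FALSE)
  t(apply(as.matrix(combos), 1L, function(idx)
    unlist(lapply(idx, function(i) one_arm[[i]]))))
}
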