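# Joint distribution of the stagewise Wald statistics Z_jk comparing each
# experimental arm to the shared control on cumulative data.

# Information level for arm k at stage j: I_jk = (sigma_k^2/N_jk +
# sigma_0^2/N_j0)^(-1), with N the cumulative per-arm sample sizes.
information_matrix <- function(design) {
  cs <- cum_sizes(design)                     # J x (K+1)
  J <- design$J; K <- design$K
  sig <- design$sigma
  if (any(cs[, 1] <= 0) || any(cs[, -1, drop = FALSE] <= 0))
    stop("undefined information: zero cumulative sample size", call. = FALSE)
  I <- matrix(NA_real_, J, K)
  for (k in seq_len(K))
    I[, k] <- 1 / (sig[k + 1]^2 / cs[, k + 1] + sig[1]^2 / cs[, 1])
  I
}

#' Expected values of the stagewise test statistics
#'
#' Mean of the z statistic Z_jk for each experimental arm k at each analysis
#' j under true effects tau: \code{E[Z_jk] = tau_k * sqrt(I_jk)}, where
#' \code{I_jk} is the information for the arm-k versus control comparison on
#' cumulative data through stage j.
#'
#' @param design A \code{\link{mams_design}}.
#' @param tau True treatment effects: scalar (recycled) or vector of length K.
#' @return J x K matrix of expectations (rows = stages, columns = arms).
#' @examples
#' d <- mams_design(K = 3, J = 2, n = 20)
#' z_mean(d, 0.5)[1, 1]  # 0.5 * sqrt(10)
#' @export
z_mean <- function(design, tau) {
  if (length(tau) == 1L) tau <- rep(tau, design$K)
  if (length(tau) != design$K)
    stop("tau must have length K", call. = FALSE)
  I <- information_matrix(design)
  sweep(sqrt(I), 2, tau, `*`)
}

# Cell ordering for the flattened (stage, arm) index: arm-major, i.e.
# cell (j,k) -> (k-1)*J + j. Used consistently by the covariance, the path
# integrals and the simulator.
cell_index <- function(j, k, J) (k - 1L) * J + j

#' Covariance of the stagewise test statistics
#'
#' Joint covariance (equal to the correlation, as each Z_jk has unit
#' variance) of all J*K stagewise statistics. For the same arm across stages
#' the covariance is \code{sqrt(I_jk / I_j'k)} (j < j'); across different
#' arms it is \code{sqrt(I_jk * I_j'k') * sigma_0^2 / N_{max(j,j'),0}},
#' the dependence induced by the shared control.
#'
#' @param design A \code{\link{mams_design}}.
#' @return (J*K) x (J*K) symmetric positive semi-definite matrix, cells
#'   ordered arm-major (arm 1 stages 1..J, then arm 2, ...), with
#'   row/column names \code{"j<j>k<k>"}.
#' @export
z_covariance <- function(design) {
  J <- design$J; K <- design$K
  I <- information_matrix(design)
  cs <- cum_sizes(design)
  sig0sq <- design$sigma[1]^2
  n <- J * K
  V <- matrix(NA_real_, n, n)
  for (k in seq_len(K)) for (j in seq_len(J)) {
    a <- cell_index(j, k, J)
    for (kk in seq_len(K)) for (jj in seq_len(J)) {
      b <- cell_index(jj, kk, J)
      if (b > a) next
      if (k == kk) {
        V[a, b] <- sqrt(min(I[j, k], I[jj, k]) / max(I[j, k], I[jj, k]))
      } else {
        V[a, b] <- sqrt(I[j, k] * I[jj, kk]) * sig0sq / cs[max(j, jj), 1]
      }
      V[b, a] <- V[a, b]
    }
  }
  nm <- as.vector(vapply(seq_len(K), function(k)
    paste0("j", seq_len(J), "k", k), character(J)))
  dimnames(V) <- list(nm, nm)
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("z covariance matrix is not positive semi-definite", call. = FALSE)
  V
}
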