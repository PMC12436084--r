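#' Interim spacing schemes
#'
#' Named information-fraction schedules for the interim analyses of a
#' J-stage design. Scheme \code{"I"} spaces the analyses equally; scheme
#' \code{"II"} conducts the first interim earlier than equal spacing and
#' spaces the rest equally thereafter; scheme \code{"III"} conducts the first
#' interim later than equal spacing.
#'
#' @param name Scheme name, one of \code{"I"}, \code{"II"}, \code{"III"}.
#' @param J Number of stages (2, 3 or 4 for the named schemes).
#' @return Numeric vector of J information fractions, strictly increasing and
#'   ending at 1.
#' @examples
#' spacing_fractions("II", 4)  # c(1/5, 7/15, 11/15, 1)
#' @export
spacing_fractions <- function(name, J) {
  schemes <- list(
    I   = list(`2` = c(1, 2) / 2,
               `3` = c(1, 2, 3) / 3,
               `4` = c(1, 2, 3, 4) / 4),
    II  = list(`2` = c(7 / 20, 1),
               `3` = c(1 / 4, 5 / 8, 1),
               `4` = c(1 / 5, 7 / 15, 11 / 15, 1)),
    III = list(`2` = c(3 / 4, 1),
               `3` = c(1 / 2, 3 / 4, 1),
               `4` = c(1 / 2, 4 / 6, 5 / 6, 1))
  )
  if (!name %in% names(schemes))
    stop("unknown spacing scheme: ", name, call. = FALSE)
  out <- schemes[[name]][[as.character(J)]]
  if (is.null(out))
    stop(sprintf("spacing scheme '%s' is not defined for J=%d", name, J),
         call. = FALSE)
  out
}

validate_spacing <- function(spacing, J) {
  if (length(spacing) != J)
    stop("spacing must have length J", call. = FALSE)
  if (any(diff(spacing) <= 0) || any(spacing <= 0))
    stop("spacing must be strictly increasing and positive", call. = FALSE)
  if (abs(spacing[J] - 1) > 1e-12)
    stop("last spacing fraction must be exactly 1", call. = FALSE)
  spacing
}

#' Specify a multi-arm multi-stage trial design
#'
#' Builds the static configuration of a group-sequential MAMS trial with K
#' experimental arms compared against a shared control over J stages, with
#' separate (arm-wise) stopping rules. Outcomes are assumed normal with known
#' standard deviations; hypotheses are one-sided
#' (H_k: mu_k - mu_0 <= 0).
#'
#' @param K Number of experimental arms (>= 1).
#' @param J Number of stages (>= 1).
#' @param n Planned group size per arm per stage for an equally incremented
#'   design. With unequal spacing, \code{n} is interpreted so that the
#'   cumulative per-arm size at stage j equals \code{n * J * spacing[j]};
#'   cumulative sizes may then be non-integer (rounding is a reporting
#'   decision, see \code{\link{calibrate_group_size}}).
#' @param spacing Either a numeric vector of J strictly increasing
#'   information fractions ending at 1, or a scheme name passed to
#'   \code{\link{spacing_fractions}}. Default: equal spacing.
#' @param sigma Outcome standard deviation(s): a scalar applied to all arms,
#'   or a vector of length K+1 (control first).
#' @param delta Target interesting treatment effect, in outcome units.
#' @param alpha Familywise error rate target (one-sided).
#' @param power Conjunctive power target (probability of rejecting all K
#'   nulls at the global alternative).
#' @param group_sizes Optional J x (K+1) matrix of per-stage group sizes
#'   (column 1 = control) overriding \code{n}/\code{spacing}-based allocation.
#' @return An object of class \code{"mams_design"}: a list with elements
#'   \code{K}, \code{J}, \code{group_sizes} (J x (K+1) matrix of per-stage
#'   increments), \code{sigma}, \code{delta}, \code{alpha}, \code{beta},
#'   \code{spacing}.
#' @examples
#' d <- mams_design(K = 3, J = 2, n = 42)
#' design_nmax(d)  # 336
#' @export
mams_design <- function(K, J, n = NULL, spacing = NULL, sigma = 1,
                        delta = 0.5, alpha = 0.05, power = 0.8,
                        group_sizes = NULL) {
  stopifnot_scalar(K, "K", positive = TRUE)
  stopifnot_scalar(J, "J", positive = TRUE)
  K <- as.integer(K); J <- as.integer(J)
  if (is.null(spacing)) spacing <- seq_len(J) / J
  if (is.character(spacing)) spacing <- spacing_fractions(spacing, J)
  spacing <- validate_spacing(spacing, J)
  if (length(sigma) == 1L) sigma <- rep(sigma, K + 1L)
  if (length(sigma) != K + 1L)
    stop("sigma must be a scalar or of length K+1", call. = FALSE)
  if (any(sigma <= 0)) stop("sigma must be positive", call. = FALSE)
  stopifnot_scalar(alpha, "alpha"); stopifnot_scalar(power, "power")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0,1)", call. = FALSE)
  if (power <= 0 || power >= 1) stop("power must lie in (0,1)", call. = FALSE)

  if (is.null(group_sizes)) {
    if (is.null(n)) n <- 1
    stopifnot_scalar(n, "n", positive = TRUE)
    inc <- n * J * diff(c(0, spacing))     # per-arm per-stage increments
    group_sizes <- matrix(rep(inc, K + 1L), nrow = J, ncol = K + 1L)
  } else {
    group_sizes <- as.matrix(group_sizes)
    if (nrow(group_sizes) != J || ncol(group_sizes) != K + 1L)
      stop("group_sizes must be a J x (K+1) matrix", call. = FALSE)
  }
  if (any(group_sizes < 0)) stop("group sizes must be >= 0", call. = FALSE)
  if (any(colSums(group_sizes) <= 0))
    stop("every arm needs a positive total sample size", call. = FALSE)
  dimnames(group_sizes) <- list(paste0("stage", seq_len(J)),
                                c("control", paste0("arm", seq_len(K))))
  structure(
    list(K = K, J = J, group_sizes = group_sizes, sigma = sigma,
         delta = delta, alpha = alpha, beta = 1 - power, spacing = spacing),
    class = "mams_design"
  )
}

#' @export
print.mams_design <- function(x, ...) {
  cat(sprintf("MAMS design: K=%d experimental arms, J=%d stages\n", x$K, x$J))
  cat(sprintf("  n_max=%.2f, alpha=%.3f, power=%.3f, delta=%.3f\n",
              design_nmax(x), x$alpha, 1 - x$beta, x$delta))
  cat("  spacing:", paste(fmt_num(x$spacing, 3), collapse = ", "), "\n")
  cat("  cumulative per-arm sizes:",
      paste(fmt_num(cumsum(x$group_sizes[, 2]), 2), collapse = ", "), "\n")
  invisible(x)
}

#' Maximum (fully recruited) sample size of a design
#'
#' @param design A \code{\link{mams_design}} object.
#' @return Total planned sample size across all arms and stages.
#' @export
design_nmax <- function(design) sum(design$group_sizes)

# Cumulative per-arm sample sizes: (J) x (K+1) matrix.
cum_sizes <- function(design) {
  cs <- apply(design$group_sizes, 2, cumsum)
  if (design$J == 1L) cs <- matrix(cs, nrow = 1L,
                                   dimnames = list(NULL, colnames(design$group_sizes)))
  cs
}

# Rescale all group sizes so the per-arm (arm 1) total equals n_arm,
# preserving allocation ratios and spacing.
scale_design <- function(design, n_arm) {
  cur <- sum(design$group_sizes[, 2])
  design$group_sizes <- design$group_sizes * (n_arm / cur)
  design
}

# Signature string for calibration memoisation: everything the calibration
# result depends on.
design_signature <- function(design, shape = NULL) {
  rel <- design$group_sizes / sum(design$group_sizes)
  paste(design$K, design$J,
        paste(signif(design$spacing, 12), collapse = ","),
        paste(signif(rel, 12), collapse = ","),
        paste(signif(design$sigma, 12), collapse = ","),
        signif(design$alpha, 12), signif(design$beta, 12),
        signif(design$delta, 12), shape, sep = "|")
}
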