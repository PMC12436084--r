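#' Stopping boundaries from a named shape family
#'
#' Generates z-scale efficacy (\code{e}) and futility (\code{f}) stopping
#' boundaries over the J analyses from a one-parameter shape family evaluated
#' at the information fractions \code{spacing}. The final futility bound is
#' always set equal to the final efficacy bound, which forces a decision for
#' every arm at stage J.
#'
#' Shapes:
#' \describe{
#'   \item{\code{obf}}{O'Brien-Fleming efficacy \code{e_j = c / sqrt(r_j)}
#'     with symmetric-magnitude interim futility \code{f_j = -e_j} (j < J).}
#'   \item{\code{pocock}}{Constant efficacy \code{e_j = c} with interim
#'     futility \code{f_j = -c} (j < J).}
#'   \item{\code{triangular}}{Triangular-test boundaries
#'     \code{e_j = c (1 + r_j) / (2 sqrt(r_j))},
#'     \code{f_j = c (3 r_j - 1) / (2 sqrt(r_j))}; the two meet at
#'     \code{r_J = 1}.}
#'   \item{\code{fixed_futility_obf}}{O'Brien-Fleming efficacy with the
#'     interim futility bounds fixed at 0 (stop an arm whose interim
#'     one-sided p-value is >= 0.5).}
#'   \item{\code{custom}}{Boundaries supplied directly via \code{e}, \code{f}.}
#' }
#'
#' The scalar \code{c} is normally found by \code{\link{calibrate_boundaries}}
#' so that the familywise error rate hits its target; only the shape of the
#' boundary matters to the user.
#'
#' @param shape Shape name (see Details).
#' @param spacing Information fractions r_1 < ... < r_J = 1.
#' @param c Positive scalar boundary parameter.
#' @param e,f Explicit boundary vectors, only for \code{shape = "custom"}.
#' @return An object of class \code{"mams_boundaries"}: list with \code{e},
#'   \code{f}, \code{shape}, \code{c}.
#' @examples
#' shape_boundaries("obf", c(0.5, 1), c = 2)       # e = (2*sqrt(2), 2)
#' shape_boundaries("fixed_futility_obf", (1:3)/3, c = 2.2)
#' @export
shape_boundaries <- function(shape, spacing, c = NULL, e = NULL, f = NULL) {
  J <- length(spacing)
  shape <- match.arg(shape, c("obf", "pocock", "triangular",
                              "fixed_futility_obf", "custom"))
  if (shape != "custom") {
    stopifnot_scalar(c, "c", positive = TRUE)
    r <- spacing
    if (shape == "obf") {
      e <- c / sqrt(r)
      f <- -e
    } else if (shape == "pocock") {
      e <- rep(c, J)
      f <- rep(-c, J)
    } else if (shape == "triangular") {
      e <- c * (1 + r) / (2 * sqrt(r))
      f <- c * (3 * r - 1) / (2 * sqrt(r))
    } else if (shape == "fixed_futility_obf") {
      e <- c / sqrt(r)
      f <- rep(0, J)
    }
  } else {
    if (is.null(e) || is.null(f))
      stop("custom boundaries need explicit e and f", call. = FALSE)
    if (length(e) != J || length(f) != J)
      stop("e and f must have length J", call. = FALSE)
  }
  f[J] <- e[J]
  if (any(f > e + 1e-12))
    stop("futility bounds must not exceed efficacy bounds", call. = FALSE)
  structure(list(e = as.numeric(e), f = as.numeric(f), shape = shape,
                 c = if (shape == "custom") NA_real_ else c),
            class = "mams_boundaries")
}

#' @export
print.mams_boundaries <- function(x, ...) {
  cat(sprintf("MAMS stopping boundaries (shape: %s", x$shape))
  if (!is.na(x$c)) cat(sprintf(", c=%.4f", x$c))
  cat(")\n")
  print(data.frame(stage = seq_along(x$e), e = x$e, f = x$f),
        row.names = FALSE)
  invisible(x)
}
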