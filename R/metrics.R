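#' Discrimination and wastage metrics
#'
#' Summary statistics of the relative age effect implied by fitted
#' travelling-Gaussian parameters.  All are evaluated at the extreme
#' birthtimes t = 0 (oldest possible) and t = 1 (youngest possible) of the
#' fitted line, i.e. the extrapolation beyond the interval midpoints, not
#' at the midpoints themselves.
#'
#' \describe{
#'   \item{discrimination index}{\eqn{I_D = (1-\Phi(C)) / (1-\Phi(C+A))}:
#'     how many times more likely a day-1-born child is to be selected than
#'     one born on the last day of the cohort year.}
#'   \item{wastage}{in a world without the relative age effect every child
#'     would face the oldest child's selection probability
#'     \eqn{1-\Phi(C)} (a horizontal baseline).  The grey fraction actually
#'     captured is \eqn{Grey = \int_0^1 (1-\Phi(C+At))\,dt / (1-\Phi(C))};
#'     wastage is the shortfall \eqn{W = 1 - Grey}.}
#'   \item{PopEx / PopCon}{\eqn{PopEx = 1/Grey} is the factor by which the
#'     population pool would have to expand to recover the wasted talent;
#'     \eqn{PopCon = Grey = 1 - W} is the effective contraction of the
#'     current pool.}
#'   \item{mean selected birthtime}{\eqn{\bar t_B} of the selected group,
#'     \eqn{\int_0^1 t(1-\Phi(C+At))dt / \int_0^1 (1-\Phi(C+At))dt}; it
#'     decreases both as A grows and as C grows, which is why it confounds
#'     advancement with selection severity.}
#' }
#'
#' The closed form of the selection-curve integral uses
#' \eqn{\int \Phi(a+bt)\,dt = [(a+bt)\Phi(a+bt) + \phi(a+bt)]/b}; the
#' quadrature route integrates the same curve adaptively and is used as an
#' independent cross-check.
#'
#' @name metrics
NULL

#' @rdname metrics
#' @param params a \code{\link{ttg_params}} object.
#' @return \code{discrimination_index} returns the ratio \eqn{I_D}.
#' @examples
#' discrimination_index(ttg_params(0.689, 2.429))  # about 8.31
#' @export
discrimination_index <- function(params) {
  odds_ratio(params, 0, 1)
}

# integral over [0,1] of the selection curve 1 - Phi(C + A t)
.grey_integral <- function(A, C, method = c("closed_form", "quadrature")) {
  method <- match.arg(method)
  if (A == 0) return(stats::pnorm(C, lower.tail = FALSE))
  if (method == "closed_form") {
    xPhi <- function(x) x * stats::pnorm(x) + stats::dnorm(x)
    1 - (xPhi(C + A) - xPhi(C)) / A
  } else {
    stats::integrate(function(t) stats::pnorm(C + A * t, lower.tail = FALSE),
                     0, 1, rel.tol = 1e-10, abs.tol = 1e-13)$value
  }
}

#' @rdname metrics
#' @param method \code{"closed_form"} (exact Gaussian integral) or
#'   \code{"quadrature"} (adaptive numerical integration).
#' @param wastage_method synonym of \code{method} for
#'   \code{rae_metrics}.
#' @return \code{wastage} and \code{rae_metrics} return an
#'   \code{rae_metrics} object: a list with \code{p_oldest},
#'   \code{p_youngest}, \code{I_D}, \code{W}, \code{PopEx}, \code{PopCon},
#'   \code{t_bar_selected}.
#' @examples
#' wastage(ttg_params(0.689, 2.429))  # W = 0.570, PopEx = 2.33
#' @export
wastage <- function(params, method = c("closed_form", "quadrature")) {
  rae_metrics(params, wastage_method = match.arg(method))
}

#' @rdname metrics
#' @export
rae_metrics <- function(params, wastage_method = c("closed_form", "quadrature")) {
  stopifnot(inherits(params, "ttg_params"))
  wastage_method <- match.arg(wastage_method)
  A <- params$A; C <- params$C
  if (A < 0)
    stop("negative advancement: reverse the time axis (reverse_grid) ",
         "so the quality increases with t", call. = FALSE)
  p0 <- selection_probability(params, 0)
  p1 <- selection_probability(params, 1)
  grey <- if (A == 0) 1 else .grey_integral(A, C, wastage_method) / p0
  W <- 1 - grey
  structure(list(p_oldest = p0, p_youngest = p1, I_D = p0 / p1,
                 W = W, PopEx = 1 / grey, PopCon = grey,
                 t_bar_selected = mean_selected_birthtime(params),
                 params = params, wastage_method = wastage_method),
            class = "rae_metrics")
}

#' @rdname metrics
#' @return \code{mean_selected_birthtime} returns \eqn{\bar t_B} of the
#'   selected group, in (0, 1); exactly 0.5 when \code{A = 0}.
#' @export
mean_selected_birthtime <- function(params) {
  stopifnot(inherits(params, "ttg_params"))
  A <- params$A; C <- params$C
  if (A == 0) return(0.5)
  num <- stats::integrate(
    function(t) t * stats::pnorm(C + A * t, lower.tail = FALSE),
    0, 1, rel.tol = 1e-10, abs.tol = 1e-13)$value
  den <- .grey_integral(A, C, "quadrature")
  num / den
}

#' @export
print.rae_metrics <- function(x, digits = 4, ...) {
  p <- x$params
  cat("Relative-age-effect metrics",
      sprintf("(A = %s, C = %s)\n", format(p$A, digits = digits),
              format(p$C, digits = digits)))
  cat(sprintf("  selection probability, oldest (t=0):   %.4f%%\n",
              100 * x$p_oldest))
  cat(sprintf("  selection probability, youngest (t=1): %.4f%%\n",
              100 * x$p_youngest))
  cat(sprintf("  discrimination index I_D: %s\n", format(x$I_D, digits = digits)))
  cat(sprintf("  wastage W: %s   PopEx: %s   PopCon: %s\n",
              format(x$W, digits = digits), format(x$PopEx, digits = digits),
              format(x$PopCon, digits = digits)))
  cat(sprintf("  mean selected birthtime: %s\n",
              format(x$t_bar_selected, digits = digits)))
  invisible(x)
}
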