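#' Travelling-Gaussian model parameters
#'
#' Container for the two parameters of the travelling-Gaussian selection
#' model.  A quality (talent, ability, attribute) is assumed distributed
#' \eqn{N(A t, 1)} at birthtime \eqn{t \in [0,1]}, where \eqn{t = 0} is the
#' oldest possible and \eqn{t = 1} the youngest possible member of the
#' cohort.  Selection retains everyone whose quality exceeds a threshold
#' sitting \eqn{C} standard deviations above the oldest children's mean.
#'
#' @param A annual advancement rate: standard deviations the quality's mean
#'   advances over one cohort year.  Negative values model declining
#'   qualities (e.g. gerontology), though all worked examples here have
#'   \code{A > 0}.
#' @param C selection criterion: z-distance of the selection threshold
#'   above the mean of the oldest children.  Larger values mean more severe
#'   selection.
#' @return An object of class \code{"ttg_params"}: a list with elements
#'   \code{A} and \code{C}.
#' @examples
#' ttg_params(A = 0.8, C = 0.5)
#' @export
ttg_params <- function(A, C) {
  if (!is.numeric(A) || length(A) != 1L || !is.finite(A))
    stop("'A' must be a single finite number", call. = FALSE)
  if (!is.numeric(C) || length(C) != 1L || !is.finite(C))
    stop("'C' must be a single finite number", call. = FALSE)
  structure(list(A = as.numeric(A), C = as.numeric(C)), class = "ttg_params")
}

#' @export
print.ttg_params <- function(x, digits = 4, ...) {
  cat("Travelling-Gaussian parameters\n")
  cat("  A (annual advancement):", format(x$A, digits = digits), "\n")
  cat("  C (selection criterion):", format(x$C, digits = digits), "\n")
  invisible(x)
}

#' Upper-tail probit transform
#'
#' Maps an upper-tail proportion to the z-score above which a standard
#' normal leaves that much mass: \eqn{z = \Phi^{-1}(1 - p)}.  This is the
#' back-translation step that turns observed selection proportions into
#' threshold positions.
#'
#' @param p proportion(s) strictly inside (0, 1).
#' @param what label used in the error message when \code{p} is degenerate;
#'   callers transforming tabulated data pass the offending interval/level.
#' @return z-score(s), strictly decreasing in \code{p}.
#' @examples
#' probit_upper(0.0968)  # 1.30
#' probit_upper(0.5)     # 0
#' @export
probit_upper <- function(p, what = "proportion") {
  if (!is.numeric(p) || any(!is.finite(p)))
    stop("'p' must be finite numeric", call. = FALSE)
  bad <- p <= 0 | p >= 1
  if (any(bad))
    stop(sprintf("%s must lie strictly in (0, 1); offending value(s): %s",
                 what, paste(format(p[bad]), collapse = ", ")),
         call. = FALSE)
  stats::qnorm(p, lower.tail = FALSE)
}

#' Model selection probability at a birthtime
#'
#' Probability that a child born at birthtime \code{t} exceeds the selection
#' threshold: \eqn{1 - \Phi(C + A t)}.  Strictly decreasing in \code{t} when
#' \code{A > 0}.
#'
#' @param params a \code{\link{ttg_params}} object.
#' @param t birthtime(s), normally in \eqn{[0, 1]} (0 = oldest possible).
#' @return selection probability in (0, 1).
#' @examples
#' selection_probability(ttg_params(0.8, 0.5), c(0, 1))  # 0.3085, 0.0968
#' @export
selection_probability <- function(params, t) {
  stopifnot(inherits(params, "ttg_params"))
  if (!is.numeric(t) || any(!is.finite(t)))
    stop("'t' must be finite numeric", call. = FALSE)
  stats::pnorm(params$C + params$A * t, lower.tail = FALSE)
}

#' Infer (A, C) from selection proportions at two birthtimes
#'
#' Back-translates two observed selection proportions into threshold
#' z-scores and solves the line \eqn{z(t) = C + A t} through the two points.
#' With the classic endpoints \code{t_old = 0}, \code{t_young = 1} this is
#' the "difference of z-scores" construction: \eqn{C = \Phi^{-1}(1-p_{old})}
#' and \eqn{A = \Phi^{-1}(1-p_{young}) - C}.
#'
#' @param p_old,p_young selection proportions at the older and younger
#'   birthtime, both strictly in (0, 1).
#' @param t_old,t_young the two birthtimes, with \code{t_old < t_young}.
#' @return a \code{\link{ttg_params}} object.
#' @examples
#' infer_params_two_point(0.3085, 0.0968)  # A = 0.8, C = 0.5
#' infer_params_two_point(0.1357, 0.0287)  # A = 0.8, C = 1.1
#' @export
infer_params_two_point <- function(p_old, p_young, t_old = 0, t_young = 1) {
  if (!isTRUE(t_old < t_young))
    stop("'t_old' must be strictly less than 't_young'", call. = FALSE)
  z_old <- probit_upper(p_old, "p_old")
  z_young <- probit_upper(p_young, "p_young")
  A <- (z_young - z_old) / (t_young - t_old)
  C <- z_old - A * t_old   # extrapolate back to t = 0
  ttg_params(A = A, C = C)
}

#' Selection odds ratio between two birthtimes
#'
#' Ratio of model selection probabilities at two birthtimes,
#' \code{selection_probability(params, t1) / selection_probability(params, t2)}.
#' With \code{t1 = 0}, \code{t2 = 1} this is the discrimination index
#' (see \code{\link{discrimination_index}}).
#'
#' @inheritParams selection_probability
#' @param t1,t2 birthtimes to compare.
#' @return positive ratio; 1 when \code{t1 == t2}.
#' @examples
#' odds_ratio(ttg_params(0.8, 1.1), 0, 1)  # 4.72
#' @export
odds_ratio <- function(params, t1, t2) {
  selection_probability(params, t1) / selection_probability(params, t2)
}
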