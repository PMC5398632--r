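#' Estimate the advancement rate from probit points
#'
#' Three estimators of the annual advancement rate A from a
#' \code{\link{probit_points}} set, in increasing order of data use:
#' \describe{
#'   \item{endpoint}{difference of z between the last and first interval at
#'     each severity level, averaged across levels and rescaled to a full
#'     year (observed midpoints span less than the year; for mid-month
#'     points of a 12-month grid the rescaling ratio is 12/11).}
#'   \item{per-level}{OLS of z on \code{t_B} within each level; A is the
#'     unweighted mean of the slopes.}
#'   \item{stacked}{a single OLS of all z on \code{t_B} plus severity-level
#'     dummies (reference = least severe level present); A is the
#'     \code{t_B} coefficient and C the intercept.}
#' }
#' All fits are unweighted ordinary least squares via \code{stats::lm}
#' (QR decomposition).
#'
#' @name estimation
NULL

new_ttg_fit <- function(method, A, C = NA_real_, level_offsets = numeric(),
                        R2 = NA_real_, t_A = NA_real_, df = NA_integer_,
                        p_A = NA_real_, per_level = NULL, model = NULL,
                        span_scale = NA_real_) {
  structure(list(method = method, A = A, C = C, level_offsets = level_offsets,
                 R2 = R2, t_A = t_A, df = df, p_A = p_A,
                 per_level = per_level, model = model,
                 span_scale = span_scale),
            class = "ttg_fit")
}

#' @export
print.ttg_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Advancement-rate fit (%s method)\n", x$method))
  cat("  A =", format(x$A, digits = digits))
  if (is.finite(x$C)) cat("   C =", format(x$C, digits = digits))
  cat("\n")
  if (is.finite(x$R2))
    cat(sprintf("  R^2 = %s,  t(%d) = %s,  p = %s\n",
                format(x$R2, digits = digits), x$df,
                format(x$t_A, digits = digits),
                format.pval(x$p_A, digits = 3)))
  if (!is.null(x$per_level)) {
    cat("  Per-level components:\n")
    print.data.frame(x$per_level, row.names = FALSE, digits = digits)
  }
  invisible(x)
}

#' @export
coef.ttg_fit <- function(object, ...) {
  c(A = object$A, C = object$C, object$level_offsets)
}

#' Fitted parameters as a ttg_params object
#'
#' @param fit a \code{ttg_fit} from \code{\link{stacked_regression}} (or any
#'   fit with a finite intercept).
#' @return a \code{\link{ttg_params}}.
#' @export
fit_params <- function(fit) {
  stopifnot(inherits(fit, "ttg_fit"))
  if (!is.finite(fit$C))
    stop("fit has no intercept; use the stacked method", call. = FALSE)
  ttg_params(A = fit$A, C = fit$C)
}

# summary.lm warns on numerically perfect fits; those arise by design for
# noiseless model-generated data, so that one warning is muffled
.quiet_summary <- function(fit) {
  withCallingHandlers(summary(fit), warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
}

.split_levels <- function(points) {
  split(as.data.frame(points),
        factor(points$level, levels = unique(points$level[
          order(points$level_index)])))
}

#' @rdname estimation
#' @param points a \code{\link{probit_points}} object.
#' @param span_scale ratio extrapolating the observed midpoint span to the
#'   full year; default \code{1 / (t_last - t_first)}.  Pass \code{12/11}
#'   to match the mid-month convention for 12-month grids.
#' @return a \code{ttg_fit} object.
#' @export
endpoint_estimate <- function(points, span_scale = NULL) {
  stopifnot(inherits(points, "probit_points"))
  t_first <- min(points$t_B); t_last <- max(points$t_B)
  if (t_last <= t_first)
    stop("degenerate input: all points share one birthtime", call. = FALSE)
  if (is.null(span_scale)) span_scale <- 1 / (t_last - t_first)
  per <- lapply(.split_levels(points), function(d) {
    i1 <- which(d$t_B == t_first); i2 <- which(d$t_B == t_last)
    if (length(i1) != 1L || length(i2) != 1L) return(NULL)
    diff_z <- d$z[i2] - d$z[i1]
    data.frame(level = d$level[1], diff_z = diff_z,
               slope = diff_z * span_scale,
               intercept = d$z[i1] - diff_z * span_scale * t_first,
               stringsAsFactors = FALSE)
  })
  skipped <- names(per)[vapply(per, is.null, TRUE)]
  if (length(skipped))
    warning("level(s) missing an endpoint interval skipped: ",
            paste(skipped, collapse = ", "), call. = FALSE)
  per <- do.call(rbind, per)
  if (is.null(per))
    stop("no level contains both the first and last interval", call. = FALSE)
  new_ttg_fit("endpoint", A = mean(per$slope), C = per$intercept[1],
              per_level = per, span_scale = span_scale)
}

#' @rdname estimation
#' @export
per_level_regression <- function(points) {
  stopifnot(inherits(points, "probit_points"))
  per <- lapply(.split_levels(points), function(d) {
    if (length(unique(d$t_B)) < 2L) return(NULL)
    f <- stats::lm(z ~ t_B, data = d)
    data.frame(level = d$level[1], slope = unname(stats::coef(f)[2]),
               intercept = unname(stats::coef(f)[1]),
               R2 = .quiet_summary(f)$r.squared, n = nrow(d),
               stringsAsFactors = FALSE)
  })
  skipped <- names(per)[vapply(per, is.null, TRUE)]
  if (length(skipped))
    warning("level(s) with fewer than two distinct birthtimes skipped: ",
            paste(skipped, collapse = ", "), call. = FALSE)
  per <- do.call(rbind, per)
  if (is.null(per))
    stop("no level has two distinct birthtimes to regress on", call. = FALSE)
  new_ttg_fit("per_level", A = mean(per$slope), C = per$intercept[1],
              per_level = per)
}

.stacked_data <- function(points) {
  d <- as.data.frame(points)
  lev_order <- unique(d$level[order(d$level_index)])
  d$level <- factor(d$level, levels = lev_order)  # reference = least severe
  d
}

.stacked_formula <- function(d, extra = NULL) {
  rhs <- "t_B"
  if (nlevels(d$level) > 1L) rhs <- paste(rhs, "+ level")
  if (!is.null(extra)) rhs <- paste(rhs, "+", extra)
  stats::as.formula(paste("z ~", rhs))
}

#' @rdname estimation
#' @export
stacked_regression <- function(points) {
  stopifnot(inherits(points, "probit_points"))
  d <- .stacked_data(points)
  fit <- stats::lm(.stacked_formula(d), data = d)
  if (fit$rank < length(stats::coef(fit)))
    stop("rank-deficient design; collinear column(s): ",
         paste(names(which(is.na(stats::coef(fit)))), collapse = ", "),
         call. = FALSE)
  s <- .quiet_summary(fit)
  cf <- s$coefficients
  offs <- stats::coef(fit)[grep("^level", names(stats::coef(fit)))]
  names(offs) <- sub("^level", "", names(offs))
  new_ttg_fit("stacked",
              A = unname(cf["t_B", "Estimate"]),
              C = unname(cf["(Intercept)", "Estimate"]),
              level_offsets = offs, R2 = s$r.squared,
              t_A = unname(cf["t_B", "t value"]),
              df = fit$df.residual,
              p_A = unname(cf["t_B", "Pr(>|t|)"]),
              model = fit)
}

#' Nested-model comparison against the linear stacked fit
#'
#' Tests whether the stacked linear model (z on birthtime plus level
#' dummies) is improved by adding either a quadratic birthtime term (a
#' check for non-linear advancement or seasonality) or
#' birthtime-by-level interactions (a check that all severity levels share
#' one slope).  The statistic is the usual incremental-R-squared F,
#' \eqn{F = (\Delta R^2 / q) / ((1 - R^2_{full}) / df_{full})}, computed
#' from residual sums of squares for numerical safety: data that fit the
#' base model exactly give F = 0, not 0/0.
#'
#' @param points a \code{\link{probit_points}} object.
#' @param variant \code{"quadratic"} adds \code{t_B^2};
#'   \code{"interaction"} adds \code{t_B} x level-dummy terms.
#' @return a \code{ttg_model_comparison} object with fields \code{F},
#'   \code{df1}, \code{df2}, \code{p}, \code{variant}, \code{R2_base},
#'   \code{R2_full}.
#' @export
compare_models <- function(points, variant = c("quadratic", "interaction")) {
  stopifnot(inherits(points, "probit_points"))
  variant <- match.arg(variant)
  d <- .stacked_data(points)
  if (variant == "interaction" && nlevels(d$level) < 2L)
    stop("interaction comparison needs at least two severity levels",
         call. = FALSE)
  base <- stats::lm(.stacked_formula(d), data = d)
  extra <- switch(variant, quadratic = "I(t_B^2)", interaction = "t_B:level")
  full <- stats::lm(.stacked_formula(d, extra), data = d)
  q <- base$df.residual - full$df.residual
  df2 <- full$df.residual
  if (df2 <= 0)
    stop("no residual degrees of freedom left for the comparison",
         call. = FALSE)
  rss_base <- sum(stats::resid(base)^2)
  rss_full <- sum(stats::resid(full)^2)
  tss <- sum((d$z - mean(d$z))^2)
  d_rss <- max(rss_base - rss_full, 0)
  # data fitting the base model to machine precision carry no evidence for
  # the added terms: report F = 0 rather than a 0/0 artefact
  exact <- rss_base <= 1e-12 * max(tss, .Machine$double.xmin)
  F_stat <- if (exact) 0 else (d_rss / q) / (rss_full / df2)
  structure(list(F = F_stat, df1 = q, df2 = df2,
                 p = stats::pf(F_stat, q, df2, lower.tail = FALSE),
                 variant = variant,
                 R2_base = 1 - rss_base / tss,
                 R2_full = 1 - rss_full / tss),
            class = "ttg_model_comparison")
}

#' @export
print.ttg_model_comparison <- function(x, digits = 4, ...) {
  cat(sprintf("Incremental R^2 test (%s terms): F(%d, %d) = %s, p = %s\n",
              x$variant, x$df1, x$df2, format(x$F, digits = digits),
              format.pval(x$p, digits = 3)))
  invisible(x)
}
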