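#' Regression-ready probit point sets
#'
#' A probit point set is the regression-ready form of grouped selection
#' data: one row per (interval, severity level) with the midpoint birthtime
#' \code{t_B}, the upper-tail proportion \code{p}, its probit \code{z}, and
#' the denominator \code{n}.  Points whose proportion is degenerate (0 or 1)
#' cannot be probit-transformed; depending on the zero-cell policy they are
#' either dropped (and recorded in the \code{excluded} attribute) or
#' continuity-corrected.
#'
#' @name probit_points
NULL

new_probit_points <- function(df, excluded = NULL) {
  if (is.null(excluded))
    excluded <- data.frame(interval = character(), level = character(),
                           reason = character(), stringsAsFactors = FALSE)
  rownames(df) <- NULL
  structure(df, excluded = excluded,
            class = c("probit_points", "data.frame"))
}

#' @export
print.probit_points <- function(x, ...) {
  cat(sprintf("Probit point set: %d points, %d level(s)\n",
              nrow(x), length(unique(x$level))))
  print.data.frame(x, row.names = FALSE, ...)
  ex <- excluded_points(x)
  if (nrow(ex) > 0) {
    cat("Excluded points:\n")
    print.data.frame(ex, row.names = FALSE)
  }
  invisible(x)
}

#' @rdname probit_points
#' @param points a \code{probit_points} object.
#' @return \code{excluded_points} returns the data frame of dropped points
#'   (columns \code{interval}, \code{level}, \code{reason}).
#' @export
excluded_points <- function(points) {
  attr(points, "excluded")
}

# shared degenerate-proportion handling; returns list(p, keep, reason)
.apply_zero_cell <- function(x, n, policy) {
  p <- x / n
  keep <- rep(TRUE, length(p))
  reason <- rep(NA_character_, length(p))
  degen <- is.finite(p) & (p <= 0 | p >= 1)
  if (policy == "correct") {
    p[degen] <- (x[degen] + 0.5) / (n[degen] + 1)
  } else {
    keep[degen] <- FALSE
    reason[degen] <- "degenerate proportion"
  }
  bad <- !is.finite(p)
  keep[bad] <- FALSE
  reason[bad] <- "zero denominator"
  list(p = p, keep = keep, reason = reason)
}

#' Probit-transform a rating table
#'
#' Converts the cumulative counts of a rating table into upper-tail
#' proportions and z-scores, one point per interval and cumulative level
#' from the second-lowest up (the "at or above lowest" column is everyone,
#' p = 1, and is never transformed).  The denominator is the interval row
#' total, i.e. ratings are treated as exhaustive within the sampled
#' children.
#'
#' @param table a \code{\link{rating_table}}.
#' @param zero_cell policy for proportions of exactly 0 or 1:
#'   \code{"exclude"} drops the point and records it, \code{"correct"}
#'   applies the continuity correction \eqn{p^* = (x + 0.5)/(n + 1)}.
#' @return a \code{\link{probit_points}} object with columns
#'   \code{interval}, \code{t_B}, \code{level}, \code{level_index},
#'   \code{p}, \code{z}, \code{n}.
#' @examples
#' g <- month_grid("Sep")
#' counts <- matrix(rpois(60, 50), 12, 5)
#' to_probit_points(rating_table(g, counts))
#' @export
to_probit_points <- function(table, zero_cell = c("exclude", "correct")) {
  stopifnot(inherits(table, "rating_table"))
  zero_cell <- match.arg(zero_cell)
  cum <- cumulate(table)
  n_lev <- ncol(cum)
  if (n_lev < 2L)
    stop("need at least two rating levels to form probit points", call. = FALSE)
  tot <- cum[, 1]
  rows <- list(); excl <- list()
  for (k in 2:n_lev) {
    h <- .apply_zero_cell(cum[, k], tot, zero_cell)
    lev <- table$levels[k]
    if (any(!h$keep))
      excl[[length(excl) + 1L]] <- data.frame(
        interval = table$grid$label[!h$keep], level = lev,
        reason = h$reason[!h$keep], stringsAsFactors = FALSE)
    ok <- h$keep
    if (any(ok))
      rows[[length(rows) + 1L]] <- data.frame(
        interval = table$grid$label[ok], t_B = table$grid$t_mid[ok],
        level = lev, level_index = k - 1L, p = h$p[ok],
        z = probit_upper(h$p[ok]), n = tot[ok], stringsAsFactors = FALSE)
  }
  zero_rows <- tot == 0
  if (any(zero_rows))
    warning("interval(s) with zero row total excluded: ",
            paste(table$grid$label[zero_rows], collapse = ", "), call. = FALSE)
  if (length(rows) == 0)
    stop("no usable probit points: all proportions degenerate", call. = FALSE)
  new_probit_points(do.call(rbind, rows),
                    if (length(excl)) do.call(rbind, excl) else NULL)
}

#' Probit points from selection counts against population pools
#'
#' Builds a single-severity probit point set from per-interval selected
#' counts (or shares of a known total) and the population pool of each
#' interval: \eqn{p_i = selected_i / pool_i}, \eqn{z_i = \Phi^{-1}(1-p_i)}.
#' Fractional selected counts are allowed; they arise naturally from
#' shares times a total.
#'
#' @param grid a \code{\link{birth_grid}} whose \code{pool} column is
#'   filled in.
#' @param selected selected count per interval, or shares summing to ~1 if
#'   \code{total_selected} is given.
#' @param total_selected total number selected, used to convert shares to
#'   counts.
#' @param zero_cell see \code{\link{to_probit_points}}.
#' @return a \code{\link{probit_points}} object with a single level
#'   \code{"selected"}.
#' @examples
#' g <- tercile_grid(c(33736, 32378, 33886))
#' selection_points(g, c(0.57, 0.29, 0.14), total_selected = 320)
#' @export
selection_points <- function(grid, selected, total_selected = NULL,
                             zero_cell = c("exclude", "correct")) {
  stopifnot(inherits(grid, "birth_grid"))
  zero_cell <- match.arg(zero_cell)
  if (any(is.na(grid$pool)) || any(grid$pool <= 0))
    stop("'grid' must carry positive population pools", call. = FALSE)
  if (length(selected) != nrow(grid))
    stop("'selected' must have one entry per interval", call. = FALSE)
  if (!is.null(total_selected)) {
    if (abs(sum(selected) - 1) > 0.02)
      warning("shares do not sum to 1 (", format(sum(selected)),
              "); converting anyway", call. = FALSE)
    selected <- selected * total_selected
  }
  if (any(selected < 0)) stop("'selected' must be non-negative", call. = FALSE)
  if (any(selected > grid$pool))
    stop("selected count exceeds pool in interval(s): ",
         paste(grid$label[selected > grid$pool], collapse = ", "),
         call. = FALSE)
  h <- .apply_zero_cell(selected, grid$pool, zero_cell)
  excl <- if (any(!h$keep))
    data.frame(interval = grid$label[!h$keep], level = "selected",
               reason = h$reason[!h$keep], stringsAsFactors = FALSE)
  ok <- h$keep
  if (!any(ok))
    stop("no usable probit points: all proportions degenerate", call. = FALSE)
  new_probit_points(
    data.frame(interval = grid$label[ok], t_B = grid$t_mid[ok],
               level = "selected", level_index = 1L, p = h$p[ok],
               z = probit_upper(h$p[ok]), n = grid$pool[ok],
               stringsAsFactors = FALSE),
    excl)
}
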