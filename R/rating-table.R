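#' Ordinal rating tables by birth interval
#'
#' Holds counts of children per birth interval and ordinal rating level
#' (lowest to highest), e.g. teacher ratings from "well below average" to
#' "well above average" by birth month.  The cumulative "at or above level
#' k" columns of such a table are the grouped selection proportions the
#' travelling-Gaussian model works with.
#'
#' @param grid a \code{\link{birth_grid}} with one row per table row.
#' @param counts integer-like matrix, intervals x levels, non-negative;
#'   column order runs lowest to highest level.
#' @param levels ordered level labels (lowest first); defaults to the
#'   column names of \code{counts} or \code{1:K}.
#' @param reverse_scored logical; \code{TRUE} marks an item whose raw scale
#'   runs opposite to the quality of interest (e.g. "is restless"), to be
#'   flipped with \code{\link{reverse_code}} before analysis.
#' @return An object of class \code{"rating_table"}.
#' @export
rating_table <- function(grid, counts, levels = NULL, reverse_scored = FALSE) {
  stopifnot(inherits(grid, "birth_grid"))
  counts <- as.matrix(counts)
  if (nrow(counts) != nrow(grid))
    stop("'counts' must have one row per grid interval", call. = FALSE)
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("'counts' must be non-negative", call. = FALSE)
  if (is.null(levels)) levels <- colnames(counts)
  if (is.null(levels)) levels <- as.character(seq_len(ncol(counts)))
  if (length(levels) != ncol(counts))
    stop("one level label per counts column required", call. = FALSE)
  dimnames(counts) <- list(grid$label, levels)
  structure(list(grid = grid, counts = counts, levels = as.character(levels),
                 reverse_scored = isTRUE(reverse_scored)),
            class = "rating_table")
}

#' @export
print.rating_table <- function(x, ...) {
  cat(sprintf("Rating table: %d intervals x %d levels%s\n", nrow(x$counts),
              ncol(x$counts), if (x$reverse_scored) " (reverse scored)" else ""))
  print(x$counts)
  invisible(x)
}

#' Reverse-code a rating table
#'
#' Flips the level order (and the count columns with it) so that higher
#' levels always mean "more of the quality of interest".  Applying it twice
#' restores the original table.
#'
#' @param table a \code{\link{rating_table}}.
#' @return the reverse-coded \code{\link{rating_table}}.
#' @export
reverse_code <- function(table) {
  stopifnot(inherits(table, "rating_table"))
  k <- ncol(table$counts)
  rating_table(table$grid, table$counts[, k:1, drop = FALSE],
               levels = rev(table$levels),
               reverse_scored = !table$reverse_scored)
}

#' Cumulative "at or above" counts
#'
#' Entry (i, k) is the number of children in interval i rated at level k or
#' higher; the lowest-level column therefore equals the interval row total.
#'
#' @param table a \code{\link{rating_table}}.
#' @return matrix of cumulative counts, intervals x levels, columns named
#'   \code{">= <level>"}.
#' @export
cumulate <- function(table) {
  stopifnot(inherits(table, "rating_table"))
  out <- t(apply(table$counts, 1, function(r) rev(cumsum(rev(r)))))
  dimnames(out) <- list(rownames(table$counts),
                        paste0(">=", table$levels))
  out
}
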