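#' Birth-interval grids
#'
#' A birth grid partitions the cohort year into contiguous, non-overlapping
#' labelled intervals (months, terciles, quarters, arbitrary day ranges),
#' assigns each the midpoint birthtime
#' \eqn{t_{mid} = (days\_before + days\_in/2)/year\_length} on \eqn{[0,1]},
#' and optionally carries the population pool size of each interval.
#' Grouped data are summarised at these midpoints (the usual grouped-data
#' assumption that the mean within an interval is its midpoint).
#'
#' @param days_in numeric vector of interval lengths in days; fractional
#'   values are allowed (e.g. 29 February weighted 0.25 over a 365.25-day
#'   year).
#' @param labels character labels, one per interval.
#' @param pools optional non-negative population counts per interval.
#' @param year_length days in the cohort year; must equal
#'   \code{sum(days_in)}.
#' @param cohort_start label of day 1 of the cohort year.
#' @return An object of class \code{"birth_grid"}: a data frame with columns
#'   \code{label}, \code{days_before}, \code{days_in}, \code{pool},
#'   \code{t_mid}, plus attributes \code{year_length} and
#'   \code{cohort_start}.
#' @examples
#' month_grid("Sep")                       # the school-year month grid
#' tercile_grid(c(33736, 32378, 33886))    # competition-year thirds
#' @export
birth_grid <- function(days_in, labels = NULL, pools = NULL,
                       year_length = sum(days_in), cohort_start = "day 1") {
  if (!is.numeric(days_in) || length(days_in) < 1L || any(days_in <= 0))
    stop("'days_in' must be positive interval lengths", call. = FALSE)
  n <- length(days_in)
  if (is.null(labels)) labels <- paste0("I", seq_len(n))
  if (length(labels) != n) stop("one label per interval required", call. = FALSE)
  if (!is.null(pools)) {
    if (length(pools) != n || any(pools < 0))
      stop("'pools' must be one non-negative count per interval", call. = FALSE)
  } else pools <- rep(NA_real_, n)
  if (abs(sum(days_in) - year_length) > 1e-8)
    stop(sprintf("interval lengths sum to %.4f but year_length is %.4f",
                 sum(days_in), year_length), call. = FALSE)
  days_before <- cumsum(c(0, days_in[-n]))
  t_mid <- (days_before + days_in / 2) / year_length
  structure(
    data.frame(label = as.character(labels), days_before = days_before,
               days_in = as.numeric(days_in), pool = as.numeric(pools),
               t_mid = t_mid, stringsAsFactors = FALSE),
    year_length = year_length, cohort_start = cohort_start,
    class = c("birth_grid", "data.frame"))
}

#' @export
print.birth_grid <- function(x, ...) {
  cat(sprintf("Birth-interval grid: %d intervals over a %s-day year (start: %s)\n",
              nrow(x), format(attr(x, "year_length")), attr(x, "cohort_start")))
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

.month_names <- c("Jan", "Feb", "Mar", "Apr", "May", "Jun",
                  "Jul", "Aug", "Sep", "Oct", "Nov", "Dec")
.month_days <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)

#' @rdname birth_grid
#' @param start_month name of the first month of the cohort year
#'   (three-letter or full English name), e.g. \code{"Sep"} for the English
#'   school year.
#' @details \code{month_grid} builds the 12-month grid.  With
#'   \code{year_length = 365} February counts 28 days; with 365.25 it counts
#'   28.25 (29 February weighted by its leap-cycle frequency).
#' @export
month_grid <- function(start_month = "Sep", year_length = 365) {
  if (!year_length %in% c(365, 365.25))
    stop("'year_length' must be 365 or 365.25", call. = FALSE)
  i <- pmatch(tolower(substr(start_month, 1, 3)), tolower(.month_names))
  if (is.na(i)) stop("unknown month name: ", start_month, call. = FALSE)
  ord <- ((i - 1 + 0:11) %% 12) + 1
  days <- .month_days[ord]
  if (year_length == 365.25) days[.month_names[ord] == "Feb"] <- 28.25
  birth_grid(days, labels = .month_names[ord], year_length = year_length,
             cohort_start = paste(.month_names[i], "1"))
}

#' @rdname birth_grid
#' @details \code{tercile_grid} builds the three thirds of the English
#'   soccer competition year (Sep-Dec, Jan-Apr, May-Aug) with day lengths
#'   122, 120.25 and 123 over a 365.25-day year, and attaches the given
#'   population pools.
#' @export
tercile_grid <- function(pools = NULL, cohort_start = "Sep 1") {
  if (!is.null(pools) && length(pools) != 3L)
    stop("'pools' must contain exactly three counts", call. = FALSE)
  birth_grid(c(122, 120.25, 123), labels = c("T1", "T2", "T3"),
             pools = pools, year_length = 365.25, cohort_start = cohort_start)
}

#' Midpoint birthtimes of a grid
#'
#' @param grid a \code{\link{birth_grid}}.
#' @return numeric vector of interval midpoints on \eqn{[0,1]}.
#' @export
midpoints <- function(grid) {
  stopifnot(inherits(grid, "birth_grid"))
  grid$t_mid
}

#' Reverse the time axis of a grid
#'
#' Reverses interval order so midpoints map \eqn{t \mapsto 1 - t}; useful
#' for qualities that decline with age (negative advancement).
#'
#' @param grid a \code{\link{birth_grid}}.
#' @return a \code{\link{birth_grid}} running the other way.
#' @export
reverse_grid <- function(grid) {
  stopifnot(inherits(grid, "birth_grid"))
  n <- nrow(grid)
  birth_grid(rev(grid$days_in), labels = rev(grid$label),
             pools = if (all(is.na(grid$pool))) NULL else rev(grid$pool),
             year_length = attr(grid, "year_length"),
             cohort_start = paste0("reversed ", attr(grid, "cohort_start")))
}
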