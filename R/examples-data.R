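#' Packaged worked-example data
#'
#' Two small datasets ship with the package as plain CSV under
#' \code{inst/extdata}:
#' \describe{
#'   \item{speaking_listening}{teacher ratings of speaking-and-listening
#'     performance for English/Welsh children of the 2000-01 school-year
#'     cohort (Millennium Cohort Study, fourth sweep), counts by birth
#'     month and five-point scale from "well below average" (1) to "well
#'     above average" (5).}
#'   \item{epl_academy}{English Premier League academy intake for the
#'     2008-09 competition year: selected boys per birth tercile
#'     (shares 57/29/14 per cent of an estimated 320 places, hence the
#'     fractional counts) against estimated tercile population pools of an
#'     aspirant-player population of 100,000.}
#' }
#'
#' @param pool_total aspirant-player population for the academy data; the
#'   printed tercile pools (33,736; 32,378; 33,886) are scaled
#'   proportionally, which is how sensitivity analyses to the judgmental
#'   pool estimate are run.
#' @return \code{speaking_listening_table} returns a
#'   \code{\link{rating_table}} on the September-start 365-day month grid;
#'   \code{epl_academy_grid} returns the tercile \code{\link{birth_grid}}
#'   with pools attached; \code{epl_academy_points} returns the
#'   regression-ready \code{\link{probit_points}} for the academy data.
#' @examples
#' stacked_regression(epl_academy_points())   # A = 0.689, C = 2.429
#' @export
speaking_listening_table <- function() {
  read_rating_table(
    system.file("extdata", "speaking_listening.csv", package = "ttgrae",
                mustWork = TRUE),
    year_length = 365, cohort_start = "Sep")
}

.epl_pools <- c(T1 = 33736, T2 = 32378, T3 = 33886)
.epl_shares <- c(0.57, 0.29, 0.14)
.epl_places <- 320

#' @rdname speaking_listening_table
#' @export
epl_academy_grid <- function(pool_total = 100000) {
  tercile_grid(unname(.epl_pools) * pool_total / 100000)
}

#' @rdname speaking_listening_table
#' @export
epl_academy_points <- function(pool_total = 100000) {
  selection_points(epl_academy_grid(pool_total), .epl_shares,
                   total_selected = .epl_places)
}
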