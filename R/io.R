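#' Read and write birth-interval tables
#'
#' The on-disk schema is a plain UTF-8 CSV with header
#' \code{interval,<level1>,...,<levelK>[,pool]}, intervals in cohort order.
#' Interval geometry (year length, cohort start) travels in a small JSON or
#' YAML config rather than in the CSV; \code{read_rating_table} accepts the
#' same keys as arguments.
#'
#' @param file path to the CSV.
#' @param grid a \code{\link{birth_grid}} describing the rows; by default a
#'   12-month grid starting at \code{cohort_start} is assumed when the file
#'   has 12 rows, and a tercile grid when it has 3.
#' @param year_length,cohort_start grid parameters used when \code{grid} is
#'   not supplied.
#' @param levels,reverse_scored see \code{\link{rating_table}}.
#' @return \code{read_rating_table} returns a \code{\link{rating_table}};
#'   the pool column, when present, is attached to its grid.
#' @export
read_rating_table <- function(file, grid = NULL, year_length = 365,
                              cohort_start = "Sep", levels = NULL,
                              reverse_scored = FALSE) {
  df <- utils::read.csv(file, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "interval")
    stop("malformed CSV: first column must be 'interval' (got '",
         names(df)[1], "')", call. = FALSE)
  has_pool <- names(df)[ncol(df)] == "pool"
  count_cols <- setdiff(names(df), c("interval", "pool"))
  counts <- as.matrix(df[count_cols])
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("malformed CSV: negative or missing counts", call. = FALSE)
  if (is.null(grid)) {
    grid <- if (nrow(df) == 12) month_grid(cohort_start, year_length)
            else if (nrow(df) == 3) tercile_grid()
            else stop("supply 'grid' for tables that are not monthly or tercile",
                      call. = FALSE)
  }
  if (!identical(as.character(df$interval), grid$label))
    stop("interval labels do not match the grid: expected ",
         paste(grid$label, collapse = ","), call. = FALSE)
  if (has_pool)
    grid <- birth_grid(grid$days_in, grid$label, pools = df$pool,
                       year_length = attr(grid, "year_length"),
                       cohort_start = attr(grid, "cohort_start"))
  rating_table(grid, counts, levels = levels %||% count_cols,
               reverse_scored = reverse_scored)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_rating_table
#' @param table a \code{\link{rating_table}} to write.
#' @export
write_rating_table <- function(table, file) {
  stopifnot(inherits(table, "rating_table"))
  df <- data.frame(interval = table$grid$label, table$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(is.na(table$grid$pool))) df$pool <- table$grid$pool
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Read and write probit point sets
#'
#' The regression-ready CSV schema is \code{t_B,level,p,z,n} (plus an
#' \code{interval} column when known).
#'
#' @param points a \code{\link{probit_points}} object.
#' @param file path to the CSV.
#' @return \code{read_probit_points} returns a \code{\link{probit_points}}
#'   object; \code{z} is recomputed from \code{p} and checked against the
#'   stored value.
#' @export
write_probit_points <- function(points, file) {
  stopifnot(inherits(points, "probit_points"))
  utils::write.csv(as.data.frame(points), file, row.names = FALSE,
                   quote = FALSE)
  invisible(file)
}

#' @rdname write_probit_points
#' @export
read_probit_points <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("t_B", "level", "p", "z", "n")
  if (!all(need %in% names(df)))
    stop("malformed probit CSV: need columns ", paste(need, collapse = ","),
         call. = FALSE)
  if (is.null(df$interval)) df$interval <- as.character(seq_len(nrow(df)))
  if (is.null(df$level_index))
    df$level_index <- as.integer(factor(df$level, levels = unique(df$level)))
  z_chk <- probit_upper(df$p)
  if (any(abs(z_chk - df$z) > 1e-3))
    warning("stored z disagrees with probit of p; using recomputed z",
            call. = FALSE)
  df$z <- z_chk
  new_probit_points(df[c("interval", "t_B", "level", "level_index",
                         "p", "z", "n")])
}

#' Read an analysis config
#'
#' Reads a JSON (or YAML, if the \pkg{yaml} package is installed) config
#' with any of the keys \code{year_length}, \code{cohort_start},
#' \code{levels}, \code{reverse_scored}, \code{zero_cell_policy},
#' \code{pools}, \code{pool_total}, \code{pool_shares}.
#'
#' @param file path to a .json, .yaml or .yml file.
#' @return named list of config values.
#' @export
read_config <- function(file) {
  ext <- tolower(tools::file_ext(file))
  cfg <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML configs need the 'yaml' package", call. = FALSE)
    yaml::read_yaml(file)
  } else jsonlite::read_json(file, simplifyVector = TRUE)
  known <- c("year_length", "cohort_start", "levels", "reverse_scored",
             "zero_cell_policy", "pools", "pool_total", "pool_shares",
             "total_selected")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    warning("ignoring unknown config key(s): ",
            paste(unknown, collapse = ", "), call. = FALSE)
  cfg
}
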