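#' Cohort simulation from the forward model
#'
#' Draws synthetic selection data from the travelling-Gaussian generative
#' model: each child born at birthtime t has a latent quality
#' \eqn{N(A t, 1)}, and clears severity level k when the quality exceeds
#' criterion \eqn{C_k}.  Because every child has a single latent quality,
#' the counts clearing successively stricter criteria are nested, exactly
#' like cumulative "at or above" columns of a rating table.
#'
#' @name simulation
NULL

# evaluate code under a temporary RNG state; caller's stream is untouched
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' @rdname simulation
#' @param grid a \code{\link{birth_grid}} with positive pools.
#' @param params a \code{\link{ttg_params}}; its \code{C} is used when
#'   \code{criteria} is not given.
#' @param criteria numeric vector of selection criteria, one per cumulative
#'   severity level, strictly increasing (stricter levels sit further into
#'   the tail).  Length 1 simulates plain selection counts; length K > 1
#'   simulates a (K+1)-category ordinal rating table.
#' @param mode \code{"binomial"} draws interval-level counts (sequential
#'   conditional binomials across nested levels); \code{"individual"} draws
#'   each child's birthtime uniformly within its interval and one latent
#'   quality, then classifies; \code{"expected"} returns the noiseless
#'   expected counts (fractional).
#' @param seed integer seed; identical seeds give identical output.
#' @return For a single criterion, a data frame with columns
#'   \code{interval}, \code{pool}, \code{selected}; otherwise a
#'   \code{\link{rating_table}}.
#' @examples
#' g <- tercile_grid(c(33736, 32378, 33886))
#' simulate_counts(g, ttg_params(0.689, 2.429), seed = 1)
#' @export
simulate_counts <- function(grid, params, criteria = NULL,
                            mode = c("binomial", "individual", "expected"),
                            seed = 20170420) {
  stopifnot(inherits(grid, "birth_grid"), inherits(params, "ttg_params"))
  mode <- match.arg(mode)
  if (is.null(criteria)) criteria <- params$C
  K <- length(criteria)
  if (K > 1 && any(diff(criteria) <= 0))
    stop("'criteria' must be strictly increasing in severity ",
         "(cumulative counts would not nest)", call. = FALSE)
  if (any(is.na(grid$pool)) || any(grid$pool <= 0))
    stop("'grid' must carry positive pools", call. = FALSE)
  A <- params$A
  n_int <- nrow(grid)
  pools <- grid$pool
  # upper-tail probability of clearing criterion k at midpoint of interval i
  p_mat <- outer(grid$t_mid, criteria,
                 function(t, C) stats::pnorm(C + A * t, lower.tail = FALSE))

  cum_counts <- with_seed(seed, {
    if (mode == "expected") {
      p_mat * pools
    } else if (mode == "binomial") {
      out <- matrix(0, n_int, K)
      prev <- round(pools)
      p_prev <- matrix(1, n_int, 1)
      for (k in seq_len(K)) {
        cond_p <- pmin(p_mat[, k] / p_prev, 1)
        out[, k] <- stats::rbinom(n_int, prev, cond_p)
        prev <- out[, k]
        p_prev <- p_mat[, k]
      }
      out
    } else {  # individual
      out <- matrix(0, n_int, K)
      yl <- attr(grid, "year_length")
      for (i in seq_len(n_int)) {
        n_i <- round(pools[i])
        t_i <- (grid$days_before[i] + stats::runif(n_i) * grid$days_in[i]) / yl
        q <- stats::rnorm(n_i, mean = A * t_i, sd = 1)
        out[i, ] <- vapply(criteria, function(C) sum(q >= C), numeric(1))
      }
      out
    }
  })
  if (K == 1L)
    return(data.frame(interval = grid$label, pool = pools,
                      selected = cum_counts[, 1], stringsAsFactors = FALSE))
  # ordinal categories from nested cumulative counts
  counts <- cbind(pools - cum_counts[, 1],
                  -t(apply(cbind(cum_counts, 0), 1, diff)))
  rating_table(grid, counts, levels = as.character(seq_len(K + 1L)))
}

#' Parameter-recovery study
#'
#' Repeatedly simulates cohorts from known parameters, refits them with the
#' full pipeline (simulate, tabulate, probit-transform, stacked
#' regression), and summarises bias, spread and RMSE of the recovered
#' advancement rate and criterion.  Replicates whose points are all
#' degenerate (or leave fewer than two usable points) are dropped and
#' counted.
#'
#' @inheritParams simulate_counts
#' @param replicates number of simulated cohorts (>= 2).
#' @return a \code{ttg_recovery} object: list with \code{estimates} (data
#'   frame of per-replicate A-hat, C-hat), \code{bias_A}, \code{sd_A},
#'   \code{rmse_A}, the same for C, \code{dropped}, \code{truth},
#'   \code{seed}.
#' @export
recover_parameters <- function(grid, params, criteria = NULL,
                               replicates = 200,
                               mode = c("binomial", "individual"),
                               seed = 20170420) {
  stopifnot(replicates >= 2)
  mode <- match.arg(mode)
  ests <- vector("list", replicates)
  dropped <- 0L
  for (r in seq_len(replicates)) {
    sim <- simulate_counts(grid, params, criteria, mode = mode,
                           seed = seed + r - 1L)
    fit <- tryCatch({
      pts <- if (inherits(sim, "rating_table"))
        suppressWarnings(to_probit_points(sim))
      else
        suppressWarnings(selection_points(grid, sim$selected))
      if (length(unique(pts$t_B)) < 2L) stop("degenerate")
      stacked_regression(pts)
    }, error = function(e) NULL)
    if (is.null(fit)) dropped <- dropped + 1L
    else ests[[r]] <- data.frame(replicate = r, A_hat = fit$A, C_hat = fit$C)
  }
  est <- do.call(rbind, ests)
  if (is.null(est)) stop("all replicates degenerate", call. = FALSE)
  structure(list(
    estimates = est,
    bias_A = mean(est$A_hat) - params$A, sd_A = stats::sd(est$A_hat),
    rmse_A = sqrt(mean((est$A_hat - params$A)^2)),
    bias_C = mean(est$C_hat) - params$C, sd_C = stats::sd(est$C_hat),
    rmse_C = sqrt(mean((est$C_hat - params$C)^2)),
    dropped = dropped, truth = params, replicates = replicates,
    mode = mode, seed = seed), class = "ttg_recovery")
}

#' @export
print.ttg_recovery <- function(x, digits = 4, ...) {
  cat(sprintf("Parameter recovery: %d replicates (%d dropped), %s mode, seed %d\n",
              x$replicates, x$dropped, x$mode, x$seed))
  cat(sprintf("  truth A = %s, C = %s\n", format(x$truth$A, digits = digits),
              format(x$truth$C, digits = digits)))
  cat(sprintf("  A-hat: bias %s, sd %s, rmse %s\n",
              format(x$bias_A, digits = digits),
              format(x$sd_A, digits = digits),
              format(x$rmse_A, digits = digits)))
  cat(sprintf("  C-hat: bias %s, sd %s, rmse %s\n",
              format(x$bias_C, digits = digits),
              format(x$sd_C, digits = digits),
              format(x$rmse_C, digits = digits)))
  invisible(x)
}
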