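# Shared fixtures: the printed worked-example tables, frozen to the digits
# shown, plus an expectation for "agrees to within one unit in the last
# printed decimal digit".

expect_printed <- function(actual, printed, digits) {
  expect_true(all(abs(actual - printed) <= 10^-digits + 1e-12),
              label = sprintf("max |diff| = %.3g vs %d d.p.",
                              max(abs(actual - printed)), digits))
}

month_labels <- c("Sep", "Oct", "Nov", "Dec", "Jan", "Feb",
                  "Mar", "Apr", "May", "Jun", "Jul", "Aug")

# teacher-rating counts by birth month x five-point scale
speak_listen_counts <- matrix(c(
   3, 39, 161, 195, 72,
  13, 34, 169, 171, 61,
   6, 36, 197, 168, 66,
   9, 52, 206, 158, 44,
   9, 60, 168, 168, 50,
  13, 53, 183, 142, 36,
  11, 52, 195, 140, 40,
  12, 49, 186, 140, 31,
  17, 59, 209, 121, 30,
  22, 60, 213, 115, 25,
  22, 71, 171, 105, 33,
  13, 64, 211,  79, 24), nrow = 12, byrow = TRUE,
  dimnames = list(month_labels, as.character(1:5)))

# printed upper-tail proportions for levels >=2..>=5.  The Sep/>=5 cell is
# printed as .1539 in the source table but 72/470 = .1532 (and the printed
# z-score 1.0228 corresponds to .1532), so the typo is corrected here.
table2_p <- matrix(c(
  .9936, .9106, .5681, .1532,
  .9710, .8951, .5179, .1362,
  .9873, .9112, .4947, .1395,
  .9808, .8699, .4307, .0938,
  .9802, .8484, .4791, .1099,
  .9696, .8454, .4169, .0843,
  .9749, .8562, .4110, .0913,
  .9713, .8541, .4091, .0742,
  .9610, .8257, .3463, .0688,
  .9494, .8115, .3218, .0575,
  .9453, .7687, .3433, .0821,
  .9668, .8031, .2634, .0614), nrow = 12, byrow = TRUE,
  dimnames = list(month_labels, paste0(">=", 2:5)))

table2_z <- matrix(c(
  -2.4902, -1.3447, -.1715, 1.0228,
  -1.8954, -1.2541, -.0448, 1.0977,
  -2.2357, -1.3482,  .0132, 1.0824,
  -2.0708, -1.1261,  .1746, 1.3176,
  -2.0583, -1.0294,  .0524, 1.2271,
  -1.8743, -1.0170,  .2099, 1.3767,
  -1.9580, -1.0632,  .2251, 1.3326,
  -1.9001, -1.0540,  .2299, 1.4455,
  -1.7625,  -.9373,  .3952, 1.4847,
  -1.6393,  -.8834,  .4626, 1.5764,
  -1.6007,  -.7344,  .4035, 1.3912,
  -1.8351,  -.8526,  .6328, 1.5433), nrow = 12, byrow = TRUE,
  dimnames = list(month_labels, paste0(">=", 2:5)))

table2_tmid <- c(.0411, .1247, .2082, .2918, .3767, .4575,
                 .5384, .6219, .7055, .7890, .8726, .9575)

speak_listen_fixture <- function() {
  rating_table(month_grid("Sep", 365), speak_listen_counts)
}

# noiseless probit points generated from the forward model at given
# midpoints and per-level criteria; used to test estimator consistency
model_points <- function(A, criteria, t_mid, n = 1000) {
  rows <- do.call(rbind, lapply(seq_along(criteria), function(k) {
    p <- pnorm(criteria[k] + A * t_mid, lower.tail = FALSE)
    data.frame(interval = as.character(seq_along(t_mid)), t_B = t_mid,
               level = paste0("L", k), level_index = k, p = p,
               z = qnorm(p, lower.tail = FALSE), n = n,
               stringsAsFactors = FALSE)
  }))
  ttgrae:::new_probit_points(rows)
}
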