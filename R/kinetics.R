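# Degradation accounting and first-order kinetics: percent removal against
# heat-killed controls, fixed-intercept log-linear decay fits, half-lives,
# condition contrasts, abiotic-loss series.

#' Construct a decay experiment
#'
#' Long-format concentration records over time, condition and replicate,
#' with a single declared time unit and a single concentration unit. Units
#' are metadata, never converted implicitly. Every condition must include a
#' record at the experiment's earliest time (the reference for residual
#' percentages and abiotic loss).
#'
#' @param time numeric vector of sampling times.
#' @param condition character vector of condition labels (e.g. `inoculated`,
#'   `untreated`, `sterilized`, `heat_killed_control`).
#' @param replicate replicate identifiers.
#' @param concentration non-negative concentrations.
#' @param time_unit e.g. `"days"` or `"hours"`.
#' @param conc_unit e.g. `"percent"`, `"ng cm^-2"`, `"ug mL^-1"`. When the
#'   unit is `"percent"` values are treated as residual percentages directly
#'   (100 = starting level).
#' @return object of class `decay_experiment`.
#' @export
decay_experiment <- function(time, condition, replicate, concentration,
                             time_unit = "days", conc_unit = "percent") {
  n <- length(time)
  if (length(condition) == 1L) condition <- rep(condition, n)
  if (length(replicate) == 1L) replicate <- rep(replicate, n)
  stopifnot(length(condition) == n, length(replicate) == n,
            length(concentration) == n, n > 0L,
            length(time_unit) == 1L, length(conc_unit) == 1L)
  if (any(!is.finite(time)) || any(!is.finite(concentration)))
    stop("times and concentrations must be finite")
  if (any(concentration < 0)) stop("concentrations must be non-negative")
  records <- data.frame(time = as.numeric(time),
                        condition = as.character(condition),
                        replicate = as.character(replicate),
                        concentration = as.numeric(concentration))
  t0 <- min(records$time)
  for (cond in unique(records$condition)) {
    if (!any(records$condition == cond & records$time == t0))
      stop("condition '", cond, "' has no record at the earliest time (",
           t0, " ", time_unit, ")")
  }
  structure(list(records = records, time_unit = time_unit,
                 conc_unit = conc_unit),
            class = "decay_experiment")
}

#' @export
print.decay_experiment <- function(x, ...) {
  cat(sprintf("decay_experiment: %d records, %d condition(s), time in %s, concentration in %s\n",
              nrow(x$records), length(unique(x$records$condition)),
              x$time_unit, x$conc_unit))
  invisible(x)
}

#' Percent removal relative to heat-killed controls
#'
#' For each sample replicate, removal is `100 * (1 - c / mean(controls))`
#' and residual is its complement. The heat-killed control mean is the
#' abiotic reference, so removals quantify the biological contribution only.
#' Removals above the control (negative removal) are reported as-is, never
#' clipped: truncation at zero would bias means.
#'
#' @param samples numeric vector of sample concentrations.
#' @param controls numeric vector of heat-killed control concentrations
#'   (mean must be positive).
#' @param compound optional compound label.
#' @return object of class `removal_result` with fields `removal_pct`,
#'   `residual_pct`, `control_mean`, `n_control`, `n_sample`.
#' @export
removal_percent <- function(samples, controls, compound = "") {
  if (length(controls) == 0L || mean(controls) <= 0)
    stop("control mean must be positive")
  removal <- 100 * (1 - samples / mean(controls))
  structure(list(compound = compound,
                 removal_pct = removal,
                 residual_pct = 100 - removal,
                 control_mean = mean(controls),
                 n_control = length(controls),
                 n_sample = length(samples)),
            class = "removal_result")
}

#' @export
print.removal_result <- function(x, ...) {
  cat(sprintf("removal_result%s: mean removal %.1f%% (n = %d vs %d controls)\n",
              if (nzchar(x$compound)) paste0(" [", x$compound, "]") else "",
              mean(x$removal_pct), x$n_sample, x$n_control))
  invisible(x)
}

# Residual percentages for one condition. Percent-unit experiments are used
# as-is; other units are normalized by the condition's earliest-time mean.
residual_pct_of <- function(e, condition) {
  rec <- e$records[e$records$condition == condition, , drop = FALSE]
  if (nrow(rec) == 0L) stop("no records for condition '", condition, "'")
  if (identical(e$conc_unit, "percent") || identical(e$conc_unit, "%")) {
    rec$residual_pct <- rec$concentration
  } else {
    t0 <- min(rec$time)
    ref <- mean(rec$concentration[rec$time == t0])
    if (ref <= 0) stop("earliest-time reference mean is not positive for ",
                       "condition '", condition, "'")
    rec$residual_pct <- 100 * rec$concentration / ref
  }
  rec
}

fixed_intercept_slope <- function(t, y, intercept_pct) {
  x <- log(y) - log(intercept_pct)
  sum(t * x) / sum(t^2)
}

#' Fit first-order decay with the intercept fixed at 100%
#'
#' Least squares on the natural log of residual percentages with the
#' intercept pinned to `log(intercept_pct)` at time zero — the fitted curve
#' passes exactly through 100% at t = 0. The slope has the closed form
#' `b = sum(t * (log(y) - log(100))) / sum(t^2)`; under first-order kinetics
#' `b = -k` and the half-life is `log(2) / -b` (infinite when `b >= 0`).
#'
#' The natural log is used so that the slope is the first-order rate
#' constant directly; the log base only rescales the slope, never the
#' half-life.
#'
#' @param e a [decay_experiment()].
#' @param condition condition label to fit.
#' @param window optional `c(t_start, t_end)` limiting the records used
#'   (inclusive); e.g. the first 4 days of a series. Default: all times.
#' @param intercept_pct fixed intercept, percent; default 100.
#' @return object of class `kinetics_fit` with `slope_b` (per time unit on
#'   the natural-log scale), `half_life`, `window`, `n_points`, `rss`.
#' @export
fit_first_order <- function(e, condition, window = NULL, intercept_pct = 100) {
  stopifnot(inherits(e, "decay_experiment"), intercept_pct > 0)
  rec <- residual_pct_of(e, condition)
  if (!is.null(window)) {
    stopifnot(length(window) == 2L)
    rec <- rec[rec$time >= window[1L] & rec$time <= window[2L], , drop = FALSE]
  }
  bad <- which(rec$residual_pct <= 0)
  if (length(bad) > 0L)
    stop("non-positive residual at condition '", condition, "', time ",
         rec$time[bad[1L]], ", replicate '", rec$replicate[bad[1L]],
         "': log-linear fit undefined")
  if (length(unique(rec$time)) < 2L)
    stop("fewer than 2 distinct time points in window for condition '",
         condition, "'")
  b <- fixed_intercept_slope(rec$time, rec$residual_pct, intercept_pct)
  resid <- (log(rec$residual_pct) - log(intercept_pct)) - b * rec$time
  structure(list(condition = condition,
                 slope_b = b,
                 half_life = if (b < 0) log(2) / (-b) else Inf,
                 window = range(rec$time),
                 n_points = nrow(rec),
                 rss = sum(resid^2),
                 intercept_pct = intercept_pct,
                 time_unit = e$time_unit),
            class = "kinetics_fit")
}

#' @export
print.kinetics_fit <- function(x, ...) {
  cat(sprintf("kinetics_fit [%s]: slope %.4f / %s, half-life %s %s (n = %d)\n",
              x$condition, x$slope_b, x$time_unit,
              if (is.finite(x$half_life)) sprintf("%.2f", x$half_life) else "Inf",
              x$time_unit, x$n_points))
  invisible(x)
}

#' Compare first-order decay rates across conditions
#'
#' Fits one fixed-intercept slope per condition (common intercept 100% at
#' t = 0) and tests all pairwise slope differences with t statistics on
#' `n_total - n_conditions` degrees of freedom. The default pools the
#' residual variance across conditions; `variance = "separate"` uses
#' per-condition variances with Welch-style degrees of freedom.
#'
#' @param e a [decay_experiment()].
#' @param conditions character vector (length >= 2) of condition labels.
#' @param window optional `c(t_start, t_end)` as in [fit_first_order()].
#' @param variance `"pooled"` (default) or `"separate"`.
#' @return object of class `decay_comparison`: `fits` (list of
#'   `kinetics_fit`), `slopes` data.frame, `contrasts` data.frame with
#'   t statistics, df and two-sided p-values.
#' @export
compare_decay <- function(e, conditions, window = NULL,
                          variance = c("pooled", "separate")) {
  variance <- match.arg(variance)
  stopifnot(length(conditions) >= 2L)
  fits <- lapply(conditions, function(cc)
    fit_first_order(e, cc, window = window))
  names(fits) <- conditions
  n_i <- vapply(fits, `[[`, integer(1L), "n_points")
  sxx <- vapply(conditions, function(cc) {
    rec <- residual_pct_of(e, cc)
    if (!is.null(window))
      rec <- rec[rec$time >= window[1L] & rec$time <= window[2L], ,
                 drop = FALSE]
    sum(rec$time^2)
  }, numeric(1L))
  rss <- vapply(fits, `[[`, numeric(1L), "rss")
  k <- length(conditions)
  n_total <- sum(n_i)
  df_pool <- n_total - k
  s2_pool <- if (df_pool > 0) sum(rss) / df_pool else 0
  b <- vapply(fits, `[[`, numeric(1L), "slope_b")

  pairs <- utils::combn(conditions, 2L)
  contrasts <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    ci <- pairs[1L, j]; cj <- pairs[2L, j]
    diff <- b[[ci]] - b[[cj]]
    if (variance == "pooled") {
      se <- sqrt(s2_pool * (1 / sxx[[ci]] + 1 / sxx[[cj]]))
      df <- df_pool
    } else {
      df_i <- n_i[[ci]] - 1L; df_j <- n_i[[cj]] - 1L
      v_i <- if (df_i > 0) rss[[ci]] / df_i / sxx[[ci]] else 0
      v_j <- if (df_j > 0) rss[[cj]] / df_j / sxx[[cj]] else 0
      se <- sqrt(v_i + v_j)
      df <- if (v_i + v_j > 0)
        (v_i + v_j)^2 / (v_i^2 / max(df_i, 1L) + v_j^2 / max(df_j, 1L))
      else df_pool
    }
    tstat <- if (diff == 0) 0 else diff / se  # 0/0 when variance collapses
    p <- if (is.nan(tstat)) NA_real_ else 2 * stats::pt(-abs(tstat), df)
    data.frame(condition_i = ci, condition_j = cj, slope_diff = diff,
               t = tstat, df = df, p_value = p, row.names = NULL)
  }))
  structure(list(fits = fits,
                 slopes = data.frame(condition = conditions,
                                     slope_b = unname(b),
                                     half_life = vapply(fits, `[[`,
                                                        numeric(1L),
                                                        "half_life"),
                                     n = unname(n_i), row.names = NULL),
                 contrasts = contrasts,
                 variance = variance,
                 s2_pooled = s2_pool,
                 df_pooled = df_pool),
            class = "decay_comparison")
}

#' @export
print.decay_comparison <- function(x, ...) {
  cat("decay_comparison (fixed intercept 100%):\n")
  print(x$slopes)
  cat("pairwise contrasts (", x$variance, " variance):\n", sep = "")
  print(x$contrasts)
  invisible(x)
}

#' Abiotic loss in a control condition over time
#'
#' Percent loss relative to the earliest-time mean of a control condition
#' (e.g. heat-killed flasks or surface-sterilized leaves):
#' `loss(t) = 100 * (1 - mean(t) / mean(t0))`. Negative losses (apparent
#' gains, within measurement noise) are reported as-is.
#'
#' @param e a [decay_experiment()].
#' @param control_condition condition label of the abiotic control.
#' @return data.frame with columns time, mean_concentration, loss_pct.
#' @export
abiotic_loss <- function(e, control_condition) {
  stopifnot(inherits(e, "decay_experiment"))
  rec <- e$records[e$records$condition == control_condition, , drop = FALSE]
  if (nrow(rec) == 0L)
    stop("no records for control condition '", control_condition, "'")
  t0 <- min(rec$time)
  ref <- mean(rec$concentration[rec$time == t0])
  if (!is.finite(ref) || ref <= 0)
    stop("missing or non-positive earliest-time reference for condition '",
         control_condition, "'")
  times <- sort(unique(rec$time))
  means <- vapply(times, function(tt)
    mean(rec$concentration[rec$time == tt]), numeric(1L))
  data.frame(time = times, mean_concentration = means,
             loss_pct = 100 * (1 - means / ref))
}
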