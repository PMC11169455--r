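#' Construct a growth curve
#'
#' An OD600 time series for one culture, as produced by automated growth
#' analysers (readings every 30 min from a starting OD of about 0.05 are
#' typical).
#'
#' @param times Hours, strictly increasing, length >= 6.
#' @param od OD600 readings, same length, >= 0.
#' @param label Strain/condition label.
#' @return An object of class `thiamsim_growth_curve`.
#' @export
growth_curve <- function(times, od, label = "culture") {
  times <- as.numeric(times); od <- as.numeric(od)
  if (length(times) != length(od))
    stop("times and od must have equal length")
  if (length(times) < 6L)
    stop("a growth curve needs at least 6 points, got ", length(times))
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing")
  if (any(od < 0)) stop("negative OD600 readings")
  structure(list(times = times, od = od, label = as.character(label)),
            class = "thiamsim_growth_curve")
}

# linear fit of y ~ x over an index window, via running sums; returns
# slope and R^2 (R^2 is NA when y has no variance in the window)
.window_fit <- function(x, y, i, j) {
  xi <- x[i:j]; yi <- y[i:j]; n <- j - i + 1L
  sx <- sum(xi); sy <- sum(yi)
  sxx <- sum(xi * xi); sxy <- sum(xi * yi); syy <- sum(yi * yi)
  vxx <- sxx - sx * sx / n
  vyy <- syy - sy * sy / n
  vxy <- sxy - sx * sy / n
  slope <- vxy / vxx
  r2 <- if (vyy <= .Machine$double.eps * max(1, syy)) NA_real_ else
    (vxy * vxy) / (vxx * vyy)
  c(slope = slope, r2 = r2)
}

#' Estimate an exponential-phase growth rate
#'
#' The default method fits a growth model to the OD series by nonlinear least
#' squares in OD space (where plate-reader noise is approximately constant):
#' a logistic curve OD(t) = K / (1 + ((K - x0)/x0) exp(-r t)) when the series
#' shows saturation, falling back to a pure exponential OD(t) = x0 exp(r t)
#' when it does not (or the logistic fit fails). The reported rate is the
#' fitted specific growth rate r (per hour) and the reported window is the
#' span where the fitted curve is in exponential phase (below a quarter of
#' the fitted carrying capacity).
#'
#' `method = "window"` instead transforms OD to natural logs, takes the
#' exponential phase as the longest contiguous run of points whose linear
#' ln(OD)-vs-time fit has R^2 at or above `r2_threshold` and a positive
#' slope, and reports that fit's slope (ties between equally long windows
#' broken by higher R^2). This is transparent and auditable but
#' underestimates the rate when early-phase readings are noise-dominated in
#' log space.
#'
#' Either way, a culture with no detectable exponential growth yields
#' `found = FALSE` rather than an error.
#'
#' @param curve A [growth_curve()].
#' @param min_window_points Minimum window length for `method = "window"`
#'   (>= 4; default 5).
#' @param r2_threshold Minimum R^2 for a qualifying window (default 0.99).
#' @param method `"nonlinear"` (default) or `"window"`.
#' @return A list: `found`, `rate` (per hour, NA when not found), `window`
#'   (start/end times in hours), `r_squared`, `n_points`, `method`, `label`.
#' @export
estimate_growth_rate <- function(curve, min_window_points = 5L,
                                 r2_threshold = 0.99,
                                 method = c("nonlinear", "window")) {
  stopifnot(inherits(curve, "thiamsim_growth_curve"), min_window_points >= 4L)
  method <- match.arg(method)
  if (method == "window")
    return(.rate_by_window(curve, min_window_points, r2_threshold))
  .rate_by_nls(curve)
}

.rate_by_window <- function(curve, min_window_points, r2_threshold) {
  ok <- curve$od > 0
  t <- curve$times; ly <- ifelse(ok, log(curve$od), NA_real_)
  n <- length(t)
  none <- list(found = FALSE, rate = NA_real_, window = c(NA_real_, NA_real_),
               r_squared = NA_real_, n_points = 0L, method = "window",
               label = curve$label)
  best <- NULL
  # longest contiguous run whose whole-window fit qualifies: O(n^2) windows
  for (i in seq_len(n - min_window_points + 1L)) {
    if (!ok[i]) next
    for (j in seq(i + min_window_points - 1L, n)) {
      if (!ok[j] || anyNA(ly[i:j])) break
      fit <- .window_fit(t, ly, i, j)
      if (is.na(fit[["r2"]]) || fit[["r2"]] < r2_threshold ||
          fit[["slope"]] <= 0) next
      len <- j - i + 1L
      if (is.null(best) || len > best$len ||
          (len == best$len && fit[["r2"]] > best$r2)) {
        best <- list(i = i, j = j, len = len,
                     slope = fit[["slope"]], r2 = fit[["r2"]])
      }
    }
  }
  if (is.null(best)) return(none)
  list(found = TRUE, rate = best$slope,
       window = c(t[best$i], t[best$j]),
       r_squared = best$r2, n_points = best$len, method = "window",
       label = curve$label)
}

.rate_by_nls <- function(curve) {
  t <- curve$times; od <- curve$od
  none <- list(found = FALSE, rate = NA_real_, window = c(NA_real_, NA_real_),
               r_squared = NA_real_, n_points = 0L, method = "nonlinear",
               label = curve$label)
  pos <- od > 0
  if (sum(pos) < 4L || max(od) <= min(od[pos])) return(none)
  x00 <- max(od[which(pos)[1L]], 1e-6)
  K0 <- max(od) * 1.05
  # start values from the logit linearisation ln(od/(K-od)) = const + r t
  mid <- pos & od < 0.95 * K0
  r0 <- if (sum(mid) >= 4L)
    .window_fit(t[mid], log(od[mid] / (K0 - od[mid])), 1L, sum(mid))[["slope"]]
  else NA_real_
  if (!is.finite(r0) || r0 <= 0) r0 <- 0.1
  # scaleOffset keeps the convergence test meaningful on zero-residual data
  ctrl <- stats::nls.control(maxiter = 200L, scaleOffset = 1)
  fit_try <- function(formula, start) tryCatch(
    stats::nls(formula, data = data.frame(t = t, od = od), start = start,
               control = ctrl),
    error = function(e) NULL)
  fit <- NULL
  for (r_start in unique(c(r0, r0 * 2, r0 / 2, 0.05, 0.2, 0.5))) {
    fit <- fit_try(od ~ K / (1 + ((K - x0) / x0) * exp(-r * t)),
                   list(K = K0, x0 = x00, r = r_start))
    if (!is.null(fit)) break
  }
  logistic <- !is.null(fit)
  if (logistic) {
    cf <- stats::coef(fit)
    # an unsaturated series cannot identify K; treat as exponential instead
    if (!is.finite(cf[["K"]]) || cf[["K"]] > 10 * max(od) ||
        cf[["r"]] <= 0 || cf[["x0"]] <= 0) { fit <- NULL; logistic <- FALSE }
  }
  if (is.null(fit))
    fit <- fit_try(od ~ x0 * exp(r * t), list(x0 = x00, r = r0))
  if (is.null(fit)) return(none)
  cf <- stats::coef(fit)
  rate <- cf[["r"]]
  if (!is.finite(rate) || rate <= 1e-8) return(none)
  sse <- sum(stats::residuals(fit)^2)
  sst <- sum((od - mean(od))^2)
  r2 <- if (sst > 0) 1 - sse / sst else NA_real_
  window <- if (logistic) {
    # exponential phase: fitted curve below a quarter of carrying capacity
    fitted_od <- stats::fitted(fit)
    inside <- fitted_od <= 0.25 * cf[["K"]]
    if (any(inside)) range(t[inside]) else c(t[1L], t[1L])
  } else range(t)
  list(found = TRUE, rate = unname(rate), window = window,
       r_squared = r2, n_points = length(t), method = "nonlinear",
       label = curve$label)
}

#' Compare growth rates between groups
#'
#' One-way ANOVA over per-replicate growth rates followed by Tukey's HSD
#' post-hoc test, with significance tiers at 0.05 (significant) and 0.01
#' (very significant). Fully degenerate input (zero variance everywhere and
#' identical group means) is reported as p = 1.
#'
#' @param estimates Named list: group label -> numeric vector of rates
#'   (>= 2 groups, >= 2 rates each).
#' @return A list: `anova` (data.frame with F and p), `tukey` (data.frame of
#'   pairwise comparisons: diff, confidence bounds, adjusted p, significance
#'   tier), `group_means`.
#' @export
compare_groups <- function(estimates) {
  if (length(estimates) < 2L)
    stop("compare_groups needs at least 2 groups")
  if (any(lengths(estimates) < 2L))
    stop("every group needs at least 2 rate estimates")
  rate <- unlist(estimates, use.names = FALSE)
  group <- factor(rep(names(estimates), lengths(estimates)))
  tier <- function(p) ifelse(is.na(p), "",
                       ifelse(p < 0.01, "very significant",
                         ifelse(p < 0.05, "significant", "ns")))
  if (stats::var(rate) <= .Machine$double.eps * max(1, mean(rate)^2)) {
    # identical rates everywhere: no evidence of any difference
    pairs <- utils::combn(names(estimates), 2L,
                          function(x) paste(x[2L], x[1L], sep = "-"))
    return(list(
      anova = data.frame(F = NA_real_, p = 1, stringsAsFactors = FALSE),
      tukey = data.frame(comparison = pairs, diff = 0, lwr = 0, upr = 0,
                         p_adj = 1, significance = "ns",
                         stringsAsFactors = FALSE),
      group_means = vapply(estimates, mean, 0)))
  }
  fit <- stats::aov(rate ~ group)
  tab <- summary(fit)[[1L]]
  f <- tab[["F value"]][1L]; p <- tab[["Pr(>F)"]][1L]
  tk <- stats::TukeyHSD(fit)$group
  tukey <- data.frame(comparison = rownames(tk),
                      diff = tk[, "diff"], lwr = tk[, "lwr"],
                      upr = tk[, "upr"], p_adj = tk[, "p adj"],
                      significance = tier(tk[, "p adj"]),
                      stringsAsFactors = FALSE)
  rownames(tukey) <- NULL
  list(anova = data.frame(F = f, p = p, stringsAsFactors = FALSE),
       tukey = tukey,
       group_means = vapply(estimates, mean, 0))
}

#' Estimate growth rates for every curve in a tidy table
#'
#' @param table Data frame with columns `time_h`, `od600`, `label`,
#'   `replicate` (the schema written by [make_growth_curves()]).
#' @param ... Passed to [estimate_growth_rate()].
#' @return Data frame with one row per (label, replicate): rate, window,
#'   R^2, found.
#' @export
estimate_growth_rates <- function(table, ...) {
  req <- c("time_h", "od600", "label", "replicate")
  missing <- setdiff(req, names(table))
  if (length(missing) > 0L)
    stop("growth table missing column(s): ", paste(missing, collapse = ", "))
  keys <- unique(table[, c("label", "replicate")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- table[table$label == keys$label[i] &
                 table$replicate == keys$replicate[i], ]
    sub <- sub[order(sub$time_h), ]
    est <- estimate_growth_rate(growth_curve(sub$time_h, sub$od600,
                                             keys$label[i]), ...)
    data.frame(label = keys$label[i], replicate = keys$replicate[i],
               found = est$found, rate = est$rate,
               window_start = est$window[1L], window_end = est$window[2L],
               r_squared = est$r_squared, n_points = est$n_points,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
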