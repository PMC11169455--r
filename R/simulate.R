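#' Simulation configuration
#'
#' @param t_end Simulation horizon in seconds (default 10000 s, i.e. 2 h 47
#'   min, long enough for the thiamin network to form a plateau).
#' @param n_output_points Number of uniformly spaced output points after t = 0
#'   (the output grid has `n_output_points + 1` points including 0). Outputs
#'   are dense-output interpolants of the adaptive solver, so refining the
#'   grid does not change the trajectory.
#' @param rel_tol,abs_tol Solver tolerances (defaults 1e-8 and 1e-12 nmol/L,
#'   suited to nmol-scale dynamics).
#' @param plateau_window Trailing fraction of the time course inspected for
#'   flatness (default 0.1).
#' @param plateau_slope_tol Maximum relative spread over the trailing window
#'   for a series to count as plateaued (default 1e-3).
#' @return An object of class `thiamsim_config`.
#' @export
simulation_config <- function(t_end = 10000, n_output_points = 1000,
                              rel_tol = 1e-8, abs_tol = 1e-12,
                              plateau_window = 0.1, plateau_slope_tol = 1e-3) {
  stopifnot(t_end > 0, n_output_points >= 10, rel_tol > 0, abs_tol > 0,
            plateau_window > 0, plateau_window < 1, plateau_slope_tol > 0)
  structure(list(t_end = t_end, n_output_points = as.integer(n_output_points),
                 rel_tol = rel_tol, abs_tol = abs_tol,
                 plateau_window = plateau_window,
                 plateau_slope_tol = plateau_slope_tol),
            class = "thiamsim_config")
}

#' Simulate a pathway model as a stiff ODE system
#'
#' Integrates dC/dt = N v(C) with the adaptive stiff/non-stiff switching
#' LSODA integrator ([deSolve::lsoda()]). Boundary (clamped) species are held
#' at their initial value by zeroing their derivative row. The result is
#' deterministic given model + config.
#'
#' @param model A validated `thiamsim_model` with every law parameterised (no
#'   unresolved `needs_fba` flags).
#' @param config A [simulation_config()].
#' @return A `thiamsim_timecourse` with components `times` (seconds,
#'   `times[1] = 0`, last = `t_end`), `conc` (time x metabolite matrix,
#'   nmol/L), `model`, `config`. Query it with [final_value()],
#'   [find_peak()], [detect_plateau()] or flatten with
#'   `as.data.frame(result)` (tidy columns time, metabolite_id,
#'   concentration).
#' @export
simulate_pathway <- function(model, config = simulation_config()) {
  unresolved <- reaction_ids(model)[vapply(model$reactions, `[[`, TRUE, "needs_fba")]
  if (length(unresolved) > 0L)
    stop("cannot simulate: unresolved needs_fba reactions: ",
         paste(unresolved, collapse = ", "),
         " (run gapfill_parameters() first)")
  rep <- validate_model(model)
  if (nrow(rep) > 0L)
    stop("cannot simulate an invalid model:\n  ",
         paste(rep$message, collapse = "\n  "))
  N <- stoich_matrix(model)
  clamped <- metabolite_ids(model) %in% boundary_ids(model)
  y0 <- initial_state(model)
  times <- seq(0, config$t_end, length.out = config$n_output_points + 1L)
  deriv <- function(t, y, parms) {
    v <- evaluate_rates(model, y)
    dy <- as.numeric(N %*% v)
    dy[clamped] <- 0
    list(dy)
  }
  out <- tryCatch(
    deSolve::lsoda(y0, times, deriv, parms = NULL,
                   rtol = config$rel_tol, atol = config$abs_tol),
    error = function(e) stop("integration failure: ", conditionMessage(e),
                             call. = FALSE))
  conc <- unname(out[, -1L, drop = FALSE])
  dimnames(conc) <- list(NULL, metabolite_ids(model))
  if (any(!is.finite(conc))) {
    bad <- which(!is.finite(conc), arr.ind = TRUE)[1L, ]
    stop("integration failure: non-finite concentration for metabolite '",
         colnames(conc)[bad[2L]], "' at t = ", out[bad[1L], 1L], " s")
  }
  structure(list(times = unname(out[, 1L]), conc = conc,
                 model = model, config = config),
            class = "thiamsim_timecourse")
}

#' @export
print.thiamsim_timecourse <- function(x, ...) {
  cat("<thiamsim time course>\n")
  cat("  t:", x$times[1L], "..", x$times[length(x$times)], "s,",
      length(x$times), "output points\n")
  cat("  metabolites:", ncol(x$conc), "\n")
  invisible(x)
}

#' @export
as.data.frame.thiamsim_timecourse <- function(x, ...) {
  data.frame(time = rep(x$times, times = ncol(x$conc)),
             metabolite_id = rep(colnames(x$conc), each = length(x$times)),
             concentration = as.vector(x$conc),
             stringsAsFactors = FALSE)
}

.series <- function(result, metabolite_id) {
  if (!metabolite_id %in% colnames(result$conc))
    stop("unknown metabolite '", metabolite_id, "'")
  result$conc[, metabolite_id]
}

#' Final concentration of a metabolite
#'
#' @param result A `thiamsim_timecourse`.
#' @param metabolite_id Metabolite id.
#' @return Concentration at `t_end` (nmol/L).
#' @export
final_value <- function(result, metabolite_id) {
  s <- .series(result, metabolite_id)
  s[length(s)]
}

#' Detect a trailing-window plateau
#'
#' A series has plateaued when the relative spread (max - min, divided by the
#' window mean magnitude) over the trailing `plateau_window` fraction of the
#' time course is below `plateau_slope_tol`. The plateau value is the mean
#' over that window; the terminal value is also reported since for a genuine
#' plateau the two coincide.
#'
#' @param x A `thiamsim_timecourse` (with `metabolite_id`) or a numeric series.
#' @param metabolite_id Metabolite id when `x` is a time course.
#' @param config A [simulation_config()]; supplies window and tolerance.
#' @return List with `reached` (logical), `value` (window mean, NA when not
#'   reached), `terminal` (last value), `window_points`.
#' @export
detect_plateau <- function(x, metabolite_id = NULL, config = simulation_config()) {
  series <- if (inherits(x, "thiamsim_timecourse")) {
    config <- x$config
    .series(x, metabolite_id)
  } else as.numeric(x)
  n <- length(series)
  if (n < 10L) stop("detect_plateau: need at least 10 output points, got ", n)
  w <- max(2L, ceiling(config$plateau_window * n))
  if (w > n) stop("detect_plateau: window longer than series")
  tail_vals <- series[(n - w + 1L):n]
  m <- mean(tail_vals)
  spread <- max(tail_vals) - min(tail_vals)
  scale <- max(abs(m), config$abs_tol)
  reached <- (spread / scale) < config$plateau_slope_tol
  list(reached = reached, value = if (reached) m else NA_real_,
       terminal = series[n], window_points = w)
}

#' Locate the peak of a concentration trajectory
#'
#' Global maximum over the output grid, refined by fitting a quadratic
#' through the grid point and its two neighbours (ties broken by earliest
#' time; no refinement at the grid ends).
#'
#' @param x A `thiamsim_timecourse` (with `metabolite_id`) or numeric series.
#' @param metabolite_id Metabolite id when `x` is a time course.
#' @param times Time grid when `x` is a bare series (defaults to indices).
#' @return List with `t_peak` (s), `v_peak` (nmol/L), and `t_peak_label`, a
#'   human-readable "Xm Ys" rendering.
#' @export
find_peak <- function(x, metabolite_id = NULL, times = NULL) {
  if (inherits(x, "thiamsim_timecourse")) {
    series <- .series(x, metabolite_id)
    times <- x$times
  } else {
    series <- as.numeric(x)
    if (is.null(times)) times <- seq_along(series) - 1
  }
  if (length(series) == 0L) stop("find_peak: empty series")
  i <- which.max(series)  # earliest index at ties
  t_peak <- times[i]
  v_peak <- series[i]
  if (i > 1L && i < length(series)) {
    # quadratic through (t_{i-1}, t_i, t_{i+1}); vertex refines the apex
    t3 <- times[(i - 1L):(i + 1L)]
    y3 <- series[(i - 1L):(i + 1L)]
    h1 <- t3[2L] - t3[1L]; h2 <- t3[3L] - t3[2L]
    d1 <- (y3[2L] - y3[1L]) / h1
    d2 <- (y3[3L] - y3[2L]) / h2
    a2 <- (d2 - d1) / (h1 + h2)  # half the second derivative
    if (a2 < 0) {
      tv <- (t3[1L] + t3[2L]) / 2 - d1 / (2 * a2)
      if (tv >= t3[1L] && tv <= t3[3L]) {
        # evaluate the interpolating quadratic at its vertex
        yv <- y3[1L] + d1 * (tv - t3[1L]) + a2 * (tv - t3[1L]) * (tv - t3[2L])
        if (yv >= v_peak) { t_peak <- tv; v_peak <- yv }
      }
    }
  }
  mins <- floor(t_peak / 60)
  secs <- round(t_peak - 60 * mins, 1)
  list(t_peak = t_peak, v_peak = v_peak,
       t_peak_label = sprintf("%dm %gs", mins, secs))
}
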