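# Independent oracles used across the suite. These deliberately re-derive
# everything from the raw model fields with naive arithmetic, so they share
# no code path with the package implementation they check.

# brute-force evaluation of one reaction's rate from its law fields
oracle_rate <- function(rxn, conc) {
  law <- rxn$law
  s <- function(i) conc[[law$substrate_ids[i]]]
  if (law$law_type == "MM1") {
    law$vmax * s(1) / (law$km + s(1))
  } else if (law$law_type == "MM2") {
    if (identical(law$variant, "pingpong")) {
      d <- law$km_b * s(1) + law$km_a * s(2) + s(1) * s(2)
      if (d == 0) 0 else law$vmax * s(1) * s(2) / d
    } else {
      law$vmax * (s(1) / (law$km_a + s(1))) * (s(2) / (law$km_b + s(2)))
    }
  } else if (law$law_type == "mass_action") {
    out <- law$k
    for (i in seq_along(law$substrate_ids)) out <- out * s(i)
    out
  } else if (law$law_type == "constant_flux") {
    law$k
  } else stop("unknown law")
}

oracle_rate_vector <- function(model, conc) {
  conc <- stats::setNames(pmax(as.numeric(conc), 0), metabolite_ids(model))
  vapply(model$reactions, oracle_rate, numeric(1L), conc = conc)
}

# fixed-step classical RK4 integration of dC/dt = N v(C); output every
# `every`-th step. Slow but simple; use short horizons.
oracle_rk4 <- function(model, t_end, dt = 1e-3, every = 1000L) {
  N <- stoich_matrix(model)
  clamped <- metabolite_ids(model) %in% boundary_ids(model)
  f <- function(y) {
    dy <- as.numeric(N %*% oracle_rate_vector(model, y))
    dy[clamped] <- 0
    dy
  }
  n_steps <- round(t_end / dt)
  y <- unname(initial_state(model))
  times <- 0
  out <- list(y)
  for (i in seq_len(n_steps)) {
    k1 <- f(y)
    k2 <- f(y + dt / 2 * k1)
    k3 <- f(y + dt / 2 * k2)
    k4 <- f(y + dt * k3)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (i %% every == 0L || i == n_steps) {
      times <- c(times, i * dt)
      out[[length(out) + 1L]] <- y
    }
  }
  conc <- do.call(rbind, out)
  colnames(conc) <- metabolite_ids(model)
  list(times = times, conc = conc)
}

# brute-force LP oracle: enumerate candidate vertices of
# {v : N v = 0, lb <= v <= ub} by fixing subsets of variables at bounds and
# solving the equality system for the rest; returns the best feasible vertex.
oracle_lp_max <- function(N, lb, ub, obj, tol = 1e-9) {
  n <- length(lb)
  r <- if (nrow(N) > 0L) qr(N)$rank else 0L
  best <- NULL
  consider <- function(v) {
    if (any(v < lb - tol) || any(v > ub + tol)) return()
    if (nrow(N) > 0L && max(abs(N %*% v)) > 1e-7) return()
    val <- sum(obj * v)
    if (is.null(best) || val > best$value + 1e-12)
      best <<- list(value = val, v = v)
  }
  for (n_free in 0:min(r, n)) {
    free_sets <- if (n_free == 0L) list(integer()) else
      utils::combn(n, n_free, simplify = FALSE)
    for (free in free_sets) {
      fixed <- setdiff(seq_len(n), free)
      # each fixed variable sits at its lower or upper bound
      grids <- rep(list(c(FALSE, TRUE)), length(fixed))
      choices <- if (length(fixed) == 0L) list(logical()) else
        do.call(expand.grid, grids)
      n_choice <- if (length(fixed) == 0L) 1L else nrow(choices)
      for (ci in seq_len(n_choice)) {
        at_ub <- if (length(fixed) == 0L) logical() else
          as.logical(choices[ci, ])
        v <- numeric(n)
        v[fixed] <- ifelse(at_ub, ub[fixed], lb[fixed])
        if (n_free == 0L) { consider(v); next }
        if (nrow(N) == 0L) next  # free vars undetermined without equalities
        A <- N[, free, drop = FALSE]
        if (qr(A)$rank < n_free) next
        b <- -N[, fixed, drop = FALSE] %*% v[fixed]
        sol <- qr.solve(qr(A), b)
        if (max(abs(A %*% sol - b)) > 1e-7) next
        v[free] <- sol
        consider(v)
      }
    }
  }
  best
}

# two-sided permutation test for a difference in group means
oracle_permutation_p <- function(x, y, n_perm = 2000L, seed = 99L) {
  obs <- abs(mean(x) - mean(y))
  pool <- c(x, y)
  nx <- length(x)
  stats <- vapply(seq_len(n_perm), function(i) {
    set.seed(seed + i)
    idx <- sample(length(pool), nx)
    abs(mean(pool[idx]) - mean(pool[-idx]))
  }, numeric(1L))
  (1 + sum(stats >= obs - 1e-15)) / (n_perm + 1)
}

# small fixture builders -------------------------------------------------

# closed two-species system S -> P under MM1
closed_sp_model <- function(s0 = 10, vmax = 1, km = 2) {
  pathway_model(
    list(metabolite("S", initial_conc = s0), metabolite("P")),
    list(reaction("R1", "E1", c(S = -1, P = 1),
                  kinetic_law("MM1", "S", vmax = vmax, km = km))))
}

# constant influx k into S consumed by MM1: steady state S* = k Km/(Vmax - k)
influx_mm1_model <- function(k = 2, vmax = 10, km = 5) {
  pathway_model(
    list(metabolite("S"), metabolite("P")),
    list(reaction("R_in", "transport", c(S = 1),
                  kinetic_law("constant_flux", k = k)),
         reaction("R1", "E1", c(S = -1, P = 1),
                  kinetic_law("MM1", "S", vmax = vmax, km = km))))
}

# mixed-law 3-reaction fixture for rate-vector checks
mixed_law_model <- function() {
  pathway_model(
    list(metabolite("A", initial_conc = 4), metabolite("B", initial_conc = 3),
         metabolite("C", initial_conc = 2), metabolite("D")),
    list(reaction("R1", "E1", c(A = -1, D = 1),
                  kinetic_law("MM1", "A", vmax = 10, km = 5)),
         reaction("R2", "E2", c(A = -1, B = -1, D = 1),
                  kinetic_law("MM2", c("A", "B"), vmax = 8, km_a = 2, km_b = 3)),
         reaction("R3", "E3", c(C = -1, D = 1),
                  kinetic_law("mass_action", "C", k = 0.25))))
}
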