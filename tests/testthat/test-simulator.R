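test_that("a closed system conserves mass and runs to completion", {
  m <- closed_sp_model(s0 = 10, vmax = 1, km = 2)
  res <- simulate_pathway(m, simulation_config(t_end = 200, n_output_points = 200))
  total <- res$conc[, "S"] + res$conc[, "P"]
  expect_lt(max(abs(total - 10)) / 10, 1e-6)
  expect_equal(final_value(res, "P"), 10, tolerance = 1e-6)
  expect_true(all(res$conc > -res$config$abs_tol))
  expect_identical(res$times[1L], 0)
  expect_identical(res$times[length(res$times)], 200)
})

test_that("constant influx against MM1 consumption reaches the analytic steady state", {
  # v_in = v_out: S* = k Km / (Vmax - k) = 2*5/8 = 1.25
  m <- influx_mm1_model(k = 2, vmax = 10, km = 5)
  res <- simulate_pathway(m, simulation_config(t_end = 100, n_output_points = 100))
  expect_equal(final_value(res, "S"), 1.25, tolerance = 1e-6)

  # generated chains hit their stored analytic steady states at every node
  for (seed in c(2L, 5L)) {
    ch <- make_mm_chain(3, seed = seed)
    r <- simulate_pathway(ch, simulation_config(t_end = 20000,
                                                n_output_points = 200))
    ss <- ch$metadata$steady_state
    for (id in names(ss))
      expect_equal(final_value(r, id), unname(ss[[id]]), tolerance = 1e-6)
  }
})

test_that("the stiff solver matches a fixed-step RK4 oracle on toy networks", {
  models <- list(mixed_law_model(), make_mm_chain(2, seed = 3),
                 make_thiamin_toy())
  for (m in models) {
    t_end <- 10
    ref <- oracle_rk4(m, t_end, dt = 1e-3, every = 2000L)
    res <- simulate_pathway(m, simulation_config(t_end = t_end,
                                                 n_output_points = 10))
    idx <- match(round(ref$times, 9), round(res$times, 9))
    expect_false(anyNA(idx))
    for (r in seq_along(idx)) {
      a <- res$conc[idx[r], ]
      b <- ref$conc[r, ]
      expect_lt(max(abs(a - b) / pmax(abs(b), 1e-8)), 1e-5)
    }
  }
})

test_that("clamped species stay at their initial value", {
  toy <- make_thiamin_toy()
  res <- simulate_pathway(toy, simulation_config(t_end = 500,
                                                 n_output_points = 50))
  for (id in boundary_ids(toy))
    expect_true(all(res$conc[, id] == initial_state(toy)[[id]]))
})

test_that("simulation is deterministic and stable under grid refinement", {
  toy <- make_thiamin_toy()
  r1 <- simulate_pathway(toy, simulation_config(t_end = 2000, n_output_points = 200))
  r2 <- simulate_pathway(toy, simulation_config(t_end = 2000, n_output_points = 200))
  expect_identical(r1$conc, r2$conc)
  r4 <- simulate_pathway(toy, simulation_config(t_end = 2000, n_output_points = 400))
  expect_lt(max(abs(r4$conc[nrow(r4$conc), ] - r1$conc[nrow(r1$conc), ])), 1e-9)
})

test_that("unresolved gap-fill flags block simulation with a clear message", {
  m <- thiamin_reference_model()
  expect_error(simulate_pathway(m), "needs_fba")
})

test_that("plateau detection separates flat tails from ramps", {
  cfg <- simulation_config(t_end = 100, n_output_points = 100)
  flat <- detect_plateau(rep(5, 101), config = cfg)
  expect_true(flat$reached)
  expect_equal(flat$value, 5)
  expect_equal(flat$terminal, 5)

  ramp <- detect_plateau(seq(0, 100, length.out = 101), config = cfg)
  expect_false(ramp$reached)
  expect_true(is.na(ramp$value))

  # a zero-valued plateau is still a plateau
  expect_true(detect_plateau(rep(0, 50), config = cfg)$reached)
  expect_error(detect_plateau(c(1, 2, 3), config = cfg), "at least 10")

  # exponential relaxation toward an asymptote plateaus once settled
  t <- seq(0, 100, length.out = 101)
  settled <- 3 - 3 * exp(-t / 2)
  expect_true(detect_plateau(settled, config = cfg)$reached)
  expect_equal(detect_plateau(settled, config = cfg)$value, 3, tolerance = 1e-3)
})

test_that("peak finding refines the grid maximum by quadratic interpolation", {
  # monotone series peaks at the end
  pk <- find_peak(seq(0, 10, length.out = 51), times = seq(0, 100, 2))
  expect_identical(pk$t_peak, 100)

  # symmetric triangle: apex recovered exactly at the shared grid point
  tri <- c(seq(0, 1, length.out = 11), seq(0.9, 0, length.out = 10))
  pk2 <- find_peak(tri, times = seq_along(tri) - 1)
  expect_equal(pk2$t_peak, 10)
  expect_equal(pk2$v_peak, 1)

  # parabola sampled off-apex: interpolation recovers the true vertex
  t <- seq(0, 10, 0.8)
  y <- -(t - 4.3)^2 + 7
  pk3 <- find_peak(y, times = t)
  expect_equal(pk3$t_peak, 4.3, tolerance = 1e-9)
  expect_equal(pk3$v_peak, 7, tolerance = 1e-9)

  # ties break to the earliest time
  pk4 <- find_peak(c(0, 1, 0, 1, 0), times = 0:4)
  expect_identical(pk4$t_peak, 1)

  # human-readable rendering
  expect_match(find_peak(c(0, 1, 0), times = c(0, 580, 1160))$t_peak_label,
               "^9m 40s$")
  expect_error(find_peak(numeric()), "empty")
})

test_that("time courses flatten to tidy long format", {
  m <- closed_sp_model()
  res <- simulate_pathway(m, simulation_config(t_end = 10, n_output_points = 10))
  df <- as.data.frame(res)
  expect_identical(names(df), c("time", "metabolite_id", "concentration"))
  expect_identical(nrow(df), 22L)
  expect_setequal(unique(df$metabolite_id), c("S", "P"))
})
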