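test_that("stationary distribution matches closed forms and a null-space oracle", {
  # symmetric two-state: open probability exactly 1/2
  s_sym <- two_state_scheme("sym", v_half = NA, p_open = 0.5, rate_scale = 200)
  expect_equal(unname(stationary_distribution(s_sym, 0)[["O"]]), 0.5)

  # k_open = 300, k_close = 100 -> pi_open = 0.75
  s_asym <- gating_scheme("asym",
    states = data.frame(name = c("C", "O"), conducting = c(FALSE, TRUE)),
    transitions = data.frame(from = c("C", "O"), to = c("O", "C"),
                             base_rate = c(300, 100)))
  expect_equal(unname(stationary_distribution(s_asym, 0)[["O"]]), 0.75)

  # 3-state scheme vs brute-force null space
  s3 <- gating_scheme("tri",
    states = data.frame(name = c("C1", "C2", "O"),
                        conducting = c(FALSE, FALSE, TRUE)),
    transitions = data.frame(
      from = c("C1", "C2", "C2", "O", "O", "C1"),
      to   = c("C2", "C1", "O", "C2", "C1", "O"),
      base_rate = c(120, 80, 50, 200, 10, 5)))
  pi_hat <- stationary_distribution(s3, 0)
  expect_equal(sum(pi_hat), 1)
  expect_true(all(pi_hat >= 0))
  oracle <- stationary_nullspace_oracle(rate_matrix_at(s3, 0))
  expect_equal(unname(pi_hat), oracle, tolerance = 1e-10)
})

test_that("voltage-dependent rates follow the Boltzmann factor", {
  s <- two_state_scheme("b", v_half = -20, slope = 12, rate_scale = 100)
  Q <- rate_matrix_at(s, -20)
  expect_equal(Q["C", "O"], 50)  # sigma(0) = 1/2
  expect_equal(channelprint:::stationary_open_probability(s, -20), 0.5)
  # pi_open(V) is exactly the designed sigmoid
  for (v in c(-60, 0, 40)) {
    expect_equal(channelprint:::stationary_open_probability(s, v),
                 1 / (1 + exp(-(v + 20) / 12)), tolerance = 1e-12)
  }
  # p_max < 1 caps the curve
  s2 <- two_state_scheme("b2", v_half = -20, slope = 12, rate_scale = 100,
                         p_max = 0.9)
  expect_equal(channelprint:::stationary_open_probability(s2, 200),
               0.9 / (1 + exp(-220 / 12)), tolerance = 1e-12)
})

test_that("a rateless scheme yields a constant path and seeds reproduce paths", {
  s <- gating_scheme("frozen",
    states = data.frame(name = c("C", "O"), conducting = c(FALSE, TRUE)),
    transitions = data.frame(from = "C", to = "O", base_rate = 0))
  p <- simulate_state_path(s, 0, 500, 4000, seed = 1, init_state = "O")
  expect_true(all(p == 2L))

  s2 <- two_state_scheme("rng", v_half = NA, p_open = 0.4, rate_scale = 300)
  p1 <- simulate_state_path(s2, 0, 5000, 4000, seed = 42)
  p2 <- simulate_state_path(s2, 0, 5000, 4000, seed = 42)
  p3 <- simulate_state_path(s2, 0, 5000, 4000, seed = 43)
  expect_identical(as.integer(p1), as.integer(p2))
  expect_false(identical(as.integer(p1), as.integer(p3)))
})

test_that("dwell times reproduce the designed mean", {
  # mean open dwell 5 ms: k_close = 200 /s
  s <- gating_scheme("dwell",
    states = data.frame(name = c("C", "O"), conducting = c(FALSE, TRUE)),
    transitions = data.frame(from = c("C", "O"), to = c("O", "C"),
                             base_rate = c(200, 200)))
  path <- simulate_state_path(s, 0, 2e5, 40000, seed = 11)
  ev <- attr(path, "events")
  dt <- diff(ev$time)
  open_dwells <- dt[ev$state[-nrow(ev)] == 2L]
  expect_gt(length(open_dwells), 400)
  expect_lt(abs(mean(open_dwells) - 0.005) / 0.005, 0.05)
})

test_that("empirical conducting fraction sits within 3 SE of the stationary value", {
  s <- two_state_scheme("frac", v_half = NA, p_open = 0.3, rate_scale = 400)
  path <- simulate_state_path(s, 0, 2e5, 4000, seed = 5)
  cond <- as.numeric(attr(path, "conducting"))
  f <- mean(cond)
  rho <- stats::acf(cond, plot = FALSE, lag.max = 1)$acf[2]
  n_eff <- length(cond) * (1 - rho) / (1 + rho)
  se <- sqrt(0.3 * 0.7 / n_eff)
  expect_lt(abs(f - 0.3), 3 * se)
})

test_that("rendering sets amplitude, sign, and noise correctly", {
  mk <- function(noise, v) {
    s <- two_state_scheme("amp", v_half = NA, p_open = 0.5, rate_scale = 200,
                          conductance = 300, noise_sd = noise)
    path <- simulate_state_path(s, v, 4000, 4000, seed = 3)
    list(rec = render_recording(path, s, v, seed = 4, sampling_rate = 4000),
         conducting = attr(path, "conducting"))
  }
  # noise-free, +60 mV: open samples at exactly 18 pA
  r <- mk(0, 60)
  expect_recording(r$rec)
  expect_equal(unique(r$rec$trace[r$conducting]), 18)
  expect_equal(unique(r$rec$trace[!r$conducting]), 0)
  # -60 mV: open-channel current is negative
  r2 <- mk(0, -60)
  expect_equal(unique(r2$rec$trace[r2$conducting]), -18)
  # noise sd ~ 1 pA within dwell segments
  r3 <- mk(1, 60)
  sds <- c(stats::sd(r3$rec$trace[r3$conducting]),
           stats::sd(r3$rec$trace[!r3$conducting]))
  expect_true(all(abs(sds - 1) < 0.1))
})

test_that("the low-pass filter attenuates fast noise but keeps the mean", {
  x <- with(list(), {set.seed(2); rnorm(20000)})
  y <- channelprint:::lowpass_single_pole(x + 5, 1000, 40000)
  expect_lt(stats::sd(y), stats::sd(x))
  expect_equal(mean(y), 5, tolerance = 0.05)
})

test_that("degenerate generators are rejected", {
  # two disconnected components: reducible
  s <- gating_scheme("red",
    states = data.frame(name = c("A", "B", "C", "D"),
                        conducting = c(FALSE, TRUE, FALSE, TRUE)),
    transitions = data.frame(from = c("A", "B", "C", "D"),
                             to = c("B", "A", "D", "C"),
                             base_rate = c(10, 10, 10, 10)))
  expect_error(stationary_distribution(s, 0), "reducible|degenerate")
  expect_error(gating_scheme("bad",
    states = data.frame(name = c("C", "O"), conducting = c(FALSE, TRUE)),
    transitions = data.frame(from = "C", to = "O", base_rate = -1)),
    "rate")
})
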