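#' Construct a Markov gating scheme
#'
#' A gating scheme describes a continuous-time Markov model of channel
#' conformational dynamics plus the observation model that turns a state path
#' into a current trace: single-channel conductance, reversal potential,
#' baseline current, Gaussian instrument noise and an optional low-pass
#' filter corner.
#'
#' Transition rates may be voltage dependent: a transition with finite
#' `v_half` and `slope` has rate
#' `base_rate / (1 + exp(-(V - v_half) / slope))` at pipette potential `V`
#' (a Boltzmann factor; a negative `slope` yields a rate that falls with
#' depolarization). Transitions with `v_half = NA` have the constant rate
#' `base_rate`.
#'
#' @param scheme_id Identifier string.
#' @param states Data frame with columns `name` (character) and `conducting`
#'   (logical); at least one conducting and one nonconducting state.
#' @param transitions Data frame with columns `from`, `to` (state names),
#'   `base_rate` (per second, >= 0) and optional `v_half` (mV), `slope` (mV).
#' @param conductance Single-channel conductance in pS (> 0); the open-channel
#'   current is `conductance * (V - reversal_potential) / 1000` pA.
#' @param reversal_potential Reversal potential in mV.
#' @param baseline_current Closed-level offset in pA.
#' @param noise_sd Gaussian noise standard deviation in pA (>= 0).
#' @param filter_corner Low-pass corner frequency in Hz, or `NA` for no
#'   filtering.
#' @return An object of class `GatingScheme`.
#' @export
gating_scheme <- function(scheme_id, states, transitions,
                          conductance = 300, reversal_potential = 0,
                          baseline_current = 0, noise_sd = 0.8,
                          filter_corner = NA_real_) {
  stopifnot(is.data.frame(states), is.data.frame(transitions))
  if (!all(c("name", "conducting") %in% names(states)))
    stop_cp("states needs columns 'name' and 'conducting'")
  if (!all(c("from", "to", "base_rate") %in% names(transitions)))
    stop_cp("transitions needs columns 'from', 'to', 'base_rate'")
  if (anyDuplicated(states$name)) stop_cp("duplicate state names")
  if (!any(states$conducting) || all(states$conducting))
    stop_cp("need at least one conducting and one nonconducting state")
  if (any(!is.finite(transitions$base_rate)) || any(transitions$base_rate < 0))
    stop_cp("transition base rates must be finite and >= 0")
  if (!all(transitions$from %in% states$name) ||
      !all(transitions$to %in% states$name))
    stop_cp("transition endpoints must be declared states")
  if (any(transitions$from == transitions$to))
    stop_cp("self-transitions are not allowed")
  if (conductance <= 0) stop_cp("conductance must be positive")
  if (noise_sd < 0) stop_cp("noise_sd must be >= 0")
  if (is.null(transitions$v_half)) transitions$v_half <- NA_real_
  if (is.null(transitions$slope)) transitions$slope <- NA_real_
  structure(list(
    scheme_id = scheme_id,
    states = states,
    transitions = transitions,
    conductance = conductance,
    reversal_potential = reversal_potential,
    baseline_current = baseline_current,
    noise_sd = noise_sd,
    filter_corner = filter_corner
  ), class = "GatingScheme")
}

#' Two-state open/closed gating scheme
#'
#' Convenience constructor for the canonical closed <-> open scheme with
#' opening rate `rate_scale * p_max * p(V)` and closing rate
#' `rate_scale * (1 - p_max * p(V))` where `p(V)` is a Boltzmann function of
#' the pipette potential. Under this parameterization the stationary open
#' probability equals `p_max * p(V)` exactly and `1 / rate_scale` sets the
#' characteristic dwell-time scale. A `p_max < 1` keeps brief closures even
#' at saturating voltages.
#'
#' @param scheme_id Identifier.
#' @param v_half Half-activation potential (mV); `NA` for a voltage-independent
#'   open probability `p_open`.
#' @param slope Activation slope (mV).
#' @param rate_scale Sum of opening and closing rates (s^-1); mean open dwell
#'   is `1 / (rate_scale * (1 - p))`, mean closed dwell `1 / (rate_scale * p)`.
#' @param p_max Maximal open probability (0 < p_max <= 1).
#' @param p_open Constant open probability used when `v_half` is `NA`.
#' @param ... Passed to [gating_scheme()] (conductance, noise_sd, ...).
#' @return A `GatingScheme`.
#' @export
two_state_scheme <- function(scheme_id, v_half = NA_real_, slope = 12,
                             rate_scale = 200, p_max = 1, p_open = 0.5, ...) {
  stopifnot(p_max > 0, p_max <= 1)
  if (is.na(v_half)) {
    stopifnot(p_open > 0, p_open < 1)
    trans <- data.frame(
      from = c("C", "O"), to = c("O", "C"),
      base_rate = c(rate_scale * p_open, rate_scale * (1 - p_open)),
      v_half = NA_real_, slope = NA_real_)
  } else if (p_max == 1) {
    # opening ~ sigma((V - v_half)/slope); closing ~ 1 - sigma = sigma with
    # negated slope, so pi_open(V) is exactly the Boltzmann curve.
    trans <- data.frame(
      from = c("C", "O"), to = c("O", "C"),
      base_rate = c(rate_scale, rate_scale),
      v_half = c(v_half, v_half), slope = c(slope, -slope))
  } else {
    # closing rate rate_scale*(1 - p_max*sigma) = (1 - p_max)*rate_scale
    # (constant part) + p_max*rate_scale*sigma(negated slope): two parallel
    # O -> C transitions keep pi_open(V) = p_max * sigma exactly.
    trans <- data.frame(
      from = c("C", "O", "O"), to = c("O", "C", "C"),
      base_rate = c(rate_scale * p_max, rate_scale * (1 - p_max),
                    rate_scale * p_max),
      v_half = c(v_half, NA, v_half), slope = c(slope, NA, -slope))
  }
  gating_scheme(
    scheme_id,
    states = data.frame(name = c("C", "O"), conducting = c(FALSE, TRUE)),
    transitions = trans, ...)
}

#' Voltage-resolved generator matrix
#'
#' Resolves the transition table of a [gating_scheme()] at a pipette potential
#' into the generator matrix Q (off-diagonal entries are rates in s^-1, rows
#' sum to zero).
#'
#' @param scheme A `GatingScheme`.
#' @param potential Pipette potential in mV.
#' @return Square numeric matrix with state names as dimnames.
#' @export
rate_matrix_at <- function(scheme, potential) {
  stopifnot(inherits(scheme, "GatingScheme"), is.finite(potential))
  s <- scheme$states$name
  Q <- matrix(0, length(s), length(s), dimnames = list(s, s))
  tr <- scheme$transitions
  for (i in seq_len(nrow(tr))) {
    r <- tr$base_rate[i]
    if (!is.na(tr$v_half[i])) {
      r <- r / (1 + exp(-(potential - tr$v_half[i]) / tr$slope[i]))
    }
    Q[tr$from[i], tr$to[i]] <- Q[tr$from[i], tr$to[i]] + r
  }
  if (any(!is.finite(Q))) stop_cp("non-finite rates at %g mV", potential)
  diag(Q) <- -rowSums(Q)
  Q
}

#' Stationary distribution of a gating scheme
#'
#' Solves `pi Q = 0`, `sum(pi) = 1` for the voltage-resolved generator.
#'
#' @inheritParams rate_matrix_at
#' @return Named probability vector over states.
#' @export
stationary_distribution <- function(scheme, potential) {
  Q <- rate_matrix_at(scheme, potential)
  n <- nrow(Q)
  # an irreducible generator has a one-dimensional null space (rank n - 1)
  if (qr(t(Q))$rank < n - 1L)
    stop_cp("generator is reducible or degenerate at %g mV (null space dimension > 1)",
            potential)
  # pi Q = 0 with normalization appended; least squares on the stacked system.
  A <- rbind(t(Q), rep(1, n))
  b <- c(rep(0, n), 1)
  pi_hat <- tryCatch(qr.solve(A, b), error = function(e)
    stop_cp("degenerate generator: %s", conditionMessage(e)))
  if (any(pi_hat < -1e-9))
    stop_cp("generator is reducible or degenerate at %g mV (negative stationary mass)",
            potential)
  resid <- max(abs(as.numeric(pi_hat %*% Q)))
  if (resid > 1e-8 * max(1, max(abs(Q))))
    stop_cp("stationary solve failed to satisfy pi Q = 0 (residual %g)", resid)
  pi_hat <- pmax(pi_hat, 0)
  pi_hat <- pi_hat / sum(pi_hat)
  names(pi_hat) <- rownames(Q)
  pi_hat
}

# Stationary open (conducting) probability of a scheme at a potential.
stationary_open_probability <- function(scheme, potential) {
  p <- stationary_distribution(scheme, potential)
  sum(p[scheme$states$conducting])
}

#' Simulate a discrete-time state path
#'
#' Simulates the continuous-time Markov chain by exact event (Gillespie)
#' sampling -- exponential holding times, embedded-chain jumps -- and then
#' samples the path with zero-order hold at `1 / sampling_rate`, so dwell-time
#' statistics are exact regardless of the sampling interval.
#'
#' @inheritParams rate_matrix_at
#' @param n_points Number of samples to produce (>= 1).
#' @param sampling_rate Sampling rate in Hz.
#' @param seed Integer seed; identical seeds give identical paths.
#' @param init_state Optional starting state name; defaults to a draw from the
#'   stationary distribution.
#' @return Integer vector of state indices (into `scheme$states`), with the
#'   state names attached as an attribute.
#' @export
simulate_state_path <- function(scheme, potential, n_points, sampling_rate,
                                seed, init_state = NULL) {
  stopifnot(n_points >= 1, sampling_rate > 0)
  Q <- rate_matrix_at(scheme, potential)
  n_states <- nrow(Q)
  out_rate <- -diag(Q)
  t_total <- n_points / sampling_rate
  with_seed(seed, {
    if (is.null(init_state)) {
      if (all(out_rate == 0)) {
        s0 <- 1L
      } else {
        s0 <- sample.int(n_states, 1, prob = stationary_distribution(scheme, potential))
      }
    } else {
      s0 <- match(init_state, rownames(Q))
      if (is.na(s0)) stop_cp("unknown init_state '%s'", init_state)
    }
    cap <- 256L
    ev_t <- numeric(cap)   # entry time of each segment
    ev_s <- integer(cap)   # state of each segment
    n_ev <- 1L
    ev_t[1] <- 0
    ev_s[1] <- s0
    t_now <- 0
    s_now <- s0
    while (t_now < t_total) {
      lam <- out_rate[s_now]
      if (lam <= 0) break  # absorbing state
      t_now <- t_now + stats::rexp(1, lam)
      if (t_now >= t_total) break
      p_jump <- Q[s_now, ]
      p_jump[s_now] <- 0
      s_now <- sample.int(n_states, 1, prob = p_jump)
      n_ev <- n_ev + 1L
      if (n_ev > cap) {
        cap <- cap * 2L
        length(ev_t) <- cap
        length(ev_s) <- cap
      }
      ev_t[n_ev] <- t_now
      ev_s[n_ev] <- s_now
    }
    ev_t <- ev_t[seq_len(n_ev)]
    ev_s <- ev_s[seq_len(n_ev)]
    sample_times <- (seq_len(n_points) - 1) / sampling_rate
    idx <- findInterval(sample_times, ev_t)
    path <- ev_s[idx]
    attr(path, "state_names") <- rownames(Q)
    attr(path, "conducting") <- scheme$states$conducting[path]
    # exact event path (segment entry times and states) for dwell analysis
    attr(path, "events") <- data.frame(time = ev_t, state = ev_s)
    path
  })
}

# Causal single-pole low-pass filter with corner frequency fc (Hz).
lowpass_single_pole <- function(x, fc, sampling_rate) {
  a <- exp(-2 * pi * fc / sampling_rate)
  as.numeric(stats::filter((1 - a) * x, a, method = "recursive", init = x[1]))
}

#' Render a state path into a current recording
#'
#' Applies the observation model: open-channel current
#' `conductance * (V - reversal) / 1000` pA on conducting states, baseline
#' offset, additive Gaussian noise and (optionally) a causal single-pole
#' low-pass filter at the scheme's corner frequency. Negative potentials yield
#' negative open-channel current.
#'
#' @inheritParams rate_matrix_at
#' @param path State path from [simulate_state_path()].
#' @param seed Integer seed for the noise draw.
#' @param sampling_rate Sampling rate in Hz (stored on the recording and used
#'   by the filter).
#' @param recording_id Identifier for the resulting recording.
#' @param cell_label Class label to attach.
#' @return A `Recording` object: list with `recording_id`, `cell_label`,
#'   `potential`, `trace` (pA), `sampling_rate`, `provenance`.
#' @export
render_recording <- function(path, scheme, potential, seed,
                             sampling_rate = 4000,
                             recording_id = "rec", cell_label = NA_character_) {
  stopifnot(length(path) > 0)
  conducting <- scheme$states$conducting[as.integer(path)]
  i_open <- scheme$conductance * (potential - scheme$reversal_potential) / 1000
  x <- scheme$baseline_current + ifelse(conducting, i_open, 0)
  x <- with_seed(seed, x + stats::rnorm(length(x), 0, scheme$noise_sd))
  if (!is.na(scheme$filter_corner)) {
    x <- lowpass_single_pole(x, scheme$filter_corner, sampling_rate)
  }
  new_recording(recording_id, cell_label, potential, x, sampling_rate,
                provenance = list(seed = seed, scheme_id = scheme$scheme_id,
                                  is_planted_anomaly = FALSE))
}

#' Recording constructor
#'
#' @param recording_id Identifier.
#' @param cell_label Class name.
#' @param potential Pipette potential (mV).
#' @param trace Numeric current trace (pA), finite, nonempty.
#' @param sampling_rate Sampling rate (Hz), positive.
#' @param provenance List of provenance fields (seed, scheme_id,
#'   is_planted_anomaly); empty for real data.
#' @return A `Recording`.
#' @export
new_recording <- function(recording_id, cell_label, potential, trace,
                          sampling_rate, provenance = list()) {
  if (length(trace) == 0) stop_cp("trace must be nonempty")
  if (any(!is.finite(trace))) stop_cp("trace must be finite")
  if (!is.finite(sampling_rate) || sampling_rate <= 0)
    stop_cp("sampling_rate must be positive")
  structure(list(recording_id = as.character(recording_id),
                 cell_label = as.character(cell_label),
                 potential = as.numeric(potential),
                 trace = as.numeric(trace),
                 sampling_rate = as.numeric(sampling_rate),
                 provenance = provenance),
            class = "Recording")
}

#' @export
print.Recording <- function(x, ...) {
  cat(sprintf("<Recording %s> %s at %+g mV, %d points @ %g Hz\n",
              x$recording_id, x$cell_label, x$potential,
              length(x$trace), x$sampling_rate))
  invisible(x)
}

#' @export
print.GatingScheme <- function(x, ...) {
  cat(sprintf("<GatingScheme %s> %d states (%d conducting), %d transitions, %g pS\n",
              x$scheme_id, nrow(x$states), sum(x$states$conducting),
              nrow(x$transitions), x$conductance))
  invisible(x)
}
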