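# Discrete-time (1 ms) simulation of the P-unit -> TmA -> LGMD-input -> LGMD
# pathway.
#
# Each P-unit emits a unit-amplitude 1 ms pulse whenever its binary coverage
# changes. A pulse (a) excites the retinotopically matching LGMD-input unit
# after `E_delay`, and (b), when lateral inhibition is enabled, dispatches
# inhibition of amplitude `L_total_gain / L_spread` to each existing lattice
# neighbour after `L_delay`; arrived inhibition decays exponentially with
# `L_decay_tau`. Unit activation is the rectified difference of excitation and
# inhibition. Self-inhibition (S) is a refractory clamp: a unit whose net
# input exceeds `activation_threshold` has its combined input clamped to zero
# for the following `S_persistence` ms. The LGMD's instantaneous output is the
# sum of unit activations; the headline trace is a leaky integral of it.

#' Simulation constants for the LGMD input network
#'
#' @param dt_ms time step; fixed at 1 ms.
#' @param L_total_gain total lateral-inhibition gain dispatched per pulse when
#'   all six neighbours exist (default 2.0, i.e. 200 x 1/6 % of activation per
#'   neighbour over six neighbours).
#' @param L_spread number of neighbours inhibition is split over (max 6).
#' @param L_delay_ms delay from pulse to inhibition arrival (default 2).
#' @param E_delay_ms delay from pulse to excitation arrival (default 1).
#' @param L_decay_tau_ms exponential decay constant of arrived inhibition
#'   (default 3).
#' @param S_persistence_ms refractory period of the self-inhibition clamp
#'   (default 7).
#' @param enable_L,enable_S switch lateral / self inhibition on or off.
#' @param output_integrator_tau_ms leaky-integrator time constant of the
#'   summed LGMD output (default 8).
#' @param activation_threshold net input above which a unit counts as
#'   activated and arms its refractory clamp (default 0).
#' @param pulse_polarity `"both"`: P-units pulse on coverage onset and offset;
#'   `"onset"`: onset only.
#' @return A `network_params` list.
#' @export
network_params <- function(dt_ms = 1,
                           L_total_gain = 2.0,
                           L_spread = 6L,
                           L_delay_ms = 2L,
                           E_delay_ms = 1L,
                           L_decay_tau_ms = 3,
                           S_persistence_ms = 7L,
                           enable_L = TRUE,
                           enable_S = TRUE,
                           output_integrator_tau_ms = 8,
                           activation_threshold = 0,
                           pulse_polarity = c("both", "onset")) {
  pulse_polarity <- match.arg(pulse_polarity)
  if (dt_ms != 1) stop("the model is defined on a 1 ms grid", call. = FALSE)
  if (L_spread < 1 || L_spread > 6)
    stop("`L_spread` must be between 1 and 6", call. = FALSE)
  if (L_total_gain < 0) stop("gains must be >= 0", call. = FALSE)
  if (any(c(L_delay_ms, E_delay_ms) < 1) ||
      any(c(L_decay_tau_ms, output_integrator_tau_ms) < dt_ms))
    stop("all delays and time constants must be >= dt", call. = FALSE)
  if (S_persistence_ms < 0)
    stop("`S_persistence_ms` must be >= 0", call. = FALSE)
  structure(list(
    dt_ms = dt_ms,
    L_total_gain = L_total_gain,
    L_spread = as.integer(L_spread),
    L_delay_ms = as.integer(L_delay_ms),
    E_delay_ms = as.integer(E_delay_ms),
    L_decay_tau_ms = L_decay_tau_ms,
    S_persistence_ms = as.integer(S_persistence_ms),
    enable_L = isTRUE(enable_L),
    enable_S = isTRUE(enable_S),
    output_integrator_tau_ms = output_integrator_tau_ms,
    activation_threshold = activation_threshold,
    pulse_polarity = pulse_polarity
  ), class = "network_params")
}

#' P-unit pulse trains from a stimulus movie
#'
#' A P-unit emits a unit-amplitude, 1 ms pulse at every frame where its binary
#' coverage changes (0 to 1, or 1 to 0 unless `polarity = "onset"`). The first
#' frame is the baseline: an object already present at motion onset does not
#' pulse until it moves.
#'
#' @param movie a `stimulus_movie` (or plain units x time 0/1 matrix).
#' @param polarity `"both"` (default) or `"onset"`.
#' @return Units x time 0/1 pulse matrix, same dimensions as the movie frames.
#' @export
p_unit_pulses <- function(movie, polarity = c("both", "onset")) {
  polarity <- match.arg(polarity)
  frames <- if (inherits(movie, "stimulus_movie")) movie$frames else movie
  if (!all(frames %in% c(0L, 1L)))
    stop("movie frames must be binary", call. = FALSE)
  T <- ncol(frames)
  pulses <- matrix(0L, nrow(frames), T)
  if (T >= 2L) {
    diffs <- frames[, -1L, drop = FALSE] - frames[, -T, drop = FALSE]
    pulses[, -1L] <- if (polarity == "both") abs(diffs) else pmax(diffs, 0L)
  }
  pulses
}

#' Initial network state
#'
#' @param array a [hex_array()].
#' @param params a [network_params()].
#' @return A `network_state` list with per-unit inhibition level, refractory
#'   timers, activations and the two output accumulators.
#' @export
init_network_state <- function(array, params = network_params()) {
  n <- nrow(array)
  structure(list(
    array = array,
    params = params,
    inhibition = numeric(n),
    refractory_ms = integer(n),
    activation = numeric(n),
    output_instant = 0,
    output_integrated = 0
  ), class = "network_state")
}

#' Advance the network by one millisecond
#'
#' Applies one update of the network dynamics given the excitation and
#' inhibition arriving this millisecond. Exposed mainly so small circuits can
#' be stepped by hand; [run_network()] drives whole movies.
#'
#' @param state a `network_state` from [init_network_state()].
#' @param excitation_arriving per-unit excitation arriving this step (pulses
#'   delayed by `E_delay_ms`).
#' @param inhibition_arriving per-unit inhibition arriving this step (already
#'   spread over neighbours and delayed by `L_delay_ms`).
#' @return The updated `network_state`.
#' @export
network_step <- function(state, excitation_arriving, inhibition_arriving = 0) {
  p <- state$params
  n <- length(state$inhibition)
  exc <- rep_len(excitation_arriving, n)
  inh_in <- rep_len(inhibition_arriving, n)

  state$inhibition <- state$inhibition * exp(-p$dt_ms / p$L_decay_tau_ms) +
    inh_in
  net <- exc - if (p$enable_L) state$inhibition else 0
  act <- pmax(net, 0)

  if (p$enable_S) {
    clamped <- state$refractory_ms > 0L
    act[clamped] <- 0
    trigger <- act > p$activation_threshold
    state$refractory_ms <- pmax(state$refractory_ms - 1L, 0L)
    state$refractory_ms[trigger] <- p$S_persistence_ms
  }

  state$activation <- act
  state$output_instant <- sum(act)
  state$output_integrated <-
    state$output_integrated * exp(-p$dt_ms / p$output_integrator_tau_ms) +
    state$output_instant
  state
}

#' Run the network over a stimulus movie
#'
#' Fully deterministic: identical movies and parameters give bit-identical
#' outputs. Excitation and inhibition scheduled to arrive after the last frame
#' are discarded so every condition is compared over the same time axis.
#'
#' @param movie a `stimulus_movie`.
#' @param params a [network_params()].
#' @return A `simulation_result`: list with `time_ms`, `output_instant`,
#'   `output_integrated`, `activation_map` (per-unit summed activation),
#'   `params`, and the movie's subtense metadata.
#' @export
run_network <- function(movie, params = network_params()) {
  stopifnot(inherits(movie, "stimulus_movie"))
  array <- movie$array
  n <- nrow(movie$frames)
  if (n != nrow(array))
    stop("movie and array dimensions disagree", call. = FALSE)
  T <- ncol(movie$frames)
  p <- params

  pulses <- p_unit_pulses(movie, p$pulse_polarity)

  shift_right <- function(m, k) {
    if (k >= ncol(m)) return(matrix(0, nrow(m), ncol(m)))
    cbind(matrix(0, nrow(m), k), m[, seq_len(ncol(m) - k), drop = FALSE])
  }
  exc_arr <- shift_right(pulses, p$E_delay_ms)
  inh_arr <- if (p$enable_L) {
    A <- .hex_adjacency(array)
    shift_right((p$L_total_gain / p$L_spread) * (A %*% pulses), p$L_delay_ms)
  } else {
    matrix(0, n, T)
  }

  state <- init_network_state(array, p)
  out_i <- numeric(T)
  out_int <- numeric(T)
  act_map <- numeric(n)
  for (t in seq_len(T)) {
    state <- network_step(state, exc_arr[, t], inh_arr[, t])
    out_i[t] <- state$output_instant
    out_int[t] <- state$output_integrated
    act_map <- act_map + state$activation
  }

  structure(list(
    time_ms = movie$time_ms,
    output_instant = out_i,
    output_integrated = out_int,
    activation_map = data.frame(unit_id = array$unit_id, activation = act_map),
    subtense_deg = movie$subtense_deg,
    stimulus_type = movie$trajectory$type,
    params = p
  ), class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf(
    "<simulation_result> %s, %d ms (L %s, S %s): final integrated output %.3f\n",
    x$stimulus_type, length(x$time_ms),
    if (x$params$enable_L) "on" else "off",
    if (x$params$enable_S) "on" else "off",
    x$output_integrated[length(x$output_integrated)]
  ))
  invisible(x)
}

#' Run the four inhibition conditions on one movie
#'
#' Runs [run_network()] with (L, S) in {(off, off), (on, off), (off, on),
#' (on, on)} on the same movie.
#'
#' @param movie a `stimulus_movie`.
#' @param params a [network_params()]; its `enable_L` / `enable_S` fields are
#'   overridden per condition.
#' @return Named list of four `simulation_result`s: `none`, `L`, `S`, `LS`.
#' @export
condition_battery <- function(movie, params = network_params()) {
  conds <- list(none = c(FALSE, FALSE), L = c(TRUE, FALSE),
                S = c(FALSE, TRUE), LS = c(TRUE, TRUE))
  lapply(conds, function(ls) {
    p <- params
    p$enable_L <- ls[1]
    p$enable_S <- ls[2]
    run_network(movie, p)
  })
}

#' First time two output series diverge
#'
#' First time point where `|a - b|` exceeds `epsilon` times the peak of `a`;
#' `NA` if the series never diverge.
#'
#' @param a,b numeric series of equal length (`a` is the reference whose peak
#'   scales the criterion).
#' @param epsilon divergence criterion as a fraction of `max(a)` (default 1%).
#' @param time_ms optional time axis; defaults to 1..length(a).
#' @return Time of first divergence (ms), or `NA_real_`.
#' @export
divergence_time <- function(a, b, epsilon = 0.01, time_ms = seq_along(a)) {
  if (length(a) == 0L || length(a) != length(b))
    stop("series must be nonempty and of equal length", call. = FALSE)
  hit <- which(abs(a - b) > epsilon * max(a))
  if (length(hit) == 0L) return(NA_real_)
  time_ms[hit[1L]]
}

#' Suppression index of an inhibited run
#'
#' `1 - final(inhibited) / final(base)` on the integrated output: 0 when
#' inhibition changes nothing, 1 when it abolishes the response.
#'
#' @param base,inhibited `simulation_result`s over the same movie.
#' @return Suppression fraction.
#' @export
suppression_index <- function(base, inhibited) {
  fb <- base$output_integrated[length(base$output_integrated)]
  fi <- inhibited$output_integrated[length(inhibited$output_integrated)]
  if (fb == 0)
    stop("suppression index undefined: base response is zero", call. = FALSE)
  1 - fi / fb
}

#' Sweep the self-inhibition persistence
#'
#' Runs the movie with S-inhibition only (L off) for each persistence value
#' and measures the suppression relative to the fully uninhibited run. The
#' saturation point is the smallest persistence whose suppression is within 1%
#' (relative) of the sweep maximum.
#'
#' @param movie a `stimulus_movie`.
#' @param params a [network_params()] (L and S switches are overridden).
#' @param persistences_ms ascending persistence values, ms.
#' @return List with `curve` (data frame `persistence_ms`, `suppression`) and
#'   `saturation_ms`.
#' @export
persistence_sweep <- function(movie, params = network_params(),
                              persistences_ms = 3:12) {
  if (length(persistences_ms) == 0L)
    stop("`persistences_ms` must be nonempty", call. = FALSE)
  if (is.unsorted(persistences_ms))
    stop("`persistences_ms` must be ascending", call. = FALSE)
  p0 <- params
  p0$enable_L <- FALSE
  p0$enable_S <- FALSE
  base <- run_network(movie, p0)
  supp <- vapply(persistences_ms, function(pp) {
    p <- p0
    p$enable_S <- TRUE
    p$S_persistence_ms <- as.integer(pp)
    suppression_index(base, run_network(movie, p))
  }, numeric(1))
  s_max <- max(supp)
  ok <- abs(supp - s_max) <= 0.01 * abs(s_max)
  list(
    curve = data.frame(persistence_ms = persistences_ms, suppression = supp),
    saturation_ms = persistences_ms[which(ok)[1L]]
  )
}
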