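#' Synaptic conductance kernels
#'
#' `conductance_double_exp()` evaluates the peak-normalised double
#' exponential `g(t) = g_max * N * (exp(-(t-t0)/tau_decay) -
#' exp(-(t-t0)/tau_rise))` (0 for `t < t0`), where N is chosen so that the
#' peak equals `g_max` ("maximum conductance"). The peak occurs at
#' `t0 + tau_rise*tau_decay/(tau_decay - tau_rise) * log(tau_decay/tau_rise)`.
#'
#' @param t Time(s), ms.
#' @param t0 Onset time, ms.
#' @param tau_rise,tau_decay Kinetic time constants, ms
#'   (`0 < tau_rise < tau_decay`).
#' @param g_max Peak conductance (any conductance unit; returned in kind).
#' @return Conductance values, same unit as `g_max`.
#' @examples
#' conductance_double_exp(1, 0, 0.3, 1.8, g_max = 0.73)
#' @export
conductance_double_exp <- function(t, t0, tau_rise, tau_decay, g_max = 1) {
  norm <- dexp_norm(tau_rise, tau_decay)
  dt <- pmax(t - t0, 0)
  out <- g_max * norm * (exp(-dt / tau_decay) - exp(-dt / tau_rise))
  out[t < t0] <- 0
  out
}

dexp_norm <- function(tau_rise, tau_decay) {
  if (!(tau_rise > 0 && tau_decay > tau_rise)) {
    abort("double-exponential kinetics need 0 < tau_rise < tau_decay.")
  }
  tp <- tau_rise * tau_decay / (tau_decay - tau_rise) *
    log(tau_decay / tau_rise)
  1 / (exp(-tp / tau_decay) - exp(-tp / tau_rise))
}

#' Magnesium block of the NMDA conductance
#'
#' Voltage dependence of the NMDA receptor conductance in 1 mM external
#' magnesium (Jahr-Stevens form):
#' `s(v) = 1 / (1 + [Mg] * exp(-gamma * v) / 3.57)`.
#' Monotone increasing in `v`, with `s -> 1` as `v -> +Inf`.
#'
#' @param v Membrane voltage, mV.
#' @param mg External magnesium concentration, mM (default 1).
#' @param gamma Voltage sensitivity, 1/mV (default 0.062).
#' @return Unblocked fraction in (0, 1).
#' @examples
#' nmda_block(0)    # ~0.78
#' nmda_block(-70)
#' @export
nmda_block <- function(v, mg = 1, gamma = 0.062) {
  1 / (1 + mg * exp(-gamma * v) / 3.57)
}

#' Homogeneous Poisson spike trains
#'
#' Draws `n_trains` independent homogeneous Poisson spike trains at `rate`
#' Hz on `[t_start, t_stop]` ms, reproducibly by seed. Used as background
#' synaptic noise.
#'
#' @param n_trains Number of trains.
#' @param rate Rate in Hz (>= 0).
#' @param t_start,t_stop Window in ms.
#' @param seed Integer seed.
#' @return A list of numeric spike-time vectors (ms).
#' @examples
#' poisson_trains(3, rate = 50, t_start = 10, t_stop = 100, seed = 1)
#' @export
poisson_trains <- function(n_trains, rate = 1, t_start = 10, t_stop = 100,
                           seed = 1L) {
  stopifnot(rate >= 0, t_stop > t_start, n_trains >= 0)
  if (rate == 0 || n_trains == 0) {
    return(replicate(n_trains, numeric(0), simplify = FALSE))
  }
  rate_ms <- rate / 1000
  block <- max(10L, ceiling(2 * rate_ms * (t_stop - t_start)) + 10L)
  withr_seed(seed, {
    lapply(seq_len(n_trains), function(i) {
      acc <- numeric(0)
      t <- t_start
      repeat {
        tt <- t + cumsum(rexp(block, rate_ms))
        acc <- c(acc, tt)
        t <- tt[length(tt)]
        if (t > t_stop) break
      }
      acc[acc <= t_stop]
    })
  })
}

#' Synapse constructors
#'
#' Build rows of the synapse table consumed by [simulate_tree()]. AMPA and
#' NMDA are peak-normalised double exponentials (`g_max` in nS); the NMDA
#' conductance is additionally gated by [nmda_block()] at the previous-step
#' local voltage. `syn_single_exp()` is the instantaneous-rise single
#' exponential (`g_max` in uS) used for spike-train input synapses.
#' Kinetics defaults: AMPA 0.3/1.8 ms, peak 0.73 nS; NMDA 8.019/34.9884 ms,
#' peak 1.31 nS; both with 0 mV reversal.
#'
#' @param node Target compartment index (one per synapse; vectorised).
#' @param times Spike times, ms: a numeric vector (one synapse) or a list.
#' @param g_max Peak conductance: nS for AMPA/NMDA, uS for single-exp.
#' @param tau_rise,tau_decay,tau Kinetics, ms.
#' @param e_syn Reversal potential, mV.
#' @return A tibble with columns `node`, `kind`, `g_max` (uS), `tau_rise`,
#'   `tau_decay`, `e_syn`, `times` (list-column).
#' @examples
#' syn_ampa(node = 5, times = c(10, 30))
#' @export
syn_ampa <- function(node, times, g_max = 0.73, tau_rise = 0.3,
                     tau_decay = 1.8, e_syn = 0) {
  syn_table(node, times, "ampa", g_max * 1e-3, tau_rise, tau_decay, e_syn)
}

#' @rdname syn_ampa
#' @export
syn_nmda <- function(node, times, g_max = 1.31, tau_rise = 8.019,
                     tau_decay = 34.9884, e_syn = 0) {
  syn_table(node, times, "nmda", g_max * 1e-3, tau_rise, tau_decay, e_syn)
}

#' @rdname syn_ampa
#' @export
syn_single_exp <- function(node, times, g_max = 0.05, tau = 0.5, e_syn = 1) {
  syn_table(node, times, "expsyn", g_max, NA_real_, tau, e_syn)
}

syn_table <- function(node, times, kind, g_max_us, tau_rise, tau_decay,
                      e_syn) {
  if (!is.list(times)) times <- list(times)
  n <- max(length(node), length(times))
  if (kind != "expsyn") dexp_norm(tau_rise, tau_decay) # validates kinetics
  if (any(g_max_us < 0)) abort("`g_max` must be non-negative.")
  tibble(
    node = rep_len(as.integer(node), n),
    kind = kind,
    g_max = rep_len(g_max_us, n),
    tau_rise = rep_len(tau_rise, n),
    tau_decay = rep_len(tau_decay, n),
    e_syn = rep_len(e_syn, n),
    times = rep_len(times, n)
  )
}

#' Simulate a compartmental neuron
#'
#' Fixed-step backward-Euler integration of the passive branched cable with
#' conductance-based synapses: at every step synaptic states advance, the
#' Hines system is assembled, solved with the selected backend, and voltages
#' advance. Somatic spikes are upward crossings of `threshold` with a
#' refractory gap for counting. The serial and DHS backends perform the same
#' arithmetic in different elimination orders and agree to near machine
#' precision.
#'
#' @param tree A compartment tree.
#' @param synapses A synapse tibble (rows from [syn_ampa()] and friends), or
#'   NULL.
#' @param i_inj Constant injected current per node, nA (scalar or vector).
#' @param t_stop Simulation length, ms.
#' @param dt Time step, ms (default 0.025).
#' @param record Node indices to record (always includes `spike_site`).
#' @param solver `"serial"` or `"dhs"`.
#' @param k Threads for the DHS backend.
#' @param spike_site Node whose trace is scanned for spikes (default soma).
#' @param threshold Spike threshold, mV (default -10, somatic upward
#'   crossing).
#' @param refractory Minimum gap between counted spikes, ms (default 2).
#' @param v0 Initial voltage (default: the leak reversal per node).
#' @return An object of class `cable_sim`: list with `times`, `traces`
#'   (matrix, one column per recorded node), `record`, `spike_times`,
#'   `n_iterations`, `solver`, `dt`. Methods: [tidy()], [glance()],
#'   [autoplot()].
#' @examples
#' sim <- simulate_tree(tree_chain(5), t_stop = 5)
#' glance(sim)
#' @export
simulate_tree <- function(tree, synapses = NULL, i_inj = 0, t_stop = 100,
                          dt = 0.025, record = 1L,
                          solver = c("serial", "dhs"), k = 4L,
                          spike_site = 1L, threshold = -10, refractory = 2,
                          v0 = NULL) {
  solver <- match.arg(solver)
  if (!is.numeric(dt) || dt <= 0) abort("`dt` must be a positive step, ms.")
  n <- nrow(tree)
  co <- tree_coefficients(tree)
  record <- sort(unique(c(as.integer(spike_site), as.integer(record))))
  n_steps <- as.integer(round(t_stop / dt))

  elim <- if (solver == "serial") {
    rev(seq_len(n)[-1])
  } else {
    unlist(lapply(dhs_partition(tree, k)$subsets, sort))
  }

  if (is.null(synapses) || nrow(as_tibble(synapses)) == 0) {
    syn <- tibble(node = integer(0), kind = character(0), g_max = numeric(0),
                  tau_rise = numeric(0), tau_decay = numeric(0),
                  e_syn = numeric(0), times = list())
  } else {
    syn <- as_tibble(synapses)
  }
  kind_code <- c(expsyn = 0L, ampa = 1L, nmda = 2L)[syn$kind]
  norm <- vapply(seq_len(nrow(syn)), function(i) {
    if (syn$kind[i] == "expsyn") 1 else dexp_norm(syn$tau_rise[i],
                                                  syn$tau_decay[i])
  }, 1)
  spike_times <- unlist(lapply(syn$times, sort), use.names = FALSE)
  if (is.null(spike_times)) spike_times <- numeric(0)
  spike_off <- c(0L, cumsum(vapply(syn$times, length, 1L)))

  res <- simulate_core_cpp(
    parent = c(-1L, tree$parent[-1] - 1L),
    elim = as.integer(elim - 1L),
    c_nf = co$c_nf, g_leak = co$g_leak, g_axial = co$g_axial, el = co$el,
    v0 = rep_len(if (is.null(v0)) co$el else v0, n),
    i_inj = rep_len(as.numeric(i_inj), n),
    dt = dt, n_steps = n_steps,
    syn_node = as.integer(syn$node - 1L), syn_kind = as.integer(kind_code),
    syn_gmax = as.numeric(syn$g_max),
    syn_tau_r = ifelse(is.na(syn$tau_rise), 1, syn$tau_rise),
    syn_tau_d = as.numeric(syn$tau_decay),
    syn_esyn = as.numeric(syn$e_syn), syn_norm = as.numeric(norm),
    spike_times = as.numeric(spike_times),
    spike_off = as.integer(spike_off),
    record = as.integer(record - 1L), mg = 1, gamma = 0.062
  )
  times <- seq_len(n_steps) * dt
  traces <- res$traces
  colnames(traces) <- paste0("node", record)
  soma_trace <- traces[, match(spike_site, record)]
  out <- list(
    times = times, traces = traces, record = record,
    spike_times = detect_spikes(times, soma_trace, threshold, refractory),
    n_iterations = n_steps, solver = solver, dt = dt,
    spike_site = spike_site, threshold = threshold
  )
  class(out) <- "cable_sim"
  out
}

detect_spikes <- function(times, v, threshold, refractory) {
  up <- which(v[-1] >= threshold & v[-length(v)] < threshold) + 1L
  if (length(up) == 0) return(numeric(0))
  keep <- numeric(0)
  last <- -Inf
  for (t in times[up]) {
    if (t - last >= refractory) {
      keep <- c(keep, t)
      last <- t
    }
  }
  keep
}

#' @describeIn simulate_tree Long-format traces: `time`, `node`, `v`.
#' @param x A `cable_sim`.
#' @param ... Unused.
#' @export
tidy.cable_sim <- function(x, ...) {
  as_tibble(x$traces) |>
    dplyr::mutate(time = x$times) |>
    tidyr::pivot_longer(-"time", names_to = "node", values_to = "v",
                        names_prefix = "node",
                        names_transform = list(node = as.integer))
}

#' @describeIn simulate_tree One-row summary: iterations, spike count,
#'   voltage range at the spike site.
#' @export
glance.cable_sim <- function(x, ...) {
  soma <- x$traces[, match(x$spike_site, x$record)]
  tibble(
    n_iterations = x$n_iterations, dt = x$dt, solver = x$solver,
    n_spikes = length(x$spike_times),
    v_min = min(soma), v_max = max(soma)
  )
}
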