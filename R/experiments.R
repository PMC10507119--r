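#' Relative-cost sweep across morphologies and thread counts
#'
#' Runs the scheduler on each model for each thread count and tabulates the
#' number of parallel steps and the cost relative to the serial solve.
#'
#' @param models A named list of compartment trees.
#' @param ks Integer vector of thread counts.
#' @return A tibble of class `dhs_cost_sweep` with columns `model`, `k`,
#'   `n_nodes`, `steps`, `relative_cost`.
#' @examples
#' cost_sweep(list(chain = tree_chain(20), star = tree_star(20)), ks = c(2, 4))
#' @export
cost_sweep <- function(models, ks) {
  stopifnot(length(models) > 0, all(ks >= 1))
  if (is.null(names(models))) names(models) <- paste0("model", seq_along(models))
  out <- purrr::imap_dfr(models, function(tree, name) {
    purrr::map_dfr(ks, function(k) {
      g <- glance(dhs_partition(tree, k))
      tibble(model = name, k = as.integer(k), n_nodes = g$n_nodes,
             steps = g$steps, relative_cost = g$relative_cost)
    })
  })
  class(out) <- unique(c("dhs_cost_sweep", class(out)))
  out
}

#' Spike-probability protocol grids
#'
#' The excitability protocol measures somatic spike probability as a
#' function of synaptic drive, in two spatial modes: `"distributed"`
#' (synapse counts 0..240 over 14 cases, spread over the dendritic tree) and
#' `"clustered"` (0..12 clusters of 20 synapses each over 9 cases, each
#' cluster on one compartment). With the default 50 samples per case the
#' full design totals (14 + 9) x 50 = 1150 simulated model instances.
#'
#' @param mode `"distributed"` or `"clustered"`.
#' @return `protocol_cases()`: integer vector of case values (synapse count
#'   or cluster count).
#' @examples
#' protocol_cases("distributed")
#' protocol_samples()
#' @export
protocol_cases <- function(mode = c("distributed", "clustered")) {
  mode <- match.arg(mode)
  if (mode == "distributed") {
    as.integer(c(0, 10, 20, seq(40, 240, by = 20)))
  } else {
    as.integer(c(0, 1, 2, 3, 4, 6, 8, 10, 12))
  }
}

#' @rdname protocol_cases
#' @param n_distributed,n_clustered Number of cases per mode.
#' @param samples Samples per case.
#' @return `protocol_samples()`: total sample count of the paired design.
#' @export
protocol_samples <- function(n_distributed = length(protocol_cases("distributed")),
                             n_clustered = length(protocol_cases("clustered")),
                             samples = 50) {
  (n_distributed + n_clustered) * samples
}

#' Spike probability from per-sample spike counts
#'
#' Fraction of sampled model instances that fired at least once.
#'
#' @param spike_counts Integer vector, somatic spikes per sample.
#' @return Fraction in \[0, 1\].
#' @examples
#' spike_probability(c(0, 2, 1, 0))
#' @export
spike_probability <- function(spike_counts) {
  if (length(spike_counts) == 0) abort("at least one sample is required.")
  mean(spike_counts >= 1)
}

# deterministic seed mixing, kept within 32-bit integer range
mix_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  acc <- 0
  for (p in parts) acc <- (acc * 7919 + as.numeric(p) + 1) %% 2147483629
  as.integer(acc)
}

#' Choose activated synapse sites for one protocol sample
#'
#' Distributed mode draws host compartments from the eligible dendrites
#' (beyond the spine distance threshold) weighted by compartment length;
#' clustered mode draws one host compartment per cluster uniformly and puts
#' 20 synapses on it. Placement is a pure function of `(seed, sample)`.
#'
#' @param tree The bare (spineless) compartment tree.
#' @param mode `"distributed"` or `"clustered"`.
#' @param value Case value: synapse count (distributed) or cluster count.
#' @param spec A [spine_spec()] (for the eligibility threshold).
#' @param seed,sample Protocol seed and sample index.
#' @param cluster_size Synapses per cluster (default 20).
#' @return Integer vector of host compartment indices, one per synapse.
#' @export
place_inputs <- function(tree, mode = c("distributed", "clustered"), value,
                         spec = spine_spec(), seed = 1L, sample = 1L,
                         cluster_size = 20L) {
  mode <- match.arg(mode)
  eligible <- which(tree$kind == "dend" &
                    tree$path_dist > spec$distance_threshold)
  if (value == 0) return(integer(0))
  if (length(eligible) == 0) abort("no eligible dendritic compartments.")
  withr_seed(mix_seed(seed, sample, if (mode == "distributed") 1 else 2), {
    if (mode == "distributed") {
      sample(eligible, size = value, replace = TRUE,
             prob = tree$length[eligible])
    } else {
      hosts <- sample(eligible, size = value, replace = FALSE)
      rep(hosts, each = cluster_size)
    }
  })
}

# attach one explicit spine per activated site and return the tree plus the
# spine-head node of each site
attach_activated_spines <- function(tree, hosts, spec) {
  n0 <- nrow(tree)
  n_act <- length(hosts)
  if (n_act == 0) return(list(tree = tree, heads = integer(0)))
  neck_idx <- n0 + 2L * seq_len(n_act) - 1L
  new_rows <- tibble(
    node = as.integer(rbind(neck_idx, neck_idx + 1L)),
    parent = as.integer(rbind(hosts, neck_idx)),
    kind = rep(c("spine_neck", "spine_head"), n_act),
    length = rep(c(spec$neck_length, spec$head_length), n_act),
    diam = rep(c(spec$neck_diam, spec$head_diam), n_act),
    cm = rep(tree$cm[hosts], each = 2),
    rm = rep(tree$rm[hosts], each = 2),
    ra = rep(tree$ra[hosts], each = 2),
    el = spec$el_spine
  )
  out <- as_compartment_tree(dplyr::bind_rows(tree[, names(new_rows)], new_rows))
  list(tree = out, heads = neck_idx + 1L)
}

#' Run the spine-excitability protocol
#'
#' For each case of the chosen grid, simulates `samples` model instances and
#' reports the somatic spike probability. Two model variants: `"full"`
#' attaches every spine explicitly at `spec$density` and activates synapses
#' on existing spine heads; `"few"` folds the spine membrane into the
#' dendrites via F_spine and attaches only the activated spines explicitly.
#' Every activated site carries an AMPA + NMDA pair on the spine-head
#' terminal, all activated simultaneously at `t_act`. Optional background
#' noise attaches `noise_trains` 1-Hz Poisson trains (AMPA + NMDA with the
#' NMDA peak drawn uniformly from 1.57-3.275 nS) to randomly selected spine
#' heads from `t_noise` onward.
#'
#' @param variant `"full"` or `"few"`.
#' @param mode `"distributed"` or `"clustered"`.
#' @param cases Case values (default the full grid of [protocol_cases()]).
#' @param samples Samples per case (default 50).
#' @param tree Bare morphology (default [synthetic_pyramidal()]).
#' @param spec A [spine_spec()].
#' @param noise Attach background noise (default TRUE).
#' @param noise_trains,noise_rate,t_noise Background-noise design.
#' @param t_stop,t_act,dt Timing, ms.
#' @param seed Protocol seed.
#' @param threshold Somatic spike threshold, mV.
#' @return A tibble of class `excitability_result`: `variant`, `mode`,
#'   `case`, `n_syn`, `fired`, `samples`, `spike_prob`.
#' @export
run_excitability <- function(variant = c("full", "few"),
                             mode = c("distributed", "clustered"),
                             cases = protocol_cases(mode), samples = 50,
                             tree = synthetic_pyramidal(),
                             spec = spine_spec(), noise = TRUE,
                             noise_trains = 400, noise_rate = 1,
                             t_noise = 10, t_stop = 100, t_act = 20,
                             dt = 0.025, seed = 1L, threshold = -10) {
  variant <- match.arg(variant)
  mode <- match.arg(mode)
  cluster_size <- 20L

  full_tree <- NULL
  head_by_host <- NULL
  if (variant == "full") {
    full_tree <- attach_spines(tree, spec, seed = mix_seed(seed, 99))
    heads <- which(full_tree$kind == "spine_head")
    hosts_of_heads <- full_tree$parent[full_tree$parent[heads]]
    head_by_host <- split(heads, hosts_of_heads)
  } else {
    few_base <- apply_fspine(tree, spec)
  }

  rows <- purrr::map_dfr(cases, function(cv) {
    n_syn <- if (mode == "distributed") cv else cv * cluster_size
    fired <- 0L
    for (s in seq_len(samples)) {
      hosts <- place_inputs(tree, mode, cv, spec, seed = seed, sample = s,
                            cluster_size = cluster_size)
      if (variant == "full") {
        model <- full_tree
        sites <- withr_seed(mix_seed(seed, s, 3), {
          vapply(hosts, function(h) {
            cand <- head_by_host[[as.character(h)]]
            if (is.null(cand)) abort("activated site has no spine available.")
            cand[sample.int(length(cand), 1L)]
          }, 1L)
        })
      } else {
        att <- attach_activated_spines(few_base, hosts, spec)
        model <- att$tree
        sites <- att$heads
      }
      syn <- NULL
      if (length(sites) > 0) {
        syn <- dplyr::bind_rows(
          syn_ampa(sites, times = rep(list(t_act), length(sites))),
          syn_nmda(sites, times = rep(list(t_act), length(sites)))
        )
      }
      if (noise && noise_trains > 0) {
        all_heads <- which(model$kind == "spine_head")
        noise_sites_pool <- if (length(all_heads) > 0) all_heads else
          which(model$kind == "dend" &
                model$path_dist > spec$distance_threshold)
        trains <- poisson_trains(noise_trains, rate = noise_rate,
                                 t_start = t_noise, t_stop = t_stop,
                                 seed = mix_seed(seed, s, 4))
        withr_seed(mix_seed(seed, s, 5), {
          nsite <- sample(noise_sites_pool, noise_trains, replace = TRUE)
          ngmax <- runif(noise_trains, 1.57, 3.275)
        })
        keep <- vapply(trains, length, 1L) > 0
        if (any(keep)) {
          syn <- dplyr::bind_rows(
            syn,
            syn_ampa(nsite[keep], times = trains[keep]),
            syn_nmda(nsite[keep], times = trains[keep],
                     g_max = ngmax[keep])
          )
        }
      }
      sim <- simulate_tree(model, synapses = syn, t_stop = t_stop, dt = dt,
                           threshold = threshold)
      if (length(sim$spike_times) >= 1) fired <- fired + 1L
    }
    tibble(variant = variant, mode = mode, case = cv, n_syn = n_syn,
           fired = fired, samples = samples,
           spike_prob = fired / samples)
  })
  class(rows) <- unique(c("excitability_result", class(rows)))
  rows
}
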