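#' Electrical coefficients of a compartment tree
#'
#' Converts specific membrane/axial parameters into the absolute quantities
#' the solver uses, in the mV / ms / nA / uS / MOhm unit system:
#' capacitance `c_nf` (nF, so c_nf/dt is in uS), leak conductance `g_leak`
#' (uS), and the axial coupling conductance `g_axial` (uS) between each
#' compartment's midpoint and its parent's midpoint (NEURON-style
#' half-resistance sum; 0 at the root).
#'
#' @param tree A compartment tree.
#' @return A tibble with columns `node`, `parent`, `c_nf`, `g_leak`,
#'   `g_axial`, `el`.
#' @export
tree_coefficients <- function(tree) {
  area_cm2 <- membrane_area(tree) * 1e-8           # um^2 -> cm^2
  c_nf <- tree$cm * area_cm2 * 1e3                 # uF -> nF
  g_leak <- area_cm2 / tree$rm * 1e6               # S -> uS
  # half axial resistance of each compartment, MOhm:
  # ra [Ohm cm] * (L/2) [um] / cross-section [um^2], with 1 Ohm cm = 1e4
  # Ohm um and 1e6 Ohm = 1 MOhm
  r_half <- tree$ra * 1e4 * (tree$length / 2) / (pi * (tree$diam / 2)^2) / 1e6
  g_axial <- numeric(nrow(tree))
  p <- tree$parent
  nonroot <- which(!is.na(p))
  g_axial[nonroot] <- 1 / (r_half[nonroot] + r_half[p[nonroot]])
  tibble(node = tree$node, parent = p, c_nf = c_nf, g_leak = g_leak,
         g_axial = g_axial, el = tree$el)
}

new_hines_system <- function(parent, d, u, l, rhs) {
  out <- tibble(
    node = seq_along(d), parent = as.integer(parent),
    d = d, u = u, l = l, rhs = rhs
  )
  class(out) <- unique(c("hines_system", class(out)))
  out
}

#' Assemble the Hines linear system for one implicit time step
#'
#' Backward-Euler finite-volume discretisation of the branched cable
#' equation: solving `A x = rhs` yields the voltages at `t + dt`. Row i has
#' diagonal `d_i = c_i/dt + g_leak_i + g_syn_i + sum(axial)`, coupling to the
#' parent `u_i` and from each child `l_c` (both `-g_axial`), and right-hand
#' side `c_i/dt * v_i + g_leak_i * E_l + g_syn_i * E_syn + I_inj`. With
#' `steady = TRUE` the capacitive terms are dropped and the solution is the
#' passive steady state.
#'
#' @param tree A compartment tree.
#' @param dt Time step in ms (> 0). Ignored when `steady = TRUE`.
#' @param v Per-node voltage at time t, mV (default the leak reversal).
#' @param g_syn Per-node total synaptic conductance at t + dt, uS.
#' @param ge_syn Per-node sum of `g * E_syn` over synapses, uS mV.
#' @param i_inj Per-node injected current, nA.
#' @param steady Drop capacitive terms (steady-state resistance problems).
#' @return A `hines_system` tibble with columns `node`, `parent`, `d`, `u`,
#'   `l`, `rhs`.
#' @examples
#' sys <- assemble_hines(tree_chain(3), dt = 0.025)
#' solve_hines(sys)
#' @export
assemble_hines <- function(tree, dt = 0.025, v = NULL, g_syn = 0,
                           ge_syn = 0, i_inj = 0, steady = FALSE) {
  if (!steady && (!is.numeric(dt) || dt <= 0)) {
    abort("`dt` must be a positive time step in ms.")
  }
  co <- tree_coefficients(tree)
  n <- nrow(co)
  if (is.null(v)) v <- co$el
  v <- rep_len(v, n)
  g_syn <- rep_len(g_syn, n)
  ge_syn <- rep_len(ge_syn, n)
  i_inj <- rep_len(i_inj, n)
  cdt <- if (steady) numeric(n) else co$c_nf / dt
  d <- cdt + co$g_leak + g_syn
  rhs <- cdt * v + co$g_leak * co$el + ge_syn + i_inj
  u <- -co$g_axial
  u[1] <- 0
  nonroot <- seq_len(n)[-1]
  d[nonroot] <- d[nonroot] + co$g_axial[nonroot]
  for (i in nonroot) d[co$parent[i]] <- d[co$parent[i]] + co$g_axial[i]
  new_hines_system(co$parent, d, u, u, rhs)
}

#' Solve a Hines system serially
#'
#' The classic two-phase tree solve. Triangularization visits every non-root
#' node exactly once, child before parent (`d_p <- d_p - l_i * u_i / d_i`,
#' `rhs_p <- rhs_p - l_i * rhs_i / d_i`); back-substitution starts at the
#' root (`x_root = rhs_root / d_root`) and proceeds parent before child
#' (`x_i = (rhs_i - u_i * x_parent) / d_i`). The serial step count (number of
#' non-root nodes) is reported in the `steps` attribute.
#'
#' @param system A `hines_system` tibble from [assemble_hines()] or
#'   [random_hines()].
#' @return Numeric solution vector `x` (mV for assembled systems) with
#'   attribute `steps`.
#' @examples
#' solve_hines(random_hines(tree_binary(7), seed = 1))
#' @export
solve_hines <- function(system) {
  n <- nrow(system)
  d <- system$d; u <- system$u; l <- system$l; rhs <- system$rhs
  parent <- system$parent
  for (i in rev(seq_len(n)[-1])) { # topological order: descending index
    if (abs(d[i]) < 1e-300) {
      abort(sprintf("zero pivot while eliminating node %d.", i))
    }
    p <- parent[i]
    f <- l[i] / d[i]
    d[p] <- d[p] - f * u[i]
    rhs[p] <- rhs[p] - f * rhs[i]
  }
  x <- numeric(n)
  x[1] <- rhs[1] / d[1]
  for (i in seq_len(n)[-1]) x[i] <- (rhs[i] - u[i] * x[parent[i]]) / d[i]
  attr(x, "steps") <- n - 1L
  x
}

#' Dense-matrix form of a Hines system
#'
#' Expands the per-node coefficients into the full n x n matrix, mainly for
#' oracle comparisons against `solve()`.
#'
#' @param system A `hines_system`.
#' @return A dense numeric matrix.
#' @export
hines_dense <- function(system) {
  n <- nrow(system)
  A <- matrix(0, n, n)
  diag(A) <- system$d
  for (i in seq_len(n)[-1]) {
    p <- system$parent[i]
    A[i, p] <- system$u[i]
    A[p, i] <- system$l[i]
  }
  A
}

#' Input and transfer resistance
#'
#' Steady-state voltage deflection (mV) at `site_b` per unit current (nA)
#' injected at `site_a`, i.e. the transfer resistance in MOhm; with
#' `site_a == site_b` this is the input resistance. Computed from one
#' steady-state solve of the passive system. For passive trees the system is
#' symmetric, so `r_ab = r_ba`.
#'
#' @param tree A compartment tree.
#' @param site_a Node index of the injection site.
#' @param site_b Node index of the measurement site (default `site_a`).
#' @return Resistance in MOhm.
#' @examples
#' transfer_resistance(tree_chain(5), 5, 1)
#' input_resistance(tree_chain(5), 1)
#' @export
transfer_resistance <- function(tree, site_a, site_b = site_a) {
  n <- nrow(tree)
  stopifnot(site_a >= 1, site_a <= n, site_b >= 1, site_b <= n)
  i_inj <- numeric(n)
  i_inj[site_a] <- 1
  sys <- assemble_hines(tree, v = 0, i_inj = i_inj, steady = TRUE)
  # measure the deflection from rest: subtract the resting solution, which
  # for a uniform-el passive tree is el itself
  rest <- assemble_hines(tree, v = 0, steady = TRUE)
  as.numeric(solve_hines(sys)[site_b] - solve_hines(rest)[site_b])
}

#' @rdname transfer_resistance
#' @param site Node index.
#' @export
input_resistance <- function(tree, site) {
  transfer_resistance(tree, site, site)
}

#' Transfer resistance from every node to a site
#'
#' Vectorised companion to [transfer_resistance()]: one steady-state solve
#' with unit injection at `site` gives, by reciprocity, the transfer
#' resistance from every node to `site`.
#'
#' @param tree A compartment tree.
#' @param site Node index (typically the soma).
#' @return Numeric vector of length `nrow(tree)`, MOhm.
#' @export
transfer_resistance_to <- function(tree, site = 1L) {
  n <- nrow(tree)
  i_inj <- numeric(n)
  i_inj[site] <- 1
  sys <- assemble_hines(tree, v = 0, i_inj = i_inj, steady = TRUE)
  rest <- assemble_hines(tree, v = 0, steady = TRUE)
  as.numeric(solve_hines(sys) - solve_hines(rest))
}
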