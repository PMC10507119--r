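#' Build an executable schedule from a DHS partition
#'
#' Assigns every scheduled node a `(step, thread)` pair: within each step the
#' subset's nodes are taken in ascending node order and placed on threads
#' 1, 2, ... in that order. Because subset sizes are non-increasing in
#' elimination pressure, thread 1 is active at every step and total node
#' counts per thread are non-increasing in thread id (the alignment used for
#' warp execution). Replaying the schedule step by step reproduces the
#' partition subsets exactly.
#'
#' @param partition A [dhs_partition()].
#' @return An object of class `dhs_schedule`: list with `table` (tibble of
#'   `node`, `step`, `thread`), `k`, `n_steps`.
#' @examples
#' build_schedule(dhs_partition(example_tree(), 4))
#' @export
build_schedule <- function(partition) {
  stopifnot(inherits(partition, "dhs_partition"))
  tab <- purrr::imap_dfr(partition$subsets, function(nodes, step) {
    nodes <- sort(nodes)
    tibble(node = nodes, step = step, thread = seq_along(nodes))
  })
  # re-index threads in descending order of total node count (stable); with
  # slot-order assignment this is already the case, but we normalise anyway
  counts <- tab |>
    dplyr::count(.data$thread, name = "n_nodes") |>
    dplyr::arrange(dplyr::desc(.data$n_nodes), .data$thread)
  remap <- setNames(seq_len(nrow(counts)), counts$thread)
  tab$thread <- as.integer(remap[as.character(tab$thread)])
  structure(
    list(table = tab, k = partition$k,
         n_steps = length(partition$subsets)),
    class = "dhs_schedule"
  )
}

#' @export
print.dhs_schedule <- function(x, ...) {
  cat(sprintf("DHS schedule: %d nodes on %d threads in %d steps\n",
              nrow(x$table), max(x$table$thread), x$n_steps))
  invisible(x)
}

#' Serial-order schedule
#'
#' The degenerate schedule that reproduces the serial Hines elimination
#' exactly: one node per step, in descending node index (child before
#' parent). Executing it is bitwise identical to [solve_hines()].
#'
#' @param n Number of compartments (including the root).
#' @return A `dhs_schedule`.
#' @export
serial_schedule <- function(n) {
  nodes <- rev(seq_len(n)[-1])
  structure(
    list(table = tibble(node = nodes, step = seq_along(nodes), thread = 1L),
         k = 1L, n_steps = n - 1L),
    class = "dhs_schedule"
  )
}

#' Execute a Hines solve under a schedule
#'
#' Simulated-parallel semantics: triangularization proceeds step by step with
#' a barrier between steps; within a step each node's contribution to its
#' parent is accumulated in ascending node order (deterministic regardless of
#' host threading). Back-substitution replays the schedule in reverse. The
#' schedule is checked against the system's dependency tree before any
#' arithmetic: every non-root node must appear exactly once, after all of its
#' children.
#'
#' @param system A `hines_system`.
#' @param schedule A `dhs_schedule` (from [build_schedule()] or
#'   [serial_schedule()]).
#' @return Numeric solution vector with attribute `steps` (parallel step
#'   count).
#' @examples
#' sys <- random_hines(tree_binary(9), seed = 1)
#' sch <- build_schedule(dhs_partition(tree_binary(9), 3))
#' all.equal(execute_schedule(sys, sch), solve_hines(sys),
#'           check.attributes = FALSE)
#' @export
execute_schedule <- function(system, schedule) {
  stopifnot(inherits(schedule, "dhs_schedule"))
  n <- nrow(system)
  tab <- dplyr::arrange(schedule$table, .data$step, .data$node)
  root <- which(is.na(system$parent))
  nonroot <- setdiff(seq_len(n), root)
  if (!setequal(tab$node, nonroot) || nrow(tab) != length(nonroot)) {
    abort("schedule must cover every non-root node exactly once.")
  }
  step_of <- integer(n)
  step_of[tab$node] <- tab$step
  for (i in nonroot) {
    p <- system$parent[i]
    if (!is.na(system$parent[p]) && step_of[p] <= step_of[i]) {
      abort(sprintf(
        "schedule violates the dependency constraint: node %d (step %d) must precede its parent %d (step %d).",
        i, step_of[i], p, step_of[p]
      ))
    }
  }
  d <- system$d; u <- system$u; l <- system$l; rhs <- system$rhs
  parent <- system$parent
  for (i in tab$node) {
    p <- parent[i]
    f <- l[i] / d[i]
    d[p] <- d[p] - f * u[i]
    rhs[p] <- rhs[p] - f * rhs[i]
  }
  x <- numeric(n)
  x[root] <- rhs[root] / d[root]
  for (i in rev(tab$node)) x[i] <- (rhs[i] - u[i] * x[parent[i]]) / d[i]
  attr(x, "steps") <- schedule$n_steps
  x
}

#' Group cells into warps
#'
#' Packs cells into groups of lockstep threads ("warps") such that one cell's
#' k threads never straddle a warp boundary. Cells are sorted by
#' (non-root node count, canonical topology signature) so that similar
#' morphologies share warps, then packed greedily, `floor(warp_size / k)`
#' cells per warp.
#'
#' @param cells A list of compartment trees.
#' @param k Threads per cell.
#' @param warp_size Threads per warp (default 32).
#' @return A tibble with one row per cell: `cell`, `n_nodes`, `signature`,
#'   `warp`.
#' @examples
#' group_warps(rep(list(tree_binary(15)), 9), k = 4)
#' @export
group_warps <- function(cells, k, warp_size = 32L) {
  if (k > warp_size) {
    abort("`k` threads per cell cannot exceed the warp size.")
  }
  info <- tibble(
    cell = seq_along(cells),
    n_nodes = vapply(cells, function(tr) nrow(tr) - 1L, 1L),
    signature = vapply(cells, canonical_topology, "")
  )
  info <- dplyr::arrange(info, .data$n_nodes, .data$signature, .data$cell)
  per_warp <- max(1L, warp_size %/% as.integer(k))
  info$warp <- as.integer((seq_len(nrow(info)) - 1L) %/% per_warp + 1L)
  info
}

#' Permute memory layout to the computing order
#'
#' Builds the bijective storage permutation that places nodes processed at
#' the same step contiguously, ordered by thread id within the step (the
#' root occupies slot 1). Executing on permuted storage and un-permuting
#' yields the identical solution.
#'
#' @param schedule A `dhs_schedule`.
#' @param n Number of compartments (including root); defaults to the number
#'   of scheduled nodes + 1.
#' @return An object of class `memory_layout`: tibble with `node` and `slot`.
#' @examples
#' permute_layout(build_schedule(dhs_partition(example_tree(), 4)))
#' @export
permute_layout <- function(schedule, n = nrow(schedule$table) + 1L) {
  tab <- dplyr::arrange(schedule$table, .data$step, .data$thread)
  scheduled <- tab$node
  rest <- setdiff(seq_len(n), c(1L, scheduled))
  out <- tibble(
    node = c(1L, scheduled, rest),
    slot = seq_len(n)
  )
  class(out) <- unique(c("memory_layout", class(out)))
  out
}

#' Apply and invert a memory layout on a Hines system
#'
#' `apply_layout()` reorders the per-node arrays of a system into storage
#' order (remapping parent indices); `unapply_layout()` maps a solution
#' computed in storage order back to node order.
#'
#' @param system A `hines_system`.
#' @param layout A `memory_layout`.
#' @param x A solution vector in storage order.
#' @return `apply_layout()`: a `hines_system` in storage order plus a
#'   remapped copy of any schedule via its `slot_of` attribute;
#'   `unapply_layout()`: the solution in node order.
#' @export
apply_layout <- function(system, layout) {
  n <- nrow(system)
  slot_of <- integer(n)
  slot_of[layout$node] <- layout$slot
  ord <- order(slot_of)
  out <- system[ord, ]
  out$parent <- ifelse(is.na(out$parent), NA_integer_,
                       slot_of[out$parent])
  out$node <- seq_len(n)
  attr(out, "slot_of") <- slot_of
  out
}

#' @rdname apply_layout
#' @export
unapply_layout <- function(x, layout) {
  n <- length(x)
  slot_of <- integer(n)
  slot_of[layout$node] <- layout$slot
  out <- numeric(n)
  out <- x[slot_of]
  out
}
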