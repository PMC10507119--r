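#' Dendritic hierarchical scheduling (DHS)
#'
#' Partitions the non-root compartments of a tree into ordered subsets
#' `V_1, ..., V_n` for `k` parallel threads: at each step the candidate set Q
#' holds every unprocessed node whose children have all been processed
#' (initially the leaves); if `|Q| <= k` the whole of Q is taken, otherwise
#' the k deepest candidates (ties broken by ascending node index). The
#' resulting partition respects the triangularization dependency (children
#' always in earlier subsets), every subset's depth sum equals the depth sum
#' of the `min(k, |Q|)` deepest candidates at that step (the max-depth
#' property), and the number of subsets is the global minimum number of
#' parallel steps.
#'
#' @param tree A compartment tree.
#' @param k Number of threads (>= 1).
#' @return An object of class `dhs_partition`: a list with `subsets` (list of
#'   integer node vectors in selection order), `k`, `n_nodes` (non-root
#'   count), `depth` (per-node depths incl. root), and `depth_sums` (the
#'   depth sum of each subset). Methods:
#'   [tidy()], [glance()], [autoplot()], `print()`.
#' @examples
#' p <- dhs_partition(example_tree(), k = 4)
#' p
#' glance(p)
#' @export
dhs_partition <- function(tree, k) {
  if (!is.numeric(k) || length(k) != 1 || k < 1) {
    abort("`k` must be a positive integer thread count.")
  }
  k <- as.integer(k)
  n <- nrow(tree)
  parent <- tree$parent
  depth <- depth_vector(parent)
  pending <- integer(n) # unprocessed children per node
  for (i in seq_len(n)[-1]) pending[parent[i]] <- pending[parent[i]] + 1L
  in_q <- which(pending == 0L & seq_len(n) > 1L)

  subsets <- list()
  depth_sums <- numeric(0)
  while (length(in_q) > 0) {
    ord <- in_q[order(-depth[in_q], in_q)]
    take <- utils::head(ord, k)
    subsets[[length(subsets) + 1L]] <- take
    depth_sums <- c(depth_sums, sum(depth[take]))
    in_q <- setdiff(in_q, take)
    for (v in take) {
      p <- parent[v]
      pending[p] <- pending[p] - 1L
      if (pending[p] == 0L && p != 1L) in_q <- c(in_q, p)
    }
  }
  structure(
    list(subsets = subsets, k = k, n_nodes = n - 1L, depth = depth,
         depth_sums = depth_sums),
    class = "dhs_partition"
  )
}

#' @export
print.dhs_partition <- function(x, ...) {
  cat(sprintf(
    "DHS partition: %d non-root nodes, k = %d -> %d steps (serial: %d)\n",
    x$n_nodes, x$k, length(x$subsets), x$n_nodes
  ))
  sizes <- vapply(x$subsets, length, 1L)
  cat("subset sizes:", paste(sizes, collapse = ", "), "\n")
  invisible(x)
}

#' Exhaustive minimum-step oracle
#'
#' Exact minimum number of parallel steps over *all* dependency-respecting
#' partitions with subsets of size at most `k`, found by breadth-first search
#' over processed-node sets (bitmask states). Exponential: restricted to
#' trees with at most 14 non-root nodes. Serves as the optimality oracle for
#' [dhs_partition()].
#'
#' @inheritParams dhs_partition
#' @return Integer minimum step count.
#' @examples
#' min_steps_exhaustive(tree_star(7), k = 4)
#' @export
min_steps_exhaustive <- function(tree, k) {
  if (!is.numeric(k) || k < 1) abort("`k` must be a positive integer.")
  n <- nrow(tree)
  if (n - 1L > 14L) {
    abort("exhaustive search is limited to trees with <= 14 non-root nodes.")
  }
  if (n == 1L) return(0L)
  bf_min_steps_cpp(as.integer(tree$parent[-1]) - 1L, as.integer(k))
}

#' Relative computational cost of a DHS schedule
#'
#' Ratio of DHS parallel steps to serial steps, `|P(V)| / |V|`, for the
#' triangularization phase; back-substitution is its mirror image, so the
#' ratio is unchanged by counting both phases.
#'
#' @inheritParams dhs_partition
#' @return A fraction in (0, 1].
#' @examples
#' relative_cost(tree_chain(10), k = 4) # 1: a chain cannot be parallelised
#' relative_cost(tree_star(17), k = 16)
#' @export
relative_cost <- function(tree, k) {
  p <- dhs_partition(tree, k)
  length(p$subsets) / p$n_nodes
}

#' @describeIn dhs_partition Per-node tidy view: one row per scheduled node
#'   with its step, within-step slot and depth.
#' @param x A `dhs_partition`.
#' @param ... Unused.
#' @export
tidy.dhs_partition <- function(x, ...) {
  purrr::imap_dfr(x$subsets, function(nodes, step) {
    tibble(step = step, slot = seq_along(nodes), node = nodes,
           depth = x$depth[nodes])
  })
}

#' @describeIn dhs_partition One-row summary: thread count, steps, serial
#'   steps and relative cost.
#' @export
glance.dhs_partition <- function(x, ...) {
  tibble(
    k = x$k, steps = length(x$subsets), n_nodes = x$n_nodes,
    serial_steps = x$n_nodes,
    relative_cost = length(x$subsets) / x$n_nodes,
    max_subset = max(vapply(x$subsets, length, 1L))
  )
}
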