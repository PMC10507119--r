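#' Compartment trees
#'
#' A compartment tree is the central container of dendrosched: a tibble with
#' one row per electrical compartment and columns
#' \describe{
#'   \item{node}{integer index, 1..n; the root (soma) is node 1 and every
#'     parent index is smaller than its children (topological order)}
#'   \item{parent}{integer index of the parent compartment, `NA` for the root}
#'   \item{kind}{one of `"soma"`, `"dend"`, `"axon"`, `"spine_neck"`,
#'     `"spine_head"`}
#'   \item{length, diam}{cylinder length and diameter, micrometres}
#'   \item{cm}{specific membrane capacitance, uF/cm^2}
#'   \item{rm}{specific membrane resistance, Ohm cm^2}
#'   \item{ra}{axial resistivity, Ohm cm}
#'   \item{el}{leak reversal potential, mV}
#'   \item{path_dist}{path distance from the soma centre to the compartment
#'     midpoint, micrometres (0 at the root)}
#' }
#'
#' `as_compartment_tree()` validates a data frame against this contract and
#' recomputes `path_dist`; `new_compartment_tree()` builds one from a parent
#' vector plus geometry, filling passive parameters from defaults.
#'
#' @param x A data frame with at least `node`, `parent`, `kind`, `length`,
#'   `diam`, `cm`, `rm`, `ra`, `el` columns.
#' @param parent Integer vector of parent indices (`NA` for the root, which
#'   must be element 1); parents must precede children.
#' @param length,diam Compartment geometry in micrometres (recycled).
#' @param kind Compartment kinds (recycled; default soma root + dendrites).
#' @param cm,rm,ra,el Passive parameters (recycled).
#' @return A tibble of class `compartment_tree`.
#' @examples
#' tr <- new_compartment_tree(parent = c(NA, 1, 2, 2))
#' tr
#' @export
new_compartment_tree <- function(parent,
                                 length = 20, diam = 1,
                                 kind = NULL,
                                 cm = 1, rm = 1e4, ra = 100, el = -65) {
  n <- base::length(parent)
  if (n < 1 || !is.na(parent[1])) {
    abort("`parent` must start with the root (NA parent).")
  }
  if (is.null(kind)) kind <- c("soma", rep("dend", n - 1))
  tr <- tibble(
    node   = seq_len(n),
    parent = as.integer(parent),
    kind   = rep_len(kind, n),
    length = rep_len(as.numeric(length), n),
    diam   = rep_len(as.numeric(diam), n),
    cm     = rep_len(as.numeric(cm), n),
    rm     = rep_len(as.numeric(rm), n),
    ra     = rep_len(as.numeric(ra), n),
    el     = rep_len(as.numeric(el), n)
  )
  as_compartment_tree(tr)
}

#' @rdname new_compartment_tree
#' @export
as_compartment_tree <- function(x) {
  need <- c("node", "parent", "kind", "length", "diam", "cm", "rm", "ra", "el")
  missing_cols <- setdiff(need, names(x))
  if (base::length(missing_cols) > 0) {
    abort(paste0(
      "compartment tree is missing column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  x <- as_tibble(x)
  n <- nrow(x)
  if (!identical(as.integer(x$node), seq_len(n))) {
    abort("`node` must be 1..n in order.")
  }
  if (sum(is.na(x$parent)) != 1L || !is.na(x$parent[1])) {
    abort("exactly one root (node 1) with `parent = NA` is required.")
  }
  p <- x$parent[-1]
  if (any(p < 1 | p >= x$node[-1])) {
    abort("every parent index must refer to an earlier node (topological order).")
  }
  bad <- !x$kind %in% c("soma", "dend", "axon", "spine_neck", "spine_head")
  if (any(bad)) abort("unknown compartment kind(s).")
  num <- c("length", "diam", "cm", "rm", "ra")
  for (col in num) {
    v <- x[[col]]
    if (any(!is.finite(v)) || any(v <= 0)) {
      abort(paste0("`", col, "` must be finite and positive."))
    }
  }
  if (any(!is.finite(x$el))) abort("`el` must be finite.")
  x$path_dist <- tree_path_dist(x$parent, x$length)
  class(x) <- unique(c("compartment_tree", class(x)))
  x
}

# midpoint-to-midpoint path distance from the soma centre; root = 0.
# The soma midpoint is the soma centre, so a child of the root sits at half
# its own length; deeper nodes add half of each of the two lengths crossed.
tree_path_dist <- function(parent, length) {
  n <- base::length(parent)
  pd <- numeric(n)
  for (i in seq_len(n)[-1]) {
    p <- parent[i]
    pd[i] <- if (p == 1L) length[i] / 2 else pd[p] + (length[p] + length[i]) / 2
  }
  pd
}

#' Node depths of a compartment tree
#'
#' The depth of a node is its number of ancestors: 0 at the root and
#' `depth(parent) + 1` elsewhere. Depth drives the scheduler's
#' deepest-candidate-first rule.
#'
#' @param tree A compartment tree (or any tibble with `node`/`parent`).
#' @return A tibble with columns `node` and `depth`.
#' @examples
#' node_depths(tree_chain(4))
#' @export
node_depths <- function(tree) {
  tibble(node = tree$node, depth = depth_vector(tree$parent))
}

depth_vector <- function(parent) {
  n <- base::length(parent)
  d <- integer(n)
  for (i in seq_len(n)[-1]) d[i] <- d[parent[i]] + 1L
  d
}

children_list <- function(parent) {
  n <- base::length(parent)
  kids <- vector("list", n)
  for (i in seq_len(n)[-1]) kids[[parent[i]]] <- c(kids[[parent[i]]], i)
  kids
}

#' Membrane areas and total neurite length
#'
#' Compartments are cylinders; the membrane area of compartment i is
#' `pi * diam * length` (sealed-end caps excluded). Used for area bookkeeping
#' across segmentation policies and for specific-to-absolute parameter
#' conversion.
#'
#' @param tree A compartment tree.
#' @return `membrane_area()`: numeric vector of areas in um^2;
#'   `total_length()`: total length in um over non-soma compartments.
#' @export
membrane_area <- function(tree) {
  pi * tree$diam * tree$length
}

#' @rdname membrane_area
#' @export
total_length <- function(tree) {
  sum(tree$length[tree$kind != "soma"])
}

# canonical topology string: invariant to child order and node labelling
canonical_topology <- function(tree) {
  kids <- children_list(tree$parent)
  rec <- function(i) {
    if (base::length(kids[[i]]) == 0) return("()")
    paste0("(", paste(sort(vapply(kids[[i]], rec, "")), collapse = ""), ")")
  }
  rec(1L)
}

#' @export
print.compartment_tree <- function(x, ...) {
  n_spine <- sum(x$kind %in% c("spine_neck", "spine_head"))
  cat(sprintf(
    "# A compartment tree: %d compartments (%d spine), max depth %d\n",
    nrow(x), n_spine, max(depth_vector(x$parent))
  ))
  NextMethod()
}
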