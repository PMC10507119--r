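#' Canonical tree fixtures
#'
#' Deterministic tree shapes used throughout tests and examples: a chain
#' (full serial dependency), a star (no dependencies among leaves), and a
#' heap-ordered binary tree.
#'
#' @param n Total number of compartments including the root.
#' @param ... Passed to [new_compartment_tree()] (geometry, passive params).
#' @return A compartment tree.
#' @examples
#' tree_chain(5)
#' tree_star(7)
#' @export
tree_chain <- function(n, ...) {
  stopifnot(n >= 2)
  new_compartment_tree(parent = c(NA, seq_len(n - 1)), ...)
}

#' @rdname tree_chain
#' @export
tree_star <- function(n, ...) {
  stopifnot(n >= 2)
  new_compartment_tree(parent = c(NA, rep(1L, n - 1)), ...)
}

#' @rdname tree_chain
#' @export
tree_binary <- function(n, ...) {
  stopifnot(n >= 2)
  new_compartment_tree(parent = c(NA, (2:n) %/% 2L), ...)
}

#' Random rooted trees
#'
#' Draws a rooted tree on `n` nodes. Under the `"uniform"` model each node's
#' parent is drawn uniformly from all earlier nodes, so every labelled rooted
#' tree with this topological labelling has positive probability; `"binary"`,
#' `"chain"` and `"star"` return the corresponding deterministic shapes.
#'
#' @param n Number of compartments (>= 2).
#' @param model One of `"uniform"`, `"binary"`, `"chain"`, `"star"`.
#' @param seed Integer seed; generation is a pure function of `(n, model, seed)`.
#' @param ... Passed to [new_compartment_tree()].
#' @return A compartment tree.
#' @examples
#' random_tree(8, seed = 1)
#' @export
random_tree <- function(n, model = c("uniform", "binary", "chain", "star"),
                        seed = 1L, ...) {
  model <- match.arg(model)
  if (n < 2) abort("`n` must be at least 2.")
  switch(model,
    chain  = tree_chain(n, ...),
    star   = tree_star(n, ...),
    binary = tree_binary(n, ...),
    uniform = {
      parent <- c(NA, withr_seed(seed, {
        vapply(2:n, function(i) sample.int(i - 1L, 1L), 1L)
      }))
      new_compartment_tree(parent = parent, ...)
    }
  )
}

# run code under a local RNG seed without disturbing the global stream
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# figure labels (0 = soma) of the 15-compartment worked example, in
# topological order, with their parents in the same labelling
example15_labels <- function() {
  list(
    label  = c(0L, 5L, 2L, 3L, 6L, 1L, 4L, 7L, 8L, 9L, 10L, 11L, 13L, 12L, 14L),
    parent = c(NA, 0L, 5L, 5L, 5L, 2L, 6L, 3L, 6L, 1L, 7L, 4L, 8L, 11L, 13L)
  )
}

#' The 15-compartment worked-example tree
#'
#' A small demonstration morphology of 15 compartments (soma + 14) whose
#' dependency tree makes the scheduler's behaviour easy to inspect: serial
#' elimination takes 14 steps, while the deepest-candidate-first schedule
#' with k = 4 threads needs only 5 steps, with subsets of sizes 4, 4, 4, 1, 1.
#' The extra `label` column carries the conventional display labels
#' (0 at the soma); `node` is the package's topological index.
#'
#' @param ... Passed to [new_compartment_tree()].
#' @return A compartment tree with 15 rows and a `label` column.
#' @examples
#' tr <- example_tree()
#' dhs_partition(tr, k = 4)
#' @export
example_tree <- function(...) {
  ex <- example15_labels()
  node_of_label <- setNames(seq_along(ex$label), ex$label)
  parent <- c(NA, unname(node_of_label[as.character(ex$parent[-1])]))
  tr <- new_compartment_tree(parent = as.integer(parent), ...)
  tr$label <- ex$label
  tr
}

#' Random diagonally dominant Hines systems
#'
#' Draws coupling coefficients and a right-hand side on a given tree such
#' that the matrix is strictly diagonally dominant (no pivoting ever needed):
#' `d_i` exceeds the absolute row sum by at least `margin`.
#'
#' @param tree A compartment tree giving the topology.
#' @param seed Integer seed.
#' @param margin Strict dominance margin (> 0).
#' @return A `hines_system` tibble (see [assemble_hines()]).
#' @examples
#' random_hines(tree_binary(7), seed = 2)
#' @export
random_hines <- function(tree, seed = 1L, margin = 0.5) {
  if (!is.numeric(margin) || margin <= 0) {
    abort("`margin` must be a positive number.")
  }
  n <- nrow(tree)
  parent <- tree$parent
  withr_seed(seed, {
    u <- c(0, -runif(n - 1, 0.1, 1)) # coupling to parent (row i, col p)
    l <- c(0, -runif(n - 1, 0.1, 1)) # coupling from child (row p, col i)
    rowsum <- abs(u)
    for (i in seq_len(n)[-1]) rowsum[parent[i]] <- rowsum[parent[i]] + abs(l[i])
    d <- rowsum + margin + runif(n, 0, 0.5)
    rhs <- runif(n, -1, 1)
  })
  new_hines_system(parent, d, u, l, rhs)
}

#' Synthetic labelled toy images
#'
#' Small grayscale images for the toy classification task: images of class k
#' have a bright vertical band in the k-th of `classes` column blocks, on top
#' of uniform pixel noise in `[0, noise]`. All pixels lie in \[0, 1\]. This
#' generator stands in for full-scale image datasets at desk scale.
#'
#' @param n_per_class Images per class.
#' @param size Image side length in pixels (>= 2).
#' @param classes Number of classes (<= `size`).
#' @param noise Amplitude of the uniform background noise (default 0.2).
#' @param seed Integer seed.
#' @return A tibble with columns `id`, `label` (0-based class), and `pixels`
#'   (list-column of `size` x `size` matrices).
#' @examples
#' toy_images(2, size = 4, classes = 2, seed = 1)
#' @export
toy_images <- function(n_per_class, size = 4, classes = 2, noise = 0.2,
                       seed = 1L) {
  if (size < 2) abort("`size` must be at least 2.")
  stopifnot(classes >= 2, classes <= size, noise >= 0, noise <= 0.2)
  block <- floor(size / classes)
  withr_seed(seed, {
    rows <- purrr::map(seq_len(classes * n_per_class) - 1L, function(idx) {
      k <- idx %% classes
      img <- matrix(runif(size * size, 0, noise), size, size)
      cols <- (k * block + 1L):(min((k + 1L) * block, size))
      img[, cols] <- img[, cols] + 0.8
      list(label = k, pixels = pmin(img, 1))
    })
  })
  tibble(
    id = seq_along(rows),
    label = vapply(rows, function(r) as.integer(r$label), 1L),
    pixels = purrr::map(rows, "pixels")
  )
}

#' Synthetic pyramidal-like test morphology
#'
#' A deterministic branched passive morphology used by the shipped
#' excitability experiments: a soma bearing `n_primary` primary dendrites
#' that each bifurcate into two daughters, discretised into
#' `seg_len`-micrometre compartments. It is a synthetic stand-in morphology,
#' not a reconstruction.
#'
#' @param n_primary Number of primary dendrites.
#' @param primary_len,daughter_len Section lengths, um.
#' @param primary_diam,daughter_diam Section diameters, um.
#' @param soma_diam Soma length = diameter, um.
#' @param seg_len Compartment length, um.
#' @param ... Passive parameters passed to [new_compartment_tree()]
#'   (defaults here follow a passive human pyramidal parameter set:
#'   cm 0.44 uF/cm^2, rm 48300 Ohm cm^2, ra 261.97 Ohm cm, el -83.1 mV).
#' @return A compartment tree.
#' @export
synthetic_pyramidal <- function(n_primary = 3, primary_len = 60,
                                daughter_len = 90, primary_diam = 2,
                                daughter_diam = 1, soma_diam = 20,
                                seg_len = 10,
                                cm = 0.44, rm = 48300, ra = 261.97,
                                el = -83.1, ...) {
  parent <- NA_integer_
  length <- soma_diam
  diam <- soma_diam
  kind <- "soma"
  add_section <- function(from, sec_len, sec_diam) {
    nseg <- max(1L, ceiling(sec_len / seg_len))
    l <- sec_len / nseg
    idx <- integer(nseg)
    for (s in seq_len(nseg)) {
      parent <<- c(parent, from)
      length <<- c(length, l)
      diam <<- c(diam, sec_diam)
      kind <<- c(kind, "dend")
      from <- base::length(parent)
      idx[s] <- from
    }
    from
  }
  for (b in seq_len(n_primary)) {
    tip <- add_section(1L, primary_len, primary_diam)
    add_section(tip, daughter_len, daughter_diam)
    add_section(tip, daughter_len, daughter_diam)
  }
  new_compartment_tree(parent = parent, length = length, diam = diam,
                       kind = kind, cm = cm, rm = rm, ra = ra, el = el, ...)
}
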