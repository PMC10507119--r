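#' Read and write SWC morphology files
#'
#' Standard 7-column SWC: `id type x y z radius parent`, `#` comments, and
#' parent `-1` marking the root. `read_swc()` validates the file (unique ids,
#' resolvable parents, positive radii, no cycles) and returns the point table;
#' `write_swc()` is its inverse, round-tripping up to float formatting.
#'
#' @param path Path to an SWC file.
#' @param morph A morphology point table as returned by `read_swc()`:
#'   a tibble with columns `id`, `type`, `x`, `y`, `z`, `radius`, `parent`.
#' @return `read_swc()`: a tibble of class `swc_morphology` with the seven
#'   SWC columns; `write_swc()`: the path, invisibly.
#' @examples
#' f <- tempfile(fileext = ".swc")
#' writeLines(c("# stick", "1 1 0 0 0 5 -1", "2 3 20 0 0 1 1",
#'              "3 3 40 0 0 1 2"), f)
#' read_swc(f)
#' @export
read_swc <- function(path) {
  if (!file.exists(path)) abort(paste0("SWC file not found: ", path))
  raw <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", raw))
  if (base::length(keep) == 0) abort("SWC file contains no data lines.")
  fields <- strsplit(trimws(raw[keep]), "\\s+")
  bad <- which(vapply(fields, base::length, 1L) != 7L)
  if (base::length(bad) > 0) {
    abort(sprintf("SWC parse error: line %d does not have 7 columns.",
                  keep[bad[1]]))
  }
  m <- suppressWarnings(
    matrix(as.numeric(unlist(fields)), ncol = 7, byrow = TRUE)
  )
  nonnum <- which(rowSums(is.na(m)) > 0)
  if (base::length(nonnum) > 0) {
    abort(sprintf("SWC parse error: non-numeric field on line %d.",
                  keep[nonnum[1]]))
  }
  morph <- tibble(
    id = as.integer(m[, 1]), type = as.integer(m[, 2]),
    x = m[, 3], y = m[, 4], z = m[, 5], radius = m[, 6],
    parent = as.integer(m[, 7])
  )
  validate_swc(morph, lines = keep)
  class(morph) <- unique(c("swc_morphology", class(morph)))
  morph
}

validate_swc <- function(morph, lines = seq_len(nrow(morph))) {
  if (anyDuplicated(morph$id)) {
    dup <- which(duplicated(morph$id))[1]
    abort(sprintf("SWC parse error: duplicate id %d on line %d.",
                  morph$id[dup], lines[dup]))
  }
  if (any(morph$radius <= 0)) {
    bad <- which(morph$radius <= 0)[1]
    abort(sprintf("SWC parse error: non-positive radius on line %d.",
                  lines[bad]))
  }
  roots <- which(morph$parent == -1L)
  if (base::length(roots) == 0) abort("SWC parse error: no root point (parent -1).")
  nonroot <- which(morph$parent != -1L)
  missing <- nonroot[!(morph$parent[nonroot] %in% morph$id)]
  if (base::length(missing) > 0) {
    abort(sprintf(
      "SWC parse error: line %d references missing parent id %d.",
      lines[missing[1]], morph$parent[missing[1]]
    ))
  }
  # cycle check: walk each point to the root, bounded by n steps
  idx_of <- setNames(seq_len(nrow(morph)), morph$id)
  for (i in seq_len(nrow(morph))) {
    cur <- i
    for (step in seq_len(nrow(morph) + 1L)) {
      p <- morph$parent[cur]
      if (p == -1L) break
      cur <- idx_of[[as.character(p)]]
      if (step > nrow(morph)) break
    }
    if (morph$parent[cur] != -1L) {
      abort(sprintf("SWC parse error: cyclic parent reference at id %d (line %d).",
                    morph$id[i], lines[i]))
    }
  }
  invisible(morph)
}

#' @rdname read_swc
#' @export
write_swc <- function(morph, path) {
  need <- c("id", "type", "x", "y", "z", "radius", "parent")
  stopifnot(all(need %in% names(morph)))
  lines <- sprintf(
    "%d %d %.6g %.6g %.6g %.6g %d",
    morph$id, morph$type, morph$x, morph$y, morph$z, morph$radius, morph$parent
  )
  writeLines(c("# SWC written by dendrosched", lines), path)
  invisible(path)
}

#' Discretise an SWC morphology into a compartment tree
#'
#' Each inter-point SWC section becomes one or more cylindrical compartments:
#' under the `"per_section"` policy a fixed count per section (default 1),
#' under `"max_length"` as many equal pieces as needed so none exceeds
#' `max_length` micrometres. Branch-point topology is preserved and total
#' neurite length is conserved exactly. The root compartment is the soma
#' point, modelled as a cylinder with length = diameter = 2 x radius.
#'
#' @param morph An `swc_morphology` tibble from [read_swc()].
#' @param policy `"per_section"` or `"max_length"`.
#' @param n_per_section Compartments per SWC section (policy `"per_section"`).
#' @param max_length Maximum compartment length in um (policy `"max_length"`).
#' @param cm,rm,ra,el Passive parameters applied to every compartment.
#' @return A compartment tree; column `swc_id` holds the id of the distal SWC
#'   point each compartment was cut from.
#' @examples
#' f <- tempfile(fileext = ".swc")
#' writeLines(c("1 1 0 0 0 5 -1", "2 3 100 0 0 1 1"), f)
#' segment_morphology(read_swc(f), policy = "max_length", max_length = 10)
#' @export
segment_morphology <- function(morph, policy = c("per_section", "max_length"),
                               n_per_section = 1L, max_length = NULL,
                               cm = 1, rm = 1e4, ra = 100, el = -65) {
  policy <- match.arg(policy)
  if (policy == "per_section" &&
      (!is.numeric(n_per_section) || n_per_section < 1)) {
    abort("`n_per_section` must be a positive integer.")
  }
  if (policy == "max_length" &&
      (is.null(max_length) || !is.numeric(max_length) || max_length <= 0)) {
    abort("`max_length` must be a positive length in micrometres.")
  }
  roots <- which(morph$parent == -1L)
  soma_candidates <- roots[morph$type[roots] == 1L]
  root_row <- if (base::length(soma_candidates) > 0) soma_candidates[1] else roots[1]

  idx_of <- setNames(seq_len(nrow(morph)), morph$id)
  # BFS from the root in ascending-id order: stable topological ordering
  kids_of <- split(seq_len(nrow(morph)),
                   factor(morph$parent, levels = morph$id))
  order_rows <- integer(0)
  queue <- root_row
  while (base::length(queue) > 0) {
    cur <- queue[1]
    queue <- queue[-1]
    order_rows <- c(order_rows, cur)
    kids <- kids_of[[as.character(morph$id[cur])]]
    if (!is.null(kids)) queue <- c(queue, kids[order(morph$id[kids])])
  }
  if (base::length(order_rows) < nrow(morph)) {
    abort("SWC morphology has points unreachable from the root.")
  }

  parent <- NA_integer_
  length <- 2 * morph$radius[root_row]
  diam <- 2 * morph$radius[root_row]
  kind <- "soma"
  swc_id <- morph$id[root_row]
  comp_of_point <- integer(nrow(morph))
  comp_of_point[root_row] <- 1L

  for (row in order_rows[-1]) {
    prow <- idx_of[[as.character(morph$parent[row])]]
    sec_len <- sqrt(
      (morph$x[row] - morph$x[prow])^2 +
      (morph$y[row] - morph$y[prow])^2 +
      (morph$z[row] - morph$z[prow])^2
    )
    if (sec_len <= 0) {
      abort(sprintf("zero-length SWC section ending at id %d.", morph$id[row]))
    }
    nseg <- if (policy == "per_section") as.integer(n_per_section)
            else as.integer(ceiling(sec_len / max_length))
    from <- comp_of_point[prow]
    for (s in seq_len(nseg)) {
      parent <- c(parent, from)
      length <- c(length, sec_len / nseg)
      diam <- c(diam, 2 * morph$radius[row])
      kind <- c(kind, swc_kind(morph$type[row]))
      swc_id <- c(swc_id, morph$id[row])
      from <- base::length(parent)
    }
    comp_of_point[row] <- from
  }
  tr <- new_compartment_tree(parent = parent, length = length, diam = diam,
                             kind = kind, cm = cm, rm = rm, ra = ra, el = el)
  tr$swc_id <- swc_id
  tr
}

swc_kind <- function(type) {
  if (type == 1L) "soma" else if (type == 2L) "axon" else "dend"
}

#' Export a compartment tree back to an SWC point table
#'
#' One SWC point per compartment, laid out along the x axis by path distance
#' (synthetic coordinates; only topology, radii and inter-point distances are
#' meaningful).
#'
#' @param tree A compartment tree.
#' @return An `swc_morphology` tibble.
#' @export
tree_to_swc <- function(tree) {
  n <- nrow(tree)
  x <- numeric(n); y <- numeric(n)
  for (i in seq_len(n)[-1]) {
    p <- tree$parent[i]
    # place each child at exactly its segment length from the parent so that
    # re-segmenting the written file conserves compartment lengths
    x[i] <- x[p] + tree$length[i]
  }
  morph <- tibble(
    id = tree$node,
    type = ifelse(tree$kind == "soma", 1L,
           ifelse(tree$kind == "axon", 2L, 3L)),
    x = x, y = y, z = 0,
    radius = tree$diam / 2,
    parent = ifelse(is.na(tree$parent), -1L, tree$parent)
  )
  class(morph) <- unique(c("swc_morphology", class(morph)))
  morph
}
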