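#' Dendritic spine specification
#'
#' Geometry and membrane parameters of a two-compartment spine (neck then
#' head) together with the density rule and the F_spine membrane-scaling
#' factor used when spines are folded into the dendritic membrane instead of
#' being modelled explicitly. Defaults follow a passive human pyramidal
#' parameter set: density 1.3 spines per micrometre on dendrites more than
#' 60 um (path distance) from the soma; neck 1.35 x 0.25 um; head area
#' 2.8 um^2 modelled as a cylinder with length = diameter = 0.944 um
#' (sealed-end caps excluded, so area = pi * 0.944 * 0.944 ~ 2.8 um^2);
#' spine leak reversal -86 mV; F_spine 1.9.
#'
#' @param density Spines per micrometre of eligible dendrite (>= 0).
#' @param distance_threshold Path distance (um) beyond which dendrites carry
#'   spines.
#' @param fspine Membrane scaling factor (>= 1).
#' @param neck_length,neck_diam Spine neck cylinder, um.
#' @param head_length,head_diam Spine head cylinder, um.
#' @param el_spine Spine leak reversal potential, mV.
#' @return A list of class `spine_spec`.
#' @examples
#' spine_spec()
#' @export
spine_spec <- function(density = 1.3, distance_threshold = 60, fspine = 1.9,
                       neck_length = 1.35, neck_diam = 0.25,
                       head_length = 0.944, head_diam = 0.944,
                       el_spine = -86) {
  if (!is.numeric(density) || density < 0) {
    abort("`density` must be non-negative.")
  }
  if (fspine < 1) abort("`fspine` must be >= 1.")
  stopifnot(distance_threshold >= 0, neck_length > 0, neck_diam > 0,
            head_length > 0, head_diam > 0)
  structure(
    list(density = density, distance_threshold = distance_threshold,
         fspine = fspine, neck_length = neck_length, neck_diam = neck_diam,
         head_length = head_length, head_diam = head_diam,
         el_spine = el_spine),
    class = "spine_spec"
  )
}

#' Attach explicit dendritic spines
#'
#' Appends `round(density * length)` two-compartment spines (neck, then head
#' as its child) to every dendritic compartment whose midpoint path distance
#' exceeds the threshold. Spine positions along the host compartment are
#' drawn uniformly (they only matter for bookkeeping: electrically a spine
#' couples to its whole host compartment). Original compartments are left
#' untouched; membrane capacitance/resistivity/axial resistivity of spines
#' equal the host dendrite values, with the spine leak reversal from `spec`.
#'
#' @param tree A compartment tree.
#' @param spec A [spine_spec()].
#' @param seed Integer seed; placement is reproducible.
#' @return A compartment tree with `2 * n_spines` appended compartments; the
#'   attribute `n_spines` records the spine count.
#' @examples
#' tr <- attach_spines(synthetic_pyramidal(), spine_spec(), seed = 1)
#' attr(tr, "n_spines")
#' @export
attach_spines <- function(tree, spec = spine_spec(), seed = 1L) {
  stopifnot(inherits(spec, "spine_spec"))
  eligible <- which(tree$kind == "dend" &
                    tree$path_dist > spec$distance_threshold)
  counts <- round(spec$density * tree$length[eligible])
  hosts <- rep(eligible, counts)
  n_spines <- base::length(hosts)
  if (n_spines == 0) return(tree)

  n0 <- nrow(tree)
  positions <- withr_seed(seed, runif(n_spines)) # fractional position on host
  neck_idx <- n0 + 2L * seq_len(n_spines) - 1L
  new_rows <- tibble(
    node = as.integer(rbind(neck_idx, neck_idx + 1L)),
    parent = as.integer(rbind(hosts, neck_idx)),
    kind = rep(c("spine_neck", "spine_head"), n_spines),
    length = rep(c(spec$neck_length, spec$head_length), n_spines),
    diam = rep(c(spec$neck_diam, spec$head_diam), n_spines),
    cm = rep(tree$cm[hosts], each = 2),
    rm = rep(tree$rm[hosts], each = 2),
    ra = rep(tree$ra[hosts], each = 2),
    el = spec$el_spine
  )
  out <- dplyr::bind_rows(tree[, names(new_rows)], new_rows)
  out <- as_compartment_tree(out)
  out$spine_pos <- c(rep(NA_real_, n0), rep(positions, each = 2))
  attr(out, "n_spines") <- n_spines
  out
}

#' Fold spine membrane into the dendrite (F_spine scaling)
#'
#' The membrane-scaling alternative to explicit spines: for dendritic
#' compartments beyond the distance threshold, membrane capacitance is
#' multiplied by F_spine and leak conductance is scaled the same way
#' (1/rm <- F_spine / rm). No compartments are added; everything else is
#' unchanged.
#'
#' @inheritParams attach_spines
#' @return The scaled compartment tree.
#' @examples
#' apply_fspine(synthetic_pyramidal(), spine_spec(fspine = 1.9))
#' @export
apply_fspine <- function(tree, spec = spine_spec()) {
  stopifnot(inherits(spec, "spine_spec"))
  sel <- tree$kind == "dend" & tree$path_dist > spec$distance_threshold
  tree$cm[sel] <- tree$cm[sel] * spec$fspine
  tree$rm[sel] <- tree$rm[sel] / spec$fspine
  tree
}
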