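# Independent oracles used across test files.

# dense linear-algebra oracle for a hines_system
dense_solve <- function(sys) {
  as.numeric(solve(hines_dense(sys), sys$rhs))
}

# --- exact rational arithmetic (num/den in exactly-representable doubles) ---
rat <- function(n, d = 1) {
  stopifnot(d != 0)
  g <- rat_gcd(abs(n), abs(d))
  s <- sign(n) * sign(d)
  out <- c(s * abs(n) / g, abs(d) / g)
  stopifnot(abs(out[1]) < 2^52, out[2] < 2^52) # guard exactness
  out
}
rat_gcd <- function(a, b) {
  while (b > 0) {
    t <- a %% b
    a <- b
    b <- t
  }
  max(a, 1)
}
rat_add <- function(x, y) rat(x[1] * y[2] + y[1] * x[2], x[2] * y[2])
rat_sub <- function(x, y) rat(x[1] * y[2] - y[1] * x[2], x[2] * y[2])
rat_mul <- function(x, y) rat(x[1] * y[1], x[2] * y[2])
rat_div <- function(x, y) {
  stopifnot(y[1] != 0)
  rat(x[1] * y[2], x[2] * y[1])
}

# Hines solve in exact rational arithmetic under an arbitrary
# child-before-parent elimination order. d, u, l, rhs are integer vectors.
rational_hines_solve <- function(parent, d, u, l, rhs, elim_order) {
  n <- length(d)
  D <- lapply(d, rat)
  U <- lapply(u, rat)
  L <- lapply(l, rat)
  R <- lapply(rhs, rat)
  for (i in elim_order) {
    p <- parent[i]
    f <- rat_div(L[[i]], D[[i]])
    D[[p]] <- rat_sub(D[[p]], rat_mul(f, U[[i]]))
    R[[p]] <- rat_sub(R[[p]], rat_mul(f, R[[i]]))
  }
  X <- vector("list", n)
  X[[1]] <- rat_div(R[[1]], D[[1]])
  for (i in rev(elim_order)) { # parent-before-child: reverse of elimination
    X[[i]] <- rat_div(rat_sub(R[[i]], rat_mul(U[[i]], X[[parent[i]]])),
                      D[[i]])
  }
  X
}

# independently replay a partition and check the candidate-set dynamics:
# every subset must consist of valid candidates and realise the depth sum of
# the min(k, |Q|) deepest candidates (the max-depth property)
check_partition_invariants <- function(tree, part) {
  parent <- tree$parent
  depth <- node_depths(tree)$depth
  n <- nrow(tree)
  all_nodes <- sort(unlist(part$subsets))
  if (!identical(all_nodes, seq_len(n)[-1])) return("subsets must cover V")
  processed <- rep(FALSE, n)
  kids <- lapply(seq_len(n), function(i) which(!is.na(parent) & parent == i))
  for (s in seq_along(part$subsets)) {
    set <- part$subsets[[s]]
    if (length(set) > part$k) return("subset larger than k")
    q <- which(!processed & seq_len(n) > 1 &
               vapply(kids, function(ch) all(processed[ch]), TRUE))
    if (!all(set %in% q)) return("node scheduled before its children")
    dmax <- sum(sort(depth[q], decreasing = TRUE)[seq_len(min(part$k,
                                                              length(q)))])
    if (sum(depth[set]) != dmax) return("max-depth property violated")
    processed[set] <- TRUE
  }
  TRUE
}

# small spiny tree + synapses reused by simulation tests
small_spiny_model <- function(seed = 5) {
  tr <- attach_spines(
    synthetic_pyramidal(n_primary = 2, daughter_len = 40),
    spine_spec(), seed = seed
  )
  heads <- which(tr$kind == "spine_head")
  sites <- heads[seq(1, length(heads), length.out = 4)]
  syn <- rbind(
    syn_ampa(sites, rep(list(c(8, 12)), length(sites))),
    syn_nmda(sites, rep(list(c(8, 12)), length(sites)))
  )
  list(tree = tr, synapses = syn)
}
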