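test_that("read_swc parses valid files and rejects malformed ones", {
  f <- withr::local_tempfile(fileext = ".swc")
  writeLines(c("# stick", "1 1 0 0 0 5 -1", "2 3 20 0 0 1 1",
               "3 3 40 0 0 1 2"), f)
  m <- read_swc(f)
  expect_equal(nrow(m), 3)
  expect_equal(m$parent, c(-1L, 1L, 2L))
  expect_equal(m$type[1], 1L)

  writeLines(c("1 1 0 0 0 5 -1", "2 3 20 0 0 1 99"), f)
  expect_error(read_swc(f), "missing parent id 99")

  writeLines(c("1 1 0 0 0 5 -1", "2 3 20 0 0 1"), f)
  expect_error(read_swc(f), "7 columns")

  writeLines(c("1 1 0 0 0 5 2", "2 3 20 0 0 1 1"), f)
  expect_error(read_swc(f), "root|cyclic")
})

test_that("SWC write -> read round-trips the point table", {
  tr <- example_tree()
  m <- tree_to_swc(tr)
  f <- withr::local_tempfile(fileext = ".swc")
  write_swc(m, f)
  m2 <- read_swc(f)
  expect_equal(nrow(m2), 15)
  expect_equal(sum(m2$parent == -1L), 1)
  for (col in c("id", "type", "x", "y", "z", "radius", "parent")) {
    expect_equal(m2[[col]], m[[col]], tolerance = 1e-6)
  }
})

test_that("the shipped worked-example fixture matches the in-code tree", {
  f <- system.file("extdata", "example15.swc", package = "dendrosched")
  tr <- segment_morphology(read_swc(f))
  ref <- example_tree()
  expect_equal(nrow(tr), 15)
  expect_identical(dendrosched:::canonical_topology(tr),
                   dendrosched:::canonical_topology(ref))
  expect_equal(total_length(tr), total_length(ref), tolerance = 1e-12)
})

test_that("segmentation respects policy, topology and length conservation", {
  f <- withr::local_tempfile(fileext = ".swc")
  writeLines(c("1 1 0 0 0 5 -1", "2 3 100 0 0 1 1"), f)
  m <- read_swc(f)
  tr <- segment_morphology(m, policy = "max_length", max_length = 10)
  expect_equal(nrow(tr), 11) # soma + 10 chained dendrite compartments
  expect_equal(tr$parent[-1], 1:10)
  expect_equal(total_length(tr), 100)

  # Y-shaped tree, one compartment per section -> soma + 3
  writeLines(c("1 1 0 0 0 5 -1", "2 3 30 0 0 1 1",
               "3 3 60 10 0 0.5 2", "4 3 60 -10 0 0.5 2"), f)
  y <- segment_morphology(read_swc(f))
  expect_equal(nrow(y), 4)
  expect_equal(sum(vapply(1:4, function(i) sum(y$parent == i, na.rm = TRUE),
                          1L) == 2), 1) # exactly one branch point

  # identical total membrane area under both policies
  a1 <- sum(membrane_area(segment_morphology(m)))
  a2 <- sum(membrane_area(segment_morphology(m, policy = "max_length",
                                             max_length = 7)))
  expect_equal(a1, a2, tolerance = 1e-9)

  expect_error(segment_morphology(m, policy = "max_length", max_length = 0),
               "positive")
})

test_that("attach_spines follows the local density rule", {
  # one eligible 100 um dendrite: a 70 um lead-in pushes it past 60 um
  tr <- new_compartment_tree(parent = c(NA, 1L, 2L),
                             length = c(10, 130, 100), diam = c(10, 2, 1))
  expect_gt(tr$path_dist[3], 60)
  spec <- spine_spec(density = 1.3)
  out <- attach_spines(tr, spec, seed = 1)
  # every eligible compartment gets round(density * length) spines
  counts <- round(1.3 * tr$length[tr$path_dist > 60])
  expect_equal(attr(out, "n_spines"), sum(counts))
  expect_equal(nrow(out), nrow(tr) + 2 * sum(counts))
  expect_true(any(round(1.3 * 100) == counts)) # 130 spines on the 100 um comp

  # pre-existing compartments untouched
  expect_equal(out$length[1:3], tr$length)
  expect_equal(out$cm[1:3], tr$cm)

  # spine geometry and membrane
  necks <- out[out$kind == "spine_neck", ]
  heads <- out[out$kind == "spine_head", ]
  expect_true(all(necks$length == 1.35 & necks$diam == 0.25))
  expect_true(all(heads$length == 0.944 & heads$diam == 0.944))
  expect_equal(unique(heads$el), -86)
  expect_equal(pi * 0.944 * 0.944, 2.8, tolerance = 0.01)

  # reproducible by seed; density 0 leaves the tree unchanged
  expect_identical(attach_spines(tr, spec, seed = 7),
                   attach_spines(tr, spec, seed = 7))
  expect_identical(attach_spines(tr, spine_spec(density = 0)), tr)
  expect_error(spine_spec(density = -1), "non-negative")
})

test_that("F_spine scaling targets only distal dendrites", {
  tr <- new_compartment_tree(parent = c(NA, 1L, 2L),
                             length = c(10, 50, 100), diam = c(10, 2, 1),
                             cm = 0.44, rm = 48300)
  expect_lt(tr$path_dist[2], 60) # proximal compartment, at 30 um
  expect_gt(tr$path_dist[3], 60)
  out <- apply_fspine(tr, spine_spec(fspine = 1.9))
  expect_equal(out$cm[3], 0.44 * 1.9)
  expect_equal(out$cm[2], 0.44)       # proximal untouched
  expect_equal(out$rm[3], 48300 / 1.9) # leak conductance scaled up
  expect_equal(nrow(out), nrow(tr))    # no nodes added

  # F_spine = 1 is the identity
  expect_equal(apply_fspine(tr, spine_spec(fspine = 1)), tr)
  expect_error(spine_spec(fspine = 0.5), ">= 1")
})

test_that("both spine treatments increase total membrane conductance", {
  tr <- synthetic_pyramidal()
  g0 <- sum(tree_coefficients(tr)$g_leak)
  g_full <- sum(tree_coefficients(attach_spines(tr, spine_spec(), 1))$g_leak)
  g_few <- sum(tree_coefficients(apply_fspine(tr, spine_spec()))$g_leak)
  expect_gt(g_full, g0)
  expect_gt(g_few, g0)
})

test_that("path distance is zero at the root and increases toward leaves", {
  tr <- random_tree(40, seed = 9)
  expect_equal(tr$path_dist[1], 0)
  nonroot <- 2:nrow(tr)
  parent_pd <- tr$path_dist[tr$parent[nonroot]]
  expect_true(all(tr$path_dist[nonroot] > parent_pd |
                  tr$parent[nonroot] == 1))
  expect_true(all(tr$path_dist[nonroot] > 0))
})
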