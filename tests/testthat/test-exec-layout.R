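test_that("schedules replay the partition and align threads", {
  tr <- example_tree()
  p <- dhs_partition(tr, 4)
  sch <- build_schedule(p)
  # replay: grouping by step reproduces the subsets as sets
  by_step <- split(sch$table$node, sch$table$step)
  expect_equal(lapply(by_step, sort),
               setNames(lapply(p$subsets, sort), 1:5))
  # 4 threads; the busiest thread carries one node per step = 5 nodes
  counts <- table(sch$table$thread)
  expect_equal(max(sch$table$thread), 4)
  expect_equal(max(counts), 5)
  # thread totals are non-increasing in thread id (alignment)
  expect_true(all(diff(as.integer(counts)) <= 0))

  # chain: single active thread at every step
  sch_chain <- build_schedule(dhs_partition(tree_chain(6), 3))
  expect_true(all(sch_chain$table$thread == 1L))

  # random tree round trip
  tr <- random_tree(35, seed = 3)
  p <- dhs_partition(tr, 5)
  sch <- build_schedule(p)
  expect_equal(lapply(split(sch$table$node, sch$table$step), sort),
               setNames(lapply(p$subsets, sort),
                        seq_along(p$subsets)))
})

test_that("executing the serial-order schedule is bitwise identical to the serial solve", {
  sys <- random_hines(random_tree(30, seed = 8), seed = 9)
  x_serial <- solve_hines(sys)
  x_sched <- execute_schedule(sys, serial_schedule(nrow(sys)))
  expect_identical(as.numeric(x_sched), as.numeric(x_serial))
})

test_that("DHS-scheduled execution matches the serial solve on random systems", {
  worst <- 0
  for (seed in 1:30) {
    tr <- random_tree(sample(c(10, 25, 50), 1), seed = seed)
    sys <- random_hines(tr, seed = seed + 500)
    x_serial <- as.numeric(solve_hines(sys))
    for (k in c(2, 4, 8)) {
      x <- execute_schedule(sys, build_schedule(dhs_partition(tr, k)))
      worst <- max(worst, max(abs(x - x_serial)) / max(abs(x_serial)))
    }
  }
  expect_lt(worst, 1e-12)
})

test_that("dependency-violating schedules fail before any arithmetic", {
  tr <- tree_chain(5)
  sys <- random_hines(tr, seed = 1)
  sch <- build_schedule(dhs_partition(tr, 2))
  bad <- sch
  bad$table$step <- rev(bad$table$step) # parents now precede children
  expect_error(execute_schedule(sys, bad), "dependency")
  incomplete <- sch
  incomplete$table <- incomplete$table[-1, ]
  expect_error(execute_schedule(sys, incomplete), "every non-root node")
})

test_that("warp grouping packs whole cells and sorts by morphology", {
  cells <- rep(list(tree_binary(15)), 8)
  w <- group_warps(cells, k = 4)
  expect_equal(length(unique(w$warp)), 1) # 8 cells x 4 threads = 32

  w9 <- group_warps(rep(list(tree_binary(15)), 9), k = 4)
  expect_equal(as.integer(table(w9$warp)), c(8L, 1L))
  expect_equal(sum(table(w9$warp)), 9) # packing conserves cells

  mixed <- list(tree_chain(10), tree_binary(15), tree_chain(10),
                tree_star(15), random_tree(8, seed = 1))
  wm <- group_warps(mixed, k = 2)
  # equal node counts end up adjacent in warp order
  expect_true(all(diff(wm$n_nodes) >= 0))
  counts <- wm$n_nodes
  expect_true(all(counts[wm$signature == wm$signature[1]] ==
                  counts[wm$signature == wm$signature[1]][1]))

  expect_error(group_warps(cells, k = 64, warp_size = 32), "warp size")
})

test_that("memory layout is a bijection with contiguous steps", {
  tr <- example_tree()
  sch <- build_schedule(dhs_partition(tr, 4))
  lay <- permute_layout(sch)
  expect_setequal(lay$slot, seq_len(15))
  expect_setequal(lay$node, seq_len(15))
  # the first step's subset occupies the first slots after the root
  step1 <- sort(sch$table$node[sch$table$step == 1])
  expect_setequal(lay$slot[match(step1, lay$node)], 2:5)
  # contiguity at every step
  for (s in unique(sch$table$step)) {
    slots <- lay$slot[match(sch$table$node[sch$table$step == s], lay$node)]
    expect_equal(max(slots) - min(slots) + 1L, length(slots))
  }
})

test_that("execution is invariant under storage permutation", {
  tr <- random_tree(30, seed = 12)
  sys <- random_hines(tr, seed = 13)
  sch <- build_schedule(dhs_partition(tr, 4))
  x_ref <- as.numeric(execute_schedule(sys, sch))

  lay <- permute_layout(sch, n = nrow(sys))
  sys_p <- apply_layout(sys, lay)
  slot_of <- attr(sys_p, "slot_of")
  sch_p <- sch
  sch_p$table$node <- slot_of[sch$table$node]
  x_p <- execute_schedule(sys_p, sch_p)
  x_back <- unapply_layout(as.numeric(x_p), lay)
  expect_equal(x_back, x_ref, tolerance = 1e-15)
})
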