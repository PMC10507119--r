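test_that("single-compartment assembly reproduces the closed-form RC update", {
  tr <- new_compartment_tree(NA_integer_, length = 20, diam = 20,
                             cm = 1, rm = 1e4, el = -65)
  dt <- 0.025
  sys <- assemble_hines(tr, dt = dt, v = -55)
  co <- tree_coefficients(tr)
  expected <- ((co$c_nf / dt) * -55 + co$g_leak * -65) /
    (co$c_nf / dt + co$g_leak)
  expect_equal(as.numeric(solve_hines(sys)), expected)
  expect_error(assemble_hines(tr, dt = 0), "positive")
})

test_that("two-compartment cable matches hand elimination", {
  tr <- new_compartment_tree(c(NA, 1L), length = 20, diam = 2,
                             cm = 1, rm = 1e4, ra = 100, el = -65)
  sys <- assemble_hines(tr, dt = 0.025, v = c(-65, -55), i_inj = c(0.1, 0))
  # hand elimination of the 2x2 system
  f <- sys$l[2] / sys$d[2]
  d1 <- sys$d[1] - f * sys$u[2]
  r1 <- sys$rhs[1] - f * sys$rhs[2]
  x1 <- r1 / d1
  x2 <- (sys$rhs[2] - sys$u[2] * x1) / sys$d[2]
  expect_equal(as.numeric(solve_hines(sys)), c(x1, x2))
  expect_equal(as.numeric(solve_hines(sys)), dense_solve(sys),
               tolerance = 1e-12)
})

test_that("a symmetric Y tree with symmetric input stays symmetric", {
  tr <- new_compartment_tree(c(NA, 1L, 1L), length = c(20, 50, 50),
                             diam = c(20, 1, 1))
  sys <- assemble_hines(tr, dt = 0.025, i_inj = c(0, 0.2, 0.2))
  x <- solve_hines(sys)
  expect_equal(x[2], x[3])
})

test_that("serial solve visits each non-root node once and matches the dense oracle", {
  x <- solve_hines(random_hines(example_tree(), seed = 1))
  expect_identical(attr(x, "steps"), 14L)

  for (seed in 1:25) {
    n <- sample(c(5, 12, 27, 50), 1)
    tr <- random_tree(n, seed = seed)
    sys <- random_hines(tr, seed = seed + 100)
    x <- solve_hines(sys)
    xd <- dense_solve(sys)
    expect_lt(max(abs(x - xd)) / max(abs(xd)), 1e-10)
    # residual check directly against the matrix equation
    res <- hines_dense(sys) %*% x - sys$rhs
    expect_lt(max(abs(res)), 1e-10 * max(abs(sys$rhs)))
  }
})

test_that("a zero pivot raises a numerical error", {
  sys <- random_hines(tree_chain(3), seed = 1)
  sys$d[3] <- 0
  expect_error(solve_hines(sys), "pivot")
})

test_that("resting membrane stays at E_l without stimuli", {
  tr <- random_tree(20, seed = 2, el = -70)
  sim <- simulate_tree(tr, t_stop = 25, dt = 0.025,
                       record = seq_len(nrow(tr)))
  expect_equal(sim$n_iterations, 1000L)
  expect_lt(max(abs(sim$traces - (-70))) / 70, 1e-12)
})

test_that("input resistance of a single compartment equals rm / area", {
  tr <- new_compartment_tree(NA_integer_, length = 20, diam = 20,
                             cm = 1, rm = 48300)
  area_cm2 <- pi * 20 * 20 * 1e-8
  expect_equal(input_resistance(tr, 1), 48300 / area_cm2 / 1e6,
               tolerance = 1e-12) # MOhm
})

test_that("transfer resistance is reciprocal and matches the two-resistor network", {
  tr <- random_tree(30, seed = 4)
  expect_equal(transfer_resistance(tr, 7, 22), transfer_resistance(tr, 22, 7),
               tolerance = 1e-10)

  # 2-compartment cable: hand circuit analysis with leak and axial resistors
  tr2 <- new_compartment_tree(c(NA, 1L), length = 30, diam = 2,
                              cm = 1, rm = 1e4, ra = 150)
  co <- tree_coefficients(tr2)
  g1 <- co$g_leak[1]; g2 <- co$g_leak[2]; ga <- co$g_axial[2]
  # inject 1 nA at node 2; solve the 2-node conductance network by hand
  det <- (g1 + ga) * (g2 + ga) - ga^2
  v2 <- (g1 + ga) / det
  v1 <- ga / det
  expect_equal(transfer_resistance(tr2, 2, 2), v2, tolerance = 1e-12)
  expect_equal(transfer_resistance(tr2, 2, 1), v1, tolerance = 1e-12)
})

test_that("transfer_resistance_to matches pairwise calls", {
  tr <- random_tree(15, seed = 6)
  r <- transfer_resistance_to(tr, 1)
  for (i in c(2, 8, 15)) {
    expect_equal(r[i], transfer_resistance(tr, i, 1), tolerance = 1e-10)
  }
})
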