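cfg <- sim_config()

test_that("bond refinement has a fixed point at 6 A and a capped step", {
  at6 <- ptrace(matrix(c(0, 0, 0, 6, 0, 0), 2, 3, byrow = TRUE))
  expect_equal(pt_coords(step_bonded(at6, cfg)), pt_coords(at6))
  at8 <- ptrace(matrix(c(0, 0, 0, 8, 0, 0), 2, 3, byrow = TRUE))
  expect_equal(pair_distance(step_bonded(at8, cfg), 1, 2), 7.5)
  at3 <- ptrace(matrix(c(0, 0, 0, 3, 0, 0), 2, 3, byrow = TRUE))
  expect_equal(pair_distance(step_bonded(at3, cfg), 1, 2), 3.5)
  # coincident points separate along the deterministic fallback axis
  co <- ptrace(matrix(0, 2, 3), resno = 1:2)
  moved <- step_bonded(co, cfg)
  expect_gt(pair_distance(moved, 1, 2), 0)
})

test_that("iterated bond refinement converges from a random chain", {
  set.seed(9)
  tr <- ptrace(matrix(runif(45, 0, 50), ncol = 3))
  for (it in 1:5000) tr <- step_bonded(tr, cfg)
  b <- pair_distance(tr, 1:14, 2:15)
  expect_true(all(abs(b - 6) < cfg$step / 2))
})

test_that("pair restraints are one-sided and converge to 17 A", {
  far <- ptrace(matrix(c(0, 0, 0, 30, 0, 0), 2, 3, byrow = TRUE))
  r <- tibble::tibble(i = 1L, j = 2L)
  expect_equal(pair_distance(step_pair_restraints(far, r, cfg), 1, 2), 29.5)
  near <- ptrace(matrix(c(0, 0, 0, 16, 0, 0), 2, 3, byrow = TRUE))
  expect_equal(pt_coords(step_pair_restraints(near, r, cfg)), pt_coords(near))
  # iterate to convergence; separation never increases along the way
  tr <- far
  prev <- 30
  repeat {
    tr <- step_pair_restraints(tr, r, cfg)
    d <- pair_distance(tr, 1, 2)
    expect_lte(d, prev + 1e-12)
    if (abs(d - prev) < cfg$step / 2) break
    prev <- d
  }
  expect_equal(pair_distance(tr, 1, 2), 17)
})

test_that("repulsion pushes apart only non-excluded pairs under 10 A", {
  tri <- ptrace(matrix(c(0, 0, 0, 6, 0, 0, 3, 8, 0), 3, 3, byrow = TRUE))
  # pair (1,3) is at 8.54 A -> repelled; bonded neighbours untouched
  out <- step_repulsion(tri, cfg)
  expect_gt(pair_distance(out, 1, 3), pair_distance(tri, 1, 3))
  far <- ptrace(matrix(c(0, 0, 0, 6, 0, 0, 3, 11, 0), 3, 3, byrow = TRUE))
  expect_equal(pt_coords(step_repulsion(far, cfg)), pt_coords(far))
  # an excluded (restrained) pair at 8 A is untouched
  out2 <- step_repulsion(tri, cfg, restraints = tibble::tibble(i = 1L, j = 3L))
  expect_equal(pt_coords(out2), pt_coords(tri))
})

test_that("local-window restoration is gated at 18 A", {
  ref <- ptrace(cbind(c(0, 6, 10), 0, 0)) # native (1,3) distance 10
  r13 <- tibble::tibble(i = 1L, j = 3L, dist = 10)
  # currently at 12: moves towards native by the step
  cur <- ptrace(cbind(c(0, 6, 12), 0, 0))
  out <- step_local_window(cur, r13, cfg)
  expect_equal(pair_distance(out, 1, 3), 11.5)
  # currently at 19 (beyond the gate): untouched
  cur19 <- ptrace(cbind(c(0, 6, 19), 0, 0))
  expect_equal(pt_coords(step_local_window(cur19, r13, cfg)), pt_coords(cur19))
  # at native distance: fixed point
  expect_equal(pt_coords(step_local_window(ref, r13, cfg)), pt_coords(ref))
})

test_that("local_native_distances covers separations 2..window-1 within chains", {
  tr <- ptrace(matrix(rnorm(60), ncol = 3), chain = rep(c("A", "B"), each = 10))
  loc <- local_native_distances(tr, cfg)
  sep <- loc$j - loc$i
  expect_true(all(sep >= 2 & sep <= 9))
  expect_true(all(tr$chain[loc$i] == tr$chain[loc$j]))
  expect_equal(loc$dist, pair_distance(tr, loc$i, loc$j))
})

test_that("SSE ideal refinement shrinks deviation from the template", {
  h <- build_helix(3)
  sses <- detect_sses(h$pairs)
  # fixed point at the template
  expect_equal(
    pt_coords(step_sse_ideal(h$trace, sses, cfg)),
    pt_coords(h$trace),
    tolerance = 1e-9
  )
  # a uniformly scaled copy moves back towards the template
  scaled <- pt_set_coords(h$trace, pt_coords(h$trace) * 1.2)
  tmpl <- sses[[1]]$template
  dev <- function(tr) {
    dm <- as.matrix(dist(pt_coords(tr)[sses[[1]]$members, ]))
    sqrt(mean((dm[upper.tri(dm)] - tmpl[upper.tri(tmpl)])^2))
  }
  out <- step_sse_ideal(scaled, sses, cfg)
  expect_lt(dev(out), dev(scaled))
})

test_that("SSE perturbation is rigid, seeded, and spares loops", {
  topo <- build_topology(topology_spec("stemloop"))
  sses <- detect_sses(topo$ss$pairs)
  mem <- sses[[1]]$members
  loops <- setdiff(seq_len(pt_length(topo$trace)), mem)
  set.seed(7)
  out <- perturb_sses(topo$trace, sses, cfg)
  # intra-SSE distances preserved (rigid motion)
  expect_equal(
    as.matrix(dist(pt_coords(out)[mem, ])),
    as.matrix(dist(pt_coords(topo$trace)[mem, ])),
    tolerance = 1e-9
  )
  # loop residues untouched
  expect_equal(pt_coords(out)[loops, ], pt_coords(topo$trace)[loops, ])
  # same seed reproduces the displacement bit-for-bit
  set.seed(7)
  again <- perturb_sses(topo$trace, sses, cfg)
  expect_identical(pt_coords(again), pt_coords(out))
  # zero level leaves the chain unchanged
  zero <- sim_config(perturb_translation = 0)
  expect_equal(pt_coords(perturb_sses(topo$trace, sses, zero)), pt_coords(topo$trace))
})

test_that("make_circle_start lays out near-ideal bonds on a circle", {
  tr <- make_circle_start(100)
  expect_equal(pt_length(tr), 100)
  expect_equal(
    max(abs(pt_coords(tr)[, 1:2])) > 90, TRUE
  ) # radius 600/(2*pi) ~ 95.5
  expect_equal(sqrt(sum(pt_coords(tr)[1, 1:2]^2)), 600 / (2 * pi))
  b <- pair_distance(tr, 1:99, 2:100)
  expect_lt(max(b) - min(b), 1e-9) # all chords equal
  expect_true(all(abs(b - 6) < 0.06)) # within 1% of the bond ideal
})

test_that("refinement-only simulation leaves a built fixture essentially fixed", {
  topo <- build_topology(topology_spec("Y", cross_links = 1))
  cfg0 <- sim_config(cycles = 300, perturb_translation = 0, replicates = 1, seed = 1)
  res <- simulate_trace(topo$trace, topo$ss, NULL, cfg0)
  expect_lt(superpose_rmsd(res$models[[1]], topo$trace), 0.5)
})

test_that("simulations are bit-reproducible under a fixed seed", {
  topo <- build_topology(topology_spec("stemloop"))
  cfgq <- quick_config()
  a <- simulate_trace(topo$trace, topo$ss, NULL, cfgq)
  b <- simulate_trace(topo$trace, topo$ss, NULL, cfgq)
  expect_identical(
    lapply(a$models, pt_coords),
    lapply(b$models, pt_coords)
  )
  # different seeds give different ensembles
  c <- simulate_trace(topo$trace, topo$ss, NULL, quick_config(seed = 43))
  expect_false(identical(pt_coords(a$models[[1]]), pt_coords(c$models[[1]])))
})

test_that("restrained separations only exceed the target, never undershoot it", {
  topo <- build_topology(topology_spec("Y", cross_links = 1))
  cl <- topo$cross_links[c("i", "j")]
  res <- simulate_trace(topo$trace, topo$ss, cl, quick_config(cycles = 400))
  for (m in res$models) {
    d <- pair_distance(m, cl$i, cl$j)
    expect_lt(d, cfg$restraint_target + cfg$step) # held near/below target
  }
})

test_that("diagnostics record per-cycle bond and restraint satisfaction", {
  topo <- build_topology(topology_spec("stemloop"))
  cfgd <- sim_config(cycles = 50, replicates = 2, seed = 1, diagnostics = TRUE)
  res <- simulate_trace(
    topo$trace, topo$ss,
    tibble::tibble(i = 1L, j = 10L), cfgd
  )
  expect_equal(nrow(res$diagnostics), 100)
  expect_true(all(res$diagnostics$mean_bond > 0))
})
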