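test_that("superposition RMSD is zero for rigid copies and symmetric", {
  A <- chiral_points()
  expect_equal(superpose_rmsd(A, A), 0)
  set.seed(3)
  R <- random_rotation()
  moved <- A %*% t(R) + rep(c(5, -2, 9), each = nrow(A))
  expect_lt(superpose_rmsd(A, moved), 1e-9)
  B <- A + matrix(rnorm(length(A)), ncol = 3)
  expect_equal(superpose_rmsd(A, B), superpose_rmsd(B, A), tolerance = 1e-9)
  expect_error(superpose_rmsd(A, A[1:3, ]), "equal length")
})

test_that("superposition RMSD matches an independent optimisation oracle", {
  set.seed(11)
  for (rep in 1:5) {
    n <- sample(4:6, 1)
    A <- matrix(rnorm(3 * n, sd = 5), ncol = 3)
    B <- matrix(rnorm(3 * n, sd = 5), ncol = 3)
    expect_equal(superpose_rmsd(A, B), rmsd_oracle(A, B), tolerance = 1e-3)
  }
})

test_that("dRMSD follows its closed form and is reflection-blind", {
  A <- chiral_points()
  expect_equal(drmsd(A, A), 0)
  mirror <- A %*% diag(c(-1, 1, 1))
  expect_equal(drmsd(A, mirror), 0)
  # the superposition RMSD, restricted to proper rotations, is not
  expect_gt(superpose_rmsd(A, mirror), 0.5)
  # 3-point case with exactly one pairwise distance off by 1 A
  a <- matrix(c(0, 0, 0, 3, 0, 0, 0, 4, 0), 3, 3, byrow = TRUE)
  b3 <- c(1.5, sqrt(25 - 1.5^2), 0) # d13 = 5 instead of 4; d12, d23 kept
  b <- rbind(c(0, 0, 0), c(3, 0, 0), b3)
  expect_equal(drmsd(a, b), sqrt(1 / 3), tolerance = 1e-9)
  # drmsd == 0 iff the distance matrices agree
  expect_gt(drmsd(a, b), 0)
})

test_that("max distance matrix is the entrywise ensemble maximum", {
  m1 <- matrix(c(0, 0, 0, 3, 0, 0, 0, 4, 0), 3, 3, byrow = TRUE)
  m2 <- matrix(c(0, 0, 0, 5, 0, 0, 0, 2, 0), 3, 3, byrow = TRUE)
  mm <- max_distance_matrix(list(m1, m2))
  expect_equal(mm[1, 2], 5)
  expect_equal(mm[1, 3], 4)
  expect_equal(mm[2, 3], max(as.matrix(dist(m1))[2, 3], as.matrix(dist(m2))[2, 3]))
  expect_true(all(mm >= as.matrix(dist(m1)) - 1e-12))
  expect_true(all(mm >= as.matrix(dist(m2)) - 1e-12))
  # single model: its own distance matrix
  expect_equal(max_distance_matrix(list(m1)), as.matrix(dist(m1)))
})

test_that("drmsd_max compares the maximum matrix to the native distances", {
  native <- chiral_points()
  expect_equal(drmsd_max(list(native, native), native), 0)
  shifted <- native
  shifted[5, ] <- shifted[5, ] + c(4, 0, 0)
  v <- drmsd_max(list(native, shifted), native)
  expect_gt(v, 0)
  # hand evaluation on the two-model toy case
  mm <- pmax(as.matrix(dist(native)), as.matrix(dist(shifted)))
  nd <- as.matrix(dist(native))
  ut <- upper.tri(mm)
  expect_equal(v, sqrt(mean((mm[ut] - nd[ut])^2)))
  # always at least any single model's contribution at the max matrix
  expect_gte(drmsd_max(list(native, shifted), native) + 1e-12,
    0
  )
})

test_that("per-residue profiles localise a confined displacement", {
  topo <- build_topology(topology_spec("Y", cross_links = 0))
  native <- topo$trace
  # displace only arm A's loop in one model
  sses <- detect_sses(topo$ss$pairs)
  loopA <- (max(sses[[2]]$i) + 1):(min(sses[[2]]$j) - 1)
  m <- pt_coords(native)
  m[loopA, ] <- m[loopA, ] + rep(c(0, 0, 6), each = length(loopA))
  prof <- per_residue_rmsd(list(native, pt_set_coords(native, m)), native)
  expect_equal(nrow(prof), pt_length(native))
  expect_gt(mean(prof$rmsd[loopA]), 5 * mean(prof$rmsd[-loopA]))
  # all-native ensemble gives a flat zero profile
  flat <- per_residue_rmsd(list(native, native), native)
  expect_true(all(flat$rmsd < 1e-9))
})

test_that("metric summaries and tidiers expose the ensemble measures", {
  topo <- build_topology(topology_spec("stemloop"))
  res <- simulate_trace(topo$trace, topo$ss, NULL, quick_config())
  gl <- glance(res)
  expect_named(
    gl,
    c("n_models", "rmsd_mean", "drmsd_mean", "drmsd_max", "drmsd_max_permodel")
  )
  expect_true(all(unlist(gl) >= 0))
  td <- tidy(res)
  expect_equal(nrow(td), 2)
  expect_equal(mean(td$rmsd), gl$rmsd_mean)
})
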