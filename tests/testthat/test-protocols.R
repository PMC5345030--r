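# Protocol tests run at reduced scale (few replicates, short runs); the
# full-scale study conditions are exercised in test-acceptance.R.

test_that("denaturation profiles have prefix structure and reproduce exactly", {
  topo <- build_topology(topology_spec("Y", cross_links = 1))
  preds <- synth_predictions(topo,
    n_true_nonlocal = 1, n_basepairs = 2,
    nonlocal_first = TRUE
  )$contacts
  cfg <- sim_config(cycles = 100, replicates = 2, seed = 4)
  prof <- denaturation_profile(topo$trace, topo$ss, preds, cfg, max_k = 3)
  expect_s3_class(prof, "denat_profile")
  expect_equal(prof$k, 0:3)
  expect_true(all(prof$rmsd_mean >= 0))
  # bit-for-bit reproducible under the same master seed
  again <- denaturation_profile(topo$trace, topo$ss, preds, cfg, max_k = 3)
  expect_identical(prof$rmsd_mean, again$rmsd_mean)
})

test_that("profile categories follow the k-th restraint's classification", {
  topo <- build_topology(topology_spec("Y", cross_links = 1))
  preds <- synth_predictions(topo,
    n_true_nonlocal = 1, n_basepairs = 1,
    nonlocal_first = TRUE
  )$contacts
  classified <- classify_contacts(preds, topo$trace, topo$ss, topo$ss$nested)
  cfg <- sim_config(cycles = 50, replicates = 1, seed = 4)
  prof <- denaturation_profile(topo$trace, topo$ss, classified, cfg)
  expect_true(is.na(prof$category[1]))
  expect_equal(prof$category[-1], as.character(classified$category))
})

test_that("control profiles share the procedure and length bookkeeping", {
  topo <- build_topology(topology_spec("stemloop"))
  cfg <- sim_config(cycles = 50, replicates = 1, seed = 4)
  ctr <- control_profiles(topo$trace, topo$ss, topo$ss$pairs, topo$ss$pairs, cfg)
  expect_named(ctr, c("observed", "rnafold"))
  expect_equal(nrow(ctr$observed), nrow(topo$ss$pairs) + 1)
  expect_identical(ctr$observed$rmsd_mean, ctr$rnafold$rmsd_mean)
})

test_that("perturbation sweep covers level x set combinations", {
  topo <- build_topology(topology_spec("stemloop"))
  cfg <- sim_config(cycles = 60, replicates = 2, seed = 4)
  sw <- perturbation_sweep(
    topo$trace, topo$ss,
    list(none = tibble::tibble(i = integer(), j = integer())),
    cfg,
    levels = c(0, 0.08)
  )
  expect_equal(nrow(sw), 2)
  # zero perturbation leaves the fixture essentially unmoved
  expect_lt(sw$rmsd_mean[sw$level == 0], 0.2)
  expect_gt(sw$rmsd_mean[sw$level == 0.08], sw$rmsd_mean[sw$level == 0])
})

test_that("folding runs start from the circle and report best-10 statistics", {
  topo <- build_topology(topology_spec("stemloop"))
  cfg <- sim_config(cycles = 300, replicates = 1, seed = 4)
  f <- fold_trace(topo$trace, topo$ss, NULL, cfg, n_runs = 3)
  expect_s3_class(f, "fold_result")
  expect_equal(f$n_models, 3)
  expect_equal(f$best10_mean_rmsd, mean(f$rmsd)) # best-10 of 3 = all 3
  expect_equal(f$rmsd, sort(f$rmsd))
  # determinism under the same master seed
  again <- fold_trace(topo$trace, topo$ss, NULL, cfg, n_runs = 3)
  expect_identical(f$rmsd, again$rmsd)
  # single run: best-10 over one model
  one <- fold_trace(topo$trace, topo$ss, NULL, cfg, n_runs = 1)
  expect_equal(one$best10_mean_rmsd, one$rmsd[1])
  gl <- glance(f)
  expect_equal(gl$n_models, 3)
})

test_that("folding actually compacts the circle towards the fold", {
  topo <- build_topology(topology_spec("stemloop"))
  cfg <- sim_config(cycles = 1000, replicates = 1, seed = 4)
  f <- fold_trace(topo$trace, topo$ss, NULL, cfg, n_runs = 4)
  start_rmsd <- superpose_rmsd(
    make_circle_start(pt_length(topo$trace)), topo$trace
  )
  # individual runs can land in the mirror-image hairpin (high RMSD under
  # proper-rotation superposition); the best run approaches the fold and
  # the ensemble as a whole compacts well below the circular start
  expect_lt(min(f$rmsd), 0.6 * start_rmsd)
  expect_lt(f$best10_mean_rmsd, start_rmsd)
  # base pairs pulled towards the restraint target in every model
  for (m in f$models) {
    pd <- pair_distance(m, topo$ss$pairs$i, topo$ss$pairs$j)
    expect_true(all(pd < 17 + 1))
  }
})

test_that("autoplot methods return ggplot objects", {
  topo <- build_topology(topology_spec("stemloop"))
  cfg <- sim_config(cycles = 30, replicates = 1, seed = 4)
  preds <- tibble::tibble(i = 1, j = 10, score = 1, rank = 1)
  prof <- denaturation_profile(topo$trace, topo$ss, preds, cfg)
  expect_s3_class(ggplot2::autoplot(prof), "ggplot")
  sw <- perturbation_sweep(
    topo$trace, topo$ss,
    list(none = tibble::tibble(i = integer(), j = integer())),
    cfg,
    levels = c(0.04, 0.08)
  )
  expect_s3_class(ggplot2::autoplot(sw), "ggplot")
  res <- simulate_trace(topo$trace, topo$ss, NULL, cfg)
  expect_s3_class(plot_distance_matrix(res, topo$trace), "ggplot")
  expect_s3_class(plot_per_residue(res$models, topo$trace), "ggplot")
})
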