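test_that("build_helix meets the engine's geometric ideals", {
  h <- build_helix(6)
  expect_equal(pt_length(h$trace), 12)
  expect_equal(nrow(h$pairs), 6)
  b <- rnadenature:::bond_pairs(h$trace)
  expect_true(all(abs(pair_distance(h$trace, b$i, b$j) - 6) < 0.05))
  pd <- pair_distance(h$trace, h$pairs$i, h$pairs$j)
  expect_true(all(abs(pd - 17) < 1))
  expect_length(detect_sses(h$pairs), 1)
  expect_error(build_helix(2), "at least 3")
})

test_that("built topologies have the expected elements and clearances", {
  specs <- list(
    list(spec = topology_spec("stemloop"), sses = 1),
    list(spec = topology_spec("Y", cross_links = 1), sses = 3),
    list(spec = topology_spec("cruciform", cross_links = 1), sses = 4)
  )
  for (case in specs) {
    topo <- build_topology(case$spec)
    sses <- detect_sses(topo$ss$pairs)
    expect_length(sses, case$sses)
    # bonds at the ideal, pairs at the pairing distance
    b <- rnadenature:::bond_pairs(topo$trace)
    expect_true(all(abs(pair_distance(topo$trace, b$i, b$j) - 6) < 1))
    # self-avoidance: non-bonded, non-SSE pairs at >= 10 A except the
    # planted cross-links, which sit in (10, 17]
    cand <- rnadenature:::repulsion_candidates(topo$trace, sses, topo$cross_links)
    expect_true(all(pair_distance(topo$trace, cand$i, cand$j) >= 10 - 1e-6))
    if (nrow(topo$cross_links) > 0) {
      d <- pair_distance(topo$trace, topo$cross_links$i, topo$cross_links$j)
      expect_true(all(d > 10 & d <= 17))
    }
  }
})

test_that("topology builds are deterministic", {
  a <- build_topology(topology_spec("Y", cross_links = 1))
  b <- build_topology(topology_spec("Y", cross_links = 1))
  expect_identical(pt_coords(a$trace), pt_coords(b$trace))
  expect_identical(a$cross_links, b$cross_links)
})

test_that("synthetic predictions carry planted truth that classify() recovers", {
  topo <- build_topology(topology_spec("Y", cross_links = 1))
  sp <- synth_predictions(topo, n_true_nonlocal = 1, n_false = 3, seed = 5)
  out <- classify_contacts(
    sp$contacts, topo$trace, topo$ss,
    rnafold_pairs = topo$ss$nested
  )
  key <- paste(out$i, out$j)
  labs <- sp$labels$label[match(key, paste(sp$labels$i, sp$labels$j))]
  expect_equal(
    as.character(out$category[labs == "basepair"]),
    rep("shared_local", sum(labs == "basepair"))
  )
  expect_equal(
    as.character(out$category[labs == "nonlocal"]),
    rep("non_local", sum(labs == "nonlocal"))
  )
  expect_equal(
    as.character(out$category[labs == "false"]),
    rep("false", sum(labs == "false"))
  )
  # with no false plants there are no false labels
  clean <- synth_predictions(topo, n_true_nonlocal = 1, n_false = 0)
  out2 <- classify_contacts(clean$contacts, topo$trace, topo$ss, topo$ss$nested)
  expect_equal(sum(out2$category == "false"), 0)
})

test_that("error-rate cutoff locates the first planted false prediction", {
  topo <- build_topology(topology_spec("Y", cross_links = 1))
  sp <- synth_predictions(topo,
    n_true_nonlocal = 1, n_false = 4,
    nonlocal_first = TRUE, seed = 9
  )
  out <- classify_contacts(sp$contacts, topo$trace, topo$ss, topo$ss$nested)
  k0 <- error_rate_cutoff(out, 0)
  # brute force: rank of the last prediction before the first false one
  labs <- as.character(out$category)
  first_false <- which(labs == "false")[1]
  expect_equal(k0, first_false - 1L)
})

test_that("score bands order the contact list as requested", {
  topo <- build_topology(topology_spec("Y", cross_links = 1))
  bp_first <- synth_predictions(topo, n_true_nonlocal = 1, n_false = 2, seed = 2)
  lab1 <- bp_first$labels$label[match(
    paste(bp_first$contacts$i[1], bp_first$contacts$j[1]),
    paste(bp_first$labels$i, bp_first$labels$j)
  )]
  expect_equal(lab1, "basepair")
  nl_first <- synth_predictions(topo,
    n_true_nonlocal = 1, n_false = 2,
    nonlocal_first = TRUE, seed = 2
  )
  expect_equal(
    paste(nl_first$contacts$i[1], nl_first$contacts$j[1]),
    paste(topo$cross_links$i, topo$cross_links$j)
  )
})

test_that("fixtures serialize and re-load identically", {
  topo <- build_topology(topology_spec("Y", cross_links = 1))
  pdb <- withr::local_tempfile(fileext = ".pdb")
  write_phosphate_trace(topo$trace, pdb)
  expect_equal(pt_coords(read_phosphate_trace(pdb)), pt_coords(topo$trace),
    tolerance = 1e-3
  )
  db <- write_dotbracket(topo$ss$pairs, pt_length(topo$trace))
  expect_equal(parse_dotbracket(db), dplyr::arrange(topo$ss$pairs, i))
  sp <- synth_predictions(topo, n_false = 2, seed = 3)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_contacts(sp$contacts, tsv)
  expect_equal(read_contacts(tsv), sp$contacts)
})
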