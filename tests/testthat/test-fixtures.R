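# Fixture generator: truth tables are the primary regression surface.

test_that("all analyses reproduce the truth tables exactly", {
  f <- fp_minifibril()
  sc <- dissociation_script(
    duration = 24, stride = 1,
    detach = data.frame(peptide = c(1, 4), time = c(6, 15),
                        dx = 0, dy = c(-40, 40), dz = 0),
    morph = data.frame(peptide = 3, t_start = 2, t_end = 10))
  fx <- generate_fixture(sc, f)
  os <- oligomer_series(fx$trajectory, fx$system)
  for (q in seq_along(os$partitions)) {
    truth <- fx$truth$partitions[[q]]
    mine <- os$partitions[[q]]$membership
    expect_identical(as.integer(factor(mine, levels = unique(mine))),
                     as.integer(factor(truth, levels = unique(truth))))
  }
  # detached peptides carry no intermolecular beta; fully morphed peptide
  # has helix interior residues
  last <- n_frames(fx$trajectory)
  ss <- assign_ss(frame_coords(fx$trajectory, last), fx$system)
  lb <- ss$labels
  expect_true(all(lb$label[lb$mol_id %in% c(1, 4)] != "beta_anti_inter"))
  helix3 <- lb$label[lb$mol_id == 3 & lb$res_local %in% 4:5]
  expect_true(all(helix3 == "helix"))
})

test_that("fixture generation is deterministic", {
  f <- fp_minifibril()
  sc <- dissociation_script(duration = 6, stride = 2,
                            breaks = data.frame(pair = 1, time = 3))
  a <- generate_fixture(sc, f)
  b <- generate_fixture(sc, f)
  expect_identical(a$trajectory$coords, b$trajectory$coords)
})

test_that("conflicting and out-of-range scripts are rejected", {
  expect_error(dissociation_script(10, detach = data.frame(
    peptide = c(2, 2), time = c(1, 2), dx = 40, dy = 0, dz = 0)),
    "detached twice")
  expect_error(dissociation_script(10, detach = data.frame(
    peptide = 1, time = 3, dx = 1, dy = 0, dz = 0)), "cutoff")
  expect_error(dissociation_script(10, breaks = data.frame(
    pair = 1, time = 40)), "within")
  expect_error(dissociation_script(10, morph = data.frame(
    peptide = 1, t_start = 5, t_end = 2)), "t_end")
})

test_that("beta -> helix morph endpoints are the ideal geometries", {
  frames <- generate_ss_morph(peptide_spec(), "beta", "helix", n_frames = 3)
  p <- build_peptide(peptide_spec())
  expect_equal(frames[[1]], p$pos, tolerance = 1e-12)
  h <- build_peptide(peptide_spec(), phi = -57, psi = -47)
  expect_equal(frames[[3]], h$pos, tolerance = 1e-12)
  # endpoint labels as assigned secondary structure
  p$pos <- frames[[3]]
  ss <- assign_ss(frames[[3]], p)
  expect_true(all(ss$labels$label[ss$labels$res_local %in% 4:12] == "helix"))
  # zero-length morph returns the input geometry
  one <- generate_ss_morph(peptide_spec(), "beta", "helix", n_frames = 1)
  expect_equal(one[[1]], build_peptide(peptide_spec())$pos)
})

test_that("a mid-fibril morph removes that peptide's bridges in truth", {
  f <- fp_minifibril()
  sc <- dissociation_script(duration = 8, stride = 4,
                            morph = data.frame(peptide = 2, t_start = 1,
                                               t_end = 5))
  fx <- generate_fixture(sc, f)
  expect_identical(unname(fx$truth$pep_phase[1, ]), rep("beta", 4))
  expect_identical(unname(fx$truth$pep_phase[3, 2]), "helix")
  ss <- assign_ss(frame_coords(fx$trajectory, 3), fx$system)
  expect_false(any(ss$labels$label[ss$labels$mol_id == 2] == "beta_anti_inter"))
})
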