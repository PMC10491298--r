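# Peptide and fibril construction, solvation, and their invariants.

test_that("capped polyalanine peptide has the template-sum atom count", {
  # oracle: ACE 6 + 13 x ALA 10 + NME 6 = 142 sites
  p <- build_peptide(peptide_spec())
  expect_identical(n_atoms(p), 142L)
  expect_identical(sum(p$atoms$res_name == "ALA") %/% 10L, 13L)
  expect_equal(nchar(peptide_spec()$sequence), 13)
  # atom-count closure for other lengths
  for (nres in c(1, 4, 8)) {
    p2 <- build_peptide(peptide_spec(strrep("A", nres)))
    expect_identical(n_atoms(p2), 12L + 10L * as.integer(nres))
  }
})

test_that("peptide construction hits the requested ideal dihedrals", {
  p <- build_peptide(peptide_spec("AAAAA"))
  rm_ <- p$resmap
  for (r in 3:5) {
    phi <- fibrilpulse:::.dihedral(p$pos[rm_$C[r - 1], ], p$pos[rm_$N[r], ],
                                   p$pos[rm_$CA[r], ], p$pos[rm_$C[r], ])
    psi <- fibrilpulse:::.dihedral(p$pos[rm_$N[r], ], p$pos[rm_$CA[r], ],
                                   p$pos[rm_$C[r], ], p$pos[rm_$N[r + 1], ])
    expect_equal(phi, -139, tolerance = 1e-6)
    expect_equal(psi, 135, tolerance = 1e-6)
  }
  # L-configuration: improper N-C-CA-CB near +120 degrees
  imp <- fibrilpulse:::.dihedral(p$pos[rm_$N[3], ], p$pos[rm_$C[3], ],
                                 p$pos[rm_$CA[3], ], p$pos[rm_$CB[3], ])
  expect_gt(imp, 110); expect_lt(imp, 130)
})

test_that("invalid peptide specs are rejected with the residue named", {
  expect_error(peptide_spec(""), "non-empty")
  expect_error(peptide_spec("AXA"), "X")
})

test_that("fibril assembly is antiparallel with a plausible H-bond registry", {
  f <- fp_fibril12()
  expect_identical(n_atoms(f), 1704L)  # 12 x 142, builder-independent count
  # adjacent in-layer strands run antiparallel
  dirs <- sapply(1:12, function(p) {
    r <- f$resmap[f$resmap$mol_id == p, ]
    ca <- r$CA[!is.na(r$CA)]
    d <- f$pos[ca[length(ca)], ] - f$pos[ca[1], ]
    d / sqrt(sum(d^2))
  })
  for (s in 1:5) {
    expect_lt(sum(dirs[, s] * dirs[, s + 1]), 0)
    expect_lt(sum(dirs[, s + 6] * dirs[, s + 7]), 0)
  }
  # designed O...N registry distances within the hydrogen-bond band
  expect_true(all(f$registry$d_ON >= 2.7 & f$registry$d_ON <= 3.3))
  expect_gt(nrow(f$registry), 100)
})

test_that("fibril spec validation", {
  expect_error(fibril_spec(n_peptides = 11, n_layers = 2), "divisible")
  expect_error(fibril_spec(strand_spacing = -1), "positive")
})

test_that("solvation adds exactly the requested three-site waters", {
  f <- fp_minifibril()
  s <- solvate(f, 40, 24, seed = 7)
  expect_identical(n_atoms(s), n_atoms(f) + 120L)
  expect_identical(sum(s$atoms$site == "OW"), 40L)
  # no water oxygen within the exclusion distance of peptide heavy atoms
  ow <- s$atoms$id[s$atoms$site == "OW"]
  hv <- s$atoms$id[s$atoms$heavy & s$atoms$mol_type == "peptide"]
  d <- fibrilpulse:::.dist_pbc(s$pos[ow, ], s$pos[hv, ], s$box)
  expect_gt(min(d), 2.4)
  # n_waters = 0 identity
  s0 <- solvate(f, 0, 24)
  expect_identical(n_atoms(s0), n_atoms(f))
  # charge neutrality survives solvation
  expect_lt(abs(sum(s$atoms$charge)), 1e-9)
})

test_that("an over-full box is refused with the achievable count", {
  expect_error(solvate(empty_system(), 5000, 10), "achievable")
})

test_that("building is deterministic given spec and seed", {
  a <- solvate(build_fibril(fibril_spec(2, 1), peptide_spec("AAA")), 20, 14,
               seed = 9)
  b <- solvate(build_fibril(fibril_spec(2, 1), peptide_spec("AAA")), 20, 14,
               seed = 9)
  expect_identical(a$pos, b$pos)
  c_ <- solvate(build_fibril(fibril_spec(2, 1), peptide_spec("AAA")), 20, 14,
                seed = 10)
  expect_false(identical(b$pos, c_$pos))
})

test_that("built fibril scores mostly intermolecular antiparallel beta", {
  f <- fp_fibril12()
  ss <- assign_ss(f$pos, f)
  expect_gt(mean(ss$labels$label == "beta_anti_inter"), 0.5)
  expect_identical(sum(ss$labels$label == "helix"), 0L)
})
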