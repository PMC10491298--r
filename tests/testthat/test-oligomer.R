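# Oligomer clustering by the 5 A heavy-atom cutoff.

test_that("the built fibril is a single dodecamer", {
  f <- fp_fibril12()
  op <- oligomer_partition(f$pos, f)
  expect_identical(op$sizes, 12L)
  expect_identical(length(unique(op$membership)), 1L)
})

test_that("peptides moved far apart become singletons", {
  f <- fp_minifibril()
  pos <- f$pos
  for (p in 1:4) {
    ids <- f$atoms$id[f$atoms$mol_id == p]
    pos[ids, ] <- sweep(pos[ids, , drop = FALSE], 2, c(0, 50 * p, 0), "+")
  }
  op <- oligomer_partition(pos, f)
  expect_identical(sort(op$sizes), rep(1L, 4))
})

test_that("contact is transitive: A-B and B-C in contact make a trimer", {
  f <- fp_cached("three_singles", {
    build_fibril(fibril_spec(n_peptides = 3, n_layers = 1),
                 peptide_spec("AAA"))
  })
  pos <- f$pos
  idx <- lapply(1:3, function(p) f$atoms$id[f$atoms$mol_id == p])
  # spread along y: A at 0, B at +4.5 (contact), C at +9 (contact with B,
  # beyond cutoff from A)
  base <- pos[idx[[1]], , drop = FALSE]
  for (p in 2:3)
    pos[idx[[p]], ] <- sweep(base, 2, c(0, 4.5 * (p - 1), 0), "+")
  dAC <- min(fibrilpulse:::.dist_pbc(pos[f$atoms$id[f$atoms$mol_id == 1 & f$atoms$heavy], ],
                                     pos[f$atoms$id[f$atoms$mol_id == 3 & f$atoms$heavy], ], NA))
  expect_gt(dAC, 5)
  op <- oligomer_partition(pos, f)
  expect_identical(op$sizes, 3L)
})

test_that("clustering agrees exactly with the brute-force oracle on random frames", {
  f <- fp_cached("six_4res", build_fibril(fibril_spec(6, 1),
                                          peptide_spec("AAAA")))
  set.seed(99)
  for (rep in 1:40) {
    pos <- f$pos
    for (p in 1:6) {
      ids <- f$atoms$id[f$atoms$mol_id == p]
      shift <- runif(3, -9, 9)
      R <- fibrilpulse:::.rot_axis(rnorm(3), runif(1, 0, 2 * pi))
      ctr <- colMeans(pos[ids, , drop = FALSE])
      pos[ids, ] <- sweep(sweep(pos[ids, , drop = FALSE], 2, ctr) %*% t(R),
                          2, ctr + shift, "+")
    }
    mine <- oligomer_partition(pos, f)
    ora <- oracle_oligomers(pos, f)
    # compare as partitions (label-invariant)
    expect_identical(as.integer(factor(mine$membership,
                                       levels = unique(mine$membership))),
                     ora)
  }
})

test_that("window histograms conserve mass and average correctly", {
  f <- fp_minifibril()
  sc <- dissociation_script(duration = 10, stride = 1,
                            detach = data.frame(peptide = c(1, 2),
                                                time = c(3, 7),
                                                dx = c(0, 0),
                                                dy = c(-40, 40), dz = 0))
  fx <- generate_fixture(sc, f)
  os <- oligomer_series(fx$trajectory, fx$system)
  # every window conserves sum(size x count) = 4
  for (w in list(1:3, 4:7, 8:11)) {
    h <- window_histogram(os, frames = w)
    expect_equal(sum(h$size * h$count), 4)
  }
  # identical-partition window returns that partition's histogram exactly
  h <- window_histogram(os, frames = 9:11)   # both detached
  expect_equal(h$count[h$size == 1], 2)
  expect_equal(h$count[h$size == 2], 1)
  expect_error(window_histogram(os, frames = integer(0)), "empty")
})

test_that("scripted detachment schedule reproduces the truth histogram", {
  f <- fp_cached("fib8", build_fibril(fibril_spec(8, 2), peptide_spec("AAAA")))
  det <- data.frame(peptide = 1:5, time = 1:5,
                    dx = c(0, 0, 0, 40, -40),
                    dy = c(-40, 40, 0, 12, 12) * c(1, 1, 0, 1, 1),
                    dz = c(0, 0, 44, 18, 18))
  sc <- dissociation_script(duration = 8, stride = 1, detach = det)
  fx <- generate_fixture(sc, f)
  os <- oligomer_series(fx$trajectory, fx$system)
  h <- window_histogram(os, frames = 7:9)  # all five detached, trimer left
  expect_equal(h$count[h$size == 1], 5)
  expect_equal(h$count[h$size == 3], 1)
  expect_equal(sum(h$size * h$count), 8)
})

test_that("pulse-window frame mapping follows the schedule", {
  field <- pulse_train(n_pulses = 10)
  times <- seq(0, 349.9, by = 0.5)
  fr <- pulse_window_frames(times, field, c(3, 4))
  k <- floor((times[fr] - field$t0_offset) / field$interval + 0.5) + 1
  expect_true(all(k %in% 3:4))
  expect_identical(length(pulse_window_frames(times, field, c(11, 12))), 0L)
})
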