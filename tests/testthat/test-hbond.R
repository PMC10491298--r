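# Hydrogen-bond kinetics: criterion, break detection, event alignment,
# periodicity.

one_frame_traj <- function(pos) {
  coords <- array(pos, dim = c(nrow(pos), 3, 1))
  structure(list(times = 0, coords = coords, box = NA_real_,
                 meta = list(n_atoms = nrow(pos))), class = "fp_trajectory")
}

test_that("designed registry pairs are all formed in the ideal fibril", {
  f <- fp_fibril12()
  traj <- one_frame_traj(f$pos)
  hb <- hbond_series(traj, f)
  expect_true(all(hb$pep[1, ]))
})

test_that("water classes are false when no water is near the peptide", {
  f <- fp_minifibril()
  s <- solvate(f, 10, 60, seed = 3)   # huge box, waters mostly far away
  # push all waters far from the peptide
  ww <- s$atoms$id[s$atoms$mol_type == "water"]
  s$pos[ww, ] <- sweep(s$pos[ww, , drop = FALSE] * 0, 2, c(55, 55, 55), "+") +
    matrix(4 * seq_along(ww), ncol = 3, nrow = length(ww))
  traj <- one_frame_traj(s$pos)
  hb <- hbond_series(traj, s)
  expect_false(any(hb$co_wat))
  expect_false(any(hb$nh_wat))
})

test_that("a degenerate 0.1 A criterion forms no bonds", {
  f <- fp_fibril12()
  hb <- hbond_series(one_frame_traj(f$pos), f,
                     criterion = hbond_criterion(distance = 0.1))
  expect_false(any(hb$pep))
})

test_that("criterion validation", {
  expect_error(hbond_criterion(distance = 0), ">")
  expect_error(hbond_criterion(angle = 0))
  expect_error(hbond_criterion(angle = 190))
})

test_that("irreversible break time follows the last-transition rule", {
  times <- 0:4
  b <- irreversible_break_time(c(TRUE, TRUE, FALSE, FALSE, FALSE), times)
  expect_identical(b$frame, 3L)
  expect_identical(b$time, 2L)
  b2 <- irreversible_break_time(c(TRUE, FALSE, TRUE, FALSE, FALSE), times)
  expect_identical(b2$frame, 4L)   # the SECOND 1 -> 0 transition
  expect_null(irreversible_break_time(c(TRUE, TRUE, TRUE), 0:2))
  expect_null(irreversible_break_time(c(FALSE, FALSE), 0:1))
})

test_that("the censoring margin removes exactly the late event", {
  times <- seq(0, 10, by = 1)
  s <- c(rep(TRUE, 9), FALSE, FALSE)   # break at t = 9
  expect_false(is.null(irreversible_break_time(s, times, margin = 1)))
  expect_null(irreversible_break_time(s, times, margin = 5))
})

test_that("single-event alignment is the identity shift", {
  f <- fp_minifibril()
  sc <- dissociation_script(duration = 20, stride = 1,
                            breaks = data.frame(pair = 2, time = 8))
  fx <- generate_fixture(sc, f)
  hb <- hbond_series(fx$trajectory, fx$system,
                     pairs = fx$system$registry[2, , drop = FALSE])
  ev <- break_events(hb)
  expect_identical(nrow(ev), 1L)
  prof <- aligned_average(hb, ev, window = 6)
  expect_true(all(prof$pep[prof$tau < 0] == 1))
  expect_true(all(prof$pep[prof$tau >= 0] == 0))
  expect_true(all(prof$n == 1))
})

test_that("scripted breaks are recovered at exactly the scheduled frames", {
  f <- fp_minifibril()
  sc <- dissociation_script(duration = 30, stride = 1,
                            breaks = data.frame(pair = c(1, 5, 9),
                                                time = c(7, 13, 22)))
  fx <- generate_fixture(sc, f)
  hb <- hbond_series(fx$trajectory, fx$system,
                     pairs = fx$system$registry[c(1, 5, 9), ])
  ev <- break_events(hb)
  expect_identical(ev$frame, fx$truth$breaks$frame)
  expect_identical(ev$time, fx$truth$breaks$time)
})

test_that("water arrives after the break in the aligned profiles", {
  f <- fp_minifibril()
  sc <- dissociation_script(duration = 30, stride = 1,
                            breaks = data.frame(pair = c(3, 7),
                                                time = c(10, 16)),
                            water_arrival = data.frame(pair = c(3, 7),
                                                       time = c(12, 18)))
  fx <- generate_fixture(sc, f)
  hb <- hbond_series(fx$trajectory, fx$system,
                     pairs = fx$system$registry[c(3, 7), ])
  ev <- break_events(hb)
  prof <- aligned_average(hb, ev, window = 8)
  before <- prof$tau < 0
  after <- prof$tau >= 2
  expect_true(all(prof$pep[before] == 1))
  expect_true(all(prof$pep[!before] == 0))
  expect_true(all(prof$co_wat[before] == 0))
  expect_true(all(prof$nh_wat[before] == 0))
  expect_true(all(prof$co_wat[after] == 1))
  expect_true(all(prof$nh_wat[after] == 1))
})

test_that("zero events is a distinct error", {
  f <- fp_minifibril()
  hb <- hbond_series(one_frame_traj(f$pos), f)
  expect_error(aligned_average(hb, break_events(hb)), "no break events")
})

test_that("all-zero water series stay flat zero in the profile", {
  f <- fp_minifibril()
  sc <- dissociation_script(duration = 20, stride = 1,
                            breaks = data.frame(pair = 4, time = 9))
  fx <- generate_fixture(sc, f)   # no water_arrival: no waters at all
  hb <- hbond_series(fx$trajectory, fx$system,
                     pairs = fx$system$registry[4, , drop = FALSE])
  prof <- aligned_average(hb, break_events(hb), window = 6)
  expect_true(all(prof$co_wat == 0))
  expect_true(all(prof$nh_wat == 0))
})

test_that("pulse periodicity recovers square-wave periods specifically", {
  dt <- 0.5
  tt <- seq(0, 350, by = dt)
  sq35 <- as.numeric((tt %% 35) < 17.5)
  expect_equal(pulse_periodicity(sq35, dt), 35, tolerance = 0.01)
  sq70 <- as.numeric((tt %% 70) < 35)
  p70 <- pulse_periodicity(sq70, dt)
  expect_equal(p70, 70, tolerance = 0.01)
  expect_gt(abs(p70 - 35), 10)
  expect_true(is.na(pulse_periodicity(rep(1, 700), dt)))
  expect_error(pulse_periodicity(c(1, 0, 1), dt), "too short")
})
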