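test_that("two-residue builds are valid but both residues stay undefined", {
  bb <- build_backbone("AV", phi = -60, psi = -45)
  expect_equal(nrow(bb), 2)
  st <- residue_states(bb)
  expect_true(is.na(st$phi[1]))
  expect_true(is.na(st$psi[2]))
  # each terminus lacks one dihedral, so neither residue is classifiable
  expect_equal(st$state, c("U", "U"))
})

test_that("impossible geometry is rejected", {
  expect_error(build_backbone("AAAAA", phi = 0, psi = 0, omega = 0),
               "impossible geometry")
})

test_that("ideal strands alternate from the requested start state", {
  st_r <- residue_states(ideal_alpha_strand("VGSNK", start_state = "R"))
  expect_equal(st_r$state[2:6], c("R", "L", "R", "L", "R"))
  st_l <- residue_states(ideal_alpha_strand("VGSNK", start_state = "L"))
  expect_equal(st_l$state[2:6], c("L", "R", "L", "R", "L"))
  # one maximal run spanning exactly the named residues, either start
  expect_equal(nrow(find_alternating_runs(st_r)), 1)
  expect_equal(find_alternating_runs(st_l)$length, 5)

  # minimal strand: exactly one RLR hit
  hits <- scan_structure(ideal_alpha_strand("VGS"), motif = "VGS",
                         required_start = "R")
  expect_equal(nrow(hits), 1)
  expect_equal(hits$pattern, "RLR")
})

test_that("zero-rate simulations stay at the initial state", {
  sim <- simulate_states(n_residues = 3, n_frames = 50,
                         baseline_states = c("R", "L", "R"),
                         flip_on_prob = 0, flip_off_prob = 0,
                         start_flipped = FALSE, seed = 1)
  expect_true(all(sim$states$states == matrix(c("R", "L", "R"), 50, 3,
                                              byrow = TRUE)))
  # started flipped, it stays flipped
  sim2 <- simulate_states(n_residues = 3, n_frames = 50,
                          baseline_states = c("R", "L", "R"),
                          flip_on_prob = 0, flip_off_prob = 0,
                          start_flipped = TRUE, seed = 1)
  expect_true(all(sim2$states$states == matrix(c("L", "R", "L"), 50, 3,
                                               byrow = TRUE)))
})

test_that("symmetric flip rates reach the half-flipped stationary state", {
  sim <- simulate_states(n_residues = 1, n_frames = 5000,
                         baseline_states = "R", flip_on_prob = 0.1,
                         flip_off_prob = 0.1, seed = 7)
  frac <- sim$manifest$transitions$flipped_frames / 5000
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 5000) * sqrt(2 / 0.2))
})

test_that("planted windows override sampling and are recorded exactly", {
  frames <- c(100:149, 300)
  sim <- simulate_states(n_residues = 5, n_frames = 1000,
                         flip_on_prob = 0.1, flip_off_prob = 0.1,
                         planted_window = list(window = 24:26,
                                               pattern = "RLR",
                                               frames = frames),
                         seed = 9)
  ws <- window_summary(sim$states, 24:26, "RLR")
  expect_gte(ws$frame_count, 51)
  expect_lte(ws$first_appearance_ps, 100 * 2)
  expect_equal(ws$frame_count, sim$manifest$planted_frame_count)
  expect_equal(which(ws$match_mask), which(sim$manifest$planted_match_mask))
  expect_lte(sim$manifest$planted_first_frame, 100)
})

test_that("simulations are reproducible and seed-sensitive", {
  a <- simulate_states(n_frames = 200, seed = 5)
  b <- simulate_states(n_frames = 200, seed = 5)
  c <- simulate_states(n_frames = 200, seed = 6)
  expect_identical(a$states$states, b$states$states)
  expect_false(identical(a$states$states, c$states$states))
})

test_that("simulate_states leaves the caller's RNG stream untouched", {
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(simulate_states(n_frames = 100, seed = 3))
  after <- runif(1)
  expect_identical(before, after)
})

test_that("planted collections are deterministic and self-consistent", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- plant_collection(d1, n_entries = 6, n_with_hits = 3,
                         occurrences = c(1, 2, 3), seed = 11)
  m2 <- plant_collection(d2, n_entries = 6, n_with_hits = 3,
                         occurrences = c(1, 2, 3), seed = 11)
  f1 <- list.files(d1, full.names = TRUE)
  f2 <- list.files(d2, full.names = TRUE)
  expect_equal(basename(f1), basename(f2))
  for (k in seq_along(f1)) {
    expect_identical(readLines(f1[k]), readLines(f2[k]))
  }
  expect_equal(m1$totals$total_occurrences, 6)
  expect_equal(m1$totals$structures_with_hits, 3)
  expect_equal(sum(m1$entries$n_occurrences), nrow(m1$hits))
})
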