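constant_frames <- function(n_frames, phi, psi, labels = c("A1", "A2", "A3")) {
  tibble::tibble(
    frame = rep(seq_len(n_frames) - 1L, each = length(labels)),
    residue_label = rep(labels, n_frames),
    phi = phi, psi = psi
  )
}

test_that("state matrices classify per cell and reject ragged frames", {
  sm <- state_matrix(constant_frames(4, -60, -45))
  expect_equal(dim(sm$states), c(4, 3))
  expect_true(all(sm$states == "R"))
  expect_equal(sm$frame_times_ps, c(0, 2, 4, 6))

  ragged <- constant_frames(4, -60, -45)[-2, ]
  expect_error(state_matrix(ragged), "ragged|same residues")
})

test_that("window summaries count frames, events and first appearance", {
  sim <- simulate_states(
    n_residues = 3, n_frames = 100, stride_ps = 2,
    baseline_states = c("R", "R", "R"),
    residue_labels = c("V24", "G25", "S26"),
    flip_on_prob = 0, flip_off_prob = 0, start_flipped = TRUE,
    planted_window = list(window = 24:26, pattern = "RLR",
                          frames = c(10, 11, 12, 40)),
    seed = 5
  )
  ws <- window_summary(sim$states, 24:26, "RLR")
  expect_equal(ws$frame_count, 4)
  expect_equal(ws$event_count, 2)
  expect_equal(ws$first_appearance_ps, 20)
  expect_equal(ws$first_appearance_ns, 0.02)
  expect_equal(ws$occupancy_fraction, 0.04)

  none <- window_summary(sim$states, 24:26, "LRL")
  expect_equal(none$frame_count, 0)
  expect_true(is.na(none$first_appearance_ps))
  expect_error(window_summary(sim$states, 30:32, "RLR"), "not present")
})

test_that("frame and event counts are mutually consistent", {
  set.seed(51)
  for (i in 1:20) {
    frames <- sort(sample(0:199, sample(0:60, 1)))
    sim <- simulate_states(
      n_residues = 3, n_frames = 200,
      baseline_states = c("R", "R", "R"),
      residue_labels = c("V24", "G25", "S26"),
      flip_on_prob = 0, flip_off_prob = 0,
      planted_window = if (length(frames)) list(window = 24:26,
                                                pattern = "RLR",
                                                frames = frames) else NULL,
      seed = i
    )
    ws <- window_summary(sim$states, 24:26, "RLR")
    mask <- ws$match_mask
    expect_equal(ws$frame_count, length(frames))
    expect_equal(ws$frame_count + sum(!mask), ws$n_frames)
    expect_gte(ws$occupancy_fraction, 0)
    expect_lte(ws$occupancy_fraction, 1)
    expect_equal(ws$event_count, sum(diff(c(0, as.integer(mask))) == 1))
    expect_lte(ws$event_count, max(ws$frame_count, 1))
  }
})

test_that("relaxing the pattern never delays the first appearance", {
  sim <- simulate_states(n_frames = 5000, flip_on_prob = 0.05,
                         flip_off_prob = 0.05, seed = 6)
  w26 <- window_summary(sim$states, 24:26, "RLR")
  w27 <- window_summary(sim$states, 24:27, "RLRL")
  w28 <- window_summary(sim$states, 24:28, "RLRLR")
  expect_gte(w26$frame_count, w27$frame_count)
  expect_gte(w27$frame_count, w28$frame_count)
  if (!is.na(w27$first_appearance_ps)) {
    expect_lte(w26$first_appearance_ps, w27$first_appearance_ps)
  }
  if (!is.na(w28$first_appearance_ps)) {
    expect_lte(w27$first_appearance_ps, w28$first_appearance_ps)
  }
  # the longer window's matches are a subset of the shorter's
  expect_true(all(which(w28$match_mask) %in% which(w27$match_mask)))
  expect_true(all(which(w27$match_mask) %in% which(w26$match_mask)))
})

test_that("transition traces flag state-change frames", {
  fr <- constant_frames(10, -120, 130, labels = c("S26"))
  fr$phi[8:10] <- -60
  fr$psi[8:10] <- -45
  tr <- transition_trace(fr, "S26")
  expect_equal(nrow(tr), 10)
  expect_equal(tr$state[7:8], c("O", "R"))
  expect_equal(which(tr$changed), 8)   # frame index 7, 0-based

  flat <- transition_trace(constant_frames(5, -60, -45, "G25"), "G25")
  expect_equal(sum(flat$changed), 0)
  expect_error(transition_trace(fr, "Z99"), "absent")
})

test_that("peptide-plane flips require concerted psi(i)/phi(i+1) change", {
  fr <- tibble::tibble(
    frame = rep(0:1, each = 3),
    residue_label = rep(c("V24", "G25", "S26"), 2),
    phi = c(-60, 60, -60, -60, 60, 120),
    psi = c(-45, -45, 150, -45, 150, 150)
  )
  # G25 psi -45 -> 150 (|delta| 165), S26 phi -60 -> 120 (|delta| 180),
  # neighbours unchanged
  ev <- detect_flips(fr)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$res_i, "G25")
  expect_equal(ev$res_i_plus_1, "S26")
  expect_equal(abs(ev$delta_psi_i), 165)
  expect_equal(abs(ev$delta_phi_ip1), 180)

  # a uniform 10-degree drift is below threshold
  drift <- tibble::tibble(
    frame = rep(0:1, each = 3),
    residue_label = rep(c("V24", "G25", "S26"), 2),
    phi = c(-60, 60, -60, -50, 70, -50),
    psi = c(-45, 45, -45, -35, 55, -35)
  )
  expect_equal(nrow(detect_flips(drift)), 0)
})

test_that("a flip and its reversal give two consecutive events and no net change", {
  fr <- flip_fixture(n_frames = 6, toggle_frames = c(2, 4))
  ev <- detect_flips(fr, compare = "consecutive")
  expect_equal(nrow(ev), 2)
  expect_equal(ev$frame_to, c(2, 4))
  expect_equal(ev$res_i, c("G25", "G25"))

  vi <- detect_flips(fr, compare = "vs_initial")
  # at the final frame the plane is back at its initial orientation
  expect_equal(nrow(vi[vi$frame_to == 5, ]), 0)
  expect_true(all(vi$frame_from == 0))
})

test_that("flip detection is symmetric under time reversal", {
  set.seed(52)
  fr <- flip_fixture(n_frames = 40, toggle_frames = sort(sample(1:39, 7)))
  fwd <- detect_flips(fr, compare = "consecutive")
  rev <- fr
  rev$frame <- max(fr$frame) - rev$frame
  bwd <- detect_flips(dplyr::arrange(rev, frame), compare = "consecutive")
  expect_equal(nrow(fwd), nrow(bwd))
  expect_equal(sort(max(fr$frame) - fwd$frame_to + 1), sort(bwd$frame_to))
})
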