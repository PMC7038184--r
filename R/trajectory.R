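new_state_matrix <- function(states, residue_labels, frame_times_ps,
                             stride_ps = NA_real_) {
  stopifnot(is.matrix(states), ncol(states) == length(residue_labels),
            nrow(states) == length(frame_times_ps))
  structure(
    list(states = states, residue_labels = residue_labels,
         frame_times_ps = as.numeric(frame_times_ps),
         stride_ps = stride_ps),
    class = "state_matrix"
  )
}

#' @export
print.state_matrix <- function(x, ...) {
  cat(sprintf(
    "<state_matrix> %d frames x %d residues (%s)\n",
    nrow(x$states), length(x$residue_labels),
    paste(x$residue_labels, collapse = " ")
  ))
  occ <- colMeans(x$states == "R" | x$states == "L")
  cat("fraction of frames in an alpha quadrant, per residue:\n")
  print(round(setNames(occ, x$residue_labels), 3))
  invisible(x)
}

#' Frames x residues conformational state matrix
#'
#' Turns per-frame dihedral records into the trajectory abstraction used
#' by the window analyses: a rectangular grid of conformational states
#' with one row per frame and one column per residue, classified with
#' [classify_state()]. Every frame must cover the same residues in the
#' same order.
#'
#' @param frames A long tibble with columns `frame`, `residue_label`,
#'   `phi`, `psi` and optionally `time_ps` -- the shape produced by
#'   [read_dihedral_table()].
#' @param stride_ps Frame spacing in ps, used for frame times when the
#'   table has no `time_ps` column.
#' @return A `state_matrix` object: fields `states` (character matrix),
#'   `residue_labels`, `frame_times_ps`, `stride_ps`.
#' @export
state_matrix <- function(frames, stride_ps = 2) {
  stopifnot(all(c("frame", "residue_label", "phi", "psi") %in% names(frames)))
  frames <- frames |> arrange(.data$frame)
  ids <- unique(frames$frame)
  labels <- frames$residue_label[frames$frame == ids[1]]
  counts <- table(frames$frame)
  if (length(unique(counts)) > 1) {
    bad <- names(counts)[counts != length(labels)][1]
    abort(paste0("ragged frames: frame ", bad, " covers ", counts[[bad]],
                 " residues, expected ", length(labels)))
  }
  per_frame <- split(frames, frames$frame)
  for (f in per_frame) {
    if (!identical(f$residue_label, labels)) {
      abort(paste0("frame ", f$frame[1],
                   " does not cover the same residues in the same order"))
    }
  }
  st <- classify_state(frames$phi, frames$psi)
  mat <- matrix(st, nrow = length(ids), ncol = length(labels), byrow = TRUE)
  times <- if ("time_ps" %in% names(frames)) {
    vapply(per_frame, function(f) f$time_ps[1], numeric(1))
  } else {
    ids * stride_ps
  }
  new_state_matrix(mat, labels, times, stride_ps = stride_ps)
}

# residue label / author-number lookup into a state_matrix
window_indices <- function(sm, window) {
  if (is.numeric(window)) {
    nums <- suppressWarnings(as.integer(str_match(sm$residue_labels,
                                                  "(\\d+)")[, 2]))
    idx <- match(window, nums)
  } else {
    idx <- match(window, sm$residue_labels)
  }
  if (anyNA(idx)) {
    abort(paste0("window residue '", window[which(is.na(idx))[1]],
                 "' not present in the state matrix"))
  }
  idx
}

#' Per-window alpha-strand occupancy of a trajectory
#'
#' For an anchored residue window and an alternating pattern, computes
#' the per-frame match mask and the counting statistics used to
#' summarise a trajectory: `frame_count` (number of frames in which the
#' window spells the pattern -- the per-region "number of alpha-strands"
#' reported for a run), `event_count` (maximal runs of consecutive
#' matching frames, i.e. distinct formation events), the
#' first-appearance time, and the occupancy fraction. Appearance time is
#' additionally reported in ns, the natural axis unit for 50-ns scale
#' runs; a window that never matches has an explicit `NA` appearance
#' time rather than a sentinel.
#'
#' @param sm A [state_matrix()].
#' @param window Author residue numbers (matched against digits in the
#'   residue labels) or exact residue labels; consecutive, same length
#'   as `pattern`.
#' @param pattern Alternating pattern string, e.g. `"RLR"`.
#' @return A `window_summary` object; see [tidy()] and [glance()]
#'   methods.
#' @export
window_summary <- function(sm, window, pattern) {
  assert_pattern(pattern)
  idx <- window_indices(sm, window)
  if (length(idx) != nchar(pattern)) {
    abort("window and pattern lengths differ")
  }
  pat <- strsplit(pattern, "")[[1]]
  sub <- sm$states[, idx, drop = FALSE]
  mask <- rowSums(sub == matrix(pat, nrow(sub), length(pat), byrow = TRUE)) ==
    length(pat)
  frame_count <- sum(mask)
  event_count <- sum(diff(c(FALSE, mask)) == 1)
  first_ps <- if (frame_count > 0) sm$frame_times_ps[which(mask)[1]] else NA_real_
  structure(
    list(
      window = window, residue_labels = sm$residue_labels[idx],
      pattern = pattern, match_mask = mask,
      frame_times_ps = sm$frame_times_ps,
      n_frames = length(mask), frame_count = frame_count,
      event_count = event_count,
      first_appearance_ps = first_ps,
      first_appearance_ns = first_ps / 1000,
      occupancy_fraction = frame_count / length(mask)
    ),
    class = "window_summary"
  )
}

#' @export
print.window_summary <- function(x, ...) {
  cat(sprintf(
    "<window_summary> %s on window %s\n", x$pattern,
    paste(x$residue_labels, collapse = "-")
  ))
  cat(sprintf(
    "  %d / %d frames match (occupancy %.3f), %d distinct events\n",
    x$frame_count, x$n_frames, x$occupancy_fraction, x$event_count
  ))
  if (is.na(x$first_appearance_ps)) {
    cat("  first appearance: absent\n")
  } else {
    cat(sprintf("  first appearance: %g ps (%g ns)\n",
                x$first_appearance_ps, x$first_appearance_ns))
  }
  invisible(x)
}

#' Dihedral and state time series of one residue
#'
#' Extracts the full (time, phi, psi, state) series of one residue from
#' per-frame dihedral records and flags the frames at which the state
#' changes, supporting "initial structure vs first alpha-strand"
#' comparisons.
#'
#' @param frames Long dihedral tibble as for [state_matrix()].
#' @param residue Residue label to trace.
#' @return A tibble `frame`, `time_ps`, `phi`, `psi`, `state`, `changed`
#'   (`TRUE` where the state differs from the previous frame).
#' @export
transition_trace <- function(frames, residue) {
  sub <- frames[frames$residue_label == residue, , drop = FALSE]
  if (nrow(sub) == 0) {
    abort(paste0("residue '", residue, "' absent from the dihedral frames"))
  }
  sub <- sub |> arrange(.data$frame)
  if (!"time_ps" %in% names(sub)) sub$time_ps <- sub$frame * 2
  sub$state <- classify_state(sub$phi, sub$psi)
  sub$changed <- c(FALSE, sub$state[-1] != sub$state[-nrow(sub)])
  sub |>
    select("frame", "time_ps", "phi", "psi", "state", "changed")
}

#' Detect peptide-plane flips in a dihedral trajectory
#'
#' A peptide-plane flip is a concerted rotation of the rigid CO--NH unit
#' between residues i and i+1: psi(i) and phi(i+1) change together by a
#' large amount while the flanking torsions phi(i) and psi(i+1) stay
#' put. For each plane and each compared frame pair this emits an event
#' when both circular changes reach `theta_deg` (default 90 degrees, the
#' scale of a quadrant crossing) while both neighbour changes stay below
#' `neighbor_theta_deg`. Differences are circular, wrapping through
#' +/-180.
#'
#' @param frames Long dihedral tibble as for [state_matrix()]; at least
#'   two frames.
#' @param theta_deg Flip threshold in degrees, in (0, 180].
#' @param neighbor_theta_deg Maximum allowed neighbour-torsion change.
#' @param compare `"consecutive"` compares each frame with the previous
#'   one; `"vs_initial"` compares every frame with the first, the
#'   superposition view used for initial-vs-first-strand figures.
#' @return A tibble of flip events: `res_i`, `res_i_plus_1`,
#'   `frame_from`, `frame_to`, `delta_psi_i`, `delta_phi_ip1`,
#'   `delta_phi_i`, `delta_psi_ip1`.
#' @export
detect_flips <- function(frames, theta_deg = 90, neighbor_theta_deg = 90,
                         compare = c("consecutive", "vs_initial")) {
  compare <- match.arg(compare)
  if (theta_deg <= 0 || theta_deg > 180) abort("theta_deg must be in (0, 180]")
  frames <- frames |> arrange(.data$frame)
  ids <- unique(frames$frame)
  if (length(ids) < 2) abort("flip detection needs at least two frames")
  labels <- frames$residue_label[frames$frame == ids[1]]
  nres <- length(labels)
  if (nrow(frames) != length(ids) * nres) {
    abort("every frame must cover the same residues")
  }
  phi <- matrix(frames$phi, nrow = length(ids), ncol = nres, byrow = TRUE)
  psi <- matrix(frames$psi, nrow = length(ids), ncol = nres, byrow = TRUE)
  pairs <- if (compare == "consecutive") {
    cbind(seq_len(length(ids) - 1), seq_len(length(ids) - 1) + 1)
  } else {
    cbind(rep(1L, length(ids) - 1), seq_len(length(ids) - 1) + 1)
  }
  out <- lapply(seq_len(nrow(pairs)), function(k) {
    a <- pairs[k, 1]; b <- pairs[k, 2]
    dphi <- circular_diff(phi[b, ], phi[a, ])
    dpsi <- circular_diff(psi[b, ], psi[a, ])
    i <- seq_len(nres - 1)
    hit <- !is.na(dpsi[i]) & !is.na(dphi[i + 1]) &
      abs(dpsi[i]) >= theta_deg & abs(dphi[i + 1]) >= theta_deg &
      (is.na(dphi[i]) | abs(dphi[i]) < neighbor_theta_deg) &
      (is.na(dpsi[i + 1]) | abs(dpsi[i + 1]) < neighbor_theta_deg)
    if (!any(hit)) return(NULL)
    w <- i[hit]
    tibble(
      res_i = labels[w], res_i_plus_1 = labels[w + 1],
      frame_from = ids[a], frame_to = ids[b],
      delta_psi_i = dpsi[w], delta_phi_ip1 = dphi[w + 1],
      delta_phi_i = dphi[w], delta_psi_ip1 = dpsi[w + 1]
    )
  })
  res <- bind_rows(out)
  if (nrow(res) == 0) {
    res <- tibble(res_i = character(), res_i_plus_1 = character(),
                  frame_from = integer(), frame_to = integer(),
                  delta_psi_i = numeric(), delta_phi_ip1 = numeric(),
                  delta_phi_i = numeric(), delta_psi_ip1 = numeric())
  }
  res
}
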