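#' Tidy a state matrix into a long tibble
#'
#' @param x A [state_matrix()].
#' @param ... Unused.
#' @return A tibble `frame` (0-based), `time_ps`, `residue_label`,
#'   `state`, one row per (frame, residue).
#' @export
tidy.state_matrix <- function(x, ...) {
  n_frames <- nrow(x$states)
  n_res <- length(x$residue_labels)
  tibble(
    frame = rep(seq_len(n_frames) - 1L, times = n_res),
    time_ps = rep(x$frame_times_ps, times = n_res),
    residue_label = rep(x$residue_labels, each = n_frames),
    state = as.vector(x$states)
  )
}

#' Per-frame match table of a window summary
#'
#' @param x A [window_summary()].
#' @param ... Unused.
#' @return A tibble `frame`, `time_ps`, `match`.
#' @export
tidy.window_summary <- function(x, ...) {
  tibble(
    frame = seq_along(x$match_mask) - 1L,
    time_ps = x$frame_times_ps,
    match = x$match_mask
  )
}

#' One-row statistics of a window summary
#'
#' @param x A [window_summary()].
#' @param ... Unused.
#' @return A one-row tibble: `window`, `pattern`, `n_frames`,
#'   `frame_count`, `event_count`, `first_appearance_ps`,
#'   `first_appearance_ns`, `occupancy_fraction`.
#' @export
glance.window_summary <- function(x, ...) {
  tibble(
    window = paste(x$residue_labels, collapse = "-"),
    pattern = x$pattern,
    n_frames = x$n_frames,
    frame_count = x$frame_count,
    event_count = x$event_count,
    first_appearance_ps = x$first_appearance_ps,
    first_appearance_ns = x$first_appearance_ns,
    occupancy_fraction = x$occupancy_fraction
  )
}

#' Per-entry table of a collection report
#'
#' @param x A [mine_collection()] report.
#' @param ... Unused.
#' @return The per-entry tibble.
#' @export
tidy.collection_report <- function(x, ...) {
  x$per_entry
}

#' Census totals of a collection report
#'
#' @param x A [mine_collection()] report.
#' @param ... Unused.
#' @return A one-row tibble of the census totals.
#' @export
glance.collection_report <- function(x, ...) {
  as_tibble(x$totals)
}

#' Ground-truth summary of a simulated trajectory
#'
#' @param x A [simulate_states()] result.
#' @param ... Unused.
#' @return A one-row tibble of the simulation parameters and planted
#'   ground truth.
#' @export
glance.sim_result <- function(x, ...) {
  p <- x$manifest$params
  tibble(
    n_residues = p$n_residues, n_frames = p$n_frames,
    stride_ps = p$stride_ps, flip_on_prob = p$flip_on_prob,
    flip_off_prob = p$flip_off_prob, seed = p$seed,
    planted_frame_count = x$manifest$planted_frame_count,
    planted_first_frame = x$manifest$planted_first_frame
  )
}

#' @export
tidy.sim_result <- function(x, ...) {
  tidy(x$states)
}
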