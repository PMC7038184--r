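STATE_FILL <- c(R = "#1b7837", L = "#762a83", O = "grey85", U = "white")

#' Ramachandran plot with sign-quadrant shading
#'
#' Scatter plot of (phi, psi) with the two alpha-strand quadrants
#' shaded: alpha_R (both negative) and alpha_L (both positive). Accepts
#' the output of [compute_phi_psi()] or [residue_states()].
#'
#' @param dihedrals A tibble with `phi` and `psi` columns (and
#'   optionally `state`).
#' @return A ggplot object.
#' @export
plot_ramachandran <- function(dihedrals) {
  quads <- tibble(
    xmin = c(-180, 0), xmax = c(0, 180), ymin = c(-180, 0),
    ymax = c(0, 180), region = c("alpha_R", "alpha_L")
  )
  d <- dihedrals |> filter(!is.na(.data$phi) & !is.na(.data$psi))
  p <- ggplot(d, aes(x = .data$phi, y = .data$psi)) +
    geom_rect(
      data = quads, inherit.aes = FALSE, alpha = 0.12,
      aes(xmin = .data$xmin, xmax = .data$xmax, ymin = .data$ymin,
          ymax = .data$ymax, fill = .data$region)
    ) +
    scale_fill_manual(values = c(alpha_R = "#1b7837", alpha_L = "#762a83"),
                      name = NULL)
  p <- if ("state" %in% names(d)) {
    p + geom_point(aes(colour = .data$state), size = 1) +
      scale_colour_manual(values = STATE_FILL, name = "state")
  } else {
    p + geom_point(size = 1)
  }
  p +
    coord_fixed(xlim = c(-180, 180), ylim = c(-180, 180), expand = FALSE) +
    labs(x = expression(phi ~ "(deg)"), y = expression(psi ~ "(deg)")) +
    theme_bw()
}

#' Heatmap of a conformational state matrix
#'
#' @param object A [state_matrix()].
#' @param ... Unused.
#' @return A ggplot object: frames on x, residues on y, tiles coloured
#'   by state.
#' @export
autoplot.state_matrix <- function(object, ...) {
  d <- tidy(object)
  d$residue_label <- factor(d$residue_label, levels = object$residue_labels)
  ggplot(d, aes(x = .data$time_ps / 1000, y = .data$residue_label,
                fill = .data$state)) +
    geom_tile() +
    scale_fill_manual(values = STATE_FILL, name = "state") +
    labs(x = "time (ns)", y = NULL) +
    theme_minimal()
}

#' Match trace of a window summary
#'
#' @param object A [window_summary()].
#' @param ... Unused.
#' @return A ggplot object: per-frame window match against time, with
#'   the first-appearance time marked.
#' @export
autoplot.window_summary <- function(object, ...) {
  d <- tidy(object)
  p <- ggplot(d, aes(x = .data$time_ps / 1000, y = as.integer(.data$match))) +
    geom_step(colour = "#1b7837") +
    scale_y_continuous(breaks = c(0, 1), labels = c("no", "match")) +
    labs(
      x = "time (ns)", y = NULL,
      title = sprintf("%s on %s: %d frames, %d events",
                      object$pattern,
                      paste(object$residue_labels, collapse = "-"),
                      object$frame_count, object$event_count)
    ) +
    theme_minimal()
  if (!is.na(object$first_appearance_ps)) {
    p <- p + geom_vline(xintercept = object$first_appearance_ns,
                        linetype = "dashed", colour = "grey40")
  }
  p
}

#' Method-stratified occurrence counts of a collection report
#'
#' @param object A [mine_collection()] report.
#' @param ... Unused.
#' @return A ggplot bar chart of structures-with-hits and occurrences
#'   per experimental method.
#' @export
autoplot.collection_report <- function(object, ...) {
  d <- object$by_method |>
    tidyr::pivot_longer(c("structures_with_hits", "occurrences"),
                        names_to = "quantity", values_to = "count")
  ggplot(d, aes(x = .data$method, y = .data$count, fill = .data$quantity)) +
    geom_col(position = "dodge") +
    scale_fill_brewer(palette = "Paired", name = NULL) +
    labs(x = NULL, y = "count") +
    theme_minimal()
}
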