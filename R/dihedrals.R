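# C(i)-N(i+1) distance beyond which the chain is treated as broken and
# dihedrals across the gap are undefined (a peptide bond is ~1.33 A)
BREAK_DISTANCE <- 2.5

#' Backbone dihedrals of every residue in a structure
#'
#' Computes phi, psi (and optionally omega) for each residue of a
#' `backbone_tbl`, per model and chain:
#' phi(i) from C(i-1)-N(i)-CA(i)-C(i), psi(i) from N(i)-CA(i)-C(i)-N(i+1),
#' omega(i) from CA(i-1)-C(i-1)-N(i)-CA(i). Dihedrals are undefined at
#' chain termini and across chain breaks -- a break is any consecutive
#' residue pair whose C--N distance exceeds 2.5 Angstrom (or with the
#' bridging atoms missing), so a numbering gap with intact geometry does
#' not by itself sever the chain, while a physical gap always does.
#'
#' @param x A `backbone_tbl` from [read_structures()] or
#'   [build_backbone()].
#' @param chain Optional chain id to restrict to; an unknown chain is an
#'   error.
#' @param model Optional model index to restrict to.
#' @param omega If `TRUE`, also report omega.
#' @return A tibble with one row per residue in chain order: `entry_id`,
#'   `model`, `chain`, `res_seq`, `ins`, `resname`, `aa`, `phi`, `psi`
#'   (and `omega`), and logical `phi_defined`, `psi_defined`. Undefined
#'   angles are `NA`.
#' @export
#' @examples
#' bb <- ideal_alpha_strand("VGSNK")
#' compute_phi_psi(bb)
compute_phi_psi <- function(x, chain = NULL, model = NULL, omega = FALSE) {
  x <- restrict_backbone(x, chain = chain, model = model)
  parts <- x |>
    group_by(.data$entry_id, .data$model, .data$chain) |>
    group_split()
  out <- lapply(parts, chain_dihedrals, omega = omega)
  bind_rows(out)
}

restrict_backbone <- function(x, chain = NULL, model = NULL) {
  if (!is.null(chain)) {
    if (!any(x$chain %in% chain)) {
      abort(paste0("chain '", chain, "' not present in structure"))
    }
    x <- x[x$chain %in% chain, , drop = FALSE]
  }
  if (!is.null(model)) {
    if (!any(x$model %in% model)) {
      abort(paste0("model ", model, " not present in structure"))
    }
    x <- x[x$model %in% model, , drop = FALSE]
  }
  x
}

coord_mat <- function(df, atom) {
  cbind(df[[paste0(atom, "_x")]], df[[paste0(atom, "_y")]],
        df[[paste0(atom, "_z")]])
}

shift_mat <- function(m, by) {
  n <- nrow(m)
  out <- matrix(NA_real_, n, ncol(m))
  if (by == 1 && n > 1) out[2:n, ] <- m[1:(n - 1), , drop = FALSE]
  if (by == -1 && n > 1) out[1:(n - 1), ] <- m[2:n, , drop = FALSE]
  out
}

# dihedrals for one ordered (model, chain) residue run
chain_dihedrals <- function(df, omega = FALSE) {
  n <- nrow(df)
  N <- coord_mat(df, "N"); CA <- coord_mat(df, "CA"); C <- coord_mat(df, "C")
  Cprev <- shift_mat(C, 1)
  CAprev <- shift_mat(CA, 1)
  Nnext <- shift_mat(N, -1)
  # broken link between i and i+1: C(i)-N(i+1) distance > BREAK_DISTANCE
  link_ok <- rep(FALSE, max(n - 1, 0))
  if (n > 1) {
    d <- sqrt(rowSums((C[-n, , drop = FALSE] - N[-1, , drop = FALSE])^2))
    link_ok <- !is.na(d) & d <= BREAK_DISTANCE
  }
  prev_ok <- c(FALSE, link_ok)   # residue i connected to i-1
  next_ok <- c(link_ok, FALSE)   # residue i connected to i+1
  phi <- dihedral_angle_many(Cprev, N, CA, C)
  psi <- dihedral_angle_many(N, CA, C, Nnext)
  phi[!prev_ok] <- NA_real_
  psi[!next_ok] <- NA_real_
  out <- tibble(
    entry_id = df$entry_id, model = df$model, chain = df$chain,
    res_seq = df$res_seq, ins = df$ins, resname = df$resname, aa = df$aa,
    phi = phi, psi = psi
  )
  if (omega) {
    om <- dihedral_angle_many(CAprev, Cprev, N, CA)
    om[!prev_ok] <- NA_real_
    out$omega <- om
  }
  out$phi_defined <- !is.na(out$phi)
  out$psi_defined <- !is.na(out$psi)
  out
}

#' Chain-break positions in a backbone table
#'
#' Reports every consecutive residue pair within a (model, chain) whose
#' C--N distance exceeds the 2.5 Angstrom break threshold or whose author
#' numbering jumps by more than one.
#'
#' @param x A `backbone_tbl`.
#' @return A tibble with columns `model`, `chain`, `res_before`,
#'   `res_after`, `c_n_distance`, `numbering_gap`, `broken_geometry`.
#' @export
chain_breaks <- function(x) {
  parts <- x |>
    group_by(.data$model, .data$chain) |>
    group_split()
  out <- lapply(parts, function(df) {
    n <- nrow(df)
    if (n < 2) return(NULL)
    C <- coord_mat(df, "C"); N <- coord_mat(df, "N")
    d <- sqrt(rowSums((C[-n, , drop = FALSE] - N[-1, , drop = FALSE])^2))
    gap <- diff(df$res_seq) > 1 & df$ins[-n] == df$ins[-1]
    broken <- is.na(d) | d > BREAK_DISTANCE
    keep <- broken | gap
    if (!any(keep)) return(NULL)
    tibble(
      model = df$model[1], chain = df$chain[1],
      res_before = df$res_seq[-n][keep], res_after = df$res_seq[-1][keep],
      c_n_distance = d[keep], numbering_gap = gap[keep],
      broken_geometry = broken[keep]
    )
  })
  bind_rows(out)
}

#' Per-residue conformational states of a structure
#'
#' Composes [compute_phi_psi()] and [classify_state()]: every residue of
#' every (model, chain) gets exactly one state in `{"R", "L", "O", "U"}`.
#'
#' @inheritParams compute_phi_psi
#' @return The [compute_phi_psi()] tibble with an additional `state`
#'   column.
#' @export
#' @examples
#' residue_states(ideal_alpha_strand("VGSNK"))
residue_states <- function(x, chain = NULL, model = NULL) {
  out <- compute_phi_psi(x, chain = chain, model = model)
  out$state <- classify_state(out$phi, out$psi)
  out
}
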