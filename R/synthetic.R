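# Canonical quadrant-interior dihedrals used for ideal alpha-strand
# geometry. Only the quadrant sign matters downstream; values are chosen
# well away from the 0/180 boundaries.
ALPHA_R_DIHEDRALS <- c(phi = -60, psi = -45)
ALPHA_L_DIHEDRALS <- c(phi = 60, psi = 45)
BETA_LIKE_DIHEDRALS <- c(phi = -120, psi = 130)

#' Standard peptide backbone geometry constants
#'
#' Bond lengths (Angstrom) and bond angles (degrees) used by the
#' internal-coordinate backbone builder. Defaults are standard peptide
#' geometry; the downstream analyses depend only on dihedral signs, so
#' these constants affect realism, not classification.
#'
#' @param n_ca,ca_c,c_n Backbone bond lengths N-CA, CA-C, C-N.
#' @param c_o Carbonyl C=O bond length.
#' @param n_ca_c,ca_c_n,c_n_ca Backbone bond angles.
#' @param ca_c_o Carbonyl bond angle.
#' @return A named list of constants.
#' @export
backbone_geometry <- function(n_ca = 1.458, ca_c = 1.525, c_n = 1.329,
                              c_o = 1.231, n_ca_c = 111.2, ca_c_n = 116.2,
                              c_n_ca = 121.7, ca_c_o = 120.5) {
  g <- list(n_ca = n_ca, ca_c = ca_c, c_n = c_n, c_o = c_o,
            n_ca_c = n_ca_c, ca_c_n = ca_c_n, c_n_ca = c_n_ca,
            ca_c_o = ca_c_o)
  if (any(unlist(g) <= 0)) abort("geometry constants must be positive")
  g
}

# NeRF atom placement: position d such that |c-d| = bond, angle(b,c,d) =
# theta_deg and torsion(a,b,c,d) = chi_deg
place_atom <- function(a, b, c, bond, theta_deg, chi_deg) {
  th <- theta_deg * pi / 180
  ch <- chi_deg * pi / 180
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  c + bond * (-cos(th) * bc + sin(th) * cos(ch) * m + sin(th) * sin(ch) * n)
}

ONE_TO_THREE <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
  E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
  M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
  Y = "TYR", V = "VAL", X = "UNK"
)

#' Build a synthetic backbone with prescribed dihedrals
#'
#' Constructs a 3-D peptide backbone (N, CA, C, O per residue) by
#' sequential internal-coordinate (NeRF) placement so that the measured
#' dihedrals equal the requested ones: psi(i) places N(i+1), omega(i+1)
#' places CA(i+1), phi(i+1) places C(i+1). The carbonyl O of residue i
#' is placed in the C(i) plane trans to N(i+1) (torsion psi(i) + 180).
#' phi of the first residue and -- except for the terminal O -- psi of
#' the last are not realised in the geometry, matching their undefined
#' status on re-measurement.
#'
#' @param sequence One-letter amino-acid sequence (unknown letters
#'   become UNK/X).
#' @param phi,psi Numeric vectors of dihedrals in degrees, one per
#'   residue (recycled if length 1).
#' @param omega Omega torsions, default 180 (trans) throughout.
#' @param start_res Author number of the first residue.
#' @param chain,entry_id Identifiers for the resulting table.
#' @param geometry A [backbone_geometry()] list.
#' @return A `backbone_tbl`; atoms closer than 0.5 Angstrom (impossible
#'   geometry) are an error.
#' @export
#' @examples
#' bb <- build_backbone("AAAAAAA", phi = -60, psi = -45)
#' residue_states(bb)
build_backbone <- function(sequence, phi, psi, omega = 180, start_res = 1L,
                           chain = "A", entry_id = "synthetic",
                           geometry = backbone_geometry()) {
  aa <- strsplit(sequence, "")[[1]]
  n <- length(aa)
  if (n < 1) abort("sequence must have at least one residue")
  phi <- rep_len(phi, n)
  psi <- rep_len(psi, n)
  omega <- rep_len(omega, n)
  if (anyNA(c(phi, psi, omega))) abort("dihedrals must be finite")
  g <- geometry

  N <- matrix(NA_real_, n, 3)
  CA <- matrix(NA_real_, n, 3)
  C <- matrix(NA_real_, n, 3)
  O <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$n_ca, 0, 0)
  th <- g$n_ca_c * pi / 180
  C[1, ] <- CA[1, ] + g$ca_c * c(-cos(th), sin(th), 0)
  if (n > 1) {
    for (i in 2:n) {
      N[i, ] <- place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                           g$c_n, g$ca_c_n, psi[i - 1])
      CA[i, ] <- place_atom(CA[i - 1, ], C[i - 1, ], N[i, ],
                            g$n_ca, g$c_n_ca, omega[i])
      C[i, ] <- place_atom(C[i - 1, ], N[i, ], CA[i, ],
                           g$ca_c, g$n_ca_c, phi[i])
    }
  }
  for (i in seq_len(n)) {
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ],
                         g$c_o, g$ca_c_o, psi[i] + 180)
  }

  coords <- rbind(N, CA, C, O)
  d <- as.matrix(stats::dist(coords))
  diag(d) <- Inf
  if (min(d) < 0.5) {
    abort(sprintf(
      "impossible geometry: atoms %.2f Angstrom apart (< 0.5) for the requested dihedrals",
      min(d)
    ))
  }

  resname <- unname(ONE_TO_THREE[aa])
  resname[is.na(resname)] <- "UNK"
  aa_out <- ifelse(aa %in% setdiff(names(ONE_TO_THREE), "X"), aa, "X")
  df <- tibble(
    entry_id = entry_id, model = 1L, chain = chain,
    res_seq = as.integer(start_res + seq_len(n) - 1), ins = "",
    resname = resname, aa = aa_out,
    N_x = N[, 1], N_y = N[, 2], N_z = N[, 3],
    CA_x = CA[, 1], CA_y = CA[, 2], CA_z = CA[, 3],
    C_x = C[, 1], C_y = C[, 2], C_z = C[, 3],
    O_x = O[, 1], O_y = O[, 2], O_z = O[, 3],
    H_x = NA_real_, H_y = NA_real_, H_z = NA_real_
  )
  new_backbone_tbl(df, method = "UNKNOWN", provenance = "synthetic")
}

#' Ideal alpha-strand backbone
#'
#' Builds a backbone in which every residue of `sequence` alternates
#' between the canonical quadrant-interior dihedrals (-60, -45) for
#' alpha_R and (60, 45) for alpha_L, starting from `start_state`. A
#' glycine cap continuing the alternating geometry is added at each end
#' so that every named residue has both phi and psi defined (a bare
#' terminus would be state "U" and invisible to the scanner); the caps
#' themselves are termini and therefore undefined, so the single maximal
#' alternating run spans exactly the named residues, and a motif scan
#' for `sequence` finds exactly one hit.
#'
#' @param sequence One-letter sequence, length >= 3.
#' @param start_state `"R"` or `"L"`: state of the first named residue.
#' @param start_res Author number of the first named residue (the caps
#'   take `start_res - 1` and `start_res + nchar(sequence)`).
#' @inheritParams build_backbone
#' @return A `backbone_tbl` of `nchar(sequence) + 2` residues.
#' @export
#' @examples
#' residue_states(ideal_alpha_strand("VGSNK"))
ideal_alpha_strand <- function(sequence, start_state = c("R", "L"),
                               start_res = 1L, chain = "A",
                               entry_id = "synthetic") {
  start_state <- match.arg(start_state)
  n <- nchar(sequence)
  if (n < 3) abort("an alpha-strand needs at least 3 residues")
  cap_state <- setdiff(c("R", "L"), start_state)
  pat <- strsplit(alternating_pattern(n + 2, cap_state), "")[[1]]
  phi <- ifelse(pat == "R", ALPHA_R_DIHEDRALS["phi"], ALPHA_L_DIHEDRALS["phi"])
  psi <- ifelse(pat == "R", ALPHA_R_DIHEDRALS["psi"], ALPHA_L_DIHEDRALS["psi"])
  build_backbone(paste0("G", sequence, "G"), phi = phi, psi = psi,
                 start_res = start_res - 1L, chain = chain,
                 entry_id = entry_id)
}

#' Simulate a state trajectory with two-state flip kinetics
#'
#' A statistical stand-in for a molecular-dynamics trajectory of the
#' alpha-strand-forming region: each flip-able residue (baseline state
#' `"R"` or `"L"`) carries an independent two-state Markov chain between
#' its baseline quadrant and the opposite (flipped) quadrant, with
#' per-frame transition probabilities `flip_on_prob`
#' (baseline to flipped) and `flip_off_prob` (flipped to baseline);
#' the long-run flipped fraction is `on / (on + off)`. Residues with
#' baseline `"O"` never flip. Chains start in the flipped state by
#' default, so the alternating window is absent from the initial frames
#' and first appears stochastically, as in a trajectory started from a
#' non-strand conformation.
#'
#' The defaults emulate the high-temperature reference condition: 25,000
#' frames at 2 ps (a 50 ns run) over the five-residue region V24--K28
#' with baseline pattern RLRLR and rates giving each residue a 40%
#' baseline occupancy, hence about 6--7% occupancy for the three-residue
#' RLR window.
#'
#' An optional `planted_window` overrides the sampled states in listed
#' frames so that a window spells a pattern there, giving exact ground
#' truth. The returned manifest records the per-frame window matches
#' (computed by direct comparison inside the generator) and the per-chain
#' transition tallies used for rate recovery.
#'
#' @param n_residues Number of residues.
#' @param n_frames Number of frames.
#' @param stride_ps Frame spacing in ps.
#' @param baseline_states Character vector over `{"R","L","O"}`, length
#'   `n_residues`.
#' @param flip_on_prob,flip_off_prob Per-frame transition probabilities
#'   in \[0, 1\].
#' @param residue_labels Labels for the columns.
#' @param planted_window Optional `list(window =, pattern =, frames =)`
#'   with 0-based frame indices.
#' @param start_flipped Start chains in the flipped state?
#' @param seed Integer seed; all randomness flows from it.
#' @return A list of class `sim_result`: `$states` (a [state_matrix()]),
#'   `$manifest` (ground truth: per-frame matches of the planted window,
#'   transition counts, parameters).
#' @export
simulate_states <- function(n_residues = 5, n_frames = 25000, stride_ps = 2,
                            baseline_states = rep(c("R", "L"),
                                                  length.out = n_residues),
                            flip_on_prob = 0.012, flip_off_prob = 0.008,
                            residue_labels = NULL,
                            planted_window = NULL, start_flipped = TRUE,
                            seed = 1L) {
  stopifnot(length(baseline_states) == n_residues,
            all(baseline_states %in% c("R", "L", "O")),
            flip_on_prob >= 0, flip_on_prob <= 1,
            flip_off_prob >= 0, flip_off_prob <= 1)
  if (is.null(residue_labels)) {
    if (n_residues == 5) {
      residue_labels <- paste0(strsplit("VGSNK", "")[[1]], 24:28)
    } else {
      residue_labels <- paste0("X", seq_len(n_residues))
    }
  }
  flip_of <- c(R = "L", L = "R", O = "O")
  flipable <- baseline_states %in% c("R", "L")

  states <- matrix(rep(baseline_states, each = n_frames), n_frames,
                   n_residues)
  transitions <- tibble(
    residue_label = residue_labels,
    flipable = flipable,
    n_on = 0L, n_on_opportunities = 0L,
    n_off = 0L, n_off_opportunities = 0L,
    flipped_frames = 0L
  )
  with_seed(seed, {
    for (r in seq_len(n_residues)) {
      if (!flipable[r]) next
      z <- logical(n_frames)            # TRUE = flipped
      z[1] <- start_flipped
      u <- runif(n_frames - 1)
      for (t in 2:n_frames) {
        z[t] <- if (z[t - 1]) u[t - 1] >= flip_off_prob else u[t - 1] < flip_on_prob
      }
      prev <- z[-n_frames]; nxt <- z[-1]
      transitions$n_on[r] <- sum(!prev & nxt)
      transitions$n_on_opportunities[r] <- sum(!prev)
      transitions$n_off[r] <- sum(prev & !nxt)
      transitions$n_off_opportunities[r] <- sum(prev)
      transitions$flipped_frames[r] <- sum(z)
      states[z, r] <- flip_of[[baseline_states[r]]]
    }
  })

  planted_mask <- NULL
  if (!is.null(planted_window)) {
    stopifnot(all(c("window", "pattern", "frames") %in% names(planted_window)))
    assert_pattern(planted_window$pattern)
    w <- planted_window$window
    idx <- if (is.numeric(w)) {
      nums <- suppressWarnings(as.integer(str_match(residue_labels,
                                                    "(\\d+)")[, 2]))
      match(w, if (all(is.na(nums))) seq_len(n_residues) else nums)
    } else {
      match(w, residue_labels)
    }
    if (anyNA(idx)) abort("planted window outside the simulated residues")
    fr <- planted_window$frames + 1L   # 0-based frames -> rows
    if (any(fr < 1 | fr > n_frames)) abort("planted frames out of range")
    pat <- strsplit(planted_window$pattern, "")[[1]]
    states[fr, idx] <- matrix(pat, length(fr), length(pat), byrow = TRUE)
    planted_mask <- rowSums(
      states[, idx, drop = FALSE] ==
        matrix(pat, n_frames, length(pat), byrow = TRUE)
    ) == length(pat)
  }

  sm <- new_state_matrix(states, residue_labels,
                         (seq_len(n_frames) - 1) * stride_ps,
                         stride_ps = stride_ps)
  manifest <- list(
    params = list(
      n_residues = n_residues, n_frames = n_frames, stride_ps = stride_ps,
      baseline_states = baseline_states, flip_on_prob = flip_on_prob,
      flip_off_prob = flip_off_prob, start_flipped = start_flipped,
      seed = seed
    ),
    transitions = transitions,
    planted = planted_window,
    planted_match_mask = planted_mask,
    planted_frame_count = if (is.null(planted_mask)) NA_integer_ else
      sum(planted_mask),
    planted_first_frame = if (is.null(planted_mask) || !any(planted_mask))
      NA_integer_ else which(planted_mask)[1] - 1L
  )
  structure(list(states = sm, manifest = manifest), class = "sim_result")
}

#' Write a mini structure collection with planted alpha-strand motifs
#'
#' Generates a directory of small multi-model PDB files with exactly
#' known ground truth for collection mining: `n_with_hits` entries carry
#' planted occurrences of `motif` in an alternating alpha-strand window
#' (one occurrence per model, embedded in beta-like context so nothing
#' else alternates), the rest are decoys carrying the same sequence in a
#' uniformly beta-like backbone. Experimental-method records alternate
#' between X-ray and NMR so that method stratification is exercised.
#' Output is bit-reproducible for a given seed.
#'
#' @param out_dir Output directory (created if needed).
#' @param n_entries Total number of entries.
#' @param n_with_hits Entries that carry planted occurrences
#'   (`<= n_entries`).
#' @param occurrences Integer vector, length `n_with_hits`: planted
#'   occurrences per hit entry (each in its own model).
#' @param motif One-letter sequence carrying the planted strand, e.g.
#'   `"VGS"`.
#' @param start_state Start state of the planted pattern.
#' @param seed Integer seed controlling which entries are hits and the
#'   method assignment.
#' @return A list of class `plant_manifest`: `$entries` (per-entry
#'   tibble: `entry_id`, `file`, `method`, `n_occurrences`), `$hits`
#'   (per-occurrence tibble), `$totals` (list with
#'   `structures_with_hits`, `total_occurrences`, `by_method`).
#' @export
plant_collection <- function(out_dir, n_entries = 12, n_with_hits = 5,
                             occurrences = rep(1L, n_with_hits),
                             motif = "VGS", start_state = "R", seed = 1L) {
  stopifnot(n_with_hits <= n_entries, length(occurrences) == n_with_hits,
            all(occurrences >= 1), nchar(motif) >= 3)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ids <- sprintf("SYN%03d", seq_len(n_entries))
  asg <- with_seed(seed, {
    list(
      hit_entries = sort(sample(n_entries, n_with_hits)),
      methods = sample(rep_len(c("XRAY", "NMR"), n_entries))
    )
  })
  flank <- "AA"   # alanine flanks held in beta-like (O) conformation
  seq_full <- paste0(flank, motif, flank)
  n <- nchar(seq_full)
  k <- nchar(motif)
  pat <- strsplit(alternating_pattern(k, start_state), "")[[1]]
  phi_hit <- c(rep(BETA_LIKE_DIHEDRALS["phi"], nchar(flank)),
               ifelse(pat == "R", ALPHA_R_DIHEDRALS["phi"],
                      ALPHA_L_DIHEDRALS["phi"]),
               rep(BETA_LIKE_DIHEDRALS["phi"], nchar(flank)))
  psi_hit <- c(rep(BETA_LIKE_DIHEDRALS["psi"], nchar(flank)),
               ifelse(pat == "R", ALPHA_R_DIHEDRALS["psi"],
                      ALPHA_L_DIHEDRALS["psi"]),
               rep(BETA_LIKE_DIHEDRALS["psi"], nchar(flank)))
  start_res <- 24L - nchar(flank)   # motif first residue at author 24

  entries <- vector("list", n_entries)
  hits <- list()
  occ_i <- 0L
  for (e in seq_len(n_entries)) {
    is_hit <- e %in% asg$hit_entries
    n_occ <- 0L
    if (is_hit) {
      occ_i <- occ_i + 1L
      n_occ <- as.integer(occurrences[match(e, asg$hit_entries)])
    }
    n_models <- max(n_occ, 1L)
    models <- lapply(seq_len(n_models), function(m) {
      if (is_hit) {
        bb <- build_backbone(seq_full, phi = phi_hit, psi = psi_hit,
                             start_res = start_res, entry_id = ids[e])
      } else {
        bb <- build_backbone(seq_full, phi = BETA_LIKE_DIHEDRALS["phi"],
                             psi = BETA_LIKE_DIHEDRALS["psi"],
                             start_res = start_res, entry_id = ids[e])
      }
      bb$model <- as.integer(m)
      bb
    })
    bb_all <- bind_rows(models)
    attr(bb_all, "method") <- asg$methods[e]
    file <- file.path(out_dir, paste0(ids[e], ".pdb"))
    write_backbone_pdb(bb_all, file, method = asg$methods[e])
    entries[[e]] <- tibble(
      entry_id = ids[e], file = file, method = asg$methods[e],
      n_occurrences = n_occ
    )
    if (is_hit) {
      hits[[length(hits) + 1]] <- tibble(
        entry_id = ids[e], model = seq_len(n_occ), chain = "A",
        start_res = 24L, length = k,
        pattern = alternating_pattern(k, start_state), sequence = motif
      )
    }
  }
  entries <- bind_rows(entries)
  hits <- if (length(hits)) bind_rows(hits) else
    tibble(entry_id = character(), model = integer(), chain = character(),
           start_res = integer(), length = integer(), pattern = character(),
           sequence = character())
  by_method <- entries |>
    filter(.data$n_occurrences > 0) |>
    group_by(method = .data$method) |>
    summarise(structures_with_hits = n(),
              occurrences = sum(.data$n_occurrences), .groups = "drop") |>
    arrange(.data$method)
  structure(
    list(
      entries = entries, hits = hits,
      totals = list(
        structures = n_entries,
        structures_with_hits = sum(entries$n_occurrences > 0),
        total_occurrences = sum(entries$n_occurrences)
      ),
      by_method = by_method,
      motif = motif, pattern = alternating_pattern(k, start_state)
    ),
    class = "plant_manifest"
  )
}
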