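# Independent oracles used to cross-check the package's own algorithms.
# They deliberately use different derivations / mechanics from the
# implementation (projection-based torsion vs plane normals; string-window
# enumeration vs run-length grouping).

# torsion by projecting the outer bonds onto the plane perpendicular to
# the central bond
oracle_dihedral <- function(p1, p2, p3, p4) {
  b <- p3 - p2
  b <- b / sqrt(sum(b^2))
  v1 <- (p1 - p2) - sum((p1 - p2) * b) * b
  v4 <- (p4 - p3) - sum((p4 - p3) * b) * b
  cr <- c(
    v1[2] * v4[3] - v1[3] * v4[2],
    v1[3] * v4[1] - v1[1] * v4[3],
    v1[1] * v4[2] - v1[2] * v4[1]
  )
  atan2(sum(cr * b), sum(v1 * v4)) * 180 / pi
}

# every maximal alternating window by explicit (start, length) enumeration
# against reference alternating strings, with explicit extension checks
oracle_runs <- function(states, min_len = 3) {
  n <- length(states)
  s <- paste(states, collapse = "")
  is_alt <- function(from, to) {
    w <- substr(s, from, to)
    first <- substr(w, 1, 1)
    if (!first %in% c("R", "L")) return(FALSE)
    ref <- paste(rep(c(first, setdiff(c("R", "L"), first)),
                     length.out = nchar(w)), collapse = "")
    identical(w, ref)
  }
  out <- list()
  for (start in seq_len(n)) {
    end <- start - 1
    for (e in start:n) {
      if (!is_alt(start, e)) break
      end <- e
    }
    len <- end - start + 1
    if (len < min_len) next
    left_ext <- start > 1 && is_alt(start - 1, end)
    if (left_ext) next
    out[[length(out) + 1]] <- data.frame(
      start_index = start, length = len,
      pattern = substr(s, start, end)
    )
  }
  if (length(out) == 0) {
    return(data.frame(start_index = integer(), length = integer(),
                      pattern = character()))
  }
  do.call(rbind, out)
}

random_state_string <- function(n) {
  sample(c("R", "L", "O", "U"), n, replace = TRUE,
         prob = c(0.35, 0.35, 0.2, 0.1))
}

# random rotation matrix via QR of a Gaussian matrix
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# random backbone spec with dihedrals away from quadrant boundaries,
# retried on (rare) steric-clash rejections
random_backbone <- function(n_res = 6) {
  repeat {
    phi <- runif(n_res, -178, 178)
    psi <- runif(n_res, -178, 178)
    phi[abs(phi) < 2] <- phi[abs(phi) < 2] + 4
    psi[abs(psi) < 2] <- psi[abs(psi) < 2] + 4
    bb <- tryCatch(
      build_backbone(paste(rep("A", n_res), collapse = ""),
                     phi = phi, psi = psi),
      error = function(e) NULL
    )
    if (!is.null(bb)) {
      return(list(bb = bb, phi = phi, psi = psi))
    }
  }
}

# long dihedral tibble for a 3-residue plane-flip trajectory: psi of the
# middle residue and phi of its successor toggle between two values at
# the given 0-based frames, everything else constant
flip_fixture <- function(n_frames, toggle_frames) {
  base <- data.frame(
    residue_label = c("V24", "G25", "S26"),
    phi = c(-60, 60, -60),
    psi = c(-45, 45, 150)
  )
  z <- logical(n_frames)
  for (f in toggle_frames) z[(f + 1):n_frames] <- !z[(f + 1):n_frames]
  rows <- lapply(seq_len(n_frames) - 1L, function(fr) {
    d <- base
    if (z[fr + 1]) {
      d$psi[2] <- -140   # G25 psi flips 45 -> -140
      d$phi[3] <- 120    # S26 phi flips -60 -> 120
    }
    d$frame <- fr
    d
  })
  out <- do.call(rbind, rows)
  tibble::as_tibble(out[, c("frame", "residue_label", "phi", "psi")])
}
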