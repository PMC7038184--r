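assert_pattern <- function(pattern) {
  letters_ok <- grepl("^[RL]+$", pattern)
  alt <- function(p) {
    s <- strsplit(p, "")[[1]]
    length(s) >= 2 && all(s[-1] != s[-length(s)])
  }
  if (!letters_ok || !alt(pattern)) {
    abort(paste0("pattern must be a strictly alternating string over {R, L} ",
                 "of length >= 2, got '", pattern, "'"))
  }
  invisible(pattern)
}

alternating_pattern <- function(len, start = "R") {
  paste(rep(c(start, setdiff(c("R", "L"), start)), length.out = len),
        collapse = "")
}

states_vector <- function(states) {
  if (is.data.frame(states)) states$state else as.character(states)
}

#' Maximal alternating alpha_R/alpha_L runs in a state sequence
#'
#' Finds every maximal run of length at least `min_len` in which
#' consecutive states strictly alternate between `"R"` (alpha_R) and
#' `"L"` (alpha_L) -- the alpha-strand motif. Either start state is
#' accepted; runs never include `"O"`, `"U"` or positions across a chain
#' break (breaks surface as `"U"` states).
#'
#' @param states Character vector over `{"R","L","O","U"}`, or a tibble
#'   from [residue_states()] (its `state` column is used and residue
#'   identities are carried into the result).
#' @param min_len Minimum run length (>= 2, default 3: the canonical
#'   alpha-strand is at least RLR).
#' @return A tibble of hits sorted by start position: `start_index`,
#'   `length`, `pattern` and, for tibble input, `model`, `chain`,
#'   `start_res`, `sequence`.
#' @export
#' @examples
#' find_alternating_runs(c("R", "L", "R", "L", "O", "R"), min_len = 3)
find_alternating_runs <- function(states, min_len = 3) {
  if (min_len < 2) abort("min_len must be >= 2")
  s <- states_vector(states)
  n <- length(s)
  hits <- tibble(start_index = integer(), length = integer(),
                 pattern = character())
  if (n > 0 && any(s %in% c("R", "L"))) {
    ok <- s %in% c("R", "L")
    # adjacent pair (i, i+1) continues a run iff both in {R,L} and different
    cont <- if (n > 1) ok[-n] & ok[-1] & s[-n] != s[-1] else logical()
    grp <- cumsum(c(TRUE, !cont))
    runs <- tibble(grp = grp, idx = seq_len(n), ok = ok) |>
      filter(.data$ok) |>
      group_by(.data$grp) |>
      summarise(start_index = min(.data$idx), length = n(), .groups = "drop") |>
      filter(.data$length >= min_len) |>
      arrange(.data$start_index)
    if (nrow(runs) > 0) {
      hits <- tibble(
        start_index = runs$start_index,
        length = runs$length,
        pattern = map_chr(seq_len(nrow(runs)), function(i) {
          paste(s[runs$start_index[i] + seq_len(runs$length[i]) - 1],
                collapse = "")
        })
      )
    }
  }
  if (is.data.frame(states) && nrow(hits) > 0) {
    hits <- hits |>
      mutate(
        model = states$model[.data$start_index],
        chain = states$chain[.data$start_index],
        start_res = states$res_seq[.data$start_index],
        sequence = map_chr(seq_len(n()), function(i) {
          paste(states$aa[.data$start_index[i] + seq_len(.data$length[i]) - 1],
                collapse = "")
        })
      ) |>
      select("model", "chain", "start_res", "start_index", "length",
             "pattern", "sequence")
  } else if (is.data.frame(states)) {
    hits <- tibble(model = integer(), chain = character(),
                   start_res = integer(), start_index = integer(),
                   length = integer(), pattern = character(),
                   sequence = character())
  }
  hits
}

#' Test whether an anchored residue window spells a given pattern
#'
#' Checks the exact residues of an anchored window (e.g. author residues
#' 24--26) for the states of `pattern`, the formulation in which
#' per-region alpha-strand counts are defined: the window matches only if
#' position k of the window is in state `pattern[k]` for every k.
#'
#' @param states A [residue_states()] tibble for one (model, chain), or a
#'   character state vector (then `window` indexes positions).
#' @param window Integer vector of consecutive author residue numbers
#'   (tibble input) or positions (vector input), same length as
#'   `pattern`.
#' @param pattern Alternating pattern string over `{R, L}`, e.g. `"RLR"`.
#' @return `TRUE` or `FALSE`. A window residue absent from the chain is
#'   an error, distinct from a non-match.
#' @export
#' @examples
#' st <- residue_states(ideal_alpha_strand("AVGSA", start_state = "L"))
#' match_anchored(st, window = 2:4, pattern = "RLR")
match_anchored <- function(states, window, pattern) {
  assert_pattern(pattern)
  if (length(window) != nchar(pattern)) {
    abort("window and pattern lengths differ")
  }
  if (any(diff(window) != 1)) {
    abort("anchored window must be consecutive residue numbers")
  }
  if (is.data.frame(states)) {
    pos <- match(window, states$res_seq)
  } else {
    pos <- window
    pos[pos < 1 | pos > length(states_vector(states))] <- NA_integer_
  }
  if (anyNA(pos)) {
    abort(paste0("window residue ", window[which(is.na(pos))[1]],
                 " absent from chain"))
  }
  s <- states_vector(states)[pos]
  identical(paste(s, collapse = ""), pattern)
}

#' Scan a structure for alpha-strand hits
#'
#' Enumerates every model and chain of a structure independently and
#' reports alpha-strand hits. Without a sequence motif, hits are the
#' maximal alternating runs of [find_alternating_runs()] (optionally
#' required to start in a given state). With `motif` set (a plain
#' one-letter subsequence such as `"VGS"`), hits are every window whose
#' one-letter sequence equals the motif and whose states strictly
#' alternate over the window, including overlapping windows.
#'
#' @param x A `backbone_tbl`.
#' @param min_len Minimum run length for motif-free scanning.
#' @param motif Optional one-letter sequence to restrict hits to.
#' @param required_start Optional `"R"` or `"L"`: the state the first
#'   residue of a hit must have. Region 24--26 analyses use `"R"`,
#'   matching the alpha_R-alpha_L-alpha_R notation of the motif.
#' @return A tibble of hits: `entry_id`, `model`, `chain`, `start_res`,
#'   `length`, `pattern`, `sequence`.
#' @export
#' @examples
#' scan_structure(ideal_alpha_strand("AVGSA"), motif = "VGS",
#'                required_start = "R")
scan_structure <- function(x, min_len = 3, motif = NULL,
                           required_start = NULL) {
  if (!is.null(required_start) && !required_start %in% c("R", "L")) {
    abort("required_start must be \"R\" or \"L\"")
  }
  entry <- if (nrow(x) > 0) x$entry_id[1] else attr(x, "provenance") %||% NA
  st <- residue_states(x)
  parts <- st |>
    group_by(.data$model, .data$chain) |>
    group_split()
  hits <- lapply(parts, function(df) {
    if (is.null(motif)) {
      h <- find_alternating_runs(df, min_len = min_len)
      if (!is.null(required_start) && nrow(h) > 0) {
        h <- h[str_sub(h$pattern, 1, 1) == required_start, , drop = FALSE]
      }
      return(h)
    }
    k <- nchar(motif)
    n <- nrow(df)
    if (n < k) return(NULL)
    starts <- which(vapply(seq_len(n - k + 1), function(i) {
      idx <- i + seq_len(k) - 1
      seq_ok <- identical(paste(df$aa[idx], collapse = ""), motif)
      if (!seq_ok) return(FALSE)
      s <- df$state[idx]
      if (!all(s %in% c("R", "L"))) return(FALSE)
      if (k > 1 && any(s[-1] == s[-k])) return(FALSE)
      if (!is.null(required_start) && s[1] != required_start) return(FALSE)
      TRUE
    }, logical(1)))
    if (length(starts) == 0) return(NULL)
    tibble(
      model = df$model[starts], chain = df$chain[starts],
      start_res = df$res_seq[starts], start_index = starts,
      length = k,
      pattern = vapply(starts, function(i) {
        paste(df$state[i + seq_len(k) - 1], collapse = "")
      }, character(1)),
      sequence = motif
    )
  })
  out <- bind_rows(hits)
  if (nrow(out) == 0) {
    return(tibble(entry_id = character(), model = integer(),
                  chain = character(), start_res = integer(),
                  length = integer(), pattern = character(),
                  sequence = character()))
  }
  out |>
    mutate(entry_id = entry) |>
    select("entry_id", "model", "chain", "start_res", "length", "pattern",
           "sequence") |>
    arrange(.data$model, .data$chain, .data$start_res)
}
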