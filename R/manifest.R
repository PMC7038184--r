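VARIANT_LABELS <- c("WT", "A2T", "D7N", "E22G", "E22Q", "D23N", "G25P")

#' Load and validate the simulation-campaign manifest
#'
#' Reads the shipped transcription of the 39-system simulation campaign
#' the alpha-strand analyses were developed on (three amyloid-beta 1-42
#' starting structures x variant x temperature x pH), or a user-supplied
#' table with the same six columns, and validates every row: temperature
#' must be 310 or 498 K, pH class NpH or LpH, low-pH rows must use
#' anionic counter ions, run length positive, variant label known.
#'
#' @param path Path to a TSV with columns `system`, `pdb_id`, `variant`,
#'   `counter_ion`, `temperature_K`, `ph_class`, `run_ns`. Default: the
#'   copy shipped with the package.
#' @return A validated tibble, one row per simulated system.
#' @export
#' @examples
#' manifest <- load_manifest()
#' nrow(manifest)
#' aggregate_run_time(manifest)
load_manifest <- function(path = NULL) {
  path <- path %||% system.file("extdata", "table1.tsv",
                                package = "alphastrand", mustWork = TRUE)
  m <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(m) == 0) return(m)
  need <- c("system", "pdb_id", "variant", "counter_ion", "temperature_K",
            "ph_class", "run_ns")
  if (!all(need %in% names(m))) {
    abort(paste0("manifest must have columns: ", paste(need, collapse = ", ")))
  }
  check <- function(cond, what) {
    if (any(!cond)) {
      abort(sprintf("manifest row %d: %s", m$system[which(!cond)[1]], what))
    }
  }
  check(m$temperature_K %in% c(310, 498), "temperature must be 310 or 498 K")
  check(m$ph_class %in% c("NpH", "LpH"), "ph_class must be NpH or LpH")
  anion <- grepl("Cl-|Cl\\^|-\\s*$", m$counter_ion)
  check(m$ph_class != "LpH" | anion,
        "low-pH systems must use anionic counter ions")
  check(is.finite(m$run_ns) & m$run_ns > 0, "run_ns must be positive")
  check(m$variant %in% VARIANT_LABELS,
        paste0("variant must be one of ", paste(VARIANT_LABELS,
                                                collapse = ", ")))
  m
}

#' Total simulated time of a campaign manifest
#'
#' @param entries A manifest tibble from [load_manifest()].
#' @return Total run length in ns (0 for an empty manifest).
#' @export
aggregate_run_time <- function(entries) {
  if (nrow(entries) == 0) return(0)
  sum(entries$run_ns)
}

#' The wild-type amyloid-beta 1-42 sequence
#'
#' Returns the 42-residue wild-type sequence shipped with the package.
#' At load time it is validated against the region anchors the
#' alpha-strand analyses rely on: positions 24-28 must read VGSNK (the
#' V24-G25-S26 window extended to K28) and the length must be 42.
#'
#' @return A single character string of length-42 one-letter codes.
#' @export
#' @examples
#' substr(ab42_sequence(), 24, 28)  # "VGSNK"
ab42_sequence <- function() {
  path <- system.file("extdata", "ab42.json", package = "alphastrand",
                      mustWork = TRUE)
  dat <- jsonlite::fromJSON(path)
  seq <- dat$wt
  if (nchar(seq) != 42) abort("shipped sequence is not 42 residues")
  if (substr(seq, 24, 28) != "VGSNK") {
    abort("shipped sequence fails the V24-G25-S26-N27-K28 checkpoint")
  }
  seq
}

#' Apply a point-mutation label to a sequence
#'
#' Parses a label of the form `<wt-letter><position><new-letter>` (e.g.
#' `"G25P"`) and applies the single substitution. The wild-type letter
#' must match the current sequence at that position; re-applying a
#' mutation is therefore an error, and motif lookups (such as VGS at
#' 24-26) reflect the change.
#'
#' @param sequence One-letter sequence string.
#' @param label Mutation label, e.g. `"A2T"`.
#' @return A one-row tibble: `label`, `sequence`, `position`, `from`,
#'   `to`.
#' @export
#' @examples
#' apply_variant(ab42_sequence(), "G25P")
apply_variant <- function(sequence, label) {
  m <- str_match(label, "^([A-Z])(\\d+)([A-Z])$")
  if (is.na(m[1, 1])) {
    abort(paste0("cannot parse mutation label '", label, "'"))
  }
  from <- m[1, 2]; pos <- as.integer(m[1, 3]); to <- m[1, 4]
  if (pos < 1 || pos > nchar(sequence)) {
    abort(paste0("position ", pos, " outside the sequence"))
  }
  if (substr(sequence, pos, pos) != from) {
    abort(sprintf(
      "label '%s' inconsistent: position %d is '%s', not '%s'",
      label, pos, substr(sequence, pos, pos), from
    ))
  }
  mutated <- sequence
  substr(mutated, pos, pos) <- to
  tibble(label = label, sequence = mutated, position = pos, from = from,
         to = to)
}

#' All sequence variants of the simulation campaign
#'
#' @return A tibble with one row per variant (WT plus the six point
#'   mutants), columns `label`, `sequence`, `position`, `from`, `to`
#'   (`NA` for WT).
#' @export
ab42_variants <- function() {
  wt <- ab42_sequence()
  path <- system.file("extdata", "ab42.json", package = "alphastrand",
                      mustWork = TRUE)
  labels <- jsonlite::fromJSON(path)$variant_labels
  bind_rows(
    tibble(label = "WT", sequence = wt, position = NA_integer_,
           from = NA_character_, to = NA_character_),
    bind_rows(lapply(labels, function(l) apply_variant(wt, l)))
  )
}
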