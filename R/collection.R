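#' Map an experimental-method header to a method class
#'
#' Maps the free-text experiment record of a structure file (`EXPDTA` in
#' PDB, `_exptl.method` in mmCIF) onto the coarse classes used for
#' census stratification.
#'
#' @param x Character vector of method strings; `NA` or empty means the
#'   record was absent.
#' @return Character vector over `c("XRAY", "NMR", "OTHER", "UNKNOWN")`.
#' @export
#' @examples
#' classify_method(c("X-RAY DIFFRACTION", "SOLUTION NMR", NA, "ELECTRON MICROSCOPY"))
classify_method <- function(x) {
  x <- as.character(x)
  up <- toupper(trimws(x))
  out <- rep("OTHER", length(x))
  out[is.na(up) | up == ""] <- "UNKNOWN"
  out[!is.na(up) & grepl("X-?RAY", up)] <- "XRAY"
  out[!is.na(up) & grepl("NMR", up)] <- "NMR"
  out[!is.na(up) & up %in% c("XRAY", "NMR", "OTHER", "UNKNOWN")] <-
    up[!is.na(up) & up %in% c("XRAY", "NMR", "OTHER", "UNKNOWN")]
  out
}

new_collection_report <- function(per_entry, hits, skipped) {
  per_entry <- per_entry |> arrange(.data$entry_id)
  hits <- hits |> arrange(.data$entry_id, .data$model, .data$chain,
                          .data$start_res)
  with_hits <- per_entry |> filter(.data$occurrence_count > 0)
  by_method <- with_hits |>
    group_by(method = .data$method) |>
    summarise(structures_with_hits = n(),
              occurrences = sum(.data$occurrence_count), .groups = "drop") |>
    arrange(.data$method)
  totals <- list(
    structures_scanned = sum(!per_entry$non_protein),
    structures_excluded_non_protein = sum(per_entry$non_protein),
    structures_skipped = nrow(skipped),
    structures_with_hits = nrow(with_hits),
    total_occurrences = sum(per_entry$occurrence_count)
  )
  structure(
    list(per_entry = per_entry, hits = hits, skipped = skipped,
         totals = totals, by_method = by_method),
    class = "collection_report"
  )
}

#' @export
print.collection_report <- function(x, ...) {
  t <- x$totals
  cat("<collection_report>\n")
  cat(sprintf("  scanned %d protein entries (%d non-protein excluded, %d skipped)\n",
              t$structures_scanned, t$structures_excluded_non_protein,
              t$structures_skipped))
  cat(sprintf("  %d structures with hits, %d occurrences\n",
              t$structures_with_hits, t$total_occurrences))
  if (nrow(x$by_method) > 0) {
    for (i in seq_len(nrow(x$by_method))) {
      cat(sprintf("    %s: %d structures, %d occurrences\n",
                  x$by_method$method[i], x$by_method$structures_with_hits[i],
                  x$by_method$occurrences[i]))
    }
  }
  invisible(x)
}

#' Mine a structure collection for alpha-strand occurrences
#'
#' Batch-scans a directory (or explicit file list) of structure files.
#' Each entry is read with [read_structures()]; entries without protein
#' chains are excluded from the census, unreadable entries are logged as
#' skipped but never abort the batch. Every model and chain of each
#' remaining entry is scanned with [scan_structure()]; an occurrence is
#' one matching window in one (model, chain), and a structure-with-hits
#' is an entry with at least one occurrence. Results are stratified by
#' experimental method.
#'
#' @param paths A directory or a character vector of structure files.
#' @param motif Optional one-letter sequence restriction (e.g. `"VGS"`).
#' @param pattern Optional exact alternating pattern the window states
#'   must spell (e.g. `"RLR"`); implies its own length and start state.
#' @param required_start Optional start state (`"R"`/`"L"`) when no
#'   exact `pattern` is given.
#' @param min_len Minimum run length for motif-free scanning.
#' @return A `collection_report`: `$per_entry`, `$hits`, `$skipped`,
#'   `$totals`, `$by_method`. Scanning the same collection twice yields
#'   identical reports, and reports of disjoint directories can be
#'   merged with [combine_reports()].
#' @export
mine_collection <- function(paths, motif = NULL, pattern = NULL,
                            required_start = NULL, min_len = 3) {
  if (length(paths) == 1 && dir.exists(paths)) {
    paths <- list.files(paths, pattern = "\\.(pdb|ent|cif|mmcif)$",
                        full.names = TRUE, ignore.case = TRUE)
  }
  paths <- sort(paths)
  if (!is.null(pattern)) {
    assert_pattern(pattern)
    required_start <- str_sub(pattern, 1, 1)
    if (!is.null(motif) && nchar(motif) != nchar(pattern)) {
      abort("motif and pattern lengths differ")
    }
    min_len <- nchar(pattern)
  }
  per_entry <- list()
  hits <- list()
  skipped <- list()
  for (p in paths) {
    bb <- tryCatch(read_structures(p), error = function(e) e)
    if (inherits(bb, "error")) {
      skipped[[length(skipped) + 1]] <-
        tibble(path = p, reason = conditionMessage(bb))
      next
    }
    entry <- if (nrow(bb) > 0) bb$entry_id[1] else entry_id_from_file(p)
    non_protein <- isTRUE(attr(bb, "non_protein"))
    h <- if (non_protein) NULL else {
      got <- scan_structure(bb, min_len = min_len, motif = motif,
                            required_start = required_start)
      if (!is.null(pattern) && nrow(got) > 0) {
        got <- got[got$pattern == pattern, , drop = FALSE]
      }
      got
    }
    n_occ <- if (is.null(h)) 0L else nrow(h)
    per_entry[[length(per_entry) + 1]] <- tibble(
      entry_id = entry, path = p, method = attr(bb, "method") %||% "UNKNOWN",
      non_protein = non_protein, occurrence_count = n_occ
    )
    if (!is.null(h) && nrow(h) > 0) hits[[length(hits) + 1]] <- h
  }
  empty_hits <- tibble(entry_id = character(), model = integer(),
                       chain = character(), start_res = integer(),
                       length = integer(), pattern = character(),
                       sequence = character())
  new_collection_report(
    per_entry = if (length(per_entry)) bind_rows(per_entry) else
      tibble(entry_id = character(), path = character(), method = character(),
             non_protein = logical(), occurrence_count = integer()),
    hits = if (length(hits)) bind_rows(hits) else empty_hits,
    skipped = if (length(skipped)) bind_rows(skipped) else
      tibble(path = character(), reason = character())
  )
}

#' Merge two collection reports
#'
#' Combines reports of disjoint entry sets: per-entry tables and hits
#' are concatenated and the totals and method strata recomputed, so
#' scanning two directories separately and merging equals scanning their
#' union.
#'
#' @param x,y `collection_report` objects with disjoint entries.
#' @return A `collection_report`.
#' @export
combine_reports <- function(x, y) {
  stopifnot(inherits(x, "collection_report"), inherits(y, "collection_report"))
  if (length(intersect(x$per_entry$entry_id, y$per_entry$entry_id)) > 0) {
    abort("cannot merge reports with overlapping entries")
  }
  new_collection_report(
    per_entry = bind_rows(x$per_entry, y$per_entry),
    hits = bind_rows(x$hits, y$hits),
    skipped = bind_rows(x$skipped, y$skipped)
  )
}
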