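BACKBONE_ATOMS <- c("N", "CA", "C", "O", "H")

backbone_cols <- function() {
  c(
    "entry_id", "model", "chain", "res_seq", "ins", "resname", "aa",
    as.vector(t(outer(BACKBONE_ATOMS, c("x", "y", "z"), paste, sep = "_")))
  )
}

new_backbone_tbl <- function(df, method = "UNKNOWN", provenance = NA_character_,
                             non_protein = FALSE) {
  out <- as_tibble(df)
  attr(out, "method") <- method
  attr(out, "provenance") <- provenance
  attr(out, "non_protein") <- non_protein
  class(out) <- c("backbone_tbl", class(out))
  out
}

empty_backbone_tbl <- function(method = "UNKNOWN", provenance = NA_character_,
                               non_protein = FALSE) {
  cols <- backbone_cols()
  df <- tibble(
    entry_id = character(), model = integer(), chain = character(),
    res_seq = integer(), ins = character(), resname = character(),
    aa = character()
  )
  for (nm in setdiff(cols, names(df))) df[[nm]] <- numeric()
  new_backbone_tbl(df, method = method, provenance = provenance,
                   non_protein = non_protein)
}

#' Read protein structures into a backbone residue table
#'
#' Parses a PDB-style coordinate file (including multi-model NMR
#' ensembles delimited by MODEL/ENDMDL) or an mmCIF file and returns one
#' row per (model, chain, residue) with the backbone atom coordinates
#' N, CA, C, O and, when present, the amide H. Parsing is delegated to
#' \pkg{bio3d}; on top of it this function applies the package's
#' residue-level policies:
#'
#' * only amino-acid residues are kept, identified as residues carrying
#'   N, CA and C atoms; nonstandard residues with a complete backbone are
#'   retained with one-letter code `"X"` (they can never match a sequence
#'   motif but remain dihedral-eligible);
#' * alternate locations are collapsed to the highest-occupancy
#'   conformer, ties broken by file order;
#' * residues are ordered within each chain by author residue number and
#'   insertion code; duplicated residue identifiers are an error;
#' * the experimental method is read from the header (`EXPDTA` /
#'   `_exptl.method`) and mapped through [classify_method()].
#'
#' An entry with no amino-acid residues (e.g. a nucleic-acid-only file)
#' yields a zero-row table flagged non-protein, which collection mining
#' uses to exclude it from the census.
#'
#' @param path Path to a coordinate file.
#' @param format `"auto"` (by extension), `"pdb"` or `"cif"`.
#' @return A `backbone_tbl` tibble with columns `entry_id`, `model`,
#'   `chain`, `res_seq`, `ins`, `resname`, `aa` and `<atom>_x/_y/_z` for
#'   each backbone atom, plus attributes `method`, `provenance` and
#'   `non_protein`.
#' @seealso [compute_phi_psi()], [scan_structure()], [build_backbone()]
#' @export
read_structures <- function(path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(paste0("cannot read structure file: '", path, "' does not exist"))
  }
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", tolower(path))) "cif" else "pdb"
  }
  pdb <- tryCatch(
    if (format == "cif") {
      suppressWarnings(bio3d::read.cif(path, multi = TRUE, rm.alt = FALSE,
                                       verbose = FALSE))
    } else {
      suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                       verbose = FALSE))
    },
    error = function(e) {
      abort(paste0("parse error in '", path, "': ", conditionMessage(e)))
    }
  )
  if (is.null(pdb$atom) || nrow(pdb$atom) == 0) {
    abort(paste0("parse error in '", path, "': no coordinate records"))
  }
  method <- classify_method(read_method_record(path, format))
  entry <- entry_id_from_file(path)

  at <- as_tibble(pdb$atom)
  at$row <- seq_len(nrow(at))
  at$insert <- ifelse(is.na(at$insert), "", as.character(at$insert))
  at$o[is.na(at$o)] <- 1

  # amino-acid residues: must carry N, CA and C
  at <- at |>
    group_by(.data$chain, .data$resno, .data$insert) |>
    filter(all(c("N", "CA", "C") %in% .data$elety)) |>
    ungroup()
  if (nrow(at) == 0) {
    return(empty_backbone_tbl(method = method, provenance = path,
                              non_protein = TRUE))
  }

  dup <- at |>
    distinct(.data$chain, .data$resno, .data$insert, .data$resid) |>
    count(.data$chain, .data$resno, .data$insert) |>
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf(
      "duplicate residue identifier %s%d%s in '%s'",
      dup$chain[1], dup$resno[1], dup$insert[1], path
    ))
  }

  # highest-occupancy altloc per atom; ties -> first encountered
  at <- at |>
    filter(.data$elety %in% BACKBONE_ATOMS) |>
    group_by(.data$chain, .data$resno, .data$insert, .data$elety) |>
    slice(which.max(.data$o)) |>
    ungroup() |>
    arrange(.data$chain, .data$resno, .data$insert, .data$row)

  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  n_models <- nrow(xyz)

  res <- at |>
    distinct(.data$chain, .data$resno, .data$insert, .data$resid) |>
    arrange(.data$chain, .data$resno, .data$insert)
  aa1 <- suppressWarnings(bio3d::aa321(res$resid))
  aa1[is.na(aa1) | !aa1 %in% LETTERS] <- "X"

  models <- lapply(seq_len(n_models), function(m) {
    co <- at
    co$x <- xyz[m, 3 * at$row - 2]
    co$y <- xyz[m, 3 * at$row - 1]
    co$z <- xyz[m, 3 * at$row]
    wide <- co |>
      select("chain", "resno", "insert", "elety", "x", "y", "z") |>
      tidyr::pivot_wider(
        names_from = "elety",
        values_from = c("x", "y", "z"),
        names_glue = "{elety}_{.value}"
      )
    wide$model <- m
    wide
  })
  out <- bind_rows(models)
  for (nm in setdiff(backbone_cols(), c(names(out), "entry_id", "res_seq",
                                        "ins", "resname", "aa"))) {
    out[[nm]] <- NA_real_
  }
  out <- out |>
    left_join(
      res |> mutate(aa = aa1),
      by = c("chain", "resno", "insert")
    ) |>
    mutate(
      entry_id = entry,
      res_seq = as.integer(.data$resno),
      ins = .data$insert,
      resname = .data$resid
    ) |>
    arrange(.data$model, .data$chain, .data$res_seq, .data$ins) |>
    select(all_of(backbone_cols()))

  bad <- !is.finite(out$N_x) | !is.finite(out$CA_x) | !is.finite(out$C_x)
  if (any(bad)) {
    abort(paste0("non-finite backbone coordinates in '", path, "' (residue ",
                 out$chain[bad][1], out$res_seq[bad][1], ")"))
  }
  new_backbone_tbl(out, method = method, provenance = path)
}

# first EXPDTA / _exptl.method record from the file header, NA when absent
read_method_record <- function(path, format) {
  lines <- tryCatch(readLines(path, n = 500L, warn = FALSE),
                    error = function(e) character())
  if (format == "cif") {
    hit <- grep("^_exptl\\.method", lines, value = TRUE)
    if (length(hit) == 0) return(NA_character_)
    return(gsub("^_exptl\\.method\\s*'?([^']*)'?\\s*$", "\\1", hit[1]))
  }
  hit <- grep("^EXPDTA", lines, value = TRUE)
  if (length(hit) == 0) return(NA_character_)
  str_trim(sub("^EXPDTA", "", hit[1]))
}

entry_id_from_file <- function(path) {
  lines <- tryCatch(readLines(path, n = 5L, warn = FALSE),
                    error = function(e) character())
  hdr <- grep("^HEADER", lines, value = TRUE)
  if (length(hdr) > 0 && nchar(hdr[1]) >= 66) {
    id <- str_trim(substr(hdr[1], 63, 66))
    if (nchar(id) == 4) return(id)
  }
  sub("\\.(pdb|ent|cif|mmcif)$", "", basename(path), ignore.case = TRUE)
}

#' Write a backbone residue table as a PDB coordinate file
#'
#' Serialises a `backbone_tbl` (typically the output of
#' [build_backbone()] or [ideal_alpha_strand()]) as PDB-format text with
#' one MODEL/ENDMDL block per model. Only the backbone atoms held in the
#' table (N, CA, C, O, H) are written. An `EXPDTA` record is emitted so
#' that method stratification survives a round trip.
#'
#' @param x A `backbone_tbl`.
#' @param path Output file path.
#' @param method Experimental-method string for the `EXPDTA` record;
#'   defaults to the table's `method` attribute.
#' @return `path`, invisibly.
#' @export
write_backbone_pdb <- function(x, path, method = NULL) {
  method <- method %||% attr(x, "method") %||% "UNKNOWN"
  expdta <- switch(method,
    XRAY = "X-RAY DIFFRACTION",
    NMR = "SOLUTION NMR",
    UNKNOWN = NULL,
    method
  )
  lines <- character()
  if (!is.null(expdta)) lines <- c(lines, sprintf("EXPDTA    %s", expdta))
  serial <- 0L
  for (m in sort(unique(x$model))) {
    lines <- c(lines, sprintf("MODEL     %4d", m))
    xm <- x[x$model == m, , drop = FALSE]
    for (i in seq_len(nrow(xm))) {
      for (atom in BACKBONE_ATOMS) {
        cx <- xm[[paste0(atom, "_x")]][i]
        if (is.na(cx)) next
        serial <- serial + 1L
        elem <- substr(atom, 1, 1)
        lines <- c(lines, sprintf(
          "ATOM  %5d  %-3s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, atom, xm$resname[i], xm$chain[i], xm$res_seq[i],
          ifelse(is.na(xm$ins[i]) | xm$ins[i] == "", " ", xm$ins[i]),
          cx, xm[[paste0(atom, "_y")]][i], xm[[paste0(atom, "_z")]][i],
          1, 0, elem
        ))
      }
    }
    lines <- c(lines, "ENDMDL")
  }
  lines <- c(lines, "END")
  writeLines(lines, path)
  invisible(path)
}

#' Read a per-frame dihedral table
#'
#' Ingests the whitespace-delimited `phi psi label` dialect written by
#' trajectory dihedral extractors (comment lines starting with `#` or `@`
#' are ignored, as in xvg-style output). Frames are delimited either by
#' an explicit leading integer frame column (`frame phi psi label`) or,
#' for three-column rows, inferred from recurrence of the first residue
#' label. Angles are wrapped into (-180, 180]; values outside
#' \[-360, 360\] are rejected.
#'
#' @param path Path to the table.
#' @param stride_ps Time between recorded frames in picoseconds, used to
#'   assign `time_ps = frame * stride_ps`. Defaults to 2 ps, the stride
#'   the reference trajectories were recorded at.
#' @return A tibble with columns `frame` (0-based), `time_ps`,
#'   `residue_label`, `phi`, `psi`.
#' @export
read_dihedral_table <- function(path, stride_ps = 2) {
  if (!file.exists(path)) {
    abort(paste0("cannot read dihedral table: '", path, "' does not exist"))
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*[#@]", lines) & !grepl("^\\s*$", lines)
  lines <- lines[keep]
  rows <- which(keep)
  if (length(lines) == 0) {
    return(tibble(frame = integer(), time_ps = numeric(),
                  residue_label = character(), phi = numeric(),
                  psi = numeric()))
  }
  fields <- str_split(str_trim(lines), "\\s+")
  nf <- lengths(fields)
  if (!all(nf %in% c(3L, 4L)) || length(unique(nf)) != 1L) {
    bad <- which(!nf %in% c(3L, 4L))[1] %||% 1L
    abort(sprintf("row %d of '%s': expected 3 or 4 whitespace-delimited fields",
                  rows[bad], path))
  }
  explicit_frame <- nf[1] == 4L
  mat <- do.call(rbind, fields)
  num <- function(col, what) {
    v <- suppressWarnings(as.numeric(mat[, col]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1]
      abort(sprintf("row %d of '%s': non-numeric %s field '%s'",
                    rows[bad], path, what, mat[bad, col]))
    }
    v
  }
  if (explicit_frame) {
    frame <- as.integer(num(1, "frame"))
    phi <- num(2, "phi"); psi <- num(3, "psi"); label <- mat[, 4]
  } else {
    phi <- num(1, "phi"); psi <- num(2, "psi"); label <- mat[, 3]
    frame <- cumsum(label == label[1]) - 1L
  }
  out_of_range <- abs(phi) > 360 | abs(psi) > 360
  if (any(out_of_range)) {
    bad <- which(out_of_range)[1]
    abort(sprintf("row %d of '%s': angle outside [-360, 360]", rows[bad], path))
  }
  tibble(
    frame = frame,
    time_ps = frame * stride_ps,
    residue_label = label,
    phi = wrap_angle(phi),
    psi = wrap_angle(psi)
  )
}

#' Write an analysis result to TSV or JSON
#'
#' Serialises the package's tabular results deterministically (fixed
#' column order, header row) so that re-reading with [read_report()]
#' yields an equal object. Data frames are written as-is;
#' [window_summary()] objects are written as their per-frame [tidy()]
#' table (TSV) or full field list (JSON); collection reports as their
#' per-entry table (TSV) or full report (JSON).
#'
#' @param x A data frame, `window_summary` or `collection_report`.
#' @param path Output path.
#' @param format `"auto"` (by extension), `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path, format = c("auto", "tsv", "json")) {
  format <- resolve_report_format(path, match.arg(format))
  UseMethod("write_report")
}

resolve_report_format <- function(path, format) {
  if (format != "auto") return(format)
  if (grepl("\\.json$", tolower(path))) "json" else "tsv"
}

#' @export
write_report.data.frame <- function(x, path, format = c("auto", "tsv", "json")) {
  format <- resolve_report_format(path, match.arg(format))
  if (format == "tsv") {
    readr::write_tsv(x, path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
  }
  invisible(path)
}

#' @export
write_report.window_summary <- function(x, path,
                                        format = c("auto", "tsv", "json")) {
  format <- resolve_report_format(path, match.arg(format))
  if (format == "tsv") {
    readr::write_tsv(tidy(x), path)
  } else {
    jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @export
write_report.collection_report <- function(x, path,
                                           format = c("auto", "tsv", "json")) {
  format <- resolve_report_format(path, match.arg(format))
  if (format == "tsv") {
    readr::write_tsv(x$per_entry, path)
  } else {
    jsonlite::write_json(
      list(per_entry = x$per_entry, hits = x$hits, skipped = x$skipped,
           totals = x$totals, by_method = x$by_method),
      path, auto_unbox = TRUE, digits = NA, dataframe = "columns"
    )
  }
  invisible(path)
}

#' Read back a report written by [write_report()]
#'
#' @param path Path written by [write_report()].
#' @param format `"auto"` (by extension), `"tsv"` or `"json"`.
#' @return A tibble (TSV) or named list (JSON).
#' @export
read_report <- function(path, format = c("auto", "tsv", "json")) {
  format <- resolve_report_format(path, match.arg(format))
  if (format == "tsv") {
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  }
}
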