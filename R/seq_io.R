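#' Read protein sequences from a FASTA file
#'
#' Parses a (possibly wrapped) multi-record FASTA file into a tibble of
#' protein records. Sequences are uppercased and stripped of whitespace and
#' gap characters (`-`, `.`); record order is preserved.
#'
#' @param path Path to a FASTA file.
#' @param strict If `TRUE` (default) only the 20 standard one-letter codes
#'   are accepted; if `FALSE`, `X` and other non-standard letters are kept
#'   verbatim (they are excluded from QTY substitution, and mass/pI
#'   computations on such sequences raise an error).
#'
#' @return A tibble with columns `id`, `description`, `sequence` and a
#'   `segments` list-column of empty transmembrane-segment tibbles (attach
#'   annotations with [attach_segments()]).
#' @seealso [write_fasta()], [read_tm_segments()]
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">demo example", "MKLLIVFAGW"), fa)
#' read_fasta(fa)
read_fasta <- function(path, strict = TRUE) {
  if (!file.exists(path)) {
    abort(paste0("FASTA file not found: ", path))
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) {
    abort(paste0("no records in FASTA file: ", path))
  }
  hdr <- names(set)
  id <- sub("\\s.*$", "", hdr)
  desc <- ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), "")
  seqs <- toupper(gsub("[\\s.-]", "", as.character(set), perl = TRUE))
  purrr::walk2(seqs, id, validate_sequence, strict = strict)
  tibble(
    id = unname(id),
    description = unname(desc),
    sequence = unname(seqs),
    segments = replicate(length(seqs), empty_segments(), simplify = FALSE)
  )
}

empty_segments <- function() {
  tibble(start = integer(), end = integer(), kind = character())
}

validate_sequence <- function(sequence, id = "<sequence>", strict = TRUE) {
  chars <- strsplit(sequence, "")[[1]]
  allowed <- if (strict) AA1 else c(AA1, "X")
  bad <- which(!(chars %in% allowed))
  if (strict && length(bad) > 0) {
    abort(sprintf(
      "illegal residue '%s' at position %d in record '%s'",
      chars[bad[1]], bad[1], id
    ))
  }
  invisible(sequence)
}

#' Write protein records to a FASTA file
#'
#' @param records A tibble with `id`, `description` and `sequence` columns,
#'   as returned by [read_fasta()].
#' @param path Output file path.
#' @param line_width Sequence line wrap width (default 60).
#'
#' @return `path`, invisibly. Round-trips with [read_fasta()] on id and
#'   sequence.
#' @export
write_fasta <- function(records, path, line_width = 60) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0) {
    abort("cannot write an empty record set")
  }
  set <- Biostrings::BStringSet(records$sequence)
  names(set) <- ifelse(
    nzchar(records$description %||% ""),
    paste(records$id, records$description),
    records$id
  )
  Biostrings::writeXStringSet(set, filepath = path, width = line_width)
  invisible(path)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Read transmembrane-segment annotations
#'
#' Reads a tab-separated annotation table with header columns
#' `id`, `start`, `end` and optional `kind` (UniProt TRANSMEM-style, 1-based
#' inclusive coordinates). Segments are sorted per record and checked for
#' overlap.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `id`, `start`, `end`, `kind` (defaulting to
#'   `"helix"`), sorted by `id` then `start`.
#' @export
read_tm_segments <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("id", "start", "end")
  if (!all(need %in% names(tab))) {
    abort("TM annotation file must have header columns id, start, end")
  }
  if (!("kind" %in% names(tab))) tab$kind <- "helix"
  tab <- tab %>%
    mutate(
      start = as.integer(.data$start),
      end = as.integer(.data$end),
      kind = as.character(.data$kind)
    ) %>%
    arrange(.data$id, .data$start)
  validate_segment_table(tab)
  tab
}

validate_segment_table <- function(tab) {
  if (any(tab$start < 1L)) {
    abort("segment start positions must be >= 1")
  }
  bad <- which(tab$start > tab$end)
  if (length(bad) > 0) {
    abort(sprintf(
      "segment start > end for id '%s' (%d > %d)",
      tab$id[bad[1]], tab$start[bad[1]], tab$end[bad[1]]
    ))
  }
  by_id <- split(tab, tab$id)
  for (seg in by_id) {
    seg <- seg[order(seg$start), , drop = FALSE]
    if (nrow(seg) > 1 && any(seg$start[-1] <= seg$end[-nrow(seg)])) {
      abort(sprintf("overlapping segments for id '%s'", seg$id[1]))
    }
  }
  invisible(tab)
}

#' Attach transmembrane segments to protein records
#'
#' Joins an annotation table onto a record tibble as a nested `segments`
#' list-column, validating that every segment lies within its record's
#' sequence.
#'
#' @param records Record tibble from [read_fasta()].
#' @param segments Either an annotation tibble with columns `id`, `start`,
#'   `end` (and optional `kind`), e.g. from [read_tm_segments()], or — for a
#'   single record — a tibble with just `start`/`end` columns.
#' @return `records` with its `segments` list-column populated; the input is
#'   not modified.
#' @export
attach_segments <- function(records, segments) {
  stopifnot(is.data.frame(records), is.data.frame(segments))
  if (!("kind" %in% names(segments))) segments$kind <- "helix"
  if (!("id" %in% names(segments))) {
    if (nrow(records) != 1) {
      abort("segments without an 'id' column require exactly one record")
    }
    segments$id <- records$id[1]
  }
  segments <- segments %>%
    mutate(start = as.integer(.data$start), end = as.integer(.data$end)) %>%
    arrange(.data$id, .data$start)
  validate_segment_table(segments)
  unknown <- setdiff(unique(segments$id), records$id)
  if (length(unknown) > 0) {
    abort(paste0("segments refer to unknown record id: ", unknown[1]))
  }
  records$segments <- purrr::map2(records$id, records$sequence, function(i, s) {
    seg <- segments[segments$id == i, c("start", "end", "kind"), drop = FALSE]
    if (nrow(seg) > 0 && max(seg$end) > nchar(s)) {
      abort(sprintf(
        "segment end %d exceeds sequence length %d for record '%s'",
        max(seg$end), nchar(s), i
      ))
    }
    as_tibble(seg)
  })
  records
}

#' Build a protein record tibble in code
#'
#' Convenience constructor used by examples, fixtures and tests.
#'
#' @param id Record identifier.
#' @param sequence One-letter amino-acid sequence.
#' @param segments Optional tibble (or data.frame) with `start`/`end`
#'   (1-based inclusive) and optional `kind` columns.
#' @param description Free-text description.
#' @param strict Passed to sequence validation (see [read_fasta()]).
#' @return A one-row record tibble.
#' @export
#' @examples
#' protein_record("toy", "MKLLIVFAGW", tibble::tibble(start = 3, end = 8))
protein_record <- function(id, sequence, segments = NULL, description = "",
                           strict = TRUE) {
  sequence <- toupper(gsub("[\\s.-]", "", sequence, perl = TRUE))
  validate_sequence(sequence, id, strict = strict)
  rec <- tibble(
    id = id, description = description, sequence = sequence,
    segments = list(empty_segments())
  )
  if (!is.null(segments)) {
    rec <- attach_segments(rec, as_tibble(segments))
  }
  rec
}
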