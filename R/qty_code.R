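#' The QTY substitution map
#'
#' The canonical QTY code replaces the hydrophobic residues leucine,
#' isoleucine, valine and phenylalanine with hydrophilic residues of
#' similar shape: L -> Q (glutamine), I -> T and V -> T (threonine),
#' F -> Y (tyrosine). The map is a function: one target per source, and
#' none of the targets is itself a source, which makes the substitution
#' idempotent.
#'
#' @return A named character vector mapping source to target residues.
#' @export
#' @examples
#' qty_map()
qty_map <- function() {
  c(L = "Q", I = "T", V = "T", F = "Y")
}

validate_substitution_map <- function(map) {
  if (is.null(names(map)) || any(!nzchar(names(map)))) {
    abort("substitution map must be a named character vector")
  }
  if (!all(names(map) %in% AA1) || !all(map %in% AA1)) {
    abort("substitution map keys and values must be standard one-letter codes")
  }
  if (anyDuplicated(names(map))) {
    abort("substitution map must assign one target per source residue")
  }
  invisible(map)
}

segment_positions <- function(segments) {
  if (is.null(segments) || nrow(segments) == 0) return(integer())
  unlist(purrr::map2(segments$start, segments$end, seq), use.names = FALSE)
}

#' Apply the QTY code inside transmembrane segments
#'
#' Replaces map-key residues at annotated transmembrane positions with their
#' hydrophilic QTY counterparts; positions outside the segments are never
#' touched. This mirrors the design rule for water-soluble membrane-protein
#' analogs: only the lipid-facing helices are made hydrophilic, so the
#' soluble domains (and hence pI and molecular weight) stay essentially
#' unchanged.
#'
#' @param records Record tibble (see [read_fasta()], [protein_record()]) with
#'   a populated `segments` list-column. Records without any transmembrane
#'   segment raise an error.
#' @param map Substitution map; default [qty_map()].
#'
#' @return A tibble of class `qty_tbl`, one row per record, with columns
#'   `id`, `native`, `analog`, `n_substitutions`, `tm_length`,
#'   `total_length`, `tm_pct`, `overall_pct` (percentages at full precision;
#'   printed to 2 decimals), plus list-columns `substitutions`
#'   (position/from/to) and `segments`.
#' @export
#' @examples
#' rec <- protein_record("toy", "MKLLIVFAGW", tibble::tibble(start = 3, end = 8))
#' qty_apply(rec)
qty_apply <- function(records, map = qty_map()) {
  stopifnot(is.data.frame(records))
  validate_substitution_map(map)
  rows <- purrr::pmap(
    list(records$id, records$sequence, records$segments),
    function(id, sequence, segments) {
      if (is.null(segments) || nrow(segments) == 0) {
        abort(paste0("no transmembrane segments annotated for record '", id, "'"))
      }
      if (max(segments$end) > nchar(sequence)) {
        abort(paste0("segments exceed sequence length for record '", id, "'"))
      }
      chars <- strsplit(sequence, "")[[1]]
      pos <- segment_positions(segments)
      hit <- pos[chars[pos] %in% names(map)]
      analog <- chars
      analog[hit] <- unname(map[chars[hit]])
      stats <- variation_stats(sequence, paste(analog, collapse = ""), segments)
      subs <- tibble(position = hit, from = chars[hit], to = analog[hit])
      tibble(
        id = id,
        native = sequence,
        analog = paste(analog, collapse = ""),
        n_substitutions = stats$n_substitutions,
        tm_length = stats$tm_length,
        total_length = stats$total_length,
        tm_pct = stats$tm_variation_pct,
        overall_pct = stats$overall_variation_pct,
        substitutions = list(subs),
        segments = list(segments)
      )
    }
  )
  out <- bind_rows(rows)
  class(out) <- c("qty_tbl", class(out))
  out
}

#' Sequence-variation statistics between a native protein and its analog
#'
#' Counts differing positions and expresses them as a percentage of the
#' transmembrane length (`tm_variation_pct`) and of the full sequence length
#' (`overall_variation_pct`). For QTY designs all differences fall inside
#' the transmembrane segments, so the TM percentage is always at least the
#' overall one; differences outside any segment are still counted but
#' trigger a warning.
#'
#' @param native,analog Equal-length one-letter sequences.
#' @param segments Tibble of transmembrane segments (`start`, `end`).
#' @return One-row tibble: `n_substitutions`, `tm_length`, `total_length`,
#'   `tm_variation_pct`, `overall_variation_pct` (full precision).
#' @export
variation_stats <- function(native, analog, segments) {
  if (nchar(native) != nchar(analog)) {
    abort("native and analog sequences must have equal length")
  }
  a <- strsplit(native, "")[[1]]
  b <- strsplit(analog, "")[[1]]
  diff <- which(a != b)
  pos <- segment_positions(segments)
  outside <- setdiff(diff, pos)
  if (length(outside) > 0) {
    warn(sprintf(
      "%d differing position(s) outside transmembrane segments (first: %d)",
      length(outside), outside[1]
    ))
  }
  tm_len <- length(pos)
  tibble(
    n_substitutions = length(diff),
    tm_length = tm_len,
    total_length = length(a),
    tm_variation_pct = if (tm_len > 0) 100 * length(diff) / tm_len else NA_real_,
    overall_variation_pct = 100 * length(diff) / length(a)
  )
}

#' Render a native-vs-analog pairwise alignment as text
#'
#' Produces fixed-width blocks of four lines: native sequence, a marker line
#' (`|` where the two sequences agree, `*` where they differ), the analog
#' sequence, and a segment line with `H` under transmembrane-helix
#' positions.
#'
#' @param native,analog Equal-length sequences.
#' @param segments Optional segment tibble for the `H` line.
#' @param width Residues per block (default 60).
#' @return A character scalar of class `qty_alignment` (cat-able).
#' @export
#' @examples
#' cat(render_alignment("MKL", "MKQ"))
render_alignment <- function(native, analog, segments = NULL, width = 60) {
  if (nchar(native) != nchar(analog)) {
    abort("native and analog sequences must have equal length")
  }
  stopifnot(width >= 1)
  n <- nchar(native)
  marker <- vapply(seq_len(n), function(i) {
    if (substr(native, i, i) == substr(analog, i, i)) "|" else "*"
  }, character(1))
  helix <- rep(" ", n)
  helix[segment_positions(segments)] <- "H"
  starts <- seq(1, n, by = width)
  blocks <- purrr::map_chr(starts, function(s) {
    e <- min(s + width - 1, n)
    paste(
      substr(native, s, e),
      paste(marker[s:e], collapse = ""),
      substr(analog, s, e),
      paste(helix[s:e], collapse = ""),
      sep = "\n"
    )
  })
  out <- paste0(paste(blocks, collapse = "\n\n"), "\n")
  class(out) <- c("qty_alignment", "character")
  out
}

#' @export
print.qty_alignment <- function(x, ...) {
  cat(unclass(x))
  invisible(x)
}

#' @export
print.qty_tbl <- function(x, ...) {
  cat("# QTY substitution results (", nrow(x), " record",
      if (nrow(x) != 1) "s", ")\n", sep = "")
  y <- as_tibble(x)
  y$tm_pct <- round(y$tm_pct, 2)
  y$overall_pct <- round(y$overall_pct, 2)
  print(y, ...)
  invisible(x)
}

#' @describeIn qty_apply `tidy()` returns the per-position substitution list
#'   across all records (columns `id`, `position`, `from`, `to`).
#' @param x A `qty_tbl`.
#' @param ... Unused.
#' @export
tidy.qty_tbl <- function(x, ...) {
  x %>%
    as_tibble() %>%
    select("id", "substitutions") %>%
    tidyr::unnest("substitutions")
}

#' @describeIn qty_apply `glance()` returns a one-row summary: number of
#'   records and the ranges of TM and overall variation percentages.
#' @export
glance.qty_tbl <- function(x, ...) {
  tibble(
    n_records = nrow(x),
    tm_pct_min = min(x$tm_pct), tm_pct_max = max(x$tm_pct),
    overall_pct_min = min(x$overall_pct), overall_pct_max = max(x$overall_pct)
  )
}
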