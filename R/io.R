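# Tabular input/output: molecule and event TSVs with lossless round trips,
# FASTA input, and BED coordinate conversion (0-based half-open on disk,
# 1-based inclusive internally).

required_molecule_cols <- c("donor_id", "assay", "reciprocal", "pool_id")

#' Write / read a molecule table
#'
#' Molecule tables are TSV with a header: `donor_id`, `assay`, `reciprocal`,
#' `pool_id`, then one column per marker position. Missing calls are written
#' as `"."` and read back as `NA`, so a write-read cycle is the identity.
#'
#' @param molecules Molecule tibble.
#' @param path File path.
#' @return `write_molecules()` returns `path` invisibly; `read_molecules()`
#'   returns the molecule tibble. Malformed rows are an error naming the
#'   offending line(s); unexpected columns only produce a warning.
#' @export
write_molecules <- function(molecules, path) {
  readr::write_tsv(molecules, path, na = ".")
  invisible(path)
}

#' @rdname write_molecules
#' @export
read_molecules <- function(path) {
  out <- readr::read_tsv(
    path, na = ".", show_col_types = FALSE,
    col_types = readr::cols(pool_id = readr::col_integer(),
                            .default = readr::col_character())
  )
  probs <- readr::problems(out)
  if (nrow(probs) > 0) {
    stopf("malformed molecule table row(s) at line(s): %s",
          paste(unique(probs$row), collapse = ", "))
  }
  missing <- setdiff(required_molecule_cols, names(out))
  if (length(missing) > 0) {
    stopf("molecule table is missing column(s): %s",
          paste(missing, collapse = ", "))
  }
  extra <- setdiff(names(out), c(required_molecule_cols, marker_cols(out)))
  if (length(extra) > 0) {
    warn(sprintf("ignoring unknown column(s): %s", paste(extra, collapse = ", ")))
  }
  out
}

#' Write / read an event table
#'
#' Event tables (see [call_events()]) serialise the list columns of marker
#' positions as `";"`-joined strings.
#'
#' @param events Event tibble.
#' @param path File path.
#' @export
write_events <- function(events, path) {
  join_pos <- function(x) {
    map_chr(x, function(p) {
      if (length(p) == 0) NA_character_ else paste(p, collapse = ";")
    })
  }
  flat <- events |>
    mutate(
      converted = join_pos(.data$converted),
      unconverted_internal = join_pos(.data$unconverted_internal)
    )
  readr::write_tsv(flat, path, na = ".")
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  out <- readr::read_tsv(
    path, na = ".", show_col_types = FALSE,
    col_types = readr::cols(converted = readr::col_character(),
                            unconverted_internal = readr::col_character())
  )
  probs <- readr::problems(out)
  if (nrow(probs) > 0) {
    stopf("malformed event table row(s) at line(s): %s",
          paste(unique(probs$row), collapse = ", "))
  }
  parse_list <- function(x) {
    map(x, function(s) {
      if (is.na(s) || s == "") numeric(0) else as.numeric(strsplit(s, ";")[[1]])
    })
  }
  out |>
    mutate(
      converted = parse_list(as.character(.data$converted)),
      unconverted_internal = parse_list(as.character(.data$unconverted_internal))
    )
}

#' Read sequences from FASTA
#'
#' @param path FASTA file path.
#' @return A `Biostrings::DNAStringSet`; contig names are trimmed at the
#'   first whitespace.
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

#' Contig lengths of a sequence set
#'
#' @param seqs A `DNAStringSet` or named character vector.
#' @return Named numeric vector of lengths.
#' @export
contig_lengths <- function(seqs) {
  if (inherits(seqs, "DNAStringSet")) {
    setNames(Biostrings::width(seqs), names(seqs))
  } else {
    setNames(nchar(seqs), names(seqs))
  }
}

#' BED coordinate conversion
#'
#' BED intervals are 0-based half-open; internal coordinates are 1-based
#' inclusive. The two conversions are inverse bijections: BED `(2, 8)` is
#' internal `3..8` (length 6).
#'
#' @param start,end Interval bounds on the source scale.
#' @return A tibble `start`, `end` on the target scale.
#' @examples
#' bed_to_internal(2, 8)  # 3..8
#' internal_to_bed(3, 8)  # 2..8
#' @export
bed_to_internal <- function(start, end) {
  if (any(start >= end)) abort("BED interval with start >= end")
  tibble(start = start + 1, end = end)
}

#' @rdname bed_to_internal
#' @export
internal_to_bed <- function(start, end) {
  if (any(start > end)) abort("internal interval with start > end")
  tibble(start = start - 1, end = end)
}

#' Read / write BED intervals
#'
#' Minimal BED3+ reader and writer with the package's coordinate
#' conventions: on disk 0-based half-open, in memory 1-based inclusive.
#' Intervals with `start >= end` are rejected with their line numbers.
#'
#' @param path BED file path.
#' @return `read_bed()` returns a tibble `contig`, `start`, `end` (internal
#'   coordinates) plus `name` when present.
#' @export
read_bed <- function(path) {
  raw <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                         comment = "#")
  if (ncol(raw) < 3) abort("BED needs at least 3 columns")
  names(raw)[1:3] <- c("contig", "start0", "end0")
  bad <- which(!is.finite(raw$start0) | !is.finite(raw$end0) |
                 raw$start0 >= raw$end0 | raw$start0 < 0)
  if (length(bad) > 0) {
    stopf("invalid BED interval(s) at line(s): %s", paste(bad, collapse = ", "))
  }
  out <- tibble(
    contig = as.character(raw$contig),
    start = raw$start0 + 1,
    end = raw$end0
  )
  if (ncol(raw) >= 4) out$name <- as.character(raw[[4]])
  out
}

#' @rdname read_bed
#' @param intervals Tibble `contig`, `start`, `end` in internal coordinates.
#' @export
write_bed <- function(intervals, path) {
  bed <- tibble(
    contig = intervals$contig,
    start0 = intervals$start - 1,
    end0 = intervals$end
  )
  if ("name" %in% names(intervals)) bed$name <- intervals$name
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' Read an STR allele-count table
#'
#' TSV with columns `contig`, `position`, `allele_length`, `count`, the
#' input of [diversity_summary()].
#'
#' @param path File path.
#' @export
read_str_table <- function(path) {
  out <- readr::read_tsv(
    path, show_col_types = FALSE,
    col_types = readr::cols(contig = readr::col_character(),
                            position = readr::col_double(),
                            allele_length = readr::col_double(),
                            count = readr::col_double())
  )
  probs <- readr::problems(out)
  if (nrow(probs) > 0) {
    stopf("malformed STR table row(s) at line(s): %s",
          paste(unique(probs$row), collapse = ", "))
  }
  out
}
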