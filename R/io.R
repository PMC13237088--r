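#' Read a protein FASTA file into a proteome tibble
#'
#' Parses a (possibly line-wrapped) multi-record amino-acid FASTA file. The
#' record identifier is the first whitespace-delimited token of the header;
#' sequences are uppercased. All downstream coordinates in the package are
#' 1-based inclusive residue positions on these sequences.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` (character), `sequence` (character,
#'   uppercase) and `length` (integer residue count), one row per record,
#'   in file order.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">p1", "AC", "DE", ">p2", "KKK"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    stop("FASTA file contains no records: ", path, call. = FALSE)
  }
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1L)
  seqs <- toupper(as.character(set))
  bad <- grepl("[^A-Z]", seqs)
  if (any(bad)) {
    stop("non-letter characters in sequence of record '", ids[which(bad)[1]],
         "'", call. = FALSE)
  }
  dup <- duplicated(ids)
  if (any(dup)) {
    stop("duplicate record id in FASTA: '", ids[which(dup)[1]], "'",
         call. = FALSE)
  }
  if (any(nchar(seqs) == 0L)) {
    stop("empty sequence for record '", ids[which(nchar(seqs) == 0L)[1]], "'",
         call. = FALSE)
  }
  tibble::tibble(id = unname(ids), sequence = unname(seqs),
                 length = nchar(unname(seqs)))
}

#' Write a proteome tibble to FASTA
#'
#' @param proteome A proteome tibble (`id`, `sequence`).
#' @param path Output path.
#' @param width Line-wrap width for sequences.
#' @return The path, invisibly.
#' @export
write_fasta <- function(proteome, path, width = 60L) {
  stopifnot(all(c("id", "sequence") %in% names(proteome)))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(proteome))) {
    writeLines(paste0(">", proteome$id[i]), con)
    s <- proteome$sequence[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Canonicalise a region tibble
#'
#' Validates coordinates (1-based inclusive, `1 <= start <= end`), sorts by
#' (method, protein_id, start, end) and drops duplicate records. Regions are
#' deduplicated but never merged here; merging is the explicit operation
#' [merge_intervals()].
#'
#' @param regions A data frame with columns `protein_id`, `start`, `end` and
#'   optionally `method`.
#' @param method Optional method label applied to all records (overrides an
#'   existing `method` column).
#' @return A sorted, deduplicated tibble with columns `protein_id`, `start`,
#'   `end`, `method`.
#' @export
as_regions <- function(regions, method = NULL) {
  regions <- tibble::as_tibble(regions)
  stopifnot(all(c("protein_id", "start", "end") %in% names(regions)))
  if (!is.null(method)) {
    regions$method <- method
  } else if (!"method" %in% names(regions)) {
    regions$method <- NA_character_
  }
  if (nrow(regions) == 0L) {
    return(tibble::tibble(protein_id = character(), start = integer(),
                          end = integer(), method = character()))
  }
  if (any(regions$start != floor(regions$start)) ||
      any(regions$end != floor(regions$end))) {
    stop("non-integer region coordinates", call. = FALSE)
  }
  regions$start <- as.integer(regions$start)
  regions$end <- as.integer(regions$end)
  bad <- regions$start < 1L | regions$start > regions$end
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("invalid region %s:%d-%d (need 1 <= start <= end)",
                 regions$protein_id[i], regions$start[i], regions$end[i]),
         call. = FALSE)
  }
  regions |>
    dplyr::select("protein_id", "start", "end", "method") |>
    dplyr::distinct() |>
    dplyr::arrange(.data$method, .data$protein_id, .data$start, .data$end)
}

#' Read a BED-like region file
#'
#' Reads tab-separated region predictions with columns
#' `protein_id<TAB>start<TAB>end[<TAB>method]` and no header. Two coordinate
#' dialects are supported: `native1` (1-based inclusive, the internal
#' convention) and `bed0` (standard BED, 0-based half-open). All records are
#' converted to 1-based inclusive on read.
#'
#' Method label precedence: the `method` argument, then a 4th column if
#' present, then the file name stem.
#'
#' @param path Path to a TSV file.
#' @param dialect `"native1"` or `"bed0"`.
#' @param method Optional method label for all records.
#' @return A region tibble (see [as_regions()]).
#' @export
read_regions <- function(path, dialect = c("native1", "bed0"), method = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("region file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(as_regions(tibble::tibble(protein_id = character(),
                                     start = integer(), end = integer()),
                      method = method))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  if (any(ncol < 3L)) {
    stop("line ", which(ncol < 3L)[1], ": fewer than 3 tab-separated columns",
         call. = FALSE)
  }
  pid <- vapply(fields, `[[`, character(1), 1L)
  s_raw <- vapply(fields, `[[`, character(1), 2L)
  e_raw <- vapply(fields, `[[`, character(1), 3L)
  s <- suppressWarnings(as.numeric(s_raw))
  e <- suppressWarnings(as.numeric(e_raw))
  bad <- is.na(s) | is.na(e) | s != floor(s) | e != floor(e)
  if (any(bad)) {
    stop("line ", which(bad)[1], ": non-integer coordinates", call. = FALSE)
  }
  if (dialect == "bed0") {
    s <- s + 1  # 0-based half-open -> 1-based inclusive; end is unchanged
  }
  bad <- s > e | s < 1
  if (any(bad)) {
    stop("line ", which(bad)[1], ": start > end after dialect conversion",
         call. = FALSE)
  }
  meth <- if (!is.null(method)) {
    method
  } else if (all(ncol >= 4L)) {
    vapply(fields, `[[`, character(1), 4L)
  } else {
    sub("\\.[^.]*$", "", basename(path))
  }
  as_regions(tibble::tibble(protein_id = pid, start = as.integer(s),
                            end = as.integer(e), method = meth))
}

#' Write a region tibble as BED-like TSV
#'
#' Inverse of [read_regions()]: round-trips bit-exactly in either dialect.
#' No header line is written; an empty region set yields an empty file.
#'
#' @param regions A region tibble.
#' @param path Output path.
#' @param dialect `"native1"` (1-based inclusive) or `"bed0"` (0-based
#'   half-open).
#' @param with_method Write the method label as a 4th column.
#' @return The path, invisibly.
#' @export
write_regions <- function(regions, path, dialect = c("native1", "bed0"),
                          with_method = TRUE) {
  dialect <- match.arg(dialect)
  regions <- as_regions(regions)
  s <- regions$start
  if (dialect == "bed0") s <- s - 1L
  cols <- list(regions$protein_id, s, regions$end)
  if (with_method && !all(is.na(regions$method))) cols <- c(cols, list(regions$method))
  lines <- do.call(paste, c(cols, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Extract region subsequences from a proteome
#'
#' The residue-level analogue of `bedtools getfasta`: returns the amino-acid
#' subsequence spanned by each region, 1-based inclusive.
#'
#' @param regions A region tibble.
#' @param proteome A proteome tibble from [read_fasta()].
#' @return The region tibble with an added `sequence` column.
#' @export
region_sequences <- function(regions, proteome) {
  regions <- as_regions(regions)
  idx <- match(regions$protein_id, proteome$id)
  if (anyNA(idx)) {
    stop("region on protein absent from proteome: '",
         regions$protein_id[which(is.na(idx))[1]], "'", call. = FALSE)
  }
  too_long <- regions$end > proteome$length[idx]
  if (any(too_long)) {
    i <- which(too_long)[1]
    stop(sprintf("region %s:%d-%d extends past protein end (length %d)",
                 regions$protein_id[i], regions$start[i], regions$end[i],
                 proteome$length[idx[i]]), call. = FALSE)
  }
  regions$sequence <- substring(proteome$sequence[idx], regions$start,
                                regions$end)
  regions
}

#' Extract one subsequence
#'
#' Scalar convenience wrapper around the coordinate arithmetic of
#' [region_sequences()].
#'
#' @param sequence A protein sequence string.
#' @param start,end 1-based inclusive bounds.
#' @return The subsequence.
#' @export
extract_subsequence <- function(sequence, start, end) {
  stopifnot(length(sequence) == 1L, start >= 1L, start <= end)
  if (end > nchar(sequence)) {
    stop(sprintf("region %d-%d out of range for sequence of length %d",
                 start, end, nchar(sequence)), call. = FALSE)
  }
  substring(sequence, start, end)
}
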