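#' Sliding-window coordinates over a sequence
#'
#' Windows of `window` residues advance by `step`; if the final residue
#' would be left uncovered, one extra window anchored at the sequence end
#' (`length - window + 1`, `length`) is appended, so every residue is
#' covered. Sequences shorter than the window are scanned as a single
#' whole-sequence window.
#'
#' @param length Sequence length in residues.
#' @param window Window size (default 20).
#' @param step Step size (default 10); `1 <= step <= window`.
#' @return A tibble with columns `start`, `end` (1-based inclusive).
#' @examples
#' sliding_windows(25) # (1,20), (6,25)
#' @export
sliding_windows <- function(length, window = 20L, step = 10L) {
  stopifnot(length >= 1L, step >= 1L, step <= window)
  if (length < window) {
    return(tibble::tibble(start = 1L, end = as.integer(length)))
  }
  starts <- seq.int(1L, length - window + 1L, by = step)
  ends <- starts + window - 1L
  if (ends[base::length(ends)] < length) {
    starts <- c(starts, length - window + 1L)
    ends <- c(ends, as.integer(length))
  }
  tibble::tibble(start = as.integer(starts), end = as.integer(ends))
}

#' Annotate reference LCRs on one protein
#'
#' Profiles every sliding window and keeps those satisfying the operational
#' reference rule — mutation percentage strictly below `max_mutation_pct`
#' AND dominance percentage strictly above `min_dominance_pct` (defaults 50
#' and 50). Overlapping or adjacent passing windows are merged into maximal
#' regions.
#'
#' @param id Protein id.
#' @param sequence Protein sequence.
#' @param window,step Window scheme (defaults 20 and 10).
#' @param max_mutation_pct,min_dominance_pct Strict thresholds in (0, 100).
#' @param x_metric `"minperiod"` or `"homorepeat"` mutation metric.
#' @return A merged region tibble with `method = "reference"`.
#' @export
annotate_protein <- function(id, sequence, window = 20L, step = 10L,
                             max_mutation_pct = 50, min_dominance_pct = 50,
                             x_metric = c("minperiod", "homorepeat")) {
  x_metric <- match.arg(x_metric)
  stopifnot(max_mutation_pct > 0, max_mutation_pct < 100,
            min_dominance_pct > 0, min_dominance_pct < 100)
  win <- sliding_windows(nchar(sequence), window, step)
  segs <- substring(sequence, win$start, win$end)
  prof <- purrr::map_dfr(segs, profile_segment, x_metric = x_metric)
  keep <- prof$mutation_pct < max_mutation_pct &
    prof$dominance_pct > min_dominance_pct
  if (!any(keep)) {
    return(as_regions(tibble::tibble(protein_id = character(),
                                     start = integer(), end = integer()),
                      method = "reference"))
  }
  merge_intervals(tibble::tibble(protein_id = id,
                                 start = win$start[keep],
                                 end = win$end[keep],
                                 method = "reference"))
}

#' Annotate reference LCRs over a whole proteome
#'
#' Maps [annotate_protein()] over all proteins; the result is the package's
#' operational reference LCR set.
#'
#' @param proteome A proteome tibble.
#' @inheritParams annotate_protein
#' @return A merged region tibble with `method = "reference"`.
#' @export
annotate_proteome <- function(proteome, window = 20L, step = 10L,
                              max_mutation_pct = 50, min_dominance_pct = 50,
                              x_metric = c("minperiod", "homorepeat")) {
  x_metric <- match.arg(x_metric)
  if (nrow(proteome) == 0L) {
    return(as_regions(tibble::tibble(protein_id = character(),
                                     start = integer(), end = integer()),
                      method = "reference"))
  }
  out <- purrr::map2_dfr(proteome$id, proteome$sequence, annotate_protein,
                         window = window, step = step,
                         max_mutation_pct = max_mutation_pct,
                         min_dominance_pct = min_dominance_pct,
                         x_metric = x_metric)
  as_regions(out, method = "reference")
}
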