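#' Dominant-motif annotation of a segment
#'
#' Finds the dominant tandem repeat unit (lengths 1-3) and classifies the
#' segment as Monopeptide, Dipeptide or Tripeptide when the unit's tandem
#' run covers at least `threshold` of the segment, by the length of the
#' primitive unit (so "AA" counts as the monopeptide "A" and "ABAB" as the
#' dipeptide "AB"); otherwise Other with an empty motif.
#'
#' @param seq A single sequence.
#' @param threshold Minimum tandem coverage to call a motif (default 0.5).
#' @return A one-row tibble: `motif`, `category`, `coverage`.
#' @examples
#' dominant_motif("ASASASAS") # AS, Dipeptide
#' @export
dominant_motif <- function(seq, threshold = 0.5) {
  rep_unit <- dominant_repeat_unit(seq, kmax = 3L)
  unit <- primitive_unit(rep_unit$unit)
  if (rep_unit$coverage >= threshold) {
    category <- c("Monopeptide", "Dipeptide", "Tripeptide")[nchar(unit)]
  } else {
    category <- "Other"
    unit <- ""
  }
  tibble::tibble(motif = unit, category = category,
                 coverage = rep_unit$coverage)
}

#' Per-consensus-tier summaries
#'
#' For each consensus level k of a [multi_intersect()] result: the
#' proportions of Monopeptide/Dipeptide/Tripeptide/Other dominant motifs,
#' and quartile summaries of Shannon entropy and purity over the tier's
#' segment sequences. Tiers with no segments (up to `k_max`) are reported
#' as empty rows, not dropped. Outlying segments are retained; excluding
#' them is a plotting choice, not a summary one.
#'
#' @param segments Consensus segments from [multi_intersect()].
#' @param proteome A proteome tibble.
#' @param k_max Highest tier to report (default: max observed k).
#' @param motif_threshold Passed to [dominant_motif()].
#' @return A tibble with one row per k: `k`, `n_segments`, motif-category
#'   proportions (`prop_monopeptide`, ..., `prop_other`), and quartiles
#'   `entropy_q1`, `entropy_median`, `entropy_q3`, `purity_q1`,
#'   `purity_median`, `purity_q3`.
#' @export
tier_summaries <- function(segments, proteome, k_max = NULL,
                           motif_threshold = 0.5) {
  if (is.null(k_max)) k_max <- max(segments$k, 1L)
  idx <- match(segments$protein_id, proteome$id)
  if (anyNA(idx)) {
    stop("segment on protein absent from proteome: '",
         segments$protein_id[which(is.na(idx))[1]], "'", call. = FALSE)
  }
  withseq <- segments |>
    dplyr::mutate(sequence = substring(proteome$sequence[idx],
                                       .data$start, .data$end))
  purrr::map_dfr(seq_len(k_max), function(kk) {
    seqs <- withseq$sequence[withseq$k == kk]
    if (length(seqs) == 0L) {
      return(tibble::tibble(k = kk, n_segments = 0L,
                            prop_monopeptide = NA_real_, prop_dipeptide = NA_real_,
                            prop_tripeptide = NA_real_, prop_other = NA_real_,
                            entropy_q1 = NA_real_, entropy_median = NA_real_,
                            entropy_q3 = NA_real_, purity_q1 = NA_real_,
                            purity_median = NA_real_, purity_q3 = NA_real_))
    }
    cats <- purrr::map_chr(seqs, function(s) dominant_motif(s, motif_threshold)$category)
    ent <- shannon_entropy(seqs)
    pur <- purity(seqs)
    qe <- stats::quantile(ent, c(.25, .5, .75), names = FALSE)
    qp <- stats::quantile(pur, c(.25, .5, .75), names = FALSE)
    tibble::tibble(k = kk, n_segments = length(seqs),
                   prop_monopeptide = mean(cats == "Monopeptide"),
                   prop_dipeptide = mean(cats == "Dipeptide"),
                   prop_tripeptide = mean(cats == "Tripeptide"),
                   prop_other = mean(cats == "Other"),
                   entropy_q1 = qe[1], entropy_median = qe[2], entropy_q3 = qe[3],
                   purity_q1 = qp[1], purity_median = qp[2], purity_q3 = qp[3])
  })
}

#' Purity-retention curves per method
#'
#' For each method, the fraction of its regions whose purity (dominance
#' fraction x 100) is at least each threshold — a non-increasing curve with
#' retained(0) = 1.
#'
#' @param region_sets A named list of region tibbles or a single tibble with
#'   a `method` column.
#' @param proteome A proteome tibble.
#' @param thresholds Purity levels in percent (default `seq(0, 100, by = 5)`).
#' @return A tibble with `method`, `threshold`, `retained`.
#' @export
purity_retention <- function(region_sets, proteome,
                             thresholds = seq(0, 100, by = 5)) {
  if (is.data.frame(region_sets)) {
    region_sets <- split(region_sets, region_sets$method)
  }
  nm <- names(region_sets)
  if (is.null(nm)) nm <- paste0("method", seq_along(region_sets))
  purrr::map2_dfr(region_sets, nm, function(rs, label) {
    rs <- as_regions(rs)
    if (nrow(rs) == 0L) {
      stop("empty region set for method '", label, "'", call. = FALSE)
    }
    pur <- 100 * purity(region_sequences(rs, proteome)$sequence)
    tibble::tibble(method = label, threshold = thresholds,
                   retained = vapply(thresholds,
                                     function(t) mean(pur >= t), numeric(1)))
  })
}
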