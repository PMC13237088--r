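#' Residue-level confusion counts against a reference
#'
#' Every residue of the proteome subset is labelled: TP if covered by both
#' the reference and the prediction, FN if reference only, FP if prediction
#' only, TN if neither; counts are pooled over proteins. The four counts
#' always sum to the total residue count.
#'
#' @param reference,predicted Region tibbles (merged internally).
#' @param proteome A proteome tibble; its proteins define the residue
#'   universe. Predictions on proteins absent from it are an error.
#' @return A one-row tibble with `TP`, `FP`, `FN`, `TN`.
#' @export
residue_confusion <- function(reference, predicted, proteome) {
  reference <- merge_intervals(reference)
  predicted <- merge_intervals(predicted)
  for (rs in list(reference, predicted)) {
    missing <- setdiff(rs$protein_id, proteome$id)
    if (length(missing) > 0L) {
      stop("regions on protein absent from proteome: '", missing[1], "'",
           call. = FALSE)
    }
  }
  rr <- ranges_by_protein(reference)
  rp <- ranges_by_protein(predicted)
  total <- sum(proteome$length)
  ref_len <- sum(reference$end - reference$start + 1)
  pred_len <- sum(predicted$end - predicted$start + 1)
  shared <- intersect(names(rr), names(rp))
  tp <- sum(vapply(shared, function(p) {
    sum(IRanges::width(IRanges::intersect(rr[[p]], rp[[p]])))
  }, numeric(1)))
  tibble::tibble(TP = tp, FP = pred_len - tp, FN = ref_len - tp,
                 TN = total - ref_len - pred_len + tp)
}

#' True-positive rate TP / (TP + FN)
#'
#' Undefined (NA) when the denominator is zero — never reported as 0.
#'
#' @param confusion A confusion tibble from [residue_confusion()].
#' @return A rate in \[0, 1\] or NA.
#' @export
tpr <- function(confusion) {
  denom <- confusion$TP + confusion$FN
  ifelse(denom > 0, confusion$TP / denom, NA_real_)
}

#' False-positive rate FP / (FP + TN)
#'
#' Undefined (NA) when the denominator is zero.
#'
#' @param confusion A confusion tibble from [residue_confusion()].
#' @return A rate in \[0, 1\] or NA.
#' @export
fpr <- function(confusion) {
  denom <- confusion$FP + confusion$TN
  ifelse(denom > 0, confusion$FP / denom, NA_real_)
}

#' Gene-length decile assignment
#'
#' Proteins are sorted by length ascending (ties stay in stable id order)
#' and split into `n_bins` contiguous groups whose sizes differ by at most
#' one, the larger groups first.
#'
#' @param proteome A proteome tibble with at least `n_bins` proteins.
#' @param n_bins Number of bins (default 10).
#' @return A tibble with `id` and `stratum` (ordered factor `"1"`..`"10"`).
#' @export
stratify_gene_length <- function(proteome, n_bins = 10L) {
  n <- nrow(proteome)
  if (n < n_bins) {
    stop("fewer proteins (", n, ") than bins (", n_bins, ")", call. = FALSE)
  }
  ord <- order(proteome$length, proteome$id)
  base_size <- n %/% n_bins
  sizes <- rep(base_size, n_bins)
  extra <- n %% n_bins
  if (extra > 0L) sizes[seq_len(extra)] <- base_size + 1L
  lev <- as.character(seq_len(n_bins))
  tibble::tibble(id = proteome$id[ord],
                 stratum = factor(rep(lev, times = sizes), levels = lev,
                                  ordered = TRUE))
}

#' LCR-to-gene entropy ratio per protein
#'
#' Shannon entropy of the concatenated reference-LCR residues of a protein
#' divided by the entropy of the full sequence; NA when the protein has no
#' reference region or zero whole-sequence entropy.
#'
#' @param proteome A proteome tibble.
#' @param reference A reference region tibble.
#' @return A tibble with `id` and `entropy_ratio`.
#' @export
entropy_ratio <- function(proteome, reference) {
  reference <- merge_intervals(reference)
  withseq <- region_sequences(reference, proteome)
  lcr_seq <- withseq |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::summarise(lcr = paste(.data$sequence, collapse = ""),
                     .groups = "drop")
  proteome |>
    dplyr::left_join(lcr_seq, by = c(id = "protein_id")) |>
    dplyr::mutate(
      whole = shannon_entropy(.data$sequence),
      entropy_ratio = dplyr::if_else(
        is.na(.data$lcr) | .data$whole == 0, NA_real_,
        unname(vapply(.data$lcr, function(s) if (is.na(s)) NA_real_ else
          shannon_entropy(s), numeric(1))) / .data$whole)) |>
    dplyr::select("id", "entropy_ratio")
}

# Protein -> stratum maps for the four stratifications. Proteins mapping to
# NA are excluded from the stratified tables.
stratum_map <- function(stratifier, proteome, reference, n_bins = 10L) {
  switch(
    stratifier,
    gene_length = stratify_gene_length(proteome, n_bins),
    lcr_count = {
      cnt <- merge_intervals(reference) |> dplyr::count(.data$protein_id)
      lev <- c("1", "2", "3", "4", "5", "6+")
      tibble::tibble(id = proteome$id) |>
        dplyr::left_join(cnt, by = c(id = "protein_id")) |>
        dplyr::mutate(stratum = dplyr::if_else(
          is.na(.data$n) | .data$n == 0L, NA_character_,
          dplyr::if_else(.data$n >= 6L, "6+", as.character(.data$n)))) |>
        dplyr::mutate(stratum = factor(.data$stratum, levels = lev,
                                       ordered = TRUE)) |>
        dplyr::select("id", "stratum")
    },
    coverage = {
      cov <- coverage_per_protein(reference, proteome)
      lev <- c("5", "10", "15", "20", ">20")
      tibble::tibble(id = cov$id,
                     stratum = factor(as.character(
                       cut(cov$coverage_pct, breaks = c(0, 5, 10, 15, 20, Inf),
                           labels = lev, right = TRUE)),
                       levels = lev, ordered = TRUE))
    },
    entropy_ratio = {
      er <- entropy_ratio(proteome, reference)
      lev <- c("0.2", "0.4", "0.6", "0.8", "1.0")
      tibble::tibble(id = er$id,
                     stratum = factor(as.character(
                       cut(er$entropy_ratio, breaks = seq(0, 1, by = 0.2),
                           labels = lev, right = TRUE,
                           include.lowest = TRUE)),
                       levels = lev, ordered = TRUE))
    },
    stop("unknown stratifier: ", stratifier, call. = FALSE)
  )
}

#' Stratified residue-level TPR/FPR evaluation
#'
#' Evaluates each prediction method against the reference under one of four
#' stratifications of the proteome — gene-length deciles, reference-LCR
#' count per protein (1-6+), reference coverage percentage (5/10/15/20/>20)
#' or LCR-to-gene entropy ratio (0.2-1.0). Residues are pooled within each
#' stratum, and an unweighted mean of the per-stratum rates summarises each
#' method. Strata with no proteins, or with an undefined rate, are reported
#' as missing.
#'
#' @param reference A reference region tibble.
#' @param predictions A named list of region tibbles or a tibble with a
#'   `method` column.
#' @param proteome A proteome tibble.
#' @param stratifier One of `"gene_length"`, `"lcr_count"`, `"coverage"`,
#'   `"entropy_ratio"`.
#' @param per_protein Average per-protein rates within each stratum instead
#'   of pooling residues (default FALSE: pooled).
#' @return A list with `strata` (tibble: `method`, `stratum`, confusion
#'   counts, `tpr`, `fpr`) and `means` (tibble: `method`, `mean_tpr`,
#'   `mean_fpr`).
#' @export
evaluate_stratified <- function(reference, predictions, proteome,
                                stratifier = c("gene_length", "lcr_count",
                                               "coverage", "entropy_ratio"),
                                per_protein = FALSE) {
  stratifier <- match.arg(stratifier)
  if (is.data.frame(predictions)) {
    predictions <- split(predictions, predictions$method)
  }
  nm <- names(predictions)
  if (is.null(nm)) nm <- paste0("method", seq_along(predictions))
  smap <- stratum_map(stratifier, proteome, reference)
  lev <- levels(smap$stratum)
  strata <- purrr::map2_dfr(predictions, nm, function(pred, label) {
    purrr::map_dfr(lev, function(st) {
      ids <- smap$id[!is.na(smap$stratum) & smap$stratum == st]
      if (length(ids) == 0L) {
        return(tibble::tibble(method = label, stratum = st, n_proteins = 0L,
                              TP = NA_real_, FP = NA_real_, FN = NA_real_,
                              TN = NA_real_, tpr = NA_real_, fpr = NA_real_))
      }
      sub_prot <- proteome[proteome$id %in% ids, , drop = FALSE]
      sub_ref <- reference[reference$protein_id %in% ids, , drop = FALSE]
      sub_pred <- pred[pred$protein_id %in% ids, , drop = FALSE]
      if (per_protein) {
        rates <- purrr::map_dfr(ids, function(one) {
          cm <- residue_confusion(
            sub_ref[sub_ref$protein_id == one, , drop = FALSE],
            sub_pred[sub_pred$protein_id == one, , drop = FALSE],
            sub_prot[sub_prot$id == one, , drop = FALSE])
          tibble::tibble(tpr = tpr(cm), fpr = fpr(cm))
        })
        cm <- residue_confusion(sub_ref, sub_pred, sub_prot)
        tibble::tibble(method = label, stratum = st,
                       n_proteins = length(ids),
                       TP = cm$TP, FP = cm$FP, FN = cm$FN, TN = cm$TN,
                       tpr = mean(rates$tpr, na.rm = TRUE),
                       fpr = mean(rates$fpr, na.rm = TRUE))
      } else {
        cm <- residue_confusion(sub_ref, sub_pred, sub_prot)
        tibble::tibble(method = label, stratum = st,
                       n_proteins = length(ids),
                       TP = cm$TP, FP = cm$FP, FN = cm$FN, TN = cm$TN,
                       tpr = tpr(cm), fpr = fpr(cm))
      }
    })
  })
  strata$stratum <- factor(strata$stratum, levels = lev, ordered = TRUE)
  means <- strata |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(mean_tpr = mean(.data$tpr, na.rm = TRUE),
                     mean_fpr = mean(.data$fpr, na.rm = TRUE),
                     .groups = "drop")
  list(strata = strata, means = means)
}
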