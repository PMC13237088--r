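#' Shannon entropy of an amino-acid sequence
#'
#' Entropy in bits, `-sum(f * log2(f))` over the observed symbol frequencies
#' of the segment itself, with no pseudocounts. For the 20-letter amino-acid
#' alphabet the ceiling is `log2(20)` (about 4.32 bits), attained at uniform
#' usage; homorepeats score 0.
#'
#' @param seq Character vector of sequences (vectorised).
#' @return Numeric vector of entropies in bits.
#' @examples
#' shannon_entropy("AAAA")                  # 0
#' shannon_entropy("ACDEFGHIKLMNPQRSTVWY") # log2(20)
#' @export
shannon_entropy <- function(seq) {
  vapply(seq, function(s) {
    if (is.na(s) || nchar(s) == 0L) stop("empty sequence", call. = FALSE)
    f <- table(strsplit(s, "", fixed = TRUE)[[1]])
    f <- f / sum(f)
    -sum(f * log2(f))
  }, numeric(1), USE.NAMES = FALSE)
}

res_counts <- function(s) {
  if (is.na(s) || nchar(s) == 0L) stop("empty sequence", call. = FALSE)
  table(strsplit(s, "", fixed = TRUE)[[1]])
}

#' Compositional dominance of a segment
#'
#' The most frequent residue and its percentage of the segment — the y-axis
#' of the LC diagram. Ties are broken by lexicographic order of the residue
#' symbol.
#'
#' @param seq Character vector of sequences.
#' @return A tibble with columns `dominant_residue` and `dominance_pct`.
#' @examples
#' dominance("ACDEFEGEIE") # E, 40
#' @export
dominance <- function(seq) {
  purrr::map_dfr(seq, function(s) {
    f <- res_counts(s)
    top <- sort(names(f)[f == max(f)])[1]
    tibble::tibble(dominant_residue = top,
                   dominance_pct = 100 * as.numeric(f[top]) / sum(f))
  })
}

#' Purity of a segment
#'
#' Fraction of residues equal to the primary (most frequent) amino acid;
#' identically `dominance_pct / 100`, in (0, 1].
#'
#' @param seq Character vector of sequences.
#' @return Numeric vector of purities.
#' @export
purity <- function(seq) {
  dominance(seq)$dominance_pct / 100
}

#' Mutational distance to the homorepeat
#'
#' Percentage of residues that must change to turn the segment into a perfect
#' homorepeat of its dominant residue; identically `100 - dominance_pct`
#' (the period-1 distance).
#'
#' @param seq Character vector of sequences.
#' @return Numeric vector of percentages.
#' @examples
#' mutation_to_homorepeat("ACDEFEGEIE") # 60
#' @export
mutation_to_homorepeat <- function(seq) {
  100 - dominance(seq)$dominance_pct
}

#' Minimal mutational distance to a perfect periodic repeat
#'
#' For each candidate period `p` the positions are partitioned into phase
#' classes by `(position - 1) mod p`; the consensus of a class is its most
#' frequent symbol and mismatches are positions differing from their phase
#' consensus. A partial terminal repeat unit is allowed. Returns the minimum
#' mismatch percentage over periods `1..max_period` and the smallest period
#' attaining it. Because period 1 is always admitted, the result never
#' exceeds [mutation_to_homorepeat()] — the triangle bound of the LC diagram.
#'
#' @param seq A single sequence.
#' @param max_period Largest period searched; defaults to `floor(L/2)` so
#'   every admitted period yields at least two (possibly partial) unit
#'   copies. Values outside `1..floor(L/2)` are clamped.
#' @return A list with `mutation_pct` and `best_period`.
#' @examples
#' min_mutation_over_periods("ABABABAB") # 0 at period 2
#' @export
min_mutation_over_periods <- function(seq, max_period = NULL) {
  stopifnot(length(seq) == 1L)
  if (is.na(seq) || nchar(seq) == 0L) stop("empty sequence", call. = FALSE)
  x <- strsplit(seq, "", fixed = TRUE)[[1]]
  L <- length(x)
  if (L < 2L) return(list(mutation_pct = 0, best_period = 1L))
  pmax_adm <- max(1L, L %/% 2L)
  if (is.null(max_period)) max_period <- pmax_adm
  max_period <- min(max(1L, as.integer(max_period)), pmax_adm)
  phase0 <- seq_len(L) - 1L
  best_mis <- L + 1L
  best_p <- 1L
  for (p in seq_len(max_period)) {
    ph <- phase0 %% p
    mis <- 0L
    for (k in 0L:(p - 1L)) {
      cnt <- tabulate(match(x[ph == k], unique(x[ph == k])))
      mis <- mis + sum(cnt) - max(cnt)
    }
    if (mis < best_mis) {
      best_mis <- mis
      best_p <- p
    }
  }
  list(mutation_pct = 100 * best_mis / L, best_period = best_p)
}

#' Dominant tandem-repeat unit of a segment
#'
#' Scans all repeat units of length `1..kmax` and every start position, and
#' finds the unit whose maximal run of tandem exact copies (a partial
#' terminal copy counts its matching residues) covers the largest fraction
#' of the segment. Ties are broken by shorter unit, then lexicographically.
#'
#' @param seq A single sequence.
#' @param kmax Maximum unit length (default 3).
#' @return A list with `unit` and `coverage` (fraction of the segment).
#' @examples
#' dominant_repeat_unit("ASASASXX") # "AS", 0.75
#' @export
dominant_repeat_unit <- function(seq, kmax = 3L) {
  stopifnot(length(seq) == 1L, kmax >= 1L)
  if (is.na(seq) || nchar(seq) == 0L) stop("empty sequence", call. = FALSE)
  x <- strsplit(seq, "", fixed = TRUE)[[1]]
  L <- length(x)
  best_cov <- -1
  best_k <- NA_integer_
  best_unit <- NA_character_
  for (k in seq_len(min(kmax, L))) {
    # streak[i]: length of the periodic run (period k) starting at i
    m <- L - k
    streak <- rep.int(k, L - k + 1L)
    if (m > 0L) {
      eq <- x[(k + 1L):L] == x[1L:(L - k)]
      tail_true <- integer(m)
      acc <- 0L
      for (i in m:1L) {
        acc <- if (eq[i]) acc + 1L else 0L
        tail_true[i] <- acc
      }
      streak[1L:m] <- k + tail_true
    }
    for (i in seq_along(streak)) {
      cov <- streak[i] / L
      if (cov > best_cov + 1e-12) {
        best_cov <- cov
        best_k <- k
        best_unit <- paste(x[i:(i + k - 1L)], collapse = "")
      } else if (abs(cov - best_cov) <= 1e-12 && k == best_k) {
        u <- paste(x[i:(i + k - 1L)], collapse = "")
        if (u < best_unit) best_unit <- u
      }
    }
  }
  list(unit = best_unit, coverage = best_cov)
}

#' Reduce a repeat unit to its primitive form
#'
#' A unit that is itself a repetition of a shorter unit ("AA" -> "A",
#' "ABAB" -> "AB") is reduced, so that homorepeats are never double-counted
#' as di- or tripeptide repeats.
#'
#' @param unit A repeat-unit string.
#' @return The primitive unit.
#' @export
primitive_unit <- function(unit) {
  k <- nchar(unit)
  for (d in seq_len(k)) {
    if (k %% d == 0L &&
        strrep(substr(unit, 1L, d), k %/% d) == unit) {
      return(substr(unit, 1L, d))
    }
  }
  unit
}

#' Classify a point of the LC diagram
#'
#' The diagram is cut at the operational 50/50 thresholds into three
#' segments: low-complexity (LCR: x < 50, y > 50), long tandem repeat
#' (LTR: x < 50, y < 50) and high-complexity (HCR: x > 50, y < 50).
#' Boundary values of exactly 50, and the unreachable x > 50 & y > 50
#' corner, are `UNDEFINED`.
#'
#' @param mutation_pct,dominance_pct Numeric vectors in \[0, 100\].
#' @return Character vector in `{"LCR","LTR","HCR","UNDEFINED"}`.
#' @export
classify_point <- function(mutation_pct, dominance_pct) {
  if (any(mutation_pct < 0 | mutation_pct > 100 |
          dominance_pct < 0 | dominance_pct > 100, na.rm = TRUE)) {
    stop("mutation_pct and dominance_pct must lie in [0, 100]", call. = FALSE)
  }
  dplyr::case_when(
    mutation_pct < 50 & dominance_pct > 50 ~ "LCR",
    mutation_pct < 50 & dominance_pct < 50 ~ "LTR",
    mutation_pct > 50 & dominance_pct < 50 ~ "HCR",
    TRUE ~ "UNDEFINED"
  )
}

#' Full complexity profile of one segment
#'
#' Bundles every per-segment descriptor of the LC diagram: Shannon entropy,
#' dominant residue and dominance percentage, purity, the minimum mutational
#' distance over periods with its best period, the period-1 homorepeat
#' distance, and the triangle segment class. The x-axis metric used for
#' classification is selectable: the minimum over periods (default) or the
#' homorepeat distance.
#'
#' @param seq A single sequence.
#' @param x_metric `"minperiod"` (default) or `"homorepeat"`.
#' @param max_period Passed to [min_mutation_over_periods()].
#' @return A one-row tibble with columns `length`, `entropy`,
#'   `dominant_residue`, `dominance_pct`, `purity`, `mutation_pct`,
#'   `best_period`, `homorepeat_mutation_pct`, `segment_class`.
#' @examples
#' profile_segment("ACDEFEGEIE")
#' @export
profile_segment <- function(seq, x_metric = c("minperiod", "homorepeat"),
                            max_period = NULL) {
  x_metric <- match.arg(x_metric)
  stopifnot(length(seq) == 1L)
  dom <- dominance(seq)
  mm <- min_mutation_over_periods(seq, max_period)
  homo <- 100 - dom$dominance_pct
  x <- if (x_metric == "minperiod") mm$mutation_pct else homo
  tibble::tibble(
    length = nchar(seq),
    entropy = shannon_entropy(seq),
    dominant_residue = dom$dominant_residue,
    dominance_pct = dom$dominance_pct,
    purity = dom$dominance_pct / 100,
    mutation_pct = x,
    best_period = mm$best_period,
    homorepeat_mutation_pct = homo,
    segment_class = classify_point(x, dom$dominance_pct)
  )
}

#' Complexity profiles for a table of regions
#'
#' Extracts each region's subsequence from the proteome and profiles it with
#' [profile_segment()]; the tabular entry point of the windowed pipeline.
#'
#' @param regions A region tibble.
#' @param proteome A proteome tibble.
#' @inheritParams profile_segment
#' @return The region tibble with the profile columns appended.
#' @export
profile_regions <- function(regions, proteome,
                            x_metric = c("minperiod", "homorepeat"),
                            max_period = NULL) {
  x_metric <- match.arg(x_metric)
  withseq <- region_sequences(regions, proteome)
  prof <- purrr::map_dfr(withseq$sequence, profile_segment,
                         x_metric = x_metric, max_period = max_period)
  dplyr::bind_cols(withseq |> dplyr::select(-"sequence"), prof)
}
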