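# IRanges does the interval arithmetic; all public surfaces are tibbles in
# 1-based inclusive coordinates, which is also IRanges' native convention.

ranges_by_protein <- function(regions) {
  split(IRanges::IRanges(start = regions$start, end = regions$end),
        regions$protein_id)
}

#' Merge overlapping and adjacent intervals
#'
#' Unites intervals on the same protein that overlap or are bookended
#' (`end + 1 == next start`); residue coverage is preserved exactly. The
#' method label survives only when it is constant within the input.
#'
#' @param regions A region tibble.
#' @return A merged, sorted region tibble.
#' @examples
#' merge_intervals(tibble::tibble(protein_id = "p1",
#'                                start = c(1, 6), end = c(5, 8)))
#' @export
merge_intervals <- function(regions) {
  regions <- as_regions(regions)
  if (nrow(regions) == 0L) return(regions)
  meth <- unique(regions$method)
  meth <- if (length(meth) == 1L) meth else NA_character_
  merged <- purrr::imap_dfr(ranges_by_protein(regions), function(ir, pid) {
    red <- IRanges::reduce(ir, min.gapwidth = 1L)
    tibble::tibble(protein_id = pid, start = IRanges::start(red),
                   end = IRanges::end(red))
  })
  as_regions(merged, method = meth)
}

#' Residue-level multi-method intersection with consensus levels
#'
#' The residue-space analogue of `bedtools multiinter`: per protein, the
#' residues covered by at least one method are partitioned into maximal runs
#' with constant method-membership. Each run becomes one consensus segment
#' carrying its consensus level `k` (number of distinct methods covering
#' every residue of the run) and the sorted method list.
#'
#' @param region_sets A list of region tibbles (one per method), or a single
#'   tibble with a `method` column distinguishing them.
#' @return A tibble of consensus segments: `protein_id`, `start`, `end`,
#'   `k`, `methods` (comma-separated sorted labels).
#' @export
multi_intersect <- function(region_sets) {
  if (is.data.frame(region_sets)) {
    region_sets <- split(region_sets, region_sets$method)
  }
  stopifnot(length(region_sets) >= 1L)
  merged <- purrr::map(region_sets, merge_intervals)
  # list names identify the methods; fall back to the method column
  labels <- purrr::imap_chr(merged, function(rs, nm) {
    if (is.character(nm) && nzchar(nm)) return(nm)
    m <- unique(rs$method)
    if (length(m) == 1L && !is.na(m)) m else paste0("method", nm)
  })
  if (anyDuplicated(labels)) {
    stop("method labels are not unique: ",
         paste(labels[duplicated(labels)], collapse = ", "), call. = FALSE)
  }
  all_regions <- purrr::map2_dfr(merged, labels,
                                 function(rs, lb) dplyr::mutate(rs, method = lb))
  if (nrow(all_regions) == 0L) {
    return(tibble::tibble(protein_id = character(), start = integer(),
                          end = integer(), k = integer(), methods = character()))
  }
  out <- purrr::map_dfr(split(all_regions, all_regions$protein_id), function(df) {
    ir <- IRanges::IRanges(df$start, df$end)
    dis <- IRanges::disjoin(ir)
    hits <- IRanges::findOverlaps(dis, ir)
    memb <- split(df$method[S4Vectors::subjectHits(hits)],
                  S4Vectors::queryHits(hits))
    key <- vapply(memb, function(m) paste(sort(unique(m)), collapse = ","),
                  character(1))
    seg <- tibble::tibble(protein_id = df$protein_id[1],
                          start = IRanges::start(dis), end = IRanges::end(dis),
                          methods = unname(key[as.character(seq_along(dis))]))
    # fuse adjacent disjoint pieces with identical membership
    if (nrow(seg) > 1L) {
      new_run <- c(TRUE, !(seg$methods[-1] == seg$methods[-nrow(seg)] &
                             seg$start[-1] == seg$end[-nrow(seg)] + 1L))
      seg$grp <- cumsum(new_run)
      seg <- seg |>
        dplyr::group_by(.data$grp) |>
        dplyr::summarise(protein_id = dplyr::first(.data$protein_id),
                         start = min(.data$start), end = max(.data$end),
                         methods = dplyr::first(.data$methods),
                         .groups = "drop") |>
        dplyr::select(-"grp")
    }
    seg
  })
  out |>
    dplyr::mutate(k = vapply(strsplit(.data$methods, ",", fixed = TRUE),
                             length, integer(1))) |>
    dplyr::select("protein_id", "start", "end", "k", "methods") |>
    dplyr::arrange(.data$protein_id, .data$start)
}

#' Residue-level Jaccard similarity of two region sets
#'
#' Intersection over union of the residue sets covered by the two inputs,
#' pooled across proteins (the `bedtools jaccard` statistic at residue
#' resolution). An empty union yields 0 by convention.
#'
#' @param a,b Region tibbles.
#' @return A similarity in \[0, 1\].
#' @export
region_jaccard <- function(a, b) {
  a <- merge_intervals(a)
  b <- merge_intervals(b)
  if (nrow(a) == 0L && nrow(b) == 0L) return(0)
  ra <- ranges_by_protein(a)
  rb <- ranges_by_protein(b)
  len_a <- sum(a$end - a$start + 1)
  len_b <- sum(b$end - b$start + 1)
  shared <- intersect(names(ra), names(rb))
  inter <- sum(vapply(shared, function(p) {
    sum(IRanges::width(IRanges::intersect(ra[[p]], rb[[p]])))
  }, numeric(1)))
  inter / (len_a + len_b - inter)
}

#' Pairwise Jaccard similarity matrix
#'
#' @param region_sets A named list of region tibbles, or a single tibble
#'   split by its `method` column.
#' @return A symmetric numeric matrix with unit diagonal (for non-empty
#'   sets), dimnames = method labels.
#' @export
jaccard_matrix <- function(region_sets) {
  if (is.data.frame(region_sets)) {
    region_sets <- split(region_sets, region_sets$method)
  }
  n <- length(region_sets)
  nm <- names(region_sets)
  if (is.null(nm)) nm <- paste0("method", seq_len(n))
  m <- diag(1, n)
  dimnames(m) <- list(nm, nm)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        m[i, j] <- m[j, i] <- region_jaccard(region_sets[[i]], region_sets[[j]])
      }
    }
  }
  for (i in seq_len(n)) {
    if (nrow(region_sets[[i]]) == 0L) m[i, i] <- 0
  }
  m
}

# Fixed bin schemes. Range labels own their right edge: (0,10], (10,20], ...
length_bin_breaks <- c(0, 10, 20, 50, 100, 200, Inf)
length_bin_labels <- c("0-10", "10-20", "20-50", "50-100", "100-200", ">200")
coverage_bin_breaks <- c(0, 20, 40, 60, 80, 100)
coverage_bin_labels <- c("0-20", "20-40", "40-60", "60-80", "80-100")
count_bin_labels <- c("0", "1-5", "5-10", "10-15", "15+")

#' Histogram of region lengths over the fixed length bins
#'
#' Bins: 0-10, 10-20, 20-50, 50-100, 100-200 and >200 residues, each label
#' owning its right edge (a length-10 region falls in "0-10").
#'
#' @param regions A region tibble.
#' @return A tibble with `bin` (ordered factor) and `n`.
#' @export
summarize_lengths <- function(regions) {
  regions <- as_regions(regions)
  len <- regions$end - regions$start + 1
  assigned <- cut(len, breaks = length_bin_breaks,
                  labels = length_bin_labels, right = TRUE)
  counts <- as.integer(table(factor(assigned, levels = length_bin_labels)))
  tibble::tibble(bin = factor(length_bin_labels, levels = length_bin_labels,
                              ordered = TRUE),
                 n = counts)
}

#' Histogram of per-protein LCR coverage over the fixed coverage bins
#'
#' Coverage is 100 x covered residues / protein length after per-protein
#' merging, binned into 0-20, 20-40, 40-60, 60-80 and 80-100 percent
#' (right-closed). Proteins with no regions are not counted.
#'
#' @param regions A region tibble.
#' @param proteome A proteome tibble.
#' @return A tibble with `bin` and `n`.
#' @export
summarize_coverage <- function(regions, proteome) {
  cov <- coverage_per_protein(regions, proteome)
  cov <- cov$coverage_pct[cov$coverage_pct > 0]
  assigned <- cut(cov, breaks = coverage_bin_breaks,
                  labels = coverage_bin_labels, right = TRUE)
  counts <- as.integer(table(factor(assigned, levels = coverage_bin_labels)))
  tibble::tibble(bin = factor(coverage_bin_labels,
                              levels = coverage_bin_labels, ordered = TRUE),
                 n = counts)
}

#' Per-protein merged coverage
#'
#' @param regions A region tibble.
#' @param proteome A proteome tibble.
#' @return A tibble with `id`, `covered` (residues) and `coverage_pct`,
#'   one row per proteome protein (zero where no region).
#' @export
coverage_per_protein <- function(regions, proteome) {
  merged <- merge_intervals(regions)
  cov <- merged |>
    dplyr::mutate(len = .data$end - .data$start + 1) |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::summarise(covered = sum(.data$len), .groups = "drop")
  proteome |>
    dplyr::select("id", "length") |>
    dplyr::left_join(cov, by = c(id = "protein_id")) |>
    dplyr::mutate(covered = dplyr::coalesce(.data$covered, 0L),
                  coverage_pct = 100 * .data$covered / .data$length) |>
    dplyr::select("id", "covered", "coverage_pct")
}

#' Histogram of raw region counts per protein
#'
#' Counts use the unmerged input (raw tool output); categories 0, 1-5,
#' 5-10, 10-15 and 15+ with right-closed ownership ([1,5], [6,10], [11,15],
#' [16, Inf)). Every proteome protein contributes one count.
#'
#' @param regions A region tibble.
#' @param proteome A proteome tibble.
#' @return A tibble with `bin` and `n`.
#' @export
summarize_counts <- function(regions, proteome) {
  regions <- as_regions(regions)
  cnt <- table(factor(regions$protein_id, levels = proteome$id))
  assigned <- cut(as.integer(cnt), breaks = c(-1, 0, 5, 10, 15, Inf),
                  labels = count_bin_labels, right = TRUE)
  counts <- as.integer(table(factor(assigned, levels = count_bin_labels)))
  tibble::tibble(bin = factor(count_bin_labels, levels = count_bin_labels,
                              ordered = TRUE),
                 n = counts)
}

#' Pooled amino-acid composition of a region set
#'
#' Residue counts pooled over all region subsequences, normalised to total
#' residues; the fractions sum to 1.
#'
#' @param regions A region tibble (non-empty).
#' @param proteome A proteome tibble.
#' @return A tibble with `residue` and `fraction`, one row per observed
#'   residue plus zero rows for unobserved standard amino acids.
#' @export
aa_composition <- function(regions, proteome) {
  regions <- as_regions(regions)
  if (nrow(regions) == 0L) {
    stop("empty region set: no residues to normalise", call. = FALSE)
  }
  seqs <- region_sequences(regions, proteome)$sequence
  chars <- strsplit(paste(seqs, collapse = ""), "", fixed = TRUE)[[1]]
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "", fixed = TRUE)[[1]]
  lev <- sort(union(aa20, unique(chars)))
  cnt <- table(factor(chars, levels = lev))
  tibble::tibble(residue = lev, fraction = as.numeric(cnt) / length(chars))
}
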