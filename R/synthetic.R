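# Deterministic synthetic proteomes with planted low-complexity structure,
# plus simulated pseudo-method predictions, so every analytic module can be
# exercised end-to-end with a known ground truth and no downloads.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "", fixed = TRUE)[[1]]

random_sequence <- function(n, composition = NULL) {
  if (is.null(composition)) {
    paste(sample(AA20, n, replace = TRUE), collapse = "")
  } else {
    stopifnot(length(composition) == 20L)
    paste(sample(AA20, n, replace = TRUE, prob = composition), collapse = "")
  }
}

mutate_sequence <- function(seq, rate) {
  if (rate <= 0) return(seq)
  x <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- stats::runif(length(x)) < rate
  if (any(hit)) {
    x[hit] <- vapply(x[hit], function(ch) sample(setdiff(AA20, ch), 1L),
                     character(1))
  }
  paste(x, collapse = "")
}

#' Declare a planted feature set
#'
#' Helper building the `features` tibble for [generate_proteome()]: each
#' row plants one region — a homorepeat (a run of one residue) or a tandem
#' repeat (consecutive copies of a short unit) — optionally degraded by iid
#' substitutions at `rate` per residue.
#'
#' @param kind `"homorepeat"` or `"tandem"` (recycled).
#' @param unit Residue (homorepeat) or unit string (tandem).
#' @param copies Number of unit copies; region length is
#'   `nchar(unit) * copies`.
#' @param rate Per-residue substitution rate in \[0, 1).
#' @return A feature tibble.
#' @export
planted_features <- function(kind, unit, copies, rate = 0) {
  tibble::tibble(kind = kind, unit = unit, copies = as.integer(copies),
                 rate = rate) |>
    dplyr::mutate(length = nchar(.data$unit) * .data$copies)
}

#' Generate a synthetic proteome with planted features
#'
#' Background sequences are iid draws from `composition` (default uniform
#' over the 20 standard amino acids); planted homorepeats and tandem
#' repeats (see [planted_features()]) are written over the background at
#' random non-overlapping positions. Fully deterministic for a given seed.
#'
#' @param n_proteins Number of proteins.
#' @param length_range Min/max protein length (uniform draw).
#' @param features A feature tibble from [planted_features()], or NULL.
#' @param composition Optional 20-vector of background residue frequencies.
#' @param seed Integer seed.
#' @param max_tries Placement retries per feature before giving up.
#' @return A list with `proteome` (tibble `id`, `sequence`, `length`) and
#'   `truth` (region tibble with `kind`, `unit`, `rate` metadata,
#'   `method = "truth"`).
#' @export
generate_proteome <- function(n_proteins, length_range = c(200L, 400L),
                              features = NULL, composition = NULL,
                              seed = 1L, max_tries = 200L) {
  stopifnot(n_proteins >= 1L, length_range[1] >= 1L,
            length_range[2] >= length_range[1])
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  lens <- sample(seq.int(length_range[1], length_range[2]), n_proteins,
                 replace = TRUE)
  ids <- sprintf("sp%03d", seq_len(n_proteins))
  seqs <- vapply(lens, random_sequence, character(1),
                 composition = composition)
  occupied <- lapply(seq_len(n_proteins), function(i) IRanges::IRanges())
  truth <- list()
  if (!is.null(features) && nrow(features) > 0L) {
    features <- planted_features(features$kind, features$unit,
                                 features$copies,
                                 if ("rate" %in% names(features)) features$rate else 0)
    stopifnot(all(features$kind %in% c("homorepeat", "tandem")),
              all(features$rate >= 0 & features$rate < 1))
    for (f in seq_len(nrow(features))) {
      flen <- features$length[f]
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        p <- sample.int(n_proteins, 1L)
        if (lens[p] < flen) next
        s <- sample.int(lens[p] - flen + 1L, 1L)
        cand <- IRanges::IRanges(s, s + flen - 1L)
        if (length(IRanges::findOverlaps(cand, occupied[[p]])) > 0L) next
        unit_seq <- strrep(features$unit[f], features$copies[f])
        unit_seq <- mutate_sequence(unit_seq, features$rate[f])
        substr(seqs[p], s, s + flen - 1L) <- unit_seq
        occupied[[p]] <- c(occupied[[p]], cand)
        truth[[length(truth) + 1L]] <- tibble::tibble(
          protein_id = ids[p], start = s, end = s + flen - 1L,
          method = "truth", kind = features$kind[f],
          unit = features$unit[f], rate = features$rate[f])
        placed <- TRUE
        break
      }
      if (!placed) {
        stop("could not place feature ", f, " (length ", flen,
             ") without overlap after ", max_tries, " tries", call. = FALSE)
      }
    }
  }
  truth_tbl <- if (length(truth) > 0L) {
    dplyr::bind_rows(truth) |>
      dplyr::arrange(.data$protein_id, .data$start, .data$end)
  } else {
    tibble::tibble(protein_id = character(), start = integer(),
                   end = integer(), method = character(), kind = character(),
                   unit = character(), rate = numeric())
  }
  list(proteome = tibble::tibble(id = ids, sequence = seqs,
                                 length = nchar(seqs)),
       truth = truth_tbl)
}

#' Simulate a pseudo-method's predictions from a ground truth
#'
#' Each truth region is emitted independently with probability
#' `sensitivity`, its endpoints jittered by a uniform integer in
#' `[-jitter, jitter]` (clamped to the protein). Decoy regions — lengths
#' resampled from the truth lengths, placed uniformly in background so the
#' expected decoy fraction of emitted regions is `fdr_rate` — model false
#' discoveries. Deterministic per seed.
#'
#' @param truth Ground-truth region tibble from [generate_proteome()].
#' @param proteome The matching proteome tibble.
#' @param sensitivity Emission probability per truth region.
#' @param fdr_rate Expected fraction of emitted regions that are decoys.
#' @param jitter Max endpoint shift in residues.
#' @param method Method label for the emitted set.
#' @param seed Integer seed.
#' @param max_tries Decoy placement retries.
#' @return A region tibble.
#' @export
simulate_predictions <- function(truth, proteome, sensitivity = 1,
                                 fdr_rate = 0, jitter = 0L,
                                 method = "pseudo", seed = 1L,
                                 max_tries = 200L) {
  stopifnot(sensitivity >= 0, sensitivity <= 1, fdr_rate >= 0, fdr_rate < 1,
            jitter >= 0L)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  emitted <- truth[stats::runif(nrow(truth)) < sensitivity, , drop = FALSE]
  out <- list()
  if (nrow(emitted) > 0L) {
    plen <- proteome$length[match(emitted$protein_id, proteome$id)]
    js <- if (jitter > 0L) sample.int(2L * jitter + 1L, nrow(emitted),
                                      replace = TRUE) - jitter - 1L else 0L
    je <- if (jitter > 0L) sample.int(2L * jitter + 1L, nrow(emitted),
                                      replace = TRUE) - jitter - 1L else 0L
    s <- pmax(1L, pmin(emitted$start + js, plen))
    e <- pmax(1L, pmin(emitted$end + je, plen))
    out$hits <- tibble::tibble(protein_id = emitted$protein_id,
                               start = pmin(s, e), end = pmax(s, e))
  }
  n_decoys <- round(nrow(emitted) * fdr_rate / (1 - fdr_rate))
  if (n_decoys > 0L) {
    if (nrow(truth) == 0L) stop("cannot draw decoy lengths: empty truth",
                                call. = FALSE)
    truth_ir <- ranges_by_protein(truth)
    dlens <- sample(truth$end - truth$start + 1L, n_decoys, replace = TRUE)
    decoys <- list()
    for (d in seq_len(n_decoys)) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        p <- sample.int(nrow(proteome), 1L)
        if (proteome$length[p] < dlens[d]) next
        s <- sample.int(proteome$length[p] - dlens[d] + 1L, 1L)
        cand <- IRanges::IRanges(s, s + dlens[d] - 1L)
        occ <- truth_ir[[proteome$id[p]]]
        if (!is.null(occ) && length(IRanges::findOverlaps(cand, occ)) > 0L) next
        decoys[[d]] <- tibble::tibble(protein_id = proteome$id[p],
                                      start = s, end = s + dlens[d] - 1L)
        placed <- TRUE
        break
      }
      if (!placed) {
        stop("could not place decoy ", d, " in background after ",
             max_tries, " tries", call. = FALSE)
      }
    }
    out$decoys <- dplyr::bind_rows(decoys)
  }
  if (length(out) == 0L) {
    return(as_regions(tibble::tibble(protein_id = character(),
                                     start = integer(), end = integer()),
                      method = method))
  }
  as_regions(dplyr::bind_rows(out), method = method)
}

#' Consensus fixture with purity increasing across tiers
#'
#' Builds a proteome and `k_max` pseudo-method region sets such that a
#' region shared by t methods has planted purity `purities[t]` — so
#' consensus-tier analyses ([multi_intersect()] + [tier_summaries()]) see a
#' known monotone purity signal across k.
#'
#' @param k_max Number of pseudo-methods (>= 2).
#' @param n_per_tier Planted regions per tier.
#' @param region_length Planted region length in residues.
#' @param purities Planted purity per tier (length `k_max`, increasing).
#' @param flank Background residues flanking each region.
#' @param seed Integer seed.
#' @return A list with `proteome`, `region_sets` (named list of region
#'   tibbles) and `truth` (tibble with `protein_id`, `start`, `end`,
#'   `tier`, `purity`).
#' @export
make_tiered_consensus_fixture <- function(k_max, n_per_tier = 10L,
                                          region_length = 30L,
                                          purities = seq(0.55, 0.95,
                                                         length.out = k_max),
                                          flank = 20L, seed = 1L) {
  stopifnot(k_max >= 2L, length(purities) == k_max)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  rows <- list()
  seqs <- character(0)
  ids <- character(0)
  i <- 0L
  for (tier in seq_len(k_max)) {
    for (r in seq_len(n_per_tier)) {
      i <- i + 1L
      id <- sprintf("tp%03d", i)
      dom <- sample(AA20, 1L)
      body <- ifelse(stats::runif(region_length) < purities[tier], dom,
                     sample(setdiff(AA20, dom), region_length, replace = TRUE))
      seqs <- c(seqs, paste0(random_sequence(flank),
                             paste(body, collapse = ""),
                             random_sequence(flank)))
      ids <- c(ids, id)
      rows[[i]] <- tibble::tibble(protein_id = id, start = flank + 1L,
                                  end = flank + region_length,
                                  tier = tier, purity = purities[tier])
    }
  }
  truth <- dplyr::bind_rows(rows)
  region_sets <- lapply(seq_len(k_max), function(m) {
    # method m reports every region of tier >= m: tier-t regions are then
    # covered by exactly t methods (methods 1..t)
    keep <- truth[truth$tier >= m, c("protein_id", "start", "end")]
    as_regions(keep, method = sprintf("pm%02d", m))
  })
  names(region_sets) <- sprintf("pm%02d", seq_len(k_max))
  list(proteome = tibble::tibble(id = ids, sequence = seqs,
                                 length = nchar(seqs)),
       region_sets = region_sets, truth = truth)
}

#' Separable two-class point cloud in LC space
#'
#' Draws labelled (x, y) points for boundary-recovery experiments with a
#' planted linear boundary `x + y = 100`. Each class is uniform over the
#' union of `grid`-percent cells lying entirely on its side of the line
#' with a gap of at least `margin`: positive (LC) cells satisfy
#' `x + y >= 100 + margin` everywhere, negative (BG) cells
#' `x + y <= 100 - margin` everywhere. Building the classes from whole
#' cells keeps them exactly separable after discretisation at bin width
#' `grid` and gives every supporting cell the same sampling density, so
#' the planted boundary is recoverable from the binned surface.
#'
#' @param n_per_class Points per class.
#' @param margin Minimum gap of the class supports from the planted line,
#'   in percent (default 0: the supports touch the line).
#' @param grid Cell width in percent; use the bin width the cloud will be
#'   analysed at. Must divide 100 evenly.
#' @param seed Integer seed.
#' @return A labelled point tibble (`x`, `y`, `label`).
#' @export
separable_boundary_points <- function(n_per_class, margin = 0, grid = 2,
                                      seed = 1L) {
  stopifnot(margin >= 0, margin < 100, 100 %% grid == 0)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  nb <- as.integer(100 / grid)
  cells <- tidyr::expand_grid(i = 0:(nb - 1L), j = 0:(nb - 1L))
  min_sum <- grid * (cells$i + cells$j)        # lowest x+y in the cell
  max_sum <- min_sum + 2 * grid                # highest x+y in the cell
  draw_cells <- function(keep, n) {
    sub <- cells[keep, , drop = FALSE]
    stopifnot(nrow(sub) > 0L)
    pick <- sub[sample.int(nrow(sub), n, replace = TRUE), ]
    tibble::tibble(x = grid * (pick$i + stats::runif(n)),
                   y = grid * (pick$j + stats::runif(n)))
  }
  dplyr::bind_rows(
    draw_cells(min_sum >= 100 + margin, n_per_class) |>
      dplyr::mutate(label = "LC"),
    draw_cells(max_sum <= 100 - margin, n_per_class) |>
      dplyr::mutate(label = "BG"))
}
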