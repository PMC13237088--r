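# Independent brute-force oracles used to check the interval algebra and
# the periodic-repeat metric against explicit set computations.

# Explicit residue set of a region table: "protein:position" strings.
oracle_residues <- function(regions) {
  if (nrow(regions) == 0L) return(character(0))
  unique(unlist(Map(function(p, s, e) paste0(p, ":", s:e),
                    regions$protein_id, regions$start, regions$end)))
}

oracle_jaccard <- function(a, b) {
  ra <- oracle_residues(a)
  rb <- oracle_residues(b)
  u <- union(ra, rb)
  if (length(u) == 0L) return(0)
  length(intersect(ra, rb)) / length(u)
}

oracle_confusion <- function(reference, predicted, proteome) {
  universe <- oracle_residues(tibble::tibble(protein_id = proteome$id,
                                             start = 1L,
                                             end = proteome$length))
  rr <- oracle_residues(reference)
  rp <- oracle_residues(predicted)
  c(TP = length(intersect(rr, rp)),
    FP = length(setdiff(rp, rr)),
    FN = length(setdiff(rr, rp)),
    TN = length(setdiff(universe, union(rr, rp))))
}

# Exhaustive minimum-mutation oracle: for every period, every explicit
# assignment of a consensus symbol to every phase class is tried.
oracle_min_mutation <- function(seq, max_period = NULL) {
  x <- strsplit(seq, "", fixed = TRUE)[[1]]
  L <- length(x)
  if (L < 2L) return(list(mutation_pct = 0, best_period = 1L))
  if (is.null(max_period)) max_period <- max(1L, L %/% 2L)
  max_period <- min(max_period, max(1L, L %/% 2L))
  alphabet <- sort(unique(x))
  best <- L + 1L
  best_p <- 1L
  for (p in seq_len(max_period)) {
    assignments <- expand.grid(rep(list(alphabet), p),
                               stringsAsFactors = FALSE)
    phase <- ((seq_len(L) - 1L) %% p) + 1L
    for (r in seq_len(nrow(assignments))) {
      cons <- unlist(assignments[r, ], use.names = FALSE)
      mism <- sum(x != cons[phase])
      if (mism < best) {
        best <- mism
        best_p <- p
      }
    }
  }
  list(mutation_pct = 100 * best / L, best_period = best_p)
}

# Independent tandem-run scan: for every unit and start, extend the run
# character by character against the cyclic unit (partial last copy
# allowed) and record the best coverage.
oracle_best_tandem <- function(seq, kmax = 3L) {
  x <- strsplit(seq, "", fixed = TRUE)[[1]]
  L <- length(x)
  best_cov <- -1
  best_unit <- NA_character_
  best_k <- NA_integer_
  for (k in seq_len(min(kmax, L))) {
    for (s in seq_len(L - k + 1L)) {
      u <- x[s:(s + k - 1L)]
      r <- 0L
      while (s + r <= L && x[s + r] == u[(r %% k) + 1L]) r <- r + 1L
      cov <- r / L
      better <- cov > best_cov + 1e-12 ||
        (abs(cov - best_cov) <= 1e-12 &&
           (k < best_k || (k == best_k &&
                             paste(u, collapse = "") < best_unit)))
      if (better) {
        best_cov <- cov
        best_unit <- paste(u, collapse = "")
        best_k <- k
      }
    }
  }
  list(unit = best_unit, coverage = best_cov)
}

# Random region fixture on a small universe.
random_regions <- function(n, proteins = c("p1", "p2"), max_len = 60L,
                           method = "m") {
  pid <- sample(proteins, n, replace = TRUE)
  s <- sample.int(max_len - 5L, n, replace = TRUE)
  e <- pmin(s + sample.int(12L, n, replace = TRUE), max_len)
  as_regions(tibble::tibble(protein_id = pid, start = s, end = e),
             method = method)
}

random_aa_seq <- function(len, alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY",
                                                   "")[[1]]) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}
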