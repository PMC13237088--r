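test_that("merging unites overlapping and bookended intervals", {
  m <- merge_intervals(tibble::tibble(protein_id = "p1", start = c(1, 4),
                                      end = c(5, 8)))
  expect_equal(m$start, 1L)
  expect_equal(m$end, 8L)
  m <- merge_intervals(tibble::tibble(protein_id = "p1", start = c(1, 6),
                                      end = c(5, 8)))
  expect_equal(nrow(m), 1L)  # bookended in 1-based inclusive space
  m <- merge_intervals(tibble::tibble(protein_id = c("p1", "p2"),
                                      start = c(1, 1), end = c(5, 5)))
  expect_equal(nrow(m), 2L)  # different proteins never merge
  # coverage is preserved exactly (residue-set oracle)
  set.seed(31)
  for (i in 1:50) {
    rs <- random_regions(sample(1:8, 1))
    expect_setequal(oracle_residues(merge_intervals(rs)),
                    oracle_residues(rs))
    m <- merge_intervals(rs)
    # merged intervals are disjoint and non-adjacent
    per <- split(m, m$protein_id)
    for (d in per) {
      if (nrow(d) > 1) expect_true(all(d$start[-1] > d$end[-nrow(d)] + 1))
    }
  }
})

test_that("multi-method intersection partitions covered residues by membership", {
  A <- as_regions(tibble::tibble(protein_id = "p1", start = 1, end = 10),
                  method = "A")
  B <- as_regions(tibble::tibble(protein_id = "p1", start = 6, end = 15),
                  method = "B")
  seg <- multi_intersect(list(A = A, B = B))
  expect_equal(seg$start, c(1L, 6L, 11L))
  expect_equal(seg$end, c(5L, 10L, 15L))
  expect_equal(seg$k, c(1L, 2L, 1L))
  expect_equal(seg$methods, c("A", "A,B", "B"))

  seg <- multi_intersect(list(A = A, B = A))
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$k, 2L)

  C <- as_regions(tibble::tibble(protein_id = "p1", start = 20, end = 25),
                  method = "C")
  seg <- multi_intersect(list(A = A, C = C))
  expect_equal(seg$k, c(1L, 1L))
})

test_that("consensus segments conserve residues and per-tier totals", {
  set.seed(32)
  for (i in 1:40) {
    sets <- lapply(1:3, function(m) random_regions(sample(1:6, 1),
                                                   method = paste0("m", m)))
    names(sets) <- paste0("m", 1:3)
    seg <- multi_intersect(sets)
    # disjointness: each covered residue in exactly one segment
    res <- unlist(Map(function(p, s, e) paste0(p, ":", s:e),
                      seg$protein_id, seg$start, seg$end))
    expect_equal(anyDuplicated(res), 0L)
    expect_setequal(res, oracle_residues(dplyr::bind_rows(sets)))
    # per-tier totals: a residue is at tier k iff covered by k merged sets
    merged <- lapply(sets, merge_intervals)
    by_res <- table(unlist(lapply(merged, oracle_residues)))
    for (kk in 1:3) {
      expect_equal(sum(seg$end[seg$k == kk] - seg$start[seg$k == kk] + 1),
                   sum(by_res == kk), info = paste("iter", i, "k", kk))
    }
    expect_true(all(seg$k >= 1 & seg$k <= 3))
  }
})

test_that("jaccard matches the explicit residue-set computation", {
  A <- as_regions(tibble::tibble(protein_id = "p1", start = 1, end = 10))
  B <- as_regions(tibble::tibble(protein_id = "p1", start = 6, end = 15))
  expect_equal(region_jaccard(A, B), 5 / 15)
  expect_equal(region_jaccard(A, A), 1)
  C <- as_regions(tibble::tibble(protein_id = "p1", start = 20, end = 22))
  expect_equal(region_jaccard(A, C), 0)
  expect_equal(region_jaccard(A[0, ], A[0, ]), 0)
  set.seed(33)
  for (i in 1:60) {
    a <- random_regions(sample(0:6, 1))
    b <- random_regions(sample(0:6, 1))
    expect_equal(region_jaccard(a, b), oracle_jaccard(a, b))
    expect_equal(region_jaccard(a, b), region_jaccard(b, a))
  }
})

test_that("jaccard matrix is symmetric with unit diagonal and per-pair consistency", {
  set.seed(34)
  sets <- lapply(1:3, function(m) random_regions(4, method = paste0("m", m)))
  names(sets) <- paste0("m", 1:3)
  m <- jaccard_matrix(sets)
  expect_equal(m, t(m))
  expect_equal(diag(m), c(m1 = 1, m2 = 1, m3 = 1))
  for (i in 1:2) for (j in (i + 1):3) {
    expect_equal(m[i, j], region_jaccard(sets[[i]], sets[[j]]))
  }
  expect_equal(jaccard_matrix(sets[1]), matrix(1, 1, 1,
                                               dimnames = list("m1", "m1")))
})

test_that("length, coverage and count bins own their right edges", {
  rs <- as_regions(tibble::tibble(protein_id = "p",
                                  start = c(1, 1, 1, 1),
                                  end = c(5, 10, 15, 250)))
  h <- summarize_lengths(rs)
  expect_equal(h$n[h$bin == "0-10"], 2L)    # lengths 5 and 10
  expect_equal(h$n[h$bin == "10-20"], 1L)   # length 15
  expect_equal(h$n[h$bin == ">200"], 1L)    # length 250
  expect_equal(sum(summarize_lengths(rs[0, ])$n), 0L)

  prot <- tibble::tibble(id = c("p", "q"), sequence = c(strrep("A", 10),
                                                        strrep("A", 10)),
                         length = c(10L, 10L))
  cov <- summarize_coverage(as_regions(tibble::tibble(protein_id = "p",
                                                      start = 1, end = 5)),
                            prot)
  expect_equal(cov$n[cov$bin == "40-60"], 1L)
  expect_equal(sum(cov$n), 1L)  # q has no coverage

  cnt <- summarize_counts(as_regions(tibble::tibble(
    protein_id = rep("p", 5), start = seq(1, 9, 2), end = seq(1, 9, 2))),
    prot)
  expect_equal(cnt$n[cnt$bin == "1-5"], 1L)  # 5 regions is still "1-5"
  expect_equal(cnt$n[cnt$bin == "0"], 1L)    # q
})

test_that("amino-acid composition pools residues and sums to one", {
  prot <- tibble::tibble(id = "p", sequence = "AAKKCDEF", length = 8L)
  one <- aa_composition(as_regions(tibble::tibble(protein_id = "p",
                                                  start = 1, end = 4)), prot)
  expect_equal(one$fraction[one$residue == "A"], 0.5)
  expect_equal(one$fraction[one$residue == "K"], 0.5)
  expect_equal(sum(one$fraction), 1)
  two <- aa_composition(as_regions(tibble::tibble(protein_id = "p",
                                                  start = c(1, 3),
                                                  end = c(2, 4))), prot)
  expect_equal(two, one)  # pooling invariance
  empty <- as_regions(tibble::tibble(protein_id = character(),
                                     start = integer(), end = integer()))
  expect_error(aa_composition(empty, prot), "empty")
})
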