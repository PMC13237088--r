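toy_proteome <- function(n = 1, len = 10) {
  tibble::tibble(id = paste0("p", seq_len(n)),
                 sequence = vapply(seq_len(n), function(i) random_aa_seq(len),
                                   character(1)),
                 length = as.integer(len))
}

test_that("residue confusion matches the hand count and the set oracle", {
  prot <- tibble::tibble(id = "p1", sequence = strrep("A", 10), length = 10L)
  ref <- as_regions(tibble::tibble(protein_id = "p1", start = 1, end = 5))
  pred <- as_regions(tibble::tibble(protein_id = "p1", start = 4, end = 8))
  cm <- residue_confusion(ref, pred, prot)
  expect_equal(c(cm$TP, cm$FP, cm$FN, cm$TN), c(2, 3, 3, 2))
  expect_equal(tpr(cm), 0.4)
  expect_equal(fpr(cm), 0.6)

  cm <- residue_confusion(ref, ref, prot)
  expect_equal(c(cm$FP, cm$FN), c(0, 0))
  expect_equal(cm$TP, 5)

  empty <- ref[0, ]
  cm <- residue_confusion(ref, empty, prot)
  expect_equal(c(cm$TP, cm$FP, cm$FN), c(0, 0, 5))

  bad <- as_regions(tibble::tibble(protein_id = "nope", start = 1, end = 2))
  expect_error(residue_confusion(ref, bad, prot), "absent")

  set.seed(51)
  prot2 <- toy_proteome(2, 60)
  prot2$id <- c("p1", "p2")
  for (i in 1:50) {
    r <- random_regions(sample(0:5, 1))
    p <- random_regions(sample(0:5, 1))
    cm <- residue_confusion(r, p, prot2)
    expect_equal(c(TP = cm$TP, FP = cm$FP, FN = cm$FN, TN = cm$TN),
                 oracle_confusion(r, p, prot2))
    expect_equal(cm$TP + cm$FP + cm$FN + cm$TN, sum(prot2$length))
  }
})

test_that("rates are undefined, not zero, on empty denominators", {
  cm <- tibble::tibble(TP = 0, FP = 0, FN = 0, TN = 5)
  expect_true(is.na(tpr(cm)))
  expect_equal(fpr(cm), 0)
  cm <- tibble::tibble(TP = 3, FP = 0, FN = 0, TN = 0)
  expect_true(is.na(fpr(cm)))
  expect_equal(tpr(cm), 1)
})

test_that("gene-length deciles split evenly with larger bins first", {
  prot <- tibble::tibble(id = sprintf("p%02d", 1:23),
                         sequence = NA_character_,
                         length = sample(100:1000, 23))
  s <- stratify_gene_length(prot, 10)
  sizes <- as.integer(table(s$stratum))
  expect_equal(sizes, c(3L, 3L, 3L, rep(2L, 7)))
  # ascending by length across bins
  lens <- prot$length[match(s$id, prot$id)]
  expect_true(all(diff(tapply(lens, s$stratum, max)) >= 0))
  # ten proteins of distinct lengths: one per bin, ascending
  p10 <- tibble::tibble(id = letters[1:10], sequence = NA, length = 10:1)
  s10 <- stratify_gene_length(p10, 10)
  expect_equal(as.character(s10$stratum), as.character(1:10))
  expect_equal(s10$id, rev(letters[1:10]))
  # equal lengths: deterministic stable order by id
  peq <- tibble::tibble(id = c("b", "a", "c"), sequence = NA, length = 5)
  expect_error(stratify_gene_length(peq, 10), "fewer")
  s3 <- stratify_gene_length(peq, 3)
  expect_equal(s3$id, c("a", "b", "c"))
})

test_that("entropy ratio compares LCR residues to the whole sequence", {
  prot <- tibble::tibble(id = c("p1", "p2"),
                         sequence = c("AAAACDEFGH", strrep("A", 10)),
                         length = 10L)
  ref <- as_regions(tibble::tibble(protein_id = c("p1", "p2"),
                                   start = 1, end = c(4, 10)))
  er <- entropy_ratio(prot, ref)
  expect_equal(er$entropy_ratio[er$id == "p1"], 0)  # homorepeat LCR
  expect_true(is.na(er$entropy_ratio[er$id == "p2"]))  # zero whole entropy
  # LCR = whole protein -> ratio 1
  prot2 <- tibble::tibble(id = "q", sequence = "ACDEACDE", length = 8L)
  ref2 <- as_regions(tibble::tibble(protein_id = "q", start = 1, end = 8))
  expect_equal(entropy_ratio(prot2, ref2)$entropy_ratio, 1)
})

test_that("stratified evaluation hits the four predictor corners exactly", {
  sim <- generate_proteome(
    20, c(150, 250),
    planted_features("homorepeat", rep(c("E", "Q"), 6), 25, 0), seed = 52)
  ref <- annotate_proteome(sim$proteome)
  # complement predictor: everything the reference is not
  complement <- purrr::map_dfr(seq_len(nrow(sim$proteome)), function(i) {
    id <- sim$proteome$id[i]
    len <- sim$proteome$length[i]
    covered <- ref[ref$protein_id == id, ]
    ir <- IRanges::gaps(IRanges::IRanges(covered$start, covered$end),
                        start = 1L, end = len)
    tibble::tibble(protein_id = id, start = IRanges::start(ir),
                   end = IRanges::end(ir))
  }) |> as_regions(method = "complement")
  all_pred <- as_regions(tibble::tibble(protein_id = sim$proteome$id,
                                        start = 1,
                                        end = sim$proteome$length),
                         method = "all")
  none_pred <- ref[0, ]
  preds <- list(perfect = ref, complement = complement, all = all_pred,
                none = none_pred)
  ev <- evaluate_stratified(ref, preds, sim$proteome, "gene_length")
  m <- ev$means
  expect_equal(m$mean_tpr[m$method == "perfect"], 1)
  expect_equal(m$mean_fpr[m$method == "perfect"], 0)
  expect_equal(m$mean_tpr[m$method == "complement"], 0)
  expect_equal(m$mean_fpr[m$method == "complement"], 1)
  expect_equal(m$mean_tpr[m$method == "all"], 1)
  expect_equal(m$mean_fpr[m$method == "all"], 1)
  expect_equal(m$mean_tpr[m$method == "none"], 0)
  expect_equal(m$mean_fpr[m$method == "none"], 0)
  # conservation: strata partition the residue universe
  strat <- ev$strata[ev$strata$method == "perfect", ]
  expect_equal(sum(strat$TP + strat$FP + strat$FN + strat$TN, na.rm = TRUE),
               sum(sim$proteome$length))
})

test_that("all four stratifiers produce rates in range with missing strata as NA", {
  sim <- generate_proteome(
    25, c(150, 250),
    planted_features("homorepeat", rep(c("E", "Q", "K", "S", "T"), 4), 25, 0),
    seed = 53)
  ref <- annotate_proteome(sim$proteome)
  pred <- simulate_predictions(sim$truth, sim$proteome, sensitivity = 0.7,
                               jitter = 3, method = "m1", seed = 54)
  for (st in c("gene_length", "lcr_count", "coverage", "entropy_ratio")) {
    ev <- evaluate_stratified(ref, list(m1 = pred), sim$proteome, st)
    ok <- !is.na(ev$strata$tpr)
    expect_true(all(ev$strata$tpr[ok] >= 0 & ev$strata$tpr[ok] <= 1),
                info = st)
    expect_true(any(ok), info = st)
  }
  # per-protein averaging is available and bounded
  evp <- evaluate_stratified(ref, list(m1 = pred), sim$proteome,
                             "gene_length", per_protein = TRUE)
  ok <- !is.na(evp$strata$tpr)
  expect_true(all(evp$strata$tpr[ok] >= 0 & evp$strata$tpr[ok] <= 1))
})
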