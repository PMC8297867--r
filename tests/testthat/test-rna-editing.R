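test_that("candidate calling applies the depth and fraction thresholds", {
  ev <- data.frame(
    cds_id = "g1", position = 1:5, ref = c("C", "C", "C", "A", "C"),
    rna_depth = c(50L, 50L, 8L, 50L, 50L),
    rna_A = c(0L, 0L, 0L, 10L, 0L),
    rna_C = c(50L, 10L, 2L, 0L, 48L),
    rna_G = 0L,
    rna_T = c(0L, 40L, 6L, 40L, 2L),
    dna_depth = 50L, dna_A = 0L, dna_C = 50L, dna_G = 0L, dna_T = 0L)
  out <- call_candidate_sites(ev)
  # all-C site not called; A site never called (C-to-U only); low depth
  # dropped; 2/50 below the edit fraction floor
  expect_equal(out$position, 2L)
  expect_equal(out$edit_fraction, 0.8)
  expect_true(all(out$ref == "C"))
  # an ambiguous reference base is skipped with a warning
  ev$ref[1] <- "N"
  expect_warning(call_candidate_sites(ev), "ambiguous")
})

test_that("genomic SNPs are filtered and missing DNA evidence is flagged", {
  sites <- data.frame(cds_id = "g1", position = c(10L, 20L, 30L), ref = "C",
                      edit_fraction = 0.8, rna_depth = 50L,
                      support = "empirical")
  ev <- data.frame(
    cds_id = "g1", position = c(10L, 20L), ref = "C",
    rna_depth = 50L, rna_A = 0L, rna_C = 10L, rna_G = 0L, rna_T = 40L,
    dna_depth = c(50L, 50L), dna_A = 0L,
    dna_C = c(50L, 20L), dna_G = 0L, dna_T = c(0L, 30L))
  res <- filter_genomic_snps(sites, ev)
  # position 10: DNA pure C -> kept and verified; 20: 60% T -> removed;
  # 30: no DNA evidence -> kept, unverified
  expect_setequal(res$sites$position, c(10L, 30L))
  expect_true(res$sites$verified[res$sites$position == 10])
  expect_false(res$sites$verified[res$sites$position == 30])
  expect_equal(res$removed$position, 20L)
})

test_that("codon classification translates edits and flags silence", {
  cds <- c(g1 = "CCAGCCATG")   # codons CCA GCC ATG
  s <- data.frame(cds_id = "g1", position = c(2L, 6L))
  cl <- classify_sites(s, cds)
  # CCA -> CTA at codon position 2: Pro -> Leu, non-silent, phil -> phob
  expect_equal(cl$codon_position[1], 2L)
  expect_equal(cl$aa_before[1], "P")
  expect_equal(cl$aa_after[1], "L")
  expect_false(cl$silent[1])
  expect_equal(cl$conversion[1], "Pro->Leu")
  expect_equal(cl$hydropathy[1], "phil->phob")
  # GCC -> GCT at codon position 3: Ala -> Ala, silent
  expect_equal(cl$codon_position[2], 3L)
  expect_true(cl$silent[2])
  expect_equal(cl$conversion[2], "Ala->Ala")
  # codons containing N are indeterminate
  cl2 <- classify_sites(data.frame(cds_id = "g2", position = 2L),
                        c(g2 = "CNA"))
  expect_equal(cl2$conversion, "indeterminate")
})

test_that("prediction concordance reproduces the published counting scheme", {
  # fixture built to the printed study shape: 1181 predicted non-silent
  # sites, 358 empirical sites of which 267 are shared and 33 silent
  set.seed(81)
  all_pos <- seq(2, 6000, by = 3)       # second codon positions
  pred_pos <- sample(all_pos, 1181)
  shared <- sample(pred_pos, 267)
  emp_only_nonsilent <- sample(setdiff(all_pos, pred_pos), 58)
  silent_pos <- sample(seq(3, 6000, by = 3), 33)
  emp <- data.frame(
    cds_id = "g1",
    position = c(shared, emp_only_nonsilent, silent_pos),
    silent = c(rep(FALSE, 267 + 58), rep(TRUE, 33)))
  pred <- data.frame(cds_id = "g1", position = pred_pos)
  cmp <- compare_with_predictions(emp, pred)
  expect_equal(cmp$n_predicted, 1181L)
  expect_equal(cmp$n_empirical, 358L)
  expect_equal(cmp$n_shared, 267L)
  expect_equal(cmp$n_empirical_silent, 33L)
  expect_equal(cmp$n_confirmed, 300L)

  # identical / disjoint lists
  e2 <- data.frame(cds_id = "g1", position = c(2L, 5L), silent = FALSE)
  expect_equal(compare_with_predictions(
    e2, data.frame(cds_id = "g1", position = c(2L, 5L)))$n_shared, 2L)
  expect_equal(compare_with_predictions(
    e2, data.frame(cds_id = "g1", position = c(8L, 11L)))$n_shared, 0L)
  # unknown cds_id rows are skipped with a warning
  expect_warning(compare_with_predictions(
    e2, data.frame(cds_id = c("g1", "gX"), position = c(2L, 5L))), "unknown")
})

test_that("the editing-frequency statistic follows the printed formula", {
  expect_identical(editing_frequency(9, 900), 1)
  expect_identical(editing_frequency(0, 500), 0)
  # scale exactness
  for (k in c(2, 7, 30))
    expect_equal(editing_frequency(9 * k, 900 * k), editing_frequency(9, 900))
  expect_error(editing_frequency(1, 0), "positive")
})

test_that("summaries aggregate codon positions, conversions and hydropathy", {
  cds <- c(g1 = strrep("CCA", 100))     # every codon Pro
  s <- data.frame(cds_id = "g1", position = c(2L, 5L, 8L, 3L))
  cl <- classify_sites(s, cds)
  sm <- summarize_editing(cl, c(g1 = 300L))
  expect_equal(sm$total_sites, 4L)
  expect_equal(sm$codon_position_counts, c(0L, 3L, 1L))
  expect_equal(sum(sm$codon_position_pct), 100)
  expect_equal(names(sm$conversion_counts)[1], "Pro->Leu")
  expect_equal(unname(sm$conversion_counts[1]), 3L)
  expect_equal(unname(sm$hydropathy_proportions["phil->phob"]), 1)
  expect_equal(sm$per_gene_frequency$frequency,
               editing_frequency(4, 300))
  # empty input: an all-zero summary
  sm0 <- summarize_editing(cl[0, , drop = FALSE])
  expect_equal(sm0$total_sites, 0L)
  expect_equal(sm0$codon_position_counts, c(0L, 0L, 0L))
})

test_that("planted editing datasets are recovered with clean precision and recall", {
  set.seed(82)
  for (seed in 1:3) {
    ds <- simulate_editing_dataset(n_cds = 5, cds_length = 600,
                                   n_edits = 60, n_snps = 12,
                                   edit_fraction_range = c(0.9, 0.9),
                                   depth_range = c(50L, 50L), seed = seed)
    cand <- call_candidate_sites(ds$evidence)
    flt <- filter_genomic_snps(cand, ds$evidence)
    truth <- paste(ds$manifest$edits$cds_id, ds$manifest$edits$position)
    called <- paste(flt$sites$cds_id, flt$sites$position)
    expect_equal(sort(called), sort(truth))
    # exactly the planted SNP confounders are removed
    snps <- paste(ds$manifest$snps$cds_id, ds$manifest$snps$position)
    expect_setequal(paste(flt$removed$cds_id, flt$removed$position), snps)
  }
})

test_that("only C-to-U events are ever emitted by the pipeline", {
  set.seed(83)
  ds <- simulate_editing_dataset(n_cds = 3, cds_length = 300, n_edits = 30,
                                 n_snps = 5, seed = 9)
  cand <- call_candidate_sites(ds$evidence)
  expect_true(all(cand$ref == "C"))
  cl <- classify_sites(filter_genomic_snps(cand, ds$evidence)$sites,
                       ds$cds_sequences)
  expect_true(all(substr(cl$codon_after, cl$codon_position,
                         cl$codon_position) == "T"))
  expect_true(all(substr(cl$codon_before, cl$codon_position,
                         cl$codon_position) == "C"))
})

test_that("SAM alignments pile up into the native evidence format", {
  ref <- "ACGTACGTCCAGCCATGACGT"
  reads <- data.frame(pos = c(1L, 1L, 9L, 9L, 9L),
                      seq = c(substr(ref, 1, 12),
                              substr(ref, 1, 12),
                              # two reads with the C at ref pos 10 read as T
                              paste0("CT", substr(ref, 11, 21)),
                              paste0("CT", substr(ref, 11, 21)),
                              substr(ref, 9, 21)))
  sam <- write_toy_sam(tempfile(fileext = ".sam"), "cds1", ref, reads)
  pu <- pileup_from_sam(sam, c(cds1 = ref))
  expect_equal(pu$ref, mitostruct:::chars(ref)[pu$position])
  # position 10 is covered by all five reads: three with the reference C,
  # two with the edited T
  p10 <- pu[pu$position == 10L, ]
  expect_equal(p10$T, 2L)
  expect_equal(p10$C, 3L)
  expect_equal(p10$depth, 5L)
  ev <- combine_evidence(pu)
  expect_true(all(is.na(ev$dna_depth)))
  cand <- call_candidate_sites(ev, min_depth = 3, min_fraction = 0.4)
  expect_equal(cand$position, 10L)
})
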