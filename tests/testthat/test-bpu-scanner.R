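test_that("the consensus object enforces its invariants", {
  cons <- bpu_consensus()
  expect_equal(cons$sequence, "AAGGTTATCCCTTTCCTGAGCGTAGCGAAGGGAAGG")
  expect_equal(nchar(cons$sequence), 36L)
  expect_equal(cons$max_edits, 7L)
  expect_equal(substr(cons$sequence, 1, 4), cons$terminal_repeat)
  expect_equal(substr(cons$sequence, 33, 36), cons$terminal_repeat)
  expect_error(bpu_consensus(max_edits = 36), "max_edits")
  expect_error(bpu_consensus(max_edits = -1), "max_edits")
})

test_that("an embedded exact copy gives one zero-distance dominant hit", {
  set.seed(41)
  cons <- bpu_consensus()
  g <- mt_genome("t", paste0(random_dna(700), cons$sequence, random_dna(700)))
  h <- scan_motif(g, cons)
  expect_equal(nrow(h), 1L)
  expect_equal(h$edit_distance, 0)
  expect_equal(h$start, 701L)
  expect_equal(h$end, 736L)
  cl <- classify_hits(h, cons)
  expect_equal(cl$hits$identity_class, "dominant_exact")
  expect_equal(cl$summary$dominant_exact, 1L)
})

test_that("a copy with eight substitutions is rejected at the seven-edit bound", {
  set.seed(42)
  cons <- bpu_consensus()
  # eight internal substitutions; flanking context may rescue edits at the
  # element ends, so the in-context minimum is verified with the
  # exhaustive window oracle before asserting on the scanner
  g <- NULL
  for (try in 1:50) {
    x <- mitostruct:::chars(cons$sequence)
    at <- sample(5:32, 8)
    x[at] <- vapply(x[at], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    far <- paste(x, collapse = "")
    cand <- mt_genome("t", paste0(random_dna(600), far, random_dna(600)))
    dmin <- min(oracle_end_dists(cons$sequence, cand$sequence, 9))
    dmin_rc <- min(oracle_end_dists(cons$sequence,
                                    rev_comp(cand$sequence), 9))
    if (min(dmin, dmin_rc) == 8) { g <- cand; break }
  }
  expect_false(is.null(g))
  h7 <- scan_motif(g, cons)
  expect_equal(nrow(h7), 0L)
  h9 <- scan_motif(g, bpu_consensus(max_edits = 9))
  expect_equal(nrow(h9), 1L)
  expect_equal(h9$edit_distance, 8)
})

test_that("minus-strand copies are found with mirrored coordinates", {
  set.seed(43)
  cons <- bpu_consensus()
  g <- mt_genome("t", paste0(random_dna(500), rev_comp(cons$sequence),
                             random_dna(500)))
  h <- scan_motif(g, cons)
  expect_equal(nrow(h), 1L)
  expect_equal(h$strand, "-")
  expect_equal(h$start, 501L)
  expect_equal(h$sequence, cons$sequence)
})

test_that("origin-spanning copies of a circular genome are detected once", {
  set.seed(44)
  cons <- bpu_consensus()
  body <- random_dna(1200)
  # split the consensus across the origin: last 20 bp at the start
  s <- paste0(substr(cons$sequence, 17, 36), body,
              substr(cons$sequence, 1, 16))
  h <- scan_motif(mt_genome("t", s, circular = TRUE), cons)
  expect_equal(nrow(h), 1L)
  expect_equal(h$edit_distance, 0)
  expect_equal(h$start, nchar(s) - 15L)
  expect_equal(h$sequence, cons$sequence)
  # the same sequence treated as linear misses the split copy
  h_lin <- scan_motif(mt_genome("t", s, circular = FALSE), cons)
  expect_equal(nrow(h_lin), 0L)
})

test_that("truncated exact copies classify by contiguous substring identity", {
  set.seed(45)
  cons <- bpu_consensus()
  trunc30 <- substr(cons$sequence, 1, 30)   # 6 trailing bases lost
  # the lost consensus tail is GGAAGG; follow the core with T/C bases so no
  # cost-neutral window extension can absorb them
  g <- mt_genome("t", paste0(random_dna(400), "T", trunc30, "TCTCTCTC",
                             random_dna(400)))
  cl <- classify_hits(scan_motif(g, cons), cons)
  expect_equal(nrow(cl$hits), 1L)
  expect_equal(cl$hits$identity_class, "truncated_exact")
  expect_equal(cl$hits$matched_length, 30L)
  # a three-substitution copy is a variant
  var3 <- mitostruct:::mutate_to_distance(cons$sequence, 3)
  g2 <- mt_genome("t", paste0(random_dna(400), var3, random_dna(400)))
  cl2 <- classify_hits(scan_motif(g2, cons), cons)
  expect_equal(cl2$hits$identity_class, "variant")
  expect_equal(cl2$summary$variant, 1L)
})

test_that("scan equals the exhaustive window oracle across edit bounds", {
  set.seed(46)
  cons <- bpu_consensus()
  n_cases <- 12
  for (i in seq_len(n_cases)) {
    g0 <- mt_genome("t", random_dna(1200), circular = TRUE)
    pm <- plant_motifs(g0, cons, edits = sample(0:9, 4), seed = 100 + i)
    for (me in c(0L, 3L, 7L)) {
      ci <- bpu_consensus(max_edits = me)
      mine <- scan_motif(pm$genome, ci)
      orc <- oracle_bpu_scan(pm$genome$sequence, cons$sequence, me,
                             circular = TRUE)
      expect_equal(hit_signature(mine), hit_signature(orc),
                   info = sprintf("case %d max_edits %d", i, me))
    }
  }
})

test_that("planted motifs at known distances are recovered accordingly", {
  set.seed(47)
  cons <- bpu_consensus()
  g0 <- mt_genome("t", random_dna(2000), circular = TRUE)
  pm <- plant_motifs(g0, cons, edits = c(0L, 0L, 5L, 8L), seed = 3)
  h <- scan_motif(pm$genome, cons)
  expect_equal(nrow(h), 3L)            # the distance-8 copy is out of reach
  expect_setequal(h$edit_distance, c(0, 0, 5))
  truth <- pm$manifest$planted
  for (i in which(truth$edit_distance <= 7))
    expect_true(any(abs(h$start - truth$start[i]) <= cons$max_edits))
})

test_that("the hit set grows monotonically with the edit bound", {
  set.seed(48)
  cons <- bpu_consensus()
  g0 <- mt_genome("t", random_dna(1500), circular = TRUE)
  pm <- plant_motifs(g0, cons, edits = c(0L, 2L, 4L, 6L, 7L), seed = 11)
  prev <- character(0)
  for (me in 0:7) {
    h <- scan_motif(pm$genome, bpu_consensus(max_edits = me))
    sig <- paste(h$start, h$strand)
    expect_true(all(prev %in% sig), info = paste("max_edits", me))
    prev <- sig
  }
})

test_that("strand symmetry: the reverse-complement genome mirrors the hit set", {
  set.seed(49)
  cons <- bpu_consensus()
  g0 <- mt_genome("t", random_dna(1500), circular = TRUE)
  pm <- plant_motifs(g0, cons, edits = c(0L, 3L, 5L), seed = 13)
  h <- scan_motif(pm$genome, cons)
  rc <- mt_genome("rc", rev_comp(pm$genome$sequence), circular = TRUE)
  h2 <- scan_motif(rc, cons)
  expect_equal(nrow(h), nrow(h2))
  n <- pm$genome$length
  mirrored_starts <- sort(n - h$end + 1L)
  expect_equal(sort(h2$start), mirrored_starts)
  expect_equal(sort(h$edit_distance), sort(h2$edit_distance))
})

test_that("flank orthology pairs shared insertion sites between genomes", {
  set.seed(50)
  cons <- bpu_consensus()
  base <- random_dna(4000)
  g0 <- mt_genome("a", base, circular = TRUE)
  pm <- plant_motifs(g0, cons, edits = rep(0L, 6), strands = rep("+", 6),
                     seed = 17)
  ga <- pm$genome
  # second genome: same insertion sites, two loci heavily diverged
  sb <- ga$sequence
  tr <- pm$manifest$planted
  for (i in 1:2) {
    flank_at <- tr$end[i] + 5L
    sb <- mitostruct:::inject(sb, flank_at, random_dna(60))
  }
  gb <- mt_genome("b", sb, circular = TRUE)
  ha <- scan_motif(ga, cons); hb <- scan_motif(gb, cons)
  cmp <- compare_genomes(ha, hb, ga, gb)
  expect_equal(cmp$n_paired, 4L)
  # a genome passed against itself self-pairs everything
  self <- compare_genomes(ha, ha, ga, ga)
  expect_equal(self$n_paired, nrow(ha))
  expect_true(all(self$pairs$a == self$pairs$b))
  # unrelated genomes share nothing
  gc <- mt_genome("c", random_dna(4000), circular = TRUE)
  pm2 <- plant_motifs(gc, cons, edits = rep(0L, 3), seed = 19)
  hc <- scan_motif(pm2$genome, cons)
  none <- compare_genomes(ha, hc, ga, pm2$genome)
  expect_equal(none$n_paired, 0L)
})
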