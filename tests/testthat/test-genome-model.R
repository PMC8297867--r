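test_that("a toy GenBank record round-trips with coordinates preserved", {
  tf <- toy_genome_file()
  g <- read_annotated_genome(tf, "genbank")
  expect_s3_class(g, "mt_genome")
  expect_equal(g$length, 1000L)
  expect_true(g$circular)
  expect_length(g$features, 3L)
  nms <- vapply(g$features, function(f) f$name, "")
  expect_setequal(nms, c("atp1", "trnM", "rrn18"))
  atp1 <- g$features[[which(nms == "atp1")]]
  expect_equal(atp1$exons$start, c(100L, 180L))
  expect_equal(atp1$exons$end, c(150L, 200L))
  expect_equal(atp1$category, "PCG")
  trnM <- g$features[[which(nms == "trnM")]]
  expect_equal(trnM$strand, "-")
})

test_that("an origin-spanning CDS keeps two internal intervals totalling 111 bp", {
  set.seed(3)
  tf <- tempfile(fileext = ".gb")
  write_toy_genbank(tf, random_dna(1000), c(
    gb_feature("CDS", "join(950..1000,1..60)", 'gene="wrapper"')))
  g <- read_annotated_genome(tf, "genbank")
  f <- g$features[[1]]
  expect_true(f$origin_spanning)
  expect_equal(nrow(f$exons), 2L)
  expect_equal(sum(f$exons$end - f$exons$start + 1L), 111L)
  # the wrap junction is continuity, not an intron
  expect_equal(nrow(catalog_introns(g)$introns), 0L)
})

test_that("unknown feature kinds are ignored with a warning", {
  set.seed(4)
  tf <- tempfile(fileext = ".gb")
  write_toy_genbank(tf, random_dna(600), c(
    gb_feature("CDS", "10..120", 'gene="nad3"'),
    gb_feature("misc_RNA", "300..350")))
  expect_warning(g <- read_annotated_genome(tf, "genbank"), "misc_RNA")
  expect_length(g$features, 1L)
})

test_that("malformed and empty inputs produce informative errors", {
  tf <- tempfile(); writeLines(c("LOCUS x", "ORIGIN", "//"), tf)
  expect_error(read_annotated_genome(tf, "genbank"), "zero-length|malformed")
  tf2 <- tempfile()
  write_toy_genbank(tf2, "ACGTACGTACGT",
                    gb_feature("CDS", "join(bogus)", 'gene="x"'))
  expect_error(read_annotated_genome(tf2, "genbank"), "location")
  expect_error(read_annotated_genome(tempfile(), "genbank"), "not found")
})

test_that("gene order reads off coordinates, strands, duplicates and trans segments", {
  feats <- list(
    gene_feature("a", "PCG", "+", data.frame(start = 100, end = 200)),
    gene_feature("b", "PCG", "-", data.frame(start = 300, end = 400)),
    gene_feature("c", "PCG", "+", data.frame(start = 500, end = 600)))
  g <- mt_genome("t", random_dna(1000), features = feats)
  expect_equal(unname(extract_gene_order(g)$markers), c("+a", "-b", "+c"))

  # two identical trnM copies: coordinate sort fixes copy numbering
  feats2 <- c(feats, list(
    gene_feature("trnM", "tRNA", "+", data.frame(start = 5000, end = 5070)),
    gene_feature("trnM", "tRNA", "+", data.frame(start = 1000, end = 1070))))
  g2 <- mt_genome("t2", random_dna(6000), features = feats2)
  mk <- unname(extract_gene_order(g2)$markers)
  expect_equal(mk[mk %in% c("+trnM#1", "+trnM#2")], c("+trnM#1", "+trnM#2"))
  expect_lt(which(mk == "+trnM#1"), which(mk == "+trnM#2"))

  # a trans-spliced gene annotated as two disjoint exon groups
  nad5 <- gene_feature("nad5", "PCG", "+",
                       data.frame(start = c(700, 4000), end = c(800, 4100),
                                  strand = c("+", "-")),
                       trans_splicing = TRUE)
  g3 <- mt_genome("t3", random_dna(6000), features = c(feats, list(nad5)))
  mk3 <- unname(extract_gene_order(g3)$markers)
  expect_true(all(c("+nad5_seg1", "-nad5_seg2") %in% mk3))
})

test_that("pseudo and foreign features are dropped on request, with errors when nothing is left", {
  feats <- list(
    gene_feature("ok", "PCG", "+", data.frame(start = 10, end = 100)),
    gene_feature("ps", "PCG", "+", data.frame(start = 200, end = 300),
                 pseudo = TRUE),
    gene_feature("cpx", "tRNA", "+", data.frame(start = 400, end = 470),
                 foreign = TRUE))
  g <- mt_genome("t", random_dna(600), features = feats)
  expect_equal(unname(extract_gene_order(g)$markers), "+ok")
  expect_length(extract_gene_order(g, drop_pseudo = FALSE,
                                   drop_foreign = FALSE)$markers, 3L)
  g2 <- mt_genome("t2", random_dna(600),
                  features = feats[2])
  expect_error(extract_gene_order(g2), "drop_pseudo")
})

test_that("rotating the origin of a circular genome rotates the gene order", {
  set.seed(11)
  len <- 1200L
  starts <- c(50L, 250L, 450L, 650L, 850L, 1050L)
  base_seq <- random_dna(len)
  make_rot <- function(shift) {
    s2 <- paste0(substr(base_seq, shift + 1, len), substr(base_seq, 1, shift))
    st <- ((starts - shift - 1L) %% len) + 1L
    feats <- lapply(seq_along(st), function(i)
      gene_feature(letters[i], "PCG", if (i %% 2) "+" else "-",
                   data.frame(start = st[i], end = st[i] + 80L)))
    extract_gene_order(mt_genome("r", s2, features = feats))$markers
  }
  ref <- unname(make_rot(0L))
  is_rotation <- function(x, y) {
    if (length(x) != length(y)) return(FALSE)
    any(vapply(seq_along(y), function(k)
      identical(c(y[k:length(y)], y[seq_len(k - 1)]), x), TRUE))
  }
  # origin shifts aligned with intergenic gaps: every rotation of the
  # annotation yields a rotation of the order
  for (shift in c(200L, 600L, 1000L)) {
    rot <- unname(make_rot(shift))
    expect_true(is_rotation(ref, rot))
  }
})

test_that("cis intron lengths and IDs follow the spliced-CDS convention", {
  # gene with exons 100..200 and 301..400: one cis intron of length 100
  f <- gene_feature("nad4", "PCG", "+",
                    data.frame(start = c(100, 301), end = c(200, 400)))
  g <- mt_genome("t", random_dna(500), features = list(f))
  ci <- catalog_introns(g)
  expect_equal(nrow(ci$introns), 1L)
  expect_equal(ci$introns$length, 100L)
  expect_equal(ci$introns$length,
               ci$introns$acceptor - ci$introns$donor - 1L)
  expect_equal(ci$introns$intron_id, "nad4i101")

  # supplied IDs are kept verbatim
  f2 <- gene_feature("nad1", "PCG", "+",
                     data.frame(start = c(100, 301), end = c(200, 400)),
                     intron_ids = "nad1i394")
  ci2 <- catalog_introns(mt_genome("t", random_dna(500), features = list(f2)))
  expect_equal(ci2$introns$intron_id, "nad1i394")

  # single-exon gene: no introns; minus strand: genome-forward coordinates
  f3 <- gene_feature("cox1", "PCG", "+", data.frame(start = 10, end = 90))
  expect_equal(nrow(catalog_introns(
    mt_genome("t", random_dna(100), features = list(f3)))$introns), 0L)
  f4 <- gene_feature("cox2", "PCG", "-",
                     data.frame(start = c(301, 100), end = c(400, 200),
                                strand = "-"))
  ci4 <- catalog_introns(mt_genome("t", random_dna(500), features = list(f4)))
  expect_equal(ci4$introns$length, 100L)
  expect_equal(ci4$introns$donor, 200L)
  expect_equal(ci4$introns$acceptor, 301L)
})

test_that("trans-spliced genes yield trans intron records at segment junctions", {
  f <- gene_feature("nad5", "PCG", "+",
                    data.frame(start = c(100, 200, 2000), end = c(150, 280, 2100),
                               segment = c(1L, 1L, 2L)),
                    trans_splicing = TRUE)
  ci <- catalog_introns(mt_genome("t", random_dna(3000), features = list(f)))
  expect_equal(sum(ci$introns$splicing == "trans"), 1L)
  expect_equal(sum(ci$introns$splicing == "cis"), 1L)
  expect_true(is.na(ci$introns$length[ci$introns$splicing == "trans"]))
  expect_equal(ci$summary$n_introns, 2L)
})

test_that("overlapping exons within one feature are an annotation error", {
  f <- gene_feature("bad", "PCG", "+",
                    data.frame(start = c(100, 150), end = c(200, 300)))
  expect_error(catalog_introns(mt_genome("t", random_dna(400),
                                         features = list(f))), "overlap")
})

test_that("intron totals + exon totals + intergenic space partition simulated genomes", {
  for (seed in 1:3) {
    plan <- list(
      list(name = "nad1", category = "PCG", strand = "+",
           exon_lengths = c(200L, 300L, 250L), intron_lengths = c(120L, 340L)),
      list(name = "cox1", category = "PCG", strand = "-",
           exon_lengths = c(400L, 100L), intron_lengths = 90L),
      list(name = "trnA", category = "tRNA", strand = "+",
           exon_lengths = 75L, intron_lengths = integer(0)))
    sim <- simulate_genome(8000L, gene_plan = plan, seed = seed)
    ci <- catalog_introns(sim$genome)
    expect_equal(ci$summary$cis_total_length, 120L + 340L + 90L)
    exon_total <- sum(vapply(sim$genome$features, function(f)
      sum(f$exons$end - f$exons$start + 1L), 1L))
    spans <- vapply(sim$genome$features, function(f)
      max(f$exons$end) - min(f$exons$start) + 1L, 1L)
    intergenic <- sim$genome$length - sum(spans)
    expect_equal(ci$summary$cis_total_length + exon_total + intergenic,
                 sim$genome$length)
  }
})

test_that("gene-order tables round-trip losslessly", {
  o <- gene_order("G1", c("+a", "-b"))
  tf <- tempfile(fileext = ".tsv")
  write_gene_order_table(list(o), tf)
  expect_equal(readLines(tf), "G1\t+a\t-b")

  set.seed(21)
  orders <- lapply(1:46, function(i) random_signed_order(12, paste0("g", i)))
  write_gene_order_table(orders, tf)
  back <- read_gene_order_table(tf)
  expect_equal(lapply(back, function(o) unname(o$markers)),
               lapply(orders, function(o) unname(o$markers)))
  expect_equal(vapply(back, function(o) o$genome_id, ""),
               vapply(orders, function(o) o$genome_id, ""))
  # duplicate ids refuse to serialize
  expect_error(write_gene_order_table(list(o, o), tf), "duplicate")
})
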