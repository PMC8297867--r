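# Fixture builders: everything is generated in code at test time.

# serialize a sequence into GenBank ORIGIN blocks
gb_origin_block <- function(seqn) {
  seqn <- tolower(seqn)
  vapply(seq(1, nchar(seqn), 60), function(i) {
    chunk <- substr(seqn, i, min(i + 59, nchar(seqn)))
    parts <- substring(chunk, seq(1, nchar(chunk), 10),
                       pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    paste0(formatC(i, width = 9), " ", paste(parts, collapse = " "))
  }, "")
}

# write a small hand-specified GenBank flat file; features is a character
# vector of pre-formatted feature-table lines
write_toy_genbank <- function(path, seqn, features,
                              topology = "circular", name = "toy") {
  lines <- c(
    sprintf("LOCUS       %s                %d bp    DNA     %s PLN 01-JAN-2021",
            name, nchar(seqn), topology),
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", nchar(seqn)),
    features,
    "ORIGIN",
    gb_origin_block(seqn),
    "//")
  writeLines(lines, path)
  path
}

gb_feature <- function(key, location, ...) {
  quals <- c(...)
  c(sprintf("     %-15s %s", key, location),
    if (length(quals)) sprintf("                     /%s", quals))
}

# the standard three-gene toy genome used across genome-model tests
toy_genome_file <- function(seed = 1) {
  set.seed(seed)
  seqn <- mitostruct::random_dna(1000)
  tf <- tempfile(fileext = ".gb")
  write_toy_genbank(tf, seqn, c(
    gb_feature("CDS", "join(100..150,180..200)", 'gene="atp1"'),
    gb_feature("tRNA", "complement(300..370)", 'gene="trnM"'),
    gb_feature("rRNA", "500..800", 'gene="rrn18"')))
  tf
}

# a tiny SAM file over one CDS reference, with simple fully-matching reads
write_toy_sam <- function(path, ref_name, ref_seq, reads) {
  # reads: data.frame(pos, seq)
  lines <- c(
    "@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", ref_name, nchar(ref_seq)),
    vapply(seq_len(nrow(reads)), function(i)
      paste(sprintf("r%03d", i), 0, ref_name, reads$pos[i], 60,
            paste0(nchar(reads$seq[i]), "M"), "*", 0, 0,
            reads$seq[i], strrep("I", nchar(reads$seq[i])), sep = "\t"), ""))
  writeLines(lines, path)
  path
}
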