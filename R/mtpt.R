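## Detection of plastid-derived insertions (MTPTs) in a mitogenome by
## local alignment of the mitochondrial sequence against a plastid genome.
## The alignment engine is NCBI blastn (-task blastn; match +2, mismatch
## -3, gap open 5, gap extend 2), the tool this analysis is normally run
## with; word size and E-value threshold are exposed (word size 7 is the
## permissive preset used for organellar homology searches).

#' Genomic spans of genes natively shared by both organellar compartments
#'
#' Returns the mitochondrial spans of the exclusion-list genes so that
#' alignment hits inside them are not reported as plastid-derived
#' insertions. The default list holds the five gene pairs that occur
#' natively in both compartments: atp1/atpA, rpl16, rps4, rrn26/rrn23 and
#' rrn18/rrn16.
#'
#' @param mt_genome an annotated [mt_genome()].
#' @param exclusion character vector of gene symbols to mask.
#' @return data.frame of masked intervals (gene, start, end).
#' @export
mask_shared_genes <- function(mt_genome,
                              exclusion = c("atp1", "atpA", "rpl16", "rps4",
                                            "rrn26", "rrn23", "rrn18", "rrn16")) {
  rows <- list()
  found <- character(0)
  for (f in mt_genome$features) {
    if (!f$name %in% exclusion) next
    found <- c(found, f$name)
    rows[[length(rows) + 1L]] <- data.frame(
      gene = f$name, start = min(f$exons$start), end = max(f$exons$end))
  }
  missing <- setdiff(exclusion, found)
  if (length(missing) > 0L && length(found) > 0L)
    warning("exclusion genes absent from annotation: ",
            paste(missing, collapse = ", "), call. = FALSE)
  if (length(rows) == 0L)
    return(data.frame(gene = character(0), start = integer(0), end = integer(0)))
  do.call(rbind, rows)
}

blast_available <- function() {
  nzchar(Sys.which("blastn")) && nzchar(Sys.which("makeblastdb"))
}

#' Find plastid-derived insertions in a mitogenome
#'
#' Aligns the mitochondrial genome against a plastid genome and reports
#' local alignments at `evalue <= threshold`, sorted by bit score. Hits
#' whose mitochondrial interval is contained in a higher-scoring hit are
#' removed, as are hits overlapping the masked spans of natively shared
#' genes. For circular sequences a short origin wrap is appended on both
#' sides so junction-spanning homology is seen. Plastid genes overlapped
#' by each hit are reported, flagged `*` when covered only partially.
#'
#' @param mt_genome mitochondrial [mt_genome()] (or DNA string).
#' @param cp_genome plastid [mt_genome()] (annotation used for the gene
#'   column) or DNA string.
#' @param evalue E-value threshold (default 1e-6).
#' @param word_size blastn word size (default 11; >= 4).
#' @param reward,penalty,gapopen,gapextend blastn scoring parameters.
#' @param mask optional data.frame from [mask_shared_genes()].
#' @param wrap bases of origin wrap appended to circular sequences.
#' @return data.frame with columns mt_start, mt_end, cp_start, cp_end,
#'   strand, length, identity, evalue, bit_score, overlapping_cp_genes.
#' @export
find_insertions <- function(mt_genome, cp_genome, evalue = 1e-6,
                            word_size = 11L, reward = 2L, penalty = -3L,
                            gapopen = 5L, gapextend = 2L, mask = NULL,
                            wrap = 500L) {
  if (word_size < 4L) stop("word_size must be >= 4")
  if (!blast_available())
    stop("blastn/makeblastdb not found on PATH; install NCBI BLAST+")
  as_seq <- function(g) if (inherits(g, "mt_genome")) g else
    mt_genome("seq", check_dna(g), circular = TRUE)
  mt <- as_seq(mt_genome); cp <- as_seq(cp_genome)
  wseq <- function(g) {
    w <- if (g$circular) min(wrap, g$length) else 0L
    if (w > 0L) paste0(g$sequence, substr(g$sequence, 1L, w)) else g$sequence
  }
  td <- tempfile("mtpt"); dir.create(td); on.exit(unlink(td, recursive = TRUE))
  qf <- file.path(td, "mt.fa"); sf <- file.path(td, "cp.fa")
  writeLines(c(">mt", wseq(mt)), qf)
  writeLines(c(">cp", wseq(cp)), sf)
  system2("makeblastdb", c("-in", sf, "-dbtype", "nucl"),
          stdout = FALSE, stderr = FALSE)
  out <- file.path(td, "hits.tsv")
  status <- system2("blastn",
                    c("-task", "blastn", "-query", qf, "-db", sf,
                      "-word_size", word_size, "-reward", reward,
                      "-penalty", penalty, "-gapopen", gapopen,
                      "-gapextend", gapextend, "-evalue",
                      format(evalue, scientific = TRUE),
                      "-outfmt", shQuote(paste("6 qstart qend sstart send",
                                               "length pident evalue bitscore")),
                      "-out", out))
  if (status != 0L) stop("blastn failed with status ", status)
  empty <- data.frame(mt_start = integer(0), mt_end = integer(0),
                      cp_start = integer(0), cp_end = integer(0),
                      strand = character(0), length = integer(0),
                      identity = numeric(0), evalue = numeric(0),
                      bit_score = numeric(0), overlapping_cp_genes = character(0))
  if (!file.exists(out) || file.info(out)$size == 0L) return(empty)
  h <- read.delim(out, header = FALSE,
                  col.names = c("qstart", "qend", "sstart", "send",
                                "length", "pident", "evalue", "bitscore"))
  strand <- ifelse(h$sstart <= h$send, "+", "-")
  cs <- pmin(h$sstart, h$send); ce <- pmax(h$sstart, h$send)
  hits <- data.frame(mt_start = h$qstart, mt_end = h$qend,
                     cp_start = cs, cp_end = ce, strand = strand,
                     length = h$length, identity = h$pident,
                     evalue = h$evalue, bit_score = h$bitscore)
  ## normalize origin-wrap coordinates and drop duplicated wrapped copies
  norm <- function(s, e, n) {
    sh <- s > n
    list(s = ifelse(sh, s - n, s), e = ifelse(sh, e - n, e))
  }
  mtn <- norm(hits$mt_start, hits$mt_end, mt$length)
  hits$mt_start <- mtn$s; hits$mt_end <- mtn$e
  cpn <- norm(hits$cp_start, hits$cp_end, cp$length)
  hits$cp_start <- cpn$s; hits$cp_end <- cpn$e
  hits <- hits[!duplicated(hits[, c("mt_start", "mt_end", "cp_start", "cp_end",
                                    "strand")]), , drop = FALSE]
  ## drop the full-length self alignment artifacts from the wrap copy
  hits <- hits[hits$mt_start <= mt$length, , drop = FALSE]
  hits <- hits[order(-hits$bit_score, hits$evalue, hits$mt_start), , drop = FALSE]
  ## containment removal on the mitochondrial intervals
  keep <- rep(TRUE, nrow(hits))
  for (i in seq_len(nrow(hits))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(hits))) {
      if (i == j || !keep[j]) next
      if (hits$mt_start[j] >= hits$mt_start[i] &&
          hits$mt_end[j] <= hits$mt_end[i] &&
          hits$bit_score[j] <= hits$bit_score[i] &&
          !(hits$mt_start[j] == hits$mt_start[i] &&
            hits$mt_end[j] == hits$mt_end[i] && j < i))
        keep[j] <- FALSE
    }
  }
  hits <- hits[keep, , drop = FALSE]
  ## mask natively shared genes
  if (!is.null(mask) && nrow(mask) > 0L) {
    ov <- vapply(seq_len(nrow(hits)), function(i)
      any(mask$start <= hits$mt_end[i] & mask$end >= hits$mt_start[i]), TRUE)
    hits <- hits[!ov, , drop = FALSE]
  }
  ## plastid gene overlap annotation (Table 3 style; '*' = partial)
  hits$overlapping_cp_genes <- vapply(seq_len(nrow(hits)), function(i) {
    labs <- character(0)
    for (f in cp$features) {
      gs <- min(f$exons$start); ge <- max(f$exons$end)
      if (gs <= hits$cp_end[i] && ge >= hits$cp_start[i]) {
        full <- hits$cp_start[i] <= gs && hits$cp_end[i] >= ge
        labs <- c(labs, paste0(f$name, if (!full) "*" else ""))
      }
    }
    if (length(labs) == 0L) "None" else paste(labs, collapse = "-")
  }, "")
  rownames(hits) <- NULL
  hits
}

#' Summarize plastid-derived insertions
#'
#' @param hits data.frame from [find_insertions()].
#' @param mt_length mitochondrial genome length in bases.
#' @return list with `count`, `total_length` (union of the mitochondrial
#'   intervals), `aligned_total` (sum of alignment lengths, the accounting
#'   usually quoted for insertion totals), `genome_fraction` (from the
#'   interval union), `min_length`, `max_length`. Per-insertion sizes use
#'   the alignment `length` column when present (gap columns included),
#'   else the mitochondrial span.
#' @export
summarize_insertions <- function(hits, mt_length) {
  if (nrow(hits) == 0L)
    return(list(count = 0L, total_length = 0L, aligned_total = 0L,
                genome_fraction = 0,
                min_length = NA_integer_, max_length = NA_integer_))
  spans <- if (!is.null(hits$length)) hits$length else
    abs(hits$mt_end - hits$mt_start) + 1L
  total <- interval_union_length(pmin(hits$mt_start, hits$mt_end),
                                 pmax(hits$mt_start, hits$mt_end))
  list(count = nrow(hits), total_length = as.integer(total),
       aligned_total = as.integer(sum(spans)),
       genome_fraction = total / mt_length,
       min_length = min(spans), max_length = max(spans))
}
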