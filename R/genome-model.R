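#' Construct an annotated (circular) genome object
#'
#' The central container of the package: a single chromosome with its DNA
#' sequence and a list of gene features. Plant mitogenomes are modelled as
#' single circular molecules; linear sequences are supported for fixtures.
#'
#' @param id character label for the genome.
#' @param sequence DNA string over {A,C,G,T,N}.
#' @param circular logical; is the molecule circular?
#' @param features list of features built with [gene_feature()].
#' @return an object of class `mt_genome` with fields `id`, `sequence`,
#'   `circular`, `length` and `features`.
#' @export
mt_genome <- function(id, sequence, circular = TRUE, features = list()) {
  sequence <- check_dna(sequence, paste0("genome '", id, "' sequence"))
  n <- nchar(sequence)
  for (f in features) {
    if (!inherits(f, "gene_feature")) stop("features must be gene_feature objects")
    if (any(f$exons$start < 1L) || any(f$exons$end > n))
      stop("feature '", f$name, "' has coordinates outside [1, ", n, "]")
  }
  structure(list(id = id, sequence = sequence, circular = isTRUE(circular),
                 length = n, features = features),
            class = "mt_genome")
}

#' @export
print.mt_genome <- function(x, ...) {
  cat(sprintf("<mt_genome> %s: %s bp, %s, %d features\n", x$id,
              format(x$length, big.mark = ","),
              if (x$circular) "circular" else "linear", length(x$features)))
  invisible(x)
}

#' Construct a gene feature
#'
#' One annotated locus: a gene symbol, its category (protein-coding gene,
#' tRNA or rRNA), strand, and an exon list in transcript order. Features of
#' trans-spliced genes whose exon groups lie at disjoint loci carry
#' `trans_splicing = TRUE`; features spanning the origin of a circular
#' molecule are split into two internal intervals and flagged
#' `origin_spanning`.
#'
#' @param name gene symbol.
#' @param category one of "PCG", "tRNA", "rRNA", "other".
#' @param strand "+" or "-" (the predominant strand; per-exon strands may
#'   differ for trans-spliced genes).
#' @param exons data.frame with columns `start`, `end` (1-based inclusive)
#'   and optionally `strand` and `segment` (explicit trans-segment
#'   grouping), in transcript order.
#' @param pseudo,foreign logicals: pseudogene / plastid- or nuclear-derived
#'   copy flags (both excluded from gene orders on request).
#' @param trans_splicing logical; exon groups at disjoint loci.
#' @param origin_spanning logical; locus wraps the sequence origin.
#' @param intron_ids optional character vector of published intron IDs
#'   (e.g. "nad1i394"), parallel to the inter-exon gaps; kept verbatim by
#'   [catalog_introns()].
#' @return an object of class `gene_feature`.
#' @export
gene_feature <- function(name, category = c("PCG", "tRNA", "rRNA", "other"),
                         strand = "+", exons, pseudo = FALSE, foreign = FALSE,
                         trans_splicing = FALSE, origin_spanning = FALSE,
                         intron_ids = NULL) {
  category <- match.arg(category)
  stopifnot(strand %in% c("+", "-"))
  exons <- as.data.frame(exons)
  if (nrow(exons) == 0L) stop("feature '", name, "' has an empty exon list")
  if (is.null(exons$strand)) exons$strand <- strand
  if (any(exons$start > exons$end))
    stop("feature '", name, "' has an interval with start > end; ",
         "origin-wrapping intervals must be split before construction")
  cols <- c("start", "end", "strand")
  if (!is.null(exons$segment)) cols <- c(cols, "segment")
  structure(list(name = name, category = category, strand = strand,
                 exons = exons[, cols],
                 pseudo = isTRUE(pseudo), foreign = isTRUE(foreign),
                 trans_splicing = isTRUE(trans_splicing),
                 origin_spanning = isTRUE(origin_spanning),
                 intron_ids = intron_ids),
            class = "gene_feature")
}

feature_first_coord <- function(f) min(f$exons$start)

## total exon length of a feature
feature_exon_length <- function(f) sum(f$exons$end - f$exons$start + 1L)

#' Extract the genomic subsequence of a (possibly wrapping) interval
#'
#' @param genome an `mt_genome`.
#' @param start,end 1-based coordinates; `end` may exceed the genome length
#'   for circular genomes, meaning the interval wraps the origin.
#' @param strand "+" or "-"; for "-" the reverse complement is returned.
#' @return character scalar.
#' @export
genome_subseq <- function(genome, start, end, strand = "+") {
  n <- genome$length
  if (end <= n) {
    s <- substr(genome$sequence, start, end)
  } else {
    if (!genome$circular) stop("interval exceeds linear genome end")
    s <- paste0(substr(genome$sequence, start, n),
                substr(genome$sequence, 1L, end - n))
  }
  if (strand == "-") rev_comp(s) else s
}

#' Read an annotated genome from standard formats
#'
#' Dispatches to the GenBank flat-file reader or to the FASTA + GFF3 reader.
#' Feature kinds other than CDS/tRNA/rRNA (and their gene parents) are
#' ignored with a warning. Origin-spanning locations such as
#' `join(950..1000,1..60)` are split into two internal intervals and the
#' feature flagged `origin_spanning`.
#'
#' @param path path to a GenBank flat file, or to a FASTA file when
#'   `format = "fasta+gff3"`.
#' @param format "genbank" or "fasta+gff3".
#' @param gff3 path to the GFF3 annotation (required for "fasta+gff3").
#' @param circular logical; overrides topology when the file does not state it.
#' @return an [mt_genome()] object.
#' @export
read_annotated_genome <- function(path, format = c("genbank", "fasta+gff3"),
                                  gff3 = NULL, circular = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("input file not found: ", path)
  if (format == "genbank") {
    read_genbank(path, circular = circular)
  } else {
    if (is.null(gff3)) stop("format 'fasta+gff3' requires the gff3= path")
    if (!file.exists(gff3)) stop("input file not found: ", gff3)
    read_fasta_gff3(path, gff3, circular = circular %||% TRUE)
  }
}
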