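#' Catalog cis- and trans-spliced introns of a genome
#'
#' For each protein-coding gene with two or more exons in one contiguous
#' locus, one cis intron record is emitted per inter-exon gap; genes
#' annotated as disjoint loci (trans-spliced) contribute one trans record
#' per segment junction. Intron IDs supplied by the annotation (published
#' nomenclature such as `nad1i394`) are kept verbatim; otherwise an ID is
#' formed as gene + "i" + the 1-based position of the last spliced-CDS base
#' preceding the intron in this genome's own CDS.
#'
#' Cis coordinates are reported in genome-forward orientation: `donor` is
#' the last exon base left of the intron and `acceptor` the first exon base
#' right of it, so `length == acceptor - donor - 1` on both strands.
#'
#' @param genome an [mt_genome()].
#' @param categories feature categories to scan (default protein-coding
#'   genes, where group II introns reside).
#' @return a list with `introns` (data.frame: gene, intron_id, splicing,
#'   length, donor, acceptor, strand) and `summary` (intron counts, summed
#'   cis length, fraction of the genome).
#' @export
catalog_introns <- function(genome, categories = "PCG") {
  rows <- list()
  for (f in genome$features) {
    if (!f$category %in% categories) next
    ex <- f$exons
    if (any(ex$start > ex$end)) stop("feature '", f$name, "' malformed exons")
    ## overlapping exons within one feature are an annotation error
    if (nrow(ex) > 1L) {
      o <- order(ex$start)
      if (any(ex$start[o][-1L] <= ex$end[o][-nrow(ex)]) && !f$origin_spanning)
        stop("overlapping exons within feature '", f$name, "'")
    }
    segs <- if (f$trans_splicing) split_trans_segments(f) else list(ex)
    spliced_pos <- 0L      # cumulative spliced-CDS length, transcript order
    gap_index <- 0L        # index into supplied intron_ids
    for (si in seq_along(segs)) {
      e <- segs[[si]]
      if (si > 1L) {       # junction with the previous segment: trans intron
        gap_index <- gap_index + 1L
        iid <- if (!is.null(f$intron_ids) && length(f$intron_ids) >= gap_index)
          f$intron_ids[gap_index] else paste0(f$name, "i", spliced_pos)
        rows[[length(rows) + 1L]] <- data.frame(
          gene = f$name, intron_id = iid, splicing = "trans",
          length = NA_integer_, donor = NA_integer_, acceptor = NA_integer_,
          strand = f$strand)
      }
      if (nrow(e) > 1L) {
        for (i in seq_len(nrow(e) - 1L)) {
          spliced_pos <- spliced_pos + (e$end[i] - e$start[i] + 1L)
          ## an origin-wrap junction is sequence continuity, not an intron
          if (f$origin_spanning && e$end[i] == genome$length &&
              e$start[i + 1L] == 1L) next
          gap_index <- gap_index + 1L
          ## genome-forward donor/acceptor
          if (e$strand[i] == "+" || e$start[i + 1L] > e$end[i]) {
            donor <- e$end[i]; acceptor <- e$start[i + 1L]
          } else {
            donor <- e$end[i + 1L]; acceptor <- e$start[i]
          }
          iid <- if (!is.null(f$intron_ids) && length(f$intron_ids) >= gap_index)
            f$intron_ids[gap_index] else paste0(f$name, "i", spliced_pos)
          rows[[length(rows) + 1L]] <- data.frame(
            gene = f$name, intron_id = iid, splicing = "cis",
            length = acceptor - donor - 1L, donor = donor, acceptor = acceptor,
            strand = e$strand[i])
        }
        spliced_pos <- spliced_pos + (e$end[nrow(e)] - e$start[nrow(e)] + 1L)
      } else {
        spliced_pos <- spliced_pos + (e$end[1L] - e$start[1L] + 1L)
      }
    }
  }
  introns <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(0), intron_id = character(0),
               splicing = character(0), length = integer(0),
               donor = integer(0), acceptor = integer(0), strand = character(0))
  cis_len <- sum(introns$length[introns$splicing == "cis"])
  list(introns = introns,
       summary = list(n_introns = nrow(introns),
                      n_cis = sum(introns$splicing == "cis"),
                      n_trans = sum(introns$splicing == "trans"),
                      cis_total_length = as.integer(cis_len),
                      genome_fraction = cis_len / genome$length))
}

#' Write an intron catalog to TSV
#' @param catalog result of [catalog_introns()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_intron_table <- function(catalog, path) {
  write_tsv(catalog$introns, path)
}
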