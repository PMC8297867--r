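## FASTA + GFF3 reading/writing. The GFF3 route goes through rtracklayer;
## CDS/tRNA/rRNA rows sharing an ID (or Parent) form one feature, rows in
## file order giving transcript order of the exons.

read_fasta_gff3 <- function(fasta, gff3, circular = TRUE) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  if (length(seqs) == 0L) stop("no sequences in ", fasta)
  if (length(seqs) > 1L)
    warning("multiple FASTA records; using the first", call. = FALSE)
  gid <- sub("\\s.*$", "", names(seqs)[1L])
  sequence <- as.character(seqs[[1L]])

  gr <- rtracklayer::import(gff3, format = "gff3")
  md <- as.data.frame(gr)
  keep <- md$type %in% c("CDS", "tRNA", "rRNA")
  other <- setdiff(unique(as.character(md$type)),
                   c("CDS", "tRNA", "rRNA", "gene", "region", "exon", "mRNA"))
  if (length(other) > 0L)
    warning("ignored unknown feature kinds: ", paste(other, collapse = ", "),
            call. = FALSE)
  md <- md[keep, , drop = FALSE]

  getattr <- function(row, key) {
    v <- md[[key]]
    if (is.null(v)) return(NULL)
    x <- v[row]
    if (is.list(x)) x <- unlist(x)
    if (length(x) == 0L || all(is.na(x))) NULL else as.character(x)[1L]
  }
  grp <- vapply(seq_len(nrow(md)), function(i) {
    getattr(i, "ID") %||% getattr(i, "Parent") %||% getattr(i, "gene") %||%
      paste0("feat", i)
  }, "")

  features <- list()
  for (g in unique(grp)) {
    rows <- which(grp == g)
    i1 <- rows[1L]
    name <- getattr(i1, "gene") %||% getattr(i1, "Name") %||% g
    is_true <- function(key) identical(tolower(getattr(i1, key) %||% "false"), "true")
    features[[length(features) + 1L]] <- gene_feature(
      name = name,
      category = c(CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA")[[as.character(md$type[i1])]],
      strand = as.character(md$strand[i1]),
      exons = {
        ex <- data.frame(start = md$start[rows], end = md$end[rows],
                         strand = as.character(md$strand[rows]))
        if (!is.null(md$segment)) ex$segment <- as.character(md$segment[rows])
        ex
      },
      pseudo = is_true("pseudo"), foreign = is_true("foreign"),
      trans_splicing = is_true("trans_splicing"),
      origin_spanning = is_true("origin_spanning"),
      intron_ids = {
        ii <- getattr(i1, "intron_ids")
        if (is.null(ii)) NULL else strsplit(ii, ",", fixed = TRUE)[[1L]]
      })
  }
  g <- mt_genome(gid, sequence, circular = circular, features = features)
  g$features <- assign_copy_indices(g$features)
  g
}

#' Write a genome to FASTA
#' @param genome an `mt_genome`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  s <- Biostrings::DNAStringSet(genome$sequence)
  names(s) <- genome$id
  Biostrings::writeXStringSet(s, path)
  invisible(path)
}

#' Write a genome's annotation to GFF3
#'
#' One row per exon; rows of a feature share an `ID` and appear in
#' transcript order, so the file round-trips through
#' [read_annotated_genome()] with `format = "fasta+gff3"`.
#'
#' @param genome an `mt_genome`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_genome_gff3 <- function(genome, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("##gff-version 3", con)
  writeLines(sprintf("##sequence-region %s 1 %d", genome$id, genome$length), con)
  type_of <- c(PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA", other = "misc_feature")
  for (i in seq_along(genome$features)) {
    f <- genome$features[[i]]
    attrs <- sprintf("ID=%s.%d;gene=%s", f$name, f$copy_index %||% i, f$name)
    for (flag in c("pseudo", "foreign", "trans_splicing", "origin_spanning"))
      if (isTRUE(f[[flag]])) attrs <- paste0(attrs, ";", flag, "=true")
    if (!is.null(f$intron_ids))
      attrs <- paste0(attrs, ";intron_ids=", paste(f$intron_ids, collapse = ","))
    for (e in seq_len(nrow(f$exons))) {
      row_attrs <- attrs
      if (!is.null(f$exons$segment))
        row_attrs <- paste0(attrs, ";segment=", f$exons$segment[e])
      writeLines(paste(genome$id, "mitostruct", type_of[[f$category]],
                       f$exons$start[e], f$exons$end[e], ".",
                       f$exons$strand[e], ".", row_attrs, sep = "\t"), con)
    }
  }
  invisible(path)
}
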