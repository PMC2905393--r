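# Readers and writers for the standard interchange formats: FASTA genome,
# GFF3 annotation (1-based inclusive), BED6 sites (0-based half-open),
# tab-delimited probe/expression tables and CSV growth curves.

#' Write / read a genome FASTA
#' @param genome named DNAStringSet.
#' @param path file path.
#' @return `read_genome_fasta` returns a DNAStringSet.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @export
read_genome_fasta <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Write / read a gene annotation as GFF3
#'
#' Genes are written as `gene` features (1-based inclusive) with `ID`,
#' `coding` and `tss` attributes.
#'
#' @param annotation annotation data.frame (gene_id, chrom, start, end,
#'   strand, coding, tss).
#' @param path file path.
#' @return `read_annotation_gff3` returns the annotation data.frame.
#' @export
write_annotation_gff3 <- function(annotation, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = annotation$chrom,
    ranges = IRanges::IRanges(annotation$start, annotation$end),
    strand = annotation$strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    type = "gene",
    ID = annotation$gene_id,
    coding = as.character(annotation$coding),
    tss = as.character(annotation$tss))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname write_annotation_gff3
#' @export
read_annotation_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  data.frame(gene_id = gr$ID,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             coding = as.logical(gr$coding),
             tss = as.integer(gr$tss),
             stringsAsFactors = FALSE)
}

#' Write binding sites as BED6
#'
#' One 1-bp interval per site apex, 0-based half-open, score = enrichment
#' level.
#'
#' @param sites site data.frame (chrom, apex_bp, level; optional site_id).
#' @param path file path.
#' @export
write_sites_bed <- function(sites, path) {
  nm <- if ("site_id" %in% names(sites)) sites$site_id
        else sprintf("site%03d", seq_len(nrow(sites)))
  lev <- if ("level" %in% names(sites)) sites$level
         else if ("level_mean" %in% names(sites)) sites$level_mean
         else rep(0, nrow(sites))
  bed <- data.frame(chrom = sites$chrom,
                    start = as.integer(round(sites$apex_bp)) - 1L,
                    end = as.integer(round(sites$apex_bp)),
                    name = nm, score = round(lev, 4), strand = ".")
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write / read a probe track as a tab-delimited table
#' @param track a `probe_track`.
#' @param path file path.
#' @return `read_probe_table` returns a `probe_track`.
#' @export
write_probe_table <- function(track, path) {
  write.table(as.data.frame(track), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_probe_table
#' @param probe_length probe length for the restored track.
#' @export
read_probe_table <- function(path, probe_length = 50L) {
  x <- read.table(path, header = TRUE, sep = "\t",
                  stringsAsFactors = FALSE)
  probe_track(x$chrom, x$start, x$strand, x$ratio,
              probe_length = probe_length)
}

#' Write / read an expression matrix as a tab-delimited table
#' @param m gene x column matrix (columns `t<min>_r<rep>`).
#' @param path file path.
#' @return `read_expression_matrix` returns the matrix.
#' @export
write_expression_matrix <- function(m, path) {
  write.table(data.frame(gene_id = rownames(m), m, check.names = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_matrix
#' @export
read_expression_matrix <- function(path) {
  x <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                  stringsAsFactors = FALSE)
  m <- as.matrix(x[, -1, drop = FALSE])
  rownames(m) <- x$gene_id
  m
}

#' Write / read growth curves as CSV
#' @param curves a `growth_curves` data.frame.
#' @param path file path.
#' @return `read_growth_csv` returns a `growth_curves` data.frame.
#' @export
write_growth_csv <- function(curves, path) {
  utils::write.csv(as.data.frame(curves), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_growth_csv
#' @export
read_growth_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(x) <- c("growth_curves", "data.frame")
  x
}
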