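# File format adapters. All in-memory tables use 0-based half-open
# coordinates; conversion to/from the 1-based GRanges world happens here.

#' Read aligned reads from a BED file
#'
#' One interval per aligned read; the strand column is required.
#'
#' @param path BED file path (BED6 or better).
#' @return data.frame with \code{chrom}, \code{start}, \code{end} (0-based,
#'   half-open), \code{strand}.
#' @export
read_bed_reads <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  strand <- as.character(BiocGenerics::strand(gr))
  if (any(strand == "*"))
    stopf("reads in %s lack strand information", path)
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = BiocGenerics::start(gr) - 1L,
             end = BiocGenerics::end(gr),
             strand = strand, stringsAsFactors = FALSE)
}

#' Write intervals to BED
#'
#' @param x data.frame with \code{chrom}, \code{start}, \code{end} (0-based,
#'   half-open) and optionally \code{strand}, \code{name}, \code{score}.
#' @param path Output path.
#' @export
write_bed <- function(x, path) {
  assert_columns(x, c("chrom", "start", "end"), "intervals")
  gr <- GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = if ("strand" %in% names(x)) x$strand else "*")
  if ("name" %in% names(x)) gr$name <- x$name
  if ("score" %in% names(x)) gr$score <- x$score
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Write promoter regions to BED6 with the pair class in the name field
#'
#' @param promoters Promoter table from [derive_promoters()].
#' @param path Output path.
#' @export
write_promoters_bed <- function(promoters, path) {
  x <- promoters
  x$name <- paste(x$gene_id, x$pair_class, sep = "|")
  x$score <- 0L
  write_bed(x, path)
}

#' Read promoter sequences from FASTA
#'
#' @param path FASTA path; record names are taken as promoter/gene ids up to
#'   the first whitespace.
#' @return A [Biostrings::DNAStringSet].
#' @export
read_promoter_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

#' Write sequences to FASTA
#' @param seqs Named character vector or DNAStringSet.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  if (!methods::is(seqs, "DNAStringSet"))
    seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Extract promoter sequences from a genome
#'
#' @param genome Named DNAStringSet of chromosome sequences.
#' @param promoters Promoter table (0-based half-open coordinates).
#' @return DNAStringSet named by gene id, in promoter orientation-agnostic
#'   genomic (+) orientation.
#' @export
promoter_sequences <- function(genome, promoters) {
  assert_columns(promoters, c("gene_id", "chrom", "start", "end"), "promoters")
  if (!all(promoters$chrom %in% names(genome)))
    stopf("promoter chromosome(s) absent from genome")
  out <- Biostrings::DNAStringSet(vapply(seq_len(nrow(promoters)), function(i)
    as.character(Biostrings::subseq(genome[[promoters$chrom[i]]],
                                    start = promoters$start[i] + 1L,
                                    end = promoters$end[i])),
    character(1)))
  names(out) <- promoters$gene_id
  out
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
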