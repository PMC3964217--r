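#' Read a gene annotation table
#'
#' Reads a RefSeq-style gene table and reduces it to one record per gene,
#' keeping the most 5' transcription start site (TSS) for genes listed with
#' multiple start sites. Coordinates are 0-based, half-open (BED convention)
#' throughout the package; the TSS of a minus-strand gene is taken as the
#' rightmost transcribed base, \code{txEnd - 1}.
#'
#' Two layouts are accepted: a headered TSV with columns \code{gene_id},
#' \code{chrom}, \code{strand}, \code{txStart}, \code{txEnd}; or headerless
#' BED6 (\code{chrom}, \code{start}, \code{end}, \code{name}, \code{score},
#' \code{strand}), in which the name field is the gene id.
#'
#' @param path Path to the annotation file.
#' @return A data.frame of gene records with columns \code{gene_id},
#'   \code{chrom}, \code{strand} (\code{"+"} or \code{"-"}) and \code{tss}
#'   (0-based position of the first transcribed base).
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("gene_id\tchrom\tstrand\ttxStart\ttxEnd",
#'              "G1\tchr1\t+\t5000\t7000",
#'              "G1\tchr1\t+\t5200\t7000",
#'              "G2\tchr1\t-\t7500\t8400"), tf)
#' read_gene_table(tf)
#' @export
read_gene_table <- function(path) {
  if (!file.exists(path)) stopf("annotation file not found: %s", path)
  first <- readLines(path, n = 1L)
  if (!length(first) || !nzchar(first)) stopf("empty annotation file: %s", path)
  headered <- grepl("gene_id", first, fixed = TRUE)
  if (headered) {
    tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
    assert_columns(tab, c("gene_id", "chrom", "strand", "txStart", "txEnd"),
                   "gene table")
  } else {
    tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(tab) < 6L) stopf("headerless input must be BED6: %s", path)
    tab <- data.frame(gene_id = as.character(tab[[4]]), chrom = tab[[1]],
                      strand = tab[[6]], txStart = tab[[2]], txEnd = tab[[3]],
                      stringsAsFactors = FALSE)
  }
  if (!nrow(tab)) stopf("empty annotation file: %s", path)
  bad <- !(tab$strand %in% c("+", "-"))
  if (any(bad)) {
    warnf("dropping %d row(s) with malformed strand symbol", sum(bad))
    tab <- tab[!bad, , drop = FALSE]
  }
  if (!nrow(tab)) stopf("no valid rows in annotation file: %s", path)
  if (any(tab$txStart < 0) || any(tab$txEnd < tab$txStart))
    stopf("invalid txStart/txEnd coordinates")

  # one record per gene; most 5' TSS across transcripts
  key <- tab$gene_id
  uniq <- !duplicated(key)
  genes <- tab[uniq, c("gene_id", "chrom", "strand"), drop = FALSE]
  conflict <- vapply(split(paste(tab$chrom, tab$strand), key), function(z)
    length(unique(z)) > 1L, logical(1))
  if (any(conflict)) {
    warnf("dropping %d gene(s) with conflicting chrom/strand across rows",
          sum(conflict))
    keep <- !(genes$gene_id %in% names(conflict)[conflict])
    genes <- genes[keep, , drop = FALSE]
    tab <- tab[key %in% genes$gene_id, , drop = FALSE]
    key <- tab$gene_id
  }
  plus_tss <- tapply(tab$txStart, key, min)
  minus_tss <- tapply(tab$txEnd, key, max) - 1L
  genes$tss <- ifelse(genes$strand == "+",
                      plus_tss[genes$gene_id], minus_tss[genes$gene_id])
  genes$tss <- as.integer(genes$tss)
  rownames(genes) <- NULL
  genes[order(genes$chrom, genes$tss, genes$gene_id), , drop = FALSE]
}

#' Derive fixed-width upstream promoters
#'
#' The promoter of a gene is the \code{width} bases of DNA immediately
#' upstream of its TSS: \code{[tss - width, tss)} for plus-strand genes and
#' \code{[tss + 1, tss + 1 + width)} for minus-strand genes (0-based,
#' half-open). Promoters that would run off the chromosome start are truncated
#' at 0 and flagged.
#'
#' @param genes Gene records as returned by [read_gene_table()].
#' @param width Promoter width in bases (default 1000).
#' @return A data.frame of promoter regions: \code{gene_id}, \code{chrom},
#'   \code{start}, \code{end}, \code{strand}, \code{clipped},
#'   \code{pair_class} (initialised to \code{"unidirectional"}) and
#'   \code{partner_id} (NA).
#' @export
derive_promoters <- function(genes, width = 1000L) {
  assert_columns(genes, c("gene_id", "chrom", "strand", "tss"), "genes")
  width <- as.integer(width)
  start <- ifelse(genes$strand == "+", genes$tss - width, genes$tss + 1L)
  end <- start + width
  clipped <- start < 0L
  if (any(clipped))
    warnf("%d promoter(s) truncated at chromosome start", sum(clipped))
  start <- pmax(start, 0L)
  data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
             start = as.integer(start), end = as.integer(end),
             strand = genes$strand, clipped = clipped,
             pair_class = "unidirectional", partner_id = NA_character_,
             stringsAsFactors = FALSE)
}

#' Classify divergent and convergent promoter pairs
#'
#' Finds gene pairs on opposite strands of the same chromosome whose TSSs lie
#' within \code{max_distance} bases of each other. A pair is
#' \emph{bidirectional} (divergent, back-to-back) when the minus-strand TSS is
#' at or to the left of the plus-strand TSS, so the two 1-kb upstream
#' promoters overlap; it is \emph{face-to-face} (convergent) when the
#' plus-strand TSS is at or to the left of the minus-strand TSS, so the
#' promoters are disjoint. Each gene joins at most one pair: candidate pairs
#' are accepted greedily by increasing TSS distance, ties broken by gene id.
#'
#' @param genes Gene records.
#' @param max_distance Maximum TSS-to-TSS distance in bases (default 1000).
#' @return A data.frame of pairs: \code{minus_gene}, \code{plus_gene},
#'   \code{chrom}, \code{tss_distance}, \code{kind} (\code{"bidirectional"} or
#'   \code{"face_to_face"}).
#' @seealso [apply_pair_classes()] to push the classification onto promoter
#'   records.
#' @export
classify_promoter_pairs <- function(genes, max_distance = 1000L) {
  assert_columns(genes, c("gene_id", "chrom", "strand", "tss"), "genes")
  empty <- data.frame(minus_gene = character(), plus_gene = character(),
                      chrom = character(), tss_distance = integer(),
                      kind = character(), stringsAsFactors = FALSE)
  cand <- lapply(split(genes, genes$chrom), function(g) {
    plus <- g[g$strand == "+", , drop = FALSE]
    minus <- g[g$strand == "-", , drop = FALSE]
    if (!nrow(plus) || !nrow(minus)) return(empty)
    # all cross-strand TSS distances within range, both orientations
    d <- outer(plus$tss, minus$tss, "-")  # plus.tss - minus.tss
    idx <- which(abs(d) <= max_distance, arr.ind = TRUE)
    if (!nrow(idx)) return(empty)
    dd <- d[idx]
    data.frame(minus_gene = minus$gene_id[idx[, 2]],
               plus_gene = plus$gene_id[idx[, 1]],
               chrom = g$chrom[1], tss_distance = abs(dd),
               kind = ifelse(dd >= 0, "bidirectional", "face_to_face"),
               stringsAsFactors = FALSE)
  })
  cand <- do.call(rbind, c(cand, list(empty)))
  if (!nrow(cand)) return(empty)
  rownames(cand) <- NULL
  # greedy nearest-partner matching, lexicographic tie-break
  ord <- order(cand$tss_distance, pmin(cand$minus_gene, cand$plus_gene),
               pmax(cand$minus_gene, cand$plus_gene))
  cand <- cand[ord, , drop = FALSE]
  taken <- character(0)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    a <- cand$minus_gene[i]; b <- cand$plus_gene[i]
    if (!(a %in% taken) && !(b %in% taken)) {
      keep[i] <- TRUE
      taken <- c(taken, a, b)
    }
  }
  out <- cand[keep, , drop = FALSE]
  rownames(out) <- NULL
  out[order(out$chrom, out$minus_gene), , drop = FALSE]
}

#' Annotate promoter records with their pair class
#'
#' @param promoters Promoter regions from [derive_promoters()].
#' @param pairs Pair table from [classify_promoter_pairs()].
#' @return The promoter data.frame with \code{pair_class} and
#'   \code{partner_id} filled in for paired genes.
#' @export
apply_pair_classes <- function(promoters, pairs) {
  assert_columns(promoters, c("gene_id", "pair_class", "partner_id"),
                 "promoters")
  if (!nrow(pairs)) return(promoters)
  m1 <- match(pairs$minus_gene, promoters$gene_id)
  m2 <- match(pairs$plus_gene, promoters$gene_id)
  promoters$pair_class[m1] <- pairs$kind
  promoters$pair_class[m2] <- pairs$kind
  promoters$partner_id[m1] <- pairs$plus_gene
  promoters$partner_id[m2] <- pairs$minus_gene
  promoters
}
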