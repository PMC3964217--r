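#' Scan a sequence for an IUPAC motif on both strands
#'
#' Plus-strand hits are positions where the pattern matches the forward
#' sequence; minus-strand hits are positions where the reverse complement of
#' the pattern matches the forward sequence. Overlapping matches are all
#' reported. IUPAC degeneracy codes in the pattern are honoured; \code{N}
#' bases in the subject never match.
#'
#' @param seqs A DNAStringSet, named character vector, or single character
#'   string of promoter sequence(s).
#' @param pattern IUPAC pattern, default the canonical ETS 7-mer
#'   \code{"CCGGAAG"}.
#' @return data.frame of hits: \code{region_id}, \code{offset} (0-based
#'   position within the region), \code{strand}, \code{matched} (the forward
#'   sequence under the match).
#' @examples
#' scan_motifs(c(p1 = "TTCCGGAAGTT"))          # one + hit at offset 2
#' scan_motifs(c(p1 = "AACTTCCGGAA"))          # one - hit at offset 3
#' @export
scan_motifs <- function(seqs, pattern = "CCGGAAG") {
  pattern <- toupper(pattern)
  ok <- strsplit(pattern, "")[[1]] %in% names(Biostrings::IUPAC_CODE_MAP)
  if (!all(ok)) stopf("invalid IUPAC symbol(s) in pattern: %s", pattern)
  if (!methods::is(seqs, "DNAStringSet")) {
    if (is.character(seqs) && is.null(names(seqs)) && length(seqs) == 1L)
      names(seqs) <- "seq1"
    seqs <- Biostrings::DNAStringSet(seqs)
  }
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  pat <- Biostrings::DNAString(pattern)
  rcpat <- Biostrings::reverseComplement(pat)
  chr <- as.character(seqs)
  hit_one <- function(p, strand) {
    # fixed = "subject": IUPAC codes in the pattern are interpreted, but
    # ambiguity letters (N etc.) in the subject never match
    m <- Biostrings::vmatchPattern(p, seqs, fixed = "subject")
    st <- BiocGenerics::start(m)
    n <- lengths(st)
    if (!sum(n)) return(NULL)
    idx <- rep(seq_along(seqs), n)
    off <- unlist(st, use.names = FALSE) - 1L
    data.frame(region_id = names(seqs)[idx], offset = off, strand = strand,
               matched = substr(chr[idx], off + 1L, off + length(p)),
               stringsAsFactors = FALSE)
  }
  out <- rbind(hit_one(pat, "+"), hit_one(rcpat, "-"))
  if (is.null(out))
    out <- data.frame(region_id = character(), offset = integer(),
                      strand = character(), matched = character(),
                      stringsAsFactors = FALSE)
  out <- out[order(out$region_id, out$offset, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "motif_width") <- nchar(pattern)
  out
}

#' Count motif hits in one promoter
#'
#' Total hits regardless of strand.
#'
#' @param hits Hit table from [scan_motifs()] restricted to one region.
#' @return Integer count.
#' @export
motif_count <- function(hits) {
  if (nrow(hits) && length(unique(hits$region_id)) > 1L)
    stopf("hits span more than one region; use motif_counts()")
  nrow(hits)
}

#' Per-promoter motif counts
#'
#' @param hits Hit table from [scan_motifs()].
#' @param region_ids Universe of region ids; regions without hits get 0.
#' @return Named integer vector of counts.
#' @export
motif_counts <- function(hits, region_ids) {
  out <- integer(length(region_ids))
  names(out) <- region_ids
  if (nrow(hits)) {
    tab <- table(hits$region_id)
    out[names(tab)] <- as.integer(tab)
  }
  out
}

#' 7-mer over-representation in bound promoters
#'
#' For each of the 4^7 = 16384 7-mers, counts the promoters containing it on
#' either strand (presence/absence, not occurrences) among all promoters and
#' among bound promoters, and computes the upper-tail hypergeometric p-value
#' for over-representation in the bound set: drawing \code{n_bound} promoters
#' from \code{n_all} of which \code{all_with} contain the 7-mer, the
#' probability of seeing at least \code{bound_with} carriers. Windows
#' containing non-ACGT letters never count.
#'
#' @param bound_seqs DNAStringSet (or named character) of bound-promoter
#'   sequences; ids must be a subset of \code{all_seqs}.
#' @param all_seqs DNAStringSet of all promoter sequences.
#' @param width Word size (default 7).
#' @return data.frame sorted by ascending p-value: \code{kmer},
#'   \code{bound_with}, \code{all_with}, \code{n_bound}, \code{n_all},
#'   \code{p_value}, \code{p_bonferroni} (Bonferroni over the 4^width words).
#' @export
enrich_7mers <- function(bound_seqs, all_seqs, width = 7L) {
  if (!methods::is(all_seqs, "DNAStringSet"))
    all_seqs <- Biostrings::DNAStringSet(all_seqs)
  if (!methods::is(bound_seqs, "DNAStringSet"))
    bound_seqs <- Biostrings::DNAStringSet(bound_seqs)
  if (is.null(names(all_seqs)) || is.null(names(bound_seqs)))
    stopf("sequences must be named by promoter id")
  if (!all(names(bound_seqs) %in% names(all_seqs)))
    stopf("bound promoter ids must be a subset of the universe")
  short <- Biostrings::width(all_seqs) < width
  if (any(short)) {
    warnf("skipping %d sequence(s) shorter than %d bases", sum(short), width)
    all_seqs <- all_seqs[!short]
    bound_seqs <- bound_seqs[names(bound_seqs) %in% names(all_seqs)]
  }
  presence_counts <- function(ss) {
    nk <- 4^width
    acc <- integer(nk)
    for (i in seq(1L, length(ss), by = 200L)) {
      blk <- ss[i:min(i + 199L, length(ss))]
      f <- Biostrings::oligonucleotideFrequency(blk, width = width)
      r <- Biostrings::oligonucleotideFrequency(
        Biostrings::reverseComplement(blk), width = width)
      acc <- acc + colSums(f > 0 | r > 0)
    }
    acc
  }
  all_with <- presence_counts(all_seqs)
  bound_with <- presence_counts(bound_seqs)
  n_all <- length(all_seqs)
  n_bound <- length(bound_seqs)
  p <- hypergeom_upper(n_all, all_with, n_bound, bound_with)
  out <- data.frame(kmer = names(all_with), bound_with = bound_with,
                    all_with = all_with, n_bound = n_bound, n_all = n_all,
                    p_value = p, p_bonferroni = pmin(1, p * 4^width),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_value, out$kmer), , drop = FALSE]
  rownames(out) <- NULL
  out
}
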