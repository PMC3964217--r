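#' Build a normalized strand-aware coverage track
#'
#' Per-base read coverage is computed separately for forward- and
#' reverse-strand reads and scaled by a single factor so that the genome-wide
#' mean of normalized coverage per kilobase equals 1 ("mean total aligned
#' reads per kb" normalization). A read fully contained in a window therefore
#' contributes its per-read factor (mean read length times the per-base
#' factor) to that window's signal, and tracks from replicates of different
#' sequencing depth are directly comparable.
#'
#' @param reads data.frame of aligned reads (\code{chrom}, \code{start},
#'   \code{end} 0-based half-open, \code{strand}).
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @return An object of class \code{coverage_track}: raw per-strand coverage
#'   as run-length encoded vectors plus the normalization factor. Signal
#'   extractors ([promoter_signal()], [find_top_peak()]) apply the factor.
#' @export
normalize_coverage <- function(reads, chrom_lengths) {
  assert_columns(reads, c("chrom", "start", "end", "strand"), "reads")
  if (!nrow(reads)) stopf("cannot normalize an empty read set")
  if (is.null(names(chrom_lengths))) stopf("chrom_lengths must be named")
  if (!all(reads$chrom %in% names(chrom_lengths)))
    stopf("read chromosome(s) absent from chrom_lengths")
  cov_one <- function(r, chrom) {
    len <- chrom_lengths[[chrom]]
    r <- r[r$chrom == chrom, , drop = FALSE]
    if (!nrow(r)) return(S4Vectors::Rle(0L, len))
    ir <- IRanges::restrict(IRanges::IRanges(r$start + 1L, r$end), 1L, len)
    IRanges::coverage(ir, width = len)
  }
  chroms <- names(chrom_lengths)
  fwd <- lapply(chroms, function(ch)
    cov_one(reads[reads$strand == "+", , drop = FALSE], ch))
  rev <- lapply(chroms, function(ch)
    cov_one(reads[reads$strand == "-", , drop = FALSE], ch))
  names(fwd) <- names(rev) <- chroms
  total_mass <- sum(vapply(fwd, function(x) sum(as.numeric(x)), 0)) +
    sum(vapply(rev, function(x) sum(as.numeric(x)), 0))
  genome_kb <- sum(as.numeric(chrom_lengths)) / 1000
  factor <- genome_kb / total_mass
  structure(list(chrom_lengths = chrom_lengths, fwd = fwd, rev = rev,
                 factor = factor, n_reads = nrow(reads),
                 mean_read_len = mean(reads$end - reads$start)),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("coverage_track:", length(x$chrom_lengths), "chromosome(s),",
      x$n_reads, "reads, normalization factor", signif(x$factor, 4), "\n")
  invisible(x)
}

#' Estimate the forward/reverse strand offset
#'
#' Returns the shift k in \code{0..search_max} that maximizes the Pearson
#' correlation between forward-strand coverage and reverse-strand coverage
#' translated left by k, pooled across chromosomes. This is the apparent
#' displacement between the two strand profiles around binding events; reads
#' are subsequently shifted toward the fragment midpoint by k/2 (see
#' [shift_reads()]) before promoter scoring.
#'
#' @param track A \code{coverage_track}.
#' @param search_max Largest shift examined (default 500).
#' @return Integer offset. A flat strand (zero variance) yields 0 with a
#'   warning.
#' @export
estimate_strand_offset <- function(track, search_max = 500L) {
  stopifnot(inherits(track, "coverage_track"))
  search_max <- as.integer(search_max)
  fs <- lapply(track$fwd, as.numeric)
  rs <- lapply(track$rev, as.numeric)
  if (all(vapply(fs, function(x) stats::var(x) == 0, TRUE)) ||
      all(vapply(rs, function(x) stats::var(x) == 0, TRUE))) {
    warnf("flat strand coverage; offset set to 0")
    return(0L)
  }
  ks <- 0:search_max
  nk <- length(ks)
  acc <- list(m = numeric(nk), sx = numeric(nk), sy = numeric(nk),
              sxx = numeric(nk), syy = numeric(nk), sxy = numeric(nk))
  for (ch in names(fs)) {
    f <- fs[[ch]]; r <- rs[[ch]]
    n <- length(f)
    if (n < search_max + 2L) next
    csf <- cumsum(f); csr <- cumsum(r)
    csf2 <- cumsum(f^2); csr2 <- cumsum(r^2)
    m <- n - ks
    # lagged cross products Sum_i f[i] r[i + k] for all k at once via FFT
    # (exact up to floating rounding; padding prevents wrap-around)
    M <- stats::nextn(n + search_max + 1L)
    F <- stats::fft(c(f, numeric(M - n)))
    R <- stats::fft(c(r, numeric(M - n)))
    cc <- Re(stats::fft(Conj(F) * R, inverse = TRUE)) / M
    acc$m <- acc$m + m
    acc$sx <- acc$sx + csf[m]
    acc$sy <- acc$sy + csr[n] - c(0, csr[ks[-1]])
    acc$sxx <- acc$sxx + csf2[m]
    acc$syy <- acc$syy + csr2[n] - c(0, csr2[ks[-1]])
    acc$sxy <- acc$sxy + cc[ks + 1L]
  }
  if (all(acc$m == 0)) {
    warnf("coverage too short for the offset search; offset set to 0")
    return(0L)
  }
  num <- acc$sxy - acc$sx * acc$sy / acc$m
  den <- sqrt(pmax(acc$sxx - acc$sx^2 / acc$m, 0) *
                pmax(acc$syy - acc$sy^2 / acc$m, 0))
  cors <- ifelse(den > 0, num / den, NA_real_)
  if (all(is.na(cors))) {
    warnf("degenerate coverage; offset set to 0")
    return(0L)
  }
  ks[which.max(cors)]
}

#' Shift reads toward the fragment midpoint
#'
#' Plus-strand reads move right and minus-strand reads move left by half the
#' estimated strand offset, so both strands pile up over the binding position.
#'
#' @param reads Read data.frame.
#' @param offset Offset from [estimate_strand_offset()].
#' @return The shifted read data.frame (intervals may be clipped at 0).
#' @export
shift_reads <- function(reads, offset) {
  k <- as.integer(offset) %/% 2L
  sgn <- ifelse(reads$strand == "+", 1L, -1L)
  reads$start <- pmax(reads$start + sgn * k, 0L)
  reads$end <- pmax(reads$end + sgn * k, reads$start)
  reads
}

#' Per-promoter binding signal
#'
#' The signal of a promoter is the sum of normalized per-base coverage (both
#' strands) over its interval; a read straddling the promoter edge contributes
#' only its overlapping bases.
#'
#' @param track A normalized, offset-corrected \code{coverage_track}.
#' @param promoters Promoter table.
#' @return data.frame with \code{gene_id} and \code{signal}.
#' @export
promoter_signal <- function(track, promoters) {
  stopifnot(inherits(track, "coverage_track"))
  assert_columns(promoters, c("gene_id", "chrom", "start", "end"), "promoters")
  out <- numeric(nrow(promoters))
  known <- promoters$chrom %in% names(track$chrom_lengths)
  if (!all(known))
    warnf("%d promoter(s) outside the covered genome; signal set to 0",
          sum(!known))
  for (ch in unique(promoters$chrom[known])) {
    idx <- which(promoters$chrom == ch)
    len <- track$chrom_lengths[[ch]]
    st <- pmax(promoters$start[idx] + 1L, 1L)
    en <- pmin(promoters$end[idx], len)
    ok <- en >= st
    tot <- track$fwd[[ch]] + track$rev[[ch]]
    v <- IRanges::Views(tot, start = st[ok], end = en[ok])
    out[idx[ok]] <- IRanges::viewSums(v) * track$factor
  }
  data.frame(gene_id = promoters$gene_id, signal = out,
             stringsAsFactors = FALSE)
}

#' Assemble a promoter-by-replicate signal matrix
#'
#' @param tracks List of \code{coverage_track}s, one per replicate.
#' @param promoters Promoter table.
#' @return Numeric matrix, rows = promoters (rownames gene_id), columns =
#'   replicates.
#' @export
signal_matrix <- function(tracks, promoters) {
  m <- vapply(tracks, function(tr) promoter_signal(tr, promoters)$signal,
              numeric(nrow(promoters)))
  m <- matrix(m, nrow = nrow(promoters))
  rownames(m) <- promoters$gene_id
  colnames(m) <- names(tracks) %||% paste0("rep", seq_len(ncol(m)))
  m
}

#' Call bound promoters by control-derived FDR and replicate intersection
#'
#' The signal threshold \code{s*} is the smallest observed signal such that
#' the fraction of pooled negative-control promoter signals at or above it is
#' at most \code{fdr}. A promoter is called bound only if \emph{every}
#' treatment replicate reaches \code{s*} (replicate intersection). Promoters
#' that also reach \code{s*} in every control replicate are attributed to bias
#' and removed (\code{bias_flag = TRUE}, \code{bound = FALSE}).
#'
#' @param treatment Numeric matrix of treatment signals (promoters x
#'   replicates, rownames = gene ids), e.g. from [signal_matrix()].
#' @param controls Numeric matrix of control signals over the same promoters.
#' @param fdr Allowed fraction of control signals above threshold
#'   (default 0.005).
#' @return data.frame with \code{gene_id}, \code{bound}, \code{bias_flag},
#'   \code{mean_signal}; the threshold is attached as attribute
#'   \code{"threshold"}.
#' @export
call_bound_promoters <- function(treatment, controls, fdr = 0.005) {
  treatment <- as.matrix(treatment); controls <- as.matrix(controls)
  if (is.null(rownames(treatment))) stopf("treatment matrix needs gene ids")
  if (nrow(treatment) != nrow(controls))
    stopf("treatment and controls cover different promoter sets")
  pooled <- as.numeric(controls)
  cand <- sort(unique(c(as.numeric(treatment), pooled)))
  if (all(pooled == 0)) {
    pos <- cand[cand > 0]
    if (!length(pos)) stopf("no positive signals to threshold")
    warnf("controls are identically zero; threshold = smallest positive signal")
    sstar <- min(pos)
  } else {
    frac <- vapply(cand, function(s) mean(pooled >= s), 0)
    ok <- which(frac <= fdr)
    # no observed signal attains the fdr: nothing is callable
    sstar <- if (length(ok)) cand[min(ok)] else Inf
  }
  hit_t <- rowSums(treatment >= sstar) == ncol(treatment)
  hit_c <- rowSums(controls >= sstar) == ncol(controls)
  bias <- hit_t & hit_c
  out <- data.frame(gene_id = rownames(treatment),
                    bound = hit_t & !bias, bias_flag = bias,
                    mean_signal = rowMeans(treatment),
                    stringsAsFactors = FALSE)
  attr(out, "threshold") <- sstar
  out
}

#' Locate the largest fixed-width peak in a promoter
#'
#' Scans every \code{width}-base window inside the promoter and returns the
#' one with the largest normalized coverage sum (ties: leftmost window). The
#' reported interval is \code{[center - width %/% 2, center + width - width
#' %/% 2)}.
#'
#' @param track A \code{coverage_track}.
#' @param promoters Promoter table (one row per promoter to scan).
#' @param width Peak width in bases (default 145).
#' @return data.frame with one row per promoter that has nonzero signal:
#'   \code{gene_id}, \code{chrom}, \code{center}, \code{start}, \code{end},
#'   \code{height}. Promoters with all-zero coverage are omitted.
#' @export
find_top_peak <- function(track, promoters, width = 145L) {
  stopifnot(inherits(track, "coverage_track"))
  width <- as.integer(width)
  half <- width %/% 2L
  rows <- lapply(seq_len(nrow(promoters)), function(i) {
    ch <- promoters$chrom[i]
    if (!ch %in% names(track$chrom_lengths)) return(NULL)
    len <- track$chrom_lengths[[ch]]
    st <- promoters$start[i]; en <- min(promoters$end[i], len)
    x <- as.numeric(S4Vectors::window(track$fwd[[ch]] + track$rev[[ch]],
                                    st + 1L, en))
    if (!any(x > 0)) return(NULL)
    L <- length(x)
    if (L <= width) {
      center <- st + L %/% 2L
      height <- sum(x) * track$factor
    } else {
      ws <- window_sum(x, 0L, width)[seq_len(L - width + 1L)]
      j <- which.max(ws)  # leftmost maximum
      center <- st + (j - 1L) + half
      height <- ws[j] * track$factor
    }
    data.frame(gene_id = promoters$gene_id[i], chrom = ch,
               center = center, start = center - half,
               end = center + (width - half), height = height,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene_id = character(), chrom = character(),
                      center = integer(), start = integer(), end = integer(),
                      height = numeric(), stringsAsFactors = FALSE)
  out
}

#' Select the top-signal fraction of bound promoters
#'
#' @param calls Binding calls from [call_bound_promoters()].
#' @param fraction Fraction to keep (default 0.5); the top
#'   \code{ceiling(n * fraction)} bound promoters by mean signal are returned,
#'   ties broken by gene id.
#' @return Character vector of gene ids.
#' @export
select_top_signal <- function(calls, fraction = 0.5) {
  b <- calls[calls$bound, , drop = FALSE]
  if (!nrow(b)) return(character(0))
  b <- b[order(-b$mean_signal, b$gene_id), , drop = FALSE]
  b$gene_id[seq_len(ceiling(nrow(b) * fraction))]
}
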