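# Independent brute-force oracles used to cross-check the implementation.

# Upper-tail hypergeometric by direct combinatorial summation.
oracle_hypergeom_upper <- function(N, K, n, k) {
  js <- k:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Windowed pair-density by explicit position-by-position counting.
oracle_spacing_density <- function(d, window = 100, range = 1000) {
  pos <- (-range):range
  vapply(pos, function(p)
    sum(d >= p - window / 2 & d < p + window / 2), 0L)
}

# All-window scan for the largest fixed-width window (leftmost tie-break).
# x is the per-base profile over the promoter; returns the 1-based start
# index of the winning window and its sum.
oracle_top_window <- function(x, width) {
  n <- length(x) - width + 1
  best_i <- 1L
  best <- -Inf
  for (i in seq_len(n)) {
    s <- sum(x[i:(i + width - 1)])
    if (s > best) {
      best <- s
      best_i <- i
    }
  }
  list(start = best_i, sum = best)
}

# Exhaustive strand-offset grid search by direct correlation.
oracle_offset <- function(f, r, kmax) {
  cors <- vapply(0:kmax, function(k) {
    m <- length(f) - k
    suppressWarnings(stats::cor(f[1:m], r[(1 + k):(m + k)]))
  }, 0)
  (0:kmax)[which.max(cors)]
}

# Greedy nearest-partner pair matching by explicit enumeration.
oracle_pair_count <- function(genes, max_distance = 1000) {
  cand <- NULL
  for (i in seq_len(nrow(genes))) for (j in seq_len(nrow(genes))) {
    gi <- genes[i, ]; gj <- genes[j, ]
    if (gi$strand != "-" || gj$strand != "+") next
    if (gi$chrom != gj$chrom) next
    d <- gj$tss - gi$tss
    if (abs(d) > max_distance) next
    cand <- rbind(cand, data.frame(
      a = gi$gene_id, b = gj$gene_id, dist = abs(d),
      kind = if (d >= 0) "bidirectional" else "face_to_face"))
  }
  if (is.null(cand)) return(c(bidirectional = 0L, face_to_face = 0L))
  cand <- cand[order(cand$dist, pmin(cand$a, cand$b), pmax(cand$a, cand$b)), ]
  taken <- character(0)
  kinds <- character(0)
  for (i in seq_len(nrow(cand))) {
    if (cand$a[i] %in% taken || cand$b[i] %in% taken) next
    taken <- c(taken, cand$a[i], cand$b[i])
    kinds <- c(kinds, cand$kind[i])
  }
  c(bidirectional = sum(kinds == "bidirectional"),
    face_to_face = sum(kinds == "face_to_face"))
}

# O(n^2) neighbourhood classification of isolated singles and dimers.
oracle_isolate <- function(sites, promoters, dimer_max = 1000,
                           isolation = 2000) {
  n <- nrow(sites)
  prom_dist <- function(chrom, pos) {
    pr <- promoters[promoters$chrom == chrom, , drop = FALSE]
    if (!nrow(pr)) return(Inf)
    min(pmax(pr$start - pos, pos - (pr$end - 1), 0))
  }
  site_dists <- function(i) {
    same <- which(sites$chrom == sites$chrom[i])
    same <- setdiff(same, i)
    if (!length(same)) return(Inf)
    abs(sites$center[same] - sites$center[i])
  }
  singles <- integer(0)
  dimers <- NULL
  for (i in seq_len(n)) {
    ds <- site_dists(i)
    if (min(ds) > isolation &&
        prom_dist(sites$chrom[i], sites$center[i]) > isolation)
      singles <- c(singles, i)
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    if (sites$chrom[i] != sites$chrom[j]) next
    d <- abs(sites$center[i] - sites$center[j])
    if (d > dimer_max) next
    others <- setdiff(which(sites$chrom == sites$chrom[i]), c(i, j))
    near_other <- length(others) &&
      any(pmin(abs(sites$center[others] - sites$center[i]),
               abs(sites$center[others] - sites$center[j])) <= isolation)
    near_prom <-
      prom_dist(sites$chrom[i], sites$center[i]) <= isolation ||
      prom_dist(sites$chrom[j], sites$center[j]) <= isolation
    if (!near_other && !near_prom)
      dimers <- rbind(dimers, data.frame(
        i = i, j = j,
        klass = if (sites$strand[i] == sites$strand[j]) "direct_dimer"
                else "inverted_dimer"))
  }
  list(singles = sort(sites$center[singles]), dimers = dimers)
}

# Distinct 7-mers of a sequence on either strand, by plain substring
# extraction.
oracle_kmer_set <- function(seq, width = 7) {
  rc <- function(s) paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]),
                          collapse = "")
  grab <- function(s) {
    n <- nchar(s)
    if (n < width) return(character(0))
    vapply(1:(n - width + 1), function(i) substr(s, i, i + width - 1), "")
  }
  ks <- unique(c(grab(seq), grab(rc(seq))))
  ks[!grepl("[^ACGT]", ks)]
}

# Simple read constructor: one fixed-length read per start position.
make_reads <- function(starts, strand, len = 50L, chrom = "chr1") {
  data.frame(chrom = chrom, start = as.integer(starts),
             end = as.integer(starts + len), strand = strand,
             stringsAsFactors = FALSE)
}
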