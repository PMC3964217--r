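#' Upper-tail hypergeometric probability
#'
#' P(X >= k) when drawing \code{n} items without replacement from a universe
#' of \code{N} items of which \code{K} are special. Evaluated through
#' [stats::phyper()], which works in log space internally, so extreme tails
#' (p-values down to ~1e-300 and below on the log10 scale) are finite.
#'
#' @param N Universe size.
#' @param K Special-class size. May be a vector.
#' @param n Draw size.
#' @param k Observed special count. May be a vector (recycled with K).
#' @param log10_p If TRUE return log10(p) instead of p, for tails beyond
#'   double-precision underflow.
#' @return Numeric vector of upper-tail probabilities (or their log10).
#' @examples
#' hypergeom_upper(10, 5, 5, 5)   # 1/252
#' hypergeom_upper(100, 2, 2, 2)  # 1/4950
#' @export
hypergeom_upper <- function(N, K, n, k, log10_p = FALSE) {
  if (!is_count1(N) || !is_count1(n)) stopf("N and n must be single counts")
  if (any(K > N) | any(n > N)) stopf("class or draw size exceeds universe")
  if (any(k > K) | any(k > n)) stopf("k exceeds class size or draw size")
  if (any(c(N, K, n, k) < 0)) stopf("counts must be non-negative")
  if (log10_p) {
    lp <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE)
    lp / log(10)
  } else {
    stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  }
}

#' Fraction of a site class bound
#'
#' @param k Number of bound regions in the class.
#' @param class_size Number of regions in the class.
#' @param digits Decimals to report (default 3).
#' @return \code{round(k / class_size, digits)}.
#' @examples
#' fraction_bound(726, 11165)       # 0.065
#' fraction_bound(103, 287, 2)      # 0.36
#' @export
fraction_bound <- function(k, class_size, digits = 3L) {
  if (any(class_size <= 0)) stopf("class_size must be positive")
  if (any(k > class_size)) stopf("k cannot exceed class_size")
  round(k / class_size, digits)
}

#' Isolated single and dimer motif-site regions
#'
#' Partitions genome-level motif sites into isolated classes. A
#' \emph{single} is a site with no other site and no promoter within
#' \code{isolation} bases; a \emph{dimer} is a pair of sites at most
#' \code{dimer_max} bases apart (center-to-center) with no third site and no
#' promoter within \code{isolation} bases of either member. Dimers on opposite
#' strands are \emph{inverted}, on the same strand \emph{direct}. A region is
#' bound when a binding-peak center lies within \code{bound_window} bases of
#' the region midpoint.
#'
#' @param sites data.frame of genome motif sites: \code{chrom}, \code{center},
#'   \code{strand}.
#' @param promoters Promoter table (may have zero rows).
#' @param peaks data.frame of binding peaks with \code{chrom}, \code{center}
#'   (may have zero rows).
#' @param dimer_max Maximum intra-dimer distance (default 1000).
#' @param isolation Exclusion radius for other sites and promoters
#'   (default 2000).
#' @param bound_window Peak-to-midpoint distance counting as bound
#'   (default 500).
#' @return data.frame of regions: \code{chrom}, \code{klass} (single,
#'   inverted_dimer, direct_dimer), \code{center} (region midpoint),
#'   \code{site1}, \code{site2} (NA for singles), \code{bound}.
#' @export
isolate_regions <- function(sites, promoters, peaks,
                            dimer_max = 1000L, isolation = 2000L,
                            bound_window = 500L) {
  assert_columns(sites, c("chrom", "center", "strand"), "sites")
  res <- lapply(split(seq_len(nrow(sites)), sites$chrom), function(idx) {
    s <- sites[idx, , drop = FALSE]
    s <- s[order(s$center), , drop = FALSE]
    n <- nrow(s)
    ctr <- s$center
    gap_prev <- c(Inf, diff(ctr))
    gap_next <- c(diff(ctr), Inf)
    prom <- promoters[promoters$chrom == s$chrom[1], , drop = FALSE]
    prom_near <- function(pos) {
      if (!nrow(prom)) return(rep(FALSE, length(pos)))
      # distance from a point to the closest promoter interval
      vapply(pos, function(p) {
        d <- pmax(prom$start - p, p - (prom$end - 1L), 0L)
        min(d) <= isolation
      }, logical(1))
    }
    near_prom <- prom_near(ctr)
    singles <- which(gap_prev > isolation & gap_next > isolation & !near_prom)
    out_s <- if (length(singles))
      data.frame(chrom = s$chrom[1], klass = "single",
                 center = ctr[singles], site1 = ctr[singles],
                 site2 = NA_integer_, stringsAsFactors = FALSE)
    i <- which(gap_next <= dimer_max)  # candidate pair (i, i + 1)
    if (length(i)) {
      ok <- gap_prev[i] > isolation & gap_next[i + 1L] > isolation &
        !near_prom[i] & !near_prom[i + 1L]
      i <- i[ok]
    }
    out_d <- if (length(i))
      data.frame(chrom = s$chrom[1],
                 klass = ifelse(s$strand[i] == s$strand[i + 1L],
                                "direct_dimer", "inverted_dimer"),
                 center = (ctr[i] + ctr[i + 1L]) %/% 2L,
                 site1 = ctr[i], site2 = ctr[i + 1L],
                 stringsAsFactors = FALSE)
    rbind(if (length(singles)) out_s, if (length(i)) out_d)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(chrom = character(), klass = character(),
                      center = integer(), site1 = integer(),
                      site2 = integer(), stringsAsFactors = FALSE)
  out$bound <- FALSE
  if (nrow(peaks) && nrow(out)) {
    for (ch in unique(out$chrom)) {
      pc <- peaks$center[peaks$chrom == ch]
      if (!length(pc)) next
      sel <- out$chrom == ch
      out$bound[sel] <- vapply(out$center[sel], function(m)
        any(abs(pc - m) <= bound_window), logical(1))
    }
  }
  rownames(out) <- NULL
  out
}

#' Association between binding and bidirectional (or convergent) promoters
#'
#' Counts each promoter pair of the requested kind as a single region ("a
#' promoter region is counted only once despite it encompassing two
#' promoters"), forms the region-level universe, and computes the overlap of
#' bound regions with paired regions plus an upper-tail hypergeometric
#' p-value. With \code{count_pairs_once = FALSE} the gene-level universe is
#' used instead (each member promoter counted separately); the choice of
#' universe changes the p-value, so both modes are exposed.
#'
#' @param calls Binding calls ([call_bound_promoters()]) or a character vector
#'   of bound gene ids.
#' @param pairs Pair table from [classify_promoter_pairs()].
#' @param promoters Promoter table (the universe).
#' @param kind Which pair kind to test (default "bidirectional").
#' @param count_pairs_once Count each pair as one region (default TRUE).
#' @return A one-row data.frame: \code{label}, \code{N} (universe), \code{K}
#'   (paired regions), \code{n} (bound regions), \code{k} (bound paired
#'   regions), \code{frac_of_bound} (share of the bound set that is paired),
#'   \code{frac_of_class} (share of paired regions bound), \code{p_value},
#'   \code{log10_p}.
#' @export
bidirectional_overlap <- function(calls, pairs, promoters,
                                  kind = "bidirectional",
                                  count_pairs_once = TRUE) {
  bound_ids <- if (is.character(calls)) calls else
    calls$gene_id[calls$bound]
  pk <- pairs[pairs$kind == kind, , drop = FALSE]
  genes <- promoters$gene_id
  bound_ids <- intersect(bound_ids, genes)
  n_genes <- length(genes)
  a_bound <- pk$minus_gene %in% bound_ids
  b_bound <- pk$plus_gene %in% bound_ids
  if (count_pairs_once) {
    N <- n_genes - nrow(pk)
    K <- nrow(pk)
    n <- length(bound_ids) - sum(a_bound & b_bound)
    k <- sum(a_bound | b_bound)
  } else {
    N <- n_genes
    K <- 2L * nrow(pk)
    n <- length(bound_ids)
    k <- sum(a_bound) + sum(b_bound)
  }
  p <- if (K == 0 || n == 0) 1 else hypergeom_upper(N, K, n, k)
  lp <- if (K == 0 || n == 0) 0 else
    hypergeom_upper(N, K, n, k, log10_p = TRUE)
  data.frame(label = kind, N = N, K = K, n = n, k = k,
             frac_of_bound = if (n > 0) k / n else NA_real_,
             frac_of_class = if (K > 0) k / K else NA_real_,
             p_value = p, log10_p = lp, stringsAsFactors = FALSE)
}

#' Contingency table for region classes (Table-style summary)
#'
#' Convenience wrapper producing one row per region class from
#' [isolate_regions()] output, with class size, bound count, fraction bound
#' and a hypergeometric p-value against a caller-supplied universe.
#'
#' @param regions Output of [isolate_regions()].
#' @param N Universe size for the hypergeometric test.
#' @param n Total bound regions in the universe.
#' @param digits Decimals for the reported fraction (default 3).
#' @return data.frame with one row per class: \code{klass}, \code{class_size},
#'   \code{bound}, \code{fraction_bound}, \code{log10_p}.
#' @export
region_class_table <- function(regions, N, n, digits = 3L) {
  cls <- split(regions, regions$klass)
  rows <- lapply(names(cls), function(cl) {
    K <- nrow(cls[[cl]])
    k <- sum(cls[[cl]]$bound)
    data.frame(klass = cl, class_size = K, bound = k,
               fraction_bound = fraction_bound(k, K, digits),
               log10_p = hypergeom_upper(N, K, n, min(k, n),
                                         log10_p = TRUE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
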