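test_that("normalization fixes mean reads per kb at 1 and is depth-invariant", {
  lens <- c(chr1 = 1000000L)
  set.seed(1)
  starts <- sort(sample.int(999950L, 1000L)) - 1L
  reads <- make_reads(starts, sample(c("+", "-"), 1000, TRUE))
  tr <- normalize_coverage(reads, lens)
  # mean normalized mass per kb window is 1 by construction
  tot <- tr$fwd$chr1 + tr$rev$chr1
  kb <- vapply(seq(1, 999001, by = 1000), function(s)
    sum(as.numeric(S4Vectors::window(tot, s, s + 999))) * tr$factor, 0)
  expect_equal(mean(kb), 1, tolerance = 1e-9)

  # duplicating every read leaves the normalized track unchanged
  tr2 <- normalize_coverage(rbind(reads, reads), lens)
  expect_equal(tr2$factor * 2, tr$factor, tolerance = 1e-12)

  # 10x depth difference, same placements: identical promoter signals
  prom <- data.frame(gene_id = "P", chrom = "chr1",
                     start = 5000L, end = 6000L)
  deep <- do.call(rbind, replicate(10, reads, simplify = FALSE))
  s1 <- promoter_signal(tr, prom)$signal
  s2 <- promoter_signal(normalize_coverage(deep, lens), prom)$signal
  expect_equal(s1, s2, tolerance = 1e-9)

  expect_error(normalize_coverage(reads[0, ], lens), "empty")
})

test_that("promoter signal counts overlapping bases only", {
  lens <- c(chr1 = 100000L)
  prom <- data.frame(gene_id = "P", chrom = "chr1",
                     start = 1000L, end = 2000L)
  # 10 reads fully inside: signal = 10 x per-read factor
  inside <- make_reads(seq(1100, 1800, length.out = 10), "+")
  tr <- normalize_coverage(inside, lens)
  per_read <- tr$factor * 50
  expect_equal(promoter_signal(tr, prom)$signal, 10 * per_read,
               tolerance = 1e-9)
  # straddling read: only its 25 in-promoter bases count
  straddle <- make_reads(975L, "+")
  tr2 <- normalize_coverage(straddle, lens)
  expect_equal(promoter_signal(tr2, prom)$signal, tr2$factor * 25,
               tolerance = 1e-9)
  # empty promoter
  empty <- data.frame(gene_id = "E", chrom = "chr1",
                      start = 50000L, end = 51000L)
  expect_equal(promoter_signal(tr, empty)$signal, 0)
  # promoter outside the covered genome
  off <- data.frame(gene_id = "X", chrom = "chrZ", start = 0L, end = 1000L)
  expect_warning(s <- promoter_signal(tr, off), "outside")
  expect_equal(s$signal, 0)
})

test_that("strand offset recovers exact and noisy shifts", {
  lens <- c(chr1 = 20000L)
  set.seed(2)
  fstarts <- sample.int(5000L, 300L) + 2000L
  # reverse profile = forward translated right by 120
  reads <- rbind(make_reads(fstarts, "+"), make_reads(fstarts + 120L, "-"))
  tr <- normalize_coverage(reads, lens)
  expect_equal(estimate_strand_offset(tr, 300), 120)

  # forward = reverse: offset 0
  reads0 <- rbind(make_reads(fstarts, "+"), make_reads(fstarts, "-"))
  expect_equal(estimate_strand_offset(normalize_coverage(reads0, lens), 300),
               0)

  # flat strand: warning and 0
  flat <- make_reads(fstarts, "+")
  expect_warning(off <- estimate_strand_offset(normalize_coverage(flat, lens)),
                 "flat")
  expect_equal(off, 0)

  # noisy two-peak profile with shift 150: matches the brute-force oracle
  peaks <- c(rep(6000L, 150), rep(6900L, 120))
  noise <- sample.int(19000L, 400L)
  fs <- c(peaks + round(rnorm(length(peaks), 0, 20)), noise)
  rs <- c(peaks + 150L + round(rnorm(length(peaks), 0, 20)), noise)
  nreads <- rbind(make_reads(fs, "+"), make_reads(rs, "-"))
  ntr <- normalize_coverage(nreads, lens)
  est <- estimate_strand_offset(ntr, 400)
  ora <- oracle_offset(as.numeric(ntr$fwd$chr1), as.numeric(ntr$rev$chr1),
                       400)
  expect_equal(est, ora)
  expect_lt(abs(est - 150), 5 + 1e-9)
})

test_that("shift_reads moves strands toward the midpoint", {
  reads <- make_reads(c(1000L, 2000L), c("+", "-"))
  sh <- shift_reads(reads, 120)
  expect_equal(sh$start, c(1060L, 1940L))
  expect_equal(sh$end - sh$start, c(50L, 50L))
})

test_that("binding calls follow threshold, intersection and bias rules", {
  genes <- sprintf("g%02d", 1:40)
  set.seed(3)
  ctrl <- matrix(rexp(120, 1), 40, 3, dimnames = list(genes, NULL))
  treat <- ctrl + 0
  # promoter g01 strongly bound in all reps; g02 in 2/3 only
  big <- max(ctrl) + 10
  treat["g01", ] <- big
  treat["g02", c(1, 2)] <- big
  # g03 high everywhere including all controls: bias
  treat["g03", ] <- big
  ctrl2 <- ctrl
  ctrl2["g03", ] <- big
  calls <- call_bound_promoters(treat, ctrl2, fdr = 0.025)
  expect_true(calls$bound[calls$gene_id == "g01"])
  expect_false(calls$bound[calls$gene_id == "g02"])  # intersection rule
  expect_false(calls$bound[calls$gene_id == "g03"])
  expect_true(calls$bias_flag[calls$gene_id == "g03"])
  expect_true(all(calls$bound[calls$bias_flag] == FALSE))

  # lowering fdr never grows the bound set
  prev <- rep(TRUE, 40)
  for (f in c(0.2, 0.1, 0.05, 0.01)) {
    cur <- call_bound_promoters(treat, ctrl2, fdr = f)$bound
    expect_true(all(cur <= prev))
    prev <- cur
  }

  # all-zero controls: threshold is the smallest positive treatment signal
  z <- matrix(0, 40, 2, dimnames = list(genes, NULL))
  expect_warning(cz <- call_bound_promoters(treat, z, fdr = 0.005),
                 "identically zero")
  expect_equal(attr(cz, "threshold"), min(treat[treat > 0]))
})

test_that("find_top_peak matches the all-window oracle and tie-breaks left", {
  lens <- c(chr1 = 10000L)
  prom <- data.frame(gene_id = "P", chrom = "chr1",
                     start = 2000L, end = 3000L)
  # a single rectangular pile-up: center at its midpoint
  rect <- make_reads(rep(2400L, 5), "+")  # covers [2400, 2450)
  tr <- normalize_coverage(rect, lens)
  pk <- find_top_peak(tr, prom)
  # every width-145 window containing the pile-up ties; leftmost wins, and
  # the winning window must cover the pile-up midpoint 2425
  expect_true(pk$start <= 2425 && 2425 < pk$end)
  expect_equal(pk$end - pk$start, 145L)
  expect_equal(pk$start, pk$center - 72L)

  # two pile-ups: the higher one wins
  two <- rbind(make_reads(rep(2200L, 5), "+"), make_reads(rep(2700L, 9), "+"))
  tr2 <- normalize_coverage(two, lens)
  pk2 <- find_top_peak(tr2, prom)
  expect_true(abs(pk2$center - 2725) <= 73)

  # oracle equality on random tracks, including ties (leftmost window)
  set.seed(7)
  for (rep in 1:5) {
    reads <- make_reads(sample(1900:3100, 40, TRUE), "+", len = 30L)
    trr <- normalize_coverage(reads, lens)
    pkr <- find_top_peak(trr, prom)
    x <- as.numeric(S4Vectors::window(trr$fwd$chr1 + trr$rev$chr1, 2001, 3000))
    ora <- oracle_top_window(x, 145L)
    expect_equal(pkr$center, 2000L + ora$start - 1L + 72L)
    expect_equal(pkr$height, ora$sum * trr$factor, tolerance = 1e-9)
  }

  # all-zero promoter: no peak
  empty <- data.frame(gene_id = "E", chrom = "chr1",
                      start = 8000L, end = 9000L)
  expect_equal(nrow(find_top_peak(tr, empty)), 0)
})

test_that("top-signal selection ranks bound promoters and keeps the top half", {
  calls <- data.frame(gene_id = sprintf("g%03d", 1:850),
                      bound = TRUE, bias_flag = FALSE,
                      mean_signal = rev(seq_len(850)))
  expect_equal(length(select_top_signal(calls, 0.5)), 425)
  small <- calls[1:4, ]
  small$mean_signal <- c(1, 2, 3, 4)
  expect_setequal(select_top_signal(small, 0.5), c("g003", "g004"))
  expect_setequal(select_top_signal(small, 1), small$gene_id)
  none <- calls[0, ]
  expect_equal(select_top_signal(none), character(0))
})
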