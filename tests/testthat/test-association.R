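test_that("hypergeometric upper tail matches enumeration for all small cases", {
  expect_equal(hypergeom_upper(10, 5, 5, 5), 1 / 252, tolerance = 1e-12)
  expect_equal(hypergeom_upper(100, 2, 2, 2), 1 / 4950, tolerance = 1e-12)
  expect_equal(hypergeom_upper(50, 10, 8, 0), 1)
  expect_error(hypergeom_upper(10, 11, 5, 2), "exceeds")
  expect_error(hypergeom_upper(10, 5, 5, 6), "exceeds")

  for (N in 1:12) for (K in 0:N) for (n in 0:N) {
    ks <- max(0, n + K - N):min(n, K)
    got <- hypergeom_upper(N, K, n, ks)
    want <- vapply(ks, function(k) oracle_hypergeom_upper(N, K, n, k), 0)
    expect_equal(got, want, tolerance = 1e-12)
    # monotone decreasing in k
    expect_true(all(diff(got) <= 1e-15))
  }
})

test_that("log-space evaluation stays finite in extreme tails", {
  lp <- hypergeom_upper(24707, 1081, 812, 500, log10_p = TRUE)
  expect_true(is.finite(lp))
  expect_lt(lp, -300)
  # log10 and linear scales agree where both are representable
  expect_equal(hypergeom_upper(1000, 100, 100, 30, log10_p = TRUE),
               log10(hypergeom_upper(1000, 100, 100, 30)),
               tolerance = 1e-9)
})

test_that("fraction_bound reproduces the published contingency fractions", {
  expect_equal(fraction_bound(726, 11165), 0.065)
  expect_equal(fraction_bound(78, 324), 0.241)
  expect_equal(fraction_bound(71, 332), 0.214)
  expect_equal(fraction_bound(83, 284, digits = 2), 0.29)
  expect_equal(fraction_bound(146, 1373, digits = 2), 0.11)
  expect_equal(fraction_bound(103, 287, digits = 2), 0.36)
  expect_error(fraction_bound(5, 0), "positive")
  expect_error(fraction_bound(5, 4), "exceed")
})

test_that("isolated region classification follows the 2-kb exclusion rules", {
  promoters <- data.frame(gene_id = "P", chrom = "chr1",
                          start = 30000L, end = 31000L)
  sites <- data.frame(
    chrom = "chr1",
    center = c(1000L,                 # lone single (neighbour 5 kb away)
               6000L,                 # single
               10000L, 10500L,        # inverted dimer, isolated
               20000L, 20400L,        # direct dimer
               29500L,                # 1500 bases from promoter: excluded
               40000L, 40500L, 41200L # triplet: no class
               ),
    strand = c("+", "+", "+", "-", "-", "-", "+", "+", "-", "+"))
  peaks <- data.frame(chrom = "chr1", center = c(10300L))
  reg <- isolate_regions(sites, promoters, peaks)
  singles <- reg[reg$klass == "single", ]
  expect_setequal(singles$center, c(1000L, 6000L))
  inv <- reg[reg$klass == "inverted_dimer", ]
  expect_equal(nrow(inv), 1)
  expect_equal(inv$site1, 10000L)
  expect_true(inv$bound)
  dir <- reg[reg$klass == "direct_dimer", ]
  expect_equal(dir$center, 20200L)
  expect_false(dir$bound)
  expect_false(29500L %in% reg$center)          # promoter proximity
  expect_false(any(c(40000L, 40500L, 41200L) %in% c(reg$site1, reg$site2)))
})

test_that("region classification matches the O(n^2) oracle on random sites", {
  set.seed(21)
  for (rep in 1:4) {
    sites <- data.frame(
      chrom = sample(c("c1", "c2"), 120, TRUE),
      center = sample.int(150000L, 120),
      strand = sample(c("+", "-"), 120, TRUE))
    promoters <- data.frame(gene_id = sprintf("p%d", 1:6),
                            chrom = sample(c("c1", "c2"), 6, TRUE),
                            start = sample.int(140000L, 6))
    promoters$end <- promoters$start + 1000L
    got <- isolate_regions(sites, promoters, peaks = data.frame(
      chrom = character(), center = integer()))
    want <- oracle_isolate(sites, promoters)
    expect_setequal(got$center[got$klass == "single"], want$singles)
    dimers_got <- got[got$klass != "single", ]
    expect_equal(nrow(dimers_got), NROW(want$dimers))
    if (NROW(want$dimers)) {
      key_w <- sort(paste(pmin(sites$center[want$dimers$i],
                               sites$center[want$dimers$j]),
                          want$dimers$klass))
      key_g <- sort(paste(pmin(dimers_got$site1, dimers_got$site2),
                          dimers_got$klass))
      expect_equal(key_g, key_w)
    }
  }
})

test_that("bidirectional overlap reports region-level counts and fractions", {
  # region universe shaped like the published study: 24707 genes, 1081
  # divergent pairs, 812 bound regions of which 177 are bidirectional
  n_genes <- 24707L
  n_pairs <- 1081L
  gene_ids <- sprintf("g%05d", seq_len(n_genes))
  pairs <- data.frame(minus_gene = gene_ids[seq_len(n_pairs) * 2 - 1],
                      plus_gene = gene_ids[seq_len(n_pairs) * 2],
                      chrom = "c1", tss_distance = 100L,
                      kind = "bidirectional")
  promoters <- data.frame(gene_id = gene_ids, chrom = "c1",
                          start = 0L, end = 1000L)
  bound <- c(pairs$minus_gene[1:177], gene_ids[10000 + 1:635])
  ov <- bidirectional_overlap(bound, pairs, promoters)
  expect_equal(ov$N, n_genes - n_pairs)
  expect_equal(ov$K, n_pairs)
  expect_equal(ov$n, 812)
  expect_equal(ov$k, 177)
  expect_equal(round(100 * ov$frac_of_bound), 22)
  expect_equal(round(100 * ov$frac_of_class), 16)
  # order of magnitude of the association p-value (universe-dependent)
  expect_lt(ov$log10_p, -55)
  expect_gt(ov$log10_p, -90)

  # counting pair members separately doubles K and k
  ov2 <- bidirectional_overlap(bound, pairs, promoters,
                               count_pairs_once = FALSE)
  expect_equal(ov2$K, 2 * n_pairs)
  expect_equal(ov2$k, 177)
  expect_equal(ov2$n, 812)

  # zero overlap with tiny classes: p = 1 within rounding
  ov3 <- bidirectional_overlap(gene_ids[5000:5002], pairs[1:2, ], promoters)
  expect_equal(ov3$k, 0)
  expect_equal(ov3$p_value, 1, tolerance = 1e-3)
})

test_that("region class table mirrors the contingency layout", {
  regions <- data.frame(chrom = "c1",
                        klass = rep(c("single", "inverted_dimer"), c(8, 4)),
                        center = 1:12, site1 = 1:12, site2 = NA,
                        bound = rep(c(TRUE, FALSE, TRUE), c(2, 6, 4)))
  tab <- region_class_table(regions, N = 1000, n = 50)
  expect_setequal(tab$klass, c("single", "inverted_dimer"))
  expect_equal(tab$fraction_bound[tab$klass == "single"],
               fraction_bound(2, 8))
  expect_equal(tab$fraction_bound[tab$klass == "inverted_dimer"], 1)
})
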