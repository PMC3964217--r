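test_that("pair geometry follows the sign and orientation conventions", {
  # left + / right -: pointing together, face-to-face, negative distance
  g <- pair_geometry(list(offset = 100L, strand = "+"),
                     list(offset = 300L, strand = "-"))
  expect_equal(g$signed_distance, -200)
  expect_equal(g$orientation, "face_to_face")
  # left - / right +: back-to-back, positive
  g2 <- pair_geometry(list(offset = 100L, strand = "-"),
                      list(offset = 300L, strand = "+"))
  expect_equal(g2$signed_distance, 200)
  expect_equal(g2$orientation, "back_to_back")
  # argument order does not matter
  g3 <- pair_geometry(list(offset = 300L, strand = "-"),
                      list(offset = 100L, strand = "+"))
  expect_equal(g3$signed_distance, -200)
  # coincident centers tie-break as face-to-face at 0
  g4 <- pair_geometry(list(offset = 100L, strand = "-"),
                      list(offset = 100L, strand = "+"))
  expect_equal(g4$signed_distance, 0)
  expect_equal(g4$orientation, "face_to_face")
  # same strand: direct, no signed distance
  g5 <- pair_geometry(list(offset = 100L, strand = "+"),
                      list(offset = 300L, strand = "+"))
  expect_equal(g5$orientation, "direct")
  expect_true(is.na(g5$signed_distance))
  # phase accompanies the distance
  expect_equal(g$phase, helical_phase(200))
})

test_that("only promoters with exactly two inverted motifs yield pairs", {
  hits <- data.frame(
    region_id = c("a", "a", "b", "b", "b", "c", "c", "d"),
    offset = c(100L, 300L, 10L, 50L, 90L, 20L, 400L, 7L),
    strand = c("+", "-", "+", "-", "+", "-", "-", "+"))
  pairs <- select_two_motif_promoters(hits)
  expect_equal(pairs$promoter_id, "a")     # b has 3 hits, c same-strand, d 1
  expect_equal(pairs$signed_distance, -200)
})

test_that("spacing density implements the 100-bp half-open window exactly", {
  one <- data.frame(promoter_id = "x", signed_distance = -200L)
  tr <- spacing_density(one)
  nz <- tr$position[tr$count > 0]
  expect_equal(range(nz), c(-249, -150))
  expect_equal(sum(tr$count), 100)
  expect_true(all(tr$count[tr$count > 0] == 1))
  # empty subset: all-zero track
  tr0 <- spacing_density(one, subset = character(0))
  expect_true(all(tr0$count == 0))
  expect_equal(nrow(tr0), 2001)
})

test_that("spacing density equals the brute-force oracle", {
  set.seed(41)
  for (rep in 1:3) {
    d <- sample(-1000:1000, 200, replace = TRUE)
    pairs <- data.frame(promoter_id = as.character(seq_along(d)),
                        signed_distance = d)
    got <- spacing_density(pairs)
    expect_equal(got$count, oracle_spacing_density(d))
  }
})

test_that("mirroring promoter sequences preserves pair geometry", {
  # reverse-complementing a promoter flips both hit strands and mirrors both
  # offsets, so an inverted pair keeps its orientation class and its signed
  # distance: the spacing analysis is strand-symmetric
  set.seed(42)
  cfg <- synth_config(n_genes = 120,
                      count_dist = c(0.2, 0, 0.8, rep(0, 11)),
                      inverted_fraction = 1)
  ann <- generate_annotation(cfg, 43)
  pl <- plant_motifs(cfg, ann, 44)
  mirrored <- Biostrings::reverseComplement(pl$promoter_seqs)
  hits_m <- scan_motifs(mirrored, cfg$pattern)
  pairs_m <- select_two_motif_promoters(hits_m)
  pm <- pairs_m$signed_distance[order(pairs_m$promoter_id)]
  po <- pl$pairs$signed_distance[order(pl$pairs$promoter_id)]
  expect_equal(pm, po)
  expect_equal(pairs_m$orientation[order(pairs_m$promoter_id)],
               pl$pairs$orientation[order(pl$pairs$promoter_id)])
})

test_that("helical phase maps distances onto (-180, 180]", {
  expect_equal(helical_phase(26), 180)
  expect_equal(helical_phase(104), 0)
  expect_equal(helical_phase(100), -138.4615, tolerance = 1e-4)
  expect_equal(helical_phase(-100), helical_phase(100))
  expect_equal(helical_phase(5.2), 180)
  phis <- helical_phase(0:2000)
  expect_true(all(phis > -180 & phis <= 180))
  # full turns are in phase
  expect_equal(helical_phase(10.4 * (1:20)), rep(0, 20))
})

test_that("resampled p-values are reproducible and calibrated at the mean", {
  set.seed(45)
  cfg <- synth_config()
  d <- sample_pair_distances(cfg, 3000)
  pairs <- data.frame(promoter_id = as.character(seq_along(d)),
                      signed_distance = d)
  obs <- spacing_density(pairs, subset = as.character(1:300))
  pv1 <- resample_pvalues(pairs, obs, sample_size = 300, runs = 200,
                          seed = 46)
  pv2 <- resample_pvalues(pairs, obs, sample_size = 300, runs = 200,
                          seed = 46)
  expect_identical(pv1, pv2)
  expect_equal(attr(pv1, "alpha_corrected"), 0.05 / 2001)
  expect_true(all(pv1$p_value > 0 & pv1$p_value <= 1))
  # where the observed count sits at the resampled mean, p is near 1/2
  at_mu <- which(abs(obs$count - pv1$mu) < 0.05 * pmax(pv1$sigma, 1e-9) &
                   pv1$sigma > 0)
  if (length(at_mu))
    expect_true(all(abs(pv1$p_value[at_mu] - 0.5) < 0.05))
  # the depletion tail is the complement of the enrichment tail
  pv_less <- resample_pvalues(pairs, obs, sample_size = 300, runs = 200,
                              seed = 46, alternative = "less")
  ok <- pv1$sigma > 0
  expect_equal(pv1$p_value[ok] + pv_less$p_value[ok], rep(1, sum(ok)),
               tolerance = 1e-9)
})

test_that("null p-values are near-uniform at probed positions", {
  set.seed(47)
  cfg <- synth_config()
  d <- sample_pair_distances(cfg, 8000)
  pairs <- data.frame(promoter_id = as.character(seq_along(d)),
                      signed_distance = d)
  probe <- seq(-900, 900, by = 200)
  pvals <- matrix(NA_real_, 60, length(probe))
  for (i in 1:60) {
    sub <- sample(pairs$promoter_id, 400)
    obs <- spacing_density(pairs, subset = sub)
    pv <- resample_pvalues(pairs, obs, sample_size = 400, runs = 150,
                           seed = 300 + i)
    pvals[i, ] <- pv$p_value[match(probe, pv$position)]
  }
  for (j in seq_along(probe)) {
    ks <- suppressWarnings(stats::ks.test(pvals[, j], "punif"))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("phase profile is flat for a neutral bound set and wraps at 180", {
  set.seed(48)
  d <- sample(7:990, 2000, replace = TRUE)
  pairs <- data.frame(promoter_id = as.character(seq_along(d)),
                      signed_distance = d, orientation = "back_to_back",
                      phase = helical_phase(d))
  pp <- phase_profile(pairs, bound_ids = pairs$promoter_id)
  expect_true(all(abs(pp$profile$relative_binding - 1) < 1e-9))
  expect_equal(mean(pp$profile$relative_binding), 1, tolerance = 1e-6)
  # window wrap: pairs at 175 and -175 share windows centred near 180
  pw <- data.frame(promoter_id = c("a", "b"), signed_distance = c(1, 2),
                   orientation = "back_to_back", phase = c(175, -175))
  ppw <- phase_profile(pw, bound_ids = "a")
  n180 <- ppw$profile$n_all[ppw$profile$phase == 180]
  expect_equal(n180, 2L)
})

test_that("a planted 90-degree phase preference is recovered", {
  cfg <- synth_config()
  set.seed(49)
  n <- 20000
  d <- sample_pair_distances(cfg, n)
  pairs <- data.frame(promoter_id = as.character(seq_len(n)),
                      signed_distance = d,
                      orientation = ifelse(d < 0, "face_to_face",
                                           "back_to_back"),
                      phase = helical_phase(d))
  fc <- synth_factor("ph", base_rate = 0.3, exponent = 0,
                     kernel_centers = NULL, phase_center = 90,
                     phase_amp = 0.8)
  counts <- stats::setNames(rep(2L, n), pairs$promoter_id)
  tb <- draw_bound(counts, pairs, fc, seed = 50)
  pp <- phase_profile(pairs, tb$gene_id[tb$bound])
  peak <- pp$profile$phase[which.max(pp$profile$fitted)]
  expect_lte(abs(peak - 90), 20)
})
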