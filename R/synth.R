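# Synthetic-data generator: annotation, motif-planted promoter sequences and
# simulated ChIP-Seq reads with known ground truth, so the full pipeline can
# be exercised and validated without external data.

#' Synthetic factor binding model
#'
#' Describes one transcription factor archetype. The probability that a
#' promoter with k motifs is bound is \code{min(1, base_rate * exp(exponent *
#' k))}; for promoters carrying exactly two inverted motifs this probability
#' is further multiplied by a spacing weight over the signed inter-motif
#' distance (Gaussian preference kernels on top of a small baseline, times a
#' suppression window centred at distance 0) and by a cosine helical-phase
#' weight. Bound promoters receive \code{enrichment}-fold extra read mass,
#' either independent of k (\code{signal_law = "constant"}) or growing as
#' k / 2 (\code{"proportional"}).
#'
#' @param name Factor label.
#' @param base_rate,exponent Parameters a, b of P(bound | k) = a e^(b k).
#' @param kernel_centers,kernel_sds,kernel_amps Gaussian spacing-preference
#'   components on the signed distance (bases); NULL for no preference.
#' @param kernel_base Baseline spacing weight outside the kernels.
#' @param depletion_d0,depletion_gamma Suppression window at distance 0: the
#'   weight is multiplied by |d|^gamma / (|d|^gamma + d0^gamma), a smooth dip
#'   reaching 0 at d = 0 and ~1 beyond d0. NA disables suppression.
#' @param phase_center,phase_amp Cosine phase preference: weight proportional
#'   to 1 + amp * cos(phase - center); amp 0 disables it.
#' @param signal_law "constant" or "proportional".
#' @param enrichment Fold read-mass enrichment of bound promoters.
#' @param n_replicates Treatment replicates.
#' @return A list of class \code{synth_factor}.
#' @export
synth_factor <- function(name, base_rate = 0.02, exponent = 0.8,
                         kernel_centers = NULL, kernel_sds = NULL,
                         kernel_amps = NULL, kernel_base = 0.05,
                         depletion_d0 = 120, depletion_gamma = 4,
                         phase_center = 90, phase_amp = 0,
                         signal_law = c("constant", "proportional"),
                         enrichment = 10, n_replicates = 3L) {
  signal_law <- match.arg(signal_law)
  stopifnot(base_rate >= 0, base_rate <= 1, enrichment > 0,
            phase_amp >= 0, phase_amp <= 1, n_replicates >= 1)
  structure(list(name = name, base_rate = base_rate, exponent = exponent,
                 kernel_centers = kernel_centers, kernel_sds = kernel_sds,
                 kernel_amps = kernel_amps, kernel_base = kernel_base,
                 depletion_d0 = depletion_d0,
                 depletion_gamma = depletion_gamma,
                 phase_center = phase_center, phase_amp = phase_amp,
                 signal_law = signal_law, enrichment = enrichment,
                 n_replicates = as.integer(n_replicates)),
            class = "synth_factor")
}

default_factors <- function() {
  list(
    # exponential probability, no signal growth, face-to-face -200 preference
    p53like = synth_factor("p53like", base_rate = 0.02, exponent = 0.8,
                           kernel_centers = c(-200, -100, 100),
                           kernel_sds = c(30, 30, 30),
                           kernel_amps = c(1, 0.5, 0.5),
                           phase_amp = 0.5, signal_law = "constant",
                           n_replicates = 3L),
    # similar, with -50/+200 spacing preference
    ets1like = synth_factor("ets1like", base_rate = 0.02, exponent = 0.7,
                            kernel_centers = c(-50, 200),
                            kernel_sds = c(30, 30),
                            kernel_amps = c(0.8, 1),
                            phase_amp = 0.4, signal_law = "constant",
                            n_replicates = 2L),
    # zero-centred preference, signal grows with motif count
    gabpalike = synth_factor("gabpalike", base_rate = 0.03, exponent = 0.45,
                             kernel_centers = c(0, -200),
                             kernel_sds = c(30, 30),
                             kernel_amps = c(1, 0.2),
                             depletion_d0 = NA, phase_amp = 0,
                             signal_law = "proportional",
                             n_replicates = 2L)
  )
}

#' Synthetic study configuration
#'
#' Defaults emulate the structure of the study system: ~4.5% of promoter
#' regions bidirectional, ETS 7-mer copy numbers 0-13 per 1-kb promoter with
#' a decaying distribution, inter-motif spacing sharply peaked near 0 with
#' shoulders out to +/-1000, and three factor archetypes (exponential
#' binding probability with flat signal and a face-to-face spacing
#' preference; the same with different kernels; and a zero-centred
#' preference with proportional signal).
#'
#' @param n_genes Number of genes.
#' @param bidirectional_fraction Bidirectional regions as a fraction of
#'   promoter regions (pairs counted once).
#' @param face_to_face_fraction Fraction of genes placed in convergent pairs.
#' @param promoter_len Promoter width (bases).
#' @param pattern Motif planted and scanned (IUPAC).
#' @param count_dist Probabilities of motif copy numbers 0..13.
#' @param spacing Pair-spacing mixture: \code{peak_weight} mass in the sharp
#'   near-zero component (SD \code{peak_sd}, magnitudes in
#'   \code{[min_abs, 49]}), the rest uniform shoulders to \code{max_abs};
#'   \code{f2f_fraction} of pairs face-to-face (negative distances).
#' @param inverted_fraction Of two-motif promoters, the fraction with the
#'   motifs on opposite strands.
#' @param factors List of [synth_factor()] models.
#' @param background_density Background read density (reads per base per
#'   replicate).
#' @param read_length,strand_shift Read length and expected forward/reverse
#'   coverage offset (bases).
#' @param peak_sd SD of simulated fragment centers around the binding
#'   position.
#' @param n_control_replicates Negative-control replicates.
#' @param genome_length Optional explicit genome length; an error is raised
#'   if the gene layout does not fit.
#' @return A list of class \code{synth_config}.
#' @export
synth_config <- function(n_genes = 1000L,
                         bidirectional_fraction = 0.045,
                         face_to_face_fraction = 0.02,
                         promoter_len = 1000L,
                         pattern = "CCGGAAG",
                         count_dist = c(0.40, 0.25, 0.18, 0.08, 0.04, 0.02,
                                        0.012, 0.006, 0.004, 0.003, 0.002,
                                        0.0015, 0.001, 0.0005),
                         spacing = list(peak_weight = 0.6, peak_sd = 25,
                                        min_abs = 7, max_abs = 990,
                                        f2f_fraction = 0.5),
                         inverted_fraction = 0.75,
                         factors = default_factors(),
                         background_density = 0.02,
                         read_length = 50L,
                         strand_shift = 120L,
                         peak_sd = 35,
                         n_control_replicates = 3L,
                         genome_length = NULL) {
  stopifnot(n_genes >= 2, bidirectional_fraction >= 0,
            bidirectional_fraction < 1, promoter_len >= 100,
            abs(sum(count_dist) - 1) < 1e-6, all(count_dist >= 0),
            spacing$peak_weight >= 0, spacing$peak_weight <= 1,
            inverted_fraction >= 0, inverted_fraction <= 1,
            background_density > 0)
  structure(list(n_genes = as.integer(n_genes),
                 bidirectional_fraction = bidirectional_fraction,
                 face_to_face_fraction = face_to_face_fraction,
                 promoter_len = as.integer(promoter_len),
                 pattern = toupper(pattern), count_dist = count_dist,
                 spacing = spacing, inverted_fraction = inverted_fraction,
                 factors = factors,
                 background_density = background_density,
                 read_length = as.integer(read_length),
                 strand_shift = as.integer(strand_shift),
                 peak_sd = peak_sd,
                 n_control_replicates = as.integer(n_control_replicates),
                 genome_length = genome_length),
            class = "synth_config")
}

#' Generate a synthetic gene annotation and background genome
#'
#' Genes are laid out in 4-kb units on one chromosome: divergent
#' (bidirectional) pair units with TSS distance drawn from 2..1000,
#' convergent (face-to-face) pair units with TSS distance 0..1000, and
#' isolated single-gene units, in shuffled order, so promoters never collide
#' except within intended pairs. The genome is random A/C/G/T background
#' (promoters are rewritten by [plant_motifs()]).
#'
#' @param cfg A [synth_config()].
#' @param seed Integer seed; the output is deterministic given cfg and seed.
#' @return List: \code{genes} (gene records), \code{chrom_lengths},
#'   \code{genome} (DNAStringSet), \code{truth_pairs} (planted pair table
#'   with kinds).
#' @export
generate_annotation <- function(cfg, seed) {
  stopifnot(inherits(cfg, "synth_config"))
  with_seed(seed, {
    n <- cfg$n_genes
    f <- cfg$bidirectional_fraction
    n_bd <- round(f * n / (1 + f))
    n_ff <- round(cfg$face_to_face_fraction * n / 2)
    n_single <- n - 2L * n_bd - 2L * n_ff
    if (n_single < 0) stopf("pair fractions exceed the gene count")
    unit <- 4000L
    units <- sample(c(rep("bd", n_bd), rep("ff", n_ff),
                      rep("s", n_single)))
    glen <- 2000L + length(units) * unit + 2000L
    if (!is.null(cfg$genome_length)) {
      if (cfg$genome_length < glen)
        stopf("genome too small for %d genes (need %d bases)", n, glen)
      glen <- as.integer(cfg$genome_length)
    }
    gid <- 0L
    next_id <- function() {
      gid <<- gid + 1L
      sprintf("G%05d", gid)
    }
    rows <- vector("list", length(units))
    tp <- vector("list", length(units))
    for (u in seq_along(units)) {
      a <- 2000L + (u - 1L) * unit + 1200L
      if (units[u] == "bd") {
        d <- sample(2:1000, 1L)
        ids <- c(next_id(), next_id())
        rows[[u]] <- data.frame(gene_id = ids, chrom = "chr1",
                                strand = c("-", "+"),
                                tss = c(a, a + d),
                                stringsAsFactors = FALSE)
        tp[[u]] <- data.frame(minus_gene = ids[1], plus_gene = ids[2],
                              tss_distance = d, kind = "bidirectional",
                              stringsAsFactors = FALSE)
      } else if (units[u] == "ff") {
        d <- sample(0:1000, 1L)
        ids <- c(next_id(), next_id())
        rows[[u]] <- data.frame(gene_id = ids, chrom = "chr1",
                                strand = c("+", "-"),
                                tss = c(a, a + d),
                                stringsAsFactors = FALSE)
        tp[[u]] <- data.frame(minus_gene = ids[2], plus_gene = ids[1],
                              tss_distance = d, kind = "face_to_face",
                              stringsAsFactors = FALSE)
      } else {
        rows[[u]] <- data.frame(gene_id = next_id(), chrom = "chr1",
                                strand = sample(c("+", "-"), 1L),
                                tss = a, stringsAsFactors = FALSE)
      }
    }
    genes <- do.call(rbind, rows)
    rownames(genes) <- NULL
    truth_pairs <- do.call(rbind, tp[!vapply(tp, is.null, TRUE)])
    genome <- Biostrings::DNAStringSet(paste0(
      sample(c("A", "C", "G", "T"), glen, replace = TRUE), collapse = ""))
    names(genome) <- "chr1"
    list(genes = genes, chrom_lengths = c(chr1 = glen), genome = genome,
         truth_pairs = truth_pairs %||%
           data.frame(minus_gene = character(), plus_gene = character(),
                      tss_distance = integer(), kind = character()))
  })
}

# One concrete instance of an IUPAC pattern.
iupac_instance <- function(pattern) {
  codes <- Biostrings::IUPAC_CODE_MAP
  paste0(vapply(strsplit(pattern, "")[[1]], function(ch) {
    opts <- strsplit(codes[[ch]], "")[[1]]
    opts[sample.int(length(opts), 1L)]
  }, character(1)), collapse = "")
}

#' Draw signed pair distances from the spacing mixture
#'
#' With probability \code{peak_weight} the magnitude comes from the sharp
#' near-zero component (half-normal, SD \code{peak_sd}, truncated to
#' \code{[min_abs, 49]}); otherwise it is uniform on \code{[50, max_abs]}.
#' The sign is negative (face-to-face) with probability
#' \code{f2f_fraction}.
#'
#' @param cfg A [synth_config()] (its \code{spacing} element is used).
#' @param n Number of distances.
#' @param seed Optional seed.
#' @return Integer vector of signed distances.
#' @export
sample_pair_distances <- function(cfg, n, seed = NULL) {
  sp <- cfg$spacing
  with_seed(seed, {
    peak <- stats::runif(n) < sp$peak_weight
    mag <- integer(n)
    np <- sum(peak)
    if (np) {
      m <- integer(0)
      while (length(m) < np) {
        cand <- round(abs(stats::rnorm(2L * np, 0, sp$peak_sd)))
        m <- c(m, cand[cand >= sp$min_abs & cand <= 49])
      }
      mag[peak] <- m[seq_len(np)]
    }
    if (any(!peak))
      mag[!peak] <- sample(50:sp$max_abs, sum(!peak), replace = TRUE)
    sgn <- ifelse(stats::runif(n) < sp$f2f_fraction, -1L, 1L)
    as.integer(sgn * mag)
  })
}

#' Spacing weight of a factor model
#'
#' The multiplicative binding-preference weight over signed inter-motif
#' distance: Gaussian kernels on a baseline, times the suppression window at
#' 0, clipped to \code{[0, 1]}.
#'
#' @param d Signed distances (vectorized).
#' @param factor_cfg A [synth_factor()].
#' @return Numeric weights in \code{[0, 1]}.
#' @export
spacing_weight <- function(d, factor_cfg) {
  fc <- factor_cfg
  if (is.null(fc$kernel_centers)) return(rep(1, length(d)))
  w <- rep(fc$kernel_base, length(d))
  for (j in seq_along(fc$kernel_centers))
    w <- w + fc$kernel_amps[j] *
      exp(-(d - fc$kernel_centers[j])^2 / (2 * fc$kernel_sds[j]^2))
  if (!is.na(fc$depletion_d0)) {
    g <- fc$depletion_gamma
    ad <- abs(d)
    w <- w * ad^g / (ad^g + fc$depletion_d0^g)
  }
  pmin(pmax(w, 0), 1)
}

#' Helical-phase weight of a factor model
#' @param phi Phases in degrees (vectorized).
#' @param factor_cfg A [synth_factor()].
#' @return Weights in \code{[0, 1]}: \code{(1 + amp cos(phi - center)) /
#'   (1 + amp)}.
#' @export
phase_weight <- function(phi, factor_cfg) {
  amp <- factor_cfg$phase_amp
  if (amp == 0) return(rep(1, length(phi)))
  (1 + amp * cos((phi - factor_cfg$phase_center) * pi / 180)) / (1 + amp)
}

#' Bound-promoter probabilities and draws under a factor model
#'
#' P(bound) = min(1, a e^(b k)), multiplied for inverted two-motif promoters
#' by the spacing and phase weights of the model.
#'
#' @param counts Named per-promoter motif counts.
#' @param pairs Pair table ([select_two_motif_promoters()] layout) for the
#'   inverted two-motif promoters; may have zero rows.
#' @param factor_cfg A [synth_factor()].
#' @param seed Optional seed for the Bernoulli draw.
#' @return data.frame: \code{gene_id}, \code{k}, \code{p_bound},
#'   \code{bound}.
#' @export
draw_bound <- function(counts, pairs, factor_cfg, seed = NULL) {
  p <- pmin(1, factor_cfg$base_rate * exp(factor_cfg$exponent * counts))
  if (nrow(pairs)) {
    m <- match(pairs$promoter_id, names(counts))
    ok <- !is.na(m)
    w <- spacing_weight(pairs$signed_distance[ok], factor_cfg) *
      phase_weight(pairs$phase[ok], factor_cfg)
    p[m[ok]] <- p[m[ok]] * w
  }
  bound <- with_seed(seed, stats::runif(length(p)) < p)
  data.frame(gene_id = names(counts), k = as.integer(counts),
             p_bound = unname(p), bound = unname(bound),
             stringsAsFactors = FALSE)
}

#' Plant motifs into promoter sequences
#'
#' Draws a motif copy number for every promoter from the configured count
#' distribution; promoters assigned exactly two motifs become inverted pairs
#' (with the configured probability) whose signed distance follows the
#' spacing mixture. Background promoter sequence is rejection-sampled free of
#' the pattern on both strands, motifs are written in, and each promoter is
#' re-scanned so the emitted ground truth is exactly what [scan_motifs()]
#' recovers. The planted promoter sequences are spliced into the genome.
#'
#' @param cfg A [synth_config()].
#' @param annotation Output of [generate_annotation()].
#' @param seed Integer seed.
#' @return List: \code{genome} (with promoters planted),
#'   \code{promoter_seqs} (DNAStringSet named by gene id, genomic
#'   orientation), \code{promoters} (region table), \code{hits} (ground-truth
#'   hit table), \code{counts} (named vector), \code{pairs} (ground-truth
#'   inverted pair table with signed distance, orientation, phase).
#' @export
plant_motifs <- function(cfg, annotation, seed) {
  stopifnot(inherits(cfg, "synth_config"))
  plen <- cfg$promoter_len
  pattern <- cfg$pattern
  wid <- nchar(pattern)
  half <- wid %/% 2L
  if (wid > plen) stopf("pattern longer than the promoter")
  promoters <- derive_promoters(annotation$genes, width = plen)
  n <- nrow(promoters)
  with_seed(seed, {
    ks <- sample(0:13, n, replace = TRUE, prob = cfg$count_dist)
    inverted <- ks == 2L & stats::runif(n) < cfg$inverted_fraction
    d_signed <- rep(NA_integer_, n)
    d_signed[inverted] <- sample_pair_distances(cfg, sum(inverted))
    # cap magnitudes to what fits in the promoter
    dmax <- plen - wid - half - 3L
    d_signed[inverted] <- pmin(pmax(d_signed[inverted], -dmax), dmax)

    # Propose a candidate sequence + placements without verifying; accidental
    # background or junction matches are caught by a bulk re-scan below.
    propose_one <- function(k, inv, d) {
      s <- paste0(sample(c("A", "C", "G", "T"), plen, replace = TRUE),
                  collapse = "")
      if (k == 0L)
        return(list(seq = s, offset = integer(0), strand = character(0)))
      if (inv) {
        mag <- abs(d)
        cl <- sample(half:(plen - wid + half - mag), 1L) + 1L  # 1-based
        centers <- c(cl, cl + mag)
        strands <- if (d < 0) c("+", "-") else c("-", "+")
      } else {
        repeat {
          cand <- sort(sample((half + 1L):(plen - wid + half + 1L), k))
          if (k == 1L || min(diff(cand)) >= wid) break
        }
        centers <- cand
        strands <- sample(c("+", "-"), k, replace = TRUE)
      }
      for (j in seq_along(centers)) {
        inst <- iupac_instance(pattern)
        if (strands[j] == "-") inst <- revcomp_chr(inst)
        substr(s, centers[j] - half, centers[j] - half + wid - 1L) <- inst
      }
      list(seq = s, offset = centers - half - 1L, strand = strands)
    }

    planted <- lapply(seq_len(n), function(i)
      propose_one(ks[i], inverted[i], d_signed[i]))
    # bulk verification: the scan must recover exactly the intended hits
    sig <- function(off, str) paste(off, str, sep = ":", collapse = ";")
    want <- vapply(planted, function(p)
      sig(p$offset, p$strand), character(1))
    for (round in 1:50) {
      ss <- Biostrings::DNAStringSet(vapply(planted, `[[`, "", "seq"))
      names(ss) <- as.character(seq_len(n))
      found <- scan_motifs(ss, pattern)
      got <- rep("", n)
      if (nrow(found)) {
        spl <- split(found, as.integer(found$region_id))
        got[as.integer(names(spl))] <- vapply(spl, function(h)
          sig(h$offset, h$strand), character(1))
      }
      bad <- which(got != want)
      if (!length(bad)) break
      if (round == 50L)
        stopf("failed to plant motifs in a clean background")
      for (i in bad) {
        planted[[i]] <- propose_one(ks[i], inverted[i], d_signed[i])
        want[i] <- sig(planted[[i]]$offset, planted[[i]]$strand)
      }
    }

    seqs <- Biostrings::DNAStringSet(vapply(planted, `[[`, "", "seq"))
    names(seqs) <- promoters$gene_id
    hit_n <- lengths(lapply(planted, `[[`, "offset"))
    hits <- data.frame(
      region_id = rep(promoters$gene_id, hit_n),
      offset = unlist(lapply(planted, `[[`, "offset")),
      strand = unlist(lapply(planted, `[[`, "strand")),
      stringsAsFactors = FALSE)
    hits <- hits[order(hits$region_id, hits$offset), , drop = FALSE]
    rownames(hits) <- NULL
    attr(hits, "motif_width") <- wid
    counts <- stats::setNames(as.integer(ks), promoters$gene_id)
    pairs <- select_two_motif_promoters(hits, motif_width = wid)
    # Splice planted promoters into the genome. Bidirectional pair promoters
    # overlap genomically; there the later promoter's sequence wins. The
    # genomic sequence only carries reads/coordinates -- promoter_seqs is the
    # authority for motif analysis.
    g <- annotation$genome[[1]]
    glen <- length(g)
    ord <- order(promoters$start)
    pieces <- vector("list", 2L * n + 1L)
    np <- 0L
    pos <- 0L  # bases [0, pos) already emitted
    for (i in ord) {
      st <- promoters$start[i]; en <- promoters$end[i]
      if (st > pos) {
        np <- np + 1L
        pieces[[np]] <- as.character(Biostrings::subseq(g, pos + 1L, st))
      }
      skip <- max(0L, pos - st)
      if (skip < en - st) {
        np <- np + 1L
        pieces[[np]] <- substr(planted[[i]]$seq, skip + 1L, en - st)
      }
      pos <- max(pos, en)
    }
    if (pos < glen) {
      np <- np + 1L
      pieces[[np]] <- as.character(Biostrings::subseq(g, pos + 1L, glen))
    }
    genome <- Biostrings::DNAStringSet(
      paste0(unlist(pieces[seq_len(np)]), collapse = ""))
    names(genome) <- names(annotation$genome)
    list(genome = genome, promoter_seqs = seqs, promoters = promoters,
         hits = hits, counts = counts, pairs = pairs)
  })
}

# Place reads for fragment centers: plus-strand reads upstream, minus-strand
# downstream, so forward/reverse coverage profiles sit strand_shift apart.
reads_from_centers <- function(centers, read_length, strand_shift,
                               chrom, chrom_len) {
  n <- length(centers)
  if (!n) return(data.frame(chrom = character(), start = integer(),
                            end = integer(), strand = character(),
                            stringsAsFactors = FALSE))
  strand <- sample(c("+", "-"), n, replace = TRUE)
  off <- (strand_shift + read_length) %/% 2L
  start <- ifelse(strand == "+", centers - off, centers + off - read_length)
  start <- pmax(pmin(start, chrom_len - read_length), 0L)
  data.frame(chrom = chrom, start = as.integer(start),
             end = as.integer(start + read_length), strand = strand,
             stringsAsFactors = FALSE)
}

#' Simulate ChIP-Seq reads for the configured factors
#'
#' For every factor: promoters are drawn bound according to the factor model
#' ([draw_bound()]); each treatment replicate receives Poisson background
#' reads uniformly over the genome plus Poisson extra reads at bound
#' promoters, with fragment centers normally scattered around the binding
#' position (the motif-region midpoint) and strand-split placement producing
#' the configured forward/reverse offset. Bound read mass is
#' \code{enrichment x background} for a constant signal law and
#' \code{enrichment x background x k / 2} for a proportional one. Control
#' replicates are background-only.
#'
#' @param cfg A [synth_config()].
#' @param annotation Output of [generate_annotation()].
#' @param planted Output of [plant_motifs()].
#' @param seed Integer seed.
#' @return List per factor: \code{treatment} (list of read data.frames),
#'   \code{controls}, \code{truth} (gene_id, k, p_bound, bound).
#' @export
simulate_chip_reads <- function(cfg, annotation, planted, seed) {
  stopifnot(inherits(cfg, "synth_config"))
  glen <- annotation$chrom_lengths[[1]]
  chrom <- names(annotation$chrom_lengths)[1]
  promoters <- planted$promoters
  counts <- planted$counts
  L <- cfg$read_length
  shift <- cfg$strand_shift
  # binding position per promoter: midpoint of motif centers, else middle
  wid <- nchar(cfg$pattern)
  half <- wid %/% 2L
  bind_pos <- promoters$start + cfg$promoter_len %/% 2L
  if (nrow(planted$hits)) {
    ctr <- tapply(planted$hits$offset + half, planted$hits$region_id,
                  function(x) as.integer(round(mean(x))))
    m <- match(names(ctr), promoters$gene_id)
    bind_pos[m] <- promoters$start[m] + as.integer(ctr)
  }
  # keep the read cloud inside the scored window so measured signal does not
  # depend on where in the promoter the motifs happen to sit
  margin <- min(4L * round(cfg$peak_sd) + cfg$read_length %/% 2L,
                cfg$promoter_len %/% 2L)
  bind_pos <- pmin(pmax(bind_pos, promoters$start + margin),
                   promoters$end - margin)
  bg_mass <- cfg$background_density * cfg$promoter_len  # reads per promoter
  with_seed(seed, {
    out <- lapply(cfg$factors, function(fc) {
      truth <- draw_bound(counts, planted$pairs, fc)
      mult <- if (fc$signal_law == "proportional")
        pmax(truth$k, 1) / 2 else rep(1, nrow(truth))
      lambda_extra <- fc$enrichment * bg_mass * mult
      treatment <- lapply(seq_len(fc$n_replicates), function(r) {
        n_bg <- stats::rpois(1, cfg$background_density * glen)
        bg_centers <- sample.int(glen, n_bg, replace = TRUE)
        bi <- which(truth$bound)
        n_extra <- stats::rpois(length(bi), lambda_extra[bi])
        extra_centers <- round(stats::rnorm(sum(n_extra),
                                            rep(bind_pos[bi], n_extra),
                                            cfg$peak_sd))
        centers <- c(bg_centers, pmax(pmin(extra_centers, glen), 1))
        reads_from_centers(centers, L, shift, chrom, glen)
      })
      controls <- lapply(seq_len(cfg$n_control_replicates), function(r) {
        n_bg <- stats::rpois(1, cfg$background_density * glen)
        reads_from_centers(sample.int(glen, n_bg, replace = TRUE),
                           L, shift, chrom, glen)
      })
      list(treatment = treatment, controls = controls, truth = truth)
    })
    names(out) <- vapply(cfg$factors, `[[`, "", "name")
    out
  })
}
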