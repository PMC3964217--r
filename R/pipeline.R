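#' Run the full synthetic-to-analysis pipeline
#'
#' Orchestrates the stages in dependency order: \code{synth} (annotation,
#' planted promoter sequences, simulated reads), \code{annotation} (promoter
#' pair classification), \code{signal} (normalization, strand-offset
#' correction, promoter scoring, binding calls per factor), \code{motifs}
#' (motif scanning and per-promoter counts), and the three analyses
#' \code{association}, \code{multiplicity} and \code{geometry}. The stage
#' list must be prefix-closed with respect to this DAG; asking for a
#' downstream stage without its inputs is an error naming the missing stage.
#'
#' @param cfg A [synth_config()] describing the simulated study.
#' @param seed Integer master seed; stage seeds are derived from it, so a
#'   rerun with identical cfg and seed reproduces every artifact.
#' @param stages Stages to execute (default: all).
#' @param fdr Binding-call false discovery threshold (default 0.005).
#' @param kmax Largest motif copy number analysed (default 6).
#' @param peak_width Peak width for [find_top_peak()] (default 145).
#' @param resample_runs Resampling runs for positional p-values
#'   (default 2500).
#' @param phase_window,phase_step Helical-phase window and grid step in
#'   degrees.
#' @param pitch Helical pitch in bases per turn (default 10.4).
#' @param top_fraction Fraction of bound promoters kept in the high-signal
#'   subset (default 0.5).
#' @param outdir Optional output directory; when given, TSV/BED/FASTA
#'   artifacts and a manifest (with md5 checksums and the full parameter
#'   set) are written.
#' @return A list with one element per executed stage plus \code{manifest}
#'   (NULL when \code{outdir} is not given).
#' @export
run_pipeline <- function(cfg = synth_config(), seed = 1L,
                         stages = c("synth", "annotation", "signal",
                                    "motifs", "association", "multiplicity",
                                    "geometry"),
                         fdr = 0.005, kmax = 6L, peak_width = 145L,
                         resample_runs = 2500L, phase_window = 40,
                         phase_step = 10, pitch = 10.4, top_fraction = 0.5,
                         outdir = NULL) {
  all_stages <- c("synth", "annotation", "signal", "motifs", "association",
                  "multiplicity", "geometry")
  deps <- list(synth = character(0), annotation = "synth",
               signal = c("synth", "annotation"),
               motifs = "synth",
               association = c("annotation", "signal"),
               multiplicity = c("signal", "motifs"),
               geometry = c("signal", "motifs"))
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stopf("unknown stage(s): %s", paste(bad, collapse = ", "))
  for (s in stages) {
    miss <- setdiff(deps[[s]], stages)
    if (length(miss))
      stopf("stage '%s' requires stage '%s' to run first", s, miss[1])
  }
  stages <- all_stages[all_stages %in% stages]
  res <- list()
  artifacts <- list()
  save <- function(obj, name, writer) {
    if (is.null(outdir)) return(invisible(NULL))
    if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
    path <- file.path(outdir, name)
    writer(obj, path)
    artifacts[[name]] <<- path
  }

  if ("synth" %in% stages) {
    ann <- generate_annotation(cfg, seed)
    planted <- plant_motifs(cfg, ann, seed + 1L)
    reads <- simulate_chip_reads(cfg, ann, planted, seed + 2L)
    res$synth <- list(annotation = ann, planted = planted, reads = reads)
    save(ann$genes, "genes.tsv", write_tsv)
    save(planted$promoter_seqs, "promoters.fa", write_fasta)
    save(planted$hits, "truth_hits.tsv", write_tsv)
  }

  if ("annotation" %in% stages) {
    genes <- res$synth$annotation$genes
    promoters <- res$synth$planted$promoters
    pairs <- classify_promoter_pairs(genes)
    promoters <- apply_pair_classes(promoters, pairs)
    res$annotation <- list(genes = genes, promoters = promoters,
                           pairs = pairs)
    save(promoters, "promoters.bed", write_promoters_bed)
    save(pairs, "pairs.tsv", write_tsv)
  }

  if ("signal" %in% stages) {
    promoters <- res$annotation$promoters
    lens <- res$synth$annotation$chrom_lengths
    res$signal <- lapply(names(res$synth$reads), function(fn) {
      fr <- res$synth$reads[[fn]]
      tr1 <- normalize_coverage(fr$treatment[[1]], lens)
      offset <- estimate_strand_offset(tr1)
      tracks <- lapply(fr$treatment, function(r)
        normalize_coverage(shift_reads(r, offset), lens))
      ctracks <- lapply(fr$controls, function(r)
        normalize_coverage(shift_reads(r, offset), lens))
      treat <- signal_matrix(tracks, promoters)
      ctrl <- signal_matrix(ctracks, promoters)
      calls <- call_bound_promoters(treat, ctrl, fdr = fdr)
      peaks <- find_top_peak(tracks[[1]],
                             promoters[promoters$gene_id %in%
                                         calls$gene_id[calls$bound], ,
                                       drop = FALSE],
                             width = peak_width)
      list(factor = fn, offset = offset, treatment = treat, control = ctrl,
           calls = calls, peaks = peaks,
           top_ids = select_top_signal(calls, top_fraction))
    })
    names(res$signal) <- names(res$synth$reads)
    for (fn in names(res$signal))
      save(res$signal[[fn]]$calls, paste0("calls_", fn, ".tsv"), write_tsv)
  }

  if ("motifs" %in% stages) {
    seqs <- res$synth$planted$promoter_seqs
    hits <- scan_motifs(seqs, cfg$pattern)
    counts <- motif_counts(hits, names(seqs))
    res$motifs <- list(hits = hits, counts = counts)
    if (!is.null(res$signal)) {
      bound1 <- res$signal[[1]]$calls
      bound_ids <- bound1$gene_id[bound1$bound]
      if (length(bound_ids) >= 2)
        res$motifs$enrichment <- enrich_7mers(seqs[bound_ids], seqs)
    }
    save(data.frame(gene_id = names(counts), count = counts),
         "motif_counts.tsv", write_tsv)
    if (!is.null(res$motifs$enrichment))
      save(utils::head(res$motifs$enrichment, 100), "enrichment_top.tsv",
           write_tsv)
  }

  if ("association" %in% stages) {
    res$association <- lapply(res$signal, function(sg) {
      rbind(bidirectional_overlap(sg$calls, res$annotation$pairs,
                                  res$annotation$promoters,
                                  kind = "bidirectional"),
            bidirectional_overlap(sg$calls, res$annotation$pairs,
                                  res$annotation$promoters,
                                  kind = "face_to_face"))
    })
    for (fn in names(res$association))
      save(res$association[[fn]], paste0("association_", fn, ".tsv"),
           write_tsv)
  }

  if ("multiplicity" %in% stages) {
    counts <- res$motifs$counts
    res$multiplicity <- lapply(res$signal, function(sg) {
      pc <- probability_curve(sg$calls, counts, kmax = kmax)
      bound_ids <- sg$calls$gene_id[sg$calls$bound]
      out <- list(probability = pc,
                  fit_exp = tryCatch(fit_exponential(pc),
                                     error = function(e) NULL),
                  fit_lin = fit_linear(pc))
      if (length(bound_ids) >= 2) {
        sc <- signal_curve(sg$treatment[bound_ids, , drop = FALSE], counts,
                           kmax = kmax)
        out$signal <- sc
        out$signal_fit <- fit_linear(sc)
      }
      out
    })
    for (fn in names(res$multiplicity))
      save(res$multiplicity[[fn]]$probability,
           paste0("probability_curve_", fn, ".tsv"), write_tsv)
  }

  if ("geometry" %in% stages) {
    pairs <- select_two_motif_promoters(res$motifs$hits, pitch = pitch)
    all_density <- spacing_density(pairs)
    res$geometry <- list(pairs = pairs, all_density = all_density)
    res$geometry$factors <- lapply(res$signal, function(sg) {
      bound_ids <- sg$calls$gene_id[sg$calls$bound]
      bd <- spacing_density(pairs, subset = bound_ids)
      n_bound_pairs <- sum(pairs$promoter_id %in% bound_ids)
      pv <- if (n_bound_pairs > 0)
        resample_pvalues(pairs, bd, sample_size = n_bound_pairs,
                         runs = resample_runs, seed = seed + 3L)
      ph <- phase_profile(pairs, bound_ids, window = phase_window,
                          step = phase_step)
      list(bound_density = bd, pvalues = pv, phase = ph,
           top_density = spacing_density(pairs, subset = sg$top_ids))
    })
    save(all_density, "spacing_density_all.tsv", write_tsv)
    for (fn in names(res$geometry$factors)) {
      save(res$geometry$factors[[fn]]$bound_density,
           paste0("spacing_density_", fn, ".tsv"), write_tsv)
      if (!is.null(res$geometry$factors[[fn]]$pvalues))
        save(res$geometry$factors[[fn]]$pvalues,
             paste0("spacing_pvalues_", fn, ".tsv"), write_tsv)
    }
  }

  if (!is.null(outdir)) {
    paths <- unlist(artifacts)
    manifest <- data.frame(artifact = names(paths), path = unname(paths),
                           md5 = unname(tools::md5sum(unname(paths))),
                           stringsAsFactors = FALSE)
    params <- data.frame(
      key = c("seed", "fdr", "kmax", "peak_width", "resample_runs",
              "phase_window", "phase_step", "pitch", "top_fraction",
              "n_genes", "pattern", "promoter_len"),
      value = as.character(c(seed, fdr, kmax, peak_width, resample_runs,
                             phase_window, phase_step, pitch, top_fraction,
                             cfg$n_genes, cfg$pattern, cfg$promoter_len)),
      stringsAsFactors = FALSE)
    write_tsv(manifest, file.path(outdir, "manifest.tsv"))
    write_tsv(params, file.path(outdir, "parameters.tsv"))
    res$manifest <- manifest
  }
  res
}
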