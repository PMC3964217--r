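#' Helical phase between two sites
#'
#' Angular offset between two positions along the B-DNA helix: 360 degrees
#' per \code{pitch} bases, mapped to (-180, 180]. 0 means the two sites sit
#' on the same face of the helix.
#'
#' @param distance Distance in bases (vectorized; negative values are taken
#'   by absolute value).
#' @param pitch Helical pitch in bases per turn (default 10.4).
#' @return Phase in degrees in (-180, 180].
#' @examples
#' helical_phase(26)    # 180  (2.5 turns)
#' helical_phase(104)   # 0    (10 turns)
#' helical_phase(100)   # -138.46
#' @export
helical_phase <- function(distance, pitch = 10.4) {
  d <- abs(distance)
  phi <- (d / pitch - floor(d / pitch + 1e-9)) * 360
  phi[phi > 360 - 1e-6] <- 0
  ifelse(phi > 180 + 1e-9, phi - 360, phi)
}

# Vectorized core of the pair-orientation convention. Centers are motif
# midpoints; the left (smaller-center) hit's strand decides the class:
#   left +, right -  -> the motifs point toward each other: face_to_face,
#                       signed distance negative;
#   left -, right +  -> they point away: back_to_back, positive.
# Coincident centers are tie-broken as face_to_face at distance 0.
pair_geometry_core <- function(c1, s1, c2, s2, pitch = 10.4) {
  same <- s1 == s2
  left_s <- ifelse(c1 <= c2, s1, s2)
  mag <- abs(c2 - c1)
  f2f <- left_s == "+" | mag == 0  # coincident centers: face_to_face
  signed <- ifelse(f2f, -mag, mag)
  orientation <- ifelse(same, "direct",
                        ifelse(f2f, "face_to_face", "back_to_back"))
  signed[same] <- NA_integer_
  data.frame(signed_distance = signed, orientation = orientation,
             phase = ifelse(same, NA_real_, helical_phase(mag, pitch)),
             stringsAsFactors = FALSE)
}

#' Signed geometry of a motif pair
#'
#' Computes the signed inter-motif distance (center-to-center), the
#' orientation class and the helical phase for two motif hits within one
#' promoter. Negative distances are face-to-face (motifs pointing toward each
#' other), positive are back-to-back. Same-strand pairs are classified
#' \code{"direct"} and carry no signed distance; they are excluded from
#' inverted-pair analyses.
#'
#' @param hit_a,hit_b Single rows of a [scan_motifs()] hit table (or lists
#'   with \code{offset} and \code{strand}).
#' @param motif_width Motif length in bases (default 7); the center is
#'   \code{offset + motif_width %/% 2}.
#' @param pitch Helical pitch for the phase (default 10.4).
#' @return One-row data.frame: \code{signed_distance}, \code{orientation},
#'   \code{phase}.
#' @export
pair_geometry <- function(hit_a, hit_b, motif_width = 7L, pitch = 10.4) {
  half <- motif_width %/% 2L
  pair_geometry_core(hit_a$offset + half, hit_a$strand,
                     hit_b$offset + half, hit_b$strand, pitch)
}

#' Inverted pairs from promoters with exactly two motifs
#'
#' Keeps promoters carrying exactly two motif hits on opposite strands (the
#' inverted two-motif configuration) and emits one signed pair per promoter.
#'
#' @param hits Hit table from [scan_motifs()].
#' @param motif_width Motif length (default taken from the hit table
#'   attribute, else 7).
#' @param pitch Helical pitch (default 10.4).
#' @return data.frame: \code{promoter_id}, \code{signed_distance},
#'   \code{orientation}, \code{phase}.
#' @export
select_two_motif_promoters <- function(hits, motif_width = NULL,
                                       pitch = 10.4) {
  motif_width <- motif_width %||% attr(hits, "motif_width") %||% 7L
  half <- as.integer(motif_width) %/% 2L
  empty <- data.frame(promoter_id = character(),
                      signed_distance = integer(), orientation = character(),
                      phase = numeric(), stringsAsFactors = FALSE)
  if (!nrow(hits)) return(empty)
  cnt <- table(hits$region_id)
  two <- names(cnt)[cnt == 2L]
  if (!length(two)) return(empty)
  h <- hits[hits$region_id %in% two, , drop = FALSE]
  h <- h[order(h$region_id, h$offset), , drop = FALSE]
  i1 <- seq(1L, nrow(h), by = 2L)
  i2 <- i1 + 1L
  inv <- h$strand[i1] != h$strand[i2]
  if (!any(inv)) return(empty)
  g <- pair_geometry_core(h$offset[i1[inv]] + half, h$strand[i1[inv]],
                          h$offset[i2[inv]] + half, h$strand[i2[inv]], pitch)
  cbind(data.frame(promoter_id = h$region_id[i1[inv]],
                   stringsAsFactors = FALSE), g)
}

#' Sliding-window density of signed pair distances
#'
#' For each position p from -range to +range, counts the pairs whose signed
#' distance d satisfies \code{p - window/2 <= d < p + window/2} (the 100-bp
#' window of the density plots). Each pair therefore contributes to exactly
#' \code{window} consecutive positions.
#'
#' @param pairs Pair table from [select_two_motif_promoters()].
#' @param subset Optional character vector of promoter ids to restrict to
#'   (e.g. bound promoters).
#' @param window Window width in bases (default 100, must be even).
#' @param range Track half-range (default 1000).
#' @return data.frame: \code{position} (-range..range), \code{count}.
#' @export
spacing_density <- function(pairs, subset = NULL, window = 100L,
                            range = 1000L) {
  window <- as.integer(window); range <- as.integer(range)
  if (window %% 2L != 0L) stopf("window must be even")
  d <- pairs$signed_distance
  if (!is.null(subset)) d <- d[pairs$promoter_id %in% subset]
  d <- d[!is.na(d) & abs(d) <= range]
  half <- window %/% 2L
  # tabulate distances on -range..range, then pad so edge windows can reach
  # distances beyond the track without wrapping
  tab <- tabulate(d + range + 1L, nbins = 2L * range + 1L)
  padded <- c(integer(half), tab, integer(half))
  cs <- c(0L, cumsum(padded))
  i <- seq_len(2L * range + 1L)  # position index; window covers
  counts <- cs[i + window] - cs[i]  # d in [p - half, p + half - 1]
  data.frame(position = (-range):range, count = counts)
}

#' Resampling null and positional p-values for a spacing density
#'
#' Builds the null distribution of windowed pair counts by repeatedly
#' drawing \code{sample_size} pairs with replacement from the full pair set
#' and recomputing the density track. At each position a normal distribution
#' is fitted to the resampled counts (sample mean and SD) and an upper-tail
#' p-value is reported for the observed count:
#' \code{p = 1 - Phi((obs - mu) / sigma)} (\code{alternative = "less"} gives
#' the depletion tail instead). The Bonferroni-corrected alpha over the 2001
#' positions, \code{0.05 / 2001}, is attached as attribute
#' \code{"alpha_corrected"}.
#'
#' @param all_pairs Full pair table (the resampling reference).
#' @param observed Observed density track from [spacing_density()].
#' @param sample_size Number of pairs per resampling draw (the bound-set
#'   size).
#' @param runs Number of resampling runs (default 2500).
#' @param seed Seed for reproducibility (the caller's RNG state is
#'   preserved).
#' @param window,range As in [spacing_density()].
#' @param alternative "greater" (enrichment, default) or "less" (depletion).
#' @return The observed track with columns \code{mu}, \code{sigma},
#'   \code{p_value} and \code{sigma_zero} (flag for degenerate positions,
#'   where p is 1 or the machine minimum) added.
#' @export
resample_pvalues <- function(all_pairs, observed, sample_size, runs = 2500L,
                             seed = NULL, window = 100L, range = 1000L,
                             alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  d_all <- all_pairs$signed_distance
  d_all <- d_all[!is.na(d_all) & abs(d_all) <= range]
  if (!length(d_all)) stopf("no pairs to resample from")
  npos <- 2L * range + 1L
  half <- window %/% 2L
  s1 <- numeric(npos); s2 <- numeric(npos)
  with_seed(seed, {
    for (r in seq_len(runs)) {
      ds <- d_all[sample.int(length(d_all), sample_size, replace = TRUE)]
      tab <- tabulate(ds + range + 1L, nbins = npos)
      cs <- c(0L, cumsum(c(integer(half), tab, integer(half))))
      cnt <- cs[seq_len(npos) + window] - cs[seq_len(npos)]
      s1 <- s1 + cnt
      s2 <- s2 + cnt * cnt
    }
  })
  mu <- s1 / runs
  sigma <- sqrt(pmax(s2 - runs * mu^2, 0) / (runs - 1))
  obs <- observed$count
  z <- (obs - mu) / sigma
  if (alternative == "less") z <- -z
  p <- stats::pnorm(z, lower.tail = FALSE)
  deg <- sigma == 0
  if (any(deg)) {
    hi <- if (alternative == "greater") obs > mu else obs < mu
    p[deg] <- ifelse(hi[deg], .Machine$double.xmin, 1)
  }
  out <- observed
  out$mu <- mu
  out$sigma <- sigma
  out$p_value <- p
  out$sigma_zero <- deg
  attr(out, "alpha_corrected") <- 0.05 / npos
  out
}

#' Helical-phase binding profile
#'
#' At each phase grid point (circular, 10-degree steps by default) the
#' relative binding is the fraction of pairs in a \code{window}-degree window
#' around the point that belong to the bound set; the profile is then divided
#' by its mean so it averages 1. A smooth curve
#' \code{1 + sum_h (a_h cos(h phi) + b_h sin(h phi))}, h = 1, 2, is fitted by
#' least squares. A phase-count profile of all pairs (normalized to mean 1)
#' is returned alongside for comparison.
#'
#' @param pairs Pair table with phases.
#' @param bound_ids Character vector of bound promoter ids.
#' @param window Window size in degrees (default 40).
#' @param step Grid step in degrees (default 10).
#' @return List of class \code{phase_profile}: \code{profile} (grid
#'   \code{phase}, \code{relative_binding}, \code{n_bound}, \code{n_all},
#'   \code{fitted}), \code{all} (normalized pair-count profile),
#'   \code{coef} (harmonic coefficients).
#' @export
phase_profile <- function(pairs, bound_ids, window = 40, step = 10) {
  phi <- pairs$phase[!is.na(pairs$phase)]
  ids <- pairs$promoter_id[!is.na(pairs$phase)]
  centers <- seq(-180 + step, 180, by = step)
  is_bound <- ids %in% bound_ids
  circ_in <- function(center) abs(((phi - center + 180) %% 360) - 180) <=
    window / 2
  n_all <- vapply(centers, function(cc) sum(circ_in(cc)), 0L)
  n_bound <- vapply(centers, function(cc) sum(circ_in(cc) & is_bound), 0L)
  keep <- n_all > 0L
  rel <- n_bound[keep] / n_all[keep]
  if (mean(rel) > 0) rel <- rel / mean(rel)
  prof <- data.frame(phase = centers[keep], relative_binding = rel,
                     n_bound = n_bound[keep], n_all = n_all[keep])
  rad <- prof$phase * pi / 180
  X <- cbind(c1 = cos(rad), s1 = sin(rad), c2 = cos(2 * rad),
             s2 = sin(2 * rad))
  fit <- stats::lm.fit(X, prof$relative_binding - 1)
  prof$fitted <- 1 + as.numeric(X %*% fit$coefficients)
  all_prof <- data.frame(phase = centers[keep],
                         relative_count = n_all[keep] / mean(n_all[keep]))
  structure(list(profile = prof, all = all_prof, coef = fit$coefficients),
            class = "phase_profile")
}

#' @export
print.phase_profile <- function(x, ...) {
  pk <- x$profile$phase[which.max(x$profile$fitted)]
  cat(sprintf("phase_profile: %d grid points, fitted maximum near %g deg\n",
              nrow(x$profile), pk))
  invisible(x)
}
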