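#' Binding probability versus motif copy number
#'
#' For each motif copy number k in \code{0..kmax}, the fraction of promoters
#' with that count that are bound. Promoters with more than \code{kmax}
#' motifs are excluded (too few to analyse); empty bins are omitted.
#'
#' @param calls Binding calls ([call_bound_promoters()]) or a character
#'   vector of bound gene ids.
#' @param counts Named integer vector of per-promoter motif counts
#'   ([motif_counts()]); the names define the promoter universe.
#' @param kmax Largest copy number analysed (default 6).
#' @return data.frame of curve points: \code{k}, \code{value} (probability),
#'   \code{n} (promoters in the bin).
#' @export
probability_curve <- function(calls, counts, kmax = 6L) {
  bound_ids <- if (is.character(calls)) calls else calls$gene_id[calls$bound]
  keep <- counts <= kmax
  counts <- counts[keep]
  is_bound <- names(counts) %in% bound_ids
  ks <- sort(unique(counts))
  rows <- lapply(ks, function(k) {
    sel <- counts == k
    data.frame(k = k, value = mean(is_bound[sel]), n = sum(sel))
  })
  do.call(rbind, rows)
}

#' Fit an exponential curve value = a * exp(b * k)
#'
#' Log-linear least squares: \code{ln(value)} regressed on k over the points
#' with positive value. The correlation coefficient R is the Pearson
#' correlation of \code{ln(value)} with k (R on the raw values is also
#' reported). Zero-value points are excluded from the fit but listed. An
#' explicit \code{exclude_k} drops stated copy numbers from the fit (used to
#' reproduce curves where a trailing point visibly departs from the trend).
#'
#' @param points Curve points (\code{k}, \code{value}).
#' @param exclude_k Copy numbers to leave out of the fit.
#' @return A \code{fit_result} list: \code{model}, \code{a}, \code{b},
#'   \code{R}, \code{R_raw}, \code{b_se}, \code{excluded_k},
#'   \code{degenerate}.
#' @export
fit_exponential <- function(points, exclude_k = NULL) {
  pts <- points[!(points$k %in% exclude_k), , drop = FALSE]
  zero_k <- pts$k[pts$value <= 0]
  pts <- pts[pts$value > 0, , drop = FALSE]
  if (nrow(pts) < 3L) stopf("need at least 3 positive points for the fit")
  y <- log(pts$value)
  if (stats::sd(y) == 0) {
    return(structure(list(model = "exponential", a = exp(y[1]), b = 0,
                          R = 0, R_raw = 0, b_se = 0,
                          excluded_k = c(exclude_k, zero_k),
                          degenerate = TRUE), class = "fit_result"))
  }
  fit <- stats::lm(y ~ pts$k)
  cf <- stats::coef(fit)
  structure(list(model = "exponential",
                 a = unname(exp(cf[1])), b = unname(cf[2]),
                 R = stats::cor(pts$k, y),
                 R_raw = stats::cor(pts$k, pts$value),
                 # a perfect fit triggers a harmless summary.lm warning
                 b_se = unname(suppressWarnings(
                   summary(fit)$coefficients[2, 2])),
                 excluded_k = c(exclude_k, zero_k), degenerate = FALSE),
            class = "fit_result")
}

#' Fit a straight line value = a + b * k
#'
#' Ordinary least squares with Pearson correlation coefficient.
#'
#' @param points Curve points (\code{k}, \code{value}).
#' @param exclude_k Copy numbers to leave out of the fit.
#' @return A \code{fit_result} list: \code{model}, \code{a} (intercept),
#'   \code{b} (slope), \code{R}, \code{b_se}, \code{degenerate}.
#' @export
fit_linear <- function(points, exclude_k = NULL) {
  pts <- points[!(points$k %in% exclude_k), , drop = FALSE]
  if (nrow(pts) < 2L) stopf("need at least 2 points for the fit")
  if (stats::sd(pts$value) == 0) {
    return(structure(list(model = "linear", a = pts$value[1], b = 0,
                          R = 0, R_raw = 0, b_se = 0,
                          excluded_k = exclude_k, degenerate = TRUE),
                     class = "fit_result"))
  }
  fit <- stats::lm(value ~ k, data = pts)
  cf <- stats::coef(fit)
  structure(list(model = "linear", a = unname(cf[1]), b = unname(cf[2]),
                 R = stats::cor(pts$k, pts$value),
                 R_raw = stats::cor(pts$k, pts$value),
                 b_se = unname(suppressWarnings(
                   summary(fit)$coefficients[2, 2])),
                 excluded_k = exclude_k, degenerate = FALSE),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  form <- if (x$model == "exponential") "a * exp(b k)" else "a + b k"
  cat(sprintf("%s fit %s: a = %.4g, b = %.4g (se %.3g), R = %.3f%s\n",
              x$model, form, x$a, x$b, x$b_se, x$R,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Relative binding signal versus motif copy number
#'
#' Each replicate's promoter signals are divided by that replicate's mean
#' promoter signal, making replicates of different depth comparable and
#' fixing the grand mean of normalized signals at 1. Each promoter is then
#' summarized by its replicate mean, and bins of equal motif copy number are
#' averaged; the standard error is across promoters within the bin.
#'
#' @param signals Numeric matrix of signals for the analysed (bound)
#'   promoters: rows = promoters (rownames = gene ids), columns = replicates.
#' @param counts Named motif counts covering the rows of \code{signals}.
#' @param kmax Largest copy number analysed (default 6).
#' @return data.frame of curve points: \code{k}, \code{value} (relative mean
#'   signal), \code{se} (NA for single-promoter bins), \code{n}.
#' @export
signal_curve <- function(signals, counts, kmax = 6L) {
  signals <- as.matrix(signals)
  if (is.null(rownames(signals))) stopf("signals matrix needs gene ids")
  k <- counts[rownames(signals)]
  if (anyNA(k)) stopf("every promoter needs a motif count")
  norm <- sweep(signals, 2, colMeans(signals), "/")
  per_prom <- rowMeans(norm)
  keep <- k <= kmax
  per_prom <- per_prom[keep]; k <- k[keep]
  ks <- sort(unique(k))
  rows <- lapply(ks, function(kk) {
    v <- per_prom[k == kk]
    data.frame(k = kk, value = mean(v),
               se = if (length(v) > 1L) stats::sd(v) / sqrt(length(v))
                    else NA_real_,
               n = length(v))
  })
  do.call(rbind, rows)
}
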