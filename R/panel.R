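#' Plant-height heterosis per hybrid
#'
#' Trait heterosis is the hybrid's height divided by the midparent height,
#' `h_j = height(hybrid) / ((height(P1) + height(P2)) / 2)`.
#'
#' @param traits trait data frame (`genotype`, `height_cm`).
#' @param cross cross-panel data frame.
#' @return named numeric vector of heterosis values, one per hybrid, in
#'   panel order.
#' @export
trait_heterosis <- function(traits, cross) {
  validate_trait(traits)
  h <- function(g) {
    i <- match(g, traits$genotype)
    if (anyNA(i))
      stop("genotype(s) absent from trait table: ",
           paste(g[is.na(i)], collapse = ", "))
    traits$height_cm[i]
  }
  out <- h(cross$hybrid) / ((h(cross$parent_female) + h(cross$parent_male)) / 2)
  names(out) <- cross$hybrid
  out
}

#' Expression-heterosis matrix across a hybrid panel
#'
#' Collects the per-feature hybrid/MP ratios (`ratio_mp`) from a list of
#' heterosis fits (or record tables) into one feature x hybrid matrix,
#' with `NA` where a feature lacks a defined ratio in a hybrid. Column
#' order follows the input order.
#'
#' @param fits list of `heterosis_fit` objects or classified record data
#'   frames, one per hybrid.
#' @return numeric matrix, features x hybrids.
#' @export
expression_heterosis_matrix <- function(fits) {
  recs <- lapply(fits, as_records)
  labels <- vapply(recs, function(r) r$hybrid[1], "")
  if (anyDuplicated(labels))
    stop("duplicate hybrid label(s): ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  features <- sort(unique(unlist(lapply(recs, `[[`, "feature_id"))))
  eh <- matrix(NA_real_, length(features), length(recs),
               dimnames = list(features, labels))
  for (j in seq_along(recs))
    eh[recs[[j]]$feature_id, j] <- recs[[j]]$ratio_mp
  eh
}

# Vectorized per-row Pearson correlation of matrix rows with a vector,
# with pairwise NA removal; returns r, n, and the t-transform p (n-2 df).
row_pearson <- function(m, y) {
  r <- rep(NA_real_, nrow(m)); n <- integer(nrow(m))
  for (i in seq_len(nrow(m))) {
    ok <- !is.na(m[i, ]) & !is.na(y)
    n[i] <- sum(ok)
    if (n[i] >= 3) {
      xi <- m[i, ok]; yi <- y[ok]
      if (stats::sd(xi) > 0 && stats::sd(yi) > 0)
        r[i] <- stats::cor(xi, yi)
    }
  }
  t <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(t), n - 2)
  p[!is.na(r) & abs(r) == 1] <- 0
  list(r = r, n = n, p = p)
}

#' Correlate expression heterosis with trait heterosis across a panel
#'
#' For every feature, the sample Pearson correlation between its
#' expression-heterosis values (hybrid/MP expression ratios) and the
#' hybrids' trait-heterosis values (hybrid/MP height ratios), over the
#' hybrids where both are defined. P-values come from the t transform
#' with n - 2 degrees of freedom. Features with fewer than `min_hybrids`
#' complete pairs, or with zero variance in either vector, are omitted;
#' the counts are recorded in attributes `"n_too_few"` and
#' `"n_zero_var"`.
#'
#' @param eh expression-heterosis matrix from
#'   [expression_heterosis_matrix()].
#' @param trait_h named trait-heterosis vector from [trait_heterosis()];
#'   names must match `colnames(eh)`.
#' @param min_hybrids minimum complete pairs per feature (default 5).
#' @param method `"pearson"` (default) or `"spearman"` (rank-based
#'   alternative).
#' @return object of class `"trait_correlation"`: data frame `feature_id`,
#'   `r`, `n`, `p`.
#' @export
protein_trait_correlation <- function(eh, trait_h, min_hybrids = 5,
                                      method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (min_hybrids < 3) stop("min_hybrids must be >= 3")
  i <- match(colnames(eh), names(trait_h))
  if (anyNA(i))
    stop("hybrid(s) missing from trait heterosis: ",
         paste(colnames(eh)[is.na(i)], collapse = ", "))
  y <- unname(trait_h[i])
  rp <- if (method == "spearman") {
    # ranks must respect each feature's availability pattern
    r <- rep(NA_real_, nrow(eh)); n <- integer(nrow(eh))
    for (k in seq_len(nrow(eh))) {
      ok <- !is.na(eh[k, ]) & !is.na(y)
      n[k] <- sum(ok)
      if (n[k] >= 3 && stats::sd(eh[k, ok]) > 0 && stats::sd(y[ok]) > 0)
        r[k] <- stats::cor(eh[k, ok], y[ok], method = "spearman")
    }
    t <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(t), n - 2)
    p[!is.na(r) & abs(r) == 1] <- 0
    list(r = r, n = n, p = p)
  } else {
    row_pearson(eh, y)
  }
  zero_var <- is.na(rp$r) & rp$n >= min_hybrids
  keep <- !is.na(rp$r) & rp$n >= min_hybrids
  out <- data.frame(feature_id = rownames(eh)[keep], r = rp$r[keep],
                    n = rp$n[keep], p = rp$p[keep],
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("trait_correlation", "data.frame")
  attr(out, "n_too_few") <- sum(rp$n < min_hybrids)
  attr(out, "n_zero_var") <- sum(zero_var)
  attr(out, "method") <- method
  attr(out, "min_hybrids") <- min_hybrids
  out
}

#' Threshold set of correlated features
#'
#' Features whose correlation exceeds (`side = "upper"`) or falls below
#' (`side = "lower"`) a cutoff — e.g. the r > 0.5 and r < -0.5 sets.
#' Ordering is deterministic: by r (descending for upper, ascending for
#' lower), ties by feature id.
#'
#' @param correlations `trait_correlation` table.
#' @param cutoff correlation cutoff.
#' @param side `"upper"` (r > cutoff) or `"lower"` (r < cutoff).
#' @return character vector of feature ids.
#' @export
correlation_threshold_set <- function(correlations, cutoff,
                                      side = c("upper", "lower")) {
  side <- match.arg(side)
  sel <- if (side == "upper") correlations$r > cutoff else correlations$r < cutoff
  sel <- sel & !is.na(correlations$r)
  ids <- correlations$feature_id[sel]
  r <- correlations$r[sel]
  ord <- if (side == "upper") order(-r, ids) else order(r, ids)
  ids[ord]
}

#' Top fraction of most trait-correlated features
#'
#' The `ceiling(fraction * n)` features with the largest correlation, ties
#' at the boundary broken by feature id (lexicographically smaller id
#' included first).
#'
#' @param correlations `trait_correlation` table.
#' @param fraction fraction in (0, 1).
#' @return character vector of feature ids.
#' @export
top_fraction <- function(correlations, fraction) {
  if (!(fraction > 0 && fraction < 1)) stop("fraction must be in (0, 1)")
  n <- nrow(correlations)
  k <- min(n, ceiling(fraction * n))
  ord <- order(-correlations$r, correlations$feature_id)
  correlations$feature_id[ord][seq_len(k)]
}

#' Hypergeometric set enrichment
#'
#' One-sided upper-tail hypergeometric test per annotation group: the
#' probability of drawing at least the observed overlap `k` when `n`
#' features are selected from a universe of `N` containing `K` group
#' members. Benjamini-Hochberg adjustment across groups.
#'
#' @param selected character vector of selected feature ids (must be a
#'   subset of `universe`).
#' @param annotation annotation data frame.
#' @param universe character vector of all feature ids under
#'   consideration.
#' @return data frame `group`, `k`, `K`, `n`, `N`, `p`, `q`, sorted by p.
#' @export
enrichment_hypergeometric <- function(selected, annotation, universe) {
  if (!length(universe)) stop("universe is empty")
  if (!all(selected %in% universe))
    stop("selected features must be a subset of the universe")
  sets <- lapply(annotation_sets(annotation), intersect, universe)
  sets <- sets[lengths(sets) > 0]
  N <- length(universe)
  n <- length(selected)
  rows <- lapply(names(sets), function(g) {
    K <- length(sets[[g]])
    k <- length(intersect(selected, sets[[g]]))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(group = g, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(group = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p = numeric(),
                      q = numeric(), stringsAsFactors = FALSE))
  out$q <- adjust_fdr(out$p)
  out <- out[order(out$p, out$group), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Kernel density of correlations per feature group
#'
#' Gaussian kernel density estimate of each group's correlation
#' coefficients on a fixed 512-point grid over \[-1.05, 1.05\], bandwidth
#' by Silverman's rule (per group). Each curve is renormalized to
#' integrate to 1 on the grid (trapezoid rule). Groups with fewer than 5
#' members with defined r are skipped with a warning.
#'
#' @param correlations `trait_correlation` table.
#' @param annotation annotation data frame.
#' @param groups group labels to include.
#' @return data frame `group`, `x`, `density` (512 rows per retained
#'   group).
#' @export
correlation_density_by_group <- function(correlations, annotation, groups) {
  sets <- annotation_sets(annotation)
  grid_n <- 512L
  rows <- list()
  for (g in groups) {
    r <- correlations$r[correlations$feature_id %in% sets[[g]]]
    r <- r[!is.na(r)]
    if (length(r) < 5) {
      warning("group '", g, "' has fewer than 5 members with defined r; skipped")
      next
    }
    bw <- stats::bw.nrd0(r)
    if (!is.finite(bw) || bw <= 0) bw <- 1e-3  # degenerate: identical values
    d <- stats::density(r, bw = bw, n = grid_n, from = -1.05, to = 1.05)
    dx <- diff(d$x[1:2])
    area <- sum((d$y[-1] + d$y[-grid_n]) / 2) * dx
    rows[[g]] <- data.frame(group = g, x = d$x, density = d$y / area,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(group = character(), x = numeric(), density = numeric())
  rownames(out) <- NULL
  out
}

#' Per-genotype mean expression matrix
#'
#' Convenience wrapper stacking [genotype_stats()] means for several
#' genotypes into a features x genotypes matrix, the input expected by
#' [negative_control_correlation()].
#'
#' @param x (normalized) abundance matrix.
#' @param design sample design data frame.
#' @param genotypes genotype labels (default: all in the design).
#' @param tissue restrict to one tissue, or `NULL`.
#' @param min_reps minimum replicates per feature (default 2).
#' @return numeric matrix of per-genotype feature means.
#' @export
genotype_mean_matrix <- function(x, design, genotypes = unique(design$genotype),
                                 tissue = NULL, min_reps = 2) {
  out <- vapply(genotypes, function(g)
    genotype_stats(x, design, g, tissue, min_reps)$mean,
    numeric(nrow(x)))
  rownames(out) <- rownames(x)
  out
}

#' Negative control: absolute expression level versus raw height
#'
#' Correlates each feature's per-genotype mean expression level with the
#' genotypes' raw plant heights. In a panel where only the hybrid/MP
#' ratios are trait-coupled, these level-vs-height correlations should be
#' near zero — the specificity control showing that expression levels per
#' se do not track plant height.
#'
#' @param levels numeric matrix of per-genotype mean expression
#'   (features x genotypes).
#' @param heights named numeric vector of raw heights; names must cover
#'   `colnames(levels)`.
#' @return data frame `feature_id`, `r`, `n`, `p`, with a `"summary"`
#'   attribute (median and IQR of |r|, median r).
#' @export
negative_control_correlation <- function(levels, heights) {
  if (is.null(rownames(levels)))
    stop("levels must carry feature rownames")
  i <- match(colnames(levels), names(heights))
  if (anyNA(i))
    stop("genotype(s) missing from heights: ",
         paste(colnames(levels)[is.na(i)], collapse = ", "))
  if (ncol(levels) < 3) stop("need >= 3 genotypes")
  rp <- row_pearson(levels, unname(heights[i]))
  keep <- !is.na(rp$r)
  out <- data.frame(feature_id = rownames(levels)[keep], r = rp$r[keep],
                    n = rp$n[keep], p = rp$p[keep],
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "summary") <- c(
    median_abs_r = stats::median(abs(out$r)),
    iqr_abs_r = stats::IQR(abs(out$r)),
    median_r = stats::median(out$r)
  )
  attr(out, "n_omitted") <- sum(!keep)
  out
}
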