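#' Normalize abundances to an anchor genotype, per run
#'
#' Multiplexed isobaric-label (TMT-style) quantification carries a
#' multiplicative batch factor per run (plex). When every run contains
#' replicates of a common anchor genotype, dividing each feature's values
#' by the arithmetic mean of that feature over the run's anchor samples
#' removes the run factor exactly and puts all samples on a common
#' anchor-relative scale.
#'
#' Features whose anchor mean in a run is missing or zero become missing
#' for all samples of that run; no ratio is fabricated. The operation is
#' idempotent, and after it the per-run anchor mean of every quantified
#' feature is exactly 1.
#'
#' @param x abundance matrix (features x samples).
#' @param design sample design data frame (see [read_design()]); every
#'   sample column of `x` must appear, and every run must contain at least
#'   one anchor-genotype sample.
#' @param anchor anchor genotype label (e.g. `"B73"`).
#' @return normalized matrix of the same shape and dimnames.
#' @export
normalize_to_anchor <- function(x, design, anchor) {
  validate_abundance(x)
  idx <- match(colnames(x), design$sample_id)
  if (anyNA(idx))
    stop("sample(s) absent from design: ",
         paste(colnames(x)[is.na(idx)], collapse = ", "))
  runs <- design$run[idx]
  geno <- design$genotype[idx]
  out <- x
  for (r in unique(runs)) {
    in_run <- runs == r
    anchor_cols <- in_run & geno == anchor
    if (!any(anchor_cols))
      stop("run '", r, "' contains no sample of anchor genotype '", anchor, "'")
    am <- rowMeans(x[, anchor_cols, drop = FALSE], na.rm = TRUE)
    am[!is.finite(am) | am <= 0] <- NA_real_
    out[, in_run] <- x[, in_run, drop = FALSE] / am
  }
  out
}

#' Counts per million
#'
#' Scales each column of a nonnegative count matrix so it sums to one
#' million, the standard library-size normalization for read counts.
#'
#' @param x nonnegative count matrix (features x samples); `NA` treated as
#'   unobserved and excluded from column sums.
#' @return matrix of CPM values, same shape and dimnames.
#' @export
counts_per_million <- function(x) {
  validate_abundance(x)
  cs <- colSums(x, na.rm = TRUE)
  zero <- names(cs)[cs <= 0]
  if (length(zero))
    stop("zero column sum for sample(s): ", paste(zero, collapse = ", "))
  sweep(x, 2, cs, "/") * 1e6
}
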