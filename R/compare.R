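#' Differential expression of a mutant versus its inbred background
#'
#' Welch two-sample t-test on log2 normalized abundances per feature,
#' Benjamini-Hochberg control, and a three-way direction call: `up` /
#' `down` at q <= alpha by the sign of the log2 ratio, `unchanged`
#' otherwise. Both genotypes must come from the same tissue and
#' normalization.
#'
#' @param x normalized abundance matrix.
#' @param design sample design data frame.
#' @param mutant,background genotype labels.
#' @param tissue restrict to one tissue, or `NULL`.
#' @param alpha FDR level for the direction call (default 0.05).
#' @param min_reps minimum replicates per genotype (default 2).
#' @return data frame `feature_id`, `log2_ratio` (mutant/background),
#'   `p`, `q`, `direction` (factor up/unchanged/down).
#' @export
mutant_contrast <- function(x, design, mutant, background, tissue = NULL,
                            alpha = 0.05, min_reps = 2) {
  M <- genotype_values(x, design, mutant, tissue)
  B <- genotype_values(x, design, background, tissue)
  lsm <- row_stats(log2_pos(M))
  lsb <- row_stats(log2_pos(B))
  keep <- lsm$n >= min_reps & lsb$n >= min_reps
  p <- welch_p(lsm$mean, lsm$var, lsm$n, lsb$mean, lsb$var, lsb$n)
  out <- data.frame(
    feature_id = rownames(M),
    log2_ratio = lsm$mean - lsb$mean,
    p = p,
    stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
  out$q <- adjust_fdr(out$p)
  dir <- rep("unchanged", nrow(out))
  sig <- !is.na(out$q) & out$q <= alpha
  dir[sig & out$log2_ratio > 0] <- "up"
  dir[sig & out$log2_ratio < 0] <- "down"
  out$direction <- factor(dir, levels = c("up", "unchanged", "down"))
  rownames(out) <- NULL
  out
}

#' Phenocopy concordance between a mutant and a hybrid
#'
#' Cross-tabulates the hybrid's nonadditivity calls (collapsed to
#' above_MP / MP / below_MP) against the mutant's direction calls
#' (up / unchanged / down) over the shared feature universe. A mutant
#' phenocopies the hybrid proteome when features above MP in the hybrid
#' are elevated — and rarely repressed — in the mutant, and vice versa.
#'
#' The concordance estimate is the fraction of features called in both
#' comparisons (hybrid non-MP and mutant changed) whose directions agree;
#' the discordant cells (above_MP & down, below_MP & up) are reported
#' explicitly.
#'
#' @param mutant_table output of [mutant_contrast()].
#' @param hybrid classified records or a `heterosis_fit`.
#' @return object of class `"phenocopy"`: list with `table` (3 x 3
#'   contingency, hybrid x mutant), `n_shared`, `n_above_mp`,
#'   `n_below_mp`, `discordant` (named counts), `concordant` (named
#'   counts), `concordance` (estimate in \[0, 1\], `NA` if no feature is
#'   called in both).
#' @export
phenocopy_concordance <- function(mutant_table, hybrid) {
  hrec <- as_records(hybrid)
  shared <- intersect(mutant_table$feature_id, hrec$feature_id)
  if (!length(shared)) stop("no shared features between mutant and hybrid tables")
  hcat <- as.character(hrec$category[match(shared, hrec$feature_id)])
  hcol <- ifelse(hcat %in% c("above_HP", "between_MP_HP"), "above_MP",
          ifelse(hcat %in% c("below_LP", "between_LP_MP"), "below_MP", "MP"))
  hcol <- factor(hcol, levels = c("above_MP", "MP", "below_MP"))
  mdir <- mutant_table$direction[match(shared, mutant_table$feature_id)]
  tab <- table(hybrid = hcol, mutant = mdir)
  disc <- c(above_MP_down = tab["above_MP", "down"],
            below_MP_up = tab["below_MP", "up"])
  conc <- c(above_MP_up = tab["above_MP", "up"],
            below_MP_down = tab["below_MP", "down"])
  called_both <- sum(disc) + sum(conc)
  structure(list(
    table = tab,
    n_shared = length(shared),
    n_above_mp = sum(hcol == "above_MP"),
    n_below_mp = sum(hcol == "below_MP"),
    discordant = disc,
    concordant = conc,
    concordance = if (called_both > 0) sum(conc) / called_both else NA_real_
  ), class = "phenocopy")
}

#' Agreement between two heterosis record tables
#'
#' Quantifies how well the midparent deviations of one data layer mirror
#' another's — e.g. protein versus transcript heterosis for the same
#' hybrid. Over the shared feature universe it reports the fraction of
#' features whose log2 hybrid/MP ratios agree in sign, the Pearson
#' correlation of the two log2 ratio vectors, and the five-way category
#' agreement rate; optionally broken down by annotation group.
#'
#' @param records_a,records_b classified records or `heterosis_fit`
#'   objects sharing a feature universe (>= 10 shared features).
#' @param annotation optional annotation data frame for a per-group
#'   breakdown.
#' @return list with `n_shared`, `sign_agreement`, `r_log2_ratio`,
#'   `category_agreement`, and `by_group` (data frame or `NULL`).
#' @export
discordance_stats <- function(records_a, records_b, annotation = NULL) {
  a <- as_records(records_a); b <- as_records(records_b)
  shared <- intersect(a$feature_id, b$feature_id)
  if (length(shared) < 10)
    stop("fewer than 10 shared features (", length(shared), ")")
  ia <- match(shared, a$feature_id); ib <- match(shared, b$feature_id)
  la <- a$log2_ratio_mp[ia]; lb <- b$log2_ratio_mp[ib]
  ok <- is.finite(la) & is.finite(lb)
  metrics <- function(sel) {
    list(
      n = sum(sel),
      sign_agreement = mean(sign(la[sel]) == sign(lb[sel])),
      r_log2_ratio = if (sum(sel) >= 3 && stats::sd(la[sel]) > 0 &&
                         stats::sd(lb[sel]) > 0)
        stats::cor(la[sel], lb[sel]) else NA_real_,
      category_agreement = mean(as.character(a$category[ia][sel]) ==
                                as.character(b$category[ib][sel]))
    )
  }
  overall <- metrics(ok)
  by_group <- NULL
  if (!is.null(annotation)) {
    sets <- annotation_sets(annotation)
    rows <- lapply(names(sets), function(g) {
      sel <- ok & shared %in% sets[[g]]
      if (sum(sel) < 3) return(NULL)
      m <- metrics(sel)
      data.frame(group = g, n = m$n, sign_agreement = m$sign_agreement,
                 r_log2_ratio = m$r_log2_ratio,
                 category_agreement = m$category_agreement,
                 stringsAsFactors = FALSE)
    })
    by_group <- do.call(rbind, rows)
  }
  list(n_shared = length(shared),
       sign_agreement = overall$sign_agreement,
       r_log2_ratio = overall$r_log2_ratio,
       category_agreement = overall$category_agreement,
       by_group = by_group)
}
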