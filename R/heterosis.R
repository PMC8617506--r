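#' Extract replicate-level values for one genotype
#'
#' Pulls the columns of a (normalized) abundance matrix belonging to one
#' genotype in one tissue, ordered by replicate index. Replicates are
#' pooled across runs, which is only meaningful after
#' [normalize_to_anchor()] has removed run effects.
#'
#' @param x abundance matrix.
#' @param design sample design data frame.
#' @param genotype genotype label.
#' @param tissue restrict to one tissue, or `NULL` for all.
#' @return matrix features x replicates.
#' @export
genotype_values <- function(x, design, genotype, tissue = NULL) {
  sel <- design$genotype == genotype
  if (!is.null(tissue)) sel <- sel & design$tissue == tissue
  ids <- design$sample_id[sel]
  ids <- ids[ids %in% colnames(x)]
  if (!length(ids))
    stop("no samples for genotype '", genotype, "'",
         if (!is.null(tissue)) paste0(" in tissue '", tissue, "'") else "")
  ord <- order(design$replicate[match(ids, design$sample_id)], ids)
  x[, ids[ord], drop = FALSE]
}

#' Per-feature summary statistics for one genotype
#'
#' Mean, unbiased variance and replicate count over non-missing values.
#' Features quantified in fewer than `min_reps` replicates are reported
#' missing (`NA` mean/variance), not zero.
#'
#' @inheritParams genotype_values
#' @param min_reps minimum replicates for a feature to be summarized
#'   (default 2).
#' @return data frame `feature_id`, `mean`, `var`, `n`, with the replicate
#'   matrix attached as attribute `"replicates"`.
#' @export
genotype_stats <- function(x, design, genotype, tissue = NULL, min_reps = 2) {
  v <- genotype_values(x, design, genotype, tissue)
  n <- rowSums(!is.na(v))
  m <- rowMeans(v, na.rm = TRUE)
  s2 <- apply(v, 1, stats::var, na.rm = TRUE)
  m[n < min_reps] <- NA_real_
  s2[n < min_reps] <- NA_real_
  m[n == 0] <- NA_real_
  out <- data.frame(feature_id = rownames(v), mean = m, var = s2, n = n,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "replicates") <- v
  attr(out, "genotype") <- genotype
  out
}

# Vectorized Welch two-sample t-test from per-feature summaries.
# Returns two-sided p-values; NA where either group has < 2 observations
# or both variances are zero.
welch_p <- function(m1, v1, n1, m2, v2, n2) {
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  p[n1 < 2 | n2 < 2] <- NA_real_
  # degenerate zero-variance cases: means equal to rounding error carry
  # no evidence, distinct means with no within-group spread are maximal
  # evidence (means are on the log2 scale, so 1e-8 is far below any
  # biologically meaningful ratio)
  zero <- is.nan(p) & !is.na(m1) & !is.na(m2)
  p[zero & abs(m1 - m2) <= 1e-8] <- 1
  p[zero & abs(m1 - m2) > 1e-8] <- 0
  p
}

row_stats <- function(v) {
  list(n = rowSums(!is.na(v)),
       mean = rowMeans(v, na.rm = TRUE),
       var = apply(v, 1, stats::var, na.rm = TRUE))
}

log2_pos <- function(v) {
  v[!is.na(v) & v <= 0] <- NA_real_
  log2(v)
}

#' Midparent / high-parent / low-parent contrasts for one hybrid
#'
#' For every feature, summarizes hybrid and parental replicates, forms the
#' midparent (MP = average of the two parental means), high-parent (HP =
#' larger parental mean) and low-parent (LP = smaller parental mean)
#' references, the linear ratios hybrid/MP, hybrid/HP, hybrid/LP, and
#' Welch two-sample t-tests on log2 values for the hybrid against each
#' reference. The MP test uses per-replicate pseudo-midparent values
#' (replicate k of parent 1 averaged with replicate k of parent 2, paired
#' by replicate index and truncated to the shorter parent), which gives MP
#' a sampling distribution without assuming equal parental variances. The
#' HP and LP tests compare the hybrid's replicates with the replicates of
#' whichever parent is high (or low) for that feature.
#'
#' Features quantified in fewer than `min_reps` replicates of the hybrid
#' or of both parents are dropped; the number dropped because both parents
#' were missing is recorded in attribute `"n_dropped"`.
#'
#' @param x normalized abundance matrix.
#' @param design sample design data frame.
#' @param hybrid,parent1,parent2 genotype labels.
#' @param tissue restrict to one tissue, or `NULL`.
#' @param min_reps minimum replicates per genotype (default 2).
#' @return data frame of per-feature heterosis records (no categories yet):
#'   `feature_id`, `hybrid`, `hybrid_mean`, `mp`, `hp`, `lp`, `ratio_mp`,
#'   `ratio_hp`, `ratio_lp`, `log2_ratio_mp`, `log2_ratio_hp`,
#'   `log2_ratio_lp`, `p_mp`, `p_hp`, `p_lp`, `n_hybrid`.
#' @export
heterosis_contrasts <- function(x, design, hybrid, parent1, parent2,
                                tissue = NULL, min_reps = 2) {
  H <- genotype_values(x, design, hybrid, tissue)
  A <- genotype_values(x, design, parent1, tissue)
  B <- genotype_values(x, design, parent2, tissue)

  sh <- row_stats(H); sa <- row_stats(A); sb <- row_stats(B)
  ok_h <- sh$n >= min_reps
  ok_a <- sa$n >= min_reps
  ok_b <- sb$n >= min_reps

  both_parents_missing <- ok_h & !ok_a & !ok_b
  keep <- ok_h & ok_a & ok_b
  n_dropped <- sum(!keep)

  mp <- (sa$mean + sb$mean) / 2
  hp <- pmax(sa$mean, sb$mean)
  lp <- pmin(sa$mean, sb$mean)
  a_is_hp <- sa$mean >= sb$mean

  # tests on log2 scale
  lH <- log2_pos(H); lA <- log2_pos(A); lB <- log2_pos(B)
  lsh <- row_stats(lH); lsa <- row_stats(lA); lsb <- row_stats(lB)

  # pseudo-midparent replicates, paired by replicate index
  k <- min(ncol(A), ncol(B))
  M <- (A[, seq_len(k), drop = FALSE] + B[, seq_len(k), drop = FALSE]) / 2
  lsm <- row_stats(log2_pos(M))

  p_mp <- welch_p(lsh$mean, lsh$var, lsh$n, lsm$mean, lsm$var, lsm$n)
  p_a <- welch_p(lsh$mean, lsh$var, lsh$n, lsa$mean, lsa$var, lsa$n)
  p_b <- welch_p(lsh$mean, lsh$var, lsh$n, lsb$mean, lsb$var, lsb$n)
  p_hp <- ifelse(a_is_hp, p_a, p_b)
  p_lp <- ifelse(a_is_hp, p_b, p_a)

  rec <- data.frame(
    feature_id = rownames(H),
    hybrid = hybrid,
    hybrid_mean = sh$mean,
    mp = mp, hp = hp, lp = lp,
    ratio_mp = sh$mean / mp,
    ratio_hp = sh$mean / hp,
    ratio_lp = sh$mean / lp,
    p_mp = p_mp, p_hp = p_hp, p_lp = p_lp,
    n_hybrid = sh$n,
    row.names = NULL, stringsAsFactors = FALSE
  )
  rec$log2_ratio_mp <- log2(rec$ratio_mp)
  rec$log2_ratio_hp <- log2(rec$ratio_hp)
  rec$log2_ratio_lp <- log2(rec$ratio_lp)
  rec <- rec[, c("feature_id", "hybrid", "hybrid_mean", "mp", "hp", "lp",
                 "ratio_mp", "ratio_hp", "ratio_lp",
                 "log2_ratio_mp", "log2_ratio_hp", "log2_ratio_lp",
                 "p_mp", "p_hp", "p_lp", "n_hybrid")]
  rec <- rec[keep, , drop = FALSE]
  rownames(rec) <- NULL
  attr(rec, "n_dropped") <- n_dropped
  attr(rec, "n_both_parents_missing") <- sum(both_parents_missing)
  if (any(both_parents_missing))
    message(sum(both_parents_missing),
            " feature(s) dropped: hybrid quantified but both parents missing")
  rec
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up false-discovery-rate adjustment applied within one contrast.
#' Missing p-values are allowed and stay missing.
#'
#' @param p numeric vector of p-values in \[0, 1\] (`NA` allowed).
#' @return q-values, same length and order.
#' @export
adjust_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Classify heterosis records into five nonadditivity categories
#'
#' Decision tree, applied in order: `above_HP` if the hybrid is
#' significantly different from HP and its mean exceeds HP; `below_LP` if
#' significantly different from LP and below LP; else `between_MP_HP`
#' (significant vs MP, mean above MP) or `between_LP_MP` (significant vs
#' MP, mean below MP); else `MP` (additive). Categories are exhaustive and
#' mutually exclusive. Records with missing q-values fall to `MP` and are
#' flagged `incomplete`.
#'
#' @param records output of [heterosis_contrasts()].
#' @param alpha FDR significance level (default 0.05).
#' @return `records` with added columns `q_mp`, `q_hp`, `q_lp`, `category`
#'   (factor with levels above_HP, between_MP_HP, MP, between_LP_MP,
#'   below_LP), `incomplete`.
#' @export
classify_records <- function(records, alpha = 0.05) {
  records$q_mp <- adjust_fdr(records$p_mp)
  records$q_hp <- adjust_fdr(records$p_hp)
  records$q_lp <- adjust_fdr(records$p_lp)
  q_mp <- records$q_mp; q_hp <- records$q_hp; q_lp <- records$q_lp
  m <- records$hybrid_mean
  incomplete <- is.na(q_mp) | is.na(q_hp) | is.na(q_lp)
  # missing significance evidence cannot trigger a nonadditive call
  t_hp <- !is.na(q_hp) & q_hp <= alpha & m > records$hp
  t_lp <- !is.na(q_lp) & q_lp <= alpha & m < records$lp
  t_up <- !is.na(q_mp) & q_mp <= alpha & m > records$mp
  t_dn <- !is.na(q_mp) & q_mp <= alpha & m < records$mp
  cat <- rep("MP", nrow(records))
  cat[t_up] <- "between_MP_HP"
  cat[t_dn] <- "between_LP_MP"
  cat[t_lp] <- "below_LP"
  cat[t_hp] <- "above_HP"
  records$category <- factor(cat, levels = heterosis_categories())
  records$incomplete <- incomplete
  records
}

#' @rdname classify_records
#' @export
heterosis_categories <- function() {
  c("above_HP", "between_MP_HP", "MP", "between_LP_MP", "below_LP")
}

#' Fit the heterosis model for one hybrid
#'
#' The central entry point: builds MP/HP/LP contrasts for one hybrid
#' against its two parents ([heterosis_contrasts()]), applies
#' Benjamini-Hochberg control per contrast, and classifies every feature
#' into one of five nonadditivity categories ([classify_records()]).
#'
#' @inheritParams heterosis_contrasts
#' @param alpha FDR level for classification (default 0.05).
#' @return object of class `"heterosis_fit"`: a list with elements
#'   `records` (classified per-feature table), `hybrid`, `parents`,
#'   `alpha`, `tissue`, `n_dropped`. Methods: `print`, `summary`, `coef`
#'   (log2 ratios), `plot` (volcano).
#' @examples
#' sim <- simulate_panel(sim_config(n_features = 200, seed = 1))
#' norm <- normalize_to_anchor(sim$matrix, sim$design, sim$config$anchor)
#' cr <- sim$cross[1, ]
#' fit <- heterosis_fit(norm, sim$design, cr$hybrid,
#'                      cr$parent_female, cr$parent_male)
#' summary(fit)
#' @export
heterosis_fit <- function(x, design, hybrid, parent1, parent2,
                          tissue = NULL, alpha = 0.05, min_reps = 2) {
  rec <- heterosis_contrasts(x, design, hybrid, parent1, parent2,
                             tissue = tissue, min_reps = min_reps)
  rec <- classify_records(rec, alpha = alpha)
  structure(list(records = rec, hybrid = hybrid,
                 parents = c(parent1, parent2), alpha = alpha,
                 tissue = tissue,
                 n_dropped = attr(rec, "n_dropped")),
            class = "heterosis_fit")
}

as_records <- function(x) {
  if (inherits(x, "heterosis_fit")) x$records else x
}

#' Mean percent excess of a feature group over a baseline
#'
#' `100 * (mean(ratio_baseline) - 1)` over the group members with a
#' defined ratio — e.g. "expressed 19% above HP, on average".
#'
#' @param records classified records or a `heterosis_fit`.
#' @param annotation annotation data frame.
#' @param group group label.
#' @param baseline one of `"MP"`, `"HP"`, `"LP"`.
#' @return percent excess (scalar).
#' @export
group_mean_excess <- function(records, annotation, group,
                              baseline = c("MP", "HP", "LP")) {
  baseline <- match.arg(baseline)
  records <- as_records(records)
  members <- annotation_sets(annotation)[[group]]
  r <- records[[paste0("ratio_", tolower(baseline))]][
    records$feature_id %in% members]
  r <- r[!is.na(r)]
  if (!length(r))
    stop("group '", group, "' has no member with a defined ratio")
  100 * (mean(r) - 1)
}

#' Wilcoxon signed-rank shift test for a feature group
#'
#' Tests whether a group's log2 ratios to a baseline are shifted away
#' from 0, i.e. whether the group as a whole is non-additively expressed.
#'
#' @inheritParams group_mean_excess
#' @return list with `statistic` (signed-rank V), `p_value` (two-sided),
#'   `median_log2_ratio`, `n`.
#' @export
group_shift_test <- function(records, annotation, group,
                             baseline = c("MP", "HP", "LP")) {
  baseline <- match.arg(baseline)
  records <- as_records(records)
  members <- annotation_sets(annotation)[[group]]
  lr <- records[[paste0("log2_ratio_", tolower(baseline))]][
    records$feature_id %in% members]
  lr <- lr[is.finite(lr)]
  if (length(lr) < 3)
    stop("group '", group, "' has fewer than 3 members with defined ratios; ",
         "at least 3 required")
  wt <- suppressWarnings(stats::wilcox.test(lr, mu = 0, exact = length(lr) < 50))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       median_log2_ratio = stats::median(lr), n = length(lr))
}

#' Volcano table for one contrast
#'
#' One row per classified feature: log2 ratio and -log10 q for the chosen
#' contrast, category, and annotation groups if supplied. Rows are sorted
#' by q ascending, ties by |log2 ratio| descending then feature id;
#' q-values of 0 are clamped to 1e-300 before the log.
#'
#' @param records classified records or a `heterosis_fit`.
#' @param contrast one of `"MP"`, `"HP"`, `"LP"`.
#' @param annotation optional annotation data frame.
#' @return data frame `feature_id`, `log2_ratio`, `neg_log10_q`,
#'   `category`, `groups`.
#' @export
volcano_table <- function(records, contrast = c("MP", "HP", "LP"),
                          annotation = NULL) {
  contrast <- match.arg(contrast)
  records <- as_records(records)
  lr <- records[[paste0("log2_ratio_", tolower(contrast))]]
  q <- records[[paste0("q_", tolower(contrast))]]
  out <- data.frame(
    feature_id = records$feature_id,
    log2_ratio = lr,
    neg_log10_q = -log10(pmax(q, 1e-300)),
    category = records$category,
    stringsAsFactors = FALSE
  )
  out$groups <- if (!is.null(annotation)) {
    annotation$groups[match(out$feature_id, annotation$feature_id)]
  } else NA_character_
  ord <- order(q, -abs(lr), out$feature_id, na.last = TRUE)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
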