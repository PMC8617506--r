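#' @export
print.heterosis_fit <- function(x, ...) {
  cat("Heterosis fit:", x$hybrid, "vs parents",
      paste(x$parents, collapse = " / "), "\n")
  cat(nrow(x$records), "features classified (alpha =", x$alpha, ")\n")
  print(table(x$records$category))
  invisible(x)
}

#' @export
summary.heterosis_fit <- function(object, ...) {
  rec <- object$records
  counts <- table(rec$category)
  out <- list(
    hybrid = object$hybrid,
    parents = object$parents,
    alpha = object$alpha,
    n_features = nrow(rec),
    n_dropped = object$n_dropped,
    category_counts = counts,
    category_percent = 100 * as.numeric(counts) / nrow(rec),
    mean_ratio_mp = mean(rec$ratio_mp, na.rm = TRUE),
    median_ratio_mp = stats::median(rec$ratio_mp, na.rm = TRUE)
  )
  class(out) <- "summary.heterosis_fit"
  out
}

#' @export
print.summary.heterosis_fit <- function(x, ...) {
  cat("Heterosis fit:", x$hybrid, "vs", paste(x$parents, collapse = " / "),
      "\n")
  cat(sprintf("%d features classified, %d dropped; alpha = %g\n",
              x$n_features, x$n_dropped, x$alpha))
  df <- data.frame(count = as.integer(x$category_counts),
                   percent = round(x$category_percent, 1),
                   row.names = names(x$category_counts))
  print(df)
  cat(sprintf("mean hybrid/MP ratio %.3f, median %.3f\n",
              x$mean_ratio_mp, x$median_ratio_mp))
  invisible(x)
}

#' @export
coef.heterosis_fit <- function(object, ...) {
  rec <- object$records
  m <- as.matrix(rec[, c("log2_ratio_mp", "log2_ratio_hp", "log2_ratio_lp")])
  rownames(m) <- rec$feature_id
  colnames(m) <- c("MP", "HP", "LP")
  m
}

#' Volcano plot of a heterosis fit
#'
#' @param x a `heterosis_fit`.
#' @param contrast which contrast to display (default `"MP"`).
#' @param ... passed to [graphics::plot()].
#' @export
plot.heterosis_fit <- function(x, contrast = c("MP", "HP", "LP"), ...) {
  contrast <- match.arg(contrast)
  vt <- volcano_table(x, contrast)
  col <- ifelse(vt$category == "MP", "grey60", "firebrick")
  graphics::plot(vt$log2_ratio, vt$neg_log10_q, pch = 16, cex = 0.5,
                 col = col,
                 xlab = paste0("log2(hybrid / ", contrast, ")"),
                 ylab = "-log10 q", ...)
  graphics::abline(h = -log10(x$alpha), lty = 2)
  invisible(vt)
}

#' @export
print.trait_correlation <- function(x, ...) {
  cat("Trait correlation table:", nrow(x), "features (",
      attr(x, "method"), ", min_hybrids =", attr(x, "min_hybrids"), ")\n")
  cat(sprintf("r: median %.3f, IQR [%.3f, %.3f]\n",
              stats::median(x$r),
              stats::quantile(x$r, 0.25), stats::quantile(x$r, 0.75)))
  cat(sprintf("%d features with r > 0.5, %d with r < -0.5\n",
              sum(x$r > 0.5), sum(x$r < -0.5)))
  invisible(x)
}

#' Density plot of trait correlations
#'
#' @param x a `trait_correlation` table.
#' @param ... passed to [graphics::plot()].
#' @export
plot.trait_correlation <- function(x, ...) {
  d <- stats::density(x$r, from = -1.05, to = 1.05)
  graphics::plot(d, xlab = "Pearson r (expression vs trait heterosis)",
                 main = "", ...)
  invisible(d)
}

#' @export
print.phenocopy <- function(x, ...) {
  cat("Phenocopy concordance over", x$n_shared, "shared features\n")
  print(x$table)
  cat(sprintf("discordant: %d above-MP repressed, %d below-MP elevated\n",
              x$discordant[["above_MP_down"]],
              x$discordant[["below_MP_up"]]))
  if (!is.na(x$concordance))
    cat(sprintf("concordance among features called in both: %.3f\n",
                x$concordance))
  invisible(x)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic panel configuration\n")
  cat(sprintf("  %d features, %d parents, %d hybrids, %d reps, anchor %s\n",
              x$n_features, x$n_parents, nrow(x$panel), x$n_reps, x$anchor))
  cat(sprintf("  sigma_r %.2f, sigma_b %.2f, sigma_g %.2f, sigma_c %.2f\n",
              x$sigma_r, x$sigma_b, x$sigma_g, x$sigma_c))
  cat(sprintf("  coupled group: %d features, beta %.2f; seed %d\n",
              x$coupled_n, x$coupled_beta, x$seed))
  invisible(x)
}

#' @export
print.sim_panel <- function(x, ...) {
  cat("Synthetic hybrid panel:",
      nrow(x$matrix), "features x", ncol(x$matrix), "samples,",
      nrow(x$cross), "hybrids,", length(unique(x$design$run)), "runs\n")
  invisible(x)
}
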