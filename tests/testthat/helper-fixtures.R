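# Small in-code fixtures shared across test files.

# abundance matrix from replicate vectors: one run, one tissue
toy_matrix <- function(...) {
  vals <- list(...)
  m <- do.call(cbind, vals)
  rownames(m) <- sprintf("F%03d", seq_len(nrow(m)))
  m
}

# design for a single-run experiment given genotype -> n_reps
toy_design <- function(genotypes, n_reps, run = "R1", tissue = "leaf") {
  df <- data.frame(
    genotype = rep(genotypes, each = n_reps),
    replicate = rep(seq_len(n_reps), times = length(genotypes)),
    stringsAsFactors = FALSE
  )
  df$sample_id <- paste0(df$genotype, "_r", df$replicate)
  df$run <- run
  df$tissue <- tissue
  df$role <- "inbred"
  df[, c("sample_id", "genotype", "replicate", "run", "tissue", "role")]
}

# matrix whose columns follow a toy_design: features x (genotype, rep)
design_matrix <- function(design, values) {
  m <- matrix(values, ncol = nrow(design))
  rownames(m) <- sprintf("F%03d", seq_len(nrow(m)))
  colnames(m) <- design$sample_id
  m
}

# run the full panel pipeline on a simulated panel
panel_pipeline <- function(sim, alpha = 0.05, min_hybrids = 5) {
  norm <- normalize_to_anchor(sim$matrix, sim$design, sim$config$anchor)
  fits <- lapply(seq_len(nrow(sim$cross)), function(i) {
    r <- sim$cross[i, ]
    heterosis_fit(norm, sim$design, r$hybrid, r$parent_female, r$parent_male,
                  alpha = alpha)
  })
  eh <- expression_heterosis_matrix(fits)
  th <- trait_heterosis(sim$traits, sim$cross)
  tc <- protein_trait_correlation(eh, th, min_hybrids = min_hybrids)
  list(norm = norm, fits = fits, eh = eh, th = th, tc = tc)
}

# brute-force five-way classifier: checks the five conditions in order,
# independent of classify_records()
brute_force_classify <- function(rec, alpha) {
  out <- character(nrow(rec))
  for (i in seq_len(nrow(rec))) {
    q_hp <- rec$q_hp[i]; q_lp <- rec$q_lp[i]; q_mp <- rec$q_mp[i]
    m <- rec$hybrid_mean[i]
    out[i] <-
      if (!is.na(q_hp) && q_hp <= alpha && m > rec$hp[i]) "above_HP"
      else if (!is.na(q_lp) && q_lp <= alpha && m < rec$lp[i]) "below_LP"
      else if (!is.na(q_mp) && q_mp <= alpha && m > rec$mp[i]) "between_MP_HP"
      else if (!is.na(q_mp) && q_mp <= alpha && m < rec$mp[i]) "between_LP_MP"
      else "MP"
  }
  out
}

# exact hypergeometric upper-tail p by enumeration over overlap counts
enumerate_hyper_p <- function(k, K, N, n) {
  ks <- max(0, n - (N - K)):min(K, n)
  probs <- choose(K, ks) * choose(N - K, n - ks) / choose(N, n)
  sum(probs[ks >= k])
}
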