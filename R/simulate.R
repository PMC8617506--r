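#' Configuration for the synthetic hybrid-panel generator
#'
#' Defines a panel of inbred parents and their hybrids with a known
#' dominance architecture and trait coupling, emulating a multiplexed
#' TMT-style proteomics design: every run carries replicates of a common
#' anchor genotype, replicate noise is multiplicative (log-normal), and
#' run effects are a single multiplicative factor per run.
#'
#' The generative model, per feature i, parent p, hybrid j:
#' \itemize{
#'   \item baseline log2 level `mu_i ~ Normal(10, 1)`; parent level
#'     `2^(mu_i + a_ip)` with `a_ip ~ Normal(0, sigma_g)`;
#'   \item hybrid true level `MP_ij * f_ij` with
#'     `f_ij = 1 + delta_i + beta_i * (h_j - 1) + eps_ij`,
#'     `eps_ij ~ Normal(0, sigma_c)`, floored at `f_floor`;
#'   \item observed replicate `true * 2^Normal(0, sigma_r) * run_effect`,
#'     `run_effect = 2^Normal(0, sigma_b)` per run;
#'   \item trait: inbred heights `~ Normal(height_mean, height_sd)`;
#'     hybrid height `= MP_height * h_j`, `h_j ~ Uniform(h_range)`.
#' }
#' Dominance deviations `delta_i` follow `dominance_fractions`: 0 for
#' additive features, `+/-Uniform(delta_dominant)` for dominant,
#' `+Uniform(delta_over)` for overdominant, `-Uniform(delta_over)` for
#' underdominant. The first `coupled_n` features form the trait-coupled
#' group (`beta = coupled_beta`, `delta = 0`, annotation group
#' `"coupled"`); all other features have `beta = 0` and group
#' `"uncoupled"`.
#'
#' All random deviates are drawn as standard normals/uniforms from one
#' seeded stream in a fixed order and then scaled by their sigma, so
#' setting any sigma to zero leaves every other draw bit-identical.
#'
#' @param n_features number of features (default 2000).
#' @param n_parents number of inbred parents (default 6; the default
#'   panel is all 15 pairwise crosses).
#' @param n_reps biological replicates per non-anchor genotype (default 4).
#' @param panel optional cross data frame (`hybrid`, `parent_female`,
#'   `parent_male`); default all pairwise crosses of the parents.
#' @param anchor anchor genotype, present in every run (default `"P1"`).
#' @param samples_per_run non-anchor samples per run (default 8).
#' @param anchor_per_run anchor replicates per run (default 2).
#' @param sigma_r replicate noise sd, log2 scale (default 0.15).
#' @param sigma_b run-effect sd, log2 scale (default 0.3).
#' @param sigma_g parental genetic effect sd, log2 scale (default 0.5).
#' @param dominance_fractions named fractions (additive, dominant, over,
#'   under) summing to 1.
#' @param delta_dominant,delta_over magnitude ranges for the dominance
#'   deviation on the ratio scale.
#' @param coupled_n size of the trait-coupled group (default 100).
#' @param coupled_beta trait-coupling slope (default 1).
#' @param sigma_c coupling noise sd on the ratio scale (default 0.05).
#' @param height_mean,height_sd inbred height distribution, cm.
#' @param h_range range of hybrid height heterosis `h_j` (default
#'   `c(1.2, 1.8)`).
#' @param f_floor lower floor on the heterosis factor `f_ij` (default
#'   0.05), preventing nonpositive expression.
#' @param tissue tissue label written into the design.
#' @param seed integer seed for the generator.
#' @return validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_features = 2000, n_parents = 6, n_reps = 4,
                       panel = NULL, anchor = "P1",
                       samples_per_run = 8, anchor_per_run = 2,
                       sigma_r = 0.15, sigma_b = 0.3, sigma_g = 0.5,
                       dominance_fractions = c(additive = 0.68,
                                               dominant = 0.12,
                                               over = 0.10, under = 0.10),
                       delta_dominant = c(0.05, 0.25),
                       delta_over = c(0.25, 0.6),
                       coupled_n = 100, coupled_beta = 1.0, sigma_c = 0.05,
                       height_mean = 150, height_sd = 10,
                       h_range = c(1.2, 1.8), f_floor = 0.05,
                       tissue = "seedling_leaf", seed = 1) {
  parents <- paste0("P", seq_len(n_parents))
  if (is.null(panel)) {
    pairs <- utils::combn(parents, 2)
    panel <- data.frame(hybrid = paste0(pairs[1, ], "x", pairs[2, ]),
                        parent_female = pairs[1, ],
                        parent_male = pairs[2, ],
                        stringsAsFactors = FALSE)
  }
  cfg <- list(n_features = n_features, n_parents = n_parents,
              n_reps = n_reps, panel = panel, anchor = anchor,
              samples_per_run = samples_per_run,
              anchor_per_run = anchor_per_run,
              sigma_r = sigma_r, sigma_b = sigma_b, sigma_g = sigma_g,
              dominance_fractions = dominance_fractions,
              delta_dominant = delta_dominant, delta_over = delta_over,
              coupled_n = coupled_n, coupled_beta = coupled_beta,
              sigma_c = sigma_c, height_mean = height_mean,
              height_sd = height_sd, h_range = h_range, f_floor = f_floor,
              tissue = tissue, seed = seed)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  fr <- cfg$dominance_fractions
  need <- c("additive", "dominant", "over", "under")
  if (!all(need %in% names(fr)))
    stop("dominance_fractions must name ", paste(need, collapse = ", "))
  if (abs(sum(fr) - 1) > 1e-8) stop("dominance fractions must sum to 1")
  if (any(fr < 0)) stop("dominance fractions must be nonnegative")
  for (s in c("sigma_r", "sigma_b", "sigma_g", "sigma_c"))
    if (cfg[[s]] < 0) stop(s, " must be >= 0")
  if (any(cfg$h_range <= 0) || cfg$h_range[1] > cfg$h_range[2])
    stop("h_range must be positive and nondecreasing")
  if (cfg$coupled_n > cfg$n_features)
    stop("coupled_n cannot exceed n_features")
  parents <- paste0("P", seq_len(cfg$n_parents))
  if (!cfg$anchor %in% parents)
    stop("anchor must be one of the parents")
  validate_cross(cfg$panel)
  absent <- setdiff(unique(c(cfg$panel$parent_female, cfg$panel$parent_male)),
                    parents)
  if (length(absent))
    stop("panel parent(s) not among the simulated parents: ",
         paste(absent, collapse = ", "))
  invisible(cfg)
}

#' Simulate a hybrid panel with known ground truth
#'
#' Draws a complete synthetic experiment from the generative model
#' described in [sim_config()]: abundance matrix, sample design, cross
#' panel, trait table, annotation, and a `truth` record sufficient to
#' reconstruct every emitted value exactly. Identical config and seed
#' give bit-identical output.
#'
#' @param config a [sim_config()] object.
#' @return list of class `"sim_panel"` with elements `matrix`, `design`,
#'   `cross`, `traits`, `annotation`, `truth`, `config`. `truth` holds
#'   per-feature `mu`, `parent_effects`, `mode`, `delta`, `beta`,
#'   `group`; per-hybrid `h` and the heterosis-factor matrix `f`;
#'   per-run `run_effect`; and the raw replicate-noise matrix
#'   `rep_noise`.
#' @export
simulate_panel <- function(config) {
  validate_sim_config(config)
  cfg <- config
  nf <- cfg$n_features
  np <- cfg$n_parents
  parents <- paste0("P", seq_len(np))
  hybrids <- cfg$panel$hybrid
  nh <- length(hybrids)
  features <- sprintf("F%05d", seq_len(nf))

  set.seed(cfg$seed)
  # fixed draw order; raw deviates scaled afterwards so that sigma = 0
  # does not perturb the stream
  mu <- 10 + stats::rnorm(nf)
  a <- matrix(stats::rnorm(nf * np), nf, np,
              dimnames = list(features, parents)) * cfg$sigma_g
  mode_u <- stats::runif(nf)
  sign_u <- stats::runif(nf)
  mag_u <- stats::runif(nf)
  fr <- cfg$dominance_fractions[c("additive", "dominant", "over", "under")]
  mode <- c("additive", "dominant", "over", "under")[
    findInterval(mode_u, cumsum(fr), left.open = TRUE) + 1]
  delta <- numeric(nf)
  d <- cfg$delta_dominant; o <- cfg$delta_over
  idx <- mode == "dominant"
  delta[idx] <- ifelse(sign_u[idx] < 0.5, -1, 1) *
    (d[1] + (d[2] - d[1]) * mag_u[idx])
  idx <- mode == "over"
  delta[idx] <- o[1] + (o[2] - o[1]) * mag_u[idx]
  idx <- mode == "under"
  delta[idx] <- -(o[1] + (o[2] - o[1]) * mag_u[idx])

  coupled <- seq_len(cfg$coupled_n)
  beta <- numeric(nf)
  beta[coupled] <- cfg$coupled_beta
  delta[coupled] <- 0
  mode[coupled] <- "additive"
  group <- ifelse(seq_len(nf) %in% coupled, "coupled", "uncoupled")

  h <- cfg$h_range[1] + diff(cfg$h_range) * stats::runif(nh)
  names(h) <- hybrids
  parent_height <- cfg$height_mean + cfg$height_sd * stats::rnorm(np)
  names(parent_height) <- parents

  eps <- matrix(stats::rnorm(nf * nh), nf, nh,
                dimnames = list(features, hybrids)) * cfg$sigma_c
  f <- 1 + delta + matrix(beta, nf, nh) *
    matrix(h - 1, nf, nh, byrow = TRUE) + eps
  f <- pmax(f, cfg$f_floor)

  # true levels
  parent_level <- 2^(mu + a)  # nf x np
  pf <- match(cfg$panel$parent_female, parents)
  pm <- match(cfg$panel$parent_male, parents)
  mp_level <- (parent_level[, pf, drop = FALSE] +
               parent_level[, pm, drop = FALSE]) / 2
  hybrid_level <- mp_level * f
  colnames(hybrid_level) <- hybrids
  true_level <- cbind(parent_level, hybrid_level)

  # design: non-anchor samples chunked into runs, each run carrying
  # dedicated anchor replicates (the anchor's biological replicates)
  other_geno <- c(setdiff(parents, cfg$anchor), hybrids)
  other <- data.frame(
    genotype = rep(other_geno, each = cfg$n_reps),
    replicate = rep(seq_len(cfg$n_reps), times = length(other_geno)),
    stringsAsFactors = FALSE)
  n_runs <- ceiling(nrow(other) / cfg$samples_per_run)
  runs <- sprintf("R%02d", seq_len(n_runs))
  # round-robin assignment spreads each genotype's replicates across
  # runs, so genotype is never confounded with run
  other$run <- runs[(seq_len(nrow(other)) - 1L) %% n_runs + 1L]
  anchor_df <- data.frame(
    genotype = cfg$anchor,
    replicate = seq_len(n_runs * cfg$anchor_per_run),
    run = rep(runs, each = cfg$anchor_per_run),
    stringsAsFactors = FALSE)
  design <- rbind(anchor_df, other)
  design$sample_id <- paste0(design$genotype, "_r", design$replicate)
  design$tissue <- cfg$tissue
  design$role <- ifelse(design$genotype %in% parents, "inbred", "hybrid")
  design <- design[, c("sample_id", "genotype", "replicate", "run",
                       "tissue", "role")]
  ns <- nrow(design)

  run_effect <- 2^(cfg$sigma_b * stats::rnorm(n_runs))
  names(run_effect) <- runs
  z <- matrix(stats::rnorm(nf * ns), nf, ns,
              dimnames = list(features, design$sample_id))

  value <- true_level[, design$genotype, drop = FALSE] *
    2^(cfg$sigma_r * z) *
    matrix(run_effect[design$run], nf, ns, byrow = TRUE)
  dimnames(value) <- list(features, design$sample_id)

  traits <- data.frame(
    genotype = c(parents, hybrids),
    height_cm = c(parent_height,
                  (parent_height[pf] + parent_height[pm]) / 2 * h),
    row.names = NULL, stringsAsFactors = FALSE)

  annotation <- data.frame(feature_id = features, groups = group,
                           stringsAsFactors = FALSE)

  truth <- list(mu = stats::setNames(mu, features),
                parent_effects = a,
                mode = stats::setNames(mode, features),
                delta = stats::setNames(delta, features),
                beta = stats::setNames(beta, features),
                group = stats::setNames(group, features),
                h = h, f = f,
                run_effect = run_effect,
                rep_noise = z,
                true_level = true_level)

  structure(list(matrix = value, design = design, cross = cfg$panel,
                 traits = traits, annotation = annotation,
                 truth = truth, config = cfg),
            class = "sim_panel")
}

#' Simulate a mutant that phenocopies a reference hybrid
#'
#' Models an inbred-background mutant (e.g. an ethylene-biosynthesis
#' double mutant) whose proteome mimics a hybrid's nonadditive
#' expression: for every feature nonadditive in the reference hybrid
#' (nonzero dominance deviation or trait coupling), the mutant/background
#' true ratio equals the hybrid's heterosis factor `f` with probability
#' `concordance` and its reciprocal (same magnitude, inverted direction)
#' otherwise; additive features are unchanged. Background and mutant
#' replicates share one new run with replicate noise as in the panel, so
#' the background serves as the run's anchor.
#'
#' @param sim a `sim_panel` from [simulate_panel()].
#' @param reference_hybrid hybrid label present in the panel.
#' @param concordance probability pi in \[0, 1\] of matching the hybrid's
#'   direction (default 0.95).
#' @param n_reps replicates per genotype (default: the panel's `n_reps`).
#' @param sigma_r replicate noise sd, log2 scale (default: the panel's;
#'   set 0 for the noise-free limit).
#' @param seed seed for the mutant's own draws.
#' @return list with `matrix` (features x samples, mutant plus
#'   background), `design`, `truth` (data frame `feature_id`,
#'   `nonadditive`, `ratio`, `concordant`), `mutant`, `background`.
#' @export
simulate_mutant <- function(sim, reference_hybrid, concordance = 0.95,
                            n_reps = NULL, sigma_r = NULL, seed = 1) {
  if (concordance < 0 || concordance > 1)
    stop("concordance must be in [0, 1]")
  cfg <- sim$config
  truth <- sim$truth
  if (!reference_hybrid %in% colnames(truth$f))
    stop("reference hybrid '", reference_hybrid, "' absent from the panel")
  if (is.null(n_reps)) n_reps <- cfg$n_reps
  if (is.null(sigma_r)) sigma_r <- cfg$sigma_r
  nf <- cfg$n_features
  features <- names(truth$mu)
  nonadd <- truth$delta != 0 | truth$beta != 0
  f_ref <- truth$f[, reference_hybrid]

  set.seed(seed)
  flip_u <- stats::runif(nf)
  ratio <- rep(1, nf)
  matched <- flip_u <= concordance
  ratio[nonadd & matched] <- f_ref[nonadd & matched]
  ratio[nonadd & !matched] <- 1 / f_ref[nonadd & !matched]

  background <- cfg$anchor
  mutant <- paste0("mut_", background)
  bg_level <- truth$true_level[, background]
  mut_level <- bg_level * ratio

  run <- "MR01"
  design <- data.frame(
    sample_id = c(paste0(background, "_m", seq_len(n_reps)),
                  paste0(mutant, "_r", seq_len(n_reps))),
    genotype = rep(c(background, mutant), each = n_reps),
    replicate = rep(seq_len(n_reps), 2),
    run = run, tissue = cfg$tissue,
    role = rep(c("inbred", "mutant"), each = n_reps),
    stringsAsFactors = FALSE)
  run_effect <- 2^(cfg$sigma_b * stats::rnorm(1))
  z <- matrix(stats::rnorm(nf * nrow(design)), nf, nrow(design),
              dimnames = list(features, design$sample_id))
  value <- cbind(matrix(bg_level, nf, n_reps),
                 matrix(mut_level, nf, n_reps)) *
    2^(sigma_r * z) * run_effect
  dimnames(value) <- list(features, design$sample_id)

  list(matrix = value, design = design,
       truth = data.frame(feature_id = features,
                          nonadditive = nonadd,
                          ratio = ratio,
                          concordant = ifelse(nonadd, matched, NA),
                          stringsAsFactors = FALSE),
       mutant = mutant, background = background)
}

#' Heterozygosity of RIL backcross hybrids relative to the F1
#'
#' A fully inbred recombinant inbred line (RIL) carries, at each of
#' `n_loci` independent biallelic loci, either founder allele with equal
#' probability. Backcrossing the RIL to one founder (the recurrent
#' parent) yields a hybrid heterozygous exactly at the loci where the
#' RIL carries the other founder's allele, while the F1 of the two
#' founders is heterozygous everywhere. The per-RIL heterozygous
#' fraction is therefore the RIL's non-recurrent allele fraction, with
#' expectation 1/2 — backcross hybrids are on average half as
#' heterozygous as the F1.
#'
#' @param n_loci number of independent loci per RIL (>= 1).
#' @param n_rils number of RILs (>= 1).
#' @param seed integer seed.
#' @return list with `per_ril` (heterozygous fraction of each backcross,
#'   relative to the F1's 1.0) and `mean` (panel mean).
#' @export
simulate_ril_heterozygosity <- function(n_loci, n_rils, seed = 1) {
  if (n_loci < 1 || n_rils < 1) stop("n_loci and n_rils must be >= 1")
  set.seed(seed)
  # locus-level draws: 1 = non-recurrent founder allele
  alleles <- matrix(stats::rbinom(n_rils * n_loci, 1L, 0.5),
                    nrow = n_rils, ncol = n_loci)
  per_ril <- rowMeans(alleles)
  list(per_ril = per_ril, mean = mean(per_ril))
}
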