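test_that("trait heterosis is the hybrid/midparent height ratio", {
  traits <- data.frame(genotype = c("A", "B", "H1", "H2"),
                       height_cm = c(100, 120, 165, 110))
  cross <- data.frame(hybrid = c("H1", "H2"),
                      parent_female = "A", parent_male = "B")
  th <- trait_heterosis(traits, cross)
  expect_equal(unname(th), c(1.5, 1.0), tolerance = 1e-12)
  expect_named(th, c("H1", "H2"))
  # five-hybrid hand arithmetic
  set.seed(2)
  tr5 <- data.frame(genotype = c("A", "B", paste0("X", 1:5)),
                    height_cm = c(140, 160, 170, 180, 190, 200, 210))
  cr5 <- data.frame(hybrid = paste0("X", 1:5),
                    parent_female = "A", parent_male = "B")
  expect_equal(unname(trait_heterosis(tr5, cr5)),
               c(170, 180, 190, 200, 210) / 150, tolerance = 1e-12)
  expect_error(trait_heterosis(traits, data.frame(
    hybrid = "H3", parent_female = "A", parent_male = "B")), "H3")
})

test_that("expression heterosis matrix assembles records in panel order", {
  mk <- function(hybrid, ids, ratios) data.frame(
    feature_id = ids, hybrid = hybrid, ratio_mp = ratios,
    stringsAsFactors = FALSE)
  recs <- list(mk("H1", c("F1", "F2"), c(1.2, 0.8)),
               mk("H2", c("F1", "F2"), c(1.4, 1.0)),
               mk("H3", "F1", 2.0))  # F2 absent in H3
  eh <- expression_heterosis_matrix(recs)
  expect_equal(dim(eh), c(2, 3))
  expect_identical(colnames(eh), c("H1", "H2", "H3"))
  expect_equal(eh["F1", ], c(H1 = 1.2, H2 = 1.4, H3 = 2.0))
  expect_true(is.na(eh["F2", "H3"]))
  expect_error(expression_heterosis_matrix(recs[c(1, 1)]), "duplicate")
})

test_that("per-feature Pearson correlation matches the covariance formula", {
  h <- c(1.1, 1.4, 1.2, 1.6, 1.3, 1.5)
  eh <- rbind(F1 = 2 * h + 1,        # proportional -> r = 1
              F2 = rev(sort(h)) [rank(h)],   # perfectly decreasing in h
              F3 = c(1.0, 1.2, 1.1, 1.3, NA, NA))
  colnames(eh) <- paste0("H", 1:6)
  th <- setNames(h, colnames(eh))
  tc <- protein_trait_correlation(eh, th, min_hybrids = 3)
  expect_equal(tc$r[tc$feature_id == "F1"], 1, tolerance = 1e-12)
  expect_equal(tc$r[tc$feature_id == "F2"], -1, tolerance = 1e-12)
  # hand formula on the four complete pairs of F3
  x <- c(1.0, 1.2, 1.1, 1.3); y <- h[1:4]
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(tc$r[tc$feature_id == "F3"], r_hand, tolerance = 1e-12)
  expect_equal(tc$n[tc$feature_id == "F3"], 4)
  # p-value agrees with cor.test's t transform
  ct <- cor.test(x, y)
  expect_equal(tc$p[tc$feature_id == "F3"], ct$p.value, tolerance = 1e-12)
})

test_that("correlations are invariant to unit changes and positive scaling", {
  set.seed(31)
  eh <- matrix(runif(40, 0.8, 1.8), 5, 8,
               dimnames = list(paste0("F", 1:5), paste0("H", 1:8)))
  th <- setNames(runif(8, 1.2, 1.8), colnames(eh))
  tc <- protein_trait_correlation(eh, th)
  # heights cm -> m (affine rescale)
  expect_equal(protein_trait_correlation(eh, th / 100)$r, tc$r)
  # one feature's heterosis values multiplied by a positive constant
  eh2 <- eh; eh2[3, ] <- eh2[3, ] * 7
  expect_equal(protein_trait_correlation(eh2, th)$r, tc$r)
  # zero-variance feature omitted with a recorded count
  eh3 <- eh; eh3[2, ] <- 1
  tc3 <- protein_trait_correlation(eh3, th)
  expect_false("F2" %in% tc3$feature_id)
  expect_equal(attr(tc3, "n_zero_var"), 1)
  # features below min_hybrids omitted
  eh4 <- eh; eh4[1, 4:8] <- NA
  tc4 <- protein_trait_correlation(eh4, th, min_hybrids = 5)
  expect_false("F1" %in% tc4$feature_id)
})

test_that("threshold sets and top fraction follow the declared rules", {
  tc <- data.frame(feature_id = c("Fa", "Fb", "Fc", "Fd"),
                   r = c(0.6, 0.4, -0.7, 0.6),
                   n = 15, p = 0.01, stringsAsFactors = FALSE)
  class(tc) <- c("trait_correlation", "data.frame")
  expect_identical(correlation_threshold_set(tc, 0.5, "upper"), c("Fa", "Fd"))
  expect_identical(correlation_threshold_set(tc, -0.5, "lower"), "Fc")
  expect_identical(correlation_threshold_set(tc, 1.0, "upper"), character(0))
  # ceiling rule: 100 features at 1.5% -> 2
  tc100 <- data.frame(feature_id = sprintf("F%03d", 1:100),
                      r = seq(-1, 0.98, length.out = 100), n = 15, p = 0.5)
  class(tc100) <- c("trait_correlation", "data.frame")
  expect_length(top_fraction(tc100, 0.015), 2)
  expect_length(top_fraction(tc100, 0.999), 100)
  # tie at the boundary: lexicographically smaller id included
  expect_identical(top_fraction(tc, 0.5), c("Fa", "Fd"))
})

test_that("hypergeometric enrichment equals exhaustive enumeration", {
  ann <- data.frame(feature_id = sprintf("F%02d", 1:10),
                    groups = c(rep("TPR", 5), rep("", 5)))
  universe <- ann$feature_id
  selected <- c("F01", "F02", "F03", "F04")  # k = 4 of K = 5, n = 4, N = 10
  res <- enrichment_hypergeometric(selected, ann, universe)
  expect_equal(res$p[res$group == "TPR"], 5 / 210, tolerance = 1e-12)
  expect_equal(res$p[res$group == "TPR"], enumerate_hyper_p(4, 5, 10, 4),
               tolerance = 1e-12)
  # degenerate group spanning the universe and empty selection
  ann2 <- data.frame(feature_id = universe, groups = "TPR")
  expect_equal(enrichment_hypergeometric(selected, ann2, universe)$p, 1)
  expect_equal(enrichment_hypergeometric(character(0), ann, universe)$p, 1)
  expect_error(enrichment_hypergeometric(selected, ann, character(0)), "empty")
  expect_error(enrichment_hypergeometric("Fxx", ann, universe), "subset")
})

test_that("enrichment p equals enumeration for every configuration up to N = 12", {
  for (N in c(5, 8, 12)) {
    universe <- sprintf("U%02d", seq_len(N))
    for (K in 1:N) {
      ann <- data.frame(feature_id = universe,
                        groups = c(rep("g", K), rep("", N - K)))
      members <- universe[seq_len(K)]
      others <- setdiff(universe, members)
      for (n in 1:N) {
        for (k in max(0, n - (N - K)):min(K, n)) {
          selected <- c(members[seq_len(k)], others[seq_len(n - k)])
          p <- enrichment_hypergeometric(selected, ann, universe)
          expect_equal(p$p[p$group == "g"], enumerate_hyper_p(k, K, N, n),
                       tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("group density curves are normalized, deterministic and localized", {
  tc <- data.frame(
    feature_id = sprintf("F%03d", 1:30),
    r = c(rep(0.8, 10), seq(-0.9, 0.9, length.out = 20)),
    n = 15, p = 0.5, stringsAsFactors = FALSE)
  ann <- data.frame(feature_id = tc$feature_id,
                    groups = c(rep("TPR", 10), rep("PhANG", 20)))
  dens <- correlation_density_by_group(tc, ann, c("TPR", "PhANG"))
  for (g in c("TPR", "PhANG")) {
    d <- dens[dens$group == g, ]
    expect_equal(nrow(d), 512)
    dx <- diff(d$x[1:2])
    area <- sum((d$density[-1] + d$density[-512]) / 2) * dx
    expect_equal(area, 1, tolerance = 1e-3)
  }
  # concentrated group peaks at its value
  dt <- dens[dens$group == "TPR", ]
  expect_lt(abs(dt$x[which.max(dt$density)] - 0.8), 0.05)
  # identical groups give identical curves
  ann2 <- ann; ann2$groups[ann2$groups == "PhANG"] <- "TPR2"
  ann2$groups[1:10] <- "TPR"
  dens_b <- correlation_density_by_group(tc, ann, "TPR")
  expect_identical(dens_b$density, dt$density)
  # undersized group skipped with warning
  ann3 <- data.frame(feature_id = tc$feature_id,
                     groups = c(rep("tiny", 3), rep("PhANG", 27)))
  expect_warning(d3 <- correlation_density_by_group(tc, ann3, c("tiny", "PhANG")),
                 "tiny")
  expect_false("tiny" %in% d3$group)
})

test_that("negative control separates level correlations from heterosis coupling", {
  # direct sanity: levels equal to heights -> r = 1
  lv <- matrix(rep(c(100, 120, 150, 170), each = 2), 2, 4, byrow = FALSE)
  lv <- rbind(lv, 5)  # constant feature -> omitted
  dimnames(lv) <- list(c("F1", "F2", "F3"), paste0("G", 1:4))
  hh <- setNames(c(100, 120, 150, 170), colnames(lv))
  nc <- negative_control_correlation(lv, hh)
  expect_equal(nc$r[nc$feature_id %in% c("F1", "F2")], c(1, 1))
  expect_false("F3" %in% nc$feature_id)
  # simulated panel: absolute levels of uncoupled features do not track height
  sim <- simulate_panel(sim_config(n_features = 400, seed = 19))
  pp <- panel_pipeline(sim)
  gm <- genotype_mean_matrix(pp$norm, sim$design)
  heights <- setNames(sim$traits$height_cm, sim$traits$genotype)
  ncs <- negative_control_correlation(gm, heights[colnames(gm)])
  uncoupled <- names(sim$truth$group)[sim$truth$group == "uncoupled"]
  expect_lt(median(abs(ncs$r[ncs$feature_id %in% uncoupled])), 0.3)
  expect_lt(attr(ncs, "summary")[["median_abs_r"]], 0.3)
})
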