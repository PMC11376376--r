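test_that("panel simulation is deterministic given the seed and validates its config", {
  cfg <- panel_config(n_lines = 40, markers_per_chrom = 60, seed = 21)
  g1 <- simulate_panel(cfg)
  g2 <- simulate_panel(cfg)
  expect_identical(g1$dosage, g2$dosage)
  expect_identical(g1$map, g2$map)
  expect_identical(g1$groups, g2$groups)

  expect_true(all(g1$dosage %in% c(0, 1, 2) | is.na(g1$dosage)))
  expect_true(all(tapply(g1$map$pos, g1$map$chrom, function(p) all(diff(p) > 0))))

  expect_error(panel_config(n_lines = 10, group_sizes = c(4, 4)), "group_sizes")
  expect_error(panel_config(differentiation = 1), "differentiation")
  expect_error(panel_config(maf_range = c(0, 0.6)), "maf_range")
  expect_error(panel_config(het_rate = 2), "het_rate")
})

test_that("zero differentiation leaves no group allele-frequency structure", {
  g <- simulate_panel(panel_config(n_lines = 300, n_chrom = 1,
                                   markers_per_chrom = 500,
                                   chrom_length_bp = 2.5e7,
                                   ld_block_len_bp = 5e4,
                                   differentiation = 0, het_rate = 0,
                                   missing_rate = 0, seed = 31))
  al <- g$dosage / 2
  groups <- g$groups
  # per-marker chi-square of allele counts across the 6 groups
  stats <- apply(al, 2, function(a) {
    tab <- rbind(tapply(a, groups, sum), tapply(1 - a, groups, sum))
    suppressWarnings(chisq.test(tab)$statistic)
  })
  # mean statistic close to its df under the no-structure null
  expect_gt(mean(stats) / 5, 0.85)
  expect_lt(mean(stats) / 5, 1.15)
})

test_that("group differentiation recovers the target Fst under a Hudson-type estimator", {
  g <- simulate_panel(panel_config(n_lines = 252, n_chrom = 4,
                                   markers_per_chrom = 500,
                                   chrom_length_bp = 2.5e7,
                                   ld_block_len_bp = 5e4,
                                   differentiation = 0.3, het_rate = 0,
                                   missing_rate = 0, seed = 41))
  al <- g$dosage / 2
  lv <- levels(g$groups)
  fsts <- c()
  for (i in seq_along(lv)) for (j in seq_along(lv)) if (i < j) {
    fsts <- c(fsts, oracle_hudson_fst(al[g$groups == lv[i], , drop = FALSE],
                                      al[g$groups == lv[j], , drop = FALSE]))
  }
  expect_lt(abs(mean(fsts) - 0.3), 0.05)
})

test_that("pairwise LD is strong within a block and gone across blocks", {
  g <- simulate_panel(panel_config(n_lines = 200, n_chrom = 1,
                                   markers_per_chrom = 200,
                                   chrom_length_bp = 5e6, het_rate = 0,
                                   missing_rate = 0, seed = 51))
  D <- g$dosage
  blk <- g$map$pos %/% 5e5
  r2 <- cor(D)^2
  d_idx <- abs(outer(g$map$pos, g$map$pos, "-"))
  same <- outer(blk, blk, "==")
  ut <- upper.tri(r2)
  near_in <- same & d_idx <= 2e5 & ut
  far_in <- same & d_idx > 3e5 & ut
  cross <- !same & ut
  expect_gt(mean(r2[near_in]), mean(r2[far_in]))   # decay with distance
  expect_gt(mean(r2[far_in]), mean(r2[cross]))     # and a drop across blocks
  expect_lt(mean(r2[cross]), 0.05)
})

test_that("planted architectures produce the stated genetic values", {
  g <- tiny_panel(61)
  # no effects, no variance components: constant genetic value
  pa0 <- plant_architecture(g, true_architecture(), seed = 1)
  expect_true(all(pa0$genetic_value == 0))
  expect_true(all(pa0$trait_value == 0))

  # single causal of effect 1 on homozygous dosages: two classes 2 apart
  gh <- simulate_panel(panel_config(n_lines = 60, n_chrom = 1,
                                    markers_per_chrom = 30,
                                    chrom_length_bp = 2e6, het_rate = 0,
                                    missing_rate = 0, seed = 62))
  mafs <- apply(gh$dosage, 2, function(x) min(mean(x) / 2, 1 - mean(x) / 2))
  m <- names(which(mafs > 0.2))[1]
  pa1 <- plant_architecture(gh, true_architecture(
    local = list(marker = m, effect = 1)))
  vals <- sort(unique(round(pa1$genetic_value, 12)))
  expect_identical(length(vals), 2L)
  expect_equal(diff(vals), 2)

  expect_error(plant_architecture(g, true_architecture(
    local = list(marker = "nope", effect = 1))), "unknown causal marker")
})

test_that("a causal sized for 50% trait variance realizes that share", {
  r2s <- sapply(1:50, function(s) {
    g <- simulate_panel(panel_config(n_lines = 200, n_chrom = 1,
                                     markers_per_chrom = 40,
                                     chrom_length_bp = 2e6, seed = s))
    D <- eqtlpanel:::impute_dosage(g$dosage)
    p <- colMeans(D) / 2
    maf <- pmin(p, 1 - p)
    j <- which.min(abs(maf - 0.32))
    eff <- effect_for_variance_fraction(0.5, maf[j], other_var = 1)
    arch <- true_architecture(local = list(marker = colnames(D)[j],
                                           effect = eff),
                              residual_var_line = 1)
    pa <- plant_architecture(g, arch, seed = s + 100)
    summary(lm(pa$trait_value ~ D[, j]))$r.squared
  })
  expect_lt(abs(mean(r2s) - 0.5), 0.07)
})

test_that("simulated Ct tables follow the delta-Ct generative model", {
  lines <- sprintf("L%02d", 1:6)
  tv <- list(PIPsim = setNames(rep(0, 6), lines))
  # no noise, zero genetics: every Ct equals its baseline
  a0 <- assay_artifact_config(bio_sd = 0, tech_sd = 0)
  ct <- simulate_ct(tv, assay = a0, seed = 1)
  expect_true(all(ct$ct[ct$gene == "PIPsim"] == 25))
  expect_true(all(ct$ct[ct$gene != "PIPsim"] == 20))
  expect_error(simulate_ct(tv, assay = a0, ref_genes = "Act1"),
               "at least 2 reference genes")
  expect_error(assay_artifact_config(base_ct = c(PIPsim = 40)), "15, 35")

  # a reference gene carrying a genetic effect biases every target's
  # relative expression in carrier lines, even with identical target Cts
  g <- tiny_panel(71, n_lines = 6, n_chrom = 1, m = 10)
  rownames(g$dosage) <- lines
  mk <- colnames(g$dosage)[1]
  g$dosage[, mk] <- c(2, 2, 2, 0, 0, 0)
  a1 <- assay_artifact_config(bio_sd = 0, tech_sd = 0,
                              ref_gene_effect = list(gene = "Ubi2",
                                                     marker = mk, effect = 1))
  ct1 <- simulate_ct(tv, g, a1, seed = 1)
  expr <- relative_expression(ct1, c("Act1", "Ef1a", "Ubi2"))
  by_line <- tapply(expr$log2_rel_expr, expr$line, mean)
  expect_true(all(ct1$ct[ct1$gene == "PIPsim"] == 25))  # targets identical
  expect_equal(as.numeric(by_line[lines[1:3]] - by_line[lines[4:6]]),
               rep(-1 / 3, 3), tolerance = 1e-12)
})

test_that("Ct simulation determinism and planted repeatability are recovered downstream", {
  g <- tiny_panel(81, n_lines = 100, n_chrom = 1, m = 10)
  tv <- list(PIPsim = setNames(rnorm(100), rownames(g$dosage)))
  c1 <- simulate_ct(tv, g, seed = 5)
  c2 <- simulate_ct(tv, g, seed = 5)
  expect_identical(c1, c2)

  # plant sigma2_g so that Vg / (Vg + Ve_eff / 3) = 0.8, with Ve_eff the
  # effective residual variance of the delta-Ct readout
  ve <- expression_residual_variance(0.4, 0.15, n_tech = 2, n_ref = 3)
  s2g <- 0.8 / (1 - 0.8) * ve / 3
  H <- sapply(1:200, function(s) {
    set.seed(s)
    gv <- list(PIPsim = setNames(rnorm(100, sd = sqrt(s2g)),
                                 rownames(g$dosage)))
    ct <- simulate_ct(gv, seed = s + 20000L)
    heritability(relative_expression(ct, c("Act1", "Ef1a", "Ubi2")), "PIPsim")$H
  })
  expect_lt(abs(mean(H) - 0.8), 0.05)
})
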