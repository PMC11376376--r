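test_that("kinship matches the explicit double-loop definition and handles edge cases", {
  set.seed(17)
  g <- tiny_panel(17, n_lines = 50, n_chrom = 2, m = 250)
  K <- compute_kinship(g)
  expect_lt(max(abs(K - oracle_kinship(g$dosage))), 1e-10)
  expect_true(isSymmetric(K))
  expect_gt(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values), -1e-8)

  # two identical lines: equal rows, and K[i,i] == K[i,j]
  d <- g$dosage
  d[2, ] <- d[1, ]
  g2 <- genotype_matrix(d, g$map)
  K2 <- compute_kinship(g2)
  expect_equal(K2[1, ], K2[2, ])
  expect_equal(K2[1, 1], K2[1, 2])

  # excluding every chromosome leaves nothing
  expect_error(compute_kinship(g, exclude_chrom = c("1", "2")),
               "fewer than 2 polymorphic markers")
})

test_that("null REML fit matches a dense-likelihood oracle and flags degenerate traits", {
  set.seed(23)
  g <- tiny_panel(23, n_lines = 60, n_chrom = 2, m = 100)
  K <- compute_kinship(g)
  L <- chol(K + diag(1e-6, 60))
  y <- setNames(drop(crossprod(L, rnorm(60))) * 0.8 + rnorm(60),
                rownames(g$dosage))
  vc <- fit_null(y, K)
  # dense REML log-likelihood at the fitted variance components
  n <- 60; X <- matrix(1, n, 1)
  V <- vc$sigma2_g * K + vc$sigma2_e * diag(n)
  Vi <- solve(V)
  b <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  r <- y - drop(X %*% b)
  ll_dense <- -0.5 * (drop(t(r) %*% Vi %*% r) +
                        determinant(V)$modulus +
                        determinant(t(X) %*% Vi %*% X)$modulus -
                        determinant(crossprod(X))$modulus +
                        (n - 1) * log(2 * pi))
  expect_equal(vc$loglik_reml, as.numeric(ll_dense), tolerance = 1e-6)
  # the optimum is a maximum over the delta grid
  expect_true(vc$sigma2_g >= 0 && vc$sigma2_e >= 0)

  vc0 <- fit_null(setNames(rep(2, 60), rownames(g$dosage)), K)
  expect_true(vc0$degenerate)
  expect_equal(vc0$sigma2_g, 0)
})

test_that("pure-noise traits yield near-zero genetic variance", {
  g <- simulate_panel(panel_config(n_lines = 200, n_chrom = 2,
                                   markers_per_chrom = 150,
                                   ld_block_len_bp = 5e4, seed = 29))
  K <- compute_kinship(g)
  ratio <- sapply(1:60, function(s) {
    set.seed(s)
    y <- setNames(rnorm(200), rownames(g$dosage))
    vc <- fit_null(y, K)
    vc$sigma2_g / vc$sigma2_e
  })
  expect_gt(mean(ratio < 0.05), 0.8)
})

test_that("planted variance ratio sigma2_g = sigma2_e is recovered by the null fit", {
  g <- simulate_panel(panel_config(n_lines = 200, n_chrom = 2,
                                   markers_per_chrom = 150,
                                   ld_block_len_bp = 5e4, seed = 30))
  K <- compute_kinship(g)
  L <- chol(K + diag(1e-8, 200))
  h2 <- sapply(1:60, function(s) {
    set.seed(s)
    # draw y with Var = 1 * K + 1 * I, i.e. sigma2_g = sigma2_e = 1
    y <- setNames(drop(crossprod(L, rnorm(200))) + rnorm(200),
                  rownames(g$dosage))
    vc <- fit_null(y, K)
    vc$sigma2_g / (vc$sigma2_g + vc$sigma2_e)
  })
  expect_lt(abs(mean(h2) - 0.5), 0.05)
})

test_that("with identity kinship the scan reduces to ordinary least squares", {
  set.seed(37)
  g <- tiny_panel(37, n_lines = 80, n_chrom = 2, m = 60)
  y <- setNames(rnorm(80), rownames(g$dosage))
  K <- diag(80); dimnames(K) <- list(names(y), names(y))
  sc <- gwas_scan(y, g, kinship_set(K), scan_config(maf_min = 0.05))
  D <- eqtlpanel:::impute_dosage(g$dosage)
  for (i in sample(nrow(sc), 10)) {
    fit <- summary(lm(y ~ D[, sc$marker[i]]))
    expect_equal(sc$p[i], fit$coefficients[2, 4], tolerance = 1e-10)
    expect_equal(sc$beta[i], fit$coefficients[2, 1], tolerance = 1e-10)
    expect_equal(sc$r2_lr[i], fit$r.squared, tolerance = 1e-10)
  }
})

test_that("the spectral shortcut equals the dense GLS oracle", {
  for (s in 1:3) {
    g <- simulate_panel(panel_config(n_lines = 50, n_chrom = 3,
                                     markers_per_chrom = 100,
                                     chrom_length_bp = 1e7, seed = s))
    pa <- plant_architecture(g, true_architecture(polygenic_var = 0.5,
                                                  residual_var_line = 0.5),
                             seed = s + 50)
    y <- setNames(pa$trait_value, pa$line)
    kin <- loco_kinship(g)
    sc <- gwas_scan(y, g, kin)
    for (cc in unique(sc$chrom)) {
      K <- kin$loco[[cc]]
      vc <- fit_null(y, K)
      idx <- sc$chrom == cc
      D <- eqtlpanel:::impute_dosage(g$dosage[, sc$marker[idx], drop = FALSE])
      o <- oracle_gls_scan(y, matrix(1, 50, 1), D, K, vc$sigma2_g, vc$sigma2_e)
      expect_lt(max(abs(sc$p[idx] - o$p) / o$p), 1e-8)
      expect_lt(max(abs(sc$beta[idx] - o$beta)), 1e-8)
    }
  }
})

test_that("p-values are invariant to affine transformation of the trait", {
  g <- tiny_panel(43, n_lines = 70, n_chrom = 2, m = 80)
  pa <- plant_architecture(g, true_architecture(polygenic_var = 0.5,
                                                residual_var_line = 0.5),
                           seed = 43)
  y <- setNames(pa$trait_value, pa$line)
  kin <- loco_kinship(g)
  s1 <- gwas_scan(y, g, kin)
  s2 <- gwas_scan(3 * y + 7, g, kin)
  expect_equal(s1$p, s2$p, tolerance = 1e-6)
})

test_that("null p-values are uniform when nothing is planted", {
  pall <- c()
  for (s in 1:5) {
    g <- simulate_panel(panel_config(n_lines = 100, n_chrom = 5,
                                     markers_per_chrom = 80,
                                     ld_block_len_bp = 5e4, seed = s))
    y <- setNames(rnorm(100), rownames(g$dosage))
    pall <- c(pall, gwas_scan(y, g)$p)
  }
  expect_gt(suppressWarnings(ks.test(pall, "punif")$p.value), 0.01)
})

test_that("per-marker REML refitting agrees with the once-per-chromosome approximation", {
  # with a strong planted signal the approximation is slightly conservative
  # (the null fit absorbs part of the marker variance into the polygenic
  # term); exact refitting can only gain significance, and the two stay
  # within a modest relative margin
  for (s in c(3, 5)) {
    sc0 <- scenario_local_eqtl(s, n_lines = 120, n_chrom = 2,
                               markers_per_chrom = 60, chrom_length_bp = 5e6)
    kin <- loco_kinship(sc0$geno)
    fast <- gwas_scan(sc0$trait, sc0$geno, kin)
    slow <- gwas_scan(sc0$trait, sc0$geno, kin, refit = TRUE)
    j <- match(sc0$causal_marker, fast$marker)
    js <- match(sc0$causal_marker, slow$marker)
    expect_false(is.na(j))
    expect_gte(slow$logp[js], fast$logp[j] - 0.05)
    expect_lt(abs(slow$logp[js] - fast$logp[j]), 0.15 * max(fast$logp[j], 1))
  }
})

test_that("conditional scans mask the covariate marker and require known ids", {
  sc0 <- scenario_local_eqtl(5, n_lines = 100, n_chrom = 2,
                             markers_per_chrom = 60, chrom_length_bp = 5e6)
  kin <- loco_kinship(sc0$geno)
  cs <- conditional_scan(sc0$trait, sc0$geno, kin, sc0$causal_marker)
  row <- cs[cs$marker == sc0$causal_marker, ]
  expect_true(is.na(row$p) && is.na(row$beta))  # flagged missing, not dropped
  expect_error(conditional_scan(sc0$trait, sc0$geno, kin, "nope"),
               "unknown covariate")
})

test_that("a covariate unrelated to trait and markers leaves other tests essentially unchanged", {
  set.seed(47)
  n <- 300
  g <- simulate_panel(panel_config(n_lines = n, n_chrom = 2,
                                   markers_per_chrom = 30,
                                   chrom_length_bp = 5e6,
                                   ld_block_len_bp = 1e4, seed = 47))
  y <- setNames(rnorm(n), rownames(g$dosage))
  K <- diag(n); dimnames(K) <- list(names(y), names(y))
  base <- gwas_scan(y, g, kinship_set(K))
  # condition on a chromosome-1 marker; inspect chromosome-2 markers, which
  # carry no LD with it. The covariate still costs one residual df, so
  # p-values move by O(1/n), not by zero.
  cov_marker <- base$marker[base$chrom == "1"][1]
  cond <- conditional_scan(y, g, kinship_set(K), cov_marker)
  common <- base$marker[base$chrom == "2"]
  expect_lt(max(abs(base$p[match(common, base$marker)] -
                      cond$p[match(common, cond$marker)])), 0.05)
})

test_that("subpanel scans re-derive everything on the retained lines", {
  sc0 <- scenario_local_eqtl(7, n_lines = 100, n_chrom = 2,
                             markers_per_chrom = 60, chrom_length_bp = 5e6)
  full <- gwas_scan(sc0$trait, sc0$geno)
  sub_all <- subpanel_scan(sc0$trait, sc0$geno, rownames(sc0$geno$dosage))
  expect_equal(full$p, sub_all$p, tolerance = 1e-12)
  expect_error(subpanel_scan(sc0$trait, sc0$geno,
                             rownames(sc0$geno$dosage)[1:10]),
               "at least 30")
})

test_that("likelihood-ratio variance explained behaves at its limits", {
  expect_equal(r2_lr(10, 10, 100), 0)
  expect_equal(r2_lr(5, 9, 100), 0)   # clipped at zero
  expect_gt(r2_lr(50, 10, 100), 0.5)
  # recovery of a planted marker R2 ~ 0.5 through the mixed-model scan
  r2s <- sapply(1:20, function(s) {
    sc0 <- scenario_local_eqtl(s, n_lines = 120, n_chrom = 2,
                               markers_per_chrom = 60, chrom_length_bp = 5e6)
    scn <- gwas_scan(sc0$trait, sc0$geno)
    scn$r2_lr[match(sc0$causal_marker, scn$marker)]
  })
  expect_lt(abs(mean(r2s, na.rm = TRUE) - 0.5), 0.08)
})
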