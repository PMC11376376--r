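test_that("kinship-corrected LD equals classical r2 at identity kinship and matches the Cholesky oracle", {
  set.seed(61)
  n <- 50
  a <- sample(0:2, n, TRUE)
  b <- sample(0:2, n, TRUE)
  K <- diag(n)
  expect_equal(kinship_corrected_r2(a, b, K), cor(a, b)^2, tolerance = 1e-12)
  expect_equal(kinship_corrected_r2(a, a, K), 1)

  g <- tiny_panel(62, n_lines = 50, n_chrom = 2, m = 120)
  Ks <- compute_kinship(g)
  D <- eqtlpanel:::impute_dosage(g$dosage[, 1:12])
  poly <- apply(D, 2, function(x) var(x) > 0)
  D <- D[, poly]
  for (j in 2:ncol(D)) {
    expect_equal(kinship_corrected_r2(D[, 1], D[, j], Ks),
                 oracle_chol_r2k(D[, 1], D[, j], Ks), tolerance = 1e-8)
  }
  # in [0, 1] always
  vals <- sapply(2:ncol(D), function(j) kinship_corrected_r2(D[, 1], D[, j], Ks))
  expect_true(all(vals >= 0 & vals <= 1))
})

make_block_panel <- function() {
  # 5 perfect-copy markers (a haplotype block) flanked by independent ones
  set.seed(63)
  n <- 80
  block <- sample(0:1, n, TRUE) * 2
  cols <- cbind(replicate(3, sample(0:1, n, TRUE) * 2),
                replicate(5, block),
                replicate(3, sample(0:1, n, TRUE) * 2))
  pos <- c(1e5, 2e5, 3e5, 4e5, 4.5e5, 5e5, 5.5e5, 6e5, 7e5, 8e5, 9e5)
  map <- data.frame(marker = sprintf("M%02d", 1:11), chrom = "1", pos = pos)
  dimnames(cols) <- list(sprintf("L%02d", 1:n), map$marker)
  genotype_matrix(cols, map)
}

test_that("LD windows span exactly a perfect-copy block and clamp degenerate cases", {
  g <- make_block_panel()
  K <- diag(80); dimnames(K) <- list(rownames(g$dosage), rownames(g$dosage))
  w <- ld_window(g, "M06", K, ld_params(min_run = 3))
  expect_equal(w$start, 4e5)
  expect_equal(w$end, 6e5)

  # focal marker with no correlated neighbor: degenerate [pos, pos]
  w2 <- ld_window(g, "M01", K, ld_params())
  expect_equal(w2$start, 1e5)
  expect_equal(w2$end, 1e5)
  # never beyond the chromosome's markers
  expect_gte(w2$start, 1)

  # monomorphic focal marker errors
  d <- g$dosage; d[, "M02"] <- 0
  g3 <- genotype_matrix(d, g$map)
  expect_error(ld_window(g3, "M02", K), "monomorphic")
})

test_that("LD windows agree with a brute-force application of the stop rule", {
  g <- tiny_panel(64, n_lines = 100, n_chrom = 1, m = 100, chrom_len = 5e6)
  K <- compute_kinship(g)
  params <- ld_params(r2k_threshold = 0.1, scan_radius_bp = 1.5e6, min_run = 2)
  Wd <- eqtlpanel:::whitened_dosages(g, g$map$marker, K)
  focals <- g$map$marker[c(10, 40, 75)]
  w <- ld_windows(g, focals, K, params)
  for (i in seq_along(focals)) {
    fi <- match(focals[i], g$map$marker)
    r2 <- eqtlpanel:::r2k_profile(Wd, fi)
    o <- oracle_ld_window(g$map$pos, r2, fi, params$r2k_threshold,
                          params$scan_radius_bp, params$min_run)
    expect_equal(unname(w$start[i]), unname(o["start"]))
    expect_equal(unname(w$end[i]), unname(o["end"]))
  }
})

test_that("eQTL grouping merges overlapping windows transitively with positional tie-breaks", {
  rec <- data.frame(marker = c("a", "b", "c"), chrom = "1",
                    pos = c(150, 200, 550), logp = c(6, 7, 8),
                    beta = 1, maf = 0.3, r2_lr = 0.1)
  win <- data.frame(marker = c("a", "b", "c"), chrom = "1",
                    start = c(100, 150, 500), end = c(200, 300, 600))
  eq <- group_eqtls(rec, win)
  expect_equal(nrow(eq), 2L)
  expect_equal(sort(eq$start), c(100, 500))
  expect_equal(sort(eq$end), c(300, 600))

  # logp tie: the smaller physical position becomes lead
  rec2 <- data.frame(marker = c("x", "y"), chrom = "1", pos = c(120, 110),
                     logp = c(9, 9), beta = 1, maf = 0.3, r2_lr = 0.2)
  win2 <- data.frame(marker = c("x", "y"), chrom = "1",
                     start = c(100, 100), end = c(200, 200))
  eq2 <- group_eqtls(rec2, win2)
  expect_equal(eq2$lead_marker, "y")

  expect_equal(nrow(group_eqtls(rec[0, ], win[0, ])), 0L)
})

test_that("random window sets group identically to a union-find oracle and stay disjoint", {
  set.seed(65)
  n <- 200
  start <- sample.int(1e6, n)
  width <- sample.int(5e4, n)
  rec <- data.frame(marker = sprintf("m%03d", 1:n),
                    chrom = sample(c("1", "2"), n, TRUE),
                    pos = start + width %/% 2,
                    logp = runif(n, 5, 30), beta = 0, maf = 0.2, r2_lr = 0)
  win <- data.frame(marker = rec$marker, chrom = rec$chrom,
                    start = start, end = start + width)
  eq <- group_eqtls(rec, win)
  memb <- attr(eq, "members")
  grp_o <- oracle_interval_groups(win$chrom, win$start, win$end)
  expect_equal(nrow(eq), length(unique(grp_o)))
  # identical partitions
  part_pkg <- lapply(memb, sort)
  part_or <- lapply(split(rec$marker, grp_o), sort)
  expect_equal(sort(unname(vapply(part_pkg, paste, "", collapse = ","))),
               sort(unname(vapply(part_or, paste, "", collapse = ","))))
  # output intervals pairwise disjoint per chromosome
  for (cc in unique(eq$chrom)) {
    e <- eq[eq$chrom == cc, ]
    e <- e[order(e$start), ]
    if (nrow(e) > 1) expect_true(all(e$start[-1] > e$end[-nrow(e)]))
  }
})

test_that("local/distant classification requires strict containment of the transcribed gene", {
  gene <- gene_model("PIP2;5", "2", 29279000, 29282000)
  expect_true(classify_local_distant("2", 29137698, 29507155, gene))
  expect_false(classify_local_distant("3", 29137698, 29507155, gene))
  # partial boundary overlap is distant
  expect_false(classify_local_distant("2", 29280000, 29507155, gene))
})

test_that("colocalization uses closed-interval overlap and matches brute force", {
  a <- data.frame(eqtl_id = "A1", chrom = "1", start = 100, end = 300)
  b <- data.frame(eqtl_id = "B1", chrom = "1", start = 300, end = 400)
  expect_equal(nrow(colocalize(a, b)), 1L)  # share exactly bp 300
  b2 <- data.frame(eqtl_id = "B2", chrom = "2", start = 100, end = 400)
  expect_equal(nrow(colocalize(a, b2)), 0L)

  set.seed(66)
  mk <- function(k, pre) data.frame(eqtl_id = paste0(pre, 1:k),
                                    chrom = sample(c("1", "2"), k, TRUE),
                                    start = (s <- sample.int(1e5, k)),
                                    end = s + sample.int(2e4, k))
  A <- mk(40, "A"); B <- mk(40, "B")
  got <- colocalize(A, B)
  want <- 0
  for (i in 1:40) for (j in 1:40) {
    if (A$chrom[i] == B$chrom[j] && A$start[i] <= B$end[j] &&
        B$start[j] <= A$end[i]) want <- want + 1
  }
  expect_equal(nrow(got), want)
})

test_that("haplotype concordance reproduces the published MITE table and its symmetries", {
  tb <- pip25_polymorphism_table()
  alle <- setNames(tb$lead_snp_dosage, tb$accession)
  mite <- setNames(tb$mite_indel, tb$accession)
  conc <- haplotype_concordance(alle, mite, carrier_class = 0)
  expect_equal(conc$n, 14L)
  expect_equal(conc$discordant, "B100")
  expect_equal(conc$excluded_het, "B97")
  expect_equal(conc$n_concordant, 13L)

  # perfect mapping scores 1; inverting the orientation scores 0
  a <- setNames(c(0, 0, 2, 2), paste0("L", 1:4))
  p <- setNames(c(TRUE, TRUE, FALSE, FALSE), names(a))
  expect_equal(haplotype_concordance(a, p, 0)$concordance, 1)
  expect_equal(haplotype_concordance(a, p, 2)$concordance, 0)
  expect_error(haplotype_concordance(a, setNames(p, paste0("X", 1:4))),
               "no lines shared")
})
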