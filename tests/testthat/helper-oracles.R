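# Independent oracles used across the suite. These deliberately take the
# slow, explicit route (dense solves, double loops, pairwise checks) so the
# fast implementations are validated against the definitions.

# Dense GLS association statistics: beta, F and p for each column of G
# given V = sigma2_g * K + sigma2_e * I, with explicit matrix inversion.
oracle_gls_scan <- function(y, X0, G, K, sigma2_g, sigma2_e) {
  n <- length(y)
  V <- sigma2_g * K + sigma2_e * diag(n)
  Vi <- solve(V)
  p0 <- ncol(X0)
  out <- data.frame(beta = numeric(ncol(G)), Fstat = numeric(ncol(G)),
                    p = numeric(ncol(G)))
  b0 <- solve(t(X0) %*% Vi %*% X0, t(X0) %*% Vi %*% y)
  r0 <- y - X0 %*% b0
  rss0 <- drop(t(r0) %*% Vi %*% r0)
  for (j in seq_len(ncol(G))) {
    X <- cbind(X0, G[, j])
    XtViX <- t(X) %*% Vi %*% X
    b <- solve(XtViX, t(X) %*% Vi %*% y)
    r <- y - X %*% b
    rss1 <- drop(t(r) %*% Vi %*% r)
    df <- n - p0 - 1
    Fs <- (rss0 - rss1) / (rss1 / df)
    out$beta[j] <- b[p0 + 1]
    out$Fstat[j] <- Fs
    out$p[j] <- pf(Fs, 1, df, lower.tail = FALSE)
  }
  out
}

# Naive O(n^2 m) centered cross-product kinship.
oracle_kinship <- function(X) {
  X <- eqtlpanel:::impute_dosage(X)
  p <- colMeans(X) / 2
  keep <- p > 0 & p < 1
  X <- X[, keep, drop = FALSE]; p <- p[keep]
  n <- nrow(X)
  K <- matrix(0, n, n)
  denom <- 2 * sum(p * (1 - p))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    K[i, j] <- sum((X[i, ] - 2 * p) * (X[j, ] - 2 * p)) / denom
  }
  dimnames(K) <- list(rownames(X), rownames(X))
  K
}

# Hudson-type Fst for two groups of haploid allele frequencies, ratio of
# averages across markers.
oracle_hudson_fst <- function(a1, a2) {
  p1 <- colMeans(a1); p2 <- colMeans(a2)
  n1 <- nrow(a1); n2 <- nrow(a2)
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  sum(num) / sum(den)
}

# Method-of-moments (balanced one-way ANOVA) repeatability.
oracle_mom_heritability <- function(d, n_rep) {
  A <- anova(lm(value ~ line, d))
  MSB <- A["line", "Mean Sq"]; MSW <- A["Residuals", "Mean Sq"]
  Vg <- max((MSB - MSW) / n_rep, 0)
  list(Vg = Vg, Ve = MSW, H = Vg / (Vg + MSW / n_rep))
}

# Brute-force transitive grouping of intervals by pairwise overlap
# (union-find), per chromosome.
oracle_interval_groups <- function(chrom, start, end) {
  n <- length(start)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && chrom[i] == chrom[j] &&
        start[i] <= end[j] && start[j] <= end[i]) {
      parent[find(i)] <- find(j)
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# Brute-force LD window by direct application of the stop rule.
oracle_ld_window <- function(pos, r2, focal_idx, threshold, radius, min_run) {
  lo <- focal_idx; run <- 0
  for (i in rev(seq_len(focal_idx - 1))) {
    if (abs(pos[i] - pos[focal_idx]) > radius) break
    if (!is.na(r2[i]) && r2[i] >= threshold) { lo <- i; run <- 0 }
    else { run <- run + 1; if (run >= min_run) break }
  }
  hi <- focal_idx; run <- 0
  for (i in seq(focal_idx + 1, length.out = length(pos) - focal_idx)) {
    if (abs(pos[i] - pos[focal_idx]) > radius) break
    if (!is.na(r2[i]) && r2[i] >= threshold) { hi <- i; run <- 0 }
    else { run <- run + 1; if (run >= min_run) break }
  }
  c(start = pos[lo], end = pos[hi])
}

# GLS correlation squared after whitening by Cholesky of (K_psd + eps*I).
oracle_chol_r2k <- function(a, b, K, eps = 1e-6) {
  e <- eigen(K, symmetric = TRUE)
  Kf <- e$vectors %*% (pmax(e$values, 0) * t(e$vectors)) +
    diag(eps * max(e$values, 1), nrow(K))
  Li <- solve(t(chol(Kf)))
  wa <- Li %*% a; wb <- Li %*% b; w1 <- Li %*% rep(1, length(a))
  ra <- wa - w1 * sum(w1 * wa) / sum(w1^2)
  rb <- wb - w1 * sum(w1 * wb) / sum(w1^2)
  sum(ra * rb)^2 / (sum(ra^2) * sum(rb^2))
}

# Small deterministic panel for quick structural tests.
tiny_panel <- function(seed = 11, n_lines = 60, n_chrom = 2, m = 80,
                       chrom_len = 5e6) {
  simulate_panel(panel_config(n_lines = n_lines, n_chrom = n_chrom,
                              markers_per_chrom = m,
                              chrom_length_bp = chrom_len, seed = seed))
}
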