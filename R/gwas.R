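#' Scan configuration
#'
#' @param maf_min minor-allele-frequency filter; markers with
#'   `MAF <= maf_min` are skipped (strictly greater than the cutoff is
#'   required, default 0.05).
#' @param logp_threshold significance threshold on `-log10(p)` (default 5).
#' @param covariates character vector of marker ids whose (mean-imputed)
#'   dosages enter the fixed-effect design of every test (conditional scan).
#' @param lines optional character vector restricting the scan to a subset
#'   of lines.
#' @param effect_allele `"alt"` (default) reports the additive effect per
#'   copy of the alternative allele; `"ref"` flips the sign so the effect is
#'   per copy of the reference allele.
#' @return A `scan_config` list.
#' @export
scan_config <- function(maf_min = 0.05, logp_threshold = 5,
                        covariates = character(), lines = NULL,
                        effect_allele = c("alt", "ref")) {
  if (maf_min < 0 || maf_min >= 0.5) stop("`maf_min` must be in [0, 0.5)", call. = FALSE)
  if (logp_threshold <= 0) stop("`logp_threshold` must be > 0", call. = FALSE)
  structure(list(maf_min = maf_min, logp_threshold = logp_threshold,
                 covariates = covariates, lines = lines,
                 effect_allele = match.arg(effect_allele)),
            class = "scan_config")
}

#' REML variance components of the null mixed model
#'
#' Fits `y = X b + g + e` with `g ~ N(0, sigma2_g K)` and
#' `e ~ N(0, sigma2_e I)` by restricted maximum likelihood, via a single
#' eigendecomposition of `K` and a 1-D optimization of the variance ratio
#' `delta = sigma2_e / sigma2_g` over `log(delta) in [-12, 12]`
#' (64-point grid initialization followed by local refinement). The fit is
#' deterministic.
#'
#' @param y named numeric trait vector (one value per line).
#' @param K kinship matrix covering the lines of `y`.
#' @param X optional fixed-covariate matrix (an intercept is always added).
#' @return list of class `variance_components` with `sigma2_g`, `sigma2_e`,
#'   `delta`, `loglik_reml`, `converged`, `degenerate` and the
#'   eigendecomposition reused by the scan.
#' @export
fit_null <- function(y, K, X = NULL) {
  if (is.null(names(y))) stop("`y` must be named by line", call. = FALSE)
  y <- y[!is.na(y)]
  lines <- names(y)
  if (!all(lines %in% rownames(K)))
    stop("kinship does not cover all trait lines", call. = FALSE)
  K <- K[lines, lines, drop = FALSE]
  n <- length(y)
  X <- if (is.null(X)) matrix(1, n, 1, dimnames = list(lines, "(Intercept)"))
       else cbind("(Intercept)" = 1, as.matrix(X)[lines, , drop = FALSE])
  p <- ncol(X)
  if (qr(X)$rank < p) stop("fixed-effect design is rank deficient", call. = FALSE)

  eig <- eigen(K, symmetric = TRUE)
  if (min(eig$values) < -1e-8 * max(abs(eig$values), 1))
    stop("kinship matrix is not positive semi-definite within tolerance",
         call. = FALSE)
  d <- pmax(eig$values, 0)
  U <- eig$vectors
  yr <- drop(crossprod(U, y))
  Xr <- crossprod(U, X)

  if (stats::var(y) == 0) {
    out <- list(sigma2_g = 0, sigma2_e = 0, delta = NA_real_,
                loglik_reml = NA_real_, converged = FALSE, degenerate = TRUE,
                lines = lines, eig = list(values = d, vectors = U),
                n = n, p = p)
    class(out) <- "variance_components"
    return(out)
  }

  ldetXX <- determinant(crossprod(X), logarithm = TRUE)$modulus
  reml <- function(logdelta) {
    delta <- exp(logdelta)
    w <- 1 / (d + delta)
    XtWX <- crossprod(Xr, Xr * w)
    beta <- solve(XtWX, crossprod(Xr, yr * w))
    r <- yr - drop(Xr %*% beta)
    rss <- sum(w * r^2)
    s2 <- rss / (n - p)
    as.numeric(-0.5 * ((n - p) * (log(2 * pi * s2) + 1) + sum(log(d + delta)) +
                         determinant(XtWX, logarithm = TRUE)$modulus - ldetXX))
  }
  grid <- seq(-12, 12, length.out = 64)
  ll <- vapply(grid, reml, numeric(1))
  i <- which.max(ll)
  lo <- grid[max(i - 1, 1)]; hi <- grid[min(i + 1, length(grid))]
  opt <- stats::optimize(reml, c(lo, hi), maximum = TRUE, tol = 1e-8)
  logdelta <- opt$maximum
  delta <- exp(logdelta)
  w <- 1 / (d + delta)
  XtWX <- crossprod(Xr, Xr * w)
  beta <- solve(XtWX, crossprod(Xr, yr * w))
  rss <- sum(w * (yr - drop(Xr %*% beta))^2)
  sigma2_g <- rss / (n - p)
  out <- list(sigma2_g = sigma2_g, sigma2_e = delta * sigma2_g, delta = delta,
              loglik_reml = opt$objective,
              converged = is.finite(opt$objective) && abs(logdelta) < 12,
              degenerate = FALSE, lines = lines,
              eig = list(values = d, vectors = U), n = n, p = p)
  class(out) <- "variance_components"
  out
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("variance components: sigma2_g = %.4g, sigma2_e = %.4g (delta = %.4g)\n",
              x$sigma2_g, x$sigma2_e, x$delta))
  if (x$degenerate) cat("(degenerate fit: constant trait)\n")
  invisible(x)
}

#' Heritability-style variance ratio of a null fit
#'
#' @param vc a `variance_components` object from [fit_null()].
#' @return `sigma2_g / (sigma2_g + sigma2_e)`, or 0 for a degenerate fit.
#' @export
h2_from_vc <- function(vc) {
  tot <- vc$sigma2_g + vc$sigma2_e
  if (!is.finite(tot) || tot <= 0) return(0)
  vc$sigma2_g / tot
}

#' Variance explained from a likelihood-ratio
#'
#' `r2_LR = 1 - exp(-(2/n) * (LL_marker - LL_null))`, clipped to `[0, 1]`.
#' Both log-likelihoods must be maximum-likelihood values on the same
#' observations. In the ordinary-least-squares limit this reduces exactly
#' to the classical coefficient of determination.
#'
#' @param ll_marker,ll_null ML log-likelihoods of the marker and null
#'   models.
#' @param n number of observations (identical in both fits).
#' @return Variance-explained estimate in `[0, 1]`.
#' @export
r2_lr <- function(ll_marker, ll_null, n) {
  min(max(1 - exp(-(2 / n) * (ll_marker - ll_null)), 0), 1)
}

# One chromosome's association statistics. yr/Xr are already rotated by U';
# G holds imputed dosages (columns = markers) on the original scale.
scan_chromosome <- function(yr, Xr, G, U, w, n) {
  p0 <- ncol(Xr)
  sw <- sqrt(w)
  Xw <- Xr * sw
  yw <- yr * sw
  Gw <- crossprod(U, G) * sw
  qrX <- qr(Xw)
  ystar <- qr.resid(qrX, yw)
  Gstar <- qr.resid(qrX, Gw)
  gg_raw <- colSums(Gw^2)
  gg <- colSums(Gstar^2)
  gy <- colSums(Gstar * ystar)
  rss0 <- sum(ystar^2)
  usable <- gg > 1e-10 * pmax(gg_raw, 1e-12)
  beta <- ifelse(usable, gy / gg, NA_real_)
  rss1 <- rss0 - ifelse(usable, gy^2 / gg, 0)
  df <- n - p0 - 1
  Fstat <- ifelse(usable, (rss0 - rss1) / (rss1 / df), NA_real_)
  pval <- ifelse(usable, stats::pf(Fstat, 1, df, lower.tail = FALSE), NA_real_)
  se <- ifelse(usable, sqrt(rss1 / df / gg), NA_real_)
  # ML likelihood ratio with profiled scale reduces to the RSS ratio
  r2 <- ifelse(usable, pmin(pmax(1 - rss1 / rss0, 0), 1), NA_real_)
  list(beta = beta, se = se, Fstat = Fstat, p = pval, r2_lr = r2)
}

#' Single-locus mixed-model association scan
#'
#' For each marker passing the MAF filter, the additive effect is estimated
#' by generalized least squares under
#' `V = sigma2_g K_-c + sigma2_e I`, where `K_-c` is the
#' leave-one-chromosome-out kinship for the marker's chromosome, and tested
#' with a 1-df F statistic. Variance components are estimated once per
#' chromosome on the null model and reused for all markers of that
#' chromosome (the P3D/EMMAX approximation); set `refit = TRUE` to
#' re-estimate them for every marker model (slow, exact). The GLS solve uses
#' the spectral shortcut: after rotation by the eigenvectors of `K_-c` the
#' model is a weighted least-squares problem.
#'
#' Markers collinear with the fixed covariates (including a tested marker
#' identical to a covariate marker) are emitted with missing statistics,
#' not dropped. Monomorphic markers are skipped and counted in the
#' `n_monomorphic` attribute; MAF-filtered markers in `n_maf_filtered`.
#'
#' @param trait named numeric vector of per-line trait values (genotypic
#'   means), or a data.frame from [genotype_means()].
#' @param geno a [genotype_matrix()].
#' @param kinships optional `kinship_set`; when `NULL`, leave-one-chromosome-
#'   out kinships are computed from `geno` on the scanned lines.
#' @param config a [scan_config()].
#' @param refit re-estimate variance components per marker (exact REML)
#'   instead of the once-per-chromosome approximation.
#' @return An `association_scan` data.frame with columns `marker`, `chrom`,
#'   `pos`, `maf`, `beta`, `se`, `Fstat`, `p`, `logp`, `r2_lr`, `n`.
#' @export
gwas_scan <- function(trait, geno, kinships = NULL, config = scan_config(),
                      refit = FALSE) {
  stopifnot(inherits(geno, "genotype_matrix"))
  y <- trait_vector(trait)
  y <- y[!is.na(y)]
  lines <- intersect(names(y), rownames(geno$dosage))
  if (!is.null(config$lines)) lines <- intersect(lines, config$lines)
  if (length(lines) < 10) stop("too few lines with trait and genotype data", call. = FALSE)
  y <- y[lines]
  unknown <- setdiff(config$covariates, colnames(geno$dosage))
  if (length(unknown))
    stop("unknown covariate marker id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  gsub_ <- subset_genotypes(geno, lines = lines)
  if (is.null(kinships)) kinships <- loco_kinship(gsub_)

  Xcov <- if (length(config$covariates)) {
    XC <- impute_dosage(gsub_$dosage[, config$covariates, drop = FALSE])
    colnames(XC) <- config$covariates
    XC
  } else NULL

  map <- gsub_$map
  D <- impute_dosage(gsub_$dosage)
  pfreq <- colMeans(D) / 2
  maf <- pmin(pfreq, 1 - pfreq)
  mono <- pfreq <= 0 | pfreq >= 1
  filtered <- !mono & maf <= config$maf_min
  testable <- !mono & !filtered

  res <- vector("list", length(unique(map$chrom)))
  names(res) <- unique(map$chrom)
  for (cc in unique(map$chrom)) {
    idx <- which(map$chrom == cc & testable)
    if (!length(idx)) next
    K <- kinship_for_chrom(kinships, cc, lines)
    vc <- fit_null(y, K, Xcov)
    if (vc$degenerate)
      stop("constant trait: association scan is undefined", call. = FALSE)
    G <- D[, idx, drop = FALSE]
    if (!refit) {
      U <- vc$eig$vectors
      w <- 1 / (vc$eig$values + vc$delta)
      X <- cbind(rep(1, length(y)), Xcov)
      st <- scan_chromosome(drop(crossprod(U, y)), crossprod(U, X), G, U, w, vc$n)
    } else {
      st <- refit_markers(y, K, Xcov, G)
    }
    res[[cc]] <- data.frame(marker = map$marker[idx], chrom = cc,
                            pos = map$pos[idx], maf = maf[idx],
                            beta = st$beta, se = st$se, Fstat = st$Fstat,
                            p = st$p, r2_lr = st$r2_lr,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(out)) out <- data.frame(marker = character(), chrom = character(),
                                      pos = numeric(), maf = numeric(),
                                      beta = numeric(), se = numeric(),
                                      Fstat = numeric(), p = numeric(),
                                      r2_lr = numeric())
  if (config$effect_allele == "ref") out$beta <- -out$beta
  out$logp <- -log10(pmax(out$p, .Machine$double.xmin))
  out$n <- length(lines)
  out <- out[order(out$chrom, out$pos),
             c("marker", "chrom", "pos", "maf", "beta", "se", "Fstat", "p",
               "logp", "r2_lr", "n")]
  rownames(out) <- NULL
  class(out) <- c("association_scan", "data.frame")
  attr(out, "n_monomorphic") <- sum(mono)
  attr(out, "n_maf_filtered") <- sum(filtered)
  attr(out, "lines") <- lines
  attr(out, "config") <- config
  out
}

# Exact mode: per-marker REML refit, Wald F on the marker coefficient.
refit_markers <- function(y, K, Xcov, G) {
  m <- ncol(G)
  beta <- se <- Fstat <- pval <- r2 <- rep(NA_real_, m)
  for (j in seq_len(m)) {
    Xj <- cbind(if (is.null(Xcov)) NULL else Xcov, marker = G[, j])
    st <- tryCatch({
      vc <- fit_null(y, K, Xj)
      U <- vc$eig$vectors
      w <- 1 / (vc$eig$values + vc$delta)
      X0 <- cbind(rep(1, length(y)), Xcov)
      scan_chromosome(drop(crossprod(U, y)), crossprod(U, X0),
                      G[, j, drop = FALSE], U, w, vc$n)
    }, error = function(e) NULL)
    if (is.null(st)) next
    beta[j] <- st$beta; se[j] <- st$se; Fstat[j] <- st$Fstat
    pval[j] <- st$p; r2[j] <- st$r2_lr
  }
  list(beta = beta, se = se, Fstat = Fstat, p = pval, r2_lr = r2)
}

#' Conditional (covariate) association scan
#'
#' Re-runs the scan with the dosages of one or more markers of interest --
#' typically the lead SNP of a large local eQTL, or of a reference-gene
#' artifact locus -- included as fixed covariates, removing all signals
#' redundant with them. Testing a marker identical to (or perfectly
#' collinear with) a covariate yields missing statistics.
#'
#' @inheritParams gwas_scan
#' @param covariate_markers character vector of marker ids to condition on.
#' @return An `association_scan` data.frame.
#' @export
conditional_scan <- function(trait, geno, kinships = NULL, covariate_markers,
                             config = scan_config()) {
  config$covariates <- unique(c(config$covariates, covariate_markers))
  gwas_scan(trait, geno, kinships, config)
}

#' Subpanel association scan
#'
#' Restricts the panel to a subset of lines (e.g. the lines homozygous for
#' the favorable allele at a primer-site polymorphism), re-derives kinship
#' and variance components on the retained lines, and scans.
#'
#' @inheritParams gwas_scan
#' @param lines_keep character vector of retained line ids (>= 30).
#' @return An `association_scan` data.frame.
#' @export
subpanel_scan <- function(trait, geno, lines_keep, config = scan_config()) {
  lines_keep <- intersect(lines_keep, rownames(geno$dosage))
  if (length(lines_keep) < 30)
    stop("subpanel scan needs at least 30 retained lines", call. = FALSE)
  config$lines <- lines_keep
  gwas_scan(trait, geno, kinships = NULL, config = config)
}

#' Genomic-control inflation factor
#'
#' @param p vector of p-values from a scan.
#' @return `lambda = median(chisq(p)) / qchisq(0.5, 1)`.
#' @export
genomic_lambda <- function(p) {
  p <- p[!is.na(p)]
  stats::median(stats::qchisq(p, df = 1, lower.tail = FALSE)) /
    stats::qchisq(0.5, df = 1)
}
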