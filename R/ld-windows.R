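#' LD-window parameters
#'
#' @param r2k_threshold kinship-corrected LD threshold defining window
#'   membership (default 0.1).
#' @param scan_radius_bp maximal distance scanned on each side of the focal
#'   SNP (default 2 Mb).
#' @param min_run number of consecutive sub-threshold markers that ends the
#'   outward scan on one side (default 3).
#' @return An `ld_params` list.
#' @export
ld_params <- function(r2k_threshold = 0.1, scan_radius_bp = 2e6, min_run = 3) {
  if (r2k_threshold <= 0 || r2k_threshold >= 1)
    stop("`r2k_threshold` must be in (0, 1)", call. = FALSE)
  if (scan_radius_bp <= 0) stop("`scan_radius_bp` must be > 0", call. = FALSE)
  if (min_run < 1) stop("`min_run` must be >= 1", call. = FALSE)
  structure(list(r2k_threshold = r2k_threshold,
                 scan_radius_bp = scan_radius_bp, min_run = min_run),
            class = "ld_params")
}

# Symmetric inverse square root of K, regularized: negative round-off
# eigenvalues are floored at zero and a small relative ridge is added, so
# the whitened matrix is exactly (K_psd + eps*dmax*I)^(-1/2).
whitening_matrix <- function(K, eps = 1e-6) {
  eig <- eigen(K, symmetric = TRUE)
  d <- pmax(eig$values, 0) + eps * max(eig$values, 1)
  eig$vectors %*% (t(eig$vectors) / sqrt(d))
}

#' Kinship-corrected squared LD
#'
#' Squared Pearson correlation of two dosage vectors after whitening by
#' `K^(-1/2)` (eigendecomposition with a relative eigenvalue floor) --
#' linkage disequilibrium corrected for cryptic relatedness (r2K). With
#' `K = I` this is exactly the classical squared correlation.
#'
#' The correlation is computed in the whitened metric with generalized
#' least-squares centering (the whitened intercept takes the place of the
#' mean), which makes the value independent of the particular square-root
#' factorization used for the whitening.
#'
#' @param a,b numeric dosage vectors over the same lines (missing values
#'   mean-imputed).
#' @param K kinship matrix (symmetric PSD) over those lines.
#' @param eps relative eigenvalue floor of the whitening.
#' @return r2K in `[0, 1]`, or `NA` if either vector is constant after
#'   whitening.
#' @export
kinship_corrected_r2 <- function(a, b, K, eps = 1e-6) {
  stopifnot(length(a) == length(b), nrow(K) == length(a))
  a[is.na(a)] <- mean(a, na.rm = TRUE)
  b[is.na(b)] <- mean(b, na.rm = TRUE)
  W <- whitening_matrix(K, eps)
  unname(r2k_profile(W %*% cbind(a, b), 1, drop(W %*% rep(1, length(a))))[2])
}

# Whitened, imputed dosage matrix for a set of markers (columns), plus the
# whitened intercept as attribute "w1".
whitened_dosages <- function(geno, markers, K, eps = 1e-6) {
  D <- impute_dosage(geno$dosage[rownames(K), markers, drop = FALSE])
  W <- whitening_matrix(K, eps)
  out <- W %*% D
  attr(out, "w1") <- drop(W %*% rep(1, nrow(D)))
  out
}

# Squared GLS correlation of the focal column against every column of a
# whitened matrix: residualize on the whitened intercept, then take squared
# cosines. Constant (post-residualization) columns give NA; a degenerate
# focal column is an error.
r2k_profile <- function(Wd, focal_idx, w1 = attr(Wd, "w1")) {
  proj <- drop(crossprod(Wd, w1)) / sum(w1^2)
  R <- Wd - outer(w1, proj)
  ss <- colSums(R^2)
  scale_ref <- colSums(Wd^2)
  f <- R[, focal_idx]
  if (ss[focal_idx] <= 1e-12 * max(scale_ref[focal_idx], 1e-12))
    stop("focal marker monomorphic after whitening", call. = FALSE)
  r2 <- drop(crossprod(R, f))^2 / (ss * ss[focal_idx])
  r2[ss <= 1e-12 * pmax(scale_ref, 1e-12)] <- NA_real_
  pmin(r2, 1)
}

# Outward scan on one side: ordered r2 values from nearest to farthest
# neighbor. Returns the index (into that ordering) of the window boundary,
# or 0 if the window does not extend on this side.
scan_side <- function(r2, threshold, min_run) {
  last_in <- 0
  run <- 0
  for (i in seq_along(r2)) {
    if (!is.na(r2[i]) && r2[i] >= threshold) {
      last_in <- i; run <- 0
    } else {
      run <- run + 1
      if (run >= min_run) break
    }
  }
  last_in
}

#' Per-SNP LD window
#'
#' Scanning outward from the focal marker within `scan_radius_bp` on its
#' chromosome, the window boundary on each side is the last marker with
#' `r2K >= r2k_threshold` encountered before `min_run` consecutive markers
#' fall below the threshold. The window always contains the focal marker; a
#' focal marker with no correlated neighbor yields the degenerate window
#' `[pos, pos]`.
#'
#' @param geno a [genotype_matrix()].
#' @param focal_marker marker id.
#' @param K kinship matrix over the lines of `geno` (used for whitening).
#' @param params an [ld_params()].
#' @return data.frame row with `marker`, `chrom`, `start`, `end`.
#' @export
ld_window <- function(geno, focal_marker, K, params = ld_params()) {
  ld_windows(geno, focal_marker, K, params)
}

#' LD windows for several focal markers
#'
#' Vectorized form of [ld_window()]: the whitening and dosage rotation are
#' done once per chromosome.
#'
#' @inheritParams ld_window
#' @param focal_markers character vector of marker ids.
#' @return data.frame with one row per focal marker: `marker`, `chrom`,
#'   `start`, `end`.
#' @export
ld_windows <- function(geno, focal_markers, K, params = ld_params()) {
  stopifnot(inherits(geno, "genotype_matrix"))
  map <- geno$map
  idx <- match(focal_markers, map$marker)
  if (anyNA(idx))
    stop("unknown focal marker id(s): ",
         paste(focal_markers[is.na(idx)], collapse = ", "), call. = FALSE)
  if (is.null(rownames(K))) dimnames(K) <- list(rownames(geno$dosage),
                                                rownames(geno$dosage))
  out <- vector("list", length(focal_markers))
  for (cc in unique(map$chrom[idx])) {
    on_c <- which(map$chrom == cc)
    Wd <- whitened_dosages(geno, map$marker[on_c], K)
    pos_c <- map$pos[on_c]
    for (k in which(map$chrom[idx] == cc)) {
      j <- match(idx[k], on_c)
      near <- which(abs(pos_c - pos_c[j]) <= params$scan_radius_bp)
      r2 <- r2k_profile(Wd[, near, drop = FALSE], match(idx[k], on_c[near]),
                        w1 = attr(Wd, "w1"))
      jl <- match(on_c[j], on_c[near])
      left <- rev(seq_len(jl - 1))          # neighbors, nearest first
      right <- seq(jl + 1, length.out = length(near) - jl)
      bl <- scan_side(r2[left], params$r2k_threshold, params$min_run)
      br <- scan_side(r2[right], params$r2k_threshold, params$min_run)
      start <- if (bl > 0) pos_c[near[left[bl]]] else pos_c[j]
      end <- if (br > 0) pos_c[near[right[br]]] else pos_c[j]
      out[[k]] <- data.frame(marker = map$marker[idx[k]], chrom = cc,
                             start = start, end = end,
                             stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Gene model constructor
#'
#' @param gene_id gene identifier.
#' @param chrom chromosome.
#' @param start,end transcribed region, 1-based inclusive bp (`start <= end`).
#' @param strand `"+"` or `"-"`.
#' @return A one-row data.frame gene model.
#' @export
gene_model <- function(gene_id, chrom, start, end, strand = "+") {
  if (start > end) stop("gene model start must be <= end", call. = FALSE)
  data.frame(gene_id = gene_id, chrom = as.character(chrom), start = start,
             end = end, strand = strand, stringsAsFactors = FALSE)
}

#' Local/distant classification of an eQTL interval
#'
#' Local means the trait gene's transcribed interval is strictly contained
#' within the eQTL interval (same chromosome, `gene start >= eQTL start` and
#' `gene end <= eQTL end`); anything else -- including a partial boundary
#' overlap or another chromosome -- is distant.
#'
#' @param chrom,start,end eQTL interval (1-based inclusive).
#' @param gene a [gene_model()] row.
#' @return Logical: `TRUE` for local.
#' @export
classify_local_distant <- function(chrom, start, end, gene) {
  as.character(chrom) == as.character(gene$chrom) &
    gene$start >= start & gene$end <= end
}

#' Group significant SNPs into eQTLs by LD-window overlap
#'
#' Significant SNPs whose LD windows overlap (transitive closure on the same
#' chromosome, closed-interval convention: sharing a single bp counts) are
#' considered one eQTL. Each eQTL interval is delimited by the external
#' limits of the windows of its most extreme member SNPs; its lead SNP is
#' the member with maximal `-log10(p)`, ties broken by smallest physical
#' position.
#'
#' @param records an `association_scan` data.frame (or subset) of
#'   significant SNPs; must contain `marker`, `chrom`, `pos`, `logp` and
#'   effect columns.
#' @param windows data.frame from [ld_windows()] covering every record.
#' @param gene optional [gene_model()] of the trait gene; sets `is_local`.
#' @param trait optional trait label carried through to the output.
#' @return An `eqtl_set` data.frame, one row per eQTL: `eqtl_id`, `trait`,
#'   `chrom`, `start`, `end`, `n_snps`, lead-SNP statistics and `is_local`.
#'   Attribute `members` maps eQTL id to its member marker ids.
#' @export
group_eqtls <- function(records, windows, gene = NULL, trait = NA_character_) {
  empty <- data.frame(eqtl_id = character(), trait = character(),
                      chrom = character(), start = numeric(), end = numeric(),
                      n_snps = integer(), lead_marker = character(),
                      lead_pos = numeric(), lead_logp = numeric(),
                      lead_beta = numeric(), lead_maf = numeric(),
                      lead_r2_lr = numeric(), is_local = logical(),
                      stringsAsFactors = FALSE)
  if (is.null(records) || !nrow(records)) {
    class(empty) <- c("eqtl_set", "data.frame")
    attr(empty, "members") <- list()
    return(empty)
  }
  w <- windows[match(records$marker, windows$marker), ]
  if (anyNA(w$marker))
    stop("every significant record needs a window", call. = FALSE)
  d <- data.frame(marker = records$marker, chrom = as.character(records$chrom),
                  pos = records$pos, logp = records$logp,
                  beta = records$beta, maf = records$maf,
                  r2_lr = if ("r2_lr" %in% names(records)) records$r2_lr else NA_real_,
                  start = w$start, end = w$end, stringsAsFactors = FALSE)
  out <- list(); members <- list(); id <- 0
  for (cc in unique(d$chrom)) {
    dc <- d[d$chrom == cc, ]
    dc <- dc[order(dc$start, dc$end), ]
    grp <- integer(nrow(dc)); cur <- 0; cur_end <- -Inf
    for (i in seq_len(nrow(dc))) {
      if (dc$start[i] > cur_end) cur <- cur + 1
      grp[i] <- cur
      cur_end <- max(cur_end, dc$end[i])
    }
    for (g in unique(grp)) {
      id <- id + 1
      dg <- dc[grp == g, ]
      lead <- dg[order(-dg$logp, dg$pos), ][1, ]
      start <- min(dg$start); end <- max(dg$end)
      out[[id]] <- data.frame(
        eqtl_id = sprintf("QTL_%d", id), trait = trait, chrom = cc,
        start = start, end = end, n_snps = nrow(dg),
        lead_marker = lead$marker, lead_pos = lead$pos,
        lead_logp = lead$logp, lead_beta = lead$beta, lead_maf = lead$maf,
        lead_r2_lr = lead$r2_lr,
        is_local = if (is.null(gene)) NA else
          classify_local_distant(cc, start, end, gene),
        stringsAsFactors = FALSE)
      members[[sprintf("QTL_%d", id)]] <- dg$marker
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(-res$lead_logp, res$chrom, res$start), ]
  rownames(res) <- NULL
  class(res) <- c("eqtl_set", "data.frame")
  attr(res, "members") <- members
  res
}

#' Call eQTLs from an association scan
#'
#' Convenience wrapper: filters the scan at the significance threshold,
#' computes per-SNP LD windows and groups them into eQTLs.
#'
#' @param scan an `association_scan` from [gwas_scan()].
#' @param geno the scanned [genotype_matrix()].
#' @param K kinship matrix used for LD whitening (typically the global
#'   kinship over the scanned lines).
#' @param gene optional [gene_model()] of the trait gene.
#' @param params an [ld_params()].
#' @param logp_threshold significance threshold on `-log10(p)`.
#' @param trait trait label.
#' @return An `eqtl_set` (see [group_eqtls()]).
#' @export
call_eqtls <- function(scan, geno, K, gene = NULL, params = ld_params(),
                       logp_threshold = 5, trait = NA_character_) {
  sig <- scan[!is.na(scan$logp) & scan$logp >= logp_threshold, ]
  if (!nrow(sig)) return(group_eqtls(sig, sig, gene, trait))
  lines <- attr(scan, "lines")
  g <- if (!is.null(lines)) subset_genotypes(geno, lines = lines) else geno
  wins <- ld_windows(g, sig$marker, K, params)
  group_eqtls(sig, wins, gene, trait)
}

#' Colocalization of two eQTL sets
#'
#' All pairs on the same chromosome whose closed intervals intersect in at
#' least 1 bp.
#'
#' @param a,b `eqtl_set` data.frames (or any data.frames with `eqtl_id`,
#'   `chrom`, `start`, `end`).
#' @return data.frame of overlapping pairs with the shared interval.
#' @export
colocalize <- function(a, b) {
  empty <- data.frame(eqtl_a = character(), eqtl_b = character(),
                      chrom = character(), overlap_start = numeric(),
                      overlap_end = numeric(), stringsAsFactors = FALSE)
  if (!nrow(a) || !nrow(b)) return(empty)
  pairs <- merge(
    data.frame(eqtl_a = a$eqtl_id, chrom = as.character(a$chrom),
               start_a = a$start, end_a = a$end),
    data.frame(eqtl_b = b$eqtl_id, chrom = as.character(b$chrom),
               start_b = b$start, end_b = b$end),
    by = "chrom")
  if (!nrow(pairs)) return(empty)
  ov <- pmax(pairs$start_a, pairs$start_b) <= pmin(pairs$end_a, pairs$end_b)
  pairs <- pairs[ov, ]
  if (!nrow(pairs)) return(empty)
  data.frame(eqtl_a = pairs$eqtl_a, eqtl_b = pairs$eqtl_b,
             chrom = pairs$chrom,
             overlap_start = pmax(pairs$start_a, pairs$start_b),
             overlap_end = pmin(pairs$end_a, pairs$end_b),
             stringsAsFactors = FALSE)
}

#' Concordance between lead-SNP haplotype and a structural polymorphism
#'
#' Compares, line by line, the homozygous allele class at a lead SNP with
#' the presence/absence of a structural polymorphism (e.g. a promoter
#' indel). Heterozygous (dosage 1) and missing lines are excluded.
#' `carrier_class` states which homozygous dosage class (0 or 2) is
#' expected to carry the polymorphism.
#'
#' @param alleles named numeric vector of dosages in \{0, 1, 2\} per line.
#' @param presence named logical (or `"+"/"-"` character) vector of
#'   polymorphism presence per line.
#' @param carrier_class homozygous dosage class expected to carry the
#'   polymorphism (0 or 2).
#' @return list with `n`, `n_concordant`, `n_discordant`, `discordant`
#'   (line ids), `excluded_het`, `excluded_missing` and `concordance`.
#' @export
haplotype_concordance <- function(alleles, presence, carrier_class = 0) {
  if (!carrier_class %in% c(0, 2))
    stop("`carrier_class` must be 0 or 2", call. = FALSE)
  if (is.character(presence)) {
    pv <- presence %in% "+"
    pv[!presence %in% c("+", "-")] <- NA
    names(pv) <- names(presence)
    presence <- pv
  }
  common <- intersect(names(alleles), names(presence))
  if (!length(common)) stop("no lines shared between the two inputs", call. = FALSE)
  a <- alleles[common]; p <- presence[common]
  het <- !is.na(a) & a == 1
  miss <- is.na(a) | is.na(p)
  use <- common[!het & !miss]
  expected <- alleles[use] == carrier_class
  conc <- expected == presence[use]
  list(n = length(use), n_concordant = sum(conc), n_discordant = sum(!conc),
       discordant = use[!conc], excluded_het = common[het],
       excluded_missing = setdiff(common[miss], common[het]),
       concordance = if (length(use)) mean(conc) else NA_real_)
}
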