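#' Configuration of the synthetic hybrid diversity panel
#'
#' Defaults emulate the structure of a 252-hybrid maize panel obtained by
#' crossing diverse dent inbred lines to one common tester: six admixture
#' groups of sizes 32, 34, 32, 16, 36 and 102 with differentiated allele
#' frequencies, blockwise linkage disequilibrium, mostly homozygous line-side
#' dosages with rare heterozygous calls, and sparse missingness. Because all
#' hybrids share the tester parent, between-hybrid genetic variation reduces
#' to the line-side alleles, so the simulator draws the line-side dosage
#' directly and the tester is an absorbed constant.
#'
#' @param n_lines number of lines (hybrids) in the panel.
#' @param n_groups number of admixture groups.
#' @param group_sizes integer vector summing to `n_lines`; defaults to the
#'   panel's published group sizes when `n_lines = 252` and `n_groups = 6`,
#'   otherwise to a near-equal split.
#' @param n_chrom number of chromosomes (desk-scale default 3; set 10 to
#'   mirror the maize genome).
#' @param markers_per_chrom markers simulated per chromosome.
#' @param chrom_length_bp chromosome length in bp.
#' @param ld_block_len_bp length of an LD block; markers in the same block
#'   are positively correlated, markers in different blocks independent.
#' @param differentiation Fst-like scalar in `[0, 1)` controlling group
#'   allele-frequency divergence (Balding--Nichols model).
#' @param maf_range interval within `(0, 0.5]` from which ancestral minor
#'   allele frequencies are drawn.
#' @param het_rate probability that a line's dosage at a marker is recoded
#'   heterozygous (rare residual heterozygosity of inbred-derived lines).
#' @param missing_rate probability of a missing dosage (MCAR).
#' @param seed integer seed; every generator is deterministic given the seed.
#' @return A `panel_config` list.
#' @export
panel_config <- function(n_lines = 252, n_groups = 6, group_sizes = NULL,
                         n_chrom = 3, markers_per_chrom = 500,
                         chrom_length_bp = 2.5e7, ld_block_len_bp = 5e5,
                         differentiation = 0.1, maf_range = c(0.05, 0.5),
                         het_rate = 0.005, missing_rate = 0.01, seed = 1) {
  if (is.null(group_sizes)) {
    group_sizes <- if (n_lines == 252 && n_groups == 6) {
      c(32, 34, 32, 16, 36, 102)
    } else {
      sz <- rep(n_lines %/% n_groups, n_groups)
      sz[seq_len(n_lines %% n_groups)] <- sz[seq_len(n_lines %% n_groups)] + 1L
      sz
    }
  }
  cfg <- list(n_lines = as.integer(n_lines), n_groups = as.integer(n_groups),
              group_sizes = as.integer(group_sizes),
              n_chrom = as.integer(n_chrom),
              markers_per_chrom = as.integer(markers_per_chrom),
              chrom_length_bp = chrom_length_bp,
              ld_block_len_bp = ld_block_len_bp,
              differentiation = differentiation, maf_range = maf_range,
              het_rate = het_rate, missing_rate = missing_rate,
              seed = as.integer(seed))
  validate_panel_config(cfg)
  structure(cfg, class = "panel_config")
}

validate_panel_config <- function(cfg) {
  if (length(cfg$group_sizes) != cfg$n_groups)
    stop("panel_config: `group_sizes` must have `n_groups` entries", call. = FALSE)
  if (sum(cfg$group_sizes) != cfg$n_lines)
    stop("panel_config: `group_sizes` must sum to `n_lines`", call. = FALSE)
  if (cfg$differentiation < 0 || cfg$differentiation >= 1)
    stop("panel_config: `differentiation` must be in [0, 1)", call. = FALSE)
  if (length(cfg$maf_range) != 2 || cfg$maf_range[1] <= 0 ||
      cfg$maf_range[2] > 0.5 || cfg$maf_range[1] > cfg$maf_range[2])
    stop("panel_config: `maf_range` must be an interval within (0, 0.5]", call. = FALSE)
  for (f in c("het_rate", "missing_rate"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop("panel_config: `", f, "` must be a probability", call. = FALSE)
  if (cfg$markers_per_chrom < 1 || cfg$n_chrom < 1 || cfg$n_lines < 2)
    stop("panel_config: sizes must be positive (>= 2 lines)", call. = FALSE)
  if (cfg$chrom_length_bp < cfg$markers_per_chrom)
    stop("panel_config: `chrom_length_bp` too short for requested marker count",
         call. = FALSE)
  invisible(cfg)
}

#' Simulate the genotype panel
#'
#' Group allele frequencies are drawn from a Balding--Nichols distribution
#' around a shared ancestral frequency, with variance governed by
#' `differentiation` (an Fst parameter). LD is induced through a latent
#' Gaussian AR(1) process per line: the autocorrelation between adjacent
#' markers decays slowly within a block (`exp(-d / (4 * ld_block_len_bp))`,
#' so LD stays high across a block) and is reset to zero at block
#' boundaries, giving a blockwise haplotype mosaic. Line-side dosages
#' are homozygous (0/2) except for rare heterozygous recodes at `het_rate`;
#' missingness is completely at random.
#'
#' @param config a [panel_config()].
#' @return A [genotype_matrix()] with `groups` set; attribute `config` holds
#'   the resolved configuration.
#' @examples
#' g <- simulate_panel(panel_config(n_lines = 40, markers_per_chrom = 50, seed = 7))
#' dim(g$dosage)
#' @export
simulate_panel <- function(config) {
  validate_panel_config(config)
  set.seed(config$seed)
  n <- config$n_lines
  groups <- factor(rep(paste0("G", seq_len(config$n_groups)), config$group_sizes))
  lines <- sprintf("L%03d", seq_len(n))
  names(groups) <- lines

  maps <- list(); dos <- list()
  for (cc in seq_len(config$n_chrom)) {
    m <- config$markers_per_chrom
    pos <- sort(sample.int(config$chrom_length_bp, m))
    block <- pos %/% config$ld_block_len_bp
    # ancestral and group frequencies are drawn per haplotype block and
    # shared by the block's markers: alleles that co-segregate on one
    # haplotype have similar frequencies, which is what sustains high
    # within-block r2. Marker-level group divergence is still exactly
    # Balding--Nichols with parameter `differentiation`.
    ublk <- unique(block)
    bidx <- match(block, ublk)
    p_blk <- stats::runif(length(ublk), config$maf_range[1], config$maf_range[2])
    p_anc <- p_blk[bidx]
    Fst <- config$differentiation
    pg <- if (Fst > 0) {
      a <- p_blk * (1 - Fst) / Fst
      b <- (1 - p_blk) * (1 - Fst) / Fst
      qb <- matrix(stats::rbeta(config$n_groups * length(ublk),
                                rep(a, each = config$n_groups),
                                rep(b, each = config$n_groups)),
                   nrow = config$n_groups)
      pmin(pmax(qb[, bidx, drop = FALSE], 1e-3), 1 - 1e-3)
    } else {
      matrix(rep(p_anc, each = config$n_groups), nrow = config$n_groups)
    }
    # latent AR(1) per line, reset across block boundaries
    Z <- matrix(0, n, m)
    Z[, 1] <- stats::rnorm(n)
    if (m > 1) for (j in 2:m) {
      rho <- if (block[j] == block[j - 1])
        exp(-(pos[j] - pos[j - 1]) / (4 * config$ld_block_len_bp)) else 0
      Z[, j] <- rho * Z[, j - 1] + sqrt(1 - rho^2) * stats::rnorm(n)
    }
    thr <- stats::qnorm(pg)[cbind(rep(as.integer(groups), m),
                                  rep(seq_len(m), each = n))]
    allele <- Z < matrix(thr, n, m)
    D <- 2 * allele
    if (config$het_rate > 0) {
      het <- matrix(stats::runif(n * m) < config$het_rate, n, m)
      D[het] <- 1
    }
    if (config$missing_rate > 0) {
      D[matrix(stats::runif(n * m) < config$missing_rate, n, m)] <- NA
    }
    nt <- c("A", "C", "G", "T")
    ra <- t(vapply(seq_len(m), function(i) sample(nt, 2), character(2)))
    maps[[cc]] <- data.frame(marker = sprintf("S%d_%d", cc, pos),
                             chrom = as.character(cc), pos = pos,
                             ref = ra[, 1], alt = ra[, 2],
                             stringsAsFactors = FALSE)
    dos[[cc]] <- D
  }
  dosage <- do.call(cbind, dos)
  map <- do.call(rbind, maps)
  dimnames(dosage) <- list(lines, map$marker)
  out <- genotype_matrix(dosage, map, groups)
  attr(out, "config") <- config
  out
}

#' Planted genetic architecture for a simulated trait
#'
#' Describes the ground truth of one expression trait: a large-effect local
#' causal variant (a marker standing in for e.g. a promoter indel in LD with
#' its surrounding SNPs), optional distant causal markers, a polygenic
#' component, line-level residual noise, optional per-group mean shifts and
#' the gene model that anchors the "local" classification.
#'
#' @param local `NULL` or `list(marker =, effect =)`: the local causal
#'   variant and its additive effect (log2 expression units per dosage unit).
#' @param distant `NULL` or data.frame with columns `marker`, `effect`.
#' @param polygenic_var variance of the polygenic component, distributed as
#'   multivariate normal with covariance `polygenic_var * K(genotypes)`.
#' @param residual_var_line variance of line-level (genotype-level) noise
#'   added on top of the genetic value.
#' @param group_shift `NULL` or named numeric of per-group mean offsets.
#' @param gene `NULL` or a gene model `list(gene_id =, chrom =, start =,
#'   end =, strand =)` placed around the local causal variant.
#' @return A `true_architecture` list.
#' @export
true_architecture <- function(local = NULL, distant = NULL, polygenic_var = 0,
                              residual_var_line = 0, group_shift = NULL,
                              gene = NULL) {
  if (polygenic_var < 0 || residual_var_line < 0)
    stop("variances must be >= 0", call. = FALSE)
  structure(list(local = local, distant = distant,
                 polygenic_var = polygenic_var,
                 residual_var_line = residual_var_line,
                 group_shift = group_shift, gene = gene),
            class = "true_architecture")
}

#' Plant a genetic architecture on a simulated panel
#'
#' Genetic value per line = sum of causal effects times (mean-imputed)
#' dosages, plus a polygenic draw with covariance
#' `polygenic_var * K(genotypes)`, plus any group shift. The returned
#' `trait_value` adds line-level noise with variance `residual_var_line`
#' and is what the qPCR simulator and direct GWAS tests consume.
#'
#' @param geno a [genotype_matrix()].
#' @param arch a [true_architecture()].
#' @param seed optional integer seed for the random components.
#' @return data.frame with columns `line`, `genetic_value`, `trait_value`,
#'   plus a `truth` attribute recording the causal markers, their positions
#'   and effects.
#' @export
plant_architecture <- function(geno, arch, seed = NULL) {
  stopifnot(inherits(geno, "genotype_matrix"), inherits(arch, "true_architecture"))
  if (!is.null(seed)) set.seed(seed)
  causal <- data.frame(marker = character(), effect = numeric(),
                       role = character(), stringsAsFactors = FALSE)
  if (!is.null(arch$local))
    causal <- rbind(causal, data.frame(marker = arch$local$marker,
                                       effect = arch$local$effect, role = "local"))
  if (!is.null(arch$distant) && nrow(arch$distant))
    causal <- rbind(causal, data.frame(marker = arch$distant$marker,
                                       effect = arch$distant$effect, role = "distant"))
  unknown <- setdiff(causal$marker, colnames(geno$dosage))
  if (length(unknown))
    stop("unknown causal marker id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  n <- nrow(geno$dosage)
  g <- numeric(n)
  if (nrow(causal)) {
    X <- impute_dosage(geno$dosage[, causal$marker, drop = FALSE])
    g <- drop(X %*% causal$effect)
  }
  if (arch$polygenic_var > 0) {
    K <- compute_kinship(geno)
    L <- chol(K + diag(1e-6, n))
    g <- g + sqrt(arch$polygenic_var) * drop(crossprod(L, stats::rnorm(n)))
  }
  if (!is.null(arch$group_shift)) {
    if (is.null(geno$groups))
      stop("group_shift given but genotypes carry no group labels", call. = FALSE)
    g <- g + arch$group_shift[as.character(geno$groups)]
  }
  y <- g + stats::rnorm(n, sd = sqrt(arch$residual_var_line))
  out <- data.frame(line = rownames(geno$dosage), genetic_value = g,
                    trait_value = y, stringsAsFactors = FALSE)
  if (nrow(causal))
    causal$pos <- geno$map$pos[match(causal$marker, geno$map$marker)]
  attr(out, "truth") <- list(causal = causal, arch = arch)
  out
}

#' Effect size for a target marker variance fraction
#'
#' Returns the additive effect such that a biallelic marker with minor allele
#' frequency `maf` (homozygous dosages 0/2) contributes a fraction
#' `target_r2` of the total trait variance, the remaining variance being
#' `other_var`. The marker's dosage variance is `4 * maf * (1 - maf)`.
#'
#' @param target_r2 desired fraction of trait variance in (0, 1).
#' @param maf minor allele frequency of the marker.
#' @param other_var variance of everything else (polygenic + noise).
#' @return The additive effect per dosage unit.
#' @export
effect_for_variance_fraction <- function(target_r2, maf, other_var) {
  stopifnot(target_r2 > 0, target_r2 < 1, maf > 0, maf < 1, other_var > 0)
  var_marker <- target_r2 / (1 - target_r2) * other_var
  sqrt(var_marker / (4 * maf * (1 - maf)))
}

#' Configuration of qPCR assay artifacts and noise
#'
#' Describes the measurement layer of the simulated RT-qPCR assay, including
#' the two artifact mechanisms the pipeline must detect: a reference gene
#' carrying its own genetic effect (which biases the relative expression of
#' every target in carrier lines) and a primer-site allele that perturbs
#' amplification of one target in carrier lines.
#'
#' @param ref_gene_effect `NULL` or `list(gene =, marker =, effect =)`: the
#'   named reference gene's Ct is shifted by `-effect * dosage/2` Ct units
#'   (full shift in homozygous carriers, half in heterozygotes).
#' @param primer_dropout `NULL` or `list(gene =, marker =, carrier_dosage =,
#'   ct_shift =, miss_prob =)`: lines whose dosage matches `carrier_dosage`
#'   (heterozygotes are shifted by half) have the target's Ct raised by
#'   `ct_shift` cycles and set missing with probability `miss_prob`.
#' @param bio_sd biological-replicate Ct noise (cycles), drawn per
#'   (line, biological replicate, gene).
#' @param tech_sd technical-replicate Ct noise (cycles).
#' @param base_ct named numeric of baseline Ct per gene; genes not listed
#'   default to `default_target_ct` (targets) or `default_ref_ct`
#'   (reference genes). All values must lie in [15, 35].
#' @param default_target_ct,default_ref_ct fallback baseline Ct values.
#' @return An `assay_artifact_config` list.
#' @export
assay_artifact_config <- function(ref_gene_effect = NULL, primer_dropout = NULL,
                                  bio_sd = 0.4, tech_sd = 0.15,
                                  base_ct = NULL, default_target_ct = 25,
                                  default_ref_ct = 20) {
  if (bio_sd < 0 || tech_sd < 0) stop("noise sds must be >= 0", call. = FALSE)
  ct_all <- c(base_ct, default_target_ct, default_ref_ct)
  if (any(ct_all < 15 | ct_all > 35))
    stop("baseline Ct values must lie within [15, 35]", call. = FALSE)
  structure(list(ref_gene_effect = ref_gene_effect,
                 primer_dropout = primer_dropout, bio_sd = bio_sd,
                 tech_sd = tech_sd, base_ct = base_ct,
                 default_target_ct = default_target_ct,
                 default_ref_ct = default_ref_ct),
            class = "assay_artifact_config")
}

#' Simulate a replicate-level qPCR Ct table
#'
#' Emulates the assay design of the panel study: each genotype measured in
#' `n_bio` biological replicates with `n_tech` technical replicates, targets
#' and reference genes on the same plate. The target Ct is
#' `base_ct - (trait value + biological noise) + technical noise`, so higher
#' expression means fewer cycles. Reference genes have no genetic signal
#' unless `ref_gene_effect` is configured; a primer-dropout artifact raises
#' (or removes) the target Ct of carrier lines.
#'
#' @param trait_values named list, one numeric vector per target gene
#'   (values named by line), e.g. the `trait_value` column from
#'   [plant_architecture()].
#' @param geno `NULL` or the [genotype_matrix()]; required when artifact
#'   mechanisms reference markers.
#' @param assay an [assay_artifact_config()].
#' @param n_bio,n_tech biological / technical replicates per genotype.
#' @param ref_genes character vector of at least 2 reference gene ids.
#' @param seed optional integer seed.
#' @return A `ct_table` data.frame with columns `line`, `bio_rep`,
#'   `tech_rep`, `gene`, `ct`; attribute `ref_genes` records the reference
#'   set.
#' @export
simulate_ct <- function(trait_values, geno = NULL,
                        assay = assay_artifact_config(), n_bio = 3, n_tech = 2,
                        ref_genes = c("Act1", "Ef1a", "Ubi2"), seed = NULL) {
  stopifnot(inherits(assay, "assay_artifact_config"))
  if (length(ref_genes) < 2)
    stop("at least 2 reference genes are required", call. = FALSE)
  if (is.null(names(trait_values)) || !is.list(trait_values))
    stop("`trait_values` must be a named list of per-line vectors", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  lines <- names(trait_values[[1]])
  targets <- names(trait_values)
  genes <- c(targets, ref_genes)

  base_ct_of <- function(gene) {
    if (!is.null(assay$base_ct) && gene %in% names(assay$base_ct))
      assay$base_ct[[gene]]
    else if (gene %in% ref_genes) assay$default_ref_ct else assay$default_target_ct
  }
  dosage_of <- function(marker) {
    if (is.null(geno)) stop("artifact references marker `", marker,
                            "` but no genotypes were supplied", call. = FALSE)
    if (!marker %in% colnames(geno$dosage))
      stop("unknown artifact marker id: ", marker, call. = FALSE)
    impute_dosage(geno$dosage[, marker, drop = FALSE])[lines, 1]
  }

  grid <- expand.grid(line = lines, bio_rep = seq_len(n_bio), gene = genes,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  gval <- numeric(nrow(grid))
  for (g in targets) {
    idx <- grid$gene == g
    gval[idx] <- trait_values[[g]][grid$line[idx]]
  }
  if (!is.null(assay$ref_gene_effect)) {
    re <- assay$ref_gene_effect
    if (!re$gene %in% ref_genes)
      stop("ref_gene_effect$gene must be one of the reference genes", call. = FALSE)
    idx <- grid$gene == re$gene
    gval[idx] <- gval[idx] + re$effect * dosage_of(re$marker)[grid$line[idx]] / 2
  }
  bio_noise <- stats::rnorm(nrow(grid), sd = assay$bio_sd)
  base <- vapply(genes, base_ct_of, numeric(1))[grid$gene]
  ct_mean <- base - (gval + bio_noise)

  dropout_shift <- numeric(nrow(grid))
  drop_miss <- logical(nrow(grid))
  if (!is.null(assay$primer_dropout)) {
    pd <- assay$primer_dropout
    if (!pd$gene %in% targets)
      stop("primer_dropout$gene must be one of the target genes", call. = FALSE)
    dos <- dosage_of(pd$marker)
    carrier_dose <- pd$carrier_dosage %||% 2
    # fraction of carrier alleles per line: 1 for carrier homozygotes, 0.5 het
    frac <- abs(dos - (2 - carrier_dose)) / 2
    idx <- grid$gene == pd$gene
    dropout_shift[idx] <- (pd$ct_shift %||% 0) * frac[grid$line[idx]]
    mp <- pd$miss_prob %||% 0
    if (mp > 0)
      drop_miss[idx] <- stats::runif(sum(idx)) < mp * frac[grid$line[idx]]
  }
  ct_mean <- ct_mean + dropout_shift

  out <- grid[rep(seq_len(nrow(grid)), each = n_tech), ]
  out$tech_rep <- rep(seq_len(n_tech), nrow(grid))
  out$ct <- rep(ct_mean, each = n_tech) + stats::rnorm(nrow(out), sd = assay$tech_sd)
  out$ct[rep(drop_miss, each = n_tech)] <- NA_real_
  rownames(out) <- NULL
  out <- out[, c("line", "bio_rep", "tech_rep", "gene", "ct")]
  class(out) <- c("ct_table", "data.frame")
  attr(out, "ref_genes") <- ref_genes
  out
}

#' Effective residual variance of a simulated expression trait
#'
#' The delta-Ct of a target against `n_ref` reference genes, with technical
#' replicates averaged first, has residual (biological-replicate-level)
#' variance `(bio_sd^2 + tech_sd^2 / n_tech) * (1 + 1/n_ref)`: the target
#' contributes one noise draw and the reference mean contributes `1/n_ref`
#' of one. Useful for planting a known repeatability.
#'
#' @param bio_sd,tech_sd Ct noise standard deviations.
#' @param n_tech technical replicates per sample.
#' @param n_ref number of reference genes.
#' @return The per-biological-replicate residual variance of the log2
#'   relative expression.
#' @export
expression_residual_variance <- function(bio_sd, tech_sd, n_tech = 2, n_ref = 3) {
  (bio_sd^2 + tech_sd^2 / n_tech) * (1 + 1 / n_ref)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
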