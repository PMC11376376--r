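#' Validation scenarios
#'
#' Ready-made synthetic study designs used throughout the package's
#' validation: each returns a simulated panel together with the planted
#' ground truth needed to score recovery. Problem sizes are desk-scale
#' (hundreds of markers, ~150 lines) versions of the panel design the
#' generator emulates; the planted parameters are the scenario's fixed
#' study conditions.
#'
#' * `scenario_structured_null()` -- population structure and a polygenic
#'   background explaining half the line-mean variance, but no causal
#'   marker: the null used for type-I-error and genomic-control
#'   calibration. The genome is split into many short LD blocks so that a
#'   single marker tags only a tiny fraction of the polygenic background,
#'   as at full genotyping density.
#' * `scenario_local_eqtl()` -- one large-effect local causal variant
#'   (default: half the trait variance, mirroring a major promoter
#'   polymorphism) planted mid-block on chromosome 2, with the trait gene
#'   placed around it; plus the polygenic background.
#' * `scenario_reference_gene_artifact()` -- a genuine local eQTL for the
#'   target plus a genetic effect on one reference gene ("ubi-eQTL"
#'   artifact), which biases the delta-Ct of every target in carrier
#'   lines.
#' * `scenario_primer_artifact()` -- a primer-site allele that raises the
#'   target's Ct in carrier lines (spurious local signal) plus a true
#'   distant eQTL that must survive the subpanel correction.
#'
#' @param seed integer seed.
#' @param n_lines,n_chrom,markers_per_chrom,chrom_length_bp panel size.
#' @param target_r2 variance fraction of the planted local causal variant.
#' @return A list; common elements are `geno`, `config` and scenario
#'   specific ground truth (see each function's return fields).
#' @name scenarios
NULL

#' @rdname scenarios
#' @export
scenario_structured_null <- function(seed, n_lines = 150, n_chrom = 10,
                                     markers_per_chrom = 200) {
  cfg <- panel_config(n_lines = n_lines, n_chrom = n_chrom,
                      markers_per_chrom = markers_per_chrom,
                      ld_block_len_bp = 5e4, seed = seed)
  geno <- simulate_panel(cfg)
  pa <- plant_architecture(geno,
                           true_architecture(polygenic_var = 0.5,
                                             residual_var_line = 0.5),
                           seed = seed + 5000L)
  list(geno = geno, config = cfg,
       trait = stats::setNames(pa$trait_value, pa$line))
}

# Mid-block marker on `chrom` with moderate MAF and >= 2 same-block
# neighbors within 200 kb on each side; nearest to the chromosome middle.
# Mirrors a causal promoter variant in LD with its surrounding SNPs.
pick_causal_marker <- function(geno, chrom = "2", min_maf = 0.2,
                               max_maf = 0.45) {
  blk <- attr(geno, "config")$ld_block_len_bp
  map <- geno$map[geno$map$chrom == chrom, ]
  D <- impute_dosage(geno$dosage[, map$marker, drop = FALSE])
  p <- colMeans(D) / 2
  maf <- pmin(p, 1 - p)
  off <- map$pos %% blk
  ok <- maf > min_maf & maf < max_maf & off > 0.2 * blk & off < 0.8 * blk
  bb <- map$pos %/% blk
  n_left <- vapply(seq_len(nrow(map)), function(i)
    sum(bb == bb[i] & map$pos < map$pos[i] & map$pos >= map$pos[i] - 2e5),
    numeric(1))
  n_right <- vapply(seq_len(nrow(map)), function(i)
    sum(bb == bb[i] & map$pos > map$pos[i] & map$pos <= map$pos[i] + 2e5),
    numeric(1))
  cand <- which(ok & n_left >= 2 & n_right >= 2)
  if (!length(cand)) cand <- which(ok)
  if (!length(cand)) stop("no suitable causal marker on chromosome ", chrom,
                          call. = FALSE)
  i <- cand[which.min(abs(map$pos[cand] - max(map$pos) / 2))]
  list(marker = map$marker[i], pos = map$pos[i], maf = maf[i])
}

#' @rdname scenarios
#' @export
scenario_local_eqtl <- function(seed, n_lines = 150, n_chrom = 3,
                                markers_per_chrom = 300,
                                chrom_length_bp = 1e7, target_r2 = 0.5) {
  cfg <- panel_config(n_lines = n_lines, n_chrom = n_chrom,
                      markers_per_chrom = markers_per_chrom,
                      chrom_length_bp = chrom_length_bp, seed = seed)
  geno <- simulate_panel(cfg)
  causal <- pick_causal_marker(geno, "2")
  eff <- effect_for_variance_fraction(target_r2, causal$maf, other_var = 1)
  gene <- gene_model("PIPsim", "2", causal$pos - 1500, causal$pos + 1500)
  arch <- true_architecture(local = list(marker = causal$marker, effect = eff),
                            polygenic_var = 0.5, residual_var_line = 0.5,
                            gene = gene)
  pa <- plant_architecture(geno, arch, seed = seed + 7000L)
  list(geno = geno, config = cfg, arch = arch, gene = gene,
       causal_marker = causal$marker, causal_pos = causal$pos,
       causal_maf = causal$maf,
       trait = stats::setNames(pa$trait_value, pa$line))
}

#' @rdname scenarios
#' @param ref_ct_effect Ct shift of the contaminated reference gene in
#'   carrier homozygotes.
#' @export
scenario_reference_gene_artifact <- function(seed, n_lines = 150,
                                             n_chrom = 3,
                                             markers_per_chrom = 300,
                                             chrom_length_bp = 1e7,
                                             ref_ct_effect = 4) {
  cfg <- panel_config(n_lines = n_lines, n_chrom = n_chrom,
                      markers_per_chrom = markers_per_chrom,
                      chrom_length_bp = chrom_length_bp, seed = seed)
  geno <- simulate_panel(cfg)
  causal <- pick_causal_marker(geno, "2")
  eff <- effect_for_variance_fraction(0.5, causal$maf, other_var = 0.3)
  gene <- gene_model("PIPsim", "2", causal$pos - 1500, causal$pos + 1500)
  arch <- true_architecture(local = list(marker = causal$marker, effect = eff),
                            polygenic_var = 0.15, residual_var_line = 0.15,
                            gene = gene)
  pa <- plant_architecture(geno, arch, seed = seed + 7000L)
  ubi_marker <- pick_causal_marker(geno, "3")
  ubi_gene <- gene_model("Ubi2", "3", ubi_marker$pos - 1500,
                         ubi_marker$pos + 1500)
  assay <- assay_artifact_config(
    ref_gene_effect = list(gene = "Ubi2", marker = ubi_marker$marker,
                           effect = ref_ct_effect))
  ct <- simulate_ct(list(PIPsim = stats::setNames(pa$trait_value, pa$line)),
                    geno, assay, ref_genes = c("Act1", "Ef1a", "Ubi2"),
                    seed = seed + 9000L)
  list(geno = geno, config = cfg, ct = ct, gene = gene, ubi_gene = ubi_gene,
       causal_marker = causal$marker, causal_pos = causal$pos,
       ubi_marker = ubi_marker$marker, ubi_pos = ubi_marker$pos,
       ref_genes = c("Act1", "Ef1a", "Ubi2"))
}

#' @rdname scenarios
#' @param dropout_ct_shift Ct increase of the target in lines carrying the
#'   perturbed primer-site allele.
#' @export
scenario_primer_artifact <- function(seed, n_lines = 150, n_chrom = 3,
                                     markers_per_chrom = 300,
                                     chrom_length_bp = 1e7,
                                     dropout_ct_shift = 2) {
  cfg <- panel_config(n_lines = n_lines, n_chrom = n_chrom,
                      markers_per_chrom = markers_per_chrom,
                      chrom_length_bp = chrom_length_bp, seed = seed)
  geno <- simulate_panel(cfg)
  # primer-site marker: minority homozygote class carries the bad allele
  primer <- pick_causal_marker(geno, "2", min_maf = 0.1, max_maf = 0.25)
  dos <- impute_dosage(geno$dosage[, primer$marker, drop = FALSE])[, 1]
  carrier_dosage <- if (mean(dos) / 2 < 0.5) 2 else 0
  # true distant eQTL on chromosome 3
  distant <- pick_causal_marker(geno, "3")
  eff <- effect_for_variance_fraction(0.4, distant$maf, other_var = 1)
  gene <- gene_model("PIPsim", "2", primer$pos - 1500, primer$pos + 1500)
  arch <- true_architecture(distant = data.frame(marker = distant$marker,
                                                 effect = eff),
                            polygenic_var = 0.5, residual_var_line = 0.5,
                            gene = gene)
  pa <- plant_architecture(geno, arch, seed = seed + 7000L)
  assay <- assay_artifact_config(
    primer_dropout = list(gene = "PIPsim", marker = primer$marker,
                          carrier_dosage = carrier_dosage,
                          ct_shift = dropout_ct_shift))
  ct <- simulate_ct(list(PIPsim = stats::setNames(pa$trait_value, pa$line)),
                    geno, assay, ref_genes = c("Act1", "Ef1a", "Ubi2"),
                    seed = seed + 9000L)
  list(geno = geno, config = cfg, ct = ct, gene = gene,
       primer_marker = primer$marker, primer_pos = primer$pos,
       carrier_dosage = carrier_dosage,
       distant_marker = distant$marker, distant_pos = distant$pos,
       ref_genes = c("Act1", "Ef1a", "Ubi2"))
}
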