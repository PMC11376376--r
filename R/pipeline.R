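#' Pipeline configuration
#'
#' Assembles the resolved configuration of an end-to-end run:
#' simulation (or file inputs), normalization, heritability, association
#' scans, eQTL definition and QC.
#'
#' @param simulate `NULL`, or a list describing the synthetic inputs:
#'   `panel` (a [panel_config()] or its argument list), `architectures`
#'   (named list, one [true_architecture()] per target gene) and optional
#'   `assay` (an [assay_artifact_config()]).
#' @param genotypes,ct_table paths to input files when not simulating.
#' @param traits character vector of target gene ids to analyze; defaults
#'   to the names of `simulate$architectures` or all non-reference genes.
#' @param ref_genes reference gene ids used for delta-Ct normalization.
#' @param gene_models `NULL`, a data.frame of [gene_model()] rows for the
#'   target (and reference) genes, or a GFF3 path.
#' @param scan a [scan_config()].
#' @param ld an [ld_params()].
#' @param covariate_trigger_logp lead -log10(p) of a local eQTL above which
#'   a conditional scan with that lead SNP as covariate is run (default 12).
#' @param primer_intervals optional data.frame for
#'   [primer_polymorphism_filter()].
#' @param out_dir output directory (created if needed); `NULL` for none.
#' @param seed master seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(simulate = NULL, genotypes = NULL, ct_table = NULL,
                            traits = NULL, ref_genes = c("Act1", "Ef1a", "Ubi2"),
                            gene_models = NULL, scan = scan_config(),
                            ld = ld_params(), covariate_trigger_logp = 12,
                            primer_intervals = NULL, out_dir = NULL, seed = 1) {
  if (is.null(simulate) && (is.null(genotypes) || is.null(ct_table)))
    stop("either `simulate` or both `genotypes` and `ct_table` must be given",
         call. = FALSE)
  structure(list(simulate = simulate, genotypes = genotypes,
                 ct_table = ct_table, traits = traits, ref_genes = ref_genes,
                 gene_models = gene_models, scan = scan, ld = ld,
                 covariate_trigger_logp = covariate_trigger_logp,
                 primer_intervals = primer_intervals, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full eQTL pipeline
#'
#' Chains the stages of the analysis: input loading or simulation,
#' delta-Ct normalization, heritability per trait, genotypic means,
#' leave-one-chromosome-out kinship, per-trait mixed-model scan, LD-window
#' eQTL grouping with local/distant classification, the conditional
#' (covariate) rescan for traits whose local eQTL exceeds the trigger
#' threshold, reference-gene and primer-site QC, and -- for simulated runs
#' -- a recovery summary comparing planted and detected signals. Every run
#' is reproducible from the resolved configuration and seed; when `out_dir`
#' is set, the result tables and the resolved configuration are written
#' there.
#'
#' @param config a [pipeline_config()] or path to a YAML file of its
#'   arguments.
#' @return list with elements `expression`, `heritability`, `scans`,
#'   `eqtls_initial`, `eqtls_covariate`, `qc`, `recovery` (simulated runs
#'   only) and `config`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- pipeline_config_from_yaml(config)
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage `", name, "` failed: ", conditionMessage(e),
           call. = FALSE))
  }
  set.seed(config$seed)

  truth <- NULL
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    pc <- if (inherits(sim$panel, "panel_config")) sim$panel
          else do.call(panel_config, c(sim$panel, list(seed = config$seed)))
    geno <- stage("simulate_panel", simulate_panel(pc))
    tv <- list(); truth <- list()
    for (g in names(sim$architectures)) {
      pa <- stage("plant_architecture",
                  plant_architecture(geno, sim$architectures[[g]]))
      tv[[g]] <- stats::setNames(pa$trait_value, pa$line)
      truth[[g]] <- attr(pa, "truth")
    }
    assay <- sim$assay %||% assay_artifact_config()
    ct <- stage("simulate_ct",
                simulate_ct(tv, geno, assay, ref_genes = config$ref_genes))
  } else {
    geno <- stage("read_genotypes", read_genotypes(config$genotypes))
    ct <- stage("read_ct_table", read_ct_table(config$ct_table, config$ref_genes))
  }

  gm <- config$gene_models
  if (is.character(gm)) gm <- stage("read_gene_models", read_gene_models(gm))

  expr <- stage("relative_expression", relative_expression(ct, config$ref_genes))
  traits <- config$traits %||% setdiff(unique(expr$gene), config$ref_genes)

  herit <- do.call(rbind, lapply(traits, function(g) {
    h <- heritability(expr, g)
    data.frame(trait = g, Vg = h$Vg, Ve = h$Ve, n = h$n, H = h$H)
  }))

  kin <- stage("kinship", loco_kinship(geno))
  scans <- list(); eq_init <- list(); eq_cov <- list()
  for (g in traits) {
    y <- trait_vector(genotype_means(expr, g))
    sc <- stage(paste0("scan:", g), gwas_scan(y, geno, kin, config$scan))
    scans[[g]] <- sc
    gmod <- if (!is.null(gm) && g %in% gm$gene_id) gm[gm$gene_id == g, ] else NULL
    eq <- stage(paste0("eqtl:", g),
                call_eqtls(sc, geno, kin$global, gmod, config$ld,
                           config$scan$logp_threshold, trait = g))
    eq_init[[g]] <- eq
    loc <- eq[!is.na(eq$is_local) & eq$is_local, ]
    if (nrow(loc) && max(loc$lead_logp) > config$covariate_trigger_logp) {
      lead <- loc$lead_marker[which.max(loc$lead_logp)]
      sc2 <- stage(paste0("covariate_scan:", g),
                   conditional_scan(y, geno, kin, lead, config$scan))
      eq_cov[[g]] <- call_eqtls(sc2, geno, kin$global, gmod, config$ld,
                                config$scan$logp_threshold, trait = g)
    }
  }

  qc <- list()
  if (!is.null(gm)) {
    ref_models <- gm[gm$gene_id %in% config$ref_genes, ]
    if (nrow(ref_models))
      qc$reference_gene <- check_reference_gene_eqtl(eq_init, ref_models)
  }
  if (!is.null(config$primer_intervals))
    qc$primer <- primer_polymorphism_filter(geno, config$primer_intervals)

  recovery <- NULL
  if (!is.null(truth)) {
    recovery <- do.call(rbind, lapply(traits, function(g) {
      tr <- truth[[g]]
      if (is.null(tr) || !nrow(tr$causal)) return(NULL)
      eq <- eq_init[[g]]
      found <- vapply(seq_len(nrow(tr$causal)), function(i) {
        any(as.character(eq$chrom) ==
              sub("^S(\\d+)_.*$", "\\1", tr$causal$marker[i]) &
              eq$start <= tr$causal$pos[i] & eq$end >= tr$causal$pos[i])
      }, logical(1))
      data.frame(trait = g, marker = tr$causal$marker, role = tr$causal$role,
                 effect = tr$causal$effect, detected = found,
                 stringsAsFactors = FALSE)
    }))
  }

  out <- list(expression = expr, heritability = herit, scans = scans,
              eqtls_initial = eq_init, eqtls_covariate = eq_cov, qc = qc,
              recovery = recovery, config = config)
  if (!is.null(config$out_dir)) write_pipeline_outputs(out, config$out_dir)
  out
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(res$heritability, file.path(out_dir, "heritability.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (g in names(res$scans))
    utils::write.table(res$scans[[g]],
                       file.path(out_dir, paste0("assoc_", g, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  eq_all <- do.call(rbind, lapply(res$eqtls_initial, as.data.frame))
  export_eqtls(eq_all, tsv = file.path(out_dir, "eqtls_initial.tsv"),
               bed = file.path(out_dir, "eqtls_initial.bed"))
  if (length(res$eqtls_covariate)) {
    eq_cov <- do.call(rbind, lapply(res$eqtls_covariate, as.data.frame))
    export_eqtls(eq_cov, tsv = file.path(out_dir, "eqtls_covariate.tsv"))
  }
  qc_json <- list(
    reference_gene = if (!is.null(res$qc$reference_gene)) res$qc$reference_gene,
    primer = if (!is.null(res$qc$primer))
      list(check = res$qc$primer$check,
           n_lines_kept = length(res$qc$primer$lines_keep)))
  jsonlite::write_json(qc_json, file.path(out_dir, "qc_report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(res$recovery))
    jsonlite::write_json(res$recovery, file.path(out_dir, "recovery.json"),
                         auto_unbox = TRUE, digits = NA)
  cfg <- res$config
  cfg_plain <- list(seed = cfg$seed, ref_genes = cfg$ref_genes,
                    traits = cfg$traits,
                    scan = unclass(cfg$scan), ld = unclass(cfg$ld),
                    covariate_trigger_logp = cfg$covariate_trigger_logp,
                    simulated = !is.null(cfg$simulate))
  yaml::write_yaml(cfg_plain, file.path(out_dir, "resolved_config.yaml"))
  invisible(out_dir)
}

# Build a pipeline_config from a YAML file of plain argument lists.
pipeline_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$scan)) y$scan <- do.call(scan_config, y$scan)
  if (!is.null(y$ld)) y$ld <- do.call(ld_params, y$ld)
  if (!is.null(y$simulate$architectures))
    y$simulate$architectures <- lapply(y$simulate$architectures, function(a)
      do.call(true_architecture, a))
  do.call(pipeline_config, y)
}
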