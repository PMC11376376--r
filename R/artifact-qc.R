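#' Check reference genes for overlapping eQTLs
#'
#' A reference gene that itself carries an eQTL contaminates the delta-Ct
#' normalization of every target measured against it. For each reference
#' gene and trait, this reports any called eQTL whose interval overlaps the
#' gene's transcribed region (the eQTL interval already embodies the local
#' LD extent, so no extra distance margin is applied) and recommends a
#' correction: re-normalizing without the gene, or adding the flagged lead
#' SNP as a scan covariate (the default, which keeps expression data
#' consistent across targets).
#'
#' @param eqtls an `eqtl_set` data.frame, or a named list of them (one per
#'   trait).
#' @param ref_gene_models data.frame of [gene_model()] rows for the
#'   reference genes.
#' @param action recommended correction recorded on each flag.
#' @return data.frame of flags: `ref_gene`, `trait`, `eqtl_id`,
#'   `lead_marker`, `lead_logp`, `chrom`, `start`, `end`, `action`;
#'   zero rows when nothing overlaps.
#' @export
check_reference_gene_eqtl <- function(eqtls, ref_gene_models,
                                      action = c("covariate_adjust",
                                                 "renormalize_without")) {
  action <- match.arg(action)
  if (is.data.frame(eqtls)) eqtls <- list(eqtls)
  flags <- list()
  for (ti in seq_along(eqtls)) {
    eq <- eqtls[[ti]]
    if (is.null(eq) || !nrow(eq)) next
    trait <- if (!is.null(names(eqtls)) && nzchar(names(eqtls)[ti]))
      names(eqtls)[ti] else eq$trait[1]
    for (gi in seq_len(nrow(ref_gene_models))) {
      g <- ref_gene_models[gi, ]
      hit <- as.character(eq$chrom) == as.character(g$chrom) &
        eq$start <= g$end & eq$end >= g$start
      if (any(hit)) {
        h <- eq[hit, ]
        flags[[length(flags) + 1]] <- data.frame(
          ref_gene = g$gene_id, trait = trait, eqtl_id = h$eqtl_id,
          lead_marker = h$lead_marker, lead_logp = h$lead_logp,
          chrom = h$chrom, start = h$start, end = h$end, action = action,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(flags))
    return(data.frame(ref_gene = character(), trait = character(),
                      eqtl_id = character(), lead_marker = character(),
                      lead_logp = numeric(), chrom = character(),
                      start = numeric(), end = numeric(),
                      action = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, flags)
  rownames(out) <- NULL
  out
}

#' Re-normalize expression without a contaminated reference gene
#'
#' Recomputes relative expression with the flagged reference gene removed
#' from the reference set.
#'
#' @param ct a `ct_table`.
#' @param drop reference gene id(s) to exclude.
#' @param ref_genes full reference set (defaults to the table's
#'   `ref_genes` attribute).
#' @return An `expression_table` normalized against the remaining
#'   references.
#' @export
renormalize_excluding_reference <- function(ct, drop, ref_genes = NULL) {
  ref_genes <- ref_genes %||% attr(ct, "ref_genes")
  if (is.null(ref_genes)) stop("reference gene set unknown", call. = FALSE)
  remaining <- setdiff(ref_genes, drop)
  if (!length(remaining))
    stop("cannot drop the last reference gene", call. = FALSE)
  # the dropped gene leaves the analysis entirely; it does not become a target
  ct <- as_ct_table(ct[!ct$gene %in% drop, ], remaining)
  relative_expression(ct, remaining)
}

#' Screen qPCR primer intervals for genotyped polymorphisms
#'
#' Identifies genotyped markers falling inside the genomic intervals
#' targeted by a gene's qPCR primers, partitions lines by their genotype
#' there, and builds the line mask used by the subpanel scan: only lines
#' homozygous for the favorable allele at every primer-site marker are
#' retained; unfavorable homozygotes and heterozygotes are discarded. The
#' favorable allele defaults to the majority homozygote class.
#'
#' @param geno a [genotype_matrix()].
#' @param primer_intervals data.frame with columns `gene`, `chrom`, `start`,
#'   `end` (1-based inclusive), one row per primer binding site.
#' @param favorable_dosage optional named numeric (by marker id) forcing
#'   the retained homozygote class (0 or 2) per marker.
#' @return list with `check` (one row per marker inside an interval:
#'   `gene`, `marker`, `chrom`, `pos`, `favorable_dosage`, `n_favorable`,
#'   `n_unfavorable`, `n_het`, `n_missing`) and `lines_keep` (character
#'   vector). With no marker inside any interval the check has zero rows,
#'   the mask retains all lines and a notice is messaged.
#' @export
primer_polymorphism_filter <- function(geno, primer_intervals,
                                       favorable_dosage = NULL) {
  stopifnot(inherits(geno, "genotype_matrix"))
  map <- geno$map
  rows <- list()
  markers <- character()
  for (i in seq_len(nrow(primer_intervals))) {
    pi_ <- primer_intervals[i, ]
    inside <- which(map$chrom == as.character(pi_$chrom) &
                      map$pos >= pi_$start & map$pos <= pi_$end)
    for (j in inside) {
      markers <- c(markers, map$marker[j])
      rows[[length(rows) + 1]] <- data.frame(
        gene = pi_$gene, marker = map$marker[j], chrom = map$chrom[j],
        pos = map$pos[j], stringsAsFactors = FALSE)
    }
  }
  all_lines <- rownames(geno$dosage)
  if (!length(rows)) {
    message("no genotyped marker inside any primer interval; all lines retained")
    return(list(check = data.frame(gene = character(), marker = character(),
                                   chrom = character(), pos = numeric(),
                                   favorable_dosage = numeric(),
                                   n_favorable = integer(),
                                   n_unfavorable = integer(),
                                   n_het = integer(), n_missing = integer(),
                                   stringsAsFactors = FALSE),
                lines_keep = all_lines))
  }
  check <- do.call(rbind, rows)
  keep <- rep(TRUE, length(all_lines)); names(keep) <- all_lines
  fav <- n_fav <- n_unfav <- n_het <- n_miss <- numeric(nrow(check))
  for (i in seq_len(nrow(check))) {
    dos <- geno$dosage[, check$marker[i]]
    f <- if (!is.null(favorable_dosage) && check$marker[i] %in% names(favorable_dosage))
      favorable_dosage[[check$marker[i]]]
    else if (sum(dos == 2, na.rm = TRUE) >= sum(dos == 0, na.rm = TRUE)) 2 else 0
    fav[i] <- f
    n_fav[i] <- sum(dos == f, na.rm = TRUE)
    n_unfav[i] <- sum(dos == (2 - f), na.rm = TRUE)
    n_het[i] <- sum(dos == 1, na.rm = TRUE)
    n_miss[i] <- sum(is.na(dos))
    keep <- keep & !is.na(dos) & dos == f
  }
  check$favorable_dosage <- fav
  check$n_favorable <- as.integer(n_fav)
  check$n_unfavorable <- as.integer(n_unfav)
  check$n_het <- as.integer(n_het)
  check$n_missing <- as.integer(n_miss)
  list(check = check, lines_keep = all_lines[keep])
}
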