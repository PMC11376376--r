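#' Read a genotype matrix from VCF or TSV
#'
#' VCF input (v4.x) is parsed with `vcfR`; only biallelic SNP records are
#' kept, multi-allelic and non-SNP records are skipped with a logged count.
#' The TSV layout is the one written by [write_genotypes()]: columns
#' `marker`, `chrom`, `pos`, `ref`, `alt` followed by one dosage column per
#' line.
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"vcf"` or `"tsv"`.
#' @return A [genotype_matrix()]; attribute `n_skipped` counts skipped VCF
#'   records.
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  if (format == "vcf") read_genotypes_vcf(path) else read_genotypes_tsv(path)
}

read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  biallelic_snp <- !grepl(",", fix$ALT) & nchar(fix$REF) == 1 &
    nchar(fix$ALT) == 1
  n_skip <- sum(!biallelic_snp)
  if (n_skip) message(n_skip, " multi-allelic or non-SNP record(s) skipped")
  gt <- vcfR::extract.gt(v, element = "GT")[biallelic_snp, , drop = FALSE]
  fix <- fix[biallelic_snp, , drop = FALSE]
  count_alt <- function(g) {
    g[is.na(g)] <- "./."
    vapply(strsplit(gsub("\\|", "/", g), "/"),
           function(a) if (any(a == ".")) NA_real_ else sum(a != "0"),
           numeric(1))
  }
  D <- apply(gt, 2, count_alt)
  if (is.null(dim(D))) D <- matrix(D, nrow = nrow(fix),
                                   dimnames = list(rownames(gt), colnames(gt)))
  ids <- ifelse(is.na(fix$ID) | fix$ID == ".",
                paste0(fix$CHROM, "_", fix$POS), fix$ID)
  map <- data.frame(marker = ids, chrom = fix$CHROM,
                    pos = as.numeric(fix$POS), ref = fix$REF, alt = fix$ALT,
                    stringsAsFactors = FALSE)
  out <- genotype_matrix(t(`rownames<-`(D, ids)), map)
  attr(out, "n_skipped") <- n_skip
  out
}

read_genotypes_tsv <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("marker", "chrom", "pos", "ref", "alt")
  if (!all(need %in% names(d)))
    stop("genotype TSV needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  map <- d[, need]
  map$chrom <- as.character(map$chrom)
  D <- t(as.matrix(d[, setdiff(names(d), need), drop = FALSE]))
  colnames(D) <- map$marker
  genotype_matrix(D, map)
}

#' Write a genotype matrix to VCF v4.2 and/or TSV
#'
#' VCF output encodes homozygous dosages as `0/0` and `1/1`, heterozygotes
#' as `0/1` and missing as `./.`. The TSV layout round-trips exactly through
#' [read_genotypes()].
#'
#' @param geno a [genotype_matrix()].
#' @param path output file.
#' @param format `"vcf"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(geno, path, format = c("tsv", "vcf")) {
  stopifnot(inherits(geno, "genotype_matrix"))
  format <- match.arg(format)
  map <- geno$map
  if (!"ref" %in% names(map)) map$ref <- "A"
  if (!"alt" %in% names(map)) map$alt <- "T"
  if (format == "tsv") {
    d <- cbind(map[, c("marker", "chrom", "pos", "ref", "alt")],
               as.data.frame(t(geno$dosage), check.names = FALSE))
    utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    gt <- c("0/0", "0/1", "1/1")[geno$dosage + 1]
    gt[is.na(gt)] <- "./."
    G <- matrix(gt, nrow = nrow(geno$dosage))
    lines_hdr <- c("##fileformat=VCFv4.2",
                   paste0("##contig=<ID=", unique(map$chrom), ">"),
                   '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
                   paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                           "FILTER", "INFO", "FORMAT", rownames(geno$dosage)),
                         collapse = "\t"))
    body <- vapply(seq_len(nrow(map)), function(i) {
      paste(c(map$chrom[i], map$pos[i], map$marker[i], map$ref[i], map$alt[i],
              ".", "PASS", ".", "GT", G[, i]), collapse = "\t")
    }, character(1))
    writeLines(c(lines_hdr, body), path)
  }
  invisible(path)
}

#' Read a Ct table from TSV
#'
#' @param path TSV with columns `line`, `bio_rep`, `tech_rep`, `gene`, `ct`.
#' @param ref_genes reference gene ids.
#' @return A `ct_table`.
#' @export
read_ct_table <- function(path, ref_genes = NULL) {
  as_ct_table(utils::read.delim(path, stringsAsFactors = FALSE), ref_genes)
}

#' Read gene models from a GFF3 file
#'
#' Extracts records of the requested feature type (default `gene`) as
#' 1-based inclusive gene models. The gene id is taken from the `ID=` (or
#' `Name=`) attribute.
#'
#' @param path GFF3 file.
#' @param feature feature type to keep.
#' @return data.frame of [gene_model()] rows.
#' @export
read_gene_models <- function(path, feature = "gene") {
  g <- ape::read.gff(path)
  g <- g[g$type == feature, ]
  if (!nrow(g)) stop("no `", feature, "` features in ", path, call. = FALSE)
  ids <- vapply(as.character(g$attributes), function(a) {
    m <- regmatches(a, regexpr("(ID|Name)=[^;]+", a))
    if (length(m)) sub("^(ID|Name)=", "", m[1]) else NA_character_
  }, character(1), USE.NAMES = FALSE)
  data.frame(gene_id = ids, chrom = as.character(g$seqid), start = g$start,
             end = g$end, strand = as.character(g$strand),
             stringsAsFactors = FALSE)
}

#' Export an eQTL set to TSV and/or BED
#'
#' The TSV mirrors the published eQTL table layout (trait, interval, member
#' SNP count, lead-SNP statistics, local flag) and round-trips exactly. The
#' BED output converts the internal 1-based inclusive intervals to BED's
#' 0-based half-open convention.
#'
#' @param eqtls an `eqtl_set` data.frame.
#' @param tsv,bed output paths (`NULL` to skip either).
#' @return Invisible list of the written paths.
#' @export
export_eqtls <- function(eqtls, tsv = NULL, bed = NULL) {
  cols <- c("eqtl_id", "trait", "chrom", "start", "end", "n_snps",
            "lead_marker", "lead_pos", "lead_logp", "lead_beta", "lead_maf",
            "lead_r2_lr", "is_local")
  if (!is.null(tsv)) {
    d <- as.data.frame(eqtls)[, intersect(cols, names(eqtls)), drop = FALSE]
    utils::write.table(d, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(bed)) {
    if (nrow(eqtls)) {
      bedd <- data.frame(chrom = eqtls$chrom, start = eqtls$start - 1,
                         end = eqtls$end, name = eqtls$eqtl_id,
                         score = round(pmin(eqtls$lead_logp * 10, 1000)),
                         strand = ".")
      utils::write.table(bedd, bed, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
    } else {
      writeLines(character(), bed)
    }
  }
  invisible(list(tsv = tsv, bed = bed))
}

#' Re-import an exported eQTL TSV
#'
#' @param path TSV written by [export_eqtls()].
#' @return data.frame of eQTLs.
#' @export
read_eqtls <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  d$chrom <- as.character(d$chrom)
  d
}

#' Structural polymorphisms around the PIP2;5 locus
#'
#' The published conservation table for candidate structural polymorphisms
#' at the PIP2;5 local eQTL: for 14 panel lines plus the common tester
#' UH007, the dosage at the local eQTL lead SNP (0 = allele associated with
#' low expression, 2 = high, 1 = heterozygous), presence/absence of the
#' MITE-containing promoter indel, the last-intron indel, the large
#' upstream indel, and the putative splice-site variant, together with the
#' line's log2 relative PIP2;5 expression in the leaf mature zone.
#'
#' @return data.frame, one row per accession.
#' @export
pip25_polymorphism_table <- function() {
  utils::read.delim(system.file("extdata", "pip25_structural_polymorphisms.tsv",
                                package = "eqtlpanel"),
                    stringsAsFactors = FALSE)
}
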