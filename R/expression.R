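#' Read or validate a replicate-level Ct table
#'
#' @param x data.frame with columns `line`, `bio_rep`, `tech_rep`, `gene`,
#'   `ct`.
#' @param ref_genes character vector of reference gene ids present in the
#'   table.
#' @return A `ct_table` data.frame.
#' @export
as_ct_table <- function(x, ref_genes = NULL) {
  need <- c("line", "bio_rep", "tech_rep", "gene", "ct")
  if (!all(need %in% names(x)))
    stop("a Ct table needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  ref_genes <- ref_genes %||% attr(x, "ref_genes")
  x <- as.data.frame(x)[, need]
  x$ct <- as.numeric(x$ct)
  if (any(is.infinite(x$ct)))
    stop("Ct values must be finite where present", call. = FALSE)
  class(x) <- c("ct_table", "data.frame")
  attr(x, "ref_genes") <- ref_genes
  x
}

#' Relative expression by the delta-Ct method
#'
#' Normalizes target Ct values against a set of reference genes. Technical
#' replicates are averaged first, on the Ct scale. For each
#' (line, biological replicate, target):
#' `delta_Ct = mean(reference technical-mean Cts) - target technical-mean Ct`.
#' The relative expression is `2^delta_Ct`, so the log2 relative expression
#' used downstream equals delta-Ct itself. Samples missing the target or any
#' requested reference are emitted with `NA` expression.
#'
#' @param ct a `ct_table` (see [as_ct_table()]).
#' @param ref_genes character vector of reference gene ids to normalize
#'   against (defaults to the table's `ref_genes` attribute).
#' @return An `expression_table` data.frame with columns `line`, `bio_rep`,
#'   `gene`, `log2_rel_expr`; attribute `ref_genes` records the reference
#'   set used.
#' @examples
#' ct <- data.frame(line = "L1", bio_rep = 1, tech_rep = 1,
#'                  gene = c("tgt", "r1", "r2", "r3"), ct = c(24, 21, 22, 23))
#' relative_expression(as_ct_table(ct), c("r1", "r2", "r3"))  # log2 value -2
#' @export
relative_expression <- function(ct, ref_genes = NULL) {
  ct <- as_ct_table(ct, ref_genes)
  ref_genes <- attr(ct, "ref_genes")
  if (is.null(ref_genes) || !length(ref_genes))
    stop("reference gene ids must be supplied", call. = FALSE)
  unknown <- setdiff(ref_genes, unique(ct$gene))
  if (length(unknown))
    stop("unknown reference gene id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  # technical means per (line, bio_rep, gene)
  key <- interaction(ct$line, ct$bio_rep, ct$gene, drop = TRUE)
  tm <- tapply(ct$ct, key, function(v) mean(v, na.rm = TRUE))
  parts <- do.call(rbind, strsplit(names(tm), ".", fixed = TRUE))
  tech <- data.frame(line = parts[, 1], bio_rep = parts[, 2], gene = parts[, 3],
                     ct = as.numeric(tm), stringsAsFactors = FALSE)
  tech$ct[is.nan(tech$ct)] <- NA_real_

  is_ref <- tech$gene %in% ref_genes
  skey <- paste(tech$line, tech$bio_rep, sep = "\r")
  refs <- tech[is_ref, ]
  ref_n <- tapply(!is.na(refs$ct), paste(refs$line, refs$bio_rep, sep = "\r"), sum)
  ref_mean <- tapply(refs$ct, paste(refs$line, refs$bio_rep, sep = "\r"), mean)
  # a sample is usable only if every requested reference amplified
  ref_mean[is.na(ref_mean) | ref_n[names(ref_mean)] < length(ref_genes)] <- NA_real_

  out <- tech[!is_ref, ]
  out$log2_rel_expr <- ref_mean[skey[!is_ref]] - out$ct
  all_missing <- tapply(is.na(out$log2_rel_expr), out$line, all)
  if (any(all_missing)) {
    warning("dropping line(s) with no usable sample: ",
            paste(names(all_missing)[all_missing], collapse = ", "), call. = FALSE)
    out <- out[!out$line %in% names(all_missing)[all_missing], ]
  }
  out <- out[order(out$line, out$bio_rep, out$gene),
             c("line", "bio_rep", "gene", "log2_rel_expr")]
  rownames(out) <- NULL
  class(out) <- c("expression_table", "data.frame")
  attr(out, "ref_genes") <- ref_genes
  out
}

#' Per-line genotypic means of a trait
#'
#' The trait value fed to the association scan is the arithmetic mean of the
#' log2 relative expression over the available (non-missing) biological
#' replicates. Lines with no usable replicate are absent from the output.
#'
#' @param expr an `expression_table` from [relative_expression()].
#' @param gene target gene id.
#' @return data.frame with columns `line`, `value`, `n_rep`; the `value`
#'   column is also returned named via attribute-free access with
#'   [trait_vector()].
#' @export
genotype_means <- function(expr, gene) {
  d <- expr[expr$gene == gene, ]
  if (!nrow(d)) stop("trait `", gene, "` not found in expression table", call. = FALSE)
  mns <- tapply(d$log2_rel_expr, d$line, function(v) mean(v, na.rm = TRUE))
  nrep <- tapply(!is.na(d$log2_rel_expr), d$line, sum)
  out <- data.frame(line = names(mns), value = as.numeric(mns),
                    n_rep = as.integer(nrep), stringsAsFactors = FALSE)
  out <- out[out$n_rep > 0, ]
  rownames(out) <- NULL
  out
}

#' Extract a named trait vector
#'
#' @param x a data.frame with `line` and `value` columns (as returned by
#'   [genotype_means()]) or an already-named numeric vector.
#' @return Named numeric vector of per-line trait values.
#' @export
trait_vector <- function(x) {
  if (is.numeric(x)) {
    if (is.null(names(x))) stop("trait vector must be named by line", call. = FALSE)
    return(x)
  }
  stats::setNames(x$value, x$line)
}

#' Repeatability ("heritability") of an expression trait
#'
#' Fits the one-way random-effects model `Expression ~ Genotype (random)` by
#' REML and returns `H = Vg / (Vg + Ve / n)`, where `Vg` is the genotypic
#' variance, `Ve` the residual variance and `n` the (median) number of
#' biological replicates per genotype. This is the repeatability of a
#' genotype mean: the fraction of its variance that is genetic.
#'
#' @param expr an `expression_table`, or a data.frame with columns `line`
#'   and `value` (one row per biological replicate).
#' @param gene target gene id (ignored when `expr` already has a `value`
#'   column).
#' @return list with elements `Vg`, `Ve`, `n`, `H`.
#' @export
heritability <- function(expr, gene = NULL) {
  d <- if ("value" %in% names(expr)) {
    data.frame(line = expr$line, value = expr$value)
  } else {
    if (is.null(gene)) stop("`gene` must be given for an expression table", call. = FALSE)
    e <- expr[expr$gene == gene, ]
    if (!nrow(e)) stop("trait `", gene, "` not found", call. = FALSE)
    data.frame(line = e$line, value = e$log2_rel_expr)
  }
  d <- d[!is.na(d$value), ]
  if (length(unique(d$line)) < 2)
    stop("heritability needs at least 2 genotypes", call. = FALSE)
  n <- stats::median(table(d$line))
  if (stats::var(d$value) == 0)
    return(list(Vg = 0, Ve = 0, n = n, H = 0))
  within_var <- tapply(d$value, d$line, stats::var)
  if (all(is.na(within_var) | within_var == 0)) {
    # no residual variance at all: the trait is perfectly repeatable
    return(list(Vg = stats::var(tapply(d$value, d$line, mean)), Ve = 0,
                n = n, H = 1))
  }
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(value ~ 1 + (1 | line), data = d, REML = TRUE)))
  vc <- as.data.frame(lme4::VarCorr(fit))
  Vg <- max(vc$vcov[vc$grp == "line"], 0)
  Ve <- vc$vcov[vc$grp == "Residual"]
  H <- if (Vg + Ve / n > 0) Vg / (Vg + Ve / n) else 0
  list(Vg = Vg, Ve = Ve, n = as.numeric(n), H = min(max(H, 0), 1))
}

#' Group-wise tests of an expression trait
#'
#' Omnibus nonparametric one-way Kruskal--Wallis test across groups, plus
#' all pairwise Wilcoxon rank-sum tests with Holm adjustment. Star flags
#' mark adjusted pairwise p-values at 0.1 (`*`), 0.05 (`**`) and 0.01
#' (`***`).
#'
#' @param trait named numeric vector of per-line trait values (see
#'   [trait_vector()]).
#' @param groups factor (or character) of group labels named by line, or in
#'   the order of `trait`.
#' @return list with `kruskal` (htest), `omnibus_p`, `pairwise` (data.frame
#'   of group pairs with adjusted p and stars).
#' @export
group_tests <- function(trait, groups) {
  trait <- trait_vector(trait)
  if (!is.null(names(groups))) groups <- groups[names(trait)]
  groups <- droplevels(as.factor(groups))
  ok <- !is.na(trait) & !is.na(groups)
  trait <- trait[ok]; groups <- droplevels(groups[ok])
  sizes <- table(groups)
  if (any(sizes < 2)) {
    warning("group(s) with < 2 lines skipped: ",
            paste(names(sizes)[sizes < 2], collapse = ", "), call. = FALSE)
    keep <- groups %in% names(sizes)[sizes >= 2]
    trait <- trait[keep]; groups <- droplevels(groups[keep])
  }
  if (nlevels(groups) < 2)
    stop("at least 2 groups with >= 2 lines each are required", call. = FALSE)
  kw <- stats::kruskal.test(trait, groups)
  pw <- stats::pairwise.wilcox.test(trait, groups, p.adjust.method = "holm",
                                    exact = FALSE)
  pm <- pw$p.value
  pairs <- which(!is.na(pm), arr.ind = TRUE)
  pdf <- data.frame(group1 = rownames(pm)[pairs[, 1]],
                    group2 = colnames(pm)[pairs[, 2]],
                    p_adj = pm[pairs], stringsAsFactors = FALSE)
  pdf$stars <- cut(pdf$p_adj, breaks = c(-Inf, 0.01, 0.05, 0.1, Inf),
                   labels = c("***", "**", "*", ""))
  list(kruskal = kw, omnibus_p = kw$p.value, pairwise = pdf)
}

#' PCA summary of expression traits
#'
#' Principal component analysis of per-line trait values with variables
#' standardized to unit variance. Lines with any missing trait are removed
#' (case-wise deletion); constant traits are dropped with a warning.
#'
#' @param traits numeric matrix or data.frame, lines in rows (rownames =
#'   line ids), traits in columns.
#' @return list with `scores` (lines x components), `loadings`
#'   (orthonormal, traits x components) and `percent_var` (sums to 100).
#' @export
pca_summary <- function(traits) {
  M <- as.matrix(traits)
  if (ncol(M) < 2 || nrow(M) < 3)
    stop("PCA needs >= 2 traits and >= 3 lines", call. = FALSE)
  M <- M[stats::complete.cases(M), , drop = FALSE]
  v <- apply(M, 2, stats::var)
  if (any(v == 0)) {
    warning("constant trait(s) removed: ",
            paste(colnames(M)[v == 0], collapse = ", "), call. = FALSE)
    M <- M[, v > 0, drop = FALSE]
  }
  if (ncol(M) < 2) stop("fewer than 2 variable traits remain", call. = FALSE)
  pc <- stats::prcomp(M, center = TRUE, scale. = TRUE)
  list(scores = pc$x, loadings = pc$rotation,
       percent_var = 100 * pc$sdev^2 / sum(pc$sdev^2))
}
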