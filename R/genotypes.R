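#' Genotype matrix with marker map
#'
#' Container for a lines x markers dosage matrix together with its marker map.
#' Dosages count copies of the alternative allele (0, 1 or 2, `NA` for
#' missing). Lines are rows; markers are columns; the map rows are in column
#' order.
#'
#' @param dosage numeric matrix, lines x markers, entries in \{0, 1, 2, NA\}.
#'   Must carry line ids as rownames and marker ids as colnames.
#' @param map data.frame with columns `marker`, `chrom`, `pos` (1-based bp)
#'   and optionally `ref`, `alt`; one row per column of `dosage`, same order.
#' @param groups optional factor (or character) of group labels, one per line.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosage`, `map` and `groups`.
#' @export
genotype_matrix <- function(dosage, map, groups = NULL) {
  if (!is.matrix(dosage)) stop("`dosage` must be a matrix", call. = FALSE)
  if (is.null(rownames(dosage)) || is.null(colnames(dosage)))
    stop("`dosage` must have line rownames and marker colnames", call. = FALSE)
  if (!all(c("marker", "chrom", "pos") %in% names(map)))
    stop("`map` must have columns marker, chrom, pos", call. = FALSE)
  if (nrow(map) != ncol(dosage) || !identical(as.character(map$marker), colnames(dosage)))
    stop("`map` rows must match `dosage` columns (same markers, same order)", call. = FALSE)
  ok <- dosage %in% c(0, 1, 2) | is.na(dosage)
  if (!all(ok)) stop("dosages must be 0, 1, 2 or NA", call. = FALSE)
  bad <- tapply(map$pos, map$chrom, function(p) any(diff(p) <= 0))
  if (any(unlist(bad)))
    stop("marker positions must be strictly increasing within each chromosome",
         call. = FALSE)
  if (!is.null(groups)) {
    if (length(groups) != nrow(dosage))
      stop("`groups` must have one label per line", call. = FALSE)
    groups <- as.factor(groups)
    if (is.null(names(groups))) names(groups) <- rownames(dosage)
  }
  map$chrom <- as.character(map$chrom)
  structure(list(dosage = dosage, map = map, groups = groups),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d lines x %d markers on %d chromosome(s)\n",
              nrow(x$dosage), ncol(x$dosage), length(unique(x$map$chrom))))
  if (!is.null(x$groups))
    cat("groups:", paste(levels(x$groups), collapse = ", "), "\n")
  invisible(x)
}

#' Subset a genotype matrix by lines and/or markers
#'
#' @param geno a [genotype_matrix()].
#' @param lines character vector of line ids to retain (default all).
#' @param markers character vector of marker ids to retain (default all).
#' @return A `genotype_matrix` restricted to the requested lines/markers.
#' @export
subset_genotypes <- function(geno, lines = NULL, markers = NULL) {
  stopifnot(inherits(geno, "genotype_matrix"))
  if (is.null(lines)) lines <- rownames(geno$dosage)
  if (is.null(markers)) markers <- colnames(geno$dosage)
  missing_l <- setdiff(lines, rownames(geno$dosage))
  if (length(missing_l))
    stop("unknown line id(s): ", paste(utils::head(missing_l, 5), collapse = ", "),
         call. = FALSE)
  missing_m <- setdiff(markers, colnames(geno$dosage))
  if (length(missing_m))
    stop("unknown marker id(s): ", paste(utils::head(missing_m, 5), collapse = ", "),
         call. = FALSE)
  d <- geno$dosage[lines, markers, drop = FALSE]
  map <- geno$map[match(markers, geno$map$marker), , drop = FALSE]
  rownames(map) <- NULL
  g <- if (is.null(geno$groups)) NULL else droplevels(geno$groups[lines])
  genotype_matrix(d, map, g)
}

# Column mean imputation of missing dosages; columns that are entirely NA
# become their (undefined) mean 0 and end up monomorphic.
impute_dosage <- function(X) {
  nas <- which(is.na(X))
  if (!length(nas)) return(X)
  cm <- colMeans(X, na.rm = TRUE)
  cm[is.nan(cm)] <- 0
  X[nas] <- cm[((nas - 1L) %/% nrow(X)) + 1L]
  X
}

#' Genomic relationship (kinship) matrix
#'
#' Centered cross-product kinship (VanRaden method 1):
#' `K = Z Z' / (2 * sum(p * (1 - p)))` with `Z = X - 2p`, where `p` is the
#' alternative-allele frequency of each marker. Missing dosages are
#' mean-imputed per marker; monomorphic markers are dropped.
#'
#' @param geno a [genotype_matrix()].
#' @param exclude_chrom optional chromosome id(s); markers on these
#'   chromosomes are excluded (leave-one-chromosome-out kinship).
#' @return Symmetric positive semi-definite lines x lines matrix with
#'   attribute `n_markers` (number of markers used).
#' @export
compute_kinship <- function(geno, exclude_chrom = NULL) {
  stopifnot(inherits(geno, "genotype_matrix"))
  keep <- !(geno$map$chrom %in% exclude_chrom)
  X <- impute_dosage(geno$dosage[, keep, drop = FALSE])
  p <- colMeans(X) / 2
  poly <- p > 0 & p < 1
  if (sum(poly) < 2)
    stop("fewer than 2 polymorphic markers remain for kinship estimation",
         call. = FALSE)
  X <- X[, poly, drop = FALSE]
  p <- p[poly]
  Z <- sweep(X, 2, 2 * p)
  K <- tcrossprod(Z) / (2 * sum(p * (1 - p)))
  attr(K, "n_markers") <- ncol(X)
  K
}

#' Global and leave-one-chromosome-out kinship matrices
#'
#' @param geno a [genotype_matrix()].
#' @return A `kinship_set`: list with `global` (all-marker kinship) and
#'   `loco`, a named list of one kinship per chromosome, each computed from
#'   all markers *except* those on that chromosome.
#' @export
loco_kinship <- function(geno) {
  stopifnot(inherits(geno, "genotype_matrix"))
  chroms <- unique(geno$map$chrom)
  loco <- if (length(chroms) > 1) {
    stats::setNames(lapply(chroms, function(cc) compute_kinship(geno, cc)), chroms)
  } else NULL
  structure(list(global = compute_kinship(geno), loco = loco),
            class = "kinship_set")
}

#' Assemble a kinship set from precomputed matrices
#'
#' Useful for supplying a fixed kinship (e.g. the identity) to
#' [gwas_scan()] instead of estimating one from the data.
#'
#' @param global lines x lines kinship matrix.
#' @param loco optional named list of per-chromosome leave-one-chromosome-out
#'   matrices; when `NULL` the global matrix is used for every chromosome.
#' @return A `kinship_set`.
#' @export
kinship_set <- function(global, loco = NULL) {
  structure(list(global = global, loco = loco), class = "kinship_set")
}

# Retrieve the kinship to use for markers on chromosome `chrom`,
# restricted/ordered to `lines`.
kinship_for_chrom <- function(kinships, chrom, lines) {
  K <- if (!is.null(kinships$loco) && chrom %in% names(kinships$loco))
    kinships$loco[[chrom]] else kinships$global
  if (is.null(rownames(K))) {
    if (nrow(K) != length(lines))
      stop("kinship matrix has no line names and wrong dimension", call. = FALSE)
    dimnames(K) <- list(lines, lines)
  }
  if (!all(lines %in% rownames(K)))
    stop("kinship matrix does not cover all lines in the scan", call. = FALSE)
  K[lines, lines, drop = FALSE]
}
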