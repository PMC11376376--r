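#' Per-cell log2 reporter/normalizer ratio
#'
#' Ratiometric readout of a dual-fluorescence reporter assay:
#' `log2(reporter / normalizer)` of the total fluorescence intensities of
#' one transformed cell. Cells with a non-positive normalizer are rejected
#' with a warning (`NA`); a zero reporter yields a missing value with a
#' warning rather than `-Inf`.
#'
#' @param reporter,normalizer numeric vectors of total intensities
#'   (arbitrary units).
#' @return numeric vector of log2 ratios; invariant to any common scaling
#'   of both channels.
#' @export
cell_log_ratio <- function(reporter, normalizer) {
  stopifnot(length(reporter) == length(normalizer))
  out <- rep(NA_real_, length(reporter))
  bad_norm <- !is.na(normalizer) & normalizer <= 0
  if (any(bad_norm))
    warning(sum(bad_norm), " cell(s) rejected: normalizer intensity <= 0",
            call. = FALSE)
  zero_rep <- !is.na(reporter) & reporter == 0 & !bad_norm
  if (any(zero_rep))
    warning(sum(zero_rep), " cell(s) with zero reporter set to missing",
            call. = FALSE)
  ok <- !bad_norm & !zero_rep & !is.na(reporter) & !is.na(normalizer) &
    reporter > 0
  out[ok] <- log2(reporter[ok] / normalizer[ok])
  out
}

#' Mixed-model test of promoter background and indel effects
#'
#' Fits, by REML, `log2(reporter/normalizer) ~ background * indel` with a
#' random intercept per experiment (replication batch), on per-cell data
#' from a 2x2 promoter-swap design: promoter background (e.g. B73 vs
#' PH207) crossed with presence/absence of a promoter indel. Fixed effects
#' use treatment coding with the first background level and indel "absent"
#' as reference, so the indel coefficient reads as the deviation caused by
#' its presence. Wald t tests with residual degrees of freedom are reported
#' by default; `test = "lrt"` substitutes likelihood-ratio tests (ML
#' refits dropping one term at a time).
#'
#' @param cells data.frame with columns `experiment`, `background`, `indel`
#'   (factor or character; `indel` coded `"absent"`/`"present"`), and
#'   either `log2_ratio` or both `reporter` and `normalizer`.
#' @param test `"wald"` (default) or `"lrt"`.
#' @return An `assay_fit` list: `coefficients` (data.frame with estimate,
#'   se, statistic, p for background, indel and interaction),
#'   `var_experiment`, `var_residual`, `n_cells`, `n_experiments`.
#' @export
fit_assay_model <- function(cells, test = c("wald", "lrt")) {
  test <- match.arg(test)
  if (!"log2_ratio" %in% names(cells)) {
    if (!all(c("reporter", "normalizer") %in% names(cells)))
      stop("cells need `log2_ratio` or `reporter` + `normalizer`", call. = FALSE)
    cells$log2_ratio <- cell_log_ratio(cells$reporter, cells$normalizer)
  }
  d <- cells[!is.na(cells$log2_ratio), ]
  d$experiment <- factor(d$experiment)
  d$background <- factor(d$background)
  d$indel <- factor(d$indel, levels = union("absent", unique(as.character(d$indel))))
  if (nlevels(d$experiment) < 2)
    stop("at least 2 experiments are required", call. = FALSE)
  combos <- table(d$background, d$indel)
  if (any(combos == 0)) {
    miss <- which(combos == 0, arr.ind = TRUE)[1, ]
    stop("design cell missing: background = ", rownames(combos)[miss[1]],
         ", indel = ", colnames(combos)[miss[2]], call. = FALSE)
  }
  if (stats::var(d$log2_ratio) == 0) {
    terms <- c("(Intercept)", "background", "indel", "background:indel")
    coefs <- data.frame(term = terms,
                        estimate = c(d$log2_ratio[1], 0, 0, 0),
                        se = 0, statistic = c(NA, 0, 0, 0),
                        p = c(NA, 1, 1, 1), stringsAsFactors = FALSE)
    return(structure(list(coefficients = coefs, var_experiment = 0,
                          var_residual = 0, n_cells = nrow(d),
                          n_experiments = nlevels(d$experiment), model = NULL),
                     class = "assay_fit"))
  }
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(log2_ratio ~ background * indel + (1 | experiment), data = d,
               REML = TRUE)))
  fe <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  df <- nrow(d) - length(fe)
  tval <- fe / se
  pval <- 2 * stats::pt(abs(tval), df = df, lower.tail = FALSE)
  coefs <- data.frame(term = names(fe), estimate = as.numeric(fe),
                      se = as.numeric(se), statistic = as.numeric(tval),
                      p = as.numeric(pval), stringsAsFactors = FALSE)
  if (test == "lrt") {
    full <- suppressMessages(suppressWarnings(
      lme4::lmer(log2_ratio ~ background * indel + (1 | experiment), data = d,
                 REML = FALSE)))
    drop1_p <- function(form) {
      red <- suppressMessages(suppressWarnings(
        lme4::lmer(form, data = d, REML = FALSE)))
      stats::pchisq(2 * (stats::logLik(full) - stats::logLik(red)), df = 1,
                    lower.tail = FALSE)
    }
    noint <- log2_ratio ~ background + indel + (1 | experiment)
    coefs$p[grepl(":", coefs$term)] <- drop1_p(noint)
    full_ni <- suppressMessages(suppressWarnings(
      lme4::lmer(noint, data = d, REML = FALSE)))
    lrt_main <- function(form) {
      red <- suppressMessages(suppressWarnings(
        lme4::lmer(form, data = d, REML = FALSE)))
      stats::pchisq(2 * (stats::logLik(full_ni) - stats::logLik(red)), df = 1,
                    lower.tail = FALSE)
    }
    coefs$p[grepl("^background", coefs$term) & !grepl(":", coefs$term)] <-
      lrt_main(log2_ratio ~ indel + (1 | experiment))
    coefs$p[grepl("^indel", coefs$term) & !grepl(":", coefs$term)] <-
      lrt_main(log2_ratio ~ background + (1 | experiment))
  }
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(coefficients = coefs,
                 var_experiment = vc$vcov[vc$grp == "experiment"],
                 var_residual = vc$vcov[vc$grp == "Residual"],
                 n_cells = nrow(d), n_experiments = nlevels(d$experiment),
                 model = fit),
            class = "assay_fit")
}

#' @export
print.assay_fit <- function(x, ...) {
  cat(sprintf("reporter-assay mixed model: %d cells, %d experiments\n",
              x$n_cells, x$n_experiments))
  cat(sprintf("random-intercept variance %.4g, residual variance %.4g\n",
              x$var_experiment, x$var_residual))
  print(x$coefficients, row.names = FALSE)
  invisible(x)
}

#' Simulate per-cell reporter-assay data
#'
#' Draws cell-level log2 ratios from the generative form of the assay
#' model: intercept + background + indel + interaction fixed effects, a
#' normal random intercept per experiment, and normal residual noise.
#' Intensities are back-computed around a configurable normalizer mean so
#' that [cell_log_ratio()] recovers the simulated ratios exactly.
#'
#' @param background_effect,indel_effect,interaction_effect fixed effects
#'   on the log2 ratio (PH207 background, indel presence, and their
#'   interaction, relative to the B73/absent reference cell).
#' @param intercept mean log2 ratio of the reference condition.
#' @param n_experiments replication batches.
#' @param cells_per_condition cells per (background x indel) condition per
#'   experiment.
#' @param experiment_sd standard deviation of the per-experiment random
#'   intercept.
#' @param residual_sd cell-level residual standard deviation.
#' @param normalizer_mean mean normalizer intensity used to back-compute
#'   channel intensities.
#' @param seed optional integer seed.
#' @return data.frame of cells with columns `experiment`, `background`,
#'   `indel`, `reporter`, `normalizer`, `log2_ratio`.
#' @export
simulate_assay <- function(background_effect = 0, indel_effect = -0.5,
                           interaction_effect = 0, intercept = 0,
                           n_experiments = 3, cells_per_condition = 40,
                           experiment_sd = 0.2, residual_sd = 0.6,
                           normalizer_mean = 1000, seed = NULL) {
  if (experiment_sd < 0 || residual_sd < 0)
    stop("variance components must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  grid <- expand.grid(cell = seq_len(cells_per_condition),
                      background = c("B73", "PH207"),
                      indel = c("absent", "present"),
                      experiment = paste0("E", seq_len(n_experiments)),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  u <- stats::setNames(stats::rnorm(n_experiments, sd = experiment_sd),
                       paste0("E", seq_len(n_experiments)))
  mu <- intercept +
    background_effect * (grid$background == "PH207") +
    indel_effect * (grid$indel == "present") +
    interaction_effect * (grid$background == "PH207") * (grid$indel == "present") +
    u[grid$experiment]
  lr <- mu + stats::rnorm(nrow(grid), sd = residual_sd)
  normalizer <- exp(stats::rnorm(nrow(grid), log(normalizer_mean), 0.25))
  data.frame(experiment = grid$experiment, background = grid$background,
             indel = grid$indel, reporter = normalizer * 2^lr,
             normalizer = normalizer, log2_ratio = lr,
             stringsAsFactors = FALSE)
}
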