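# Per-study logistic association and per-disease fixed-effects
# meta-analysis producing the signed z-scores consumed by the CCMA
# statistic.

#' Per-study logistic association for one variant
#'
#' Maximum-likelihood log-odds for the variant dosage from a binomial GLM
#' (case status ~ dosage + covariates), with Wald standard error from the
#' observed information. Separation (monomorphic in one class, runaway
#' coefficient) is flagged as non-converged rather than reported.
#'
#' @param panel a [genotype_panel()] with exactly one case phenotype
#'   (samples with the other disease are ignored).
#' @param variant variant id (or column index) to test.
#' @param covariates optional matrix of per-sample covariates; defaults to
#'   `panel$covariates` plus a sex indicator when available.
#' @return List: `beta`, `se`, `p`, `converged`, `n`.
#' @export
study_logistic_assoc <- function(panel, variant, covariates = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  j <- if (is.numeric(variant)) as.integer(variant)
       else match(variant, panel$variants$variant_id)
  if (is.na(j)) stop("variant not found: ", variant)
  pheno <- panel$phenotype
  case_lvl <- setdiff(unique(as.character(pheno)), "control")
  if (length(case_lvl) != 1) stop("panel must contain exactly one case phenotype")
  use <- pheno %in% c("control", case_lvl)
  y <- as.integer(pheno[use] == case_lvl)
  x <- panel$dosages[use, j]
  if (is.null(covariates)) {
    covariates <- panel$covariates
    if (!is.null(panel$sex))
      covariates <- cbind(covariates, sex = as.integer(panel$sex) - 1L)
  }
  X <- if (is.null(covariates)) NULL else as.matrix(covariates)[use, , drop = FALSE]
  ok <- !is.na(x) & !is.na(y)
  if (!is.null(X)) ok <- ok & complete.cases(X)
  y <- y[ok]; x <- x[ok]
  if (length(unique(y)) < 2) stop("both phenotype classes must be present")
  dat <- data.frame(y = y, g = x)
  if (!is.null(X)) dat <- cbind(dat, as.data.frame(X[ok, , drop = FALSE]))
  fit <- suppressWarnings(glm(y ~ ., data = dat, family = binomial()))
  beta <- coef(fit)[["g"]]
  se <- sqrt(vcov(fit)["g", "g"])
  converged <- fit$converged && is.finite(beta) && is.finite(se) &&
    abs(beta) < 10 && se < 10
  list(beta = beta, se = se,
       p = pchisq((beta / se)^2, df = 1, lower.tail = FALSE),
       converged = converged, n = length(y))
}

#' Inverse-variance fixed-effects meta-analysis
#'
#' Pools per-study log-odds with weights `w_i = 1/se_i^2`:
#' `pooled_beta = sum(w b) / sum(w)`, `pooled_se = 1/sqrt(sum(w))`,
#' `z = pooled_beta / pooled_se`, with Cochran's Q heterogeneity statistic.
#'
#' @param beta,se numeric vectors of per-study estimates (harmonized to a
#'   common effect allele).
#' @return List of class `meta_result`: `pooled_beta`, `pooled_se`, `z`,
#'   `p`, `n_studies`, `heterogeneity_q`.
#' @export
fixed_effects_meta <- function(beta, se) {
  stopifnot(length(beta) == length(se), length(beta) >= 1)
  if (any(!is.finite(se)) || any(se <= 0)) stop("all se must be positive")
  w <- 1 / se^2
  pb <- sum(w * beta) / sum(w)
  ps <- 1 / sqrt(sum(w))
  z <- pb / ps
  structure(list(pooled_beta = pb, pooled_se = ps, z = z,
                 p = 2 * pnorm(-abs(z)), n_studies = length(beta),
                 heterogeneity_q = sum(w * (beta - pb)^2)),
            class = "meta_result")
}

#' Sample-size-weighted z-score meta-analysis
#'
#' The alternative weighting scheme of standard meta-analysis software:
#' `z = sum(sqrt(n_i) z_i) / sqrt(sum(n_i))`. Effective sample size per
#' study is conventionally `4 / (1/n_cases + 1/n_controls)` (see
#' [effective_n()]).
#'
#' @param z per-study signed z-scores.
#' @param n per-study effective sample sizes (> 0).
#' @return Pooled signed z-score.
#' @export
sample_size_meta <- function(z, n) {
  stopifnot(length(z) == length(n), all(n > 0))
  sum(sqrt(n) * z) / sqrt(sum(n))
}

#' Effective sample size of a case-control study
#'
#' @param n_cases,n_controls counts.
#' @return `4 / (1/n_cases + 1/n_controls)`.
#' @export
effective_n <- function(n_cases, n_controls) 4 / (1 / n_cases + 1 / n_controls)

#' Meta-analyse a set of studies variant-by-variant
#'
#' Convenience wrapper: harmonized [study_summary()] objects for one
#' disease are pooled per variant (matched on variant id) with
#' [fixed_effects_meta()] (default) or [sample_size_meta()].
#'
#' @param studies list of harmonized [study_summary()] objects.
#' @param scheme `"ivw"` (inverse-variance, default) or `"samplesize"`.
#' @return data.frame: variant key columns plus `pooled_beta`, `pooled_se`,
#'   `z`, `p`, `n_studies`, `heterogeneity_q`.
#' @export
meta_analyse <- function(studies, scheme = c("ivw", "samplesize")) {
  scheme <- match.arg(scheme)
  if (inherits(studies, "study_summary")) studies <- list(studies)
  all_ids <- unique(unlist(lapply(studies, function(s) s$records$variant_id)))
  m <- length(all_ids); S <- length(studies)
  B <- SE <- NC <- NT <- matrix(NA_real_, m, S)
  keys <- NULL
  for (s in seq_len(S)) {
    rec <- studies[[s]]$records
    idx <- match(all_ids, rec$variant_id)
    hit <- !is.na(idx)
    B[hit, s] <- rec$beta[idx[hit]]
    SE[hit, s] <- rec$se[idx[hit]]
    NC[hit, s] <- rec$n_cases[idx[hit]]
    NT[hit, s] <- rec$n_controls[idx[hit]]
    if (is.null(keys)) {
      keys <- rec[idx, c("variant_id", "chrom", "pos", "effect_allele",
                         "other_allele"), drop = FALSE]
    } else {
      fill <- is.na(keys$variant_id) & hit
      keys[fill, ] <- rec[idx[fill], c("variant_id", "chrom", "pos",
                                       "effect_allele", "other_allele")]
    }
  }
  if (any(SE <= 0, na.rm = TRUE)) stop("all se must be positive")
  n_studies <- rowSums(!is.na(B))
  if (scheme == "ivw") {
    W <- 1 / SE^2
    sw <- rowSums(W, na.rm = TRUE)
    pb <- rowSums(W * B, na.rm = TRUE) / sw
    ps <- 1 / sqrt(sw)
    z <- pb / ps
    q <- rowSums(W * (B - pb)^2, na.rm = TRUE)
  } else {
    ne <- effective_n(NC, NT)
    z <- rowSums(sqrt(ne) * (B / SE), na.rm = TRUE) / sqrt(rowSums(ne, na.rm = TRUE))
    pb <- ps <- q <- rep(NA_real_, m)
  }
  out <- cbind(keys,
               data.frame(pooled_beta = pb, pooled_se = ps, z = z,
                          p = 2 * pnorm(-abs(z)), n_studies = n_studies,
                          heterogeneity_q = q))
  rownames(out) <- NULL
  out
}
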