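# Synthetic multi-cohort two-disease case-control data with known variant
# classes (AD-only, PSO-only, shared, opposing, null), so every analysis
# stage is testable end-to-end without external data.

.sim_classes <- c("AD_only", "PSO_only", "shared", "opposing", "null")

#' Simulation configuration
#'
#' Describes a multi-cohort two-disease study: per-cohort design (disease,
#' subphenotype, ancestry-offset scale, case/control counts), variant
#' counts per truth class, per-class odds ratios, the allele-frequency
#' distribution, LD-block structure and baseline prevalences.
#'
#' The default cohorts emulate a 3 AD + 3 PSO case-control design (one AD
#' cohort childhood-onset) at roughly one tenth of the scale of a large
#' published meta-analysis, so full pipelines run in minutes; default odds
#' ratios (1.6 disease-specific, 1.5 shared/opposing) give active
#' components expected meta z-scores above ~6 at that scale, i.e.
#' well-powered variants. Baseline prevalences are 10% (AD) and 2% (PSO).
#'
#' @param cohorts data.frame with columns `cohort`, `disease`,
#'   `subphenotype`, `ancestry_scale`, `n_cases`, `n_controls`.
#' @param n_per_class named integer vector over
#'   `AD_only, PSO_only, shared, opposing, null`.
#' @param or_ad,or_pso named numeric vectors of per-class odds ratios.
#' @param eaf_range allele-frequency bounds (within (0.05, 0.95)).
#' @param ld_block_len,ld_rho LD-block length (variants) and within-block
#'   haplotype-copying probability (population method only).
#' @param prev_ad,prev_pso baseline disease prevalences.
#' @param seed integer RNG seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(cohorts = NULL,
                       n_per_class = c(AD_only = 100, PSO_only = 100,
                                       shared = 100, opposing = 100, null = 100),
                       or_ad = c(AD_only = 1.6, PSO_only = 1, shared = 1.5,
                                 opposing = 1.5, null = 1),
                       or_pso = c(AD_only = 1, PSO_only = 1.6, shared = 1.5,
                                  opposing = 1 / 1.5, null = 1),
                       eaf_range = c(0.1, 0.9), ld_block_len = 1,
                       ld_rho = 0.8, prev_ad = 0.10, prev_pso = 0.02,
                       seed = 42L) {
  if (is.null(cohorts))
    cohorts <- data.frame(
      cohort = c("AD_de", "AD_ichip", "AD_child", "PSO_de", "PSO_ichip", "PSO_uk"),
      disease = c("AD", "AD", "AD", "PSO", "PSO", "PSO"),
      subphenotype = c("general", "general", "childhood",
                       "general", "general", "general"),
      ancestry_scale = c(0.010, 0.015, 0.012, 0.010, 0.015, 0.020),
      n_cases = c(250L, 300L, 200L, 350L, 400L, 300L),
      n_controls = c(400L, 500L, 350L, 550L, 600L, 450L),
      stringsAsFactors = FALSE)
  stopifnot(all(.sim_classes %in% names(n_per_class)),
            all(.sim_classes %in% names(or_ad)),
            all(.sim_classes %in% names(or_pso)),
            all(cohorts$n_cases > 0), all(cohorts$n_controls > 0),
            all(or_ad > 0), all(or_pso > 0),
            eaf_range[1] > 0.05, eaf_range[2] < 0.95)
  structure(list(cohorts = cohorts, n_per_class = n_per_class[.sim_classes],
                 or_ad = or_ad[.sim_classes], or_pso = or_pso[.sim_classes],
                 eaf_range = eaf_range, ld_block_len = ld_block_len,
                 ld_rho = ld_rho, prev_ad = prev_ad, prev_pso = prev_pso,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# ground-truth variant table shared by both generators
.sim_truth <- function(config) {
  counts <- config$n_per_class
  cls <- rep(names(counts), counts)
  m <- length(cls)
  eaf <- runif(m, config$eaf_range[1], config$eaf_range[2])
  truth <- data.frame(
    variant_id = sprintf("sim%05d", seq_len(m)),
    chrom = as.character(rep_len(1:22, m)),
    pos = 1000L + 1000L * seq_len(m),
    effect_allele = rep_len(c("A", "C"), m),
    other_allele = rep_len(c("G", "T"), m),
    class = cls,
    beta_AD = log(unname(config$or_ad[cls])),
    beta_PSO = log(unname(config$or_pso[cls])),
    base_eaf = eaf, stringsAsFactors = FALSE)
  truth
}

.expit <- function(x) 1 / (1 + exp(-x))

# intercept a with E_g[expit(a + beta*g)] = prev under HWE at frequency p
.calibrate_intercept <- function(beta, p, prev) {
  pg <- c((1 - p)^2, 2 * p * (1 - p), p^2)
  f <- function(a) sum(pg * .expit(a + beta * (0:2))) - prev
  uniroot(f, c(-30, 10), tol = 1e-12)$root
}

# per-cohort allele frequencies: base + Gaussian ancestry offset, clipped
.cohort_eaf <- function(truth, cohorts) {
  m <- nrow(truth)
  out <- vapply(seq_len(nrow(cohorts)), function(ci)
    pmin(pmax(truth$base_eaf + rnorm(m, 0, cohorts$ancestry_scale[ci]),
              0.02), 0.98), numeric(m))
  matrix(out, nrow = m)
}

#' Simulate per-study summary statistics directly
#'
#' Fast path for meta-analysis-level testing: for each cohort and variant,
#' draws `beta_hat ~ N(true beta, se^2)` where the standard error comes
#' from the standard case-control 2x2 variance approximation
#' `se^2 = (1/(2 p q)) (1/n_cases + 1/n_controls)` at the cohort's
#' ancestry-offset allele frequency. No genotypes are generated.
#'
#' @param config a [sim_config()].
#' @param seed optional override of `config$seed`.
#' @return List: `studies` (list of [study_summary()]), `truth`
#'   (data.frame with class labels, true betas and per-cohort `eaf_*`
#'   columns).
#' @export
simulate_summary_stats <- function(config = sim_config(), seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(if (is.null(seed)) config$seed else seed)
  truth <- .sim_truth(config)
  eafs <- .cohort_eaf(truth, config$cohorts)
  studies <- lapply(seq_len(nrow(config$cohorts)), function(ci) {
    co <- config$cohorts[ci, ]
    p <- eafs[, ci]
    b_true <- if (co$disease == "AD") truth$beta_AD else truth$beta_PSO
    se <- sqrt((1 / (2 * p * (1 - p))) * (1 / co$n_cases + 1 / co$n_controls))
    beta <- rnorm(nrow(truth), b_true, se)
    z <- beta / se
    rec <- data.frame(variant_id = truth$variant_id, chrom = truth$chrom,
                      pos = truth$pos, effect_allele = truth$effect_allele,
                      other_allele = truth$other_allele, eaf = p,
                      beta = beta, se = se, p = 2 * pnorm(-abs(z)),
                      n_cases = co$n_cases, n_controls = co$n_controls,
                      info = 1, stringsAsFactors = FALSE)
    study_summary(co$cohort, co$disease, rec, co$subphenotype, co$cohort)
  })
  colnames(eafs) <- paste0("eaf_", config$cohorts$cohort)
  list(studies = studies, truth = cbind(truth, eafs))
}

# haplotype-copying genotypes: within a block, each haplotype allele copies
# its left neighbour with probability rho, otherwise is a fresh Bernoulli
# draw at that variant's frequency. Dosage = sum of two independent
# haplotypes, so HWE holds exactly within an ancestry stratum.
.hap_block_genotypes <- function(n, p, block_len, rho) {
  m <- length(p)
  one_hap <- function() {
    h <- matrix(0L, n, m)
    for (j in seq_len(m)) {
      fresh <- rbinom(n, 1L, p[j])
      if (j == 1 || ((j - 1) %% block_len) == 0) {
        h[, j] <- fresh
      } else {
        copy <- rbinom(n, 1L, rho)
        h[, j] <- ifelse(copy == 1L, h[, j - 1], fresh)
      }
    }
    h
  }
  one_hap() + one_hap()
}

#' Simulate cohort genotype panels
#'
#' Two documented sampling methods:
#'
#' * `"population"`: per cohort, a population pool of haplotype-copying
#'   genotypes (HWE within the cohort, LD by first-order copying at
#'   `ld_rho` within blocks of `ld_block_len`) is generated at the
#'   cohort's ancestry-offset allele frequencies; disease status follows
#'   the joint logistic model `P(disease | g)` over all configured effects,
#'   with the intercept solved numerically so the pool prevalence matches
#'   the configured prevalence; cases and controls (free of both diseases)
#'   are then sampled to the requested counts. Faithful but intended for
#'   configurations with a modest number of non-null variants (a joint
#'   model with hundreds of strong effects has no realistic prevalence
#'   calibration, and an error is raised if calibration fails).
#' * `"conditional"`: per variant, case genotypes are drawn from
#'   `P(g | case) \%propto\% P(g) P(case | g)` and control genotypes from
#'   `P(g | neither disease)`, each variant treated as the sole causal
#'   variant (the marginal-effect regime in which per-variant association
#'   testing is evaluated). Exact and fast at any variant count; no LD.
#'
#' Both methods attach sex (Bernoulli 1/2) and four standard-normal
#' principal-component-score covariates, and are byte-reproducible given
#' the seed.
#'
#' @param config a [sim_config()].
#' @param method `"population"` or `"conditional"`.
#' @param seed optional override of `config$seed`.
#' @return List: `panels` (named list of [genotype_panel()], one per
#'   cohort; phenotype levels control/AD/PSO), `truth` (as in
#'   [simulate_summary_stats()]).
#' @export
simulate_cohorts <- function(config = sim_config(),
                             method = c("population", "conditional"),
                             seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  method <- match.arg(method)
  set.seed(if (is.null(seed)) config$seed else seed)
  truth <- .sim_truth(config)
  eafs <- .cohort_eaf(truth, config$cohorts)
  m <- nrow(truth)
  vk <- variant_key(truth$variant_id, truth$chrom, truth$pos,
                    truth$effect_allele, truth$other_allele)
  prev <- c(AD = config$prev_ad, PSO = config$prev_pso)
  panels <- lapply(seq_len(nrow(config$cohorts)), function(ci) {
    co <- config$cohorts[ci, ]
    p <- eafs[, ci]
    if (method == "population") {
      pool_n <- ceiling(1.5 * max(co$n_cases / prev[[co$disease]],
                                  co$n_controls / (1 - sum(prev))))
      G <- .hap_block_genotypes(pool_n, p, config$ld_block_len, config$ld_rho)
      risk <- function(beta_vec, pv) {
        eta0 <- drop(G %*% beta_vec)
        f <- function(a) mean(.expit(a + eta0)) - pv
        lo <- -30; hi <- 10
        if (f(lo) > 0 || f(hi) < 0)
          stop("prevalence unreachable under the configured joint effects")
        a <- uniroot(f, c(lo, hi), tol = 1e-10)$root
        .expit(a + eta0)
      }
      pr_ad <- risk(truth$beta_AD, prev[["AD"]])
      pr_pso <- risk(truth$beta_PSO, prev[["PSO"]])
      is_ad <- runif(pool_n) < pr_ad
      is_pso <- runif(pool_n) < pr_pso
      case_pool <- if (co$disease == "AD") which(is_ad) else which(is_pso)
      ctrl_pool <- which(!is_ad & !is_pso)
      if (length(case_pool) < co$n_cases || length(ctrl_pool) < co$n_controls)
        stop("pool too small for requested case/control counts")
      rows <- c(sample(case_pool, co$n_cases), sample(ctrl_pool, co$n_controls))
      dos <- G[rows, , drop = FALSE]
    } else {
      pg <- rbind((1 - p)^2, 2 * p * (1 - p), p^2)       # 3 x m
      a_ad <- vapply(seq_len(m), function(j)
        .calibrate_intercept(truth$beta_AD[j], p[j], prev[["AD"]]), 0)
      a_pso <- vapply(seq_len(m), function(j)
        .calibrate_intercept(truth$beta_PSO[j], p[j], prev[["PSO"]]), 0)
      gsupp <- 0:2
      ones <- rep(1, 3)
      pr_ad_g <- .expit(ones %o% a_ad +
                          outer(gsupp, truth$beta_AD, `*`))  # 3 x m
      pr_pso_g <- .expit(ones %o% a_pso +
                           outer(gsupp, truth$beta_PSO, `*`))
      p_case <- pg * (if (co$disease == "AD") pr_ad_g else pr_pso_g)
      p_ctrl <- pg * (1 - pr_ad_g) * (1 - pr_pso_g)
      draw <- function(probs, n) {
        counts <- apply(probs, 2, function(q) rmultinom(1, n, q))
        apply(counts, 2, function(k) {
          g <- rep(gsupp, k)
          g[sample.int(length(g))]
        })
      }
      dos <- rbind(draw(p_case, co$n_cases), draw(p_ctrl, co$n_controls))
    }
    n_tot <- co$n_cases + co$n_controls
    ids <- sprintf("%s_s%04d", co$cohort, seq_len(n_tot))
    pheno <- c(rep(co$disease, co$n_cases), rep("control", co$n_controls))
    sex <- c("female", "male")[rbinom(n_tot, 1, 0.5) + 1]
    pcs <- matrix(rnorm(n_tot * 4), n_tot, 4,
                  dimnames = list(NULL, paste0("PC", 1:4)))
    genotype_panel(ids, dos, vk, pheno, sex, pcs)
  })
  names(panels) <- config$cohorts$cohort
  colnames(eafs) <- paste0("eaf_", config$cohorts$cohort)
  list(panels = panels, truth = cbind(truth, eafs))
}

#' Pool cohort panels into one analysis panel
#'
#' Stacks per-cohort panels (shared variant set). Cohort-membership
#' indicator covariates can be appended, but are off by default: when every
#' collection carries cases of a single disease, study indicators perfectly
#' predict the absent case category and quasi-separate the three-category
#' model (their coefficients diverge while the dosage effect is untouched).
#' Ancestry and batch structure is instead carried by the
#' principal-component score covariates.
#'
#' @param panels named list of [genotype_panel()] objects with identical
#'   variant tables.
#' @param cohort_covariates append membership indicators (default `FALSE`;
#'   only sensible when each cohort contains all outcome categories).
#' @return A single [genotype_panel()].
#' @export
pool_panels <- function(panels, cohort_covariates = FALSE) {
  stopifnot(length(panels) >= 1)
  v0 <- panels[[1]]$variants
  for (p in panels) stopifnot(identical(p$variants$variant_id, v0$variant_id))
  ns <- vapply(panels, function(p) length(p$sample_ids), 0L)
  cohort <- rep(names(panels), ns)
  covs <- do.call(rbind, lapply(panels, function(p) p$covariates))
  k <- length(panels)
  if (cohort_covariates && k > 1) {
    ind <- sapply(names(panels)[-1], function(nm) as.numeric(cohort == nm))
    colnames(ind) <- paste0("cohort_", names(panels)[-1])
    covs <- cbind(covs, ind)
  }
  genotype_panel(
    unlist(lapply(panels, function(p) p$sample_ids), use.names = FALSE),
    do.call(rbind, lapply(panels, function(p) p$dosages)), v0,
    unlist(lapply(panels, function(p) as.character(p$phenotype)), use.names = FALSE),
    unlist(lapply(panels, function(p) as.character(p$sex)), use.names = FALSE),
    covs)
}

#' Per-variant association scan of one cohort panel
#'
#' Runs [study_logistic_assoc()] across variants and packages the result
#' as a [study_summary()] for meta-analysis.
#'
#' @param panel a single-disease [genotype_panel()].
#' @param study_id,disease,subphenotype,ancestry_label study metadata;
#'   disease inferred from the panel when `NULL`.
#' @return A [study_summary()] (non-converged variants are dropped).
#' @export
panel_to_summary <- function(panel, study_id, disease = NULL,
                             subphenotype = "general", ancestry_label = "") {
  stopifnot(inherits(panel, "genotype_panel"))
  if (is.null(disease))
    disease <- setdiff(as.character(unique(panel$phenotype)), "control")
  n_cases <- sum(panel$phenotype == disease)
  n_controls <- sum(panel$phenotype == "control")
  v <- panel$variants
  rows <- lapply(seq_len(nrow(v)), function(j) {
    r <- tryCatch(study_logistic_assoc(panel, j), error = function(e) NULL)
    if (is.null(r) || !r$converged) return(NULL)
    data.frame(variant_id = v$variant_id[j], chrom = v$chrom[j], pos = v$pos[j],
               effect_allele = v$effect_allele[j], other_allele = v$other_allele[j],
               eaf = mean(panel$dosages[, j], na.rm = TRUE) / 2,
               beta = r$beta, se = r$se, p = max(r$p, 1e-300),
               n_cases = n_cases, n_controls = n_controls, info = 1,
               stringsAsFactors = FALSE)
  })
  rec <- do.call(rbind, rows)
  study_summary(study_id, disease, rec, subphenotype, ancestry_label)
}
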