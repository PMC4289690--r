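# How much do opposing risk loci explain the epidemiological mutual
# exclusivity of the two diseases? Exact genotype enumeration under
# independent HWE loci and per-disease log-additive risk models, assuming
# the diseases are conditionally independent given genotype.

#' Specify an exclusivity model
#'
#' A set of loci with risk-allele frequency and per-disease odds ratios,
#' plus marginal prevalences and the observed fold-reduction of AD
#' prevalence among psoriasis cases. Defaults follow the conventional
#' epidemiological figures: 10% AD, 2% psoriasis, and a 25-fold lower AD
#' prevalence within psoriasis cases.
#'
#' @param loci data.frame with columns `freq` (risk-allele frequency in
#'   (0,1)), `or_ad`, `or_pso` (> 0). May have zero rows.
#' @param prevalence_ad,prevalence_pso marginal prevalences.
#' @param fold_reduction observed fold-reduction of AD among PSO cases.
#' @return List of class `exclusivity_model`.
#' @export
exclusivity_model <- function(loci = data.frame(freq = numeric(),
                                                or_ad = numeric(),
                                                or_pso = numeric()),
                              prevalence_ad = 0.10, prevalence_pso = 0.02,
                              fold_reduction = 25) {
  stopifnot(all(loci$freq > 0 & loci$freq < 1),
            all(loci$or_ad > 0), all(loci$or_pso > 0),
            prevalence_ad > 0, prevalence_ad < 1,
            prevalence_pso > 0, prevalence_pso < 1)
  structure(list(loci = loci, prevalence_ad = prevalence_ad,
                 prevalence_pso = prevalence_pso,
                 fold_reduction = fold_reduction),
            class = "exclusivity_model")
}

# all 3^L genotype vectors with their HWE probabilities and per-disease
# log-odds contributions
.genotype_grid <- function(loci) {
  L <- nrow(loci)
  if (L == 0)
    return(list(prob = 1, eta_ad = 0, eta_pso = 0))
  if (L > 15) stop("exact enumeration supports at most 15 loci")
  g <- as.matrix(expand.grid(rep(list(0:2), L)))
  pg <- rep(1, nrow(g))
  for (j in seq_len(L)) {
    p <- loci$freq[j]
    pg <- pg * c((1 - p)^2, 2 * p * (1 - p), p^2)[g[, j] + 1]
  }
  list(prob = pg,
       eta_ad = drop(g %*% log(loci$or_ad)),
       eta_pso = drop(g %*% log(loci$or_pso)))
}

# intercept such that sum_g P(g) expit(a + eta_g) = prev
.calibrate_grid_intercept <- function(prob, eta, prev) {
  f <- function(a) sum(prob * .expit(a + eta)) - prev
  lo <- -40; hi <- 20
  if (f(lo) > 0 || f(hi) < 0) stop("intercept calibration failed to bracket")
  uniroot(f, c(lo, hi), tol = 1e-13)$root
}

#' Genetically implied P(AD | PSO)
#'
#' Each disease follows a log-additive genotype risk model over the model's
#' loci, with the intercept calibrated so the marginal prevalence matches;
#' genotypes are independent HWE loci; the two diseases are conditionally
#' independent given genotype. Then
#' `P(AD | PSO) = sum_g P(AD|g) P(PSO|g) P(g) / P(PSO)`,
#' computed by exact enumeration over the `3^L` genotype vectors.
#'
#' @param model an [exclusivity_model()].
#' @return `P(AD | PSO)` as a probability.
#' @export
conditional_prevalence <- function(model) {
  stopifnot(inherits(model, "exclusivity_model"))
  gr <- .genotype_grid(model$loci)
  a_ad <- .calibrate_grid_intercept(gr$prob, gr$eta_ad, model$prevalence_ad)
  a_pso <- .calibrate_grid_intercept(gr$prob, gr$eta_pso, model$prevalence_pso)
  p_ad_g <- .expit(a_ad + gr$eta_ad)
  p_pso_g <- .expit(a_pso + gr$eta_pso)
  sum(p_ad_g * p_pso_g * gr$prob) / sum(p_pso_g * gr$prob)
}

#' Epidemiological mutual-exclusivity gap
#'
#' The observed reduction of AD prevalence within psoriasis cases, in
#' percentage points: `100 * (prev_AD - prev_AD / fold_reduction)`. With
#' the default 10% prevalence and 25-fold reduction this is the 9.6-point
#' gap from 10% in the population to 0.4% among psoriasis cases.
#'
#' @param model an [exclusivity_model()].
#' @return Gap in percentage points.
#' @export
exclusivity_gap <- function(model) {
  stopifnot(inherits(model, "exclusivity_model"))
  if (model$fold_reduction <= 1) stop("fold_reduction must exceed 1")
  100 * (model$prevalence_ad - model$prevalence_ad / model$fold_reduction)
}

#' Fraction of mutual exclusivity explained by the modelled loci
#'
#' Compares the genetically implied reduction of AD prevalence among PSO
#' cases with the observed reduction:
#' `100 * (prev_AD - P(AD|PSO)_genetic) / (prev_AD - prev_AD/fold_reduction)`
#' in percentage of the observed gap. A genetic `P(AD|PSO)` equal to the
#' marginal prevalence explains 0%; one matching the observed conditional
#' prevalence explains 100%.
#'
#' @param model an [exclusivity_model()].
#' @param genetic_p_ad_given_pso genetically implied `P(AD | PSO)`;
#'   computed from the model by [conditional_prevalence()] when missing.
#' @return Percentage of the observed exclusivity gap explained.
#' @export
exclusivity_explained <- function(model,
                                  genetic_p_ad_given_pso = conditional_prevalence(model)) {
  stopifnot(inherits(model, "exclusivity_model"))
  if (model$fold_reduction <= 1) stop("fold_reduction must exceed 1")
  if (genetic_p_ad_given_pso > model$prevalence_ad + 1e-12)
    stop("genetic P(AD|PSO) exceeds the marginal prevalence")
  100 * (model$prevalence_ad - genetic_p_ad_given_pso) /
    (model$prevalence_ad - model$prevalence_ad / model$fold_reduction)
}
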