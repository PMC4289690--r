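# shared small pooled panel for several blocks
mk_pool <- function(n_per_class = c(AD_only = 2, PSO_only = 2, shared = 2,
                                    opposing = 2, null = 2), seed = 81) {
  cfg <- sim_config(n_per_class = n_per_class)
  sim <- simulate_cohorts(cfg, method = "conditional", seed = seed)
  list(pool = pool_panels(sim$panels), truth = sim$truth)
}

test_that("Wald contrasts have their closed forms", {
  # null point: all five p = 1
  w0 <- wald_tests(0, 0, diag(2) * 0.01)
  expect_equal(unlist(w0), c(p_overall = 1, p_AD = 1, p_PSO = 1,
                             p_shared = 1, p_opposing = 1))
  # beta = (0.2, 0.2), Sigma = 0.01 I
  w <- wald_tests(0.2, 0.2, diag(2) * 0.01)
  expect_equal(w$p_shared, pchisq(0.4^2 / 0.02, 1, lower.tail = FALSE))
  expect_equal(w$p_shared, 0.0047, tolerance = 0.01)
  expect_equal(w$p_opposing, 1)
  # orthogonal-contrast identity: overall 2-df stat = shared + opposing
  # 1-df stats when Sigma is spherical
  set.seed(82)
  for (i in 1:10) {
    b <- rnorm(2); s2 <- runif(1, 0.001, 0.1)
    w <- wald_tests(b[1], b[2], diag(2) * s2)
    q2 <- qchisq(w$p_overall, 2, lower.tail = FALSE)
    q_sh <- qchisq(w$p_shared, 1, lower.tail = FALSE)
    q_op <- qchisq(w$p_opposing, 1, lower.tail = FALSE)
    expect_equal(q2, q_sh + q_op, tolerance = 1e-8)
  }
  expect_error(wald_tests(1, 1, matrix(c(1, 2, 2, 1), 2)), "positive definite")
})

test_that("minimum-p classification and tie-breaks are deterministic", {
  r <- classify_mnm(0.001, 0.5, 0.03, 0.4)
  expect_equal(as.character(r$category), "AD")
  expect_equal(r$p_MNM, 0.001)
  tie <- classify_mnm(0.2, 0.2, 0.2, 0.2)
  expect_equal(as.character(tie$category), "AD")
  tie2 <- classify_mnm(0.5, 0.2, 0.2, 0.2)
  expect_equal(as.character(tie2$category), "PSO")
})

test_that("multinomial fit agrees with the nnet reference", {
  skip_if_not_installed("nnet")
  mk <- mk_pool(seed = 83)
  r <- fit_multinomial(mk$pool, "sim00001")
  df <- data.frame(y = factor(as.character(mk$pool$phenotype),
                              levels = c("control", "AD", "PSO")),
                   g = mk$pool$dosages[, 1],
                   sex = as.integer(mk$pool$sex) - 1L,
                   mk$pool$covariates)
  ref <- nnet::multinom(y ~ ., df, trace = FALSE, reltol = 1e-14, maxit = 500)
  co <- coef(ref)
  expect_equal(r$beta_AD, co["AD", "g"], tolerance = 1e-5)
  expect_equal(r$beta_PSO, co["PSO", "g"], tolerance = 1e-5)
  V <- vcov(ref)
  expect_equal(r$se_AD, sqrt(V["AD:g", "AD:g"]), tolerance = 1e-3)
  expect_equal(r$se_PSO, sqrt(V["PSO:g", "PSO:g"]), tolerance = 1e-3)
})

test_that("multinomial fit is null-calibrated and refuses degenerate data", {
  mk <- mk_pool(seed = 84)
  nulls <- mk$truth$variant_id[mk$truth$class == "null"]
  hits <- 0
  for (s in 1:20) {
    sim <- simulate_cohorts(
      sim_config(n_per_class = c(AD_only = 0, PSO_only = 0, shared = 0,
                                 opposing = 0, null = 1)),
      method = "conditional", seed = 8400 + s)
    pool <- pool_panels(sim$panels)
    r <- fit_multinomial(pool, 1)
    if (abs(r$beta_AD) < 3 * r$se_AD && abs(r$beta_PSO) < 3 * r$se_PSO)
      hits <- hits + 1
  }
  expect_gte(hits, 19)

  # two-category data refused
  two <- mk$pool
  keep <- two$phenotype != "PSO"
  two <- genotype_panel(two$sample_ids[keep], two$dosages[keep, ],
                        two$variants, two$phenotype[keep], two$sex[keep],
                        two$covariates[keep, ])
  expect_error(fit_multinomial(two, 1), "three outcome categories")
})

test_that("multinomial recovers per-disease effects with nominal coverage", {
  covered_ad <- 0; covered_pso <- 0; n_rep <- 30
  for (s in seq_len(n_rep)) {
    sim <- simulate_cohorts(
      sim_config(n_per_class = c(AD_only = 1, PSO_only = 0, shared = 0,
                                 opposing = 0, null = 0),
                 cohorts = data.frame(        # homogeneous population:
                   cohort = c("AD1", "PSO1"), # coverage needs a correctly
                   disease = c("AD", "PSO"),  # specified model
                   subphenotype = "general", ancestry_scale = 0,
                   n_cases = c(800L, 800L), n_controls = c(1200L, 1200L))),
      method = "conditional", seed = 8500 + s)
    r <- fit_multinomial(pool_panels(sim$panels), 1)
    or_true <- exp(sim$truth$beta_AD[1])           # CI is on the OR scale
    if (r$ci_AD[1] <= or_true && or_true <= r$ci_AD[2])
      covered_ad <- covered_ad + 1
    if (r$ci_PSO[1] <= 1 && 1 <= r$ci_PSO[2]) covered_pso <- covered_pso + 1
  }
  expect_gte(covered_ad, 25)      # ~95% nominal over 30 replicates
  expect_gte(covered_pso, 25)
})

test_that("p_AD tracks the binary logistic p-value", {
  mk <- mk_pool(n_per_class = c(AD_only = 3, PSO_only = 0, shared = 0,
                                opposing = 0, null = 3), seed = 86)
  for (v in mk$truth$variant_id[mk$truth$class == "AD_only"]) {
    r <- fit_multinomial(mk$pool, v)
    keep <- mk$pool$phenotype != "PSO"
    bin <- genotype_panel(mk$pool$sample_ids[keep], mk$pool$dosages[keep, ],
                          mk$pool$variants, mk$pool$phenotype[keep],
                          mk$pool$sex[keep], mk$pool$covariates[keep, ])
    rb <- study_logistic_assoc(bin, v)
    expect_equal(log(r$p_AD), log(rb$p), tolerance = 0.1)
  }
})

test_that("well-powered variants are classified to their generating class", {
  mk <- mk_pool(n_per_class = c(AD_only = 10, PSO_only = 10, shared = 10,
                                opposing = 10, null = 0), seed = 87)
  scan <- mnm_scan(mk$pool)
  acc <- mean(scan$category == sub("_only", "", mk$truth$class))
  expect_gte(acc, 0.9)
  # reported OR and CI are exp(beta -/+ 1.96 se) exactly
  r <- fit_multinomial(mk$pool, 1)
  expect_equal(r$or_AD, exp(r$beta_AD))
  expect_equal(r$ci_AD, exp(r$beta_AD + c(-1, 1) * 1.96 * r$se_AD))
})

test_that("stepwise conditional analysis dissects multi-signal regions", {
  set.seed(88)
  n <- 4000
  # two causal variants in weak LD plus proxies of the first
  hap_pair <- function(p1, p2, r) {
    # haplotype copying: second allele copies first with prob r
    h1 <- rbinom(n, 1, p1)
    h2 <- ifelse(rbinom(n, 1, r) == 1, h1, rbinom(n, 1, p2))
    cbind(h1, h2)
  }
  mk_geno <- function() {
    a <- hap_pair(0.4, 0.4, 0.32); b <- hap_pair(0.4, 0.4, 0.32)
    g1 <- a[, 1] + b[, 1]; g2 <- a[, 2] + b[, 2]      # r2 ~ 0.1
    prox <- function(g) {            # strong proxy of g1 (r2 >= 0.8)
      flip <- rbinom(n, 1, 0.03)
      h <- a[, 1]; h2 <- ifelse(flip == 1, 1 - h, h)
      f <- rbinom(n, 1, 0.03)
      hb <- b[, 1]; hb2 <- ifelse(f == 1, 1 - hb, hb)
      h2 + hb2
    }
    cbind(g1, g2, prox(), prox(), prox())
  }
  G <- mk_geno()
  eta_ad <- -2 + 0.5 * G[, 1] + 0.5 * G[, 2]
  eta_pso <- -2.5 + 0.4 * G[, 1]
  u <- runif(n)
  ph <- ifelse(u < 1 / (1 + exp(-eta_ad)) * 0.5, "AD",
               ifelse(u > 1 - 1 / (1 + exp(-eta_pso)) * 0.5, "PSO", "control"))
  vk <- variant_key(paste0("v", 1:5), "1", c(1e5, 2e5, 1.1e5, 1.2e5, 1.3e5),
                    "A", "G")
  pan <- genotype_panel(paste0("s", 1:n), G, vk, ph)
  expect_gte(genotype_r2(G[, 1], G[, 3]), 0.8)
  expect_lt(genotype_r2(G[, 1], G[, 2]), 0.3)

  res <- stepwise_conditional(pan, paste0("v", 1:5), stop_p = 1e-4)
  expect_setequal(res$conditioning, c("v1", "v2"))
  expect_equal(nrow(res$full_model), 2)

  # proxies alone collapse to a single signal
  pan1 <- genotype_panel(paste0("s", 1:n), G[, c(1, 3, 4, 5)],
                         vk[c(1, 3, 4, 5), ], ph)
  res1 <- stepwise_conditional(pan1, c("v1", "v3", "v4", "v5"), stop_p = 1e-4)
  expect_equal(length(res1$conditioning), 1)

  # degenerate threshold selects nothing
  res0 <- stepwise_conditional(pan, paste0("v", 1:5), stop_p = 0)
  expect_equal(length(res0$conditioning), 0)
  expect_equal(nrow(res0$signals), 0)
})
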