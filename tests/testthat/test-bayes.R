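test_that("distance model applies the disease and subphenotype inflation rules", {
  # two studies at ethnic distance 1
  cent <- matrix(c(0, 0, 1, 0), 2, 2, byrow = TRUE)
  same <- build_distance_model(cent, c("AD", "AD"))
  expect_equal(same$D_Total[1, 2], 1)                  # D_Disease = 0
  cross <- build_distance_model(cent, c("AD", "PSO"))
  expect_equal(cross$D_Total[1, 2], 1 + 2 * 1)         # 2 x max rule
  subph <- build_distance_model(cent, c("AD", "AD"),
                                subphenotype = c("general", "childhood"))
  expect_equal(subph$D_Total[1, 2], 1 + 1)             # max rule
  for (m in list(same, cross, subph)) {
    expect_true(isSymmetric(m$D_Total))
    expect_equal(diag(m$D_Total), c(0, 0), ignore_attr = TRUE)
    expect_equal(m$D_Total, m$D_Disease + m$D_Ethnicity)
  }
  expect_error(build_distance_model(cent, c("AD", NA)), "labels")
})

test_that("partition enumeration is exhaustive, merged and normalised", {
  # two studies: exactly the two set partitions
  cent <- matrix(c(0, 0, 1, 0), 2, 2, byrow = TRUE)
  pp2 <- enumerate_partitions(build_distance_model(cent, c("AD", "AD")))
  expect_equal(length(pp2$partitions), 2)
  expect_setequal(vapply(pp2$partitions, paste, "", collapse = ""),
                  c("11", "12"))
  expect_equal(sum(pp2$weight), 1)

  # three equidistant studies: at most Bell(3) = 5 distinct partitions
  tri <- matrix(c(0, 0, 1, 0, 0.5, sqrt(3) / 2), 3, 2, byrow = TRUE)
  pp3 <- enumerate_partitions(build_distance_model(tri, rep("AD", 3)))
  expect_lte(length(pp3$partitions), 5)
  expect_equal(sum(pp3$weight), 1)
  # brute force over (T, center-set) pairs reproduces the weights
  D <- build_distance_model(tri, rep("AD", 3))$D_Total
  tally <- new.env(parent = emptyenv())
  n_pairs <- 0
  for (T in 1:3) for (cs in utils::combn(3, T, simplify = FALSE)) {
    n_pairs <- n_pairs + 1
    lab <- cs[apply(D[, cs, drop = FALSE], 1, which.min)]
    key <- paste(match(lab, unique(lab)), collapse = "")
    tally[[key]] <- (if (is.null(tally[[key]])) 0 else tally[[key]]) + 1
  }
  for (i in seq_along(pp3$partitions)) {
    key <- paste(pp3$partitions[[i]], collapse = "")
    expect_equal(pp3$weight[i], tally[[key]] / n_pairs)
  }
})

test_that("every mixed-centre-set partition separates the diseases", {
  pp <- enumerate_partitions(six_study_model())
  expect_equal(sum(pp$weight), 1)
  # multi-cluster partitions induced by centre sets containing both
  # diseases always split AD from PSO: cross-disease merging can only come
  # from single-disease centre sets
  labs <- pp$partitions
  mixed_ok <- vapply(labs, function(l) {
    n_clust <- length(unique(l))
    sep <- separates_diseases(l)
    ad_side <- unique(l[1:3]); pso_side <- unique(l[4:6])
    sep || length(ad_side) == 1 || length(pso_side) == 1
  }, TRUE)
  expect_true(all(mixed_ok))
  # and the top-weighted partition is the clean two-disease split
  expect_true(separates_diseases(pp$partitions[[1]]))
})

test_that("single-study Bayes factor matches the closed univariate form", {
  cent <- matrix(c(0, 0, 1, 0), 2, 2, byrow = TRUE)
  pp1 <- structure(list(partitions = list(1L), weight = 1, study_ids = "a"),
                   class = "partition_prior")
  b <- 0.25; s <- 0.08; W <- 0.04
  r <- log10_bayes_factor(b, s, pp1, W)
  hand <- sqrt(s^2 / (s^2 + W)) * exp(b^2 * W / (2 * s^2 * (s^2 + W)))
  expect_equal(r$log10_bf, log10(hand), tolerance = 1e-10)
})

test_that("partition Bayes factor matches numerical quadrature", {
  set.seed(71)
  tri <- matrix(c(0, 0, 1, 0, 0.5, 0.9), 3, 2, byrow = TRUE)
  pp <- enumerate_partitions(build_distance_model(tri, c("AD", "AD", "PSO")))
  for (i in 1:5) {
    beta <- rnorm(3, 0, 0.3); se <- runif(3, 0.05, 0.2); W <- runif(1, 0.02, 0.1)
    got <- log10_bayes_factor(beta, se, pp, W)$log10_bf
    expect_equal(got, bf_quadrature_oracle(beta, se, pp, W), tolerance = 1e-6)
  }
  # evidence for the null when all effects are zero
  expect_lt(log10_bayes_factor(rep(0, 3), rep(0.1, 3), pp, 0.04)$log10_bf, 0)
})

test_that("BFDP is the posterior null probability with prior odds PO", {
  expect_equal(bfdp(0, PO = 1), 0.5)
  expect_equal(bfdp(log10(99 * 19), PO = 99), 0.05, tolerance = 1e-12)
  expect_equal(bfdp(300, PO = 99), 0)
  expect_lt(bfdp(2, 99), bfdp(1, 99))     # decreasing in BF
  expect_error(bfdp(1, PO = 0), "PO")
})

test_that("posterior partition mass follows the true effect structure", {
  model <- six_study_model()
  pp <- enumerate_partitions(model)
  # shared effect, no disease inflation: one-cluster partition dominates
  flat <- model; flat$D_Disease[] <- 0; flat$D_Total <- flat$D_Ethnicity
  ppf <- enumerate_partitions(flat)
  bf <- log10_bayes_factor(rep(0.3, 6), rep(0.03, 6), ppf, W = 0.04)
  best <- ppf$partitions[[which.max(bf$posterior_partition)]]
  expect_equal(length(unique(best)), 1)

  # opposing effects at b/se = 3: maximum-posterior partition separates
  # diseases in >= 95% of seeds
  hits <- 0; n_seed <- 60
  for (s in seq_len(n_seed)) {
    set.seed(100 + s)
    beta <- c(rnorm(3, 0.15, 0.05), rnorm(3, -0.15, 0.05))
    r <- log10_bayes_factor(beta, rep(0.05, 6), pp, W = 0.04)
    best <- pp$partitions[[which.max(r$posterior_partition)]]
    if (separates_diseases(best)) hits <- hits + 1
  }
  expect_gte(hits / n_seed, 0.95)
})

test_that("ethnicity-only prior ranks variants concordantly with the full prior", {
  cfg <- sim_config(n_per_class = c(AD_only = 30, PSO_only = 30, shared = 30,
                                    opposing = 30, null = 60))
  sim <- simulate_summary_stats(cfg, seed = 73)
  h <- harmonize_alleles(sim$studies, sim$studies[[1]])
  model <- six_study_model()
  model$study_ids <- vapply(sim$studies, function(s) s$study_id, "")
  eth_only <- model
  eth_only$D_Disease[] <- 0
  eth_only$D_Total <- eth_only$D_Ethnicity
  full <- bayes_meta(h, enumerate_partitions(model))
  eth <- bayes_meta(h, enumerate_partitions(eth_only))
  expect_gt(cor(full$log10_bf, eth$log10_bf, method = "spearman"), 0.95)
  # and the sets passing the conventional filter largely coincide
  a <- full$variant_id[full$bfdp < 0.05]
  b <- eth$variant_id[eth$bfdp < 0.05]
  expect_gt(length(intersect(a, b)) / length(union(a, b)), 0.8)
})

test_that("bayes_meta and CCMA select overlapping strong variants", {
  cfg <- sim_config(n_per_class = c(AD_only = 40, PSO_only = 40, shared = 40,
                                    opposing = 40, null = 100))
  sim <- simulate_summary_stats(cfg, seed = 72)
  h <- harmonize_alleles(sim$studies, sim$studies[[1]])
  model <- six_study_model()
  model$study_ids <- vapply(sim$studies, function(s) s$study_id, "")
  pp <- enumerate_partitions(model)
  bm <- bayes_meta(h, pp, W = 0.04, PO = 99)
  cc <- ccma(meta_analyse(h[1:3]), meta_analyse(h[4:6]))
  sel_bf <- bm$variant_id[bm$bfdp < 0.05]
  sel_cc <- cc$variant_id[cc$T_max > 4.7]
  jac <- length(intersect(sel_bf, sel_cc)) / length(union(sel_bf, sel_cc))
  expect_gt(jac, 0.5)
  expect_gt(length(sel_bf), 100)     # most of the 160 non-null variants
})
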