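# Independent oracles and small fixture builders used across the suite.
# Each oracle re-derives the quantity from its definition by a route
# different from the package implementation.

# Exact HWE p by direct enumeration: conditional probability of h
# heterozygotes given allele counts is proportional to
# n! / (nAA! h! naa!) * 2^h; sum probabilities <= observed (with relative
# tie tolerance matching the implementation's).
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  rare <- min(nA, na)
  if (rare == 0) return(1)
  hs <- seq(rare %% 2, rare, by = 2)
  logp <- vapply(hs, function(h) {
    hom_r <- (rare - h) / 2
    hom_c <- n - h - hom_r
    lgamma(n + 1) - lgamma(hom_r + 1) - lgamma(h + 1) - lgamma(hom_c + 1) +
      h * log(2)
  }, 0)
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  pobs <- pr[match(n_Aa, hs)]
  sum(pr[pr <= pobs * (1 + 1e-12)])
}

# vectorised HWE oracle over all het values for one (n, nA): returns the
# p-value for every possible observed heterozygote count, smallest-first
hwe_oracle_all <- function(n, nA) {
  na <- 2 * n - nA
  rare <- min(nA, na)
  if (rare == 0) return(1)
  hs <- seq(rare %% 2, rare, by = 2)
  hom_r <- (rare - hs) / 2
  hom_c <- n - hs - hom_r
  logp <- lgamma(n + 1) - lgamma(hom_r + 1) - lgamma(hs + 1) -
    lgamma(hom_c + 1) + hs * log(2)
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  # p-value for observed h = mass of configurations no more probable:
  # sort ascending, cumulative-sum, look up each h's cutoff
  o <- order(pr)
  cs <- cumsum(pr[o])
  idx <- findInterval(pr * (1 + 1e-12), pr[o])
  pmin(cs[idx], 1)
}

# Greedy clumping re-derived from its definition with plain loops and
# per-pair genotype_r2 calls (no vectorisation, no shared code path).
clump_oracle <- function(results, panel, stat_col, stat_threshold,
                         max_dist, min_r2) {
  res <- results[results[[stat_col]] > stat_threshold, , drop = FALSE]
  res <- res[res$variant_id %in% panel$variants$variant_id, , drop = FALSE]
  out <- list()
  while (nrow(res) > 0) {
    best <- which(res[[stat_col]] == max(res[[stat_col]]))
    if (length(best) > 1) best <- best[which.min(res$pos[best])]
    lead <- res[best, , drop = FALSE]
    members <- lead$variant_id
    gi <- function(id) panel$dosages[, match(id, panel$variants$variant_id)]
    for (i in seq_len(nrow(res))) {
      if (i == best) next
      if (res$chrom[i] != lead$chrom) next
      if (abs(res$pos[i] - lead$pos) > max_dist) next
      r2 <- genotype_r2(gi(lead$variant_id), gi(res$variant_id[i]))
      if (!is.na(r2) && r2 >= min_r2) members <- c(members, res$variant_id[i])
    }
    out[[length(out) + 1]] <- list(lead = lead$variant_id, members = sort(members))
    res <- res[!(res$variant_id %in% members), , drop = FALSE]
  }
  out
}

# Partition-model Bayes factor by numerical quadrature of each cluster
# integral (same prior weights, independent marginal-likelihood route).
bf_quadrature_oracle <- function(beta, se, prior, W) {
  cluster_ratio <- function(b, s) {
    num <- integrate(function(x)
      dnorm(x, 0, sqrt(W)) *
        vapply(x, function(xx) prod(dnorm(b, xx, s)), 0),
      lower = -10, upper = 10, rel.tol = 1e-12, abs.tol = 0)$value
    num / prod(dnorm(b, 0, s))
  }
  terms <- vapply(seq_along(prior$partitions), function(pi_) {
    lab <- prior$partitions[[pi_]]
    prior$weight[pi_] *
      prod(vapply(unique(lab), function(k)
        cluster_ratio(beta[lab == k], se[lab == k]), 0))
  }, 0)
  log10(sum(terms))
}

# random panel + association results for clump testing: blocks of
# correlated variants, random statistics, one or two chromosomes
mk_clump_fixture <- function(m, n = 80, n_chrom = 2, seed = 1) {
  set.seed(seed)
  dos <- matrix(NA_real_, n, m)
  j <- 1
  while (j <= m) {
    p <- runif(1, 0.1, 0.9)
    base <- rbinom(n, 1, p) + rbinom(n, 1, p)
    len <- min(sample(1:3, 1), m - j + 1)
    for (k in seq_len(len)) {
      noise <- rbinom(n, 1, 0.15)
      g <- ifelse(noise == 1, rbinom(n, 1, p) + rbinom(n, 1, p), base)
      dos[, j + k - 1] <- g
    }
    j <- j + len
  }
  chrom <- sort(sample(as.character(seq_len(n_chrom)), m, TRUE))
  pos <- unlist(tapply(seq_len(m), chrom, function(i)
    sort(sample.int(6e5, length(i)))))
  vk <- variant_key(paste0("v", 1:m), chrom, pos, "A", "G")
  pan <- genotype_panel(paste0("s", 1:n), dos, vk)
  res <- data.frame(variant_id = vk$variant_id, chrom = vk$chrom,
                    pos = vk$pos, stat = round(runif(m, 0, 10), 2),
                    stringsAsFactors = FALSE)
  list(panel = pan, results = res)
}

# six-study distance model typical of a 3 AD + 3 PSO design with modest
# ancestry offsets
six_study_model <- function() {
  cent <- matrix(c(0, 0, 0.2, 0.1, 0.1, 0.3,
                   1.0, 1.0, 1.2, 1.0, 1.1, 1.2), ncol = 2, byrow = TRUE)
  rownames(cent) <- c("AD1", "AD2", "AD3", "PSO1", "PSO2", "PSO3")
  build_distance_model(cent,
                       disease = c("AD", "AD", "AD", "PSO", "PSO", "PSO"),
                       subphenotype = c("general", "general", "childhood",
                                        "general", "general", "general"))
}

# small HWE genotype vector at frequency p
hwe_dosages <- function(n, p) rbinom(n, 1, p) + rbinom(n, 1, p)

# does a partition (cluster-label vector over the 6-study model) keep AD
# studies (1:3) and PSO studies (4:6) in disjoint clusters?
separates_diseases <- function(lab) {
  !any(vapply(unique(lab), function(k) {
    idx <- which(lab == k)
    any(idx <= 3) && any(idx > 3)
  }, TRUE))
}

# tiny well-formed summary TSV
write_toy_summary <- function(path, n = 3, se = rep(0.1, n)) {
  df <- data.frame(SNP = paste0("rs", seq_len(n)), CHR = "1",
                   POS = seq_len(n) * 1000, EA = "A", OA = "G",
                   EAF = seq(0.2, 0.4, length.out = n),
                   BETA = seq(-0.1, 0.1, length.out = n), SE = se,
                   P = rep(0.5, n), N_CASES = 100, N_CONTROLS = 200,
                   INFO = 0.99)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  df
}
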