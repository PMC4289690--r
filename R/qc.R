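# Variant- and sample-level quality control, identity-by-state relatedness,
# classical MDS of the IBS matrix, and genomic-control inflation.

#' Default QC thresholds
#'
#' Bundles the filtering thresholds used throughout QC. Defaults: variant
#' missingness > 5% excluded, MAF < 5% excluded, Hardy-Weinberg exact
#' p < 1e-8 excluded, imputation info < 0.4 excluded (strict `<`),
#' call rate < 95% excluded, sample missingness > 5% excluded, and pairs
#' with PI_HAT > 0.1875 (halfway between expected IBD sharing of third- and
#' second-degree relatives) reduced to one member.
#'
#' @param max_variant_missing,min_maf,min_hwe_p,min_info,min_call_rate,max_pihat,max_sample_missing
#'   numeric scalars as described above.
#' @param het_sd heterozygosity outlier bound in sample SD units (mean +/-
#'   `het_sd` x SD; default 3).
#' @return A named list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(max_variant_missing = 0.05, min_maf = 0.05,
                          min_hwe_p = 1e-8, min_info = 0.4,
                          min_call_rate = 0.95, max_pihat = 0.1875,
                          max_sample_missing = 0.05, het_sd = 3) {
  th <- list(max_variant_missing = max_variant_missing, min_maf = min_maf,
             min_hwe_p = min_hwe_p, min_info = min_info,
             min_call_rate = min_call_rate, max_pihat = max_pihat,
             max_sample_missing = max_sample_missing, het_sd = het_sd)
  fr <- c("max_variant_missing", "min_maf", "min_call_rate",
          "max_sample_missing")
  stopifnot(all(unlist(th[fr]) >= 0), all(unlist(th[fr]) <= 1))
  structure(th, class = "qc_thresholds")
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test on genotype counts: conditional on the allele
#' counts, sums the probabilities of all heterozygote configurations no more
#' probable than the observed one. Monomorphic variants return p = 1 by
#' convention. Vectorised over the three count vectors.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (recycled to common length).
#' @return p-values in (0, 1\].
#' @export
hwe_exact_p <- function(n_AA, n_Aa, n_aa) {
  m <- max(length(n_AA), length(n_Aa), length(n_aa))
  n_AA <- rep_len(as.integer(n_AA), m)
  n_Aa <- rep_len(as.integer(n_Aa), m)
  n_aa <- rep_len(as.integer(n_aa), m)
  if (any(n_AA + n_Aa + n_aa <= 0)) stop("total genotype count must be > 0")
  .hwe_exact_cpp(n_AA, n_Aa, n_aa)
}

# genotype counts from (possibly fractional) dosages; rounds to best guess
.genotype_counts <- function(dosages) {
  g <- round(dosages)
  n_aa <- colSums(g == 0, na.rm = TRUE)   # other-allele homozygote
  n_Aa <- colSums(g == 1, na.rm = TRUE)
  n_AA <- colSums(g == 2, na.rm = TRUE)   # effect-allele homozygote
  cbind(n_AA = n_AA, n_Aa = n_Aa, n_aa = n_aa)
}

#' Variant-level QC filtering
#'
#' Applies the variant filters as a pure conjunction of per-variant
#' predicates; a variant is removed iff it violates at least one threshold,
#' and every removal is annotated with all applicable reason codes
#' (`"missing"`, `"maf"`, `"hwe"`, `"info"`, `"callrate"`). For a
#' [genotype_panel()], missingness/call-rate, MAF and HWE are computed from
#' the dosages (HWE from controls only when phenotypes are present, the
#' usual convention). For a [study_summary()], only MAF (from `eaf`) and
#' info can be checked.
#'
#' @param x a [genotype_panel()] or [study_summary()].
#' @param thresholds a [qc_thresholds()].
#' @return List with `retained` (character vector of variant ids), and
#'   `failures` (data.frame `variant_id`, `reasons` — comma-joined codes).
#' @export
filter_variants <- function(x, thresholds = qc_thresholds()) {
  if (inherits(x, "genotype_panel")) {
    ids <- x$variants$variant_id
    if (!length(ids)) stop("empty panel")
    miss <- colMeans(is.na(x$dosages))
    ctrl <- x$phenotype == "control"
    hwe_rows <- if (any(ctrl)) x$dosages[ctrl, , drop = FALSE] else x$dosages
    gc <- .genotype_counts(hwe_rows)
    tot <- rowSums(gc)
    hwe <- ifelse(tot > 0, hwe_exact_p(gc[, 1], gc[, 2], gc[, 3]), 1)
    eaf <- colMeans(x$dosages, na.rm = TRUE) / 2
    maf <- pmin(eaf, 1 - eaf)
    fail <- list(
      missing = miss > thresholds$max_variant_missing,
      callrate = (1 - miss) < thresholds$min_call_rate,
      maf = maf < thresholds$min_maf,
      hwe = hwe < thresholds$min_hwe_p)
  } else if (inherits(x, "study_summary")) {
    rec <- x$records
    ids <- rec$variant_id
    if (!length(ids)) stop("empty study")
    maf <- pmin(rec$eaf, 1 - rec$eaf)
    fail <- list(
      maf = maf < thresholds$min_maf,
      info = !is.na(rec$info) & rec$info < thresholds$min_info)
  } else stop("x must be a genotype_panel or study_summary")
  failmat <- do.call(cbind, fail)
  any_fail <- rowSums(failmat) > 0
  reasons <- apply(failmat[any_fail, , drop = FALSE], 1, function(r)
    paste(names(fail)[r], collapse = ","))
  list(retained = ids[!any_fail],
       failures = data.frame(variant_id = ids[any_fail],
                             reasons = as.character(reasons),
                             stringsAsFactors = FALSE))
}

#' Method-of-moments relatedness (PI_HAT) for a sample pair
#'
#' Estimates the proportion of the genome shared identical-by-descent for
#' one pair of samples from identity-by-state counts and allele
#' frequencies, in the method-of-moments style of standard GWAS toolkits:
#' expected IBS-class counts under IBD states 0/1/2 are accumulated across
#' variants from the panel-wide allele frequencies, the IBD-state
#' proportions are solved sequentially, clipped to \[0,1\] and renormalised,
#' and `PI_HAT = P(IBD=1)/2 + P(IBD=2)`.
#'
#' Dosages are rounded to best-guess genotypes. Variants should be pruned
#' for LD beforehand (see [prune_ld()]); fewer than 100 jointly non-missing
#' variants triggers a warning.
#'
#' @param panel a [genotype_panel()].
#' @param pair length-2 vector of sample ids (or indices).
#' @return List of class `relatedness_estimate`: `sample_pair`, `ibs0`,
#'   `ibs1`, `ibs2`, `pihat`.
#' @export
estimate_relatedness <- function(panel, pair) {
  stopifnot(inherits(panel, "genotype_panel"), length(pair) == 2)
  idx <- if (is.numeric(pair)) as.integer(pair) else match(pair, panel$sample_ids)
  if (anyNA(idx)) stop("pair samples not found in panel")
  g <- round(panel$dosages)
  a <- g[idx[1], ]; b <- g[idx[2], ]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) stop("no jointly non-missing variants for this pair")
  if (sum(ok) < 100) warning("fewer than 100 jointly non-missing variants; PI_HAT unstable")
  a <- a[ok]; b <- b[ok]
  p <- colMeans(panel$dosages, na.rm = TRUE)[ok] / 2
  usable <- p > 0 & p < 1
  a <- a[usable]; b <- b[usable]; p <- p[usable]; q <- 1 - p
  d <- abs(a - b)
  ibs0 <- sum(d == 2); ibs1 <- sum(d == 1); ibs2 <- sum(d == 0)
  # expected per-variant IBS-class probabilities given IBD state
  e0_ibs0 <- sum(2 * p^2 * q^2)
  e0_ibs1 <- sum(4 * p^3 * q + 4 * p * q^3)
  e0_ibs2 <- sum(p^4 + q^4 + 4 * p^2 * q^2)
  e1_ibs1 <- sum(2 * p^2 * q + 2 * p * q^2)
  e1_ibs2 <- sum(p^3 + q^3 + p^2 * q + p * q^2)
  m <- length(p)
  z0 <- ibs0 / e0_ibs0
  z1 <- (ibs1 - z0 * e0_ibs1) / e1_ibs1
  z2 <- (ibs2 - z0 * e0_ibs2 - z1 * e1_ibs2) / m
  z <- pmax(c(z0, z1, z2), 0)
  z <- z / sum(z)
  pihat <- min(max(z[2] / 2 + z[3], 0), 1)
  structure(list(sample_pair = panel$sample_ids[idx], ibs0 = ibs0,
                 ibs1 = ibs1, ibs2 = ibs2, pihat = pihat),
            class = "relatedness_estimate")
}

#' Pairwise PI_HAT for every sample pair
#'
#' Vectorised all-pairs version of [estimate_relatedness()]: IBS-class
#' counts come from genotype-indicator cross-products and the expected
#' class counts under each IBD state are accumulated over the jointly
#' observed variants of each pair, so the estimate matches the single-pair
#' function. Monomorphic variants are excluded.
#'
#' @param panel a [genotype_panel()] (ideally LD-pruned).
#' @return data.frame `id1`, `id2`, `pihat` over all unordered pairs.
#' @export
pihat_pairs <- function(panel) {
  g <- round(panel$dosages)
  p_all <- colMeans(panel$dosages, na.rm = TRUE) / 2
  keep <- p_all > 0 & p_all < 1 & !is.na(p_all)
  g <- g[, keep, drop = FALSE]
  p <- p_all[keep]; q <- 1 - p
  n <- nrow(g)
  obs <- !is.na(g)
  ind <- lapply(0:2, function(k) (g == k & obs) * 1)
  # observed IBS-class counts for all pairs
  ibs0 <- tcrossprod(ind[[1]], ind[[3]]) + tcrossprod(ind[[3]], ind[[1]])
  ibs1 <- tcrossprod(ind[[1]], ind[[2]]) + tcrossprod(ind[[2]], ind[[1]]) +
    tcrossprod(ind[[2]], ind[[3]]) + tcrossprod(ind[[3]], ind[[2]])
  joint <- tcrossprod(obs * 1)
  ibs2 <- joint - ibs0 - ibs1
  # expected class counts over jointly observed variants
  wsum <- function(w) (sweep(obs * 1, 2, w, `*`)) %*% t(obs * 1)
  e0_0 <- wsum(2 * p^2 * q^2)
  e0_1 <- wsum(4 * p^3 * q + 4 * p * q^3)
  e0_2 <- wsum(p^4 + q^4 + 4 * p^2 * q^2)
  e1_1 <- wsum(2 * p^2 * q + 2 * p * q^2)
  e1_2 <- wsum(p^3 + q^3 + p^2 * q + p * q^2)
  z0 <- ibs0 / e0_0
  z1 <- (ibs1 - z0 * e0_1) / e1_1
  z2 <- (ibs2 - z0 * e0_2 - z1 * e1_2) / pmax(joint, 1)
  z0 <- pmax(z0, 0); z1 <- pmax(z1, 0); z2 <- pmax(z2, 0)
  tot <- z0 + z1 + z2
  pihat <- pmin(pmax((z1 / 2 + z2) / tot, 0), 1)
  ut <- which(upper.tri(pihat), arr.ind = TRUE)
  data.frame(id1 = panel$sample_ids[ut[, 1]], id2 = panel$sample_ids[ut[, 2]],
             pihat = pihat[ut], stringsAsFactors = FALSE)
}

#' Window-based LD pruning
#'
#' Greedy pruning: slide a window of `window` variants with step `step`;
#' within each window, repeatedly drop one of any pair with dosage r^2 above
#' `max_r2` (the later variant is dropped). Used before IBD estimation.
#'
#' @param panel a [genotype_panel()].
#' @param window,step window size and slide step in variant counts.
#' @param max_r2 prune pairs above this squared correlation (default 0.2).
#' @return Character vector of retained variant ids.
#' @export
prune_ld <- function(panel, window = 50, step = 5, max_r2 = 0.2) {
  m <- ncol(panel$dosages)
  keep <- rep(TRUE, m)
  start <- 1
  while (start <= m) {
    win <- seq(start, min(start + window - 1, m))
    win <- win[keep[win]]
    if (length(win) > 1) {
      cc <- suppressWarnings(cor(panel$dosages[, win, drop = FALSE],
                                 use = "pairwise.complete.obs"))^2
      cc[is.na(cc)] <- 0
      for (j in seq_along(win)) {
        if (!keep[win[j]]) next
        hi <- which(cc[j, ] > max_r2)
        hi <- hi[hi > j & keep[win[hi]]]
        keep[win[hi]] <- FALSE
      }
    }
    if (start + window - 1 >= m) break
    start <- start + step
  }
  panel$variants$variant_id[keep]
}

#' Pairwise IBS distance matrix
#'
#' Mean per-variant identity-by-state dissimilarity `|g_i - g_j| / 2` over
#' jointly non-missing variants, for all sample pairs.
#'
#' @param panel a [genotype_panel()].
#' @return Symmetric `n x n` distance matrix with zero diagonal.
#' @export
ibs_distance <- function(panel) {
  g <- round(panel$dosages)
  n <- nrow(g)
  obs <- !is.na(g)
  g0 <- g; g0[!obs] <- 0
  # |gi-gj| summed: use expansion over the 3 genotype classes
  d <- matrix(0, n, n)
  cnt <- tcrossprod(obs * 1)              # jointly observed counts
  for (ai in 0:2) for (bi in 0:2) {
    if (ai >= bi) next
    A <- (g0 == ai & obs) * 1
    B <- (g0 == bi & obs) * 1
    d <- d + abs(ai - bi) * (tcrossprod(A, B) + tcrossprod(B, A))
  }
  d <- d / (2 * pmax(cnt, 1))
  dimnames(d) <- list(panel$sample_ids, panel$sample_ids)
  d
}

#' Classical MDS of the IBS matrix
#'
#' Classical (Torgerson) multidimensional scaling of the pairwise IBS
#' distance matrix: double-centred squared-distance eigendecomposition,
#' axes ordered by decreasing eigenvalue. Coordinates are deterministic up
#' to the sign of each axis. Rank-deficient inputs return fewer axes with a
#' warning.
#'
#' @param panel a [genotype_panel()], or a precomputed symmetric distance
#'   matrix.
#' @param k number of dimensions requested.
#' @return Numeric matrix `samples x k'` (`k' <= k`) of coordinates.
#' @export
mds_of_ibs <- function(panel, k = 4) {
  d <- if (inherits(panel, "genotype_panel")) ibs_distance(panel) else as.matrix(panel)
  if (nrow(d) < k + 1) stop("need at least k+1 samples")
  fit <- suppressWarnings(cmdscale(d, k = k, eig = TRUE))
  pts <- fit$points
  if (ncol(pts) < k)
    warning("distance matrix rank-deficient: returning ", ncol(pts), " axes")
  pts
}

#' Sample-level QC
#'
#' Flags and removes samples with (i) missingness above threshold, (ii)
#' heterozygosity beyond mean +/- `het_sd` SD (excess heterozygosity or
#' homozygosity), then (iii) one member of each pair with
#' `PI_HAT > max_pihat` on an LD-pruned variant set — the member with the
#' higher missingness is dropped. Applied before variant-level filters.
#'
#' @param panel a [genotype_panel()].
#' @param thresholds a [qc_thresholds()].
#' @param pihat_pairs optionally, a precomputed data.frame `id1,id2,pihat`;
#'   when `NULL`, all pairs are estimated with [pihat_pairs()] on an
#'   LD-pruned variant set.
#' @return List: `retained` ids, `exclusions` data.frame (`sample_id`,
#'   `reason`).
#' @export
qc_samples <- function(panel, thresholds = qc_thresholds(), pihat_pairs = NULL) {
  g <- round(panel$dosages)
  miss <- rowMeans(is.na(g))
  het <- rowMeans(g == 1, na.rm = TRUE)
  het_mu <- mean(het); het_sd_ <- sd(het)
  excl <- list()
  bad_miss <- miss > thresholds$max_sample_missing
  bad_het <- het_sd_ > 0 & abs(het - het_mu) > thresholds$het_sd * het_sd_
  for (i in which(bad_miss)) excl[[length(excl) + 1]] <-
    c(panel$sample_ids[i], "missingness")
  for (i in which(bad_het & !bad_miss)) excl[[length(excl) + 1]] <-
    c(panel$sample_ids[i], "heterozygosity")
  alive <- !(bad_miss | bad_het)
  if (is.null(pihat_pairs)) {
    ids <- panel$sample_ids[alive]
    keepv <- prune_ld(panel)
    sub <- genotype_panel(ids,
                          panel$dosages[alive, match(keepv, panel$variants$variant_id),
                                        drop = FALSE],
                          panel$variants[match(keepv, panel$variants$variant_id), ,
                                         drop = FALSE])
    pihat_pairs <- crosspheno::pihat_pairs(sub)
  }
  flag <- pihat_pairs[pihat_pairs$pihat > thresholds$max_pihat, , drop = FALSE]
  for (i in seq_len(nrow(flag))) {
    m1 <- miss[match(flag$id1[i], panel$sample_ids)]
    m2 <- miss[match(flag$id2[i], panel$sample_ids)]
    drop_id <- if (m1 >= m2) flag$id1[i] else flag$id2[i]
    j <- match(drop_id, panel$sample_ids)
    if (alive[j]) {
      alive[j] <- FALSE
      excl[[length(excl) + 1]] <- c(drop_id, "relatedness")
    }
  }
  exclusions <- if (length(excl))
    data.frame(sample_id = vapply(excl, `[`, "", 1),
               reason = vapply(excl, `[`, "", 2), stringsAsFactors = FALSE)
  else data.frame(sample_id = character(), reason = character())
  list(retained = panel$sample_ids[alive], exclusions = exclusions)
}

#' Genomic-control inflation factor
#'
#' `lambda = median(qchisq(1 - p, 1)) / qchisq(0.5, 1)` — the median
#' association chi-square over its theoretical null median (computed, not
#' hard-coded).
#'
#' @param p_values numeric vector of association p-values (>= 100 expected).
#' @return List of class `inflation_estimate`: `lambda_gc`, `n_variants`.
#' @export
lambda_gc <- function(p_values) {
  p_values <- p_values[is.finite(p_values)]
  if (length(p_values) < 100)
    warning("fewer than 100 p-values; lambda estimate unstable")
  chisq <- qchisq(p_values, df = 1, lower.tail = FALSE)
  lam <- median(chisq) / qchisq(0.5, df = 1)
  structure(list(lambda_gc = lam, n_variants = length(p_values)),
            class = "inflation_estimate")
}
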