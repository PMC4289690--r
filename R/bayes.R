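# Bayesian partition-model meta-analysis over all studies of both diseases,
# with a composite disease/ethnicity distance prior, exhaustively enumerated
# partitions, conjugate-normal cluster marginal likelihoods, and Bayesian
# false discovery probability filtering.

#' Build the composite study distance model
#'
#' `D_Ethnicity` is the matrix of pairwise Euclidean distances between study
#' centroids in MDS space (the "genetic distance" between study centres).
#' `D_Disease` inflates cross-phenotype pairs: entries are
#' `2 * max(D_Ethnicity)` for pairs of studies of different diseases,
#' `max(D_Ethnicity)` for same-disease pairs of different subphenotype
#' (e.g. general vs childhood collections), and 0 otherwise. The prior
#' distance is their sum, `D_Total = D_Disease + D_Ethnicity`.
#'
#' @param centroids numeric matrix, one row per study (MDS coordinates of
#'   the study centre); row names taken as study ids when present.
#' @param disease character vector of per-study disease labels (`AD`/`PSO`).
#' @param subphenotype character vector of per-study subphenotype labels
#'   (default all `"general"`).
#' @param study_ids optional character vector of ids.
#' @return Object of class `study_distance_model`: `study_ids`, `disease`,
#'   `subphenotype`, `centroids`, `D_Ethnicity`, `D_Disease`, `D_Total`.
#' @export
build_distance_model <- function(centroids, disease, subphenotype = NULL,
                                 study_ids = NULL) {
  centroids <- as.matrix(centroids)
  S <- nrow(centroids)
  stopifnot(S >= 2)
  if (is.null(study_ids))
    study_ids <- if (!is.null(rownames(centroids))) rownames(centroids)
                 else paste0("study", seq_len(S))
  if (is.null(subphenotype)) subphenotype <- rep("general", S)
  if (length(disease) != S || length(subphenotype) != S || anyNA(disease))
    stop("disease/subphenotype labels must be present for every study")
  d_eth <- as.matrix(dist(centroids))
  mx <- max(d_eth)
  cross <- outer(disease, disease, `!=`)
  subph <- !cross & outer(subphenotype, subphenotype, `!=`)
  d_dis <- matrix(0, S, S)
  d_dis[cross] <- 2 * mx
  d_dis[subph] <- mx
  dimnames(d_eth) <- dimnames(d_dis) <- list(study_ids, study_ids)
  structure(list(study_ids = study_ids, disease = as.character(disease),
                 subphenotype = as.character(subphenotype),
                 centroids = centroids, D_Ethnicity = d_eth,
                 D_Disease = d_dis, D_Total = d_dis + d_eth),
            class = "study_distance_model")
}

#' Enumerate the partition prior
#'
#' Center-based partition scheme: for every cluster count `T` and every
#' `T`-subset of studies taken as cluster centres, each study joins its
#' nearest centre under `D_Total` (distance ties resolved to the
#' lowest-index centre). Duplicate induced partitions are merged with their
#' weights summed, starting from a uniform prior over the `2^S - 1`
#' `(T, centre-set)` pairs. Exhaustive, hence exact, for a dozen or fewer
#' studies.
#'
#' @param model a [build_distance_model()] result.
#' @return Object of class `partition_prior`: `partitions` (list of integer
#'   cluster-assignment vectors, relabelled canonically), `weight` (sums to
#'   1), `study_ids`.
#' @export
enumerate_partitions <- function(model) {
  stopifnot(inherits(model, "study_distance_model"))
  S <- length(model$study_ids)
  if (S > 12) stop("exhaustive enumeration supports at most 12 studies")
  D <- model$D_Total
  seen <- new.env(parent = emptyenv())
  n_pairs <- 0L
  for (T in seq_len(S)) {
    centers_sets <- utils::combn(S, T, simplify = FALSE)
    for (cs in centers_sets) {
      n_pairs <- n_pairs + 1L
      dmat <- D[, cs, drop = FALSE]
      assign_to <- cs[max.col(-dmat, ties.method = "first")]
      # canonical relabelling: clusters numbered by first appearance
      lab <- match(assign_to, unique(assign_to))
      key <- paste(lab, collapse = ".")
      prev <- if (!is.null(seen[[key]])) seen[[key]] else list(lab = lab, w = 0)
      prev$w <- prev$w + 1
      seen[[key]] <- prev
    }
  }
  keys <- ls(seen)
  parts <- lapply(keys, function(k) seen[[k]]$lab)
  w <- vapply(keys, function(k) seen[[k]]$w, 0) / n_pairs
  o <- order(-w)
  structure(list(partitions = parts[o], weight = unname(w[o]),
                 study_ids = model$study_ids),
            class = "partition_prior")
}

# log of the cluster marginal-likelihood ratio against the null for one
# cluster: integral of N(b; 0, W) * prod N(beta_i; b, se_i^2) db over
# prod N(beta_i; 0, se_i^2), in closed conjugate form.
.log_cluster_ratio <- function(beta, se, W) {
  prec <- 1 / se^2
  lam <- 1 / W + sum(prec)
  mu <- sum(prec * beta) / lam
  -0.5 * log(W * lam) + 0.5 * mu^2 * lam
}

#' Partition-model log10 Bayes factor for one variant
#'
#' The Bayes factor compares the partition alternative — within each
#' cluster of a partition, studies share one true log-odds effect `b` drawn
#' from a zero-centred normal prior with variance `W`; clusters are
#' independent — against the global null of no association in any study.
#' The marginal likelihood is averaged over partitions with the prior
#' weights, and each cluster integral has closed conjugate-normal form, so
#' the result is exact given the enumeration:
#' `BF = sum_P pi(P) prod_k integral(N(b;0,W) prod_{i in k} N(beta_i; b, se_i^2) db) / prod_i N(beta_i; 0, se_i^2)`.
#'
#' @param beta,se per-study harmonized effect estimates for one variant, in
#'   the order of `prior$study_ids`.
#' @param prior a [enumerate_partitions()] result.
#' @param W prior variance of a cluster effect (default 0.04, i.e. a prior
#'   SD of 0.2 on the log-odds scale — odds ratios mostly within ~1.5).
#' @return List of class `bayes_result`: `log10_bf`, `W`, and
#'   `posterior_partition` (posterior weight of each partition given the
#'   data; same order as `prior$partitions`).
#' @export
log10_bayes_factor <- function(beta, se, prior, W = 0.04) {
  stopifnot(inherits(prior, "partition_prior"), W > 0,
            length(beta) == length(prior$study_ids),
            length(se) == length(beta), all(se > 0))
  log_terms <- vapply(prior$partitions, function(lab) {
    sum(vapply(unique(lab), function(k)
      .log_cluster_ratio(beta[lab == k], se[lab == k], W), 0))
  }, 0)
  lw <- log(prior$weight) + log_terms
  mx <- max(lw)
  log_bf <- mx + log(sum(exp(lw - mx)))
  structure(list(log10_bf = log_bf / log(10), W = W,
                 posterior_partition = exp(lw - mx) / sum(exp(lw - mx))),
            class = "bayes_result")
}

#' Bayesian false discovery probability
#'
#' Posterior probability of no association given a Bayes factor for the
#' alternative and prior odds `PO` in favour of the null:
#' `BFDP = PO / (PO + BF)`. Strictly decreasing in the Bayes factor at
#' fixed `PO`. Conventional filters use `BFDP < 0.05` with `PO = 99` (one
#' true association per hundred variants a priori) or `PO = 999`.
#'
#' @param log10_bf log10 Bayes factor(s) in favour of association.
#' @param PO prior odds in favour of H0 (> 0).
#' @return BFDP in \[0, 1\] (vectorised).
#' @export
bfdp <- function(log10_bf, PO = 99) {
  stopifnot(PO > 0)
  # PO/(PO+BF) = 1/(1 + 10^(log10_bf - log10(PO))), stable for huge BF
  1 / (1 + 10^(log10_bf - log10(PO)))
}

#' Partition-model meta-analysis over a variant table
#'
#' Applies [log10_bayes_factor()] and [bfdp()] to every variant shared by a
#' list of harmonized studies.
#'
#' @param studies list of harmonized [study_summary()] objects, in the order
#'   of `prior$study_ids`.
#' @param prior a [enumerate_partitions()] result.
#' @param W,PO see [log10_bayes_factor()] and [bfdp()].
#' @return data.frame: `variant_id`, `log10_bf`, `bfdp`.
#' @export
bayes_meta <- function(studies, prior, W = 0.04, PO = 99) {
  stopifnot(length(studies) == length(prior$study_ids))
  ids <- Reduce(intersect, lapply(studies, function(s) s$records$variant_id))
  B <- vapply(studies, function(s)
    s$records$beta[match(ids, s$records$variant_id)], numeric(length(ids)))
  SE <- vapply(studies, function(s)
    s$records$se[match(ids, s$records$variant_id)], numeric(length(ids)))
  if (length(ids) == 1) { B <- matrix(B, 1); SE <- matrix(SE, 1) }
  lbf <- vapply(seq_along(ids), function(i)
    log10_bayes_factor(B[i, ], SE[i, ], prior, W)$log10_bf, 0)
  data.frame(variant_id = ids, log10_bf = lbf, bfdp = bfdp(lbf, PO),
             stringsAsFactors = FALSE)
}
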