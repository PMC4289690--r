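# Genotype-based LD, greedy clumping of association results, and
# locus/region definitions.

#' Composite (phase-free) LD between two dosage vectors
#'
#' Squared Pearson correlation of dosages over jointly non-missing samples.
#' Symmetric; returns `NA` when either vector has zero variance or fewer
#' than two jointly observed samples.
#'
#' @param a,b numeric dosage vectors of equal length.
#' @return r-squared in \[0, 1\], or `NA`.
#' @export
genotype_r2 <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 2) return(NA_real_)
  a <- a[ok]; b <- b[ok]
  if (var(a) == 0 || var(b) == 0) return(NA_real_)
  cor(a, b)^2
}

# r2 of one lead column against many columns; per-pair so the value is
# bit-identical to genotype_r2 (thresholds compare exactly)
.r2_vec <- function(dos, lead_j, js) {
  vapply(js, function(j) genotype_r2(dos[, lead_j], dos[, j]), 0)
}

#' Greedy LD-based clumping of association results
#'
#' Repeatedly takes the best remaining variant passing `stat_threshold` as
#' a clump lead, absorbs every remaining variant on the same chromosome
#' within `max_dist` base pairs of the lead (closed interval,
#' lead-to-member) and with dosage `r^2 >= min_r2` against the lead, and
#' iterates until no variant passes the threshold. Clumps are disjoint:
#' each threshold-passing variant lands in exactly one clump. Better
#' statistic means larger value of `results[[stat_col]]`; exact ties break
#' to the smaller position. By default the LD reference is the panel's
#' controls (reference-free); set `ld_samples = "all"` to use every sample.
#'
#' @param results data.frame with `variant_id`, `chrom`, `pos` and the
#'   statistic column.
#' @param panel a [genotype_panel()] sharing variant ids with `results`.
#' @param stat_col name of the statistic column (e.g. `"T_max"`); the
#'   caller decides which statistic drives clumping.
#' @param stat_threshold only variants with statistic above this seed or
#'   join clumps (default `-Inf`: clump everything).
#' @param max_dist distance window in bp (default 250000).
#' @param min_r2 LD threshold, inclusive (default 0.5).
#' @param ld_samples `"controls"` (default) or `"all"`.
#' @return List of `locus_clump` objects: each has `lead` (row of
#'   `results`), `members` (data.frame `variant_id`, `r2`), `span`
#'   (`chrom`, `min_pos`, `max_pos`).
#' @export
clump <- function(results, panel, stat_col = "T_max", stat_threshold = -Inf,
                  max_dist = 250000, min_r2 = 0.5,
                  ld_samples = c("controls", "all")) {
  ld_samples <- match.arg(ld_samples)
  stopifnot(all(c("variant_id", "chrom", "pos", stat_col) %in% names(results)))
  res <- results[is.finite(results[[stat_col]]) &
                   results[[stat_col]] > stat_threshold, , drop = FALSE]
  pj <- match(res$variant_id, panel$variants$variant_id)
  if (anyNA(pj)) {
    warning(sum(is.na(pj)), " variants absent from panel left unclumped")
    res <- res[!is.na(pj), , drop = FALSE]
    pj <- pj[!is.na(pj)]
  }
  dos <- panel$dosages
  if (ld_samples == "controls" && any(panel$phenotype == "control"))
    dos <- dos[panel$phenotype == "control", , drop = FALSE]
  # order: statistic descending, position ascending for ties
  o <- order(-res[[stat_col]], res$pos)
  res <- res[o, , drop = FALSE]; pj <- pj[o]
  alive <- rep(TRUE, nrow(res))
  clumps <- list()
  for (i in seq_len(nrow(res))) {
    if (!alive[i]) next
    alive[i] <- FALSE
    cand <- which(alive & res$chrom == res$chrom[i] &
                    abs(res$pos - res$pos[i]) <= max_dist)
    r2 <- .r2_vec(dos, pj[i], pj[cand])
    take <- cand[!is.na(r2) & r2 >= min_r2]
    members <- data.frame(variant_id = c(res$variant_id[i], res$variant_id[take]),
                          r2 = c(1, r2[match(take, cand)]),
                          stringsAsFactors = FALSE)
    alive[take] <- FALSE
    clumps[[length(clumps) + 1]] <- structure(
      list(lead = res[i, , drop = FALSE], members = members,
           span = list(chrom = res$chrom[i],
                       min_pos = min(res$pos[c(i, take)]),
                       max_pos = max(res$pos[c(i, take)]))),
      class = "locus_clump")
  }
  clumps
}

#' Define a genetic locus around a lead variant
#'
#' A locus is the lead variant plus every candidate with dosage
#' `r^2 > 0.5` against it (strict inequality — the locus definition —
#' while [clump()] uses the inclusive `>= 0.5`).
#'
#' @param lead variant id of the lead.
#' @param candidates variant ids to test for membership.
#' @param panel a [genotype_panel()].
#' @param min_r2 exclusive membership threshold (default 0.5).
#' @return A `locus_clump` (lead statistic columns absent).
#' @export
define_locus <- function(lead, candidates, panel, min_r2 = 0.5) {
  v <- panel$variants
  li <- match(lead, v$variant_id)
  if (is.na(li)) stop("lead not in panel")
  cj <- match(setdiff(candidates, lead), v$variant_id)
  cj <- cj[!is.na(cj)]
  r2 <- .r2_vec(panel$dosages, li, cj)
  take <- cj[!is.na(r2) & r2 > min_r2]
  members <- data.frame(variant_id = c(v$variant_id[li], v$variant_id[take]),
                        r2 = c(1, r2[match(take, cj)]),
                        stringsAsFactors = FALSE)
  structure(list(lead = data.frame(variant_id = v$variant_id[li],
                                   chrom = v$chrom[li], pos = v$pos[li],
                                   stringsAsFactors = FALSE),
                 members = members,
                 span = list(chrom = v$chrom[li],
                             min_pos = min(v$pos[c(li, take)]),
                             max_pos = max(v$pos[c(li, take)]))),
            class = "locus_clump")
}

#' Shared regions between two diseases
#'
#' Reports 2-Mb blocks of genomic DNA containing at least one clump for
#' each disease: AD and PSO clump leads on the same chromosome within
#' `window` bp of each other are merged into shared regions.
#'
#' @param clumps_ad,clumps_pso lists of `locus_clump` objects.
#' @param window block width in bp (default 2e6).
#' @return data.frame: `chrom`, `start`, `end`, `ad_leads`, `pso_leads`.
#' @export
shared_regions <- function(clumps_ad, clumps_pso, window = 2e6) {
  lead_tab <- function(cl) data.frame(
    variant_id = vapply(cl, function(x) x$lead$variant_id[1], ""),
    chrom = vapply(cl, function(x) x$span$chrom, ""),
    pos = vapply(cl, function(x) x$lead$pos[1], 0),
    stringsAsFactors = FALSE)
  a <- lead_tab(clumps_ad); p <- lead_tab(clumps_pso)
  out <- list()
  for (i in seq_len(nrow(a))) {
    near <- p$chrom == a$chrom[i] & abs(p$pos - a$pos[i]) <= window
    if (any(near)) {
      lo <- min(a$pos[i], p$pos[near]); hi <- max(a$pos[i], p$pos[near])
      out[[length(out) + 1]] <- data.frame(
        chrom = a$chrom[i], start = lo, end = hi,
        ad_leads = a$variant_id[i],
        pso_leads = paste(p$variant_id[near], collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(data.frame(chrom = character(), start = numeric(),
                                      end = numeric(), ad_leads = character(),
                                      pso_leads = character()))
  do.call(rbind, out)
}
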