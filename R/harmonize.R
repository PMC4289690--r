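# Allele harmonization across studies: orient every study's effect allele to
# a reference study so that signed z-scores are comparable, resolving strand
# flips by complementing and dropping unresolvable palindromic variants.

.complement <- c(A = "T", C = "G", G = "C", T = "A")

.comp_allele <- function(a) {
  out <- .complement[a]
  out[is.na(out)] <- a[is.na(out)]  # indel tokens pass through
  unname(out)
}

.is_palindromic <- function(ea, oa) .comp_allele(ea) == oa

# canonical unordered key for matching on (chrom, pos, allele set)
.pos_key <- function(vk) paste(vk$chrom, vk$pos, sep = ":")

#' Harmonize allele orientation across studies
#'
#' Re-orients each study so that, for every variant shared with the
#' reference study, the effect allele equals the reference's effect allele.
#' Where the orientation is reversed, `beta` flips sign and `eaf` becomes
#' `1 - eaf`. Where the allele pair only matches after complementing both
#' alleles, a strand flip is assumed and resolved the same way. Palindromic
#' variants (A/T or C/G) with minor-allele frequency above `palindromic_maf`
#' in either study are dropped: for those, strand cannot be resolved from
#' frequency. Variants whose allele sets remain irreconcilable are dropped
#' and reported. Variants absent from the reference pass through untouched.
#'
#' The operation is idempotent: harmonized studies are already oriented, so
#' a second pass is a no-op.
#'
#' @param studies list of [study_summary()] objects.
#' @param reference a [study_summary()] providing the target orientation.
#' @param match_on `"position"` (default; chrom+pos+allele-set) or `"id"`
#'   (variant_id).
#' @param palindromic_maf drop palindromic variants with MAF above this in
#'   either the study or the reference (default 0.4).
#' @return List of harmonized [study_summary()] objects, with an attribute
#'   `"dropped"`: a data.frame of (study_id, variant_id, reason).
#' @export
harmonize_alleles <- function(studies, reference,
                              match_on = c("position", "id"),
                              palindromic_maf = 0.4) {
  if (inherits(studies, "study_summary")) studies <- list(studies)
  stopifnot(length(studies) >= 1, inherits(reference, "study_summary"))
  match_on <- match.arg(match_on)
  ref <- reference$records
  ref_key <- if (match_on == "id") ref$variant_id else .pos_key(ref)
  dropped <- list()
  out <- lapply(studies, function(st) {
    rec <- st$records
    key <- if (match_on == "id") rec$variant_id else .pos_key(rec)
    idx <- match(key, ref_key)
    hit <- !is.na(idx)
    if (!any(hit)) return(st)
    r_ea <- ref$effect_allele[idx[hit]]
    r_oa <- ref$other_allele[idx[hit]]
    s_ea <- rec$effect_allele[hit]
    s_oa <- rec$other_allele[hit]

    same <- s_ea == r_ea & s_oa == r_oa
    swap <- s_ea == r_oa & s_oa == r_ea
    flip_same <- !same & !swap & .comp_allele(s_ea) == r_ea & .comp_allele(s_oa) == r_oa
    flip_swap <- !same & !swap & .comp_allele(s_ea) == r_oa & .comp_allele(s_oa) == r_ea
    bad <- !(same | swap | flip_same | flip_swap)

    pal <- .is_palindromic(s_ea, s_oa)
    s_maf <- pmin(rec$eaf[hit], 1 - rec$eaf[hit])
    r_maf <- pmin(ref$eaf[idx[hit]], 1 - ref$eaf[idx[hit]])
    pal_drop <- pal & (s_maf > palindromic_maf | r_maf > palindromic_maf)

    h <- which(hit)
    reorient <- swap | flip_swap
    ri <- h[reorient & !bad & !pal_drop]
    rec$beta[ri] <- -rec$beta[ri]
    rec$eaf[ri] <- 1 - rec$eaf[ri]
    rec$effect_allele[h[!bad & !pal_drop]] <- r_ea[!bad & !pal_drop]
    rec$other_allele[h[!bad & !pal_drop]] <- r_oa[!bad & !pal_drop]

    drop_i <- h[bad | pal_drop]
    if (length(drop_i)) {
      dropped[[st$study_id]] <<- data.frame(
        study_id = st$study_id, variant_id = rec$variant_id[drop_i],
        reason = ifelse(bad[match(drop_i, h)], "irreconcilable_alleles",
                        "palindromic_high_maf"),
        stringsAsFactors = FALSE)
      rec <- rec[-drop_i, , drop = FALSE]
      rownames(rec) <- NULL
    }
    study_summary(st$study_id, st$disease, rec, st$subphenotype, st$ancestry_label)
  })
  drops <- if (length(dropped)) do.call(rbind, c(dropped, make.row.names = FALSE))
           else data.frame(study_id = character(), variant_id = character(),
                           reason = character(), stringsAsFactors = FALSE)
  if (nrow(drops))
    message(nrow(drops), " variant records dropped during harmonization")
  attr(out, "dropped") <- drops
  out
}
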