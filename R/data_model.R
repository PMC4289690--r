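# Domain containers. Lightweight S3 built on data.frames/matrices, in the
# style of summary-statistics toolkits: a "study" is a header plus a record
# table, a "panel" is dosages with sample metadata.

#' Construct a table of variant keys
#'
#' A variant key identifies a bi-allelic variant by genomic position and its
#' allele pair, oriented so that `effect_allele` is the allele whose dosage
#' the effect estimates refer to. Positions are 1-based (hg19-style
#' coordinates); all interval logic downstream treats base-pair intervals as
#' closed. Multi-allelic sites are represented as distinct bi-allelic
#' records.
#'
#' @param variant_id character vector of variant identifiers (e.g. rs ids).
#' @param chrom character vector of chromosome labels.
#' @param pos integer vector of 1-based base-pair positions.
#' @param effect_allele,other_allele character vectors; `A`/`C`/`G`/`T` or
#'   indel tokens (e.g. `I`, `D`, or explicit sequences). Must differ
#'   per-row.
#' @return A `data.frame` with class `variant_key` and the five columns.
#' @export
variant_key <- function(variant_id, chrom, pos, effect_allele, other_allele) {
  pos <- as.integer(pos)
  chrom <- as.character(chrom)
  effect_allele <- toupper(as.character(effect_allele))
  other_allele <- toupper(as.character(other_allele))
  stopifnot(all(pos >= 1L), all(nzchar(effect_allele)), all(nzchar(other_allele)))
  if (any(effect_allele == other_allele))
    stop("effect_allele must differ from other_allele")
  vk <- data.frame(variant_id = as.character(variant_id), chrom = chrom,
                   pos = pos, effect_allele = effect_allele,
                   other_allele = other_allele, stringsAsFactors = FALSE)
  class(vk) <- c("variant_key", "data.frame")
  vk
}

#' Construct a per-study summary-statistics object
#'
#' Holds one study's per-variant association evidence on the log-odds scale,
#' oriented to the effect allele. This is the unit entering fixed-effects
#' meta-analysis and the partition-model meta-analysis.
#'
#' @param study_id single string.
#' @param disease `"AD"` or `"PSO"`.
#' @param records data.frame with columns `variant_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `p`, `n_cases`,
#'   `n_controls` and optionally `info`.
#' @param subphenotype `"general"` or `"childhood"` (AD cohorts distinguish
#'   childhood-onset collections).
#' @param ancestry_label free-text ancestry/cohort origin label.
#' @return An object of class `study_summary`.
#' @export
study_summary <- function(study_id, disease, records,
                          subphenotype = "general", ancestry_label = "") {
  disease <- match.arg(disease, c("AD", "PSO"))
  subphenotype <- match.arg(subphenotype, c("general", "childhood"))
  req <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
           "eaf", "beta", "se", "p", "n_cases", "n_controls")
  miss <- setdiff(req, names(records))
  if (length(miss)) stop("records missing columns: ", paste(miss, collapse = ", "))
  if (!"info" %in% names(records)) records$info <- NA_real_
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (anyDuplicated(records$variant_id))
    stop("variant_id must be unique within a study")
  bad <- !is.finite(records$se) | records$se <= 0
  bad <- bad | !(records$p > 0 & records$p <= 1)
  bad <- bad | !(records$eaf >= 0 & records$eaf <= 1)
  if (any(bad))
    stop(sum(bad), " records violate study_summary invariants (se>0, p in (0,1], eaf in [0,1])")
  structure(list(study_id = as.character(study_id), disease = disease,
                 subphenotype = subphenotype,
                 ancestry_label = as.character(ancestry_label),
                 records = records),
            class = "study_summary")
}

#' @export
print.study_summary <- function(x, ...) {
  cat(sprintf("<study_summary> %s (%s/%s, %s): %d variants\n",
              x$study_id, x$disease, x$subphenotype,
              if (nzchar(x$ancestry_label)) x$ancestry_label else "unlabelled",
              nrow(x$records)))
  invisible(x)
}

#' Construct a genotype panel
#'
#' Individual-level dosage data with sample phenotype/covariate metadata,
#' used by the multinomial model, LD computation, relatedness and QC.
#' Dosages are expected allele counts in \[0, 2\]; missing entries are `NA`
#' (R's missing sentinel; every consumer in this package handles it
#' explicitly).
#'
#' @param sample_ids character vector, unique.
#' @param dosages numeric matrix, samples x variants, entries in \[0,2\] or
#'   `NA`.
#' @param variants a [variant_key()] table, one row per dosage column.
#' @param phenotype factor/character with levels among
#'   `control`, `AD`, `PSO`.
#' @param sex optional factor/character (`female`/`male`), `NA` allowed.
#' @param covariates optional numeric matrix (samples x q), e.g. principal
#'   component scores.
#' @return An object of class `genotype_panel`.
#' @export
genotype_panel <- function(sample_ids, dosages, variants,
                           phenotype = NULL, sex = NULL, covariates = NULL) {
  dosages <- as.matrix(dosages)
  n <- length(sample_ids)
  if (nrow(dosages) != n) stop("dosages rows must match sample_ids")
  if (nrow(variants) != ncol(dosages)) stop("variants rows must match dosage columns")
  rng <- suppressWarnings(range(dosages, na.rm = TRUE))
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 2))
    stop("non-missing dosages must lie in [0, 2]")
  if (is.null(phenotype)) phenotype <- rep("control", n)
  phenotype <- factor(as.character(phenotype), levels = c("control", "AD", "PSO"))
  if (length(phenotype) != n) stop("phenotype length mismatch")
  if (!is.null(sex)) {
    sex <- factor(as.character(sex), levels = c("female", "male"))
    if (length(sex) != n) stop("sex length mismatch")
  }
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != n) stop("covariates rows must match samples")
  }
  rownames(dosages) <- sample_ids
  colnames(dosages) <- variants$variant_id
  structure(list(sample_ids = as.character(sample_ids), dosages = dosages,
                 variants = variants, phenotype = phenotype, sex = sex,
                 covariates = covariates),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  tab <- table(x$phenotype)
  cat(sprintf("<genotype_panel> %d samples x %d variants (%s)\n",
              length(x$sample_ids), nrow(x$variants),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Construct a classical-allele probability table
#'
#' Probabilistic classical HLA-allele calls: for each sample and allele,
#' posterior probabilities of carrying 0, 1 or 2 copies. These are hardened
#' to best-guess dosages with [harden_hla_dosages()].
#'
#' @param sample_ids character vector.
#' @param alleles character vector of classical-allele names
#'   (e.g. `"C*06:02"`).
#' @param probabilities numeric array `samples x alleles x 3`, third
#'   dimension = copy number 0/1/2. Per sample and allele the three
#'   probabilities must sum to at most 1 (+ small tolerance).
#' @return An object of class `hla_call_table`.
#' @export
hla_call_table <- function(sample_ids, alleles, probabilities) {
  probabilities <- as.array(probabilities)
  if (length(dim(probabilities)) != 3 ||
      dim(probabilities)[1] != length(sample_ids) ||
      dim(probabilities)[2] != length(alleles) ||
      dim(probabilities)[3] != 3)
    stop("probabilities must be samples x alleles x 3")
  sums <- apply(probabilities, c(1, 2), sum)
  if (any(sums > 1 + 1e-6)) stop("copy-number probabilities must sum to <= 1")
  structure(list(sample_ids = as.character(sample_ids),
                 alleles = as.character(alleles),
                 probabilities = probabilities),
            class = "hla_call_table")
}

#' Harden classical-allele probabilities to best-guess dosages
#'
#' For each sample and allele, the hardened dosage is the copy number whose
#' posterior probability strictly exceeds `threshold`; when no copy number
#' does, the call is missing (`NA`). The strict `>` comparison means a
#' threshold of 1 can never be met, so at `threshold = 1` every call is
#' missing.
#'
#' @param table an [hla_call_table()].
#' @param threshold probability in (0.5, 1\]; default 0.9.
#' @return A [genotype_panel()] whose "variants" are the classical alleles
#'   (placed on chromosome 6; the allele name doubles as variant id, with
#'   presence/absence coded as effect/other allele).
#' @export
harden_hla_dosages <- function(table, threshold = 0.9) {
  stopifnot(inherits(table, "hla_call_table"))
  if (!(threshold > 0.5 && threshold <= 1))
    stop("threshold must be in (0.5, 1]")
  p <- table$probabilities
  n <- dim(p)[1]; m <- dim(p)[2]
  dos <- matrix(NA_real_, n, m)
  for (k in 0:2) {
    hit <- p[, , k + 1, drop = FALSE][, , 1] > threshold
    dos[hit] <- k
  }
  vk <- variant_key(variant_id = table$alleles, chrom = rep("6", m),
                    pos = seq_len(m), effect_allele = rep("P", m),
                    other_allele = rep("A", m))
  genotype_panel(table$sample_ids, dos, vk)
}
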