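# Readers/writers for the plain-text interchange formats: summary-statistic
# TSV (gzip-transparent), genotype-matrix TSV, phenotype/covariate sidecar,
# and VCF (via vcfR when available).

.summary_cols <- c(variant_id = "SNP", chrom = "CHR", pos = "POS",
                   effect_allele = "EA", other_allele = "OA", eaf = "EAF",
                   beta = "BETA", se = "SE", p = "P", n_cases = "N_CASES",
                   n_controls = "N_CONTROLS", info = "INFO")

#' Read per-study GWAS summary statistics
#'
#' Reads a (possibly gzipped) tab-delimited summary-statistics file into a
#' [study_summary()]. The default header layout is
#' `SNP CHR POS EA OA EAF BETA SE P N_CASES N_CONTROLS INFO` (`INFO`
#' optional); other layouts are accommodated through `column_map`. Rows that
#' violate record-level invariants (non-positive or non-numeric `se`,
#' `p` outside (0,1\], `eaf` outside \[0,1\]) are dropped with a warning that
#' carries their line numbers; if more than `max_bad_frac` of rows fail, the
#' read aborts.
#'
#' @param path file path (plain or `.gz`).
#' @param study_id,disease,subphenotype,ancestry_label study metadata passed
#'   to [study_summary()].
#' @param column_map named character vector mapping internal field names
#'   (`variant_id`, `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`,
#'   `beta`, `se`, `p`, `n_cases`, `n_controls`, `info`) to file column
#'   names; defaults to the standard layout. Partial maps override only the
#'   named fields.
#' @param max_bad_frac abort if the fraction of invalid rows exceeds this
#'   (default 0.01).
#' @return A [study_summary()].
#' @export
read_summary <- function(path, study_id, disease, subphenotype = "general",
                         ancestry_label = "", column_map = NULL,
                         max_bad_frac = 0.01) {
  if (!file.exists(path)) stop("no such file: ", path)
  cmap <- .summary_cols
  if (!is.null(column_map)) {
    unknown <- setdiff(names(column_map), names(cmap))
    if (length(unknown)) stop("unknown fields in column_map: ",
                              paste(unknown, collapse = ", "))
    cmap[names(column_map)] <- column_map
  }
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = unname(cmap[c("chrom")])),
                          showProgress = FALSE, data.table = FALSE)
  mandatory <- setdiff(names(cmap), "info")
  miss <- setdiff(unname(cmap[mandatory]), names(dt))
  if (length(miss)) stop("missing mandatory columns: ", paste(miss, collapse = ", "))
  has_info <- cmap[["info"]] %in% names(dt)
  rec <- data.frame(
    variant_id = as.character(dt[[cmap[["variant_id"]]]]),
    chrom = as.character(dt[[cmap[["chrom"]]]]),
    pos = suppressWarnings(as.integer(dt[[cmap[["pos"]]]])),
    effect_allele = toupper(as.character(dt[[cmap[["effect_allele"]]]])),
    other_allele = toupper(as.character(dt[[cmap[["other_allele"]]]])),
    eaf = suppressWarnings(as.numeric(dt[[cmap[["eaf"]]]])),
    beta = suppressWarnings(as.numeric(dt[[cmap[["beta"]]]])),
    se = suppressWarnings(as.numeric(dt[[cmap[["se"]]]])),
    p = suppressWarnings(as.numeric(dt[[cmap[["p"]]]])),
    n_cases = suppressWarnings(as.integer(dt[[cmap[["n_cases"]]]])),
    n_controls = suppressWarnings(as.integer(dt[[cmap[["n_controls"]]]])),
    info = if (has_info) suppressWarnings(as.numeric(dt[[cmap[["info"]]]])) else NA_real_,
    stringsAsFactors = FALSE)
  bad <- !is.finite(rec$beta) | !is.finite(rec$se) | rec$se <= 0 |
    !is.finite(rec$p) | rec$p <= 0 | rec$p > 1 |
    !is.finite(rec$eaf) | rec$eaf < 0 | rec$eaf > 1 |
    is.na(rec$pos) | rec$pos < 1
  if (any(bad)) {
    lines <- which(bad) + 1L  # +1 for the header line
    if (mean(bad) > max_bad_frac)
      stop(sum(bad), " of ", nrow(rec), " rows invalid (lines ",
           paste(head(lines, 10), collapse = ","),
           if (sum(bad) > 10) ",..." else "", "); aborting")
    warning(sum(bad), " invalid rows dropped (file lines ",
            paste(head(lines, 10), collapse = ","),
            if (sum(bad) > 10) ",..." else "", ")")
    rec <- rec[!bad, , drop = FALSE]
    rownames(rec) <- NULL
  }
  study_summary(study_id, disease, rec, subphenotype, ancestry_label)
}

#' Write summary statistics in the standard layout
#'
#' Inverse of [read_summary()] (up to column order and float formatting).
#'
#' @param study a [study_summary()].
#' @param path output path; `.gz` suffix compresses.
#' @return `path`, invisibly.
#' @export
write_summary <- function(study, path) {
  stopifnot(inherits(study, "study_summary"))
  out <- study$records
  names(out) <- .summary_cols[names(out)]
  data.table::fwrite(out, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Read a genotype panel from a plain TSV matrix plus phenotype sidecar
#'
#' The matrix dialect: first five columns `SNP CHR POS EA OA`, then one
#' column per sample holding dosages in \[0,2\] (`NA` for missing); i.e.
#' variants are rows. The sidecar is a TSV with columns
#' `SAMPLE PHENOTYPE SEX` plus any numeric covariate columns (e.g.
#' `PC1..PC4`).
#'
#' @param geno_path genotype matrix TSV (gzip-transparent).
#' @param pheno_path optional phenotype/covariate sidecar TSV.
#' @return A [genotype_panel()].
#' @export
read_panel_tsv <- function(geno_path, pheno_path = NULL) {
  dt <- data.table::fread(geno_path, sep = "\t", header = TRUE,
                          showProgress = FALSE, data.table = FALSE)
  fixed <- c("SNP", "CHR", "POS", "EA", "OA")
  miss <- setdiff(fixed, names(dt))
  if (length(miss)) stop("genotype matrix missing columns: ",
                         paste(miss, collapse = ", "))
  vk <- variant_key(dt$SNP, dt$CHR, dt$POS, dt$EA, dt$OA)
  samp <- setdiff(names(dt), fixed)
  dos <- t(as.matrix(dt[, samp, drop = FALSE]))
  phenotype <- NULL; sex <- NULL; covar <- NULL
  if (!is.null(pheno_path)) {
    ph <- data.table::fread(pheno_path, sep = "\t", header = TRUE,
                            showProgress = FALSE, data.table = FALSE)
    if (!all(c("SAMPLE", "PHENOTYPE") %in% names(ph)))
      stop("sidecar needs SAMPLE and PHENOTYPE columns")
    idx <- match(samp, ph$SAMPLE)
    if (anyNA(idx)) stop("samples absent from sidecar: ",
                         paste(head(samp[is.na(idx)]), collapse = ", "))
    ph <- ph[idx, , drop = FALSE]
    phenotype <- ph$PHENOTYPE
    if ("SEX" %in% names(ph)) sex <- tolower(ph$SEX)
    cc <- setdiff(names(ph), c("SAMPLE", "PHENOTYPE", "SEX"))
    if (length(cc)) covar <- as.matrix(ph[, cc, drop = FALSE])
  }
  genotype_panel(samp, dos, vk, phenotype, sex, covar)
}

#' Write a genotype panel as TSV matrix plus sidecar
#'
#' @param panel a [genotype_panel()].
#' @param geno_path,pheno_path output paths (sidecar optional).
#' @return `geno_path`, invisibly.
#' @export
write_panel_tsv <- function(panel, geno_path, pheno_path = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  v <- panel$variants
  out <- data.frame(SNP = v$variant_id, CHR = v$chrom, POS = v$pos,
                    EA = v$effect_allele, OA = v$other_allele,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(t(panel$dosages)))
  names(out) <- c("SNP", "CHR", "POS", "EA", "OA", panel$sample_ids)
  data.table::fwrite(out, geno_path, sep = "\t", na = "NA", quote = FALSE)
  if (!is.null(pheno_path)) {
    ph <- data.frame(SAMPLE = panel$sample_ids,
                     PHENOTYPE = as.character(panel$phenotype),
                     stringsAsFactors = FALSE)
    if (!is.null(panel$sex)) ph$SEX <- as.character(panel$sex)
    if (!is.null(panel$covariates)) ph <- cbind(ph, as.data.frame(panel$covariates))
    data.table::fwrite(ph, pheno_path, sep = "\t", na = "NA", quote = FALSE)
  }
  invisible(geno_path)
}

#' Read a genotype panel from VCF
#'
#' Uses the `DS` FORMAT field when present, otherwise converts `GT` calls to
#' allele counts of the ALT allele. Requires the `vcfR` package.
#' Multi-allelic records are split into distinct bi-allelic rows is *not*
#' supported here; such records are dropped with a warning (represent them
#' as separate bi-allelic VCF lines instead).
#'
#' @param vcf_path path to a VCF (optionally bgzipped).
#' @param pheno_path optional sidecar TSV as in [read_panel_tsv()].
#' @return A [genotype_panel()]; effect allele = ALT.
#' @export
read_panel_vcf <- function(vcf_path, pheno_path = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("read_panel_vcf requires the vcfR package")
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    warning(sum(multi), " multi-allelic VCF records dropped")
    v <- v[!multi, ]
    fix <- vcfR::getFIX(v)
  }
  fmt <- unique(unlist(strsplit(v@gt[, 1], ":", fixed = TRUE)))
  if ("DS" %in% fmt) {
    dos <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(v, element = "GT")
    dos <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
    clean <- gsub("|", "/", gt, fixed = TRUE)
    dos[clean == "0/0"] <- 0; dos[clean %in% c("0/1", "1/0")] <- 1
    dos[clean == "1/1"] <- 2
  }
  ids <- fix[, "ID"]
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(fix[noid, "CHROM"], ":", fix[noid, "POS"])
  vk <- variant_key(ids, fix[, "CHROM"], as.integer(fix[, "POS"]),
                    fix[, "ALT"], fix[, "REF"])
  samp <- colnames(dos)
  panel <- genotype_panel(samp, t(dos), vk)
  if (!is.null(pheno_path)) {
    tmp <- tempfile(fileext = ".tsv")
    on.exit(unlink(tmp))
    write_panel_tsv(panel, tmp)
    panel <- read_panel_tsv(tmp, pheno_path)
  }
  panel
}

#' Write a genotype panel as a minimal VCF
#'
#' Emits a VCFv4.2 text file with a `DS` FORMAT field carrying dosages
#' (missing as `.`). REF = other allele, ALT = effect allele.
#'
#' @param panel a [genotype_panel()].
#' @param path output path (plain text).
#' @return `path`, invisibly.
#' @export
write_panel_vcf <- function(panel, path) {
  stopifnot(inherits(panel, "genotype_panel"))
  v <- panel$variants
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", panel$sample_ids), collapse = "\t")),
             con)
  dosc <- format(round(t(panel$dosages), 4), trim = TRUE)
  dosc[is.na(t(panel$dosages))] <- "."
  body <- paste(v$chrom, v$pos, v$variant_id, v$other_allele, v$effect_allele,
                ".", "PASS", ".", "DS",
                apply(dosc, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(body, con)
  invisible(path)
}
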