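test_that("summary TSV parses, enforces invariants, and respects column maps", {
  tmp <- tempfile(fileext = ".tsv")
  df <- write_toy_summary(tmp)
  st <- read_summary(tmp, "s1", "AD")
  expect_s3_class(st, "study_summary")
  expect_equal(nrow(st$records), 3)
  expect_equal(st$records$beta, df$BETA)

  # a zero-se row is rejected with a warning naming its line
  df_bad <- df; df_bad$SE[2] <- 0
  write.table(df_bad, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_warning(st2 <- read_summary(tmp, "s1", "AD", max_bad_frac = 0.5), "line")
  expect_equal(nrow(st2$records), 2)
  expect_false("rs2" %in% st2$records$variant_id)

  # too many bad rows aborts
  df_bad$SE <- 0
  write.table(df_bad, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_summary(tmp, "s1", "AD"), "invalid")

  # missing mandatory column is a format error
  write.table(df[, setdiff(names(df), "SE")], tmp, sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(read_summary(tmp, "s1", "AD"), "SE")

  # swapped allele columns under a custom column_map give the identical study
  df_sw <- df
  names(df_sw)[names(df_sw) == "EA"] <- "A1"
  names(df_sw)[names(df_sw) == "OA"] <- "A2"
  write.table(df_sw, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  st3 <- read_summary(tmp, "s1", "AD",
                      column_map = c(effect_allele = "A1", other_allele = "A2"))
  expect_equal(st3$records, st$records)
})

test_that("write_summary/read_summary round-trips records", {
  set.seed(7)
  rec <- data.frame(variant_id = paste0("rs", 1:20), chrom = "2",
                    pos = sort(sample.int(1e6, 20)),
                    effect_allele = sample(c("A", "C", "G", "T"), 20, TRUE),
                    other_allele = "X", eaf = runif(20, 0.05, 0.95),
                    beta = rnorm(20, 0, 0.2), se = runif(20, 0.02, 0.2),
                    p = runif(20), n_cases = 500L, n_controls = 800L,
                    info = runif(20, 0.4, 1), stringsAsFactors = FALSE)
  rec$other_allele <- ifelse(rec$effect_allele == "A", "G", "A")
  st <- study_summary("rt", "PSO", rec)
  tmp <- tempfile(fileext = ".tsv")
  write_summary(st, tmp)
  back <- read_summary(tmp, "rt", "PSO")
  expect_equal(back$records, st$records, tolerance = 1e-12)
})

test_that("genotype panel TSV and VCF round-trips preserve dosages", {
  set.seed(3)
  vk <- variant_key(paste0("v", 1:4), "5", c(100, 200, 300, 400),
                    c("A", "C", "G", "T"), c("G", "T", "A", "C"))
  dos <- matrix(sample(c(0:2, NA), 24, TRUE), 6, 4)
  pan <- genotype_panel(paste0("s", 1:6), dos, vk,
                        phenotype = c("AD", "AD", "PSO", "control", "control", "control"),
                        sex = rep(c("female", "male"), 3),
                        covariates = matrix(rnorm(12), 6, 2,
                                            dimnames = list(NULL, c("PC1", "PC2"))))
  g <- tempfile(fileext = ".tsv"); ph <- tempfile(fileext = ".tsv")
  write_panel_tsv(pan, g, ph)
  back <- read_panel_tsv(g, ph)
  expect_equal(unname(back$dosages), unname(pan$dosages))
  expect_equal(as.character(back$phenotype), as.character(pan$phenotype))
  expect_equal(back$variants, pan$variants)

  skip_if_not_installed("vcfR")
  vcf <- tempfile(fileext = ".vcf")
  write_panel_vcf(pan, vcf)
  vback <- read_panel_vcf(vcf)
  expect_equal(unname(vback$dosages), unname(pan$dosages))
  expect_equal(vback$variants$effect_allele, pan$variants$effect_allele)
})

test_that("allele harmonization flips, drops palindromes, and is idempotent", {
  mk <- function(id, ea, oa, beta, eaf)
    data.frame(variant_id = id, chrom = "1", pos = match(id, paste0("v", 1:9)) * 100,
               effect_allele = ea, other_allele = oa, eaf = eaf, beta = beta,
               se = 0.1, p = 0.5, n_cases = 100L, n_controls = 100L,
               info = NA_real_, stringsAsFactors = FALSE)
  ref <- study_summary("ref", "AD", rbind(
    mk("v1", "G", "A", 0.1, 0.3),    # plain swap target
    mk("v2", "A", "T", 0.1, 0.48),   # palindromic, high MAF
    mk("v3", "C", "T", 0.1, 0.2),    # strand-flip target (G/A on other strand)
    mk("v4", "A", "C", 0.1, 0.2)))   # irreconcilable in study
  st <- study_summary("b", "AD", rbind(
    mk("v1", "A", "G", -0.2, 0.7),
    mk("v2", "A", "T", 0.15, 0.48),
    mk("v3", "G", "A", 0.3, 0.8),    # complement of C/T
    mk("v4", "A", "G", 0.1, 0.2)))
  h <- harmonize_alleles(list(st), ref)
  r <- h[[1]]$records
  expect_equal(r$beta[r$variant_id == "v1"], 0.2)            # sign flip
  expect_equal(r$eaf[r$variant_id == "v1"], 0.3)             # eaf complement
  expect_false("v2" %in% r$variant_id)                       # palindrome dropped
  expect_equal(r$effect_allele[r$variant_id == "v3"], "C")   # strand resolved
  expect_equal(r$beta[r$variant_id == "v3"], 0.3)
  expect_false("v4" %in% r$variant_id)                       # irreconcilable
  drops <- attr(h, "dropped")
  expect_setequal(drops$variant_id, c("v2", "v4"))

  h2 <- harmonize_alleles(h, ref)
  expect_equal(h2[[1]]$records, h[[1]]$records)              # idempotent
})

test_that("random orientations harmonize back to generating truth", {
  set.seed(11)
  n <- 10
  truth_beta <- rnorm(n, 0, 0.3)
  alle <- data.frame(ea = c("A", "C", "G", "T")[sample.int(4, n, TRUE)])
  alle$oa <- c(A = "C", C = "A", G = "T", T = "G")[alle$ea]  # non-palindromic
  mkrec <- function(ea, oa, beta, eaf)
    data.frame(variant_id = paste0("v", 1:n), chrom = "1", pos = (1:n) * 50,
               effect_allele = ea, other_allele = oa, eaf = eaf, beta = beta,
               se = 0.05, p = 0.5, n_cases = 100L, n_controls = 100L,
               info = NA_real_, stringsAsFactors = FALSE)
  eaf <- runif(n, 0.1, 0.9)
  ref <- study_summary("ref", "AD", mkrec(alle$ea, alle$oa, truth_beta, eaf))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  scramble <- function() {
    swap <- runif(n) < 0.5; flip <- runif(n) < 0.5
    ea <- ifelse(swap, alle$oa, alle$ea); oa <- ifelse(swap, alle$ea, alle$oa)
    ea2 <- ifelse(flip, comp[ea], ea); oa2 <- ifelse(flip, comp[oa], oa)
    study_summary(paste0("s", sample.int(1e6, 1)), "AD",
                  mkrec(ea2, oa2, ifelse(swap, -truth_beta, truth_beta),
                        ifelse(swap, 1 - eaf, eaf)))
  }
  h <- harmonize_alleles(list(scramble(), scramble()), ref)
  for (st in h) {
    expect_equal(nrow(st$records), n)
    expect_equal(st$records$beta, truth_beta)
    expect_equal(st$records$effect_allele, alle$ea)
  }
})

test_that("HLA dosage hardening follows the strict probability threshold", {
  pr <- array(0, c(3, 2, 3))
  pr[1, 1, ] <- c(0.02, 0.95, 0.03)   # -> 1
  pr[2, 1, ] <- c(0.4, 0.4, 0.2)      # -> missing
  pr[3, 1, ] <- c(1, 0, 0)            # -> 0 at 0.9, missing at threshold 1
  pr[, 2, ] <- rep(c(0, 0, 1), each = 3)
  tab <- hla_call_table(paste0("s", 1:3), c("C*06:02", "B*57:01"), pr)
  pan <- harden_hla_dosages(tab)
  expect_equal(unname(pan$dosages[, 1]), c(1, NA, 0))
  expect_equal(unname(pan$dosages[, 2]), c(2, 2, 2))
  strict <- harden_hla_dosages(tab, threshold = 1)
  expect_true(all(is.na(strict$dosages[, 1])))
  expect_true(all(is.na(strict$dosages[, 2])))   # ">" not ">=": 1.0 fails

  # missing exactly where max copy-number probability <= threshold
  set.seed(5)
  pr2 <- array(runif(5 * 4 * 3), c(5, 4, 3))
  pr2 <- pr2 / (1.05 * as.vector(apply(pr2, c(1, 2), sum)))  # sums under 1
  tab2 <- hla_call_table(paste0("s", 1:5), paste0("a", 1:4), pr2)
  for (t in c(0.6, 0.7, 0.9)) {
    pan2 <- harden_hla_dosages(tab2, t)
    expect_equal(is.na(pan2$dosages),
                 apply(pr2, c(1, 2), max) <= t, ignore_attr = TRUE)
  }
})
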