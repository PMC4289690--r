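# Three-category multinomial logistic model (control baseline, AD and PSO
# case categories) with the five Wald linear-hypothesis tests, minimum-p
# effect classification, and stepwise conditional dissection of
# multi-signal regions.

# Newton-Raphson fit of the baseline-category multinomial logit:
# P(outcome = d | x) = exp(x'beta_d) / (1 + sum_d' exp(x'beta_d')) with
# beta_control = 0. Covariance from the inverse observed information.
# Convergence: relative log-likelihood change < tol; step-halving guards
# against overshoot.
.mnm_newton <- function(X, Y, tol = 1e-10, maxit = 100L) {
  n <- nrow(X); p <- ncol(X)
  b <- matrix(0, p, 2)                      # columns: AD, PSO
  loglik <- function(b) {
    eta <- X %*% b
    m <- pmax(eta[, 1], eta[, 2], 0)        # log-sum-exp stabilisation
    lse <- m + log(exp(-m) + exp(eta[, 1] - m) + exp(eta[, 2] - m))
    sum(Y[, 1] * eta[, 1] + Y[, 2] * eta[, 2] - lse)
  }
  ll <- loglik(b)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- X %*% b
    m <- pmax(eta[, 1], eta[, 2], 0)
    e0 <- exp(-m); e1 <- exp(eta[, 1] - m); e2 <- exp(eta[, 2] - m)
    den <- e0 + e1 + e2
    pi1 <- e1 / den; pi2 <- e2 / den
    g <- c(crossprod(X, Y[, 1] - pi1), crossprod(X, Y[, 2] - pi2))
    w11 <- pi1 * (1 - pi1); w22 <- pi2 * (1 - pi2); w12 <- -pi1 * pi2
    H <- rbind(cbind(crossprod(X, X * w11), crossprod(X, X * w12)),
               cbind(crossprod(X, X * w12), crossprod(X, X * w22)))
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) break
    sc <- 1
    repeat {
      bn <- b + matrix(sc * step, p, 2)
      lln <- loglik(bn)
      if (is.finite(lln) && lln >= ll - 1e-12) break
      sc <- sc / 2
      if (sc < 1e-8) break
    }
    if (sc < 1e-8) break
    rel <- abs(lln - ll) / (abs(ll) + 1e-10)
    b <- bn; ll <- lln
    if (rel < tol) { converged <- TRUE; break }
  }
  # observed information at the optimum
  eta <- X %*% b
  m <- pmax(eta[, 1], eta[, 2], 0)
  e0 <- exp(-m); e1 <- exp(eta[, 1] - m); e2 <- exp(eta[, 2] - m)
  den <- e0 + e1 + e2
  pi1 <- e1 / den; pi2 <- e2 / den
  w11 <- pi1 * (1 - pi1); w22 <- pi2 * (1 - pi2); w12 <- -pi1 * pi2
  H <- rbind(cbind(crossprod(X, X * w11), crossprod(X, X * w12)),
             cbind(crossprod(X, X * w12), crossprod(X, X * w22)))
  V <- tryCatch(solve(H), error = function(e) matrix(NA_real_, 2 * p, 2 * p))
  list(beta = b, vcov = V, loglik = ll,
       converged = converged && all(is.finite(V)) && all(abs(b) < 15))
}

# assemble the design matrix: intercept + dosage + covariates
.mnm_design <- function(panel, variant, covariates, extra_dosage = NULL) {
  j <- if (is.numeric(variant)) as.integer(variant)
       else match(variant, panel$variants$variant_id)
  if (is.na(j)) stop("variant not found: ", variant)
  x <- panel$dosages[, j]
  if (is.null(covariates)) {
    covariates <- panel$covariates
    if (!is.null(panel$sex))
      covariates <- cbind(covariates, sex = as.integer(panel$sex) - 1L)
  }
  X <- cbind(`(Intercept)` = 1, g = x)
  if (!is.null(covariates)) X <- cbind(X, as.matrix(covariates))
  if (!is.null(extra_dosage)) X <- cbind(X, as.matrix(extra_dosage))
  ph <- panel$phenotype
  Y <- cbind(AD = as.integer(ph == "AD"), PSO = as.integer(ph == "PSO"))
  ok <- stats::complete.cases(X) & !is.na(ph)
  X <- X[ok, , drop = FALSE]; Y <- Y[ok, , drop = FALSE]
  # drop aliased columns (keep intercept and dosage)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep <- sort(qrX$pivot[seq_len(qrX$rank)])
    if (!all(c(1, 2) %in% keep)) stop("dosage column aliased with covariates")
    X <- X[, keep, drop = FALSE]
  }
  list(X = X, Y = Y)
}

#' Fit the multinomial case-case-control model for one variant
#'
#' Maximum-likelihood multinomial logit with controls as the baseline
#' category and AD / PSO as case categories: the variant dosage enters with
#' per-disease log-odds `beta_AD` and `beta_PSO`; covariates default to sex
#' plus any panel covariates (principal-component scores). Returns the
#' dosage coefficients, their 2x2 covariance from the inverse observed
#' information, the five Wald tests and the minimum-p classification.
#'
#' @param panel a [genotype_panel()] containing controls and both case
#'   groups.
#' @param variant variant id or column index.
#' @param covariates optional covariate matrix overriding the panel's.
#' @param condition_on optional matrix of conditioning dosages added as
#'   covariates (for conditional analysis).
#' @return List of class `mnm_result`: `beta_AD`, `beta_PSO`, `se_AD`,
#'   `se_PSO`, `cov` (2x2, order AD, PSO), `p_overall`, `p_AD`, `p_PSO`,
#'   `p_shared`, `p_opposing`, `p_MNM`, `category`, `or_AD`, `or_PSO`,
#'   `ci_AD`, `ci_PSO`, `converged`, `n`.
#' @export
fit_multinomial <- function(panel, variant, covariates = NULL,
                            condition_on = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  ph <- panel$phenotype
  if (!all(c("control", "AD", "PSO") %in% as.character(unique(ph))))
    stop("all three outcome categories (control, AD, PSO) must be present")
  d <- .mnm_design(panel, variant, covariates, condition_on)
  fit <- .mnm_newton(d$X, d$Y)
  gi <- which(colnames(d$X) == "g")
  p <- ncol(d$X)
  idx <- c(gi, p + gi)                       # (beta_AD, beta_PSO) positions
  beta <- fit$beta[gi, ]                     # AD, PSO
  V <- fit$vcov[idx, idx]
  wt <- wald_tests(beta_PSO = beta[2], beta_AD = beta[1],
                   cov = V[c(2, 1), c(2, 1)])
  cls <- classify_mnm(wt$p_AD, wt$p_PSO, wt$p_shared, wt$p_opposing)
  se <- unname(sqrt(diag(V)))
  structure(c(list(beta_AD = beta[1], beta_PSO = beta[2],
                   se_AD = se[1], se_PSO = se[2], cov = V),
              wt,
              list(p_MNM = cls$p_MNM, category = cls$category,
                   or_AD = exp(beta[1]), or_PSO = exp(beta[2]),
                   ci_AD = exp(beta[1] + c(-1, 1) * 1.96 * se[1]),
                   ci_PSO = exp(beta[2] + c(-1, 1) * 1.96 * se[2]),
                   converged = fit$converged, n = nrow(d$X))),
            class = "mnm_result")
}

#' The five Wald tests of the multinomial model
#'
#' Given `(beta_PSO, beta_AD)` and their covariance, computes the 2-df
#' overall test (quadratic form `beta' Sigma^{-1} beta`, equivalent to
#' testing `(beta_PSO + beta_AD, beta_PSO - beta_AD) = (0, 0)` since the
#' contrast matrix is invertible) and four 1-df contrasts
#' `(c'beta)^2 / (c' Sigma c)` referred to chi-square(1):
#' PSO effect `c = (1, 0)`, AD effect `c = (0, 1)`, shared effect
#' `c = (1, 1)`, opposing effect `c = (1, -1)`.
#'
#' @param beta_PSO,beta_AD dosage coefficients.
#' @param cov 2x2 covariance of `(beta_PSO, beta_AD)` (symmetric positive
#'   definite).
#' @return List: `p_overall`, `p_AD`, `p_PSO`, `p_shared`, `p_opposing`.
#' @export
wald_tests <- function(beta_PSO, beta_AD, cov) {
  cov <- (cov + t(cov)) / 2
  if (any(!is.finite(cov)) || det(cov) <= 0)
    stop("covariance must be symmetric positive definite")
  b <- c(beta_PSO, beta_AD)
  q2 <- drop(t(b) %*% solve(cov, b))
  one_df <- function(ct) {
    stat <- drop(ct %*% b)^2 / drop(t(ct) %*% cov %*% ct)
    pchisq(stat, df = 1, lower.tail = FALSE)
  }
  list(p_overall = pchisq(q2, df = 2, lower.tail = FALSE),
       p_AD = one_df(c(0, 1)), p_PSO = one_df(c(1, 0)),
       p_shared = one_df(c(1, 1)), p_opposing = one_df(c(1, -1)))
}

#' Minimum-p effect classification
#'
#' `p_MNM = min(p_AD, p_PSO, p_shared, p_opposing)`; the category is the
#' arg-min, with ties broken in the fixed order AD, PSO, shared, opposing.
#'
#' @param p_AD,p_PSO,p_shared,p_opposing the four 1-df Wald p-values
#'   (vectorised).
#' @return List: `category` (factor AD/PSO/shared/opposing), `p_MNM`.
#' @export
classify_mnm <- function(p_AD, p_PSO, p_shared, p_opposing) {
  pm <- cbind(p_AD, p_PSO, p_shared, p_opposing)
  stopifnot(all(pm >= 0 & pm <= 1))
  wi <- max.col(-pm, ties.method = "first")
  list(category = factor(.ccma_categories[wi], levels = .ccma_categories),
       p_MNM = pm[cbind(seq_len(nrow(pm)), wi)])
}

#' Multinomial scan over many variants
#'
#' @param panel a [genotype_panel()].
#' @param variants variant ids (default all).
#' @param covariates,condition_on as in [fit_multinomial()].
#' @return data.frame with one row per variant: coefficients, standard
#'   errors, the five p-values, `p_MNM`, `category`, `converged`.
#' @export
mnm_scan <- function(panel, variants = NULL, covariates = NULL,
                     condition_on = NULL) {
  if (is.null(variants)) variants <- panel$variants$variant_id
  rows <- lapply(variants, function(v) {
    r <- tryCatch(fit_multinomial(panel, v, covariates, condition_on),
                  error = function(e) NULL)
    if (is.null(r))
      return(data.frame(variant_id = v, beta_AD = NA_real_, beta_PSO = NA_real_,
                        se_AD = NA_real_, se_PSO = NA_real_, p_overall = NA_real_,
                        p_AD = NA_real_, p_PSO = NA_real_, p_shared = NA_real_,
                        p_opposing = NA_real_, p_MNM = NA_real_,
                        category = NA_character_, converged = FALSE))
    data.frame(variant_id = v, beta_AD = r$beta_AD, beta_PSO = r$beta_PSO,
               se_AD = r$se_AD, se_PSO = r$se_PSO, p_overall = r$p_overall,
               p_AD = r$p_AD, p_PSO = r$p_PSO, p_shared = r$p_shared,
               p_opposing = r$p_opposing, p_MNM = r$p_MNM,
               category = as.character(r$category), converged = r$converged)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Stepwise conditional analysis of a region
#'
#' Iteratively dissects a multi-signal region: all region variants are
#' refit with the current conditioning set (any pre-supplied dosages, e.g.
#' known null-mutation carrier columns, plus previously selected
#' variants) as covariates; the variant with the smallest conditional
#' `p_MNM` is added as an independent signal if `p_MNM < stop_p`; repeat
#' until no variant qualifies. Conditioning candidates with dosage
#' `r^2 > 0.95` against the existing conditioning set are skipped with a
#' warning. A final joint fit of all selected variants is returned.
#'
#' @param panel a [genotype_panel()].
#' @param region character vector of variant ids to scan (or `chrom:start-end`
#'   string).
#' @param precondition optional matrix of pre-supplied conditioning dosage
#'   columns.
#' @param stop_p selection threshold on conditional `p_MNM` (default 1e-5,
#'   the conventional suggestive level).
#' @param covariates optional covariate override.
#' @return List of class `stepwise_result`: `signals` (data.frame of
#'   selected variants with their conditional statistics and selection
#'   round), `full_model` (joint [mnm_scan()] of selected variants, each
#'   conditioned on all the others), `conditioning` (ids in selection
#'   order).
#' @export
stepwise_conditional <- function(panel, region, precondition = NULL,
                                 stop_p = 1e-5, covariates = NULL) {
  if (length(region) == 1 && grepl("^[^:]+:[0-9]+-[0-9]+$", region)) {
    ch <- sub(":.*", "", region)
    rng <- as.numeric(strsplit(sub(".*:", "", region), "-")[[1]])
    v <- panel$variants
    region <- v$variant_id[v$chrom == ch & v$pos >= rng[1] & v$pos <= rng[2]]
  }
  stopifnot(all(region %in% panel$variants$variant_id))
  cond <- precondition
  selected <- character()
  rows <- list()
  round_i <- 0L
  repeat {
    remaining <- setdiff(region, selected)
    if (!length(remaining) || stop_p <= 0) break
    round_i <- round_i + 1L
    scan <- mnm_scan(panel, remaining, covariates, cond)
    scan <- scan[scan$converged & !is.na(scan$p_MNM), , drop = FALSE]
    if (!nrow(scan)) break
    best <- scan[which.min(scan$p_MNM), , drop = FALSE]
    if (best$p_MNM >= stop_p) break
    newdos <- panel$dosages[, match(best$variant_id, panel$variants$variant_id)]
    if (!is.null(cond) && ncol(cond) > 0) {
      r2 <- suppressWarnings(cor(newdos, cond, use = "pairwise.complete.obs"))^2
      if (any(r2 > 0.95, na.rm = TRUE)) {
        warning("signal ", best$variant_id,
                " collinear with conditioning set (r2 > 0.95); skipped")
        region <- setdiff(region, best$variant_id)
        next
      }
    }
    newcol <- setNames(data.frame(newdos), best$variant_id)
    cond <- if (is.null(cond)) newcol else cbind(cond, newcol)
    best$round <- round_i
    rows[[length(rows) + 1]] <- best
    selected <- c(selected, best$variant_id)
  }
  signals <- if (length(rows)) do.call(rbind, rows)
             else data.frame()
  full <- NULL
  if (length(selected)) {
    full <- do.call(rbind, lapply(seq_along(selected), function(i) {
      others <- selected[-i]
      extra <- if (length(others))
        panel$dosages[, match(others, panel$variants$variant_id), drop = FALSE]
      else NULL
      if (!is.null(precondition)) extra <- cbind(precondition, extra)
      mnm_scan(panel, selected[i], covariates, extra)
    }))
  }
  structure(list(signals = signals, full_model = full,
                 conditioning = selected),
            class = "stepwise_result")
}
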