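# Compare-and-contrast meta-analysis (CCMA): the four-component max-z
# statistic over the two disease meta z-scores, its Monte-Carlo null, an
# analytic tail oracle by bivariate-normal integration, threshold
# calibration, and empirical p-values.

.ccma_categories <- c("AD", "PSO", "shared", "opposing")

#' The CCMA statistic and effect category
#'
#' Given the signed meta-analysis z-scores `T1` (disease 1, AD) and `T2`
#' (disease 2, PSO), forms the orthogonal shared and opposing components
#' `(T1+T2)/sqrt(2)` and `(T1-T2)/sqrt(2)` — the sqrt(2) divisor gives both
#' unit variance under the null, so all four components are exchangeable —
#' and takes `T_max` as the largest absolute component. The variant is
#' categorized by the arg-max component: AD-specific, PSO-specific, shared
#' (same direction in both diseases) or opposing (directions differ). Exact
#' ties break in the fixed order AD, PSO, shared, opposing.
#'
#' @param T1,T2 signed z-scores (vectorised, recycled).
#' @return data.frame: `T1`, `T2`, `T_shared`, `T_opposing`, `T_max`,
#'   `category` (factor).
#' @export
ccma_statistic <- function(T1, T2) {
  m <- max(length(T1), length(T2))
  T1 <- rep_len(as.numeric(T1), m); T2 <- rep_len(as.numeric(T2), m)
  stopifnot(all(is.finite(T1)), all(is.finite(T2)))
  ts <- (T1 + T2) / sqrt(2)
  to <- (T1 - T2) / sqrt(2)
  comp <- cbind(abs(T1), abs(T2), abs(ts), abs(to))
  which_max <- max.col(comp, ties.method = "first")
  data.frame(T1 = T1, T2 = T2, T_shared = ts, T_opposing = to,
             T_max = comp[cbind(seq_len(m), which_max)],
             category = factor(.ccma_categories[which_max],
                               levels = .ccma_categories))
}

#' Simulate the CCMA null distribution
#'
#' Draws `n_sims` realisations of two independent standard normals
#' `(Z1, Z2)` and records `Z_max = max(|Z1|, |Z2|, |Z1+Z2|/sqrt(2),
#' |Z1-Z2|/sqrt(2))`. Simulation is chunked so memory stays bounded at any
#' `n_sims`; results are reproducible given `seed` and returned sorted.
#'
#' @param n_sims number of replicate draws (default 1e7, a practical
#'   genome-wide null size).
#' @param seed integer RNG seed.
#' @param chunk chunk size (draws per allocation).
#' @return Object of class `ccma_null`: `draws` (sorted ascending),
#'   `n_sims`, `seed`.
#' @export
simulate_null <- function(n_sims = 1e7, seed = 1L, chunk = 2e6L) {
  stopifnot(n_sims >= 1)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  n_left <- n_sims
  parts <- list()
  i <- 1
  while (n_left > 0) {
    b <- as.integer(min(chunk, n_left))
    z1 <- rnorm(b); z2 <- rnorm(b)
    parts[[i]] <- pmax(abs(z1), abs(z2), abs(z1 + z2) / sqrt(2),
                       abs(z1 - z2) / sqrt(2))
    n_left <- n_left - b
    i <- i + 1
  }
  structure(list(draws = sort(unlist(parts)), n_sims = as.integer(n_sims),
                 seed = as.integer(seed)),
            class = "ccma_null")
}

#' Empirical CCMA p-value
#'
#' The plus-one empirical formula
#' `P = (#(Z_max > T_max) + 1) / (n_sims + 1)`; the smallest attainable
#' p-value is therefore `1/(n_sims+1)`. Vectorised over `T_max`.
#'
#' @param T_max observed statistic value(s).
#' @param null a `ccma_null` from [simulate_null()].
#' @return p-values in (0, 1\].
#' @export
empirical_p <- function(T_max, null) {
  stopifnot(inherits(null, "ccma_null"), length(null$draws) >= 1)
  n <- length(null$draws)
  # draws sorted ascending: #(draws > t) = n - #(draws <= t)
  n_le <- findInterval(T_max, null$draws)
  (n - n_le + 1) / (n + 1)
}

#' Analytic tail probability of the CCMA null
#'
#' `P(Z_max > t)` for two independent standard normals, computed by
#' one-dimensional numerical integration: the acceptance region
#' `{max component <= t}` is a regular octagon with apothem `t`, and the
#' complement probability is
#' `2*Phibar(t) + int_{-t}^{t} phi(z1) [Phi(L(z1)) + Phibar(U(z1))] dz1`
#' where `[L, U]` is the admissible `z2` band at `z1`. Every term is a
#' small positive tail quantity, so the result keeps full relative accuracy
#' down to ~1e-300 (well past the 1e-10 region used for calibration).
#'
#' @param t non-negative threshold(s) (vectorised).
#' @return Tail probabilities `P(Z_max > t)`.
#' @export
analytic_tail_p <- function(t) {
  vapply(as.numeric(t), function(tt) {
    stopifnot(tt >= 0)
    if (tt == 0) return(1)
    s2 <- sqrt(2)
    band <- function(z1) {
      L <- pmax(-tt, -tt * s2 - z1, z1 - tt * s2)
      U <- pmin(tt, tt * s2 - z1, z1 + tt * s2)
      dnorm(z1) * (pnorm(L) + pnorm(U, lower.tail = FALSE))
    }
    inner <- integrate(band, -tt, tt, rel.tol = 1e-12, abs.tol = 0,
                       subdivisions = 500L)$value
    2 * pnorm(tt, lower.tail = FALSE) + inner
  }, 0)
}

#' Calibrate CCMA thresholds for target tail probabilities
#'
#' Returns, for each target p-value, the threshold `t` with
#' `P(Z_max > t) = p`, by monotone root-finding on the tail function. Two
#' modes: `"analytic"` (default; valid to arbitrarily small targets) and
#' `"empirical"` (inverts a Monte-Carlo null; refuses targets below its
#' validity bound `10/(n_sims+1)`, below which the empirical curve is
#' noise — use analytic mode there).
#'
#' @param p_targets vector of tail probabilities (e.g. `c(1e-5, 1e-8)` for
#'   the conventional suggestive and genome-wide levels).
#' @param null optional `ccma_null`; supplying one selects empirical mode.
#' @return Object of class `ccma_calibration`: data.frame `p_target`,
#'   `threshold`, plus attributes `mode` and `validity_bound`.
#' @export
calibrate <- function(p_targets, null = NULL) {
  stopifnot(all(p_targets > 0), all(p_targets <= 1))
  if (is.null(null)) {
    mode <- "analytic"; bound <- 1e-300
    thr <- vapply(p_targets, function(p) {
      if (p >= 1) return(0)
      uniroot(function(t) log(analytic_tail_p(t)) - log(p),
              interval = c(0, 50), tol = 1e-10)$root
    }, 0)
  } else {
    stopifnot(inherits(null, "ccma_null"))
    mode <- "empirical"
    bound <- 10 / (null$n_sims + 1)
    if (any(p_targets < bound))
      stop("target below the empirical validity bound ", signif(bound, 3),
           "; use analytic mode (null = NULL)")
    n <- null$n_sims
    thr <- vapply(p_targets, function(p) {
      # smallest draw t with empirical tail <= p
      k <- max(0, floor(p * (n + 1) - 1)) # allowed count of draws above t
      null$draws[n - k]
    }, 0)
  }
  out <- data.frame(p_target = p_targets, threshold = thr)
  attr(out, "mode") <- mode
  attr(out, "validity_bound") <- bound
  class(out) <- c("ccma_calibration", "data.frame")
  out
}

#' Run CCMA over two disease meta-analyses
#'
#' Joins the AD and PSO meta results on variant id, computes the CCMA
#' statistic and category for every shared variant, and attaches empirical
#' p-values from a simulated null (or analytic p-values when `null` is
#' `NULL`).
#'
#' @param meta_ad,meta_pso data.frames from [meta_analyse()] (must contain
#'   `variant_id` and `z`).
#' @param null optional `ccma_null` for empirical p-values.
#' @return data.frame: variant key columns, `T1`, `T2`, `T_shared`,
#'   `T_opposing`, `T_max`, `category`, `p_emp`.
#' @export
ccma <- function(meta_ad, meta_pso, null = NULL) {
  idx <- match(meta_ad$variant_id, meta_pso$variant_id)
  hit <- !is.na(idx)
  ad <- meta_ad[hit, , drop = FALSE]
  ps <- meta_pso[idx[hit], , drop = FALSE]
  st <- ccma_statistic(ad$z, ps$z)
  st$p_emp <- if (is.null(null)) analytic_tail_p(st$T_max)
              else empirical_p(st$T_max, null)
  cbind(ad[, intersect(c("variant_id", "chrom", "pos", "effect_allele",
                         "other_allele"), names(ad)), drop = FALSE], st)
}
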