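# Statistical core of the differential occupancy test.
#
# Model: position-wise T-C transition counts Y[p, s] for sample s of
# condition c follow NB(L_s * a[p, c], phi_p), with L_s the per-gene total
# of T-C events after TMM adjustment and phi_p a tagwise dispersion shrunk
# toward a transcript-common value. Everything is computed per transcript,
# which absorbs expression-level differences between conditions, and the
# two groups are compared by a conditional exact test on the group sums
# (the sum of n iid NB(mu, phi) variables is NB(n*mu, phi/n)).

#' Quantile-normalize a count matrix across samples
#'
#' Every column receives the same sorted value multiset (row-wise means of
#' the order statistics); ties within a column get the mean of the
#' quantile values they span. Delegates to
#' [limma::normalizeQuantiles()] with `ties = TRUE`, which implements
#' exactly this rule. Values stay real; [round_half_up()] re-integerizes
#' them before count modeling.
#'
#' @param m numeric matrix, columns = samples.
#' @return real-valued matrix of the same shape.
#' @export
quantile_normalize <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) < 2) {
    warning("single column: quantile normalization is the identity")
    return(m)
  }
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}

#' Mask of positions with enough signal to test
#'
#' A position is valid when at least `min_samples` samples (across both
#' conditions) carry at least `min_count` transition events.
#'
#' @param m integer count matrix, rows = positions, columns = samples.
#' @param min_count,min_samples filter constants (defaults 2 and 2).
#' @return logical vector per row.
#' @export
valid_position_mask <- function(m, min_count = 2, min_samples = 2) {
  rowSums(m >= min_count) >= min_samples
}

#' Keep genes with enough valid positions
#'
#' @param valid_counts named integer vector: valid positions per gene.
#' @param min_positions minimum (default 50); genes with fewer are dropped,
#'   exactly `min_positions` is kept.
#' @return character vector of kept gene ids.
#' @export
filter_genes <- function(valid_counts, min_positions = 50) {
  names(valid_counts)[valid_counts >= min_positions]
}

#' Trimmed-mean-of-M-values normalization factors
#'
#' Scaling-factor normalization robust to a minority of changed positions,
#' computed per gene over its valid positions. The reference sample is the
#' one whose 75th-percentile count fraction is closest to the mean of
#' those fractions; per sample, log-ratios (M) and average log-abundances
#' (A) against the reference are computed on double-positive positions,
#' the extreme 30% of M and 5% of A are trimmed from both tails, and the
#' factor is the precision-weighted mean of the remaining M values
#' (weights = inverse asymptotic variance of M), exponentiated. Factors
#' are rescaled to multiply to 1.
#'
#' @param m count matrix (positions x samples).
#' @param lib_sizes per-sample library sizes; default = column sums.
#' @param logratio_trim,sum_trim trim fractions for M and A.
#' @return numeric vector of per-sample factors.
#' @export
tmm_factors <- function(m, lib_sizes = colSums(m),
                        logratio_trim = 0.3, sum_trim = 0.05) {
  m <- as.matrix(m)
  assert_that(all(lib_sizes > 0), "library sizes must be positive")
  f75 <- vapply(seq_len(ncol(m)),
                function(j) quantile(m[, j], 0.75) / lib_sizes[j], numeric(1))
  ref <- which.min(abs(f75 - mean(f75)))
  f <- vapply(seq_len(ncol(m)), function(j) {
    tmm_pair(m[, j], m[, ref], lib_sizes[j], lib_sizes[ref],
             logratio_trim, sum_trim)
  }, numeric(1))
  f / exp(mean(log(f)))
}

tmm_pair <- function(obs, ref, n_obs, n_ref, logratio_trim, sum_trim) {
  keep <- obs > 0 & ref > 0
  if (sum(keep) < 5) {
    warning("fewer than 5 double-positive positions; TMM factor set to 1")
    return(1)
  }
  o <- obs[keep]
  r <- ref[keep]
  M <- log2((o / n_obs) / (r / n_ref))
  A <- 0.5 * log2((o / n_obs) * (r / n_ref))
  n <- length(M)
  loM <- floor(n * logratio_trim) + 1
  hiM <- n + 1 - loM
  loA <- floor(n * sum_trim) + 1
  hiA <- n + 1 - loA
  rM <- rank(M)
  rA <- rank(A)
  keep2 <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  if (!any(keep2)) return(1)
  w <- (n_obs - o) / (n_obs * o) + (n_ref - r) / (n_ref * r)  # var of M
  f <- sum(M[keep2] / w[keep2]) / sum(1 / w[keep2])
  if (!is.finite(f)) f <- 0
  2^f
}

#' Direction-mixture gene filter
#'
#' A transcript whose positional fold changes point overwhelmingly in one
#' direction reflects a residual expression shift rather than local
#' occupancy changes and is excluded: drop when
#' max(#positive, #negative) / #nonzero exceeds `threshold` strictly.
#' Zero fold changes are excluded from the tally.
#'
#' @param m count matrix over valid positions.
#' @param condition factor/character of length `ncol(m)` with two levels.
#' @param eff_sizes effective library sizes (library size x TMM factor).
#' @param threshold mixture threshold, default 2/3.
#' @return list: `keep` (logical), `n_pos`, `n_neg`, `n_nonzero`.
#' @export
direction_mixture_filter <- function(m, condition, eff_sizes,
                                     threshold = 2 / 3) {
  m <- as.matrix(m)
  cond <- as.character(condition)
  lv <- unique(cond)
  norm <- sweep(m, 2, eff_sizes, "/")
  mean_a <- rowMeans(norm[, cond == lv[1], drop = FALSE])
  mean_b <- rowMeans(norm[, cond == lv[2], drop = FALSE])
  fc <- mean_b - mean_a
  n_pos <- sum(fc > 0)
  n_neg <- sum(fc < 0)
  nz <- n_pos + n_neg
  keep <- if (nz == 0) TRUE else max(n_pos, n_neg) / nz <= threshold
  list(keep = keep, n_pos = n_pos, n_neg = n_neg, n_nonzero = nz)
}

#' Scale counts to a common library size
#'
#' Counts are scaled to the geometric mean of the effective library sizes,
#' a single-pass simplification of iterative quantile-adjusted
#' equalization: pseudo-count expectations then share one library size, as
#' the conditional exact test requires.
#'
#' @param m count matrix.
#' @param eff_sizes positive effective library sizes per sample.
#' @return list: `counts` (real-valued matrix), `common_size`.
#' @export
equalize_libraries <- function(m, eff_sizes) {
  assert_that(all(eff_sizes > 0), "effective library sizes must be positive")
  m <- as.matrix(m)
  common <- exp(mean(log(eff_sizes)))
  list(counts = sweep(m, 2, common / eff_sizes, "*"), common_size = common)
}

# conditional NB log-likelihood of within-group counts given group sums ----
#
# For n iid NB(mu, phi) with r = 1/phi, the counts given their sum S follow
# a Dirichlet-multinomial with concentration r per sample; the conditional
# log-likelihood is free of mu, which is what makes dispersion estimation
# by conditional maximum likelihood possible. phi may be a scalar or a
# per-position vector (rows of y).
cond_ll <- function(y, condition, phi) {
  make_cond_ll(y, condition)(phi)
}

# closure precomputing the phi-independent pieces; the returned function
# evaluates the conditional log-likelihood per position for scalar or
# per-position phi
make_cond_ll <- function(y, condition) {
  y <- as.matrix(y)
  cond <- as.character(condition)
  P <- nrow(y)
  groups <- list()
  for (lv in unique(cond)) {
    yg <- y[, cond == lv, drop = FALSE]
    n <- ncol(yg)
    if (n < 2) next
    S <- .rowSums(yg, P, n)
    groups[[length(groups) + 1L]] <- list(
      yg = yg, n = n, S = S,
      const = lgamma(S + 1) - .rowSums(lgamma(yg + 1), P, n)
    )
  }
  function(phi) {
    r <- 1 / phi  # recycles along rows for vector phi
    total <- numeric(P)
    for (g in groups) {
      acc <- lgamma(g$yg[, 1] + r)
      for (j in 2:g$n) acc <- acc + lgamma(g$yg[, j] + r)
      total <- total + acc - g$n * lgamma(r) + g$const -
        lgamma(g$S + g$n * r) + lgamma(g$n * r)
    }
    total
  }
}

# vectorized golden-section maximization on [lo, hi]; f maps a vector of x
# (one per problem) to a vector of objective values
golden_max <- function(f, lo, hi, n_problems, tol = 1e-4) {
  invphi <- (sqrt(5) - 1) / 2
  a <- rep(lo, n_problems)
  b <- rep(hi, n_problems)
  n_iter <- ceiling(log(tol / (hi - lo)) / log(invphi))
  x1 <- b - invphi * (b - a)
  x2 <- a + invphi * (b - a)
  f1 <- f(x1)
  f2 <- f(x2)
  for (i in seq_len(n_iter)) {
    right <- f1 < f2  # maximum lies in [x1, b]
    a_new <- ifelse(right, x1, a)
    b_new <- ifelse(right, b, x2)
    x1_new <- ifelse(right, x2, b_new - invphi * (b_new - a_new))
    x2_new <- ifelse(right, a_new + invphi * (b_new - a_new), x1)
    fe <- f(ifelse(right, x2_new, x1_new))
    f1_new <- ifelse(right, f2, fe)
    f2_new <- ifelse(right, fe, f1)
    a <- a_new; b <- b_new; x1 <- x1_new; x2 <- x2_new
    f1 <- f1_new; f2 <- f2_new
  }
  (a + b) / 2
}

#' Estimate the transcript-common NB dispersion
#'
#' Maximizes the summed conditional log-likelihood of within-condition
#' counts given their sums over all positions of the transcript, by
#' golden-section search on log10(phi) in [-6, 1] (tolerance 1e-4).
#'
#' @param m count matrix (equalized pseudo-counts, rounded).
#' @param condition two-level condition labels per column.
#' @return scalar dispersion estimate.
#' @export
estimate_common_dispersion <- function(m, condition) {
  m <- round_half_up(as.matrix(m))
  ll <- make_cond_ll(m, condition)
  f <- function(x) {
    vapply(x, function(xi) sum(ll(10^xi)), numeric(1))
  }
  x <- golden_max(f, -6, 1, n_problems = 1)
  val <- f(x)
  assert_that(is.finite(val), "non-finite conditional likelihood")
  10^x
}

#' Estimate tagwise (per-position) NB dispersions
#'
#' Weighted-likelihood shrinkage: each position maximizes its own
#' conditional log-likelihood plus `prior_weight` times the average
#' per-position conditional log-likelihood of the transcript. Large
#' weights pull every estimate to the common maximizer; weight 0 gives
#' per-position maximum likelihood. The shared term is precomputed on a
#' fine log10-dispersion grid and interpolated inside the per-position
#' golden-section search.
#'
#' @inheritParams estimate_common_dispersion
#' @param prior_weight shrinkage weight in pseudo-positions (default 10).
#' @return numeric vector of dispersions, one per row of `m`.
#' @export
estimate_tagwise_dispersion <- function(m, condition, prior_weight = 10) {
  m <- round_half_up(as.matrix(m))
  P <- nrow(m)
  ll <- make_cond_ll(m, condition)
  if (prior_weight > 0) {
    grid <- seq(-6, 1, by = 0.05)
    gbar <- vapply(grid, function(x) mean(ll(10^x)), numeric(1))
    shared <- stats::splinefun(grid, gbar, method = "natural")
  } else {
    shared <- function(x) 0
  }
  f <- function(x) ll(10^x) + prior_weight * shared(x)
  x <- golden_max(f, -6, 1, n_problems = P)
  10^x
}

#' Conditional negative-binomial exact test
#'
#' Tests whether the group sums of equalized counts at one position are
#' compatible with a common relative abundance. Conditional on the total
#' T, every split (k, T-k) has a mu-free probability (negative
#' hypergeometric; binomial in the Poisson limit phi = 0); the two-sided
#' p-value sums the probabilities of all splits as or less likely than the
#' observed one, the analogue of Fisher's exact test for overdispersed
#' counts.
#'
#' @param y_a,y_b equalized per-sample counts of the two conditions at one
#'   position (numeric vectors; group sums are rounded half-up).
#' @param phi NB dispersion (0 = Poisson limit).
#' @return two-sided p-value in (0, 1]; `T = 0` gives 1.
#' @export
nb_exact_test <- function(y_a, y_b, phi = 0) {
  s_a <- round_half_up(sum(y_a))
  s_b <- round_half_up(sum(y_b))
  n_a <- length(y_a)
  n_b <- length(y_b)
  tot <- s_a + s_b
  if (tot == 0) return(1)
  k <- 0:tot
  if (phi <= 0) {
    lp <- dbinom(k, tot, n_a / (n_a + n_b), log = TRUE)
  } else {
    r <- 1 / phi
    a <- n_a * r
    b <- n_b * r
    lp <- lgamma(k + a) - lgamma(k + 1) + lgamma(tot - k + b) -
      lgamma(tot - k + 1)
    lp <- lp - max(lp)
    lp <- lp - log(sum(exp(lp)))
  }
  obs <- lp[s_a + 1]
  p <- sum(exp(lp[lp <= obs + 1e-10]))
  min(max(p, .Machine$double.xmin), 1)
}

#' Empirical FDR from a replicate-swap null
#'
#' Compares the real p-value distribution with the null distribution
#' obtained by rerunning the identical analysis with replicate condition
#' labels swapped. FDR(t) = #null(p <= t) / max(1, #real(p <= t)), rescaled
#' by the ratio of tested-set sizes when they differ, then made monotone
#' non-decreasing in t by cumulative maximum from small t and capped at 1.
#'
#' @param p_real p-values from the real comparison.
#' @param p_null p-values from the swapped-label null run.
#' @param target FDR target for the reported threshold (default 0.1).
#' @return list: `fdr` (per element of `p_real`), `threshold` (largest
#'   real p with FDR < target, or NA).
#' @export
empirical_fdr <- function(p_real, p_null, target = 0.1) {
  assert_that(length(p_null) > 0, "empty null p-value set")
  n_real <- length(p_real)
  n_null <- length(p_null)
  ord <- order(p_real)
  ps <- p_real[ord]
  null_sorted <- sort(p_null)
  n_null_le <- findInterval(ps, null_sorted)
  n_real_le <- findInterval(ps, ps)
  raw <- (n_null_le / pmax(1, n_real_le)) * (n_real / n_null)
  mono <- pmin(cummax(raw), 1)
  fdr <- numeric(n_real)
  fdr[ord] <- mono
  below <- ps[mono < target]
  threshold <- if (length(below) > 0) max(below) else NA_real_
  list(fdr = fdr, threshold = threshold)
}
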