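#' Median-of-ratios size factors
#'
#' Each sample's factor is the median ratio of its counts to the
#' geometric-mean pseudo-reference, computed over features with positive
#' counts in every sample; when no such feature exists the factors fall
#' back to column-sum ratios. Factors are rescaled to geometric mean 1.
#'
#' @param counts Integer matrix, features x samples.
#' @return Numeric vector of size factors (one per sample).
#' @export
estimate_size_factors <- function(counts) {
  if (all(counts == 0)) stop("cannot estimate size factors: all counts are zero")
  allpos <- rowSums(counts > 0) == ncol(counts)
  if (any(allpos)) {
    k <- counts[allpos, , drop = FALSE]
    logref <- rowMeans(log(k))
    sf <- apply(k, 2, function(col) exp(median(log(col) - logref)))
  } else {
    cs <- colSums(counts)
    sf <- cs / mean(cs)
  }
  sf / exp(mean(log(sf)))
}

#' Per-feature NB dispersion: method of moments with trend shrinkage
#'
#' Computes a method-of-moments dispersion from the within-group variance
#' of normalised counts (`alpha = (var - mean) / mean^2`, NB2
#' parameterisation `var = mu + alpha mu^2`), floors it at `floor`, fits a
#' parametric mean-dispersion trend `a0 + a1 / mean` across features, and
#' returns the weighted average `feature_weight * mom + (1 - feature_weight)
#' * trend`. With 2 replicates per group the per-feature estimate has a
#' single residual degree of freedom per group and is extremely noisy;
#' heavy trend shrinkage (default weight 0.3 on the per-feature estimate)
#' is what keeps the downstream Wald test close to its nominal size.
#' Deterministic.
#'
#' @param counts Features x samples count matrix.
#' @param size_factors From [estimate_size_factors()].
#' @param groups Group label per column (>= 2 samples per group).
#' @param feature_weight Weight retained on the per-feature estimate.
#' @param floor Lower bound for dispersions.
#' @return Numeric vector of per-feature dispersions.
#' @export
estimate_dispersion <- function(counts, size_factors, groups,
                                feature_weight = 0.3, floor = 1e-8) {
  q <- sweep(counts, 2, size_factors, "/")
  gl <- unique(groups)
  if (any(table(groups) < 2)) stop("every group needs >= 2 samples")
  m <- rowMeans(q)
  ss <- 0
  for (g in gl) {
    qg <- q[, groups == g, drop = FALSE]
    ss <- ss + rowSums((qg - rowMeans(qg))^2)
  }
  v <- ss / (ncol(q) - length(gl))
  mom <- pmax((v - m) / pmax(m, 1e-8)^2, floor)

  # trend fitted only on informative features (low-count features have
  # wildly unstable MoM values that would otherwise dominate the 1/mean
  # term) with outliers clipped; floored estimates stay in the fit so the
  # trend is not selection-biased upwards on near-Poisson data
  use <- m >= 1
  trend <- NULL
  if (sum(use) >= 10) {
    fit <- lm(pmin(mom[use], 10) ~ I(1 / m[use]))
    if (!anyNA(coef(fit))) {
      trend <- pmax(coef(fit)[1] + coef(fit)[2] / pmax(m, 1e-8), floor)
    }
  }
  if (is.null(trend)) trend <- rep(max(mean(mom), floor), length(mom))
  pmax(feature_weight * mom + (1 - feature_weight) * trend, floor)
}

#' Negative-binomial Wald test per feature (two groups)
#'
#' Fits an NB GLM with log link and a group indicator,
#' `mu_ij = s_j exp(b0 + b1 x_j)` with fixed per-feature dispersion, by
#' IRLS (relative deviance change < 1e-8 or 100 iterations). The Wald
#' statistic is `b1 / SE(b1)` with a two-sided normal p-value; log2 fold
#' changes are the pseudo-stabilised GLM coefficient on the log2 scale
#' (the fit adds `pseudo_count` to every observation, which is negligible
#' at moderate counts but keeps the Wald statistic finite when one group
#' is all zero — otherwise complete separation drives the coefficient to
#' the boundary and the test silently loses all power), with no posterior
#' shrinkage. Features whose total raw count is below `min_count` are
#' skipped and excluded from the BH family; non-converged fits are
#' flagged and carry no p-value.
#'
#' @param counts Features x samples matrix.
#' @param size_factors Per-sample factors.
#' @param dispersions Per-feature dispersions.
#' @param groups Factor-like with exactly two levels; the second level is
#'   the treatment (numerator of the fold change).
#' @param min_count Total-count threshold below which a feature is
#'   `low-count-skipped` (default 2).
#' @param pseudo_count Stabilising constant added to every count in the
#'   GLM fit (default 0.25).
#' @return data.frame: `feature`, `baseMean`, `log2FC`, `lfcSE`, `stat`,
#'   `pvalue`, `padj`, `status`.
#' @export
nb_wald_test <- function(counts, size_factors, dispersions, groups,
                         min_count = 2, pseudo_count = 0.25) {
  lev <- unique(groups)
  if (length(lev) != 2) stop("exactly two groups are required")
  if (any(table(groups) < 2)) stop("both groups need >= 2 replicates")
  x <- as.numeric(groups == lev[2])
  nfeat <- nrow(counts)
  n <- ncol(counts)
  q <- sweep(counts, 2, size_factors, "/")
  baseMean <- rowMeans(q)

  status <- ifelse(rowSums(counts) < min_count, "low-count-skipped", "tested")
  test <- which(status == "tested")

  b0 <- b1 <- se <- rep(NA_real_, nfeat)
  if (length(test) > 0) {
    K <- counts[test, , drop = FALSE] + pseudo_count
    disp <- dispersions[test]
    off <- matrix(log(size_factors), nrow = length(test), ncol = n,
                  byrow = TRUE)
    m1 <- rowMeans(q[test, x == 0, drop = FALSE])
    m2 <- rowMeans(q[test, x == 1, drop = FALSE])
    beta0 <- log(pmax(m1, 0.1))
    beta1 <- log(pmax(m2, 0.1)) - beta0
    conv <- rep(FALSE, length(test))
    dev_old <- rep(Inf, length(test))
    for (it in seq_len(100)) {
      eta <- beta0 + outer(beta1, x) + off
      mu <- pmin(exp(eta), 1e12)
      W <- mu / (1 + disp * mu)
      z <- (eta - off) + (K - mu) / mu
      a11 <- rowSums(W)
      a12 <- as.vector(W %*% x)
      a22 <- as.vector(W %*% (x^2))
      r1 <- rowSums(W * z)
      r2 <- as.vector((W * z) %*% x)
      det <- a11 * a22 - a12^2
      ok <- det > 1e-12
      nb0 <- ifelse(ok, (a22 * r1 - a12 * r2) / det, beta0)
      nb1 <- ifelse(ok, (a11 * r2 - a12 * r1) / det, beta1)
      # bound steps to keep exp() finite on degenerate features
      nb0 <- pmin(pmax(nb0, -50), 50)
      nb1 <- pmin(pmax(nb1, -50), 50)
      dev <- nb_deviance(K, pmin(exp(nb0 + outer(nb1, x) + off), 1e12), disp)
      done <- abs(dev - dev_old) < 1e-8 * (abs(dev_old) + 1e-8)
      conv <- conv | done
      beta0 <- nb0; beta1 <- nb1; dev_old <- dev
      if (all(conv)) break
    }
    eta <- beta0 + outer(beta1, x) + off
    mu <- pmin(exp(eta), 1e12)
    W <- mu / (1 + disp * mu)
    a11 <- rowSums(W)
    a12 <- as.vector(W %*% x)
    a22 <- as.vector(W %*% (x^2))
    det <- a11 * a22 - a12^2
    b0[test] <- beta0
    b1[test] <- beta1
    se[test] <- sqrt(pmax(a11 / det, 0))
    status[test][!conv] <- "not-converged"
  }

  pvalue <- rep(NA_real_, nfeat)
  tested <- status == "tested"
  pvalue[tested] <- 2 * pnorm(-abs(b1[tested] / se[tested]))
  padj <- rep(NA_real_, nfeat)
  padj[tested] <- bh_adjust(pvalue[tested])

  data.frame(feature = rownames(counts) %||% as.character(seq_len(nfeat)),
             baseMean = baseMean,
             log2FC = b1 / log(2),
             lfcSE = se / log(2),
             stat = b1 / se,
             pvalue = pvalue, padj = padj, status = status,
             stringsAsFactors = FALSE, row.names = NULL)
}

nb_deviance <- function(K, mu, disp) {
  # analytic NB2 deviance, continuous in K (tolerates pseudo-counts);
  # reduces to the Poisson deviance as disp -> 0
  if (length(disp) == 1) disp <- rep(disp, nrow(K))
  d <- matrix(disp, nrow(K), ncol(K))
  t1 <- ifelse(K > 0, K * log(K / mu), 0)
  t2 <- ifelse(d < 1e-12,
               K - mu,
               (K + 1 / pmax(d, 1e-12)) * log((1 + d * K) / (1 + d * mu)))
  rowSums(2 * (t1 - t2))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment over one family of raw p-values (skipped
#' features are excluded from the family by the callers).
#'
#' @param pvalues Numeric vector in `[0, 1]` (NA allowed and preserved).
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

#' Generic per-feature NB GLM fit with fixed dispersion
#'
#' IRLS for `y ~ NB(mu = exp(X beta + offset), alpha)`; used by the
#' differential-translation interaction test.
#'
#' @param y Integer counts (one feature).
#' @param X Design matrix.
#' @param offset Per-sample offset (log size factors).
#' @param alpha NB dispersion.
#' @return List with `beta`, `se`, `converged`.
#' @keywords internal
nb_glm <- function(y, X, offset, alpha, max_iter = 100, tol = 1e-8) {
  beta <- qr.solve(X, log(pmax(y, 0.5)) - offset)
  dev_old <- Inf
  conv <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- as.vector(X %*% beta) + offset
    mu <- pmin(exp(eta), 1e12)
    W <- mu / (1 + alpha * mu)
    z <- (eta - offset) + (y - mu) / mu
    XtW <- t(X * W)
    beta_new <- tryCatch(solve(XtW %*% X, XtW %*% z),
                         error = function(e) NULL)
    if (is.null(beta_new)) break
    beta_new <- pmin(pmax(as.vector(beta_new), -50), 50)
    mu_new <- pmin(exp(as.vector(X %*% beta_new) + offset), 1e12)
    dev <- as.numeric(nb_deviance(matrix(y, 1), matrix(mu_new, 1), alpha))
    beta <- beta_new
    if (abs(dev - dev_old) < tol * (abs(dev_old) + tol)) { conv <- TRUE; break }
    dev_old <- dev
  }
  eta <- as.vector(X %*% beta) + offset
  mu <- pmin(exp(eta), 1e12)
  W <- mu / (1 + alpha * mu)
  cov <- tryCatch(solve(t(X * W) %*% X), error = function(e) NULL)
  se <- if (is.null(cov)) rep(NA_real_, length(beta)) else sqrt(pmax(diag(cov), 0))
  list(beta = beta, se = se, converged = conv)
}

#' Transcription-conditioned differential translation
#'
#' Joint NB GLM on stacked RNA-seq and Ribo-seq counts with covariates
#' assay, group, and their interaction; a change in Ribo-seq signal beyond
#' what the RNA-seq change predicts loads on the interaction term. Size
#' factors are estimated separately per assay, dispersions from the
#' stacked normalised counts over the four assay x group cells. The
#' BH-adjusted interaction Wald p-value is the q-value, with q < 0.01 the
#' conventional significance threshold.
#'
#' @param rna_counts,ribo_counts Features x samples matrices with the same
#'   features.
#' @param groups Group labels for the columns of each matrix (two levels;
#'   the second is the evolved/treatment group).
#' @param feature_weight Dispersion shrinkage weight, see
#'   [estimate_dispersion()].
#' @param min_count Skip threshold on the total stacked count.
#' @param pseudo_count Stabilising constant added in the fit, see
#'   [nb_wald_test()].
#' @return data.frame: `feature`, `log2FC_interaction`, `lfcSE`, `stat`,
#'   `pvalue`, `qvalue`, `status`.
#' @export
differential_translation <- function(rna_counts, ribo_counts, groups,
                                     feature_weight = 0.3, min_count = 2,
                                     pseudo_count = 0.25) {
  stopifnot(nrow(rna_counts) == nrow(ribo_counts),
            ncol(rna_counts) == length(groups),
            ncol(ribo_counts) == length(groups))
  lev <- unique(groups)
  if (length(lev) != 2) stop("exactly two groups are required")

  sf <- c(estimate_size_factors(rna_counts), estimate_size_factors(ribo_counts))
  K <- cbind(rna_counts, ribo_counts)
  grp <- as.numeric(rep(groups == lev[2], 2))
  assay <- rep(c(0, 1), times = c(ncol(rna_counts), ncol(ribo_counts)))
  cell <- paste(assay, grp)
  disp <- estimate_dispersion(K, sf, cell, feature_weight = feature_weight)

  X <- cbind(1, assay, grp, assay * grp)
  colnames(X) <- c("intercept", "assay", "group", "interaction")
  off <- log(sf)

  nfeat <- nrow(K)
  est <- se <- rep(NA_real_, nfeat)
  status <- ifelse(rowSums(K) < min_count, "low-count-skipped", "tested")
  for (i in which(status == "tested")) {
    fit <- nb_glm(as.numeric(K[i, ]) + pseudo_count, X, off, disp[i])
    if (!fit$converged || is.na(fit$se[4])) { status[i] <- "not-converged"; next }
    est[i] <- fit$beta[4]
    se[i] <- fit$se[4]
  }
  pvalue <- rep(NA_real_, nfeat)
  tested <- status == "tested"
  pvalue[tested] <- 2 * pnorm(-abs(est[tested] / se[tested]))
  qvalue <- rep(NA_real_, nfeat)
  qvalue[tested] <- bh_adjust(pvalue[tested])

  data.frame(feature = rownames(rna_counts) %||% as.character(seq_len(nfeat)),
             log2FC_interaction = est / log(2),
             lfcSE = se / log(2),
             stat = est / se,
             pvalue = pvalue, qvalue = qvalue, status = status,
             stringsAsFactors = FALSE, row.names = NULL)
}
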