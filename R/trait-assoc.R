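#' Deregress estimated breeding values into pseudo-phenotypes
#'
#' EBVs from routine genetic evaluation are shrunken towards the mean in
#' proportion to their reliability; dividing by the reliability removes the
#' shrinkage so the result can serve as a pseudo-phenotype in an association
#' model. The accompanying weight r2/(1 - r2) reflects the information
#' content of each record and is capped to keep near-unit reliabilities
#' from dominating.
#'
#' @param ebv Numeric vector of estimated breeding values.
#' @param reliability Reliabilities (r2) in (0, 1], recycled to `ebv`.
#' @param max_weight Cap on the weight (default 20).
#'
#' @return Data frame with `pseudo` (= ebv / reliability) and `weight`
#'   (= min(reliability / (1 - reliability), max_weight)).
#' @export
deregress <- function(ebv, reliability, max_weight = 20) {
  if (any(reliability <= 0 | reliability > 1))
    stop("reliability must be in (0, 1]")
  reliability <- rep_len(reliability, length(ebv))
  w <- ifelse(reliability >= 1, max_weight,
              pmin(reliability / (1 - reliability), max_weight))
  data.frame(pseudo = ebv / reliability, weight = w)
}

#' Genomic relationship matrix (VanRaden method 1)
#'
#' G = Z Z' / (2 sum_j p_j (1 - p_j)) with Z the dosage matrix centred by
#' twice the sample allele frequency. Monomorphic SNPs carry no information
#' and are dropped with a message.
#'
#' @param x A [phased_geno()] object or an animals x SNPs dosage matrix
#'   (0/1/2) with animal ids as rownames.
#' @return Symmetric GRM with animal ids as dimnames (diagonal about
#'   1 + inbreeding).
#' @export
compute_grm <- function(x) {
  d <- if (inherits(x, "phased_geno")) alt_dosage(x) else as.matrix(x)
  if (nrow(d) < 2L) stop("need at least 2 animals")
  p <- colMeans(d) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("all SNPs are monomorphic; GRM undefined")
  if (any(!poly))
    message(sum(!poly), " monomorphic SNP(s) dropped from the GRM")
  d <- d[, poly, drop = FALSE]
  p <- p[poly]
  z <- sweep(d, 2L, 2 * p)
  g <- tcrossprod(z) / (2 * sum(p * (1 - p)))
  dimnames(g) <- list(rownames(d), rownames(d))
  g
}

# Spectral REML machinery: eigendecompose G once, profile the variance
# ratio delta = sigma2_g / sigma2_e on the rotated data (EMMA-style exact
# one-component REML).
grm_eigen <- function(G, ridge = 1e-6) {
  G <- (G + t(G)) / 2
  e <- eigen(G, symmetric = TRUE)
  if (min(e$values) < -1e-8) {
    message("GRM not positive semi-definite; ridge of ", ridge, " applied")
    e$values <- e$values + ridge
  }
  e$values[e$values < 0] <- 0
  e
}

# Maximize the restricted likelihood over delta: coarse log-grid search
# refined by 1-D optimization between the flanking grid points; the
# boundary delta = 0 (no genetic variance) is checked explicitly.
reml_opt_delta <- function(yr, Xr, D) {
  grid <- 10^seq(-4, 4, length.out = 33)
  ll <- vapply(grid, reml_ll_rot, numeric(1), yr = yr, Xr = Xr, D = D)
  k <- which.max(ll)
  lo <- grid[max(1L, k - 1L)]
  hi <- grid[min(length(grid), k + 1L)]
  opt <- stats::optimize(function(ld) reml_ll_rot(exp(ld), yr, Xr, D),
                         interval = log(c(lo, hi)), maximum = TRUE)
  delta <- exp(opt$maximum)
  best <- max(opt$objective, ll[k])
  if (ll[k] > opt$objective) delta <- grid[k]
  if (reml_ll_rot(0, yr, Xr, D) >= best) delta <- 0
  delta
}

# Restricted log-likelihood at variance ratio delta for rotated data.
reml_ll_rot <- function(delta, yr, Xr, D) {
  n <- length(yr); q <- ncol(Xr)
  v <- delta * D + 1
  w <- 1 / v
  XtWX <- crossprod(Xr, Xr * w)
  beta <- solve(XtWX, crossprod(Xr, yr * w))
  rss <- sum(w * (yr - Xr %*% beta)^2)
  ld <- determinant(XtWX, logarithm = TRUE)$modulus
  -0.5 * ((n - q) * log(2 * pi * rss / (n - q)) + (n - q) +
            sum(log(v)) + as.numeric(ld))
}

#' Restricted-likelihood profile over the variance ratio
#'
#' Evaluates the REML log-likelihood of the one-component animal model on a
#' grid of variance ratios delta = sigma2_g / sigma2_e. Exposed for
#' diagnostics and for verifying that the fitted ratio attains the profile
#' maximum.
#'
#' @param y Phenotype vector.
#' @param X Fixed-effect design matrix (with intercept).
#' @param G Genomic relationship matrix aligned with `y`.
#' @param deltas Grid of variance ratios (default logarithmic in
#'   [1e-4, 1e4]).
#' @return Data frame `delta`, `logLik`.
#' @export
reml_profile <- function(y, X, G, deltas = 10^seq(-4, 4, length.out = 41)) {
  e <- grm_eigen(G)
  yr <- crossprod(e$vectors, y)
  Xr <- crossprod(e$vectors, X)
  data.frame(delta = deltas,
             logLik = vapply(deltas, reml_ll_rot, numeric(1),
                             yr = yr, Xr = Xr, D = e$values))
}

#' Fit a one-component genomic mixed model
#'
#' Animal model y = X b + g + e with g ~ N(0, G sigma2_g),
#' e ~ N(0, I sigma2_e), fitted by exact restricted maximum likelihood via
#' a single eigendecomposition of G and one-dimensional optimization of the
#' variance ratio (grid search refined by golden-section). The last column
#' of the design is the tested covariate; its Wald p-value is reported.
#'
#' @param y Phenotype (pseudo-phenotype) vector.
#' @param x Tested covariate (e.g. risk-allele dosage).
#' @param G GRM aligned with `y` and `x`.
#' @param covariates Optional matrix of additional fixed covariates.
#' @param delta Fix the variance ratio sigma2_g/sigma2_e instead of
#'   estimating it (0 gives ordinary least squares).
#' @param target,trait_code Labels carried into the result.
#'
#' @return One-row data frame of class `assoc_result`: `target`,
#'   `trait_code`, `n`, `beta`, `se`, `p_value`, `sigma2_g`, `sigma2_e`,
#'   `h2`, `model`.
#' @export
lmm_fit <- function(y, x, G, covariates = NULL, delta = NULL,
                    target = NA_character_, trait_code = NA_character_) {
  if (any(!is.finite(y))) stop("non-finite phenotypes")
  if (any(!is.finite(x))) stop("non-finite covariate")
  X <- cbind(`(Intercept)` = 1, covariates, x = x)
  if (qr(X)$rank < ncol(X))
    stop("singular design: tested covariate is constant or collinear")
  stopifnot(length(y) == nrow(G), length(x) == length(y))
  e <- grm_eigen(G)
  yr <- as.vector(crossprod(e$vectors, y))
  Xr <- crossprod(e$vectors, X)
  D <- e$values
  if (is.null(delta)) delta <- reml_opt_delta(yr, Xr, D)
  n <- length(yr); q <- ncol(X)
  v <- delta * D + 1
  w <- 1 / v
  XtWX <- crossprod(Xr, Xr * w)
  beta <- solve(XtWX, crossprod(Xr, yr * w))
  rss <- sum(w * (yr - Xr %*% beta)^2)
  sigma2_e <- rss / (n - q)
  sigma2_g <- delta * sigma2_e
  covb <- solve(XtWX) * sigma2_e
  b <- beta[q]
  se <- sqrt(covb[q, q])
  z <- b / se
  out <- data.frame(
    target = target, trait_code = trait_code, n = n,
    beta = b, se = se, p_value = 2 * stats::pnorm(-abs(z)),
    sigma2_g = sigma2_g, sigma2_e = sigma2_e,
    h2 = sigma2_g / (sigma2_g + sigma2_e), model = "LMM",
    stringsAsFactors = FALSE
  )
  class(out) <- c("assoc_result", "data.frame")
  out
}

#' Associate a haplotype diplotype with a trait
#'
#' Deregresses the trait's EBVs into pseudo-phenotypes and fits the genomic
#' mixed model with risk-allele copies (0/1/2, additive coding) as the
#' tested covariate.
#'
#' @param diplotypes Output of [assign_diplotypes()] (or any data frame
#'   with `animal_id` and `copies`).
#' @param traits Trait table: `animal_id`, `trait`, `ebv`, `reliability`.
#' @param G GRM whose dimnames cover the animals used.
#' @param trait_code Trait abbreviation to analyse.
#' @param min_informative Minimum number of animals with phenotype,
#'   genotype and GRM entry (default 30).
#'
#' @return An `assoc_result` row (see [lmm_fit()]).
#' @export
haplotype_association <- function(diplotypes, traits, G, trait_code,
                                  min_informative = 30) {
  tr <- traits[traits$trait == trait_code, , drop = FALSE]
  if (nrow(tr) == 0L) stop("trait ", trait_code, " not present")
  ids <- intersect(intersect(diplotypes$animal_id, tr$animal_id),
                   rownames(G))
  if (length(ids) < min_informative)
    stop("only ", length(ids), " informative animals (< ", min_informative,
         "); association refused")
  tr <- tr[match(ids, tr$animal_id), ]
  dr <- deregress(tr$ebv, tr$reliability)
  x <- diplotypes$copies[match(ids, diplotypes$animal_id)]
  lmm_fit(dr$pseudo, x, G[ids, ids],
          target = "haplotype", trait_code = trait_code)
}

#' Genome-wide single-SNP association scan
#'
#' Mixed-model GWAS of every polymorphic SNP against a trait's deregressed
#' EBVs. Variance components are estimated once under the covariate-free
#' null model and reused for every SNP (the standard two-stage
#' approximation), so each SNP costs one generalized least-squares fit on
#' the rotated data. A Bonferroni threshold alpha / m over the m tested
#' SNPs flags genome-wide significance.
#'
#' @param geno A [phased_geno()] object.
#' @param traits Trait table (`animal_id`, `trait`, `ebv`, `reliability`).
#' @param G GRM over (at least) the genotyped animals.
#' @param trait_code Trait abbreviation to analyse.
#' @param alpha Family-wise error level before Bonferroni division
#'   (default 0.05).
#'
#' @return Data frame with one row per tested SNP: `snp_id`, `chrom`,
#'   `pos_bp`, `beta`, `se`, `p_value`, `significant`; attributes
#'   `threshold` (= alpha/m) and `m`.
#' @export
gwas_scan <- function(geno, traits, G, trait_code, alpha = 0.05) {
  tr <- traits[traits$trait == trait_code, , drop = FALSE]
  if (nrow(tr) == 0L) stop("trait ", trait_code, " not present")
  ids <- intersect(intersect(geno$animal_ids, tr$animal_id), rownames(G))
  tr <- tr[match(ids, tr$animal_id), ]
  dr <- deregress(tr$ebv, tr$reliability)
  y <- dr$pseudo
  d <- alt_dosage(geno)[ids, , drop = FALSE]
  p <- colMeans(d) / 2
  poly <- which(p > 0 & p < 1)
  m <- length(poly)
  if (m == 0L) stop("no polymorphic SNPs to test")
  thr <- alpha / m

  e <- grm_eigen(G[ids, ids])
  yr <- as.vector(crossprod(e$vectors, y))
  ones_r <- crossprod(e$vectors, rep(1, length(y)))
  # variance ratio from the null (intercept-only) model, reused per SNP
  delta <- reml_opt_delta(yr, ones_r, e$values)
  w <- 1 / (delta * e$values + 1)

  dr_rot <- crossprod(e$vectors, d[, poly, drop = FALSE])
  n <- length(yr)
  res <- matrix(NA_real_, m, 3)
  for (j in seq_len(m)) {
    Xr <- cbind(ones_r, dr_rot[, j])
    XtWX <- crossprod(Xr, Xr * w)
    beta <- solve(XtWX, crossprod(Xr, yr * w))
    rss <- sum(w * (yr - Xr %*% beta)^2)
    s2 <- rss / (n - 2L)
    se <- sqrt(solve(XtWX)[2, 2] * s2)
    res[j, ] <- c(beta[2], se, 2 * stats::pnorm(-abs(beta[2] / se)))
  }
  out <- data.frame(
    snp_id = geno$map$snp_id[poly], chrom = geno$map$chrom[poly],
    pos_bp = geno$map$pos_bp[poly],
    beta = res[, 1], se = res[, 2], p_value = res[, 3],
    significant = res[, 3] < thr, stringsAsFactors = FALSE
  )
  attr(out, "threshold") <- thr
  attr(out, "m") <- m
  out
}
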