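test_that("deregression rescales EBVs and caps weights", {
  d <- deregress(2.0, 0.5)
  expect_equal(d$pseudo, 4.0)
  expect_equal(d$weight, 1.0)
  d1 <- deregress(c(1, -2), 1)
  expect_equal(d1$pseudo, c(1, -2))     # reliability 1: no shrinkage
  expect_equal(d1$weight, c(20, 20))    # weight capped
  expect_error(deregress(1, 0), "reliability")
  # simulated EBVs deregress to an unbiased pseudo-phenotype
  sim <- fx_assoc_sim()
  tr <- simulate_trait_ebvs(sim$pedigree, sim$truth, h2 = 0.5,
                            reliability = 0.6, seed = 13)
  pseudo <- deregress(tr$ebvs$ebv, tr$ebvs$reliability)$pseudo
  err <- mean(pseudo) - mean(tr$tbv)
  se <- stats::sd(pseudo - tr$tbv) / sqrt(length(pseudo))
  expect_lt(abs(err), 3 * se + 1e-12)
})

test_that("GRM matches the VanRaden closed form and is well-behaved", {
  # 2 animals, 1 SNP at p = 0.5, dosages 0 and 2
  d <- matrix(c(0, 2), 2, 1, dimnames = list(c("a", "b"), "s1"))
  G <- compute_grm(d)
  expect_equal(unname(G), matrix(c(2, -2, -2, 2), 2))
  # duplicated animal: off-diagonal equals the diagonal
  sim <- fx_assoc_sim()
  ids <- sim$genotypes$animal_ids[1:40]
  dd <- alt_dosage(subset_animals(sim$genotypes, ids))
  dd2 <- rbind(dd, dup = dd[1, ])
  rownames(dd2) <- c(ids, "dup")
  G2 <- compute_grm(dd2)
  expect_equal(G2["dup", ids[1]], G2[ids[1], ids[1]])
  # symmetric; diagonal near 1 for the founder animals
  Gf <- compute_grm(subset_animals(sim$genotypes,
                                   sim$genotypes$animal_ids[1:150]))
  expect_equal(Gf, t(Gf))
  expect_lt(abs(mean(diag(Gf)) - 1), 0.05)
  # permutation equivariance
  perm <- rev(ids)
  Gp <- compute_grm(dd[perm, ])
  G0 <- compute_grm(dd)
  expect_equal(Gp[perm, perm][ids, ids], G0[ids, ids], tolerance = 1e-12)
  expect_error(compute_grm(matrix(0, 3, 2)), "monomorphic")
})

test_that("the mixed model reduces to OLS when the genetic variance is off", {
  set.seed(8)
  y <- stats::rnorm(80)
  x <- stats::rnorm(80)
  f <- lmm_fit(y, x, diag(80), delta = 0)
  ols <- summary(stats::lm(y ~ x))$coefficients
  expect_equal(f$beta, ols[2, 1], tolerance = 1e-10)
  expect_equal(f$se, ols[2, 2], tolerance = 1e-10)
  expect_error(lmm_fit(y, rep(1, 80), diag(80)), "singular")
  expect_error(lmm_fit(c(y[-1], NA), x, diag(80)), "non-finite")
})

test_that("the fitted variance ratio attains the restricted-likelihood profile maximum", {
  sim <- fx_assoc_sim()
  ids <- sim$genotypes$animal_ids[1:300]
  G <- compute_grm(subset_animals(sim$genotypes, ids))
  set.seed(15)
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  g <- e$vectors %*% (sqrt(pmax(e$values, 0) * 0.5) * stats::rnorm(300))
  y <- as.vector(g) + stats::rnorm(300, 0, sqrt(0.5))
  x <- stats::rnorm(300)
  f <- lmm_fit(y, x, G)
  prof <- reml_profile(y, cbind(1, x), G)
  ll_hat <- reml_profile(y, cbind(1, x), G,
                         deltas = f$sigma2_g / f$sigma2_e)$logLik
  expect_gte(ll_hat + 1e-6, max(prof$logLik))
})

test_that("haplotype association recovers a negative effect and guards its inputs", {
  sim <- fx_assoc_sim()
  tr <- simulate_trait_ebvs(sim$pedigree, sim$truth, h2 = 0.5,
                            hap_effect = -0.5, reliability = 0.9, seed = 2)
  dip <- assign_diplotypes(sim$genotypes, sim$truth$window,
                           sim$truth$pattern)
  G <- compute_grm(sim$genotypes)
  a <- haplotype_association(dip, tr$ebvs, G, "NRh")
  expect_lt(a$beta, 0)
  expect_lt(a$p_value, 0.05)
  expect_error(haplotype_association(dip, tr$ebvs, G, "BWd"),
               "not present")
  few <- dip[1:10, ]
  expect_error(haplotype_association(few, tr$ebvs, G, "NRh"),
               "informative")
  # constant covariate refused
  dip0 <- dip; dip0$copies <- 0L
  expect_error(haplotype_association(dip0, tr$ebvs, G, "NRh"), "singular")
})

test_that("permuted phenotypes give uniform association p-values", {
  sim <- fx_assoc_sim()
  ids <- sim$genotypes$animal_ids[1:250]
  G <- compute_grm(subset_animals(sim$genotypes, ids))
  dip <- assign_diplotypes(sim$genotypes, sim$truth$window,
                           sim$truth$pattern)
  dip <- dip[match(ids, dip$animal_id), ]
  set.seed(77)
  base <- stats::rnorm(250)
  pvals <- replicate(200, {
    y <- sample(base)
    lmm_fit(y, dip$copies, G, delta = 0)$p_value
  })
  ks <- stats::ks.test(pvals, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("the GWAS scan localizes a sublethal additive signal", {
  hits <- 0L
  for (s in 1:10) {
    sim <- simulate_population(sim_config(
      n_founders = 200, n_generations = 2, offspring_per_dam = 3,
      penetrance = 0, risk_hap_freq = 0.1, female_genotyping_rate = 1,
      seed = s))
    tr <- simulate_trait_ebvs(sim$pedigree, sim$truth, h2 = 0.5,
                              hap_effect = -0.8, reliability = 0.9,
                              seed = s)
    G <- compute_grm(sim$genotypes)
    gw <- gwas_scan(sim$genotypes, tr$ebvs, G, "NRh")
    expect_equal(attr(gw, "threshold"), 0.05 / attr(gw, "m"))
    top <- gw[which.min(gw$p_value), ]
    tw <- sim$truth$window
    if (top$chrom == tw$chrom && top$pos_bp >= tw$bp_start - 5e5 &&
          top$pos_bp <= tw$bp_end + 5e5) hits <- hits + 1L
  }
  expect_gte(hits, 6L)
  sim <- fx_assoc_sim()
  G <- compute_grm(sim$genotypes)
  expect_error(gwas_scan(sim$genotypes,
                         data.frame(animal_id = "x", trait = "NRh",
                                    ebv = 1, reliability = 0.5),
                         G, "GLm"), "not present")
  # under the null, genome-wide hits are rare
  null_hits <- vapply(1:5, function(s) {
    tr <- simulate_trait_ebvs(sim$pedigree, sim$truth, h2 = 0.5,
                              hap_effect = 0, reliability = 0.9, seed = s)
    sum(gwas_scan(sim$genotypes, tr$ebvs, G, "NRh")$significant)
  }, numeric(1))
  expect_gte(mean(null_hits == 0), 0.8)
})
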