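test_that("config validation rejects degenerate scenarios", {
  expect_error(sim_config(risk_hap_freq = 0), "risk_hap_freq")
  expect_error(sim_config(trait_h2 = 1.2), "trait_h2")
  expect_error(sim_config(n_snps = 60, n_chromosomes = 2,
                          risk_window_size = 50), "n_snps too small")
  # a scan over this population would be vacuous: fewer than one expected
  # carrier x carrier mating
  tiny <- sim_config(n_founders = 20, n_generations = 1,
                     offspring_per_dam = 1, risk_hap_freq = 0.02)
  expect_error(simulate_population(tiny), "carrier")
})

test_that("identical config and seed give bit-identical populations", {
  cfg <- sim_config(n_founders = 60, n_generations = 2,
                    offspring_per_dam = 2, risk_hap_freq = 0.2, seed = 9)
  s1 <- simulate_population(cfg)
  s2 <- simulate_population(cfg)
  expect_identical(s1$pedigree, s2$pedigree)
  expect_identical(s1$genotypes$hap, s2$genotypes$hap)
  expect_identical(s1$truth$copies, s2$truth$copies)
  # byte-identical external representation too
  f1 <- tempfile(fileext = ".vcf"); f2 <- tempfile(fileext = ".vcf")
  write_phased_vcf(s1$genotypes, f1)
  write_phased_vcf(s2$genotypes, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("full lethality leaves no living homozygote, across seeds", {
  for (s in 1:5) {
    sim <- simulate_population(sim_config(
      n_founders = 80, n_generations = 2, offspring_per_dam = 3,
      risk_hap_freq = 0.2, penetrance = 1, seed = s))
    expect_identical(sum(sim$truth$copies == 2L), 0L)
  }
})

test_that("risk haplotype is seeded at the target founder frequency", {
  for (s in 1:5) {
    cfg <- sim_config(n_founders = 150, n_generations = 1,
                      offspring_per_dam = 2, risk_hap_freq = 0.1, seed = s)
    sim <- simulate_population(cfg)
    q <- sim$truth$founder_freq
    se <- sqrt(0.1 * 0.9 / (2 * 150))
    expect_lt(abs(q - 0.1), 2 * se + 1 / 300)  # rounding of the seed count
  }
})

test_that("offspring homozygote fraction matches Hardy-Weinberg without lethality", {
  # near-random mating: broad sire panel with uniform usage
  cfg <- sim_config(n_founders = 400, n_generations = 1,
                    offspring_per_dam = 8, n_sires_per_gen = 200,
                    sire_usage_decay = 1, penetrance = 0,
                    risk_hap_freq = 0.3, female_genotyping_rate = 1,
                    seed = 11)
  sim <- simulate_population(cfg)
  off <- sim$pedigree$animal_id[sim$pedigree$generation == 1L]
  copies <- sim$truth$copies[off]
  q <- sim$truth$founder_freq
  n <- length(off)
  p_hom <- mean(copies == 2L)
  se <- sqrt(q^2 * (1 - q^2) / n)
  expect_lt(abs(p_hom - q^2), 3 * se)
})

test_that("every offspring haplotype is a mosaic of its parent's haplotypes", {
  sim <- fx_sim()
  ped <- sim$pedigree
  geno <- sim$genotypes
  idx <- match(ped$animal_id, geno$animal_ids)
  off <- which(!is.na(ped$sire_id) & !is.na(idx) &
                 ped$sire_id %in% geno$animal_ids &
                 ped$dam_id %in% geno$animal_ids)
  off <- off[seq_len(min(50, length(off)))]
  for (o in off) {
    oi <- idx[o]
    si <- match(ped$sire_id[o], geno$animal_ids)
    di <- match(ped$dam_id[o], geno$animal_ids)
    pat <- geno$hap[2L * oi - 1L, ]
    mat <- geno$hap[2L * oi, ]
    s1 <- geno$hap[2L * si - 1L, ]; s2 <- geno$hap[2L * si, ]
    d1 <- geno$hap[2L * di - 1L, ]; d2 <- geno$hap[2L * di, ]
    expect_true(all(pat == s1 | pat == s2))
    expect_true(all(mat == d1 | mat == d2))
  }
})

test_that("maternal grandsire resolves through the dam", {
  ped <- fx_sim()$pedigree
  has_mgs <- !is.na(ped$mgs_id)
  expect_true(any(has_mgs))
  dam_sire <- ped$sire_id[match(ped$dam_id[has_mgs], ped$animal_id)]
  expect_identical(ped$mgs_id[has_mgs], dam_sire)
  # pedigree is acyclic: parents always precede offspring in the table
  pos <- seq_len(nrow(ped))
  si <- match(ped$sire_id, ped$animal_id)
  expect_true(all(si[!is.na(si)] < pos[!is.na(si)]))
})

test_that("EBV simulation has the declared reliability structure", {
  sim <- fx_sim()
  # reliability 1 => EBV equals TBV exactly
  tr <- simulate_trait_ebvs(sim$pedigree, sim$truth, h2 = 0.4,
                            reliability = 1, seed = 3)
  expect_equal(tr$ebvs$ebv, unname(tr$tbv))
  expect_error(simulate_trait_ebvs(sim$pedigree, sim$truth, h2 = 1.5),
               "h2")
  # with no haplotype effect the EBV ~ dosage regression is null
  pvals <- vapply(1:8, function(s) {
    tr <- simulate_trait_ebvs(sim$pedigree, sim$truth, h2 = 0.4,
                              hap_effect = 0, seed = s)
    x <- as.numeric(sim$truth$copies[tr$ebvs$animal_id])
    summary(stats::lm(tr$ebvs$ebv ~ x))$coefficients[2, 4]
  }, numeric(1))
  expect_gte(mean(pvals > 0.01), 7 / 8)
})
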