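test_that("per-offspring homozygosity probabilities follow the closed forms", {
  expect_equal(per_offspring_prob("trio", 1, 1), 0.25)
  expect_equal(per_offspring_prob("trio", 0, 2), 0)
  expect_equal(per_offspring_prob("trio", 2, 2), 1)
  expect_equal(per_offspring_prob("pgp", 1, 1, q = 0.02), 0.13)
  expect_equal(per_offspring_prob("pgp", 1, 0, q = 0), 0)
  expect_equal(per_offspring_prob("pgp", 2, 2, q = 0), 0.5)
  # vectorized
  expect_equal(per_offspring_prob("trio", c(1, 2), c(1, 1)), c(0.25, 0.5))
  expect_error(per_offspring_prob("trio", 3, 1))
})

test_that("expected homozygotes is an order-invariant sum", {
  expect_equal(expected_homozygotes(rep(0.25, 4)), 1)
  expect_equal(expected_homozygotes(rep(0.125, 8)), 1)
  pi <- c(0.25, 0.13, 0.125, 0.5)
  expect_equal(expected_homozygotes(pi), expected_homozygotes(rev(pi)))
  expect_warning(e0 <- expected_homozygotes(numeric(0)), "no mating")
  expect_equal(e0, 0)
})

test_that("exact deficit test matches closed-form binomial tails", {
  expect_equal(exact_deficit_test(rep(0.25, 8), 0), 0.75^8)
  expect_equal(exact_deficit_test(rep(0.25, 8), 8), 1)
  expect_equal(exact_deficit_test(rep(0.3, 10), 3),
               stats::pbinom(3, 10, 0.3))
  # zero-probability offspring cannot contribute homozygotes
  expect_equal(exact_deficit_test(c(rep(0.25, 8), rep(0, 100)), 0), 0.75^8)
  expect_error(exact_deficit_test(c(0.5, 1.2), 0), "\\[0, 1\\]")
  expect_error(exact_deficit_test(rep(0.5, 3), 4), "exceeds")
})

test_that("Poisson-binomial tail equals exhaustive enumeration", {
  set.seed(101)
  for (rep in 1:40) {
    n <- sample(1:10, 1)
    pi <- stats::runif(n)
    obs <- sample(0:n, 1)
    expect_equal(exact_deficit_test(pi, obs), pb_enum_tail(pi, obs),
                 tolerance = 1e-12)
  }
  # heterogeneous example at realistic mating probabilities
  pi <- c(0.25, 0.13, 0.125)
  expect_equal(exact_deficit_test(pi, 1), pb_enum_tail(pi, 1),
               tolerance = 1e-12)
})

test_that("BY adjustment reproduces the step-up construction", {
  expect_equal(by_adjust(0.03), 0.03)           # m = 1: c(1) = 1
  expect_equal(by_adjust(c(0.01, 0.02, 0.9)), c(0.055, 0.055, 1))
  set.seed(5)
  p <- stats::runif(50)
  expect_true(all(by_adjust(p) >= p))
  expect_true(all(by_adjust(p) <= 1))
})

test_that("deficiency percentage follows the reporting convention", {
  expect_identical(deficiency_pct(7, 28), 75L)
  expect_identical(deficiency_pct(0, 157), 100L)
  expect_identical(deficiency_pct(10, 10), 0L)
  expect_error(deficiency_pct(1, 0), "expected")
})

test_that("the scan finds an embedded lethal and reports a region over it", {
  sim <- simulate_population(power_cfg(21))
  res <- scan_deficit(sim$genotypes, sim$pedigree, "trio")
  tw <- sim$truth$window
  hit <- res[res$allele == sim$truth$pattern &
               res$snp_start == tw$snp_start, ]
  expect_identical(nrow(hit), 1L)
  expect_identical(hit$observed_hom, 0L)
  expect_identical(hit$deficiency_pct, 100L)
  expect_lt(hit$p_adj_BY, 0.05)
  expect_true(all(res$p_adj_BY >= res$p_raw))
  reg <- merge_regions(res)
  expect_gte(nrow(reg), 1L)
  covering <- reg[reg$chrom == tw$chrom & reg$snp_start <= tw$snp_start &
                    reg$snp_end >= tw$snp_end, ]
  expect_identical(nrow(covering), 1L)
  expect_identical(covering$best_observed, 0L)
})

test_that("trio scan refuses a population without genotyped dams", {
  sim <- simulate_population(sim_config(
    n_founders = 60, n_generations = 2, offspring_per_dam = 2,
    risk_hap_freq = 0.2, female_genotyping_rate = 0, seed = 4))
  expect_error(scan_deficit(sim$genotypes, sim$pedigree, "trio"), "pgp")
})

test_that("region merging separates disjoint signals and breaks ties deterministically", {
  row <- function(snp_start, snp_end, p_raw, expected = 20, bp0 = snp_start,
                  chrom = 1L) {
    data.frame(chrom = chrom, snp_start = as.integer(snp_start),
               snp_end = as.integer(snp_end),
               bp_start = as.integer(bp0 * 1000),
               bp_end = as.integer(snp_end * 1000),
               allele = "x", design = "trio", n_offspring = 100L,
               observed_hom = 0L, expected_hom = expected,
               deficiency_pct = 100L, allele_freq_pct = 5,
               deficit = TRUE, p_raw = p_raw, p_adj_BY = p_raw,
               stringsAsFactors = FALSE)
  }
  res <- rbind(row(1, 50, 1e-8), row(200, 249, 1e-6))
  reg <- merge_regions(res)
  expect_identical(nrow(reg), 2L)
  # overlapping chain merges into one region spanning the union
  res2 <- rbind(row(1, 50, 1e-6), row(10, 59, 1e-9), row(20, 69, 1e-7))
  reg2 <- merge_regions(res2)
  expect_identical(nrow(reg2), 1L)
  expect_identical(reg2$snp_start, 1L)
  expect_identical(reg2$snp_end, 69L)
  expect_equal(reg2$best_p_raw, 1e-9)
  # tie on p: larger expected wins, then leftmost bp
  res3 <- rbind(row(1, 50, 1e-6, expected = 15),
                row(2, 51, 1e-6, expected = 30),
                row(3, 52, 1e-6, expected = 30))
  reg3 <- merge_regions(res3)
  expect_equal(reg3$best_expected, 30)
  expect_identical(reg3$best_snp_start, 2L)
  # non-significant rows never form regions
  expect_identical(nrow(merge_regions(row(1, 50, 0.9))), 0L)
})
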