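#' Simulation configuration for a synthetic AI breeding population
#'
#' Bundles and validates the parameters of the gene-drop simulator. The
#' defaults describe a small dairy-cattle-like population bred by artificial
#' insemination: few heavily used sires per generation, all males genotyped,
#' females genotyped only partially, and one recessive risk haplotype
#' segregating at low frequency.
#'
#' @param n_founders Number of unrelated founder animals (half female).
#' @param n_generations Number of bred generations after the founders.
#' @param n_sires_per_gen Number of sires in service per generation; usage
#'   follows a geometric weight so a handful of bulls father most offspring.
#' @param offspring_per_dam Conceptuses per dam and generation.
#' @param n_snps Total number of biallelic SNPs across all chromosomes.
#' @param n_chromosomes Number of autosomes simulated.
#' @param map_length_cM_per_chr Genetic length of each simulated
#'   chromosome (segment) in centimorgan; physical length is taken as
#'   1 Mb per cM. The default emulates array-density segments: 100 SNPs
#'   over 2.5 cM gives 50-SNP windows of about 1.25 cM, the window scale
#'   at which missing-homozygosity scans operate on ~114k-SNP maps.
#' @param risk_hap_freq Target founder frequency of the risk haplotype.
#' @param penetrance Probability that a conceptus homozygous for the risk
#'   haplotype dies before entering the genotyped population
#'   (1 = fully embryonic lethal).
#' @param trait_h2 Narrow-sense heritability of the simulated polygenic trait.
#' @param hap_trait_effect Additive effect of one risk-allele copy on the
#'   trait, in trait standard deviations (0 for a purely recessive lethal).
#' @param female_genotyping_rate Fraction of females that are genotyped;
#'   males are always genotyped.
#' @param sire_usage_decay Geometric decay of sire usage weights; 1 gives
#'   uniform usage (approximate random mating), smaller values concentrate
#'   matings on the top bulls.
#' @param risk_window_size Number of consecutive SNPs spanned by the risk
#'   haplotype (matches the downstream scan window).
#' @param seed Integer seed; identical seed and configuration give
#'   bit-identical output.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_population()]
#' @export
sim_config <- function(n_founders = 200,
                       n_generations = 3,
                       n_sires_per_gen = 15,
                       offspring_per_dam = 3,
                       n_snps = 200,
                       n_chromosomes = 2,
                       map_length_cM_per_chr = 2.5,
                       risk_hap_freq = 0.05,
                       penetrance = 1,
                       trait_h2 = 0.3,
                       hap_trait_effect = 0,
                       female_genotyping_rate = 0.7,
                       sire_usage_decay = 0.85,
                       risk_window_size = 50,
                       seed = 1L) {
  cfg <- list(
    n_founders = as.integer(n_founders),
    n_generations = as.integer(n_generations),
    n_sires_per_gen = as.integer(n_sires_per_gen),
    offspring_per_dam = as.integer(offspring_per_dam),
    n_snps = as.integer(n_snps),
    n_chromosomes = as.integer(n_chromosomes),
    map_length_cM_per_chr = map_length_cM_per_chr,
    risk_hap_freq = risk_hap_freq,
    penetrance = penetrance,
    trait_h2 = trait_h2,
    hap_trait_effect = hap_trait_effect,
    female_genotyping_rate = female_genotyping_rate,
    sire_usage_decay = sire_usage_decay,
    risk_window_size = as.integer(risk_window_size),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(
    cfg$n_founders >= 4,
    cfg$n_generations >= 1,
    cfg$n_sires_per_gen >= 1,
    cfg$offspring_per_dam >= 1,
    cfg$n_chromosomes >= 1,
    cfg$map_length_cM_per_chr > 0,
    cfg$risk_hap_freq > 0, cfg$risk_hap_freq < 1,
    cfg$penetrance >= 0, cfg$penetrance <= 1,
    cfg$trait_h2 > 0, cfg$trait_h2 < 1,
    cfg$female_genotyping_rate >= 0, cfg$female_genotyping_rate <= 1,
    cfg$sire_usage_decay > 0, cfg$sire_usage_decay <= 1,
    cfg$risk_window_size >= 2
  )
  # the risk window must fit on the chromosome that carries it
  if (snps_per_chrom(cfg$n_snps, cfg$n_chromosomes)[1] < cfg$risk_window_size)
    stop("n_snps too small: the first chromosome has fewer SNPs than ",
         "risk_window_size (", cfg$risk_window_size, ")")
  invisible(cfg)
}

snps_per_chrom <- function(n_snps, n_chromosomes) {
  base <- n_snps %/% n_chromosomes
  extra <- n_snps %% n_chromosomes
  base + c(rep(1L, extra), rep(0L, n_chromosomes - extra))
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_founders, "founders,", x$n_generations,
      "generations,", x$n_snps, "SNPs on", x$n_chromosomes, "chromosome(s)\n")
  cat("  risk haplotype: freq", x$risk_hap_freq, "penetrance", x$penetrance,
      "window", x$risk_window_size, "SNPs\n")
  invisible(x)
}

# Expected number of at-risk matings implied by a configuration, used to
# reject configurations under which the downstream scan would be vacuous.
expected_carrier_matings <- function(cfg) {
  n_off <- 0
  n_fem <- cfg$n_founders / 2
  for (g in seq_len(cfg$n_generations)) {
    off_g <- n_fem * cfg$offspring_per_dam
    n_off <- n_off + off_g
    n_fem <- off_g / 2
  }
  q <- cfg$risk_hap_freq
  het <- 2 * q * (1 - q)
  n_off * het^2
}
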