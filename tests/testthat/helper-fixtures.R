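# Shared simulation scenarios and independent oracles.

# Small structural fixture, memoized across test files.
fx_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_population(sim_config(
        n_founders = 100, n_generations = 2, offspring_per_dam = 3,
        risk_hap_freq = 0.15, female_genotyping_rate = 0.8, seed = 42))
    cache
  }
})

# Larger fully-genotyped fixture for GRM / mixed-model tests.
fx_assoc_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_population(sim_config(
        n_founders = 200, n_generations = 2, offspring_per_dam = 3,
        penetrance = 0, risk_hap_freq = 0.1,
        female_genotyping_rate = 1, seed = 7))
    cache
  }
})

# Fully lethal scenario sized so the truth window carries >= 20 expected
# homozygous offspring in essentially every replicate: moderately broad
# sire panel to keep the carrier-mating mass stable, high female
# genotyping so trio and pgp sets are both large.
power_cfg <- function(seed) {
  sim_config(n_founders = 400, offspring_per_dam = 3, risk_hap_freq = 0.25,
             n_sires_per_gen = 40, sire_usage_decay = 0.95,
             female_genotyping_rate = 0.9, seed = seed)
}

# No lethality: every tested window allele is a true null.
null_cfg <- function(seed) {
  sim_config(n_founders = 120, offspring_per_dam = 4, penetrance = 0,
             risk_hap_freq = 0.1, female_genotyping_rate = 0.9,
             seed = seed)
}

# Exhaustive-enumeration oracle for the Poisson-binomial lower tail:
# sums P(outcome) over all 2^n carrier/non-carrier outcome vectors.
pb_enum_tail <- function(pi, observed) {
  n <- length(pi)
  total <- 0
  for (k in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(k)[1:n])
    if (sum(bits) <= observed)
      total <- total + prod(ifelse(bits == 1L, pi, 1 - pi))
  }
  total
}

# Hand-built candidate fixture: six variants violating exactly one
# array-design rule each, plus one variant passing all rules.
# Animals: 6 Holstein + 2 OtherBreed; region chr1:[1e6, 3e6].
filter_fixture <- function() {
  ids <- c(paste0("H", 1:6), paste0("B", 1:2))
  breed <- stats::setNames(c(rep("Holstein", 6), rep("OtherBreed", 2)), ids)
  dos <- function(...) as.integer(c(...))
  dosage <- rbind(
    pass      = dos(0, 1, 0, 0, 0, 0, 0, 0),  # all rules satisfied
    region    = dos(0, 1, 0, 0, 0, 0, 0, 0),  # outside the region
    hardfail  = dos(0, 1, 0, 0, 0, 0, 0, 0),  # fails hard filtering
    nobreed   = dos(0, 0, 0, 0, 0, 0, 1, 1),  # no Holstein carrier
    toomany   = dos(1, 1, 1, 1, 1, 1, 1, 0),  # carrier fraction 7/8
    twohom    = dos(2, 2, 0, 0, 0, 0, 0, 0),  # two homozygous carriers
    noncoding = dos(0, 1, 0, 0, 0, 0, 0, 0)   # non protein-changing
  )
  variants <- data.frame(
    chrom = 1L,
    pos = c(2e6, 5e6, 2.1e6, 2.2e6, 2.3e6, 2.4e6, 2.5e6),
    ref = "A", alt = "T",
    consequence = c("missense", "missense", "missense", "missense",
                    "missense", "missense", "other"),
    filter_pass = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
  colnames(dosage) <- ids
  candidate_set(variants, dosage, breed)
}

fixture_region <- function() list(chrom = 1L, bp_start = 1e6, bp_end = 3e6)
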