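#' Simulate an AI breeding population with an embedded recessive haplotype
#'
#' Gene-drop simulation of a dairy-type breeding population. Founders are
#' unrelated with per-SNP allele frequencies drawn from Uniform(0.05, 0.95).
#' One contiguous risk haplotype (a fixed allele pattern across
#' `risk_window_size` SNPs on the first chromosome) is seeded into founder
#' haplotypes at frequency `risk_hap_freq`. Each subsequent generation mates
#' the previous generation's females to a small panel of sires whose usage
#' follows a geometric weight, emulating artificial-insemination overuse.
#' Meiosis uses Haldane's model (Poisson crossover count over the map
#' length, uniform placement, no interference). Conceptuses homozygous for
#' the risk haplotype are removed silently with probability `penetrance`
#' before they can be genotyped, so lethality is observable downstream only
#' as missing homozygosity.
#'
#' @param config A [sim_config()] object.
#'
#' @return A list of class `lethal_sim` with elements
#'   \describe{
#'     \item{pedigree}{Data frame: `animal_id`, `sire_id`, `dam_id`,
#'       `mgs_id` (maternal grandsire, resolved through the dam), `sex`
#'       ("M"/"F"), `birth_year`, `generation`, `genotyped`.}
#'     \item{genotypes}{A [phased_geno()] over the genotyped animals.}
#'     \item{truth}{List: `window` (chrom, 1-based inclusive SNP column
#'       indices and bp span of the risk window), `pattern` (risk allele
#'       string), `copies` (named integer vector, risk-allele copies of
#'       every animal, dead conceptuses excluded), `founder_freq`
#'       (realized founder frequency), `config`.}
#'   }
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ecm <- expected_carrier_matings(config)
  if (ecm < 1)
    stop("configuration yields ", signif(ecm, 3), " expected carrier x ",
         "carrier matings (< 1): the deficit scan would be vacuous. ",
         "Increase population size or risk_hap_freq.")
  set.seed(config$seed)

  m_chr <- snps_per_chrom(config$n_snps, config$n_chromosomes)
  map <- build_map(m_chr, config$map_length_cM_per_chr)
  p <- stats::runif(config$n_snps, 0.05, 0.95)

  nf <- config$n_founders
  hap <- matrix(stats::rbinom(2L * nf * config$n_snps, 1L,
                              rep(p, each = 2L * nf)),
                nrow = 2L * nf)

  # seed the risk haplotype on chromosome 1
  w <- config$risk_window_size
  start <- (m_chr[1] - w) %/% 2L + 1L
  widx <- start:(start + w - 1L)
  pattern <- stats::rbinom(w, 1L, p[widx])
  n_seed <- max(1L, round(2L * nf * config$risk_hap_freq))
  if (n_seed > nf)
    stop("risk_hap_freq > 0.5 not supported: founders carry at most one ",
         "risk haplotype each (a lethal does not survive in homozygotes)")
  # one risk haplotype per carrier founder: no homozygous founders
  carrier_f <- sample.int(nf, n_seed)
  seeded <- 2L * carrier_f - stats::rbinom(n_seed, 1L, 0.5)
  hap[seeded, widx] <- matrix(pattern, n_seed, w, byrow = TRUE)

  ped <- data.frame(
    animal_id = sprintf("F%04d", seq_len(nf)),
    sire_id = NA_character_, dam_id = NA_character_,
    sex = rep(c("M", "F"), length.out = nf),
    birth_year = 2000L, generation = 0L,
    stringsAsFactors = FALSE
  )

  chrom_cols <- split(seq_len(config$n_snps), map$chrom)
  cm <- map$cM
  is_risk_hom <- function(h1, h2)
    all(h1[widx] == pattern) && all(h2[widx] == pattern)

  counter <- nf
  for (g in seq_len(config$n_generations)) {
    prev <- which(ped$generation == g - 1L)
    males <- prev[ped$sex[prev] == "M"]
    dams <- prev[ped$sex[prev] == "F"]
    if (length(males) < 1L || length(dams) < 1L)
      stop("generation ", g, " has no available sires or dams")
    sires <- males[sample.int(length(males),
                              min(config$n_sires_per_gen, length(males)))]
    wts <- config$sire_usage_decay^(seq_along(sires) - 1)
    wts <- wts / sum(wts)

    gen_rows <- vector("list", length(dams) * config$offspring_per_dam)
    gen_haps <- vector("list", length(gen_rows))
    kept <- 0L
    for (d in dams) {
      sire_draw <- sires[sample.int(length(sires), config$offspring_per_dam,
                                    replace = TRUE, prob = wts)]
      for (s in sire_draw) {
        pat <- meiosis(hap[2L * s - 1L, ], hap[2L * s, ], chrom_cols, cm)
        mat <- meiosis(hap[2L * d - 1L, ], hap[2L * d, ], chrom_cols, cm)
        if (is_risk_hom(pat, mat) &&
            stats::runif(1) < config$penetrance) next  # dies unrecorded
        kept <- kept + 1L
        counter <- counter + 1L
        gen_rows[[kept]] <- data.frame(
          animal_id = sprintf("A%05d", counter),
          sire_id = ped$animal_id[s], dam_id = ped$animal_id[d],
          sex = if (stats::runif(1) < 0.5) "M" else "F",
          birth_year = 2000L + g, generation = g,
          stringsAsFactors = FALSE
        )
        gen_haps[[kept]] <- rbind(pat, mat)
      }
    }
    if (kept == 0L) stop("generation ", g, " produced no live offspring")
    ped <- rbind(ped, do.call(rbind, gen_rows[seq_len(kept)]))
    hap <- rbind(hap, do.call(rbind, gen_haps[seq_len(kept)]))
  }

  ped$mgs_id <- ped$sire_id[match(ped$dam_id, ped$animal_id)]
  ped$genotyped <- ped$sex == "M" |
    stats::runif(nrow(ped)) < config$female_genotyping_rate
  ped <- ped[, c("animal_id", "sire_id", "dam_id", "mgs_id", "sex",
                 "birth_year", "generation", "genotyped")]

  copies <- hap_pattern_copies(hap, widx, pattern)
  names(copies) <- ped$animal_id

  gidx <- which(ped$genotyped)
  geno <- phased_geno(hap[as.vector(hap_rows(gidx)), , drop = FALSE],
                      ped$animal_id[gidx], map, phase_known = TRUE)

  truth <- list(
    window = list(chrom = map$chrom[widx[1]], snp_start = widx[1],
                  snp_end = widx[length(widx)],
                  bp_start = map$pos_bp[widx[1]],
                  bp_end = map$pos_bp[widx[length(widx)]]),
    pattern = paste(pattern, collapse = ""),
    copies = copies,
    founder_freq = n_seed / (2 * nf),
    config = config
  )
  structure(list(pedigree = ped, genotypes = geno, truth = truth),
            class = "lethal_sim")
}

#' @export
print.lethal_sim <- function(x, ...) {
  cat("lethal_sim:", nrow(x$pedigree), "animals (",
      sum(x$pedigree$genotyped), "genotyped ),",
      nrow(x$genotypes$map), "SNPs\n")
  cat("  risk window chr", x$truth$window$chrom, "SNP",
      x$truth$window$snp_start, "-", x$truth$window$snp_end,
      "; carriers:", sum(x$truth$copies >= 1L),
      "; live homozygotes:", sum(x$truth$copies == 2L), "\n")
  invisible(x)
}

build_map <- function(m_chr, len_cM) {
  len_bp <- round(len_cM * 1e6)  # 1 cM per Mb
  do.call(rbind, lapply(seq_along(m_chr), function(ch) {
    pos <- sort(sample.int(len_bp, m_chr[ch]))
    data.frame(snp_id = sprintf("chr%d_%d", ch, pos), chrom = ch,
               pos_bp = pos, cM = pos / 1e6, stringsAsFactors = FALSE)
  }))
}

# One gamete from a pair of parental haplotypes: Haldane model, crossover
# count Poisson in chromosome map length, uniform placement, random start
# strand, independent across chromosomes.
meiosis <- function(h1, h2, chrom_cols, cm) {
  gam <- h1
  for (cols in chrom_cols) {
    len <- cm[cols[length(cols)]] - cm[cols[1]]
    nco <- stats::rpois(1L, len / 100)
    strand <- stats::rbinom(1L, 1L, 0.5)
    if (nco == 0L) {
      if (strand == 1L) gam[cols] <- h2[cols]
    } else {
      xo <- sort(stats::runif(nco, cm[cols[1]], cm[cols[length(cols)]]))
      seg <- (findInterval(cm[cols], xo) + strand) %% 2L
      gam[cols] <- ifelse(seg == 0L, h1[cols], h2[cols])
    }
  }
  gam
}

# Risk-allele copies per animal from a stacked 2-rows-per-animal matrix.
hap_pattern_copies <- function(hap, widx, pattern) {
  seg <- hap[, widx, drop = FALSE]
  match_pat <- rowSums(seg == matrix(pattern, nrow(seg), length(pattern),
                                     byrow = TRUE)) == length(pattern)
  odd <- seq(1L, nrow(hap), by = 2L)
  as.integer(match_pat[odd]) + as.integer(match_pat[odd + 1L])
}
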