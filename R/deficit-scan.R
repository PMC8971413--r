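#' Per-offspring homozygosity probability under the trio or pgp design
#'
#' Probability that one offspring is homozygous for a target haplotype
#' allele, given the diplotypes of its genotyped ancestors. With
#' transmission probability t(0) = 0, t(1) = 1/2, t(2) = 1 for an ancestor
#' carrying 0/1/2 copies:
#' \describe{
#'   \item{trio}{both parents genotyped; pi = t(sire) * t(dam).}
#'   \item{pgp}{sire and maternal grandsire genotyped; the dam's
#'     untracked (granddam-derived) haplotype is modelled at the population
#'     allele frequency `q`: pi = t(sire) * (t(mgs)/2 + q/2).}
#' }
#'
#' @param design `"trio"` or `"pgp"`.
#' @param sire_copies Integer vector, copies carried by the sire (0/1/2).
#' @param dam_or_mgs_copies Copies carried by the dam (trio) or maternal
#'   grandsire (pgp).
#' @param q Population frequency of the target allele (used by pgp only).
#'
#' @return Numeric vector of probabilities in [0, 1].
#' @export
per_offspring_prob <- function(design = c("trio", "pgp"), sire_copies,
                               dam_or_mgs_copies, q = 0) {
  design <- match.arg(design)
  stopifnot(all(sire_copies %in% 0:2), all(dam_or_mgs_copies %in% 0:2),
            q >= 0, q < 1)
  t <- c(0, 0.5, 1)
  ts <- t[sire_copies + 1L]
  if (design == "trio") {
    ts * t[dam_or_mgs_copies + 1L]
  } else {
    ts * (0.5 * t[dam_or_mgs_copies + 1L] + 0.5 * q)
  }
}

#' Expected number of homozygous offspring
#'
#' Sum of per-offspring homozygosity probabilities over a set of mating
#' records (the "expected" column of a missing-homozygosity report).
#'
#' @param pi Numeric vector of per-offspring probabilities in [0, 1].
#' @return The sum of `pi`; 0 with a warning for an empty input.
#' @export
expected_homozygotes <- function(pi) {
  if (length(pi) == 0L) {
    warning("no mating records; expected homozygotes is 0", call. = FALSE)
    return(0)
  }
  if (any(pi < 0 | pi > 1)) stop("probabilities must be in [0, 1]")
  sum(pi)
}

#' Exact one-sided homozygosity-deficit test
#'
#' Tests whether the observed number of homozygous offspring is lower than
#' expected given the realized matings. The number of homozygotes is a sum
#' of independent Bernoulli(pi_i) indicators, i.e. Poisson-binomial; the
#' lower-tail probability P(X <= observed) is evaluated exactly by
#' dynamic-programming convolution (truncated at `observed`, so the cost is
#' O(n * observed)). For homogeneous pi this reduces to the binomial lower
#' tail.
#'
#' @param pi Per-offspring homozygosity probabilities.
#' @param observed Observed number of homozygous offspring.
#' @return The exact one-sided p-value P(X <= observed).
#' @export
exact_deficit_test <- function(pi, observed) {
  if (any(pi < 0 | pi > 1)) stop("probabilities must be in [0, 1]")
  observed <- as.integer(observed)
  if (observed < 0) stop("observed must be >= 0")
  if (observed > length(pi))
    stop("observed exceeds the number of offspring")
  pi <- pi[pi > 0]
  if (observed >= length(pi)) return(1)
  dp <- c(1, numeric(observed))  # dp[k+1] = P(X = k), truncated
  for (p in pi) {
    dp <- dp * (1 - p) + c(0, dp[-length(dp)]) * p
  }
  min(1, sum(dp))
}

#' Homozygosity deficiency percentage
#'
#' The reporting convention for a homozygosity deficit:
#' round(100 * (1 - observed / expected)), i.e. the rounded percentage of
#' expected homozygotes that were not observed (100 for a fully lethal
#' haplotype, 0 when observed equals expected).
#'
#' @param observed Observed homozygote count.
#' @param expected Expected homozygote count (> 0).
#' @return Integer percentage.
#' @export
deficiency_pct <- function(observed, expected) {
  if (any(expected <= 0)) stop("expected must be > 0")
  as.integer(round(100 * (1 - observed / expected)))
}

#' Benjamini-Yekutieli false discovery rate adjustment
#'
#' Step-up FDR adjustment valid under arbitrary dependence of the tests
#' (overlapping sliding windows are strongly dependent), as implemented by
#' [stats::p.adjust()] with `method = "BY"`.
#'
#' @param p Numeric vector of raw p-values in [0, 1].
#' @return Adjusted p-values, elementwise >= `p`, capped at 1.
#' @export
by_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  stats::p.adjust(p, method = "BY")
}

# Offspring records usable under a design: indices into the genotype matrix
# for offspring/sire/dam-or-mgs triples where all required animals are
# genotyped. Each animal contributes as offspring exactly once.
design_records <- function(geno, pedigree, design) {
  gi <- match(pedigree$animal_id, geno$animal_ids)     # NA if not genotyped
  off_gi <- gi
  sire_gi <- gi[match(pedigree$sire_id, pedigree$animal_id)]
  if (design == "trio") {
    anc_gi <- gi[match(pedigree$dam_id, pedigree$animal_id)]
  } else {
    anc_gi <- gi[match(pedigree$mgs_id, pedigree$animal_id)]
  }
  keep <- !is.na(off_gi) & !is.na(sire_gi) & !is.na(anc_gi)
  list(off = off_gi[keep], sire = sire_gi[keep], anc = anc_gi[keep])
}

#' Scan all sliding windows for missing homozygosity
#'
#' For every window haplotype allele with frequency at least `maf_floor`,
#' computes observed and expected homozygous offspring under the chosen
#' design, tests the deficit exactly ([exact_deficit_test()]), and adjusts
#' across all tested alleles by Benjamini-Yekutieli. Alleles whose expected
#' count falls below `min_expected` are not tested (a deficit among a
#' handful of expected homozygotes is uninformative). All tested alleles
#' are returned, flagged by `deficit`; downstream reporting and region
#' merging use the deficit rows only, but the full set is needed for an
#' unbiased view of the test's behaviour.
#'
#' @param geno A [phased_geno()] object (the genotyped population).
#' @param pedigree Pedigree data frame with `animal_id`, `sire_id`,
#'   `dam_id`, `mgs_id` columns.
#' @param design `"trio"` (sire and dam genotyped) or `"pgp"` (sire and
#'   maternal grandsire genotyped).
#' @param window_size,step Sliding-window geometry (default 50 SNPs, step 1).
#' @param min_expected Minimum expected homozygote count for an allele to
#'   be tested (default 10).
#' @param maf_floor Minimum allele frequency for an allele to be
#'   considered (default 0.01).
#' @param pgp_use_popfreq If `TRUE` (default) the pgp design models the
#'   dam's untracked haplotype at the population allele frequency; `FALSE`
#'   sets that term to zero (sensitivity analysis).
#'
#' @return Data frame of class `deficit_scan`, sorted by adjusted then raw
#'   p-value: window coordinates, `allele`, `design`, `n_offspring`,
#'   `observed_hom`, `expected_hom`, `deficiency_pct`
#'   (= round(100 (1 - observed/expected))), `allele_freq_pct`, `deficit`,
#'   `p_raw`, `p_adj_BY`.
#' @export
scan_deficit <- function(geno, pedigree, design = c("trio", "pgp"),
                         window_size = 50, step = 1, min_expected = 10,
                         maf_floor = 0.01, pgp_use_popfreq = TRUE) {
  design <- match.arg(design)
  rec <- design_records(geno, pedigree, design)
  if (length(rec$off) == 0L) {
    if (design == "trio")
      stop("no offspring with genotyped sire and dam; with ungenotyped ",
           "dams use design = 'pgp'")
    stop("no offspring with genotyped sire and maternal grandsire")
  }
  windows <- enumerate_windows(geno, window_size, step)
  n_hap <- 2L * n_animals(geno)
  t <- c(0, 0.5, 1)

  rows <- vector("list", nrow(windows))
  for (wi in seq_len(nrow(windows))) {
    w <- windows[wi, ]
    s <- window_hap_strings(geno, w$snp_start, w$snp_end)
    tab <- table(s)
    freq <- as.numeric(tab) / n_hap
    alleles <- names(tab)[freq >= maf_floor]
    freqs <- freq[freq >= maf_floor]
    if (length(alleles) == 0L) next
    odd <- seq(1L, n_hap, by = 2L)
    sA <- s[odd]; sB <- s[odd + 1L]
    res <- vector("list", length(alleles))
    for (ai in seq_along(alleles)) {
      a <- alleles[ai]
      copies <- (sA == a) + (sB == a)
      q <- freqs[ai]
      ts <- t[copies[rec$sire] + 1L]
      pi <- if (design == "trio") {
        ts * t[copies[rec$anc] + 1L]
      } else {
        ts * (0.5 * t[copies[rec$anc] + 1L] +
                if (pgp_use_popfreq) 0.5 * q else 0)
      }
      expected <- sum(pi)
      if (expected < min_expected) next
      observed <- sum(copies[rec$off] == 2L)
      res[[ai]] <- data.frame(
        chrom = w$chrom, snp_start = w$snp_start, snp_end = w$snp_end,
        bp_start = w$bp_start, bp_end = w$bp_end,
        allele = a, design = design, n_offspring = length(pi),
        observed_hom = observed, expected_hom = expected,
        deficiency_pct = deficiency_pct(observed, expected),
        allele_freq_pct = 100 * q,
        deficit = observed < expected,
        p_raw = exact_deficit_test(pi, observed),
        stringsAsFactors = FALSE
      )
    }
    res <- res[!vapply(res, is.null, logical(1))]
    if (length(res)) rows[[wi]] <- do.call(rbind, res)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    warning("no window allele reached min_expected = ", min_expected,
            "; nothing tested", call. = FALSE)
    out <- data.frame()
    class(out) <- c("deficit_scan", "data.frame")
    return(out)
  }
  out <- do.call(rbind, rows)
  out$p_adj_BY <- by_adjust(out$p_raw)
  out <- out[order(out$p_adj_BY, out$p_raw, -out$expected_hom,
                   out$bp_start), ]
  rownames(out) <- NULL
  class(out) <- c("deficit_scan", "data.frame")
  out
}

#' Merge significant deficit windows into haplotype regions
#'
#' Groups significant deficit windows (BY-adjusted p below `alpha`,
#' observed below expected) that overlap by at least one SNP on the same
#' chromosome into named regions, and designates each region's most
#' significant window (lowest raw p; ties broken by larger expected count,
#' then leftmost bp start).
#'
#' @param results A `deficit_scan` result (one design, one scan).
#' @param alpha Significance level on BY-adjusted p-values (default 0.05).
#' @param prefix Region name prefix (default "HR", haplotype region).
#'
#' @return Data frame: `name`, `chrom`, `bp_start`, `bp_end`, `snp_start`,
#'   `snp_end`, `supporting_windows`, `designs`, plus the best window's
#'   allele, observed/expected counts, deficiency and p-values
#'   (`best_` columns).
#' @export
merge_regions <- function(results, alpha = 0.05, prefix = "HR") {
  sig <- results[results$deficit & results$p_adj_BY < alpha, , drop = FALSE]
  empty <- data.frame(
    name = character(), chrom = integer(), bp_start = integer(),
    bp_end = integer(), snp_start = integer(), snp_end = integer(),
    supporting_windows = integer(), designs = character(),
    best_snp_start = integer(), best_snp_end = integer(),
    best_allele = character(), best_observed = integer(),
    best_expected = numeric(), best_deficiency_pct = integer(),
    best_allele_freq_pct = numeric(), best_p_raw = numeric(),
    best_p_adj_BY = numeric(), stringsAsFactors = FALSE
  )
  if (nrow(sig) == 0L) return(empty)
  regions <- list()
  for (ch in sort(unique(sig$chrom))) {
    sc <- sig[sig$chrom == ch, , drop = FALSE]
    sc <- sc[order(sc$snp_start, sc$snp_end), , drop = FALSE]
    grp <- integer(nrow(sc)); grp[1] <- 1L
    hi <- sc$snp_end[1]
    if (nrow(sc) > 1) for (i in 2:nrow(sc)) {
      if (sc$snp_start[i] <= hi) grp[i] <- grp[i - 1L]
      else grp[i] <- grp[i - 1L] + 1L
      hi <- max(hi, sc$snp_end[i])
    }
    for (g in unique(grp)) {
      m <- sc[grp == g, , drop = FALSE]
      best <- m[order(m$p_raw, -m$expected_hom, m$bp_start), ][1, ]
      regions[[length(regions) + 1L]] <- data.frame(
        chrom = ch, bp_start = min(m$bp_start), bp_end = max(m$bp_end),
        snp_start = min(m$snp_start), snp_end = max(m$snp_end),
        supporting_windows = nrow(m),
        designs = paste(sort(unique(m$design)), collapse = "/"),
        best_snp_start = best$snp_start, best_snp_end = best$snp_end,
        best_allele = best$allele, best_observed = best$observed_hom,
        best_expected = best$expected_hom,
        best_deficiency_pct = best$deficiency_pct,
        best_allele_freq_pct = best$allele_freq_pct,
        best_p_raw = best$p_raw, best_p_adj_BY = best$p_adj_BY,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, regions)
  out <- out[order(out$chrom, out$bp_start), , drop = FALSE]
  out <- cbind(name = sprintf("%s-%02d", prefix, seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
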