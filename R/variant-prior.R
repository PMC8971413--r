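#' Protein-changing consequence classes
#'
#' The consequence vocabulary used when restricting candidate causal
#' variants to protein-changing SNVs and short indels.
#' @return Character vector of consequence classes.
#' @export
protein_changing_consequences <- function() {
  c("missense", "nonsense", "frameshift", "inframe_deletion",
    "inframe_insertion", "splice", "start_lost")
}

#' Candidate variant set
#'
#' Container for candidate causal variants inside a region of interest:
#' a variant table plus a per-animal alt-allele dosage matrix (missing
#' genotypes allowed) and per-animal breed labels.
#'
#' @param variants Data frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `consequence`, `filter_pass` (logical, GATK-style hard-filter status
#'   from the VCF FILTER field).
#' @param dosage Integer matrix variants x animals with values 0/1/2 or
#'   `NA` (missing call).
#' @param breed Named character vector of breed labels, one per animal
#'   column of `dosage`.
#' @return An object of class `candidate_set`.
#' @export
candidate_set <- function(variants, dosage, breed) {
  dosage <- as.matrix(dosage)
  stopifnot(
    nrow(variants) == nrow(dosage),
    all(c("chrom", "pos", "ref", "alt", "consequence",
          "filter_pass") %in% names(variants)),
    ncol(dosage) == length(breed),
    all(dosage %in% c(0L, 1L, 2L) | is.na(dosage))
  )
  if (is.null(names(breed))) names(breed) <- colnames(dosage)
  structure(list(variants = as.data.frame(variants), dosage = dosage,
                 breed = breed),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat("candidate_set:", nrow(x$variants), "variants x",
      ncol(x$dosage), "animals (breeds:",
      paste(unique(x$breed), collapse = ", "), ")\n")
  invisible(x)
}

# Per-variant carrier statistics over non-missing genotypes.
variant_stats <- function(cand) {
  d <- cand$dosage
  n_nm <- rowSums(!is.na(d))
  n_car <- rowSums(d >= 1L, na.rm = TRUE)
  n_hom <- rowSums(d == 2L, na.rm = TRUE)
  data.frame(n_non_missing = n_nm, n_carriers = n_car, n_hom_alt = n_hom,
             carrier_fraction = ifelse(n_nm > 0, n_car / n_nm, NA_real_))
}

#' Expand a haplotype region by flanking sequence
#'
#' @param region One row of [merge_regions()] output (or any list with
#'   `chrom`, `bp_start`, `bp_end`).
#' @param flank_bp Flank added on each side (default 2 Mb).
#' @param chrom_length Optional chromosome length to clip the right end.
#' @return List `chrom`, `bp_start`, `bp_end` (left end clipped at 1).
#' @export
expand_region <- function(region, flank_bp = 2e6, chrom_length = NULL) {
  start <- max(1, region$bp_start - flank_bp)
  end <- region$bp_end + flank_bp
  if (!is.null(chrom_length)) end <- min(end, chrom_length)
  list(chrom = region$chrom, bp_start = start, bp_end = end)
}

#' Filter candidate variants by array-design rules
#'
#' Keeps a variant iff it (i) passes hard filtering, (ii) lies inside the
#' expanded region, (iii) has at least one carrier of the target breed,
#' (iv) has carrier fraction at most `max_carrier_fraction` (inclusive)
#' over non-missing genotypes, (v) has at most `max_hom` homozygous-alt
#' animals, and (vi) when `require_consequence` is non-empty, carries one
#' of those consequence classes. A carrier is any animal with at least one
#' alt allele; missing genotypes are excluded from denominators.
#'
#' @param cand A [candidate_set()].
#' @param region Expanded region (list with `chrom`, `bp_start`, `bp_end`).
#' @param target_breed Breed that must contribute at least one carrier.
#' @param max_carrier_fraction Inclusive upper bound (default 0.75).
#' @param max_hom Maximum homozygous-alt animals allowed (default 1).
#' @param require_consequence Consequence classes to require; empty vector
#'   disables the rule (default [protein_changing_consequences()]).
#' @return The filtered [candidate_set()].
#' @export
candidate_filter <- function(cand, region, target_breed = "Holstein",
                             max_carrier_fraction = 0.75, max_hom = 1,
                             require_consequence =
                               protein_changing_consequences()) {
  stopifnot(inherits(cand, "candidate_set"))
  if (!target_breed %in% cand$breed)
    stop("unknown breed label '", target_breed, "'; labels seen: ",
         paste(sort(unique(cand$breed)), collapse = ", "))
  st <- variant_stats(cand)
  v <- cand$variants
  in_region <- v$chrom == region$chrom &
    v$pos >= region$bp_start & v$pos <= region$bp_end
  breed_cols <- which(cand$breed == target_breed)
  breed_carrier <- rowSums(cand$dosage[, breed_cols, drop = FALSE] >= 1L,
                           na.rm = TRUE) >= 1L
  keep <- v$filter_pass & in_region & breed_carrier &
    !is.na(st$carrier_fraction) &
    st$carrier_fraction <= max_carrier_fraction &
    st$n_hom_alt <= max_hom
  if (length(require_consequence))
    keep <- keep & v$consequence %in% require_consequence
  candidate_set(v[keep, , drop = FALSE],
                cand$dosage[keep, , drop = FALSE], cand$breed)
}

#' Squared-correlation linkage disequilibrium between two dosage vectors
#'
#' r2 as the squared Pearson correlation over pairwise-complete animals;
#' used both between variant genotypes and between a variant and a
#' haplotype diplotype (both coded 0/1/2).
#'
#' @param dosage_a,dosage_b Numeric dosage vectors of equal length,
#'   `NA` allowed.
#' @return r2 in [0, 1], or `NA` with a warning when fewer than two
#'   complete pairs remain or either vector is constant.
#' @export
ld_r2 <- function(dosage_a, dosage_b) {
  stopifnot(length(dosage_a) == length(dosage_b))
  ok <- !is.na(dosage_a) & !is.na(dosage_b)
  a <- dosage_a[ok]; b <- dosage_b[ok]
  if (length(a) < 2L) {
    warning("fewer than 2 complete pairs; r2 undefined", call. = FALSE)
    return(NA_real_)
  }
  if (stats::var(a) == 0 || stats::var(b) == 0) {
    warning("constant dosage vector; r2 undefined", call. = FALSE)
    return(NA_real_)
  }
  stats::cor(a, b)^2
}

#' Hardy-Weinberg equilibrium chi-square test for one variant
#'
#' One-degree-of-freedom chi-square of the observed genotype counts
#' against Hardy-Weinberg expectations at the sample allele frequency.
#' A monomorphic sample gives chi-square 0 (p = 1).
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (reference homozygote,
#'   heterozygote, alternate homozygote).
#' @return List `chi2`, `p`.
#' @export
hwe_chisq <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n == 0) stop("no genotyped animals")
  p <- (2 * n_AA + n_Aa) / (2 * n)
  q <- 1 - p
  if (p == 0 || q == 0) return(list(chi2 = 0, p = 1))
  e <- n * c(p^2, 2 * p * q, q^2)
  chi2 <- sum((c(n_AA, n_Aa, n_aa) - e)^2 / e)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Rank candidate variants by linkage with a haplotype
#'
#' Computes r2 between every candidate's dosage and the haplotype
#' diplotype (risk-allele copies), attaches a single-variant HWE
#' chi-square p-value, and ranks by r2 descending with ties broken by
#' smaller carrier fraction, then position.
#'
#' @param cand A filtered [candidate_set()].
#' @param diplotypes Data frame with `animal_id` and `copies` (e.g. from
#'   [assign_diplotypes()]); matched to the candidate animals by id.
#' @return Data frame: `rank`, `chrom`, `pos`, `ref`, `alt`,
#'   `consequence`, `carrier_fraction`, `n_hom_alt`, `r2_to_haplotype`,
#'   `hwe_chi2`, `hwe_p`. Variants with undefined r2 are dropped; an
#'   empty result triggers a warning.
#' @export
rank_candidates <- function(cand, diplotypes) {
  stopifnot(inherits(cand, "candidate_set"))
  if (nrow(cand$variants) == 0L) {
    warning("no candidate variants to rank", call. = FALSE)
    return(data.frame())
  }
  ids <- colnames(cand$dosage)
  hcop <- diplotypes$copies[match(ids, diplotypes$animal_id)]
  st <- variant_stats(cand)
  n_var <- nrow(cand$variants)
  r2 <- numeric(n_var); hw_chi <- numeric(n_var); hw_p <- numeric(n_var)
  for (i in seq_len(n_var)) {
    d <- cand$dosage[i, ]
    r2[i] <- suppressWarnings(ld_r2(d, hcop))
    counts <- c(sum(d == 0L, na.rm = TRUE), sum(d == 1L, na.rm = TRUE),
                sum(d == 2L, na.rm = TRUE))
    hw <- hwe_chisq(counts[1], counts[2], counts[3])
    hw_chi[i] <- hw$chi2; hw_p[i] <- hw$p
  }
  out <- cbind(cand$variants[, c("chrom", "pos", "ref", "alt",
                                 "consequence")],
               carrier_fraction = st$carrier_fraction,
               n_hom_alt = st$n_hom_alt,
               r2_to_haplotype = r2, hwe_chi2 = hw_chi, hwe_p = hw_p)
  out <- out[!is.na(out$r2_to_haplotype), , drop = FALSE]
  if (nrow(out) == 0L) {
    warning("no candidate with defined r2", call. = FALSE)
    return(out)
  }
  out <- out[order(-out$r2_to_haplotype, out$carrier_fraction, out$pos), ,
             drop = FALSE]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Simulate candidate variants around a simulated risk haplotype
#'
#' Builds a synthetic candidate-variant set for validating the
#' prioritization stage: one causal variant whose alt allele resides on
#' every copy of the risk haplotype (dosage equal to the risk diplotype),
#' plus decoy variants whose genotypes are taken from randomly chosen SNPs
#' near the region. All variants pass hard filtering, carry
#' protein-changing consequence annotations, and the animals are labelled
#' with the target breed.
#'
#' @param sim A `lethal_sim` object from [simulate_population()].
#' @param n_decoys Number of decoy variants (default 20).
#' @param breed Breed label for all animals (default "Holstein").
#' @param seed Integer seed.
#' @return List: `candidates` (a [candidate_set()]) and `causal_pos`
#'   (bp position of the causal variant).
#' @export
simulate_candidate_variants <- function(sim, n_decoys = 20,
                                        breed = "Holstein", seed = 1L) {
  set.seed(as.integer(seed))
  geno <- sim$genotypes
  w <- sim$truth$window
  ids <- geno$animal_ids
  causal_dosage <- as.integer(sim$truth$copies[ids])
  causal_pos <- round((w$bp_start + w$bp_end) / 2)

  on_chr <- which(geno$map$chrom == w$chrom)
  d_all <- alt_dosage(geno)
  # two decoy kinds: raw SNP genotypes (mostly common, realistic filter
  # fodder) and rare window-haplotype indicator variants that survive the
  # carrier-fraction rule and compete on LD
  n_snp_decoy <- n_decoys %/% 2L
  cols <- on_chr[sample.int(length(on_chr),
                            min(n_snp_decoy, length(on_chr)))]
  n_hap_decoy <- n_decoys - length(cols)
  wins <- enumerate_windows(geno, w$snp_end - w$snp_start + 1L, step = 1)
  wins <- wins[wins$chrom == w$chrom, , drop = FALSE]
  hap_decoys <- list(); hap_pos <- integer()
  attempts <- 0L
  while (length(hap_decoys) < n_hap_decoy &&
         (attempts <- attempts + 1L) <= 50L * n_hap_decoy) {
    wr <- wins[sample.int(nrow(wins), 1L), ]
    al <- window_alleles(geno, wr)
    al <- al[al$frequency >= 0.01 & al$frequency <= 0.3, , drop = FALSE]
    if (nrow(al) == 0L) next
    a <- al$allele[sample.int(nrow(al), 1L)]
    hap_decoys[[length(hap_decoys) + 1L]] <-
      assign_diplotypes(geno, wr, a)$copies
    hap_pos <- c(hap_pos, wr$bp_start)
  }
  cons <- protein_changing_consequences()
  n_var <- 1L + length(cols) + length(hap_decoys)
  variants <- data.frame(
    chrom = w$chrom,
    pos = c(causal_pos, geno$map$pos_bp[cols], hap_pos),
    ref = "A", alt = "T",
    consequence = c("inframe_deletion",
                    cons[1 + (seq_len(n_var - 1L) %% length(cons))]),
    filter_pass = TRUE,
    stringsAsFactors = FALSE
  )
  dosage <- rbind(causal_dosage, t(d_all[, cols, drop = FALSE]),
                  do.call(rbind, lapply(hap_decoys, as.integer)))
  dimnames(dosage) <- list(NULL, ids)
  br <- stats::setNames(rep(breed, length(ids)), ids)
  list(candidates = candidate_set(variants, dosage, br),
       causal_pos = causal_pos)
}
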