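#' Enumerate sliding SNP windows
#'
#' Produces the sliding-window decomposition used by the missing-homozygosity
#' scan: fixed-size windows of consecutive SNPs, advanced by `step`, never
#' spanning a chromosome boundary. SNP column indices are 1-based inclusive;
#' bp coordinates are 1-based inclusive.
#'
#' @param geno A [phased_geno()] object.
#' @param window_size Number of SNPs per window (default 50).
#' @param step Step between window starts in SNPs (default 1).
#'
#' @return Data frame with one row per window: `chrom`, `snp_start`,
#'   `snp_end` (global column indices into `geno$hap`), `bp_start`,
#'   `bp_end`. Chromosomes with fewer than `window_size` SNPs are skipped
#'   with a warning.
#' @export
enumerate_windows <- function(geno, window_size = 50, step = 1) {
  stopifnot(inherits(geno, "phased_geno"), window_size >= 2)
  if (step < 1) stop("step must be >= 1")
  out <- lapply(unique(geno$map$chrom), function(ch) {
    cols <- which(geno$map$chrom == ch)
    n <- length(cols)
    if (n < window_size) {
      warning("chromosome ", ch, " has ", n, " SNPs < window_size ",
              window_size, "; skipped", call. = FALSE)
      return(NULL)
    }
    starts <- seq(1L, n - window_size + 1L, by = step)
    data.frame(
      chrom = ch,
      snp_start = cols[starts],
      snp_end = cols[starts + window_size - 1L],
      bp_start = geno$map$pos_bp[cols[starts]],
      bp_end = geno$map$pos_bp[cols[starts + window_size - 1L]]
    )
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(chrom = integer(), snp_start = integer(),
                      snp_end = integer(), bp_start = integer(),
                      bp_end = integer())
  rownames(out) <- NULL
  out
}

# All window haplotype strings, two consecutive entries per animal.
window_hap_strings <- function(geno, snp_start, snp_end) {
  cols <- snp_start:snp_end
  do.call(paste0, as.data.frame(geno$hap[, cols, drop = FALSE]))
}

#' Observed haplotype alleles of one window
#'
#' Treats each distinct allele string across the window as one haplotype
#' allele and counts it over all phased haplotypes of the genotyped animals.
#'
#' @param geno A [phased_geno()] object.
#' @param window One row of [enumerate_windows()] (or any list with
#'   `snp_start`, `snp_end`).
#'
#' @return Data frame sorted by decreasing frequency: `allele` (0/1
#'   string), `count`, `frequency` (= count / (2 x number of animals);
#'   frequencies sum to 1).
#' @export
window_alleles <- function(geno, window) {
  s <- window_hap_strings(geno, window$snp_start, window$snp_end)
  tab <- sort(table(s), decreasing = TRUE)
  data.frame(allele = names(tab), count = as.integer(tab),
             frequency = as.integer(tab) / length(s),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Assign per-animal diplotypes for a target haplotype allele
#'
#' Counts, for every genotyped animal, how many of its two phased window
#' haplotypes match the target allele string exactly (no mismatch
#' tolerance), and labels carrier status.
#'
#' @param geno A [phased_geno()] object with known phase.
#' @param window One row of [enumerate_windows()].
#' @param allele Target allele string of length `snp_end - snp_start + 1`.
#'
#' @return Data frame `animal_id`, `copies` (0/1/2), `status`
#'   (non-carrier / carrier / homozygous).
#' @export
assign_diplotypes <- function(geno, window, allele) {
  if (!geno$phase_known)
    stop("diplotype assignment requires phased genotypes")
  if (nchar(allele) != window$snp_end - window$snp_start + 1L)
    stop("allele string length does not match the window size")
  s <- window_hap_strings(geno, window$snp_start, window$snp_end)
  odd <- seq(1L, length(s), by = 2L)
  copies <- as.integer(s[odd] == allele) + as.integer(s[odd + 1L] == allele)
  data.frame(
    animal_id = geno$animal_ids,
    copies = copies,
    status = c("non-carrier", "carrier", "homozygous")[copies + 1L],
    stringsAsFactors = FALSE
  )
}
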