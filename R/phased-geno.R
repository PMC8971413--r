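#' Construct a phased genotype matrix
#'
#' Container for phased biallelic SNP genotypes: each animal contributes two
#' haplotype rows (alleles coded 0/1) over an ordered SNP map. Animal `i`
#' occupies haplotype rows `2i - 1` and `2i`.
#'
#' @param hap Integer matrix of 0/1 alleles with `2 * length(animal_ids)`
#'   rows and one column per SNP.
#' @param animal_ids Character vector of animal identifiers.
#' @param map Data frame with columns `snp_id`, `chrom`, `pos_bp`, `cM`;
#'   positions must be strictly increasing within each chromosome.
#' @param phase_known Logical; whether the phase of `hap` is known. The
#'   windowing and diplotype machinery requires `TRUE`.
#'
#' @return An object of class `phased_geno`.
#' @export
phased_geno <- function(hap, animal_ids, map, phase_known = TRUE) {
  hap <- as.matrix(hap)
  storage.mode(hap) <- "integer"
  dimnames(hap) <- NULL
  stopifnot(
    nrow(hap) == 2L * length(animal_ids),
    ncol(hap) == nrow(map),
    all(hap %in% c(0L, 1L)),
    all(c("snp_id", "chrom", "pos_bp", "cM") %in% names(map)),
    !anyDuplicated(animal_ids)
  )
  for (ch in unique(map$chrom)) {
    pos <- map$pos_bp[map$chrom == ch]
    if (any(diff(pos) <= 0))
      stop("SNP positions must be strictly increasing within chromosome ", ch)
  }
  structure(
    list(hap = hap, animal_ids = as.character(animal_ids),
         map = as.data.frame(map), phase_known = isTRUE(phase_known)),
    class = "phased_geno"
  )
}

#' @export
print.phased_geno <- function(x, ...) {
  cat("phased_geno:", length(x$animal_ids), "animals,", nrow(x$map),
      "SNPs on", length(unique(x$map$chrom)), "chromosome(s); phase",
      if (x$phase_known) "known" else "unknown", "\n")
  invisible(x)
}

#' Number of animals in a phased genotype matrix
#' @param geno A [phased_geno()] object.
#' @return Integer count of animals.
#' @export
n_animals <- function(geno) length(geno$animal_ids)

# Haplotype row indices for given animal indices (or all animals).
hap_rows <- function(animal_index) {
  rbind(2L * animal_index - 1L, 2L * animal_index)
}

#' Allele dosages (0/1/2) of the alternate allele per animal and SNP
#' @param geno A [phased_geno()] object.
#' @return Integer matrix animals x SNPs with `animal_ids` rownames.
#' @export
alt_dosage <- function(geno) {
  n <- n_animals(geno)
  odd <- seq(1L, 2L * n, by = 2L)
  d <- geno$hap[odd, , drop = FALSE] + geno$hap[odd + 1L, , drop = FALSE]
  dimnames(d) <- list(geno$animal_ids, geno$map$snp_id)
  d
}

#' Subset a phased genotype matrix to a set of animals
#' @param geno A [phased_geno()] object.
#' @param ids Animal identifiers to retain (order preserved).
#' @return A [phased_geno()] restricted to `ids`.
#' @export
subset_animals <- function(geno, ids) {
  idx <- match(ids, geno$animal_ids)
  if (anyNA(idx)) stop("unknown animal id(s): ",
                       paste(ids[is.na(idx)], collapse = ", "))
  rows <- as.vector(hap_rows(idx))
  phased_geno(geno$hap[rows, , drop = FALSE], ids, geno$map,
              geno$phase_known)
}
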