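#' Write a phased genotype matrix as VCF 4.2
#'
#' Emits an uncompressed phased VCF: one contig line per chromosome, the
#' per-SNP genetic position carried in an INFO `CM` tag, and GT fields with
#' the `|` phase separator.
#'
#' @param geno A [phased_geno()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(geno, path) {
  map <- geno$map
  n <- n_animals(geno)
  odd <- seq(1L, 2L * n, by = 2L)
  gt <- matrix(paste0(t(geno$hap[odd, , drop = FALSE]), "|",
                      t(geno$hap[odd + 1L, , drop = FALSE])),
               nrow = nrow(map))  # SNPs x animals
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=hapdeficit",
    sprintf("##contig=<ID=%s,length=%d>", unique(map$chrom),
            vapply(unique(map$chrom),
                   function(ch) max(map$pos_bp[map$chrom == ch]) + 1L,
                   integer(1))),
    "##INFO=<ID=CM,Number=1,Type=Float,Description=\"Genetic map position in cM\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Phased genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", geno$animal_ids), collapse = "\t")
  )
  body <- paste(map$chrom, map$pos_bp, map$snp_id, "A", "B", ".", "PASS",
                sprintf("CM=%.10g", map$cM), "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a phased VCF into a phased genotype matrix
#'
#' Parses a VCF (via the vcfR package), requires fully phased biallelic
#' GT fields, and recovers the genetic map position from the INFO `CM` tag
#' when present (otherwise 1 cM per Mb is assumed).
#'
#' @param path Path to a VCF file.
#' @return A [phased_geno()] object.
#' @export
read_phased_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (any(grepl("/", gt, fixed = TRUE)))
    stop("unphased genotypes ('/' separator) in ", path,
         "; a phased VCF is required")
  ids <- colnames(gt)
  a1 <- substr(gt, 1L, 1L)
  a2 <- substr(gt, 3L, 3L)
  if (!all(c(a1, a2) %in% c("0", "1")))
    stop("only biallelic 0/1 genotypes are supported")
  m <- nrow(gt); n <- length(ids)
  hap <- matrix(0L, 2L * n, m)
  hap[seq(1L, 2L * n, by = 2L), ] <- t(matrix(as.integer(a1), m, n))
  hap[seq(2L, 2L * n, by = 2L), ] <- t(matrix(as.integer(a2), m, n))
  cm <- suppressWarnings(as.numeric(sub(".*CM=([0-9.eE+-]+).*", "\\1",
                                        fix$INFO)))
  pos <- as.integer(fix$POS)
  map <- data.frame(
    snp_id = ifelse(is.na(fix$ID) | fix$ID == ".",
                    paste0(fix$CHROM, "_", pos), fix$ID),
    chrom = type.convert(fix$CHROM, as.is = TRUE),
    pos_bp = pos,
    cM = ifelse(is.na(cm), pos / 1e6, cm),
    stringsAsFactors = FALSE
  )
  phased_geno(hap, ids, map, phase_known = TRUE)
}

#' Read candidate variants and breed labels
#'
#' Parses a candidate-variant VCF (per-sample GT, FILTER column, optional
#' `CSQ` INFO tag carrying the consequence class) together with a
#' two-column tab-separated sample-metadata file (`animal_id`, `breed`).
#'
#' @param vcf_path Path to the candidate VCF.
#' @param breed_path Path to the sample-metadata file.
#' @return A [candidate_set()].
#' @export
read_candidate_vcf <- function(vcf_path, breed_path) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  alt_count <- function(x) {
    a <- strsplit(gsub("\\|", "/", x), "/", fixed = FALSE)
    vapply(a, function(g) {
      if (any(g == ".")) return(NA_integer_)
      sum(as.integer(g) > 0L)
    }, integer(1))
  }
  dosage <- t(apply(gt, 1L, alt_count))
  dimnames(dosage) <- dimnames(gt)
  csq <- sub(".*CSQ=([A-Za-z_]+).*", "\\1", fix$INFO)
  csq[!grepl("CSQ=", fix$INFO)] <- "other"
  variants <- data.frame(
    chrom = type.convert(fix$CHROM, as.is = TRUE),
    pos = as.integer(fix$POS), ref = fix$REF, alt = fix$ALT,
    consequence = csq,
    filter_pass = fix$FILTER %in% c("PASS", "."),
    stringsAsFactors = FALSE
  )
  meta <- utils::read.table(breed_path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  breed <- stats::setNames(meta$breed, meta$animal_id)[colnames(dosage)]
  candidate_set(variants, dosage, breed)
}

#' Write a candidate-variant set as VCF 4.2 plus a breed table
#'
#' Inverse of [read_candidate_vcf()]: unphased GT fields from the dosage
#' matrix (`./.` for missing), consequence class in an INFO `CSQ` tag,
#' FILTER `PASS`/`FAIL`, and a two-column `animal_id`/`breed` metadata
#' file.
#'
#' @param cand A [candidate_set()].
#' @param vcf_path,breed_path Output file paths.
#' @return `vcf_path`, invisibly.
#' @export
write_candidate_vcf <- function(cand, vcf_path, breed_path) {
  gt_code <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow(cand$dosage), ncol(cand$dosage))
  ok <- !is.na(cand$dosage)
  gt[ok] <- gt_code[cand$dosage[ok] + 1L]
  v <- cand$variants
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=hapdeficit",
    sprintf("##contig=<ID=%s>", unique(v$chrom)),
    "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Consequence class\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(cand$dosage)), collapse = "\t")
  )
  body <- paste(v$chrom, v$pos, sprintf("var%d", seq_len(nrow(v))),
                v$ref, v$alt, ".",
                ifelse(v$filter_pass, "PASS", "FAIL"),
                paste0("CSQ=", v$consequence), "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), vcf_path)
  utils::write.table(
    data.frame(animal_id = colnames(cand$dosage), breed = cand$breed),
    breed_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(vcf_path)
}

#' Write / read a pedigree table
#'
#' Tab-separated with columns animal_id, sire_id, dam_id, sex, birth_year,
#' genotyped (the maternal grandsire is re-derived on read).
#'
#' @param pedigree Pedigree data frame.
#' @param path File path.
#' @return `path` (write) or the pedigree data frame with `mgs_id`
#'   re-derived (read).
#' @export
write_pedigree <- function(pedigree, path) {
  utils::write.table(
    pedigree[, c("animal_id", "sire_id", "dam_id", "sex", "birth_year",
                 "genotyped")],
    path, sep = "\t", quote = FALSE, row.names = FALSE, na = "0")
  invisible(path)
}

#' @rdname write_pedigree
#' @export
read_pedigree <- function(path) {
  ped <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = c(animal_id = "character",
                                          sire_id = "character",
                                          dam_id = "character"))
  ped$sire_id[ped$sire_id == "0"] <- NA_character_
  ped$dam_id[ped$dam_id == "0"] <- NA_character_
  ped$mgs_id <- ped$sire_id[match(ped$dam_id, ped$animal_id)]
  ped
}

#' Write / read a trait table
#'
#' Tab-separated with columns animal_id, trait, ebv, reliability.
#' @param traits Trait data frame.
#' @param path File path.
#' @return `path` (write) or the trait data frame (read).
#' @export
write_traits <- function(traits, path) {
  utils::write.table(traits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_traits
#' @export
read_traits <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE,
                    colClasses = c(animal_id = "character"))
}

#' Write the simulation truth record as a key-value file
#'
#' @param truth Truth record from [simulate_population()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  carriers <- names(truth$copies)[truth$copies >= 1L]
  homozygotes <- names(truth$copies)[truth$copies == 2L]
  lines <- c(
    paste0("chrom=", truth$window$chrom),
    paste0("snp_start=", truth$window$snp_start),
    paste0("snp_end=", truth$window$snp_end),
    paste0("bp_start=", truth$window$bp_start),
    paste0("bp_end=", truth$window$bp_end),
    paste0("pattern=", truth$pattern),
    paste0("founder_freq=", truth$founder_freq),
    paste0("carriers=", paste(carriers, collapse = ",")),
    paste0("homozygotes=", paste(homozygotes, collapse = ","))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Write a missing-homozygosity report
#'
#' Tab-separated summary of merged regions in the style of a published
#' haplotype table: name, chromosome, Mb span, design(s), observed,
#' expected, deficiency and allele-frequency percentages, raw and
#' BY-adjusted p.
#'
#' @param regions Output of [merge_regions()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_region_report <- function(regions, path) {
  if (nrow(regions) == 0L) {
    writeLines(paste(c("name", "chr", "span_Mb", "designs", "observed",
                       "expected", "deficient_pct", "allele_freq_pct",
                       "p_raw", "p_adj_BY"), collapse = "\t"), path)
    return(invisible(path))
  }
  rep <- data.frame(
    name = regions$name, chr = regions$chrom,
    span_Mb = sprintf("%.3f-%.3f", regions$bp_start / 1e6,
                      regions$bp_end / 1e6),
    designs = regions$designs, observed = regions$best_observed,
    expected = round(regions$best_expected, 1),
    deficient_pct = regions$best_deficiency_pct,
    allele_freq_pct = round(regions$best_allele_freq_pct, 2),
    p_raw = signif(regions$best_p_raw, 3),
    p_adj_BY = signif(regions$best_p_adj_BY, 3),
    stringsAsFactors = FALSE
  )
  utils::write.table(rep, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
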