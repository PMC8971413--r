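#' Parse a flat key=value run configuration
#'
#' Reads a configuration file of `key = value` lines (`#` comments
#' allowed), coerces numeric-looking values, and applies overrides (e.g.
#' from command-line flags), which take precedence.
#'
#' @param path Optional path to a config file.
#' @param overrides Named list of overriding values.
#' @return Named list merged over the pipeline defaults.
#' @export
run_config <- function(path = NULL, overrides = list()) {
  cfg <- list(
    outdir = "hapdeficit_out", vcf = NULL, pedigree = NULL, traits = NULL,
    variants = NULL, breeds = NULL,
    window_size = 50, step = 1, min_expected = 10, alpha = 0.05,
    maf_floor = 0.01, trait = "NRh", bonferroni_alpha = 0.05,
    flank_bp = 2e6, max_carrier_fraction = 0.75, max_hom = 1,
    seed = 1,
    # simulate-stage scenario: a population in which an embedded fully
    # lethal haplotype is reliably detectable in one run
    sim_founders = 300, sim_generations = 3, sim_sires = 30,
    sim_offspring_per_dam = 3, sim_risk_freq = 0.2, sim_penetrance = 1,
    sim_female_genotyping = 0.9, sim_usage_decay = 0.95,
    sim_hap_effect = -0.5, sim_h2 = 0.5
  )
  if (!is.null(path)) {
    lines <- readLines(path)
    lines <- sub("#.*", "", lines)
    lines <- trimws(lines[nzchar(trimws(lines))])
    for (ln in lines) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      if (length(kv) != 2L) stop("malformed config line: ", ln)
      key <- trimws(kv[1]); val <- trimws(kv[2])
      num <- suppressWarnings(as.numeric(val))
      cfg[[key]] <- if (!is.na(num)) num else val
    }
  }
  for (k in names(overrides)) {
    if (!is.null(overrides[[k]])) cfg[[k]] <- overrides[[k]]
  }
  cfg
}

log_stage <- function(outdir, stage, params, inputs = character(),
                      elapsed = NA_real_) {
  hashes <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  entry <- list(stage = stage, params = params, input_md5 = hashes,
                elapsed_sec = round(elapsed, 3))
  cat(jsonlite::toJSON(entry, auto_unbox = TRUE, null = "null"), "\n",
      sep = "", file = file.path(outdir, "run_log.jsonl"), append = TRUE)
}

#' Run one pipeline stage
#'
#' Orchestrates the pipeline: `simulate` writes a synthetic population
#' (phased VCF, pedigree, traits, truth record), `scan` runs the
#' missing-homozygosity scan for one design, `assoc` associates the top
#' region's haplotype with a trait, `prioritize` ranks candidate variants
#' against the top region, and `report` concatenates the per-design region
#' tables into one summary. Every stage appends a JSON-lines entry
#' (stage, parameters, input hashes, wall time) to `run_log.jsonl` in the
#' output directory.
#'
#' @param subcommand One of `"simulate"`, `"scan"`, `"assoc"`,
#'   `"prioritize"`, `"report"`.
#' @param config A [run_config()] list.
#' @param design Scan design (`"trio"` or `"pgp"`), for `scan`/`assoc`.
#' @return Invisibly, the main object produced by the stage.
#' @export
run_pipeline <- function(subcommand, config = run_config(),
                         design = "trio") {
  t0 <- proc.time()[["elapsed"]]
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- switch(
    subcommand,
    simulate = {
      sim <- simulate_population(sim_config(
        n_founders = config$sim_founders,
        n_generations = config$sim_generations,
        n_sires_per_gen = config$sim_sires,
        offspring_per_dam = config$sim_offspring_per_dam,
        risk_hap_freq = config$sim_risk_freq,
        penetrance = config$sim_penetrance,
        female_genotyping_rate = config$sim_female_genotyping,
        sire_usage_decay = config$sim_usage_decay,
        trait_h2 = config$sim_h2,
        hap_trait_effect = config$sim_hap_effect,
        seed = config$seed))
      tr <- simulate_trait_ebvs(sim$pedigree, sim$truth,
                                h2 = config$sim_h2,
                                hap_effect = config$sim_hap_effect,
                                trait_code = config$trait,
                                seed = config$seed)
      write_phased_vcf(sim$genotypes,
                       file.path(config$outdir, "genotypes.vcf"))
      write_pedigree(sim$pedigree,
                     file.path(config$outdir, "pedigree.tsv"))
      write_traits(tr$ebvs, file.path(config$outdir, "traits.tsv"))
      write_truth(sim$truth, file.path(config$outdir, "truth.txt"))
      sc <- simulate_candidate_variants(sim, seed = config$seed)
      write_candidate_vcf(sc$candidates,
                          file.path(config$outdir, "candidates.vcf"),
                          file.path(config$outdir, "breeds.tsv"))
      sim
    },
    scan = {
      geno <- read_phased_vcf(pipeline_input(config, "vcf", "genotypes.vcf"))
      ped <- read_pedigree(pipeline_input(config, "pedigree",
                                          "pedigree.tsv"))
      res <- scan_deficit(geno, ped, design = design,
                          window_size = config$window_size,
                          step = config$step,
                          min_expected = config$min_expected,
                          maf_floor = config$maf_floor)
      utils::write.table(res, file.path(config$outdir,
                                        paste0("scan_", design, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      regions <- merge_regions(res, alpha = config$alpha)
      utils::write.table(regions, file.path(config$outdir, "regions.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      regions
    },
    assoc = {
      geno <- read_phased_vcf(pipeline_input(config, "vcf", "genotypes.vcf"))
      traits <- read_traits(pipeline_input(config, "traits", "traits.tsv"))
      regions <- utils::read.table(file.path(config$outdir, "regions.tsv"),
                                   header = TRUE, sep = "\t",
                                   stringsAsFactors = FALSE,
                                   colClasses = c(best_allele = "character"))
      if (nrow(regions) == 0L) stop("no regions to associate")
      best <- regions[which.min(regions$best_p_raw), ]
      win <- list(snp_start = best$best_snp_start,
                  snp_end = best$best_snp_end)
      dip <- assign_diplotypes(geno, win, best$best_allele)
      G <- compute_grm(geno)
      res <- haplotype_association(dip, traits, G, config$trait)
      utils::write.table(res, file.path(config$outdir, "assoc.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      res
    },
    prioritize = {
      geno <- read_phased_vcf(pipeline_input(config, "vcf", "genotypes.vcf"))
      cand <- read_candidate_vcf(
        pipeline_input(config, "variants", "candidates.vcf"),
        pipeline_input(config, "breeds", "breeds.tsv"))
      regions <- utils::read.table(file.path(config$outdir, "regions.tsv"),
                                   header = TRUE, sep = "\t",
                                   stringsAsFactors = FALSE,
                                   colClasses = c(best_allele = "character"))
      if (nrow(regions) == 0L) stop("no regions to prioritize")
      best <- regions[which.min(regions$best_p_raw), ]
      reg <- expand_region(best, flank_bp = config$flank_bp)
      filt <- candidate_filter(
        cand, reg, max_carrier_fraction = config$max_carrier_fraction,
        max_hom = config$max_hom)
      win <- list(snp_start = best$best_snp_start,
                  snp_end = best$best_snp_end)
      dip <- assign_diplotypes(geno, win, best$best_allele)
      ranked <- rank_candidates(filt, dip)
      utils::write.table(ranked, file.path(config$outdir, "candidates.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      ranked
    },
    report = {
      regions <- utils::read.table(file.path(config$outdir, "regions.tsv"),
                                   header = TRUE, sep = "\t",
                                   stringsAsFactors = FALSE,
                                   colClasses = c(best_allele = "character"))
      write_region_report(regions, file.path(config$outdir, "report.tsv"))
      regions
    },
    stop("unknown subcommand: ", subcommand)
  )
  log_stage(config$outdir, subcommand,
            params = c(config[vapply(config, is.numeric, logical(1))],
                       list(design = design)),
            elapsed = proc.time()[["elapsed"]] - t0)
  invisible(out)
}

pipeline_input <- function(config, key, default_name) {
  path <- config[[key]]
  if (is.null(path)) path <- file.path(config$outdir, default_name)
  if (!file.exists(path)) stop("input not found: ", path)
  path
}
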