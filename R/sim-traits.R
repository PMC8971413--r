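#' Trait abbreviations understood by the association layer
#'
#' Fertility, birth and survival trait codes used in dairy-cattle routine
#' evaluations: non-return rates (NRh, NRc), insemination intervals (IFLh,
#' IFLc, DFS), calving ease (CEd, CEm), stillbirth (SBd, SBm), birth weight
#' (BWd, BWm), gestation length (GLd, GLm), multiple birth (MBd, MBm), and
#' survival periods (P1, P2h, P2b).
#'
#' @return Character vector of trait codes.
#' @export
trait_codes <- function() {
  c("NRh", "NRc", "IFLh", "IFLc", "DFS", "CEd", "SBd", "BWd", "GLd", "MBd",
    "CEm", "SBm", "BWm", "GLm", "MBm", "P1", "P2h", "P2b")
}

#' Simulate EBV-like pseudo-phenotypes over a simulated pedigree
#'
#' Generates a polygenic (infinitesimal) true breeding value down the
#' pedigree, adds an optional additive effect of the risk haplotype, and
#' produces estimated breeding values with per-animal reliabilities. The
#' trait is on a unit-variance scale: founders draw a polygenic value from
#' N(0, h2), non-founders receive the parent average plus a Mendelian
#' sampling deviation N(0, h2/2). EBVs follow the classical shrinkage form
#' EBV = r2 * TBV + e with var(e) = r2 (1 - r2) var(TBV), so that the
#' declared reliability equals var(EBV)/var(TBV) and EBV/r2 is an unbiased
#' pseudo-phenotype (see [deregress()]).
#'
#' @param pedigree Pedigree data frame as returned by
#'   [simulate_population()] (parents must precede offspring).
#' @param truth Truth record from [simulate_population()]; supplies the
#'   risk-allele dosage. May be `NULL` when `hap_effect = 0`.
#' @param h2 Heritability in (0, 1).
#' @param hap_effect Additive effect of one risk-allele copy, trait SD units.
#' @param trait_code Trait abbreviation (see [trait_codes()]).
#' @param reliability Either a single reliability in (0, 1] applied to all
#'   animals, or a length-2 range from which per-animal reliabilities are
#'   drawn uniformly.
#' @param seed Integer seed.
#'
#' @return A list with `ebvs` (data frame `animal_id`, `trait`, `ebv`,
#'   `reliability`) and `tbv` (named numeric vector of true breeding
#'   values, for validation).
#' @export
simulate_trait_ebvs <- function(pedigree, truth = NULL, h2 = 0.3,
                                hap_effect = 0, trait_code = "NRh",
                                reliability = c(0.5, 0.95), seed = 1L) {
  if (h2 <= 0 || h2 >= 1) stop("h2 must be in (0, 1)")
  stopifnot(trait_code %in% trait_codes())
  set.seed(as.integer(seed))
  n <- nrow(pedigree)
  a <- numeric(n)
  si <- match(pedigree$sire_id, pedigree$animal_id)
  di <- match(pedigree$dam_id, pedigree$animal_id)
  for (i in seq_len(n)) {
    if (is.na(si[i]) || is.na(di[i])) {
      a[i] <- stats::rnorm(1, 0, sqrt(h2))
    } else {
      a[i] <- 0.5 * (a[si[i]] + a[di[i]]) + stats::rnorm(1, 0, sqrt(h2 / 2))
    }
  }
  tbv <- a
  if (hap_effect != 0) {
    if (is.null(truth)) stop("truth record required when hap_effect != 0")
    tbv <- tbv + hap_effect * as.numeric(truth$copies[pedigree$animal_id])
  }
  rel <- if (length(reliability) == 1L) rep(reliability, n)
         else stats::runif(n, reliability[1], reliability[2])
  if (any(rel <= 0 | rel > 1)) stop("reliability must be in (0, 1]")
  v <- stats::var(tbv)
  ebv <- rel * tbv + stats::rnorm(n, 0, sqrt(rel * (1 - rel) * v))
  names(tbv) <- pedigree$animal_id
  list(
    ebvs = data.frame(animal_id = pedigree$animal_id, trait = trait_code,
                      ebv = ebv, reliability = rel,
                      stringsAsFactors = FALSE),
    tbv = tbv
  )
}
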