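#' @include AllClasses.R AllGenerics.R
NULL

# probability that a parent transmits the transgene allele
.transmitProb <- c(WT = 0, HEMI = 0.5, HOMO = 1)

.checkGenotype <- function(g) {
  if (length(g) != 1 || !g %in% GENOTYPES)
    stop("genotype must be one of ", paste(GENOTYPES, collapse = ", "))
  g
}

#' Mendelian offspring distribution with paternal sex-ratio distortion
#'
#' Exact single-locus Mendelian genotype probabilities for an autosomal
#' transgene, plus the brood's male probability.  Transgenic fathers (hemi-
#' or homozygous) sire male eggs with probability \code{maleBias} (0.95 by
#' default); wild-type fathers with probability 0.5.  Mothers never bias the
#' sex ratio.
#'
#' @param father,mother Genotype strings (see [GENOTYPES]).
#' @param maleBias Male probability under a transgenic father.
#' @return A [CrossDistribution-class].
#' @examples
#' offspringDistribution("HEMI", "WT")   # half the brood transgenic, 95% male
#' @export
offspringDistribution <- function(father, mother, maleBias = 0.95) {
  pf <- .transmitProb[[.checkGenotype(father)]]
  pm <- .transmitProb[[.checkGenotype(mother)]]
  probs <- c(WT = (1 - pf) * (1 - pm),
             HEMI = pf * (1 - pm) + (1 - pf) * pm,
             HOMO = pf * pm)
  new("CrossDistribution", probs = probs,
      maleProb = if (father %in% c("HEMI", "HOMO")) maleBias else 0.5)
}

#' Empty brood-count matrix
#'
#' Brood composition is represented throughout as a genotype x sex integer
#' matrix (rows \code{GENOTYPES}, columns \code{SEXES}).
#'
#' @return A zero 3 x 2 matrix with the standard dimnames.
#' @export
emptyBrood <- function() {
  matrix(0L, nrow = 3, ncol = 2, dimnames = list(GENOTYPES, SEXES))
}

#' Sample a brood's genotype and sex composition
#'
#' Genotype counts are multinomial under the pair's Mendelian distribution;
#' each egg's sex is then drawn independently with the pair's male
#' probability (binomial within genotype class).  Genotype and sex are
#' independent for an autosomal transgene.
#'
#' @param nEggs Number of eggs (>= 0).
#' @inheritParams offspringDistribution
#' @param dist Optionally, a precomputed [CrossDistribution-class] (then
#'   \code{father}/\code{mother} are ignored).
#' @return Genotype x sex count matrix totalling \code{nEggs}.
#' @examples
#' set.seed(1)
#' sampleBrood(10, "HEMI", "WT")
#' @export
sampleBrood <- function(nEggs, father, mother, maleBias = 0.95, dist = NULL) {
  if (length(nEggs) != 1 || is.na(nEggs) || nEggs < 0)
    stop("nEggs must be a single non-negative count")
  if (is.null(dist)) dist <- offspringDistribution(father, mother, maleBias)
  out <- emptyBrood()
  if (nEggs == 0) return(out)
  g <- stats::rmultinom(1, nEggs, crossProbs(dist))[, 1]
  m <- stats::rbinom(3, g, maleProb(dist))
  out[, "M"] <- m
  out[, "F"] <- g - m
  out
}

#' Transgenic fraction of a brood-count matrix
#' @param brood Genotype x sex count matrix (see [emptyBrood()]).
#' @return Fraction of individuals carrying the transgene (NA if empty).
#' @export
transgenicFraction <- function(brood) {
  tot <- sum(brood)
  if (tot == 0) return(NA_real_)
  sum(brood[c("HEMI", "HOMO"), ]) / tot
}

#' Female fraction of a brood-count matrix
#' @inheritParams transgenicFraction
#' @return Fraction female (NA if empty).
#' @export
femaleFraction <- function(brood) {
  tot <- sum(brood)
  if (tot == 0) return(NA_real_)
  sum(brood[, "F"]) / tot
}
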