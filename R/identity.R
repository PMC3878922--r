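#' Probability of identity at one locus under Hardy-Weinberg equilibrium
#'
#' The probability that two unrelated individuals drawn from a population in
#' HWE share the same unordered genotype at the locus:
#' `PI = 2 (sum p_i^2)^2 - sum p_i^4`.
#'
#' @param p numeric allele-frequency vector summing to 1.
#' @return PI in (0, 1].
#' @examples
#' pi_hwe_locus(c(0.5, 0.5))   # 0.375
#' @export
pi_hwe_locus <- function(p) {
  check_freqs(p)
  s2 <- sum(p^2); s4 <- sum(p^4)
  2 * s2^2 - s4
}

#' Probability of identity at one locus for full siblings
#'
#' The probability that two full siblings (HWE parents, Mendelian
#' segregation) share the same unordered genotype:
#' `PI_sibs = 1/4 + (1/2) sum p_i^2 + (1/2) (sum p_i^2)^2 - (1/4) sum p_i^4`.
#' Always at least as large as the unrelated-pair PI.
#'
#' @param p numeric allele-frequency vector summing to 1.
#' @return PI in (0, 1].
#' @examples
#' pi_sibs_locus(c(0.5, 0.5))  # 0.59375
#' @export
pi_sibs_locus <- function(p) {
  check_freqs(p)
  s2 <- sum(p^2); s4 <- sum(p^4)
  0.25 + 0.5 * s2 + 0.5 * s2^2 - 0.25 * s4
}

#' Multilocus probability of identity
#'
#' Product of per-locus PIs under the chosen relatedness model, assuming
#' locus independence.
#'
#' @param loci named list of allele-frequency vectors.
#' @param model `"hwe"` (unrelated) or `"sibs"` (full siblings).
#' @return list: `per_locus` (named vector), `multilocus` (product).
#' @export
multilocus_pi <- function(loci, model = c("hwe", "sibs")) {
  model <- match.arg(model)
  if (length(loci) == 0) stop("empty locus panel")
  f <- if (model == "hwe") pi_hwe_locus else pi_sibs_locus
  per <- vapply(loci, f, numeric(1))
  list(per_locus = per, multilocus = prod(per))
}

#' Compare donor and clone genotypes locus by locus
#'
#' Genotypes are unordered allele pairs: a heterozygote recorded with its
#' alleles swapped still matches. Loci typed in only one individual are
#' flagged missing and excluded from the all-match conjunction.
#'
#' @param donor,clone genotype data.frames with columns `locus`, `allele1`,
#'   `allele2` (one row per locus per individual).
#' @return list: `per_locus` (data.frame `locus`, `match`, `missing`),
#'   `all_match` (TRUE iff every co-typed locus matches).
#' @export
genotype_match <- function(donor, clone) {
  loci <- union(donor$locus, clone$locus)
  rows <- lapply(loci, function(l) {
    d <- donor[donor$locus == l, , drop = FALSE]
    c_ <- clone[clone$locus == l, , drop = FALSE]
    if (nrow(d) != 1 || nrow(c_) != 1)
      return(data.frame(locus = l, match = NA, missing = TRUE))
    gd <- sort(c(d$allele1, d$allele2))
    gc <- sort(c(c_$allele1, c_$allele2))
    data.frame(locus = l, match = identical(gd, gc), missing = FALSE)
  })
  per <- do.call(rbind, rows)
  typed <- per[!per$missing, , drop = FALSE]
  list(per_locus = per,
       all_match = nrow(typed) > 0 && all(typed$match))
}
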