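# Per-SNP diversity statistics and the method-of-moments individual
# inbreeding coefficient FIS (excess of observed over expected homozygous
# genotypes, with the small-sample correction on expected homozygosity).

#' Per-SNP heterozygosity, MAF and allele frequencies
#'
#' Frequencies are always computed from the analysed sample itself. Expected
#' heterozygosity is reported as plain `2p(1-p)`; the small-sample-corrected
#' version `2p(1-p) n/(n-1)` is also returned as `he_corrected` for SNPs
#' with at least two non-missing calls.
#'
#' @param genotypes samples x SNPs matrix coded 0/1/2/NA.
#' @return list with `per_snp` (data.frame `snp_id`, `n`, `p`, `maf`, `ho`,
#'   `he`, `he_corrected`), `summary` (means and SDs of HO, HE, MAF over
#'   SNPs with data), and `skipped` (ids of SNPs with no non-missing call).
#' @export
snp_stats <- function(genotypes) {
  validate_genotypes(genotypes)
  if (nrow(genotypes) == 0 || ncol(genotypes) == 0)
    stop("empty genotype matrix")
  n <- colSums(!is.na(genotypes))
  p <- ifelse(n > 0, colMeans(genotypes, na.rm = TRUE) / 2, NA_real_)
  ho <- ifelse(n > 0, colMeans(genotypes == 1, na.rm = TRUE), NA_real_)
  he <- 2 * p * (1 - p)
  hec <- ifelse(n > 1, he * n / (n - 1), NA_real_)
  ids <- colnames(genotypes)
  if (is.null(ids)) ids <- paste0("snp", seq_len(ncol(genotypes)))
  per_snp <- data.frame(snp_id = ids, n = n, p = p,
                        maf = pmin(p, 1 - p), ho = ho, he = he,
                        he_corrected = hec, row.names = NULL,
                        stringsAsFactors = FALSE)
  ok <- n > 0
  summary <- list(
    mean_ho = mean(ho[ok]), sd_ho = stats::sd(ho[ok]),
    mean_he = mean(he[ok]), sd_he = stats::sd(he[ok]),
    mean_maf = mean(per_snp$maf[ok]), sd_maf = stats::sd(per_snp$maf[ok]),
    n_snps = sum(ok))
  list(per_snp = per_snp, summary = summary, skipped = ids[!ok])
}

#' Individual inbreeding from the excess of homozygous genotypes (FIS)
#'
#' For animal *i*, over its non-missing SNPs *j*:
#' `e_hom = sum_j (1 - 2 p_j (1 - p_j) n_j / (n_j - 1))` where `n_j` is the
#' number of non-missing calls at SNP *j*, and
#' `fis = (o_hom - e_hom) / (n - e_hom)`. Negative values indicate
#' lower-than-average homozygosity. SNPs with fewer than two non-missing
#' calls are excluded from every animal's sums (they are listed in the
#' `excluded_snps` attribute).
#'
#' @param genotypes samples x SNPs matrix coded 0/1/2/NA, at least 2 samples.
#' @return data.frame per animal: `animal`, `n_nonmissing`, `o_hom`,
#'   `e_hom`, `fis`, `undefined` (TRUE where the denominator is zero).
#' @export
fis <- function(genotypes) {
  validate_genotypes(genotypes)
  if (nrow(genotypes) < 2)
    stop("FIS needs at least two samples (sample-size correction)")
  n_j <- colSums(!is.na(genotypes))
  usable <- n_j >= 2
  excluded <- colnames(genotypes)[!usable]
  g <- genotypes[, usable, drop = FALSE]
  n_j <- n_j[usable]
  p <- colMeans(g, na.rm = TRUE) / 2
  ehom_j <- 1 - 2 * p * (1 - p) * n_j / (n_j - 1)

  obs <- !is.na(g)
  n_i <- rowSums(obs)
  o_hom <- rowSums(g == 0 | g == 2, na.rm = TRUE)
  e_hom <- as.numeric(obs %*% ehom_j)
  denom <- n_i - e_hom
  undef <- abs(denom) < .Machine$double.eps^0.5
  f <- ifelse(undef, NA_real_, (o_hom - e_hom) / denom)
  ids <- rownames(genotypes)
  if (is.null(ids)) ids <- paste0("S", seq_len(nrow(genotypes)))
  out <- data.frame(animal = ids, n_nonmissing = n_i, o_hom = o_hom,
                    e_hom = e_hom, fis = f, undefined = undef,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "excluded_snps") <- excluded
  out
}
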