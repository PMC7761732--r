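# The three relationship matrices — pedigree-based (A), SNP-based
# (VanRaden G), and ROH-overlap-based — and the comparison of the
# inbreeding coefficients they imply.

#' Pedigree numerator relationship matrix (tabular method)
#'
#' Founders get diagonal 1 and off-diagonal 0; for animal *i* with parents
#' *s*, *d*: `a(i,j) = (a(j,s) + a(j,d)) / 2` for earlier animals *j*, and
#' `a(i,i) = 1 + a(s,d)/2`. An unknown parent contributes 0 (founders are
#' assumed non-inbred and unrelated). The individual inbreeding coefficient
#' is `F_i = a(i,i) - 1`.
#'
#' @param pedigree data.frame `id`, `sire`, `dam`, topologically sorted
#'   (e.g. from [read_pedigree()] or [simulate_pedigree()]).
#' @return matrix with animal ids as dimnames and attribute `F` (named
#'   per-animal inbreeding coefficients).
#' @export
pedigree_a_matrix <- function(pedigree) {
  ids <- pedigree$id
  n <- length(ids)
  si <- match(pedigree$sire, ids)
  di <- match(pedigree$dam, ids)
  if (any(si >= seq_len(n) | di >= seq_len(n), na.rm = TRUE))
    stop("pedigree is not topologically sorted (parent after offspring)")
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1) {
      j <- seq_len(i - 1)
      as_ <- if (!is.na(s)) A[j, s] else 0
      ad_ <- if (!is.na(d)) A[j, d] else 0
      v <- (as_ + ad_) / 2
      A[j, i] <- v
      A[i, j] <- v
    }
    A[i, i] <- 1 + (if (!is.na(s) && !is.na(d)) A[s, d] / 2 else 0)
  }
  attr(A, "F") <- stats::setNames(diag(A) - 1, ids)
  A
}

#' VanRaden genomic relationship matrix
#'
#' Missing genotypes are imputed with the SNP mean (`2p`) before centering
#' (a mean-imputation stand-in appropriate at the low missingness left after
#' quality control); genotypes are then centered by `2p` and
#' `G = Z Z' / (2 sum_j p_j (1 - p_j))`, with allele frequencies computed
#' from the analysed sample. Monomorphic SNPs contribute zero to both the
#' numerator and the scaling sum.
#'
#' @param genotypes samples x SNPs matrix coded 0/1/2/NA, at least 2
#'   samples.
#' @return symmetric matrix with animal ids as dimnames.
#' @export
vanraden_g <- function(genotypes) {
  validate_genotypes(genotypes)
  if (nrow(genotypes) < 2) stop("G needs at least two animals")
  p <- colMeans(genotypes, na.rm = TRUE) / 2
  denom <- 2 * sum(p * (1 - p), na.rm = TRUE)
  if (denom <= 0) stop("all SNPs monomorphic: zero scaling denominator")
  M <- genotypes
  na <- which(is.na(M), arr.ind = TRUE)
  if (nrow(na)) M[na] <- 2 * p[na[, 2]]
  Z <- sweep(M, 2, 2 * p)
  G <- tcrossprod(Z) / denom
  dimnames(G) <- list(rownames(genotypes), rownames(genotypes))
  G
}

# Per-chromosome elementary intervals of a run set: breakpoints, interval
# lengths, and an animals x intervals carrier indicator.
run_coverage_intervals <- function(runset, animals, ch) {
  rr <- runset[runset$chrom == ch, , drop = FALSE]
  brk <- sort(unique(c(rr$start_bp, rr$end_bp)))
  len <- diff(brk)
  ind <- matrix(0, length(animals), length(len),
                dimnames = list(animals, NULL))
  for (r in seq_len(nrow(rr))) {
    i0 <- findInterval(rr$start_bp[r], brk)
    i1 <- findInterval(rr$end_bp[r], brk) - 1
    if (i1 >= i0) ind[rr$animal[r], i0:i1] <- 1
  }
  list(len = len, ind = ind)
}

#' ROH-overlap relationship matrix
#'
#' The numerator for animals *i*, *j* is the total basepairs of pairwise
#' intersection of their runs (the diagonal is each animal's total run
#' length). The denominator is the population-wide sum, over the maximal
#' genomic intervals with a constant set of run carriers, of interval
#' length times carrier frequency (carriers / `n` animals). This makes the
#' statistic dimensionless and symmetric, and weights longer, more widely
#' shared runs proportionally more. `denominator = "pairwise"` instead
#' scales each pair by the same frequency-weighted sum restricted to the
#' intervals where at least one of the two animals has a run.
#'
#' @param runset a `run_set`; a list of per-animal run sets is also
#'   accepted and row-bound after checking that all were produced with the
#'   same parameters and panel (provenance).
#' @param animals panel animal ids (so animals without runs get zero rows);
#'   defaults to the animals present in the run set.
#' @param denominator `"population"` (default) or `"pairwise"`.
#' @return symmetric matrix with animal ids as dimnames.
#' @export
roh_relationship <- function(runset, animals = NULL,
                             denominator = c("population", "pairwise")) {
  denominator <- match.arg(denominator)
  if (is.list(runset) && !is.data.frame(runset)) {
    sig <- lapply(runset, function(x)
      list(attr(x, "panel_hash"), attr(x, "params")))
    if (length(unique(vapply(sig, function(s)
      paste(s[[1]], paste(deparse(s[[2]]), collapse = ""), collapse = "|"),
      ""))) > 1)
      stop("mixed provenance: run sets come from different panels or parameters")
    runset <- do.call(rbind, runset)
  }
  if (is.null(animals)) animals <- sort(unique(runset$animal))
  n <- length(animals)
  num <- matrix(0, n, n, dimnames = list(animals, animals))
  denom <- 0
  for (ch in unique(runset$chrom)) {
    cov <- run_coverage_intervals(runset, animals, ch)
    if (!length(cov$len)) next
    X <- sweep(cov$ind, 2, cov$len, `*`)
    num <- num + X %*% t(cov$ind)
    carriers <- colSums(cov$ind)
    denom <- denom + sum(carriers / n * cov$len)
  }
  if (denominator == "population") {
    if (denom <= 0) stop("no runs: zero denominator")
    return(num / denom)
  }
  # pairwise denominator: recompute per chromosome with union indicators
  dp <- matrix(0, n, n, dimnames = list(animals, animals))
  for (ch in unique(runset$chrom)) {
    cov <- run_coverage_intervals(runset, animals, ch)
    if (!length(cov$len)) next
    carriers <- colSums(cov$ind)
    w <- carriers / n * cov$len
    ci <- cov$ind
    # union(i,j) weight = sum_k w_k * (c_ik | c_jk)
    Wi <- ci %*% diag(w, nrow = length(w))
    tot_i <- rowSums(Wi)
    both <- Wi %*% t(ci)          # sum over intervals carried by both
    dp <- dp + outer(tot_i, tot_i, `+`) - both
  }
  if (any(dp == 0)) dp[dp == 0] <- Inf
  num / dp
}

#' Join and correlate inbreeding coefficients
#'
#' Inner-joins pedigree inbreeding, FIS and FROH (total and per length
#' class) on animal id and returns Pearson and Spearman correlation
#' matrices over all coefficient columns.
#'
#' @param f_ped named numeric vector of pedigree inbreeding coefficients
#'   (e.g. `attr(pedigree_a_matrix(ped), "F")`).
#' @param fis_table output of [fis()].
#' @param froh_table output of [froh()].
#' @return list: `table` (joined per-animal coefficients), `pearson`,
#'   `spearman` (correlation matrices), `n_common`, `excluded` (animal ids
#'   dropped by the join).
#' @export
compare_inbreeding <- function(f_ped, fis_table, froh_table) {
  ids <- intersect(intersect(names(f_ped), fis_table$animal),
                   froh_table$animal)
  excluded <- setdiff(unique(c(names(f_ped), fis_table$animal,
                               froh_table$animal)), ids)
  if (length(ids) < 3)
    stop("fewer than 3 animals common to all coefficient sets")
  tab <- data.frame(animal = ids, f_ped = unname(f_ped[ids]),
                    fis = fis_table$fis[match(ids, fis_table$animal)],
                    stringsAsFactors = FALSE)
  froh_cols <- setdiff(names(froh_table), "animal")
  for (cc in froh_cols)
    tab[[cc]] <- froh_table[[cc]][match(ids, froh_table$animal)]
  m <- as.matrix(tab[, -1])
  list(table = tab,
       pearson = stats::cor(m, method = "pearson"),
       spearman = stats::cor(m, method = "spearman"),
       n_common = length(ids), excluded = excluded)
}

#' Write a relationship matrix as labeled CSV and long-format TSV
#'
#' @param mat square labeled matrix.
#' @param csv_path,tsv_path output paths (either may be NULL to skip).
#' @export
write_relationship <- function(mat, csv_path = NULL, tsv_path = NULL) {
  if (!is.null(csv_path))
    utils::write.csv(as.data.frame(mat), csv_path, row.names = TRUE)
  if (!is.null(tsv_path)) {
    long <- data.frame(i = rep(rownames(mat), times = ncol(mat)),
                       j = rep(colnames(mat), each = nrow(mat)),
                       value = as.vector(mat))
    utils::write.table(long, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(NULL)
}
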