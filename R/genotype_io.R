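# Reading/writing PLINK PED/MAP text files and pedigrees, plus the
# quality-control filters applied before any run detection.

#' Read PLINK PED/MAP text files into a genotype matrix and marker map
#'
#' Genotypes are recoded to counts of a per-SNP "counted" allele: the first
#' allele symbol encountered for that SNP scanning samples in file order.
#' An allele pair containing the missing symbol `0` becomes `NA`.
#' SNP columns are reordered to follow the map sorted by (chromosome,
#' position).
#'
#' @param ped_path path to a PED file (6 mandatory columns, then two allele
#'   columns per SNP).
#' @param map_path path to a MAP file (4 columns: chrom, snp id, cM, bp).
#' @return list with elements `genotypes` (samples x SNPs integer matrix,
#'   `NA` = missing), `map` (data.frame `snp_id`, `chrom`, `pos_bp`, `cm`).
#' @export
read_ped_map <- function(ped_path, map_path) {
  if (!file.exists(ped_path)) stop("PED file not found: ", ped_path)
  if (!file.exists(map_path)) stop("MAP file not found: ", map_path)
  mp <- utils::read.table(map_path, header = FALSE, stringsAsFactors = FALSE,
                          colClasses = c("character", "character", "numeric",
                                         "numeric"))
  if (ncol(mp) != 4) stop("MAP file must have 4 columns")
  map <- data.frame(snp_id = mp[[2]], chrom = mp[[1]], pos_bp = mp[[4]],
                    cm = mp[[3]], stringsAsFactors = FALSE)
  n_snp <- nrow(map)

  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  n_sam <- length(lines)
  ids <- character(n_sam)
  a1 <- matrix("", n_sam, n_snp)
  a2 <- matrix("", n_sam, n_snp)
  for (i in seq_len(n_sam)) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(f) < 6 || (length(f) - 6) %% 2 != 0)
      stop("malformed PED line ", i, ": ", length(f),
           " fields (odd number of allele fields)")
    if ((length(f) - 6) / 2 != n_snp)
      stop("PED line ", i, " has ", (length(f) - 6) / 2,
           " SNPs but MAP lists ", n_snp)
    ids[i] <- f[2]
    al <- f[-(1:6)]
    a1[i, ] <- al[seq(1, length(al), by = 2)]
    a2[i, ] <- al[seq(2, length(al), by = 2)]
  }

  geno <- matrix(NA_integer_, n_sam, n_snp, dimnames = list(ids, map$snp_id))
  for (j in seq_len(n_snp)) {
    miss <- a1[, j] == "0" | a2[, j] == "0"
    obs <- c(rbind(a1[!miss, j], a2[!miss, j]))  # sample order, a1 before a2
    if (length(obs)) {
      counted <- obs[1]
      syms <- unique(obs)
      if (length(syms) > 2)
        stop("more than two allele symbols at SNP ", map$snp_id[j], ": ",
             paste(syms, collapse = ","))
      geno[!miss, j] <- (a1[!miss, j] == counted) + (a2[!miss, j] == counted)
    }
  }

  ord <- sort_map_order(map)
  map <- map[ord, , drop = FALSE]
  rownames(map) <- NULL
  geno <- geno[, ord, drop = FALSE]
  validate_marker_map(map)
  validate_genotypes(geno, map)
  list(genotypes = geno, map = map)
}

#' Write a genotype matrix and marker map as PLINK PED/MAP text files
#'
#' The counted allele is written as symbol `A`, the other as `B`
#' (heterozygotes as `A B`); missing genotypes as `0 0`. Files written here
#' are re-readable by [read_ped_map()]; the round trip is the identity up to
#' per-SNP allele relabeling (a SNP whose first non-missing genotype carries
#' zero copies of the counted allele is re-read with the coding flipped,
#' since the reader counts the first-observed allele).
#'
#' @param genotypes samples x SNPs matrix coded 0/1/2/NA.
#' @param map marker map data.frame (`snp_id`, `chrom`, `pos_bp`, optional
#'   `cm`).
#' @param ped_path,map_path output paths.
#' @return invisibly, the two paths.
#' @export
write_ped_map <- function(genotypes, map, ped_path, map_path) {
  validate_marker_map(map)
  validate_genotypes(genotypes, map)
  cm <- if ("cm" %in% names(map)) map$cm else rep(0, nrow(map))
  utils::write.table(
    data.frame(map$chrom, map$snp_id, cm, map$pos_bp),
    map_path, quote = FALSE, sep = "\t", row.names = FALSE, col.names = FALSE)

  ids <- rownames(genotypes)
  if (is.null(ids)) ids <- paste0("S", seq_len(nrow(genotypes)))
  pair <- c("B B", "A B", "A A")  # codes 0,1,2
  con <- file(ped_path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(genotypes))) {
    g <- genotypes[i, ]
    al <- ifelse(is.na(g), "0 0", pair[g + 1])
    writeLines(paste(c(ids[i], ids[i], "0", "0", "0", "-9", al),
                     collapse = " "), con)
  }
  invisible(c(ped = ped_path, map = map_path))
}

#' Read a pedigree file and return it topologically sorted
#'
#' Accepts whitespace- or comma-separated animal/sire/dam triples; `0` or an
#' empty field denotes an unknown parent. Parents that are named but have no
#' record of their own are added as founder records. The result is ordered so
#' that every parent precedes its offspring.
#'
#' @param path pedigree file path.
#' @return data.frame with character columns `id`, `sire`, `dam` (`NA` =
#'   unknown parent), parents before offspring.
#' @export
read_pedigree <- function(path) {
  if (!file.exists(path)) stop("pedigree file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sep <- if (any(grepl(",", lines))) "," else ""
  df <- utils::read.table(text = lines, header = FALSE, sep = sep,
                          stringsAsFactors = FALSE, strip.white = TRUE,
                          colClasses = "character", fill = TRUE)
  if (ncol(df) < 3) stop("pedigree file must have 3 columns (id, sire, dam)")
  ped <- data.frame(id = df[[1]], sire = df[[2]], dam = df[[3]],
                    stringsAsFactors = FALSE)
  unk <- function(x) ifelse(is.na(x) | x == "0" | x == "", NA_character_, x)
  ped$sire <- unk(ped$sire)
  ped$dam <- unk(ped$dam)
  if (anyDuplicated(ped$id)) stop("duplicated animal ids in pedigree")
  parents <- setdiff(c(ped$sire, ped$dam), c(ped$id, NA))
  if (length(parents))
    ped <- rbind(data.frame(id = parents, sire = NA_character_,
                            dam = NA_character_, stringsAsFactors = FALSE),
                 ped)
  sort_pedigree(ped)
}

#' Topologically sort a pedigree (parents before offspring)
#'
#' @param ped data.frame with columns `id`, `sire`, `dam`.
#' @return the same records reordered; error (listing one cycle) if the
#'   pedigree is cyclic.
#' @export
sort_pedigree <- function(ped) {
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$id)
  si <- idx[ped$sire]
  di <- idx[ped$dam]
  placed <- logical(n)
  out <- integer(n)
  k <- 0L
  repeat {
    ready <- !placed &
      (is.na(si) | placed[ifelse(is.na(si), 1L, si)]) &
      (is.na(di) | placed[ifelse(is.na(di), 1L, di)])
    if (!any(ready)) break
    r <- which(ready)
    out[k + seq_along(r)] <- r
    k <- k + length(r)
    placed[r] <- TRUE
  }
  if (k < n) {
    # a cycle remains among the unplaced animals; walk one out for the message
    rem <- which(!placed)
    cur <- rem[1]
    path <- character()
    repeat {
      path <- c(path, ped$id[cur])
      nxt <- if (!is.na(si[cur]) && !placed[si[cur]]) si[cur] else di[cur]
      if (is.na(nxt)) nxt <- si[cur]
      cur <- nxt
      if (ped$id[cur] %in% path) {
        path <- c(path, ped$id[cur])
        break
      }
    }
    stop("pedigree contains a cycle: ", paste(rev(path), collapse = " -> "))
  }
  res <- ped[out, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Apply genotype quality control
#'
#' Filters, in this fixed order: (1) optionally drop SNPs on non-autosomal or
#' unplaced chromosomes; (2) drop SNPs with call rate below
#' `min_snp_call_rate`; (3) drop samples with a missing fraction strictly
#' greater than `max_sample_missing`. No MAF filter is applied: in a
#' single-population design rare alleles are informative for homozygosity
#' and removing them would bias run detection.
#'
#' @param genotypes samples x SNPs matrix coded 0/1/2/NA.
#' @param map marker map aligned with the genotype columns.
#' @param min_snp_call_rate SNPs with call rate `<` this are removed
#'   (default 0.95).
#' @param max_sample_missing samples with missing fraction `>` this are
#'   removed (default 0.15; a sample at exactly the threshold is retained).
#' @param drop_nonautosomal drop chromosomes in `exclude_chroms`?
#' @param exclude_chroms chromosome labels treated as non-autosomal or
#'   unplaced.
#' @return list with `genotypes`, `map`, and `report` (counts removed at each
#'   step, in order).
#' @export
apply_qc <- function(genotypes, map, min_snp_call_rate = 0.95,
                     max_sample_missing = 0.15, drop_nonautosomal = TRUE,
                     exclude_chroms = c("X", "Y", "MT", "0")) {
  stopifnot(min_snp_call_rate >= 0, min_snp_call_rate <= 1,
            max_sample_missing >= 0, max_sample_missing <= 1)
  validate_marker_map(map)
  validate_genotypes(genotypes, map)
  n_snp_in <- ncol(genotypes)
  n_sam_in <- nrow(genotypes)

  keep_auto <- if (drop_nonautosomal) !(map$chrom %in% exclude_chroms)
               else rep(TRUE, nrow(map))
  n_nonauto <- sum(!keep_auto)
  genotypes <- genotypes[, keep_auto, drop = FALSE]
  map <- map[keep_auto, , drop = FALSE]

  call_rate <- colMeans(!is.na(genotypes))
  keep_snp <- call_rate >= min_snp_call_rate
  n_lowcall <- sum(!keep_snp)
  genotypes <- genotypes[, keep_snp, drop = FALSE]
  map <- map[keep_snp, , drop = FALSE]
  if (ncol(genotypes) == 0)
    stop("all SNPs removed by quality control: empty panel")

  miss_frac <- rowMeans(is.na(genotypes))
  keep_sam <- miss_frac <= max_sample_missing   # strictly more than -> removed
  n_badsam <- sum(!keep_sam)
  genotypes <- genotypes[keep_sam, , drop = FALSE]

  rownames(map) <- NULL
  report <- list(
    n_snps_in = n_snp_in, n_samples_in = n_sam_in,
    n_snps_nonautosomal_removed = n_nonauto,
    n_snps_low_call_rate_removed = n_lowcall,
    n_samples_high_missing_removed = n_badsam,
    n_snps_out = ncol(genotypes), n_samples_out = nrow(genotypes),
    min_snp_call_rate = min_snp_call_rate,
    max_sample_missing = max_sample_missing)
  list(genotypes = genotypes, map = map, report = report)
}

#' Write a QC report as JSON
#'
#' @param report the `report` element returned by [apply_qc()].
#' @param path output path.
#' @export
write_qc_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
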