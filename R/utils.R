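# Shared validators and small helpers used across modules.

# Chromosome labels are opaque strings; numeric labels sort numerically,
# non-numeric labels after them alphabetically.
chrom_rank <- function(chrom) {
  num <- suppressWarnings(as.numeric(chrom))
  order(is.na(num), num, chrom)
}

#' Sort a marker map by (chromosome, position)
#'
#' Numeric chromosome labels sort numerically, others alphabetically after
#' them; positions sort increasingly within chromosome.
#'
#' @param map marker map data.frame with columns `snp_id`, `chrom`, `pos_bp`.
#' @return index vector such that `map[sort_map_order(map), ]` is sorted.
#' @keywords internal
sort_map_order <- function(map) {
  num <- suppressWarnings(as.numeric(map$chrom))
  order(is.na(num), num, map$chrom, map$pos_bp)
}

validate_marker_map <- function(map, sorted = TRUE) {
  stopifnot(is.data.frame(map))
  req <- c("snp_id", "chrom", "pos_bp")
  if (!all(req %in% names(map)))
    stop("marker map must have columns snp_id, chrom, pos_bp")
  if (anyDuplicated(map$snp_id))
    stop("duplicated snp_id in marker map")
  if (any(map$pos_bp < 1)) stop("pos_bp must be >= 1 (1-based coordinates)")
  if (sorted && nrow(map) > 1) {
    for (ch in unique(map$chrom)) {
      p <- map$pos_bp[map$chrom == ch]
      if (any(diff(p) <= 0))
        stop("positions not strictly increasing on chromosome ", ch)
    }
  }
  invisible(map)
}

validate_genotypes <- function(geno, map = NULL) {
  if (!is.matrix(geno)) stop("genotypes must be a matrix")
  vals <- geno[!is.na(geno)]
  if (length(vals) && !all(vals %in% c(0L, 1L, 2L)))
    stop("genotype codes outside {0,1,2,NA} found")
  if (!is.null(map) && ncol(geno) != nrow(map))
    stop("genotype columns (", ncol(geno), ") do not match marker map rows (",
         nrow(map), ")")
  invisible(geno)
}

# Cheap deterministic fingerprint of a SNP panel, used for run-set provenance.
panel_signature <- function(map) {
  paste(nrow(map),
        if (nrow(map)) map$snp_id[1] else "",
        if (nrow(map)) map$snp_id[nrow(map)] else "",
        sum(as.numeric(map$pos_bp)) %% 2^31,
        sep = ":")
}

empty_runs <- function() {
  data.frame(animal = character(), chrom = character(),
             start_bp = numeric(), end_bp = numeric(), length_bp = numeric(),
             n_snps = integer(), n_het = integer(), n_hom = integer(),
             n_missing = integer(), kind = character(),
             stringsAsFactors = FALSE)
}

new_run_set <- function(df, params, map, kind) {
  df <- df[order(df$animal, match(df$chrom, unique(map$chrom)), df$start_bp), ,
           drop = FALSE]
  rownames(df) <- NULL
  attr(df, "params") <- params
  attr(df, "panel_hash") <- panel_signature(map)
  class(df) <- c("run_set", class(df))
  df
}

#' Convert 1-based inclusive segments to BED (0-based half-open)
#'
#' @param df data.frame with columns `chrom`, `start_bp`, `end_bp` (1-based,
#'   inclusive endpoints) and optionally further columns, which are kept.
#' @return data.frame with `chrom`, `start`, `end` in BED convention.
#' @export
runs_to_bed <- function(df) {
  out <- data.frame(chrom = df$chrom, start = df$start_bp - 1,
                    end = df$end_bp, stringsAsFactors = FALSE)
  extra <- setdiff(names(df), c("chrom", "start_bp", "end_bp"))
  cbind(out, df[, extra, drop = FALSE])
}

#' Convert BED intervals back to 1-based inclusive segments
#'
#' Inverse of [runs_to_bed()].
#'
#' @param df data.frame with columns `chrom`, `start`, `end` (BED convention).
#' @return data.frame with `chrom`, `start_bp`, `end_bp`.
#' @export
bed_to_runs <- function(df) {
  out <- data.frame(chrom = df$chrom, start_bp = df$start + 1,
                    end_bp = df$end, stringsAsFactors = FALSE)
  extra <- setdiff(names(df), c("chrom", "start", "end"))
  cbind(out, df[, extra, drop = FALSE])
}
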