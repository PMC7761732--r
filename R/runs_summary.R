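# Summaries over detected run sets: size-class tables, ROH-based inbreeding
# (FROH, overall and per length class), per-SNP in-run frequency, island
# detection, and the exponential length <-> generations relation.

#' Tabulate runs by size class
#'
#' Bins are left-closed, right-open `[a, b)`; the last bin is open-ended.
#' Runs shorter than the first boundary are counted in an `underflow` row.
#'
#' @param runset a `run_set` (or any data.frame with `length_bp`).
#' @param boundaries_mb strictly increasing class boundaries in Mb; the
#'   default gives the seven classes 2-4, 4-8, 8-12, 12-16, 16-20, 20-30 and
#'   >30 Mb.
#' @return data.frame per class: `class`, `lower_mb`, `upper_mb`, `n`,
#'   `avg_size_kb`, `freq` (`n` / total runs in classes, underflow excluded
#'   from the total).
#' @export
classify_by_size <- function(runset, boundaries_mb = c(2, 4, 8, 12, 16, 20, 30)) {
  stopifnot(length(boundaries_mb) >= 1, !is.unsorted(boundaries_mb, strictly = TRUE))
  len_mb <- runset$length_bp / 1e6
  lower <- boundaries_mb
  upper <- c(boundaries_mb[-1], Inf)
  labels <- c(paste0(boundaries_mb[-length(boundaries_mb)], "-",
                     boundaries_mb[-1]),
              paste0(">", boundaries_mb[length(boundaries_mb)]))
  bin <- findInterval(len_mb, boundaries_mb)   # 0 = underflow
  n <- vapply(seq_along(labels), function(k) sum(bin == k), integer(1))
  avg <- vapply(seq_along(labels), function(k)
    if (n[k]) mean(len_mb[bin == k]) * 1000 else NA_real_, numeric(1))
  total <- sum(n)
  out <- data.frame(class = labels, lower_mb = lower, upper_mb = upper,
                    n = n, avg_size_kb = avg,
                    freq = if (total) n / total else rep(0, length(n)),
                    stringsAsFactors = FALSE)
  n_under <- sum(bin == 0)
  if (n_under)
    out <- rbind(data.frame(class = paste0("<", boundaries_mb[1]),
                            lower_mb = 0, upper_mb = boundaries_mb[1],
                            n = n_under,
                            avg_size_kb = mean(len_mb[bin == 0]) * 1000,
                            freq = NA_real_, stringsAsFactors = FALSE),
                 out)
  attr(out, "n_underflow") <- n_under
  out
}

#' ROH-based inbreeding coefficients (FROH)
#'
#' `froh_total` is the summed run length of an animal divided by `l_auto_mb`
#' (the autosomal genome length covered by the SNP panel); per-length-class
#' FROH uses only the runs falling in each bin. Bins are left-closed
#' `[a, b)` with the last bin open-ended, so the bin values sum to
#' `froh_total` whenever the bins cover all run lengths.
#'
#' @param runset a `run_set`.
#' @param l_auto_mb autosomal genome length in Mb covered by the panel.
#' @param bins_mb left bin edges in Mb (default 2, 4, 8, 16: classes 2-4,
#'   4-8, 8-16, >16 Mb).
#' @param animals animal ids to report (so animals with zero runs appear
#'   with FROH 0); defaults to the animals present in the run set.
#' @return data.frame: `animal`, `froh_total`, one `froh_<bin>` column per
#'   bin.
#' @export
froh <- function(runset, l_auto_mb, bins_mb = c(2, 4, 8, 16), animals = NULL) {
  stopifnot(l_auto_mb > 0)
  if (nrow(runset) && any(runset$length_bp / 1e6 > l_auto_mb))
    stop("run longer than the stated autosomal genome length")
  if (is.null(animals)) animals <- sort(unique(runset$animal))
  labels <- c(paste0(bins_mb[-length(bins_mb)], "_", bins_mb[-1]),
              paste0(bins_mb[length(bins_mb)], "plus"))
  out <- data.frame(animal = animals, froh_total = 0,
                    stringsAsFactors = FALSE)
  for (lb in labels) out[[paste0("froh_", lb)]] <- 0
  if (nrow(runset)) {
    len_mb <- runset$length_bp / 1e6
    bin <- findInterval(len_mb, bins_mb)
    tot <- tapply(len_mb, runset$animal, sum)
    out$froh_total <- unname(tot[out$animal]) / l_auto_mb
    out$froh_total[is.na(out$froh_total)] <- 0
    for (k in seq_along(labels)) {
      sel <- bin == k
      if (any(sel)) {
        t_k <- tapply(len_mb[sel], runset$animal[sel], sum)
        v <- unname(t_k[out$animal]) / l_auto_mb
        v[is.na(v)] <- 0
        out[[paste0("froh_", labels[k])]] <- v
      }
    }
  }
  out
}

#' Per-SNP in-run frequency
#'
#' For every SNP, the number of runs covering its position divided by the
#' number of animals: the locus "homozygosity" (or heterozygosity, for
#' ROHet sets) profile in `[0, 1]` along the genome.
#'
#' @param runset a `run_set`.
#' @param map sorted marker map.
#' @param n_animals number of animals in the panel (denominator).
#' @return data.frame `snp_id`, `chrom`, `pos_bp`, `freq`.
#' @export
snp_run_frequency <- function(runset, map, n_animals) {
  stopifnot(n_animals >= 1)
  validate_marker_map(map)
  cnt <- numeric(nrow(map))
  if (nrow(runset)) {
    for (ch in unique(runset$chrom)) {
      cols <- which(map$chrom == ch)
      if (!length(cols))
        stop("run on chromosome ", ch, " absent from the marker map")
      pos <- map$pos_bp[cols]
      rr <- runset[runset$chrom == ch, , drop = FALSE]
      if (any(rr$start_bp < pos[1] & rr$end_bp < pos[1]) ||
          any(rr$start_bp > pos[length(pos)]))
        stop("run outside the mapped positions on chromosome ", ch)
      d <- numeric(length(pos) + 1)
      lo <- findInterval(rr$start_bp - 0.5, pos) + 1  # first SNP >= start
      hi <- findInterval(rr$end_bp + 0.5, pos)        # last SNP <= end
      for (r in seq_len(nrow(rr))) {
        if (hi[r] >= lo[r]) {
          d[lo[r]] <- d[lo[r]] + 1
          d[hi[r] + 1] <- d[hi[r] + 1] - 1
        }
      }
      cnt[cols] <- cumsum(d[-length(d)])
    }
  }
  data.frame(snp_id = map$snp_id, chrom = map$chrom, pos_bp = map$pos_bp,
             freq = cnt / n_animals, stringsAsFactors = FALSE)
}

#' Detect run islands from a per-SNP frequency profile
#'
#' The threshold is either the empirical `q`-quantile of the frequency
#' vector (inverse empirical CDF, i.e. `stats::quantile(..., type = 1)`;
#' membership is `>=` the threshold) or a fixed value (membership is
#' strictly `>`). Maximal stretches of consecutive member SNPs on one
#' chromosome become islands; stretches separated by even a single
#' non-member SNP are not merged.
#'
#' @param freq_df output of [snp_run_frequency()].
#' @param mode `"quantile"` or `"fixed"`.
#' @param q quantile for `mode = "quantile"` (default 0.999).
#' @param t threshold for `mode = "fixed"` (default 0.25).
#' @param kind label carried into the output (`"ROH"` or `"ROHet"`).
#' @return data.frame `chrom`, `start_bp`, `end_bp`, `n_snps`, `peak_freq`,
#'   `kind`; attribute `threshold` holds the threshold used.
#' @export
detect_islands <- function(freq_df, mode = c("quantile", "fixed"), q = 0.999,
                           t = 0.25, kind = "ROH") {
  mode <- match.arg(mode)
  f <- freq_df$freq
  if (mode == "quantile") {
    if (all(f == 0)) {
      warning("all-zero frequency vector: no islands")
      return(data.frame(chrom = character(), start_bp = numeric(),
                        end_bp = numeric(), n_snps = integer(),
                        peak_freq = numeric(), kind = character(),
                        stringsAsFactors = FALSE))
    }
    thr <- unname(stats::quantile(f, q, type = 1))
    member <- f >= thr
  } else {
    thr <- t
    member <- f > thr
  }
  out <- list()
  for (ch in unique(freq_df$chrom)) {
    sel <- which(freq_df$chrom == ch)
    m <- member[sel]
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in which(r$values)) {
      idx <- sel[starts[k]:ends[k]]
      out[[length(out) + 1]] <- data.frame(
        chrom = ch, start_bp = freq_df$pos_bp[idx[1]],
        end_bp = freq_df$pos_bp[idx[length(idx)]], n_snps = length(idx),
        peak_freq = max(freq_df$freq[idx]), kind = kind,
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out)
         else data.frame(chrom = character(), start_bp = numeric(),
                         end_bp = numeric(), n_snps = integer(),
                         peak_freq = numeric(), kind = character(),
                         stringsAsFactors = FALSE)
  attr(res, "threshold") <- thr
  res
}

#' Generations to the common ancestor implied by a run length
#'
#' The length of autozygous IBD segments is exponentially distributed with
#' mean `1/(2g)` Morgans, `g` generations after the common ancestor; so a
#' segment of a given length points, in expectation, to
#' `g = 100 / (2 * length_cM)` generations back. At 1 cM/Mb a 4 Mb run
#' corresponds to 12.5 generations, a 16 Mb run to about 3.
#'
#' @param length_mb run length in Mb (> 0).
#' @param cm_per_mb genetic map density (default 1 cM/Mb).
#' @return generations `g`.
#' @export
expected_generations <- function(length_mb, cm_per_mb = 1) {
  if (any(length_mb <= 0)) stop("run length must be positive")
  100 / (2 * length_mb * cm_per_mb)
}
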