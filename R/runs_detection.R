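# Run detection: runs of homozygosity by the sliding-window method, and
# runs of either state by the window-free consecutive method.

#' Parameters for sliding-window ROH detection
#'
#' Defaults correspond to a widely used medium-density-array base scenario:
#' 50-SNP windows, a window-hit proportion of 0.05 (low, so SNPs at the
#' edges of true segments are still called), at least 30 SNPs and 2 Mb per
#' run, a maximum gap of 1000 kb between consecutive SNPs, a minimum mean
#' density of one SNP per 100 kb, and at most one heterozygous and one
#' missing call allowed in a run.
#'
#' @param window_snps SNPs per sliding window.
#' @param window_hit_proportion minimum fraction of eligible windows
#'   covering a SNP for it to be called in-run (inclusive threshold).
#' @param min_snps minimum SNPs in an emitted run.
#' @param min_length_mb minimum run length (Mb), `end_bp - start_bp`.
#' @param max_gap_kb maximum gap (kb) between consecutive SNPs in a run.
#' @param density_kb_per_snp maximum mean kb per SNP over the run.
#' @param max_het,max_missing heterozygous and missing calls allowed, applied
#'   both when scoring windows and (unless `window_only = TRUE`) to each
#'   emitted run, so the per-run guarantee holds literally.
#' @param window_only apply the het/missing allowances at window level only.
#' @return list of class `roh_params`.
#' @export
roh_params <- function(window_snps = 50, window_hit_proportion = 0.05,
                       min_snps = 30, min_length_mb = 2, max_gap_kb = 1000,
                       density_kb_per_snp = 100, max_het = 1,
                       max_missing = 1, window_only = FALSE) {
  p <- list(window_snps = window_snps,
            window_hit_proportion = window_hit_proportion,
            min_snps = min_snps, min_length_mb = min_length_mb,
            max_gap_kb = max_gap_kb, density_kb_per_snp = density_kb_per_snp,
            max_het = max_het, max_missing = max_missing,
            window_only = window_only)
  stopifnot(window_snps >= 1, window_hit_proportion > 0,
            window_hit_proportion <= 1, min_snps >= 1, min_length_mb > 0,
            max_gap_kb > 0, density_kb_per_snp > 0, max_het >= 0,
            max_missing >= 0)
  class(p) <- "roh_params"
  p
}

#' Parameters for consecutive-method run detection
#'
#' Defaults are the usual heterozygosity-rich-region settings: at least 15
#' consecutive SNPs and 250 kb, a maximum gap of 1000 kb, and at most three
#' opposite-state (homozygous) and two missing calls per run.
#'
#' @param target run state: `"het"` (heterozygosity-rich regions) or
#'   `"hom"`.
#' @param min_snps minimum SNPs in an emitted run.
#' @param min_length_kb minimum run length (kb), `end_bp - start_bp`.
#' @param max_gap_kb maximum gap (kb) between consecutive SNPs in a run.
#' @param max_opposite opposite-state calls allowed inside a run.
#' @param max_missing missing calls allowed inside a run.
#' @return list of class `consecutive_params`.
#' @export
consecutive_params <- function(target = c("het", "hom"), min_snps = 15,
                               min_length_kb = 250, max_gap_kb = 1000,
                               max_opposite = 3, max_missing = 2) {
  target <- match.arg(target)
  p <- list(target = target, min_snps = min_snps,
            min_length_kb = min_length_kb, max_gap_kb = max_gap_kb,
            max_opposite = max_opposite, max_missing = max_missing)
  stopifnot(min_snps >= 1, min_length_kb > 0, max_gap_kb > 0,
            max_opposite >= 0, max_missing >= 0)
  class(p) <- "consecutive_params"
  p
}

# Assemble candidate SNP indices into emitted segments. `candidate` is a
# logical vector over one chromosome's SNPs. Candidate stretches are split
# at gaps; each resulting segment is then partitioned greedily into maximal
# pieces holding at most max_het heterozygous and max_missing missing calls
# (so the per-run allowance holds literally while relaxing an allowance can
# never shrink total detected length), pieces are trimmed to homozygous
# non-missing endpoints, and finally filtered by the size/density
# constraints.
assemble_segments <- function(candidate, pos, het, mis, min_snps,
                              min_length_bp, max_gap_bp,
                              density_kb_per_snp = Inf,
                              max_het = Inf, max_missing = Inf,
                              trim = TRUE) {
  out <- list()
  emit <- function(i0, i1) {
    if (trim) {
      # trim to homozygous, non-missing endpoints
      ok <- which(!het[i0:i1] & !mis[i0:i1])
      if (!length(ok)) return()
      i0t <- i0 + ok[1] - 1L
      i1t <- i0 + ok[length(ok)] - 1L
    } else {
      i0t <- i0; i1t <- i1
    }
    ns <- i1t - i0t + 1L
    len <- pos[i1t] - pos[i0t]
    if (ns < min_snps || len < min_length_bp) return()
    if ((len / 1000) / ns > density_kb_per_snp) return()
    nh <- sum(het[i0t:i1t]); nm <- sum(mis[i0t:i1t])
    out[[length(out) + 1L]] <<- c(i0t, i1t, ns, nh, nm)
  }
  r <- rle(candidate)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (k in which(r$values)) {
    a <- starts[k]; b <- ends[k]
    gaps <- which(diff(pos[a:b]) > max_gap_bp)
    bounds <- c(a - 1, a - 1 + gaps, b)   # gap-split boundaries
    for (s in seq_len(length(bounds) - 1)) {
      i0 <- bounds[s] + 1; i1 <- bounds[s + 1]
      # greedy partition under the het/missing allowances
      p0 <- i0
      nh <- 0L; nm <- 0L
      j <- i0
      while (j <= i1) {
        nh2 <- nh + het[j]; nm2 <- nm + mis[j]
        if (nh2 > max_het || nm2 > max_missing) {
          if (j > p0) emit(p0, j - 1L)
          else j <- j + 1L   # a single SNP alone violates; skip it
          p0 <- j
          nh <- 0L; nm <- 0L
        } else {
          nh <- nh2; nm <- nm2
          j <- j + 1L
        }
      }
      if (i1 >= p0) emit(p0, i1)
    }
  }
  out
}

#' Detect runs of homozygosity with the sliding-window method
#'
#' Per animal and chromosome: (1) every window of `window_snps` consecutive
#' SNPs is scored eligible iff it contains at most `max_het` heterozygous
#' and `max_missing` missing calls; (2) each SNP's hit rate is the fraction
#' of windows containing it that are eligible (near chromosome ends the
#' reduced number of existing windows is the denominator, so edge SNPs can
#' still be called); (3) SNPs with hit rate `>= window_hit_proportion` are
#' candidates; (4) maximal stretches of consecutive candidates are split at
#' gaps wider than `max_gap_kb`; (5) each segment is partitioned greedily
#' into maximal pieces that themselves contain at most `max_het`
#' heterozygous and `max_missing` missing calls (so the per-run allowance
#' holds literally for every emitted run, and relaxing an allowance never
#' shrinks the total detected length), pieces are trimmed to homozygous
#' non-missing endpoints, and each piece is emitted iff it has at least
#' `min_snps` SNPs, spans at least `min_length_mb`, and has mean density at
#' most `density_kb_per_snp`. With `window_only = TRUE` the allowances act
#' at window level only (step 5 keeps whole segments, untrimmed).
#'
#' @param genotypes samples x SNPs matrix coded 0/1/2/NA.
#' @param map sorted marker map aligned with the genotype columns.
#' @param params a [roh_params()].
#' @return a `run_set` data.frame (`animal`, `chrom`, `start_bp`, `end_bp`,
#'   `length_bp`, `n_snps`, `n_het`, `n_hom`, `n_missing`, `kind = "ROH"`),
#'   sorted by (animal, chromosome, start); runs of one animal never
#'   overlap. Chromosomes with fewer SNPs than `window_snps` yield no
#'   windows and hence no runs (one warning is raised).
#' @export
detect_roh_sliding <- function(genotypes, map, params = roh_params()) {
  stopifnot(inherits(params, "roh_params"))
  validate_marker_map(map)
  validate_genotypes(genotypes, map)
  w <- params$window_snps
  max_gap_bp <- params$max_gap_kb * 1000
  min_len_bp <- params$min_length_mb * 1e6
  chroms <- unique(map$chrom)
  short <- character(0)
  res <- list()
  ids <- rownames(genotypes)
  if (is.null(ids)) ids <- paste0("S", seq_len(nrow(genotypes)))

  for (ch in chroms) {
    cols <- which(map$chrom == ch)
    L <- length(cols)
    if (L < w) { short <- c(short, ch); next }
    pos <- map$pos_bp[cols]
    nW <- L - w + 1
    # window index ranges covering SNP k, shared across animals
    lo <- pmax(1L, seq_len(L) - w + 1L)
    hi <- pmin(seq_len(L), nW)
    n_win <- hi - lo + 1
    for (i in seq_len(nrow(genotypes))) {
      g <- genotypes[i, cols]
      het <- !is.na(g) & g == 1L
      mis <- is.na(g)
      ch_ <- cumsum(c(0L, het))
      cm_ <- cumsum(c(0L, mis))
      win_het <- ch_[(1:nW) + w] - ch_[1:nW]
      win_mis <- cm_[(1:nW) + w] - cm_[1:nW]
      elig <- as.integer(win_het <= params$max_het &
                           win_mis <= params$max_missing)
      ce <- cumsum(c(0L, elig))
      n_elig <- ce[hi + 1] - ce[lo]
      candidate <- n_elig / n_win >= params$window_hit_proportion
      segs <- assemble_segments(
        candidate, pos, het, mis, params$min_snps, min_len_bp, max_gap_bp,
        density_kb_per_snp = params$density_kb_per_snp,
        max_het = if (params$window_only) Inf else params$max_het,
        max_missing = if (params$window_only) Inf else params$max_missing,
        trim = !params$window_only)
      for (sg in segs) {
        res[[length(res) + 1]] <- data.frame(
          animal = ids[i], chrom = ch, start_bp = pos[sg[1]],
          end_bp = pos[sg[2]], length_bp = pos[sg[2]] - pos[sg[1]],
          n_snps = sg[3], n_het = sg[4], n_hom = sg[3] - sg[4] - sg[5],
          n_missing = sg[5], kind = "ROH", stringsAsFactors = FALSE)
      }
    }
  }
  if (length(short))
    warning("chromosome(s) with fewer SNPs than the window: ",
            paste(short, collapse = ", "), " (no runs called there)")
  df <- if (length(res)) do.call(rbind, res) else empty_runs()
  new_run_set(df, params, map, "ROH")
}

#' Detect runs with the consecutive (window-free) method
#'
#' Per animal and chromosome, SNPs are scanned left to right extending a
#' current segment; the segment is broken when adding the next SNP would
#' exceed `max_opposite` opposite-state calls or `max_missing` missing
#' calls, or would jump a gap wider than `max_gap_kb`. At each break the
#' segment is trimmed so both endpoints are target-state SNPs, then emitted
#' iff it still has at least `min_snps` SNPs and spans at least
#' `min_length_kb`; scanning restarts at the SNP that caused the break.
#'
#' @inheritParams detect_roh_sliding
#' @param params a [consecutive_params()].
#' @return a `run_set` data.frame as in [detect_roh_sliding()], with
#'   `kind = "ROHet"` when `target = "het"` and `kind = "ROH"` otherwise.
#' @export
detect_runs_consecutive <- function(genotypes, map,
                                    params = consecutive_params()) {
  stopifnot(inherits(params, "consecutive_params"))
  validate_marker_map(map)
  validate_genotypes(genotypes, map)
  max_gap_bp <- params$max_gap_kb * 1000
  min_len_bp <- params$min_length_kb * 1000
  kind <- if (params$target == "het") "ROHet" else "ROH"
  ids <- rownames(genotypes)
  if (is.null(ids)) ids <- paste0("S", seq_len(nrow(genotypes)))
  res <- list()

  for (ch in unique(map$chrom)) {
    cols <- which(map$chrom == ch)
    pos <- map$pos_bp[cols]
    L <- length(cols)
    for (i in seq_len(nrow(genotypes))) {
      g <- genotypes[i, cols]
      mis <- is.na(g)
      is_target <- !mis & (if (params$target == "het") g == 1L else g != 1L)
      is_opp <- !mis & !is_target
      s <- 1L
      while (s <= L) {
        n_opp <- 0L; n_mis <- 0L
        j <- s
        while (j <= L) {
          if (j > s && pos[j] - pos[j - 1] > max_gap_bp) break
          add_opp <- n_opp + is_opp[j]
          add_mis <- n_mis + mis[j]
          if (add_opp > params$max_opposite ||
              add_mis > params$max_missing) break
          n_opp <- add_opp; n_mis <- add_mis
          j <- j + 1L
        }
        e <- j - 1L
        if (e >= s) {
          tgt <- which(is_target[s:e])
          if (length(tgt)) {
            i0 <- s + tgt[1] - 1L
            i1 <- s + tgt[length(tgt)] - 1L
            ns <- i1 - i0 + 1L
            len <- pos[i1] - pos[i0]
            if (ns >= params$min_snps && len >= min_len_bp) {
              nh <- sum(!mis[i0:i1] & g[i0:i1] == 1L)
              nm <- sum(mis[i0:i1])
              res[[length(res) + 1]] <- data.frame(
                animal = ids[i], chrom = ch, start_bp = pos[i0],
                end_bp = pos[i1], length_bp = len, n_snps = ns,
                n_het = nh, n_hom = ns - nh - nm, n_missing = nm,
                kind = kind, stringsAsFactors = FALSE)
            }
          }
        }
        s <- if (j == s) s + 1L else j  # restart at the SNP that broke the run
      }
    }
  }
  df <- if (length(res)) do.call(rbind, res) else empty_runs()
  new_run_set(df, params, map, kind)
}

#' Re-validate a run set against the genotype matrix
#'
#' Recounts the heterozygous, homozygous and missing calls inside every run
#' and checks them (and the SNP counts and lengths) against the stored
#' values.
#'
#' @param runset a `run_set`.
#' @inheritParams detect_roh_sliding
#' @return TRUE invisibly; error describing the first mismatch otherwise.
#' @export
validate_runs <- function(runset, genotypes, map) {
  ids <- rownames(genotypes)
  for (r in seq_len(nrow(runset))) {
    idx <- which(map$chrom == runset$chrom[r] &
                   map$pos_bp >= runset$start_bp[r] &
                   map$pos_bp <= runset$end_bp[r])
    g <- genotypes[match(runset$animal[r], ids), idx]
    nh <- sum(g == 1L, na.rm = TRUE)
    nm <- sum(is.na(g))
    ok <- length(idx) == runset$n_snps[r] && nh == runset$n_het[r] &&
      nm == runset$n_missing[r] &&
      runset$length_bp[r] == runset$end_bp[r] - runset$start_bp[r]
    if (!ok) stop("run ", r, " does not re-validate against the genotypes")
  }
  invisible(TRUE)
}

#' Write a run set as TSV
#'
#' @param runset a `run_set`.
#' @param path output path.
#' @export
write_runs <- function(runset, path) {
  out <- data.frame(animal = runset$animal, chrom = runset$chrom,
                    start = runset$start_bp, end = runset$end_bp,
                    length_kb = runset$length_bp / 1000,
                    n_snps = runset$n_snps, n_het = runset$n_het,
                    n_missing = runset$n_missing, kind = runset$kind)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
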