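# Independent brute-force oracles. These re-derive expected results by the
# most transparent (quadratic, loop-based) route available, sharing no code
# with the package internals.

# Sliding-window ROH calling, step by step with explicit window index sets.
oracle_sliding <- function(geno_row, pos, p) {
  L <- length(geno_row)
  w <- p$window_snps
  if (L < w) return(data.frame())
  het <- !is.na(geno_row) & geno_row == 1
  mis <- is.na(geno_row)
  wins <- lapply(seq_len(L - w + 1), function(i) i:(i + w - 1))
  elig <- vapply(wins, function(ix)
    sum(het[ix]) <= p$max_het && sum(mis[ix]) <= p$max_missing, logical(1))
  cand <- vapply(seq_len(L), function(k) {
    covering <- which(vapply(wins, function(ix) k %in% ix, logical(1)))
    sum(elig[covering]) / length(covering) >= p$window_hit_proportion
  }, logical(1))
  oracle_assemble(cand, pos, het, mis, opp = het, # opposite of hom = het
                  min_snps = p$min_snps, min_len = p$min_length_mb * 1e6,
                  max_gap = p$max_gap_kb * 1000,
                  density = p$density_kb_per_snp,
                  max_opp = p$max_het, max_mis = p$max_missing)
}

# Shared naive assembly: gap-split candidate stretches, greedy partition
# under the allowances (recounting from scratch at every step), trim to
# target-state endpoints, filter.
oracle_assemble <- function(cand, pos, het, mis, opp, min_snps, min_len,
                            max_gap, density, max_opp, max_mis) {
  runs <- list()
  k <- 1
  while (k <= length(cand)) {
    if (!cand[k]) { k <- k + 1; next }
    e <- k
    while (e + 1 <= length(cand) && cand[e + 1]) e <- e + 1
    # gap split
    pieces <- list(); s0 <- k
    for (j in k:e) {
      if (j > s0 && pos[j] - pos[j - 1] > max_gap) {
        pieces[[length(pieces) + 1]] <- c(s0, j - 1); s0 <- j
      }
    }
    pieces[[length(pieces) + 1]] <- c(s0, e)
    for (pc in pieces) {
      s <- pc[1]
      while (s <= pc[2]) {
        j <- s
        best <- s - 1
        while (j <= pc[2] &&
               sum(opp[s:j]) <= max_opp && sum(mis[s:j]) <= max_mis) {
          best <- j; j <- j + 1
        }
        if (best < s) { s <- s + 1; next }
        tgt <- which(!opp[s:best] & !mis[s:best])
        if (length(tgt)) {
          i0 <- s + tgt[1] - 1; i1 <- s + tgt[length(tgt)] - 1
          ns <- i1 - i0 + 1
          len <- pos[i1] - pos[i0]
          if (ns >= min_snps && len >= min_len &&
              (len / 1000) / ns <= density)
            runs[[length(runs) + 1]] <- data.frame(
              start_bp = pos[i0], end_bp = pos[i1], n_snps = ns)
        }
        s <- best + 1
      }
    }
    k <- e + 1
  }
  if (length(runs)) do.call(rbind, runs) else data.frame()
}

# Consecutive-method runs by naive greedy extension with full recounts.
oracle_consecutive <- function(geno_row, pos, p) {
  L <- length(geno_row)
  mis <- is.na(geno_row)
  tgt <- !mis & (if (p$target == "het") geno_row == 1 else geno_row != 1)
  opp <- !mis & !tgt
  runs <- list()
  s <- 1
  while (s <= L) {
    j <- s; best <- s - 1
    while (j <= L) {
      if (j > s && pos[j] - pos[j - 1] > p$max_gap_kb * 1000) break
      if (sum(opp[s:j]) > p$max_opposite || sum(mis[s:j]) > p$max_missing)
        break
      best <- j; j <- j + 1
    }
    if (best >= s) {
      ix <- which(tgt[s:best])
      if (length(ix)) {
        i0 <- s + ix[1] - 1; i1 <- s + ix[length(ix)] - 1
        ns <- i1 - i0 + 1
        len <- pos[i1] - pos[i0]
        if (ns >= p$min_snps && len >= p$min_length_kb * 1000)
          runs[[length(runs) + 1]] <- data.frame(
            start_bp = pos[i0], end_bp = pos[i1], n_snps = ns)
      }
    }
    s <- if (best < s) s + 1 else max(best + 1, j)
  }
  if (length(runs)) do.call(rbind, runs) else data.frame()
}

# All maximal contiguous index ranges satisfying the run constraints
# (target-state endpoints, allowance counts, gaps, minimum size). On clean
# planted fixtures these are disjoint and equal the planted runs.
oracle_max_segments <- function(geno_row, pos, target, max_opp, max_mis,
                                max_gap, min_snps, min_len) {
  L <- length(geno_row)
  mis <- is.na(geno_row)
  tgt <- !mis & (if (target == "het") geno_row == 1 else geno_row != 1)
  opp <- !mis & !tgt
  ok <- function(i, j) {
    tgt[i] && tgt[j] && sum(opp[i:j]) <= max_opp && sum(mis[i:j]) <= max_mis &&
      (j == i || all(diff(pos[i:j]) <= max_gap)) &&
      (j - i + 1) >= min_snps && (pos[j] - pos[i]) >= min_len
  }
  segs <- list()
  for (i in seq_len(L)) for (j in i:L) if (ok(i, j))
    segs[[length(segs) + 1]] <- c(i, j)
  if (!length(segs)) return(data.frame())
  keep <- vapply(seq_along(segs), function(a)
    !any(vapply(seq_along(segs), function(b)
      b != a && segs[[b]][1] <= segs[[a]][1] && segs[[b]][2] >= segs[[a]][2],
      logical(1))), logical(1))
  segs <- segs[keep]
  do.call(rbind, lapply(segs, function(s)
    data.frame(start_bp = pos[s[1]], end_bp = pos[s[2]],
               n_snps = s[2] - s[1] + 1)))
}

# Per-SNP in-run frequency by direct interval stabbing.
oracle_snp_freq <- function(runset, map, n_animals) {
  vapply(seq_len(nrow(map)), function(k)
    sum(runset$chrom == map$chrom[k] & runset$start_bp <= map$pos_bp[k] &
          runset$end_bp >= map$pos_bp[k]) / n_animals, numeric(1))
}

# VanRaden G by double loops.
oracle_g <- function(geno) {
  p <- colMeans(geno, na.rm = TRUE) / 2
  M <- geno
  for (j in seq_len(ncol(M))) M[is.na(M[, j]), j] <- 2 * p[j]
  n <- nrow(M)
  G <- matrix(0, n, n)
  denom <- 2 * sum(p * (1 - p))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    s <- 0
    for (k in seq_len(ncol(M)))
      s <- s + (M[i, k] - 2 * p[k]) * (M[j, k] - 2 * p[k])
    G[i, j] <- s / denom
  }
  dimnames(G) <- list(rownames(geno), rownames(geno))
  G
}

# Monte-Carlo inbreeding by single-locus allele dropping (no linkage):
# founders get unique allele labels, each transmission picks one parental
# allele at random; F_i is the fraction of replicates in which animal i's
# two alleles are copies of the same founder allele.
oracle_allele_drop <- function(ped, n_rep = 1e5) {
  ids <- ped$id
  n <- length(ids)
  si <- match(ped$sire, ids)
  di <- match(ped$dam, ids)
  a1 <- matrix(0L, n, n_rep)
  a2 <- matrix(0L, n, n_rep)
  nxt <- 1L
  for (i in seq_len(n)) {
    if (is.na(si[i]) && is.na(di[i])) {
      a1[i, ] <- nxt; a2[i, ] <- nxt + 1L
      nxt <- nxt + 2L
    } else {
      pick1 <- stats::runif(n_rep) < 0.5
      a1[i, ] <- ifelse(pick1, a1[si[i], ], a2[si[i], ])
      pick2 <- stats::runif(n_rep) < 0.5
      a2[i, ] <- ifelse(pick2, a1[di[i], ], a2[di[i], ])
    }
  }
  f_hat <- rowMeans(a1 == a2)
  se <- sqrt(f_hat * (1 - f_hat) / n_rep)
  data.frame(id = ids, f_hat = f_hat, se = se)
}

# Pairwise ROH overlap numerators by direct interval intersection.
oracle_roh_overlap <- function(runset, animals) {
  n <- length(animals)
  num <- matrix(0, n, n, dimnames = list(animals, animals))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    ri <- runset[runset$animal == animals[i], , drop = FALSE]
    rj <- runset[runset$animal == animals[j], , drop = FALSE]
    tot <- 0
    for (a in seq_len(nrow(ri))) for (b in seq_len(nrow(rj))) {
      if (ri$chrom[a] != rj$chrom[b]) next
      ov <- min(ri$end_bp[a], rj$end_bp[b]) - max(ri$start_bp[a], rj$start_bp[b])
      if (ov > 0) tot <- tot + ov
    }
    num[i, j] <- tot
  }
  num
}

# Inverse-empirical-CDF (type 1) quantile by sorting.
oracle_quantile_type1 <- function(x, q) {
  xs <- sort(x)
  xs[max(1L, ceiling(q * length(xs)))]
}
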