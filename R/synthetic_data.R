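# Gene-drop simulation: pedigrees with controlled mating designs, founder
# haplotypes dropped through the pedigree with Poisson (Haldane) crossovers,
# and a truth track of autozygous (IBD) segments. Also deterministic
# "planted run" fixtures that make detector behaviour checkable exactly.

#' Build a simulation configuration
#'
#' Defaults emulate a small semi-feral cattle population genotyped on a
#' medium-density (~50k) SNP array: a few dozen founders, a shallow
#' pedigree (~4 discrete generations), 29 autosomes totalling ~2541 Mb,
#' ~100 kb inter-SNP spacing, a uniform founder allele-frequency spectrum,
#' and low genotyping error and missingness.
#'
#' @param n_founders number of founder animals (even, they are paired).
#' @param n_generations number of discrete non-founder generations.
#' @param offspring_per_mating children per mating.
#' @param mating_design `"random"`, `"circular"` (each parent mated to the
#'   next in a rotating ring, an inbreeding-limiting scheme), or
#'   `"full_sib_loop"` (founder pairs, then repeated full-sib matings within
#'   each family line, giving known expected inbreeding: F = 0.25 after the
#'   first sib mating).
#' @param n_chrom,snps_per_chrom,chrom_length_mb genome layout; SNPs are
#'   evenly spaced.
#' @param founder_maf_low,founder_maf_high uniform bounds for the counted
#'   allele frequency of each SNP in the founder pool, in (0, 0.5].
#' @param cm_per_mb map density (default 1 cM/Mb, the usual cattle-scale
#'   equivalence of genetic and physical distance).
#' @param genotyping_error_rate per-call probability that one allele of a
#'   genotype is flipped.
#' @param missing_rate per-call probability that a genotype is masked as
#'   missing. A masked call cannot also carry an error.
#' @param two_herds simulate two weakly connected herd clusters (founder
#'   pairs split into two herds; matings stay within herd except an
#'   occasional shared sire).
#' @param shared_sire_prob probability a mating uses a sire from the other
#'   herd when `two_herds = TRUE`.
#' @param seed integer seed; all outputs are bit-reproducible given the seed.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_founders = 50, n_generations = 4,
                       offspring_per_mating = 2,
                       mating_design = c("random", "circular", "full_sib_loop"),
                       n_chrom = 29, snps_per_chrom = 1690,
                       chrom_length_mb = 87.6,
                       founder_maf_low = 0.05, founder_maf_high = 0.5,
                       cm_per_mb = 1, genotyping_error_rate = 0.002,
                       missing_rate = 0.02, two_herds = FALSE,
                       shared_sire_prob = 0.1, seed = 1) {
  mating_design <- match.arg(mating_design)
  cfg <- list(n_founders = n_founders, n_generations = n_generations,
              offspring_per_mating = offspring_per_mating,
              mating_design = mating_design, n_chrom = n_chrom,
              snps_per_chrom = snps_per_chrom,
              chrom_length_mb = chrom_length_mb,
              founder_maf_low = founder_maf_low,
              founder_maf_high = founder_maf_high, cm_per_mb = cm_per_mb,
              genotyping_error_rate = genotyping_error_rate,
              missing_rate = missing_rate, two_herds = two_herds,
              shared_sire_prob = shared_sire_prob, seed = seed)
  stopifnot(n_founders >= 2, n_founders %% 2 == 0, n_generations >= 0,
            offspring_per_mating >= 1, n_chrom >= 1, snps_per_chrom >= 1,
            chrom_length_mb > 0,
            founder_maf_low > 0, founder_maf_high <= 0.5,
            founder_maf_low <= founder_maf_high, cm_per_mb > 0,
            genotyping_error_rate >= 0, genotyping_error_rate <= 1,
              missing_rate >= 0, missing_rate <= 1,
            shared_sire_prob >= 0, shared_sire_prob <= 1)
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a pedigree under a chosen mating design
#'
#' Founders form generation 0 and are paired; each subsequent generation is
#' produced by the configured mating design. Sexes alternate within each
#' sibship so that matings can always be formed.
#'
#' @param config a [sim_config()].
#' @return data.frame `id`, `sire`, `dam`, `generation`, `sex`, `herd`,
#'   topologically sorted (parents precede offspring).
#' @export
simulate_pedigree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_herds <- if (isTRUE(config$two_herds)) 2L else 1L
  founders <- data.frame(
    id = sprintf("G0_%03d", seq_len(config$n_founders)),
    sire = NA_character_, dam = NA_character_, generation = 0L,
    sex = rep(c("M", "F"), length.out = config$n_founders),
    herd = rep(seq_len(n_herds),
               each = ceiling(config$n_founders / n_herds))[
                 seq_len(config$n_founders)],
    stringsAsFactors = FALSE)
  ped <- founders
  prev <- founders
  # family line membership, used by the full-sib design
  family <- stats::setNames(rep(seq_len(config$n_founders / 2), each = 2),
                            founders$id)

  for (g in seq_len(config$n_generations)) {
    matings <- make_matings(prev, config, g, family)
    if (!nrow(matings)) break
    kids <- do.call(rbind, lapply(seq_len(nrow(matings)), function(k) {
      n_off <- config$offspring_per_mating
      data.frame(
        id = sprintf("G%d_%03d_%d", g, k, seq_len(n_off)),
        sire = matings$sire[k], dam = matings$dam[k], generation = g,
        sex = rep(c("M", "F"), length.out = n_off),
        herd = matings$herd[k], stringsAsFactors = FALSE)
    }))
    family <- c(family,
                stats::setNames(rep(matings$family, each = config$offspring_per_mating),
                                kids$id))
    ped <- rbind(ped, kids)
    prev <- kids
  }
  rownames(ped) <- NULL
  ped
}

# Pair animals of the previous generation into matings according to the
# design. Returns data.frame(sire, dam, herd, family).
make_matings <- function(prev, config, g, family) {
  males <- prev[prev$sex == "M", , drop = FALSE]
  females <- prev[prev$sex == "F", , drop = FALSE]
  switch(config$mating_design,
    full_sib_loop = {
      fams <- split(prev$id, family[prev$id])
      pairs <- lapply(fams, function(ids) {
        m <- ids[prev$sex[match(ids, prev$id)] == "M"]
        f <- ids[prev$sex[match(ids, prev$id)] == "F"]
        if (length(m) && length(f)) c(m[1], f[1]) else NULL
      })
      pairs <- pairs[!vapply(pairs, is.null, logical(1))]
      data.frame(sire = vapply(pairs, `[`, "", 1),
                 dam = vapply(pairs, `[`, "", 2),
                 herd = prev$herd[match(vapply(pairs, `[`, "", 1), prev$id)],
                 family = as.integer(names(pairs)),
                 stringsAsFactors = FALSE)
    },
    circular = {
      # ring of males and females, rotated by one position each generation
      n <- min(nrow(males), nrow(females))
      if (n == 0) return(data.frame())
      f_idx <- ((seq_len(n) - 1 + g) %% n) + 1
      data.frame(sire = males$id[seq_len(n)], dam = females$id[f_idx],
                 herd = males$herd[seq_len(n)],
                 family = seq_len(n), stringsAsFactors = FALSE)
    },
    random = {
      out <- lapply(sort(unique(prev$herd)), function(h) {
        m <- males[males$herd == h, , drop = FALSE]
        f <- females[females$herd == h, , drop = FALSE]
        other_m <- males[males$herd != h, , drop = FALSE]
        n <- min(nrow(m), nrow(f))
        if (n == 0) return(NULL)
        mi <- sample(nrow(m))[seq_len(n)]
        fi <- sample(nrow(f))[seq_len(n)]
        sires <- m$id[mi]
        if (nrow(other_m) && config$two_herds) {
          swap <- stats::runif(n) < config$shared_sire_prob
          sires[swap] <- sample(other_m$id, sum(swap), replace = TRUE)
        }
        data.frame(sire = sires, dam = f$id[fi], herd = h,
                   family = seq_len(n), stringsAsFactors = FALSE)
      })
      do.call(rbind, out[!vapply(out, is.null, logical(1))])
    })
}

# --- haplotype tracks -------------------------------------------------------
# A haplotype on one chromosome is a piecewise-constant founder-origin
# function stored as list(brk, org): segment i covers [brk[i], brk[i+1]) with
# brk[1] = 0 and an implicit final end at the chromosome length.

slice_track <- function(trk, from, to) {
  i1 <- findInterval(from, trk$brk)
  i2 <- max(which(trk$brk < to))
  idx <- i1:i2
  list(brk = c(from, trk$brk[idx][-1]), org = trk$org[idx])
}

merge_track <- function(brk, org) {
  keep <- c(TRUE, org[-1] != org[-length(org)])
  list(brk = brk[keep], org = org[keep])
}

# One meiosis on one chromosome: Poisson crossovers (Haldane model, no
# interference), random starting haplotype, origins copied piecewise.
meiosis <- function(hap1, hap2, len_bp, morgans) {
  k <- stats::rpois(1, morgans)
  x <- if (k > 0) sort(stats::runif(k, 0, len_bp)) else numeric(0)
  x <- unique(x)
  bounds <- c(0, x, len_bp)
  cur <- sample.int(2L, 1L)
  brk <- numeric(0); org <- integer(0)
  for (s in seq_len(length(bounds) - 1)) {
    src <- if (cur == 1L) hap1 else hap2
    piece <- slice_track(src, bounds[s], bounds[s + 1])
    brk <- c(brk, piece$brk); org <- c(org, piece$org)
    cur <- 3L - cur
  }
  merge_track(brk, org)
}

# IBD segments of one animal on one chromosome: intervals where the two
# haplotype origin tracks agree.
ibd_segments <- function(hap1, hap2, len_bp) {
  u <- sort(unique(c(hap1$brk, hap2$brk)))
  o1 <- hap1$org[findInterval(u, hap1$brk)]
  o2 <- hap2$org[findInterval(u, hap2$brk)]
  eq <- o1 == o2
  ends <- c(u[-1], len_bp)
  keep <- eq & ends > u
  if (!any(keep)) return(cbind(start = numeric(0), end = numeric(0)))
  s <- u[keep]; e <- ends[keep]
  # merge adjacent
  out_s <- s[1]; out_e <- e[1]
  if (length(s) > 1) for (i in 2:length(s)) {
    if (s[i] <= out_e[length(out_e)]) out_e[length(out_e)] <- max(out_e[length(out_e)], e[i])
    else { out_s <- c(out_s, s[i]); out_e <- c(out_e, e[i]) }
  }
  cbind(start = out_s, end = out_e)
}

#' Drop founder haplotypes through a pedigree with recombination
#'
#' Founder haplotypes are drawn from per-SNP allele frequencies uniform in
#' `[founder_maf_low, founder_maf_high]`; each meiosis places crossovers as a
#' Poisson process with rate `cm_per_mb / 100` per bp (Haldane map function,
#' no interference). Every transmitted chromosome is tracked by founder
#' haplotype of origin, so autozygous (IBD) segments — where an animal's two
#' origin tracks coincide — are known exactly and reported as the truth
#' track. Genotyping errors flip one allele of a call with the configured
#' rate; missingness masks calls first (a masked call cannot also be an
#' error).
#'
#' @param pedigree a topologically sorted pedigree (e.g. from
#'   [simulate_pedigree()]); every animal must have either two known parents
#'   present in the pedigree or none. An optional logical `inbred` column
#'   marks founders that carry two copies of a single haplotype (fully
#'   autozygous by construction).
#' @param config a [sim_config()].
#' @return list with `genotypes` (animals x SNPs, 0/1/2/NA), `map`
#'   (`snp_id`, `chrom`, `pos_bp`, `cm`), and `truth`: a list with
#'   `segments` (data.frame `animal`, `chrom`, `start_bp`, `end_bp` of IBD
#'   segments) and `fraction` (named per-animal autozygous genome fraction).
#' @export
gene_drop <- function(pedigree, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  n_chrom <- config$n_chrom
  len_bp <- round(config$chrom_length_mb * 1e6)
  S <- config$snps_per_chrom
  chroms <- as.character(seq_len(n_chrom))
  # irregular marker spacing, as on real arrays: uniform draws without
  # replacement along each chromosome
  pos_list <- lapply(chroms, function(c) sort(sample.int(len_bp, S)))
  map <- data.frame(
    snp_id = unlist(lapply(chroms, function(c) sprintf("snp_%s_%04d", c, seq_len(S)))),
    chrom = rep(chroms, each = S),
    pos_bp = unlist(pos_list),
    cm = unlist(pos_list) / 1e6 * config$cm_per_mb,
    stringsAsFactors = FALSE)

  ids <- pedigree$id
  n <- length(ids)
  sire_i <- match(pedigree$sire, ids)
  dam_i <- match(pedigree$dam, ids)
  is_founder <- is.na(sire_i) & is.na(dam_i)
  if (any(xor(is.na(sire_i), is.na(dam_i))))
    stop("animals must have two known parents or none")
  if (any(!is_founder & (sire_i >= seq_len(n) | dam_i >= seq_len(n)), na.rm = TRUE))
    stop("pedigree is not topologically sorted (parent after offspring)")

  n_f <- sum(is_founder)
  hap_id <- matrix(seq_len(2 * n_f), ncol = 2, byrow = TRUE)  # founder haplotype ids
  founder_row <- cumsum(is_founder)

  # founder allele frequencies and haplotype alleles, per chromosome
  freqs <- matrix(stats::runif(n_chrom * S, config$founder_maf_low,
                               config$founder_maf_high), nrow = n_chrom,
                  byrow = TRUE)
  hap_alleles <- lapply(seq_len(n_chrom), function(c)
    matrix(stats::rbinom(2 * n_f * S, 1, rep(freqs[c, ], each = 2 * n_f)),
           nrow = 2 * n_f))

  morgans <- len_bp / 1e6 * config$cm_per_mb / 100
  # tracks[[i]][[c]] = list(h1, h2)
  tracks <- vector("list", n)
  geno <- matrix(NA_integer_, n, n_chrom * S, dimnames = list(ids, map$snp_id))
  seg_list <- list()
  frac <- stats::setNames(numeric(n), ids)

  for (i in seq_len(n)) {
    tr <- vector("list", n_chrom)
    for (c in seq_len(n_chrom)) {
      pos <- pos_list[[c]]
      if (is_founder[i]) {
        fr <- founder_row[i]
        h1 <- list(brk = 0, org = hap_id[fr, 1])
        # founders flagged in an optional `inbred` pedigree column carry two
        # copies of the same haplotype (fully autozygous by construction)
        h2 <- if (isTRUE(pedigree$inbred[i])) h1
              else list(brk = 0, org = hap_id[fr, 2])
      } else {
        ts <- tracks[[sire_i[i]]][[c]]
        td <- tracks[[dam_i[i]]][[c]]
        h1 <- meiosis(ts[[1]], ts[[2]], len_bp, morgans)
        h2 <- meiosis(td[[1]], td[[2]], len_bp, morgans)
      }
      tr[[c]] <- list(h1, h2)
      o1 <- h1$org[findInterval(pos, h1$brk)]
      o2 <- h2$org[findInterval(pos, h2$brk)]
      al <- hap_alleles[[c]]
      g <- al[cbind(o1, seq_len(S))] + al[cbind(o2, seq_len(S))]
      geno[i, (c - 1) * S + seq_len(S)] <- g
      segs <- ibd_segments(h1, h2, len_bp)
      if (nrow(segs)) {
        seg_list[[length(seg_list) + 1]] <- data.frame(
          animal = ids[i], chrom = chroms[c],
          start_bp = round(segs[, "start"]), end_bp = round(segs[, "end"]),
          stringsAsFactors = FALSE)
        frac[i] <- frac[i] + sum(segs[, "end"] - segs[, "start"])
      }
    }
    tracks[[i]] <- tr
  }
  frac <- frac / (n_chrom * len_bp)

  # missingness first, then errors on the surviving calls
  nc <- length(geno)
  if (config$missing_rate > 0) {
    mask <- stats::runif(nc) < config$missing_rate
    geno[mask] <- NA_integer_
  }
  if (config$genotyping_error_rate > 0) {
    err <- which(!is.na(geno) & stats::runif(nc) < config$genotyping_error_rate)
    if (length(err)) {
      g <- geno[err]
      flip_up <- stats::runif(length(err)) < 0.5
      newg <- ifelse(g == 0, 1L, ifelse(g == 2, 1L, ifelse(flip_up, 2L, 0L)))
      geno[err] <- newg
    }
  }

  segments <- if (length(seg_list)) do.call(rbind, seg_list)
              else data.frame(animal = character(), chrom = character(),
                              start_bp = numeric(), end_bp = numeric(),
                              stringsAsFactors = FALSE)
  list(genotypes = geno, map = map,
       truth = list(segments = segments, fraction = frac))
}

#' Plant deterministic runs on a neutral background
#'
#' Produces a genotype matrix whose background alternates heterozygous and
#' homozygous calls along the map (so no run of either kind can occur by
#' accident), then forces each specified window to be homozygous
#' (`kind = "hom"`) or heterozygous (`kind = "het"`), except for a stated
#' number of opposite-state and missing calls placed at evenly spaced
#' interior positions (run endpoints stay in the target state). This gives
#' exact, hand-checkable expectations for the run detectors.
#'
#' @param n_animals number of rows.
#' @param map marker map (sorted).
#' @param run_specs data.frame with columns `animal` (row index), `chrom`,
#'   `start_bp`, `end_bp`, `kind` ("hom"/"het"), `n_opposite`, `n_missing`.
#' @return genotype matrix (0/1/2/NA).
#' @export
plant_runs <- function(n_animals, map, run_specs) {
  validate_marker_map(map)
  n_snp <- nrow(map)
  background <- rep(c(1L, 2L), length.out = n_snp)
  geno <- matrix(rep(background, each = n_animals), nrow = n_animals,
                 dimnames = list(paste0("A", seq_len(n_animals)), map$snp_id))
  if (is.null(run_specs) || nrow(run_specs) == 0) return(geno)
  for (a in unique(run_specs$animal)) {
    sp <- run_specs[run_specs$animal == a, , drop = FALSE]
    iv <- lapply(seq_len(nrow(sp)), function(k)
      which(map$chrom == sp$chrom[k] & map$pos_bp >= sp$start_bp[k] &
              map$pos_bp <= sp$end_bp[k]))
    all_idx <- unlist(iv)
    if (anyDuplicated(all_idx))
      stop("overlapping run specs for animal ", a)
    for (k in seq_len(nrow(sp))) {
      idx <- iv[[k]]
      if (length(idx) < 3) stop("run spec window holds fewer than 3 SNPs")
      target <- if (sp$kind[k] == "hom") 2L else 1L
      opposite <- if (sp$kind[k] == "hom") 1L else 2L
      geno[a, idx] <- target
      # force opposite-state flanks (within the chromosome, outside other
      # spec windows) so the planted run is exactly maximal
      for (fl in c(idx[1] - 1L, idx[length(idx)] + 1L)) {
        if (fl >= 1 && fl <= n_snp && map$chrom[fl] == sp$chrom[k] &&
            !(fl %in% all_idx))
          geno[a, fl] <- opposite
      }
      n_op <- sp$n_opposite[k]
      n_mi <- sp$n_missing[k]
      n_bl <- n_op + n_mi
      if (n_bl > 0) {
        interior <- idx[-c(1, length(idx))]
        if (n_bl > length(interior))
          stop("more blemishes than interior SNPs in run spec")
        at <- interior[round(seq(1, length(interior),
                                 length.out = n_bl + 2))[2:(n_bl + 1)]]
        if (anyDuplicated(at))
          at <- interior[unique(round(seq(1, length(interior),
                                          length.out = n_bl)))]
        if (n_op > 0) geno[a, at[seq_len(n_op)]] <- opposite
        if (n_mi > 0) geno[a, at[n_op + seq_len(n_mi)]] <- NA_integer_
      }
    }
  }
  geno
}
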