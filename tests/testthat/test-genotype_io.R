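test_that("PED/MAP parsing recodes alleles and flags missing calls", {
  io <- write_tiny_ped_map()
  res <- read_ped_map(io$ped, io$map)
  # map re-sorted by (chrom, pos): rs1, rs2 on chr1; rs3 on chr2
  expect_equal(res$map$snp_id, c("rs1", "rs2", "rs3"))
  expect_equal(rownames(res$genotypes), c("A1", "A2"))
  # rs1: first observed allele A; A1 = A A -> 2, A2 = A A -> 2
  expect_equal(unname(res$genotypes[, "rs1"]), c(2, 2))
  # rs2: first observed A; A1 = A C -> 1, A2 = C C -> 0
  expect_equal(unname(res$genotypes[, "rs2"]), c(1, 0))
  # rs3: A2 is "0 0" -> exactly one missing cell
  expect_equal(sum(is.na(res$genotypes)), 1)
  expect_true(is.na(res$genotypes["A2", "rs3"]))
})

test_that("malformed PED rows raise errors naming the line", {
  io <- write_tiny_ped_map()
  bad <- readLines(io$ped)
  bad[2] <- paste(bad[2], "G")  # odd allele field count
  writeLines(bad, io$ped)
  expect_error(read_ped_map(io$ped, io$map), "line 2")
  writeLines(c(bad[1], "F1 A2 0 0 2 -9 A A C C"), io$ped)  # 2 SNPs vs 3
  expect_error(read_ped_map(io$ped, io$map), "MAP")
})

test_that("write/read round trip is the identity up to allele relabeling", {
  set.seed(21)
  map <- make_map(12, chrom = "3")
  g <- matrix(sample(c(0:2, NA), 8 * 12, TRUE, prob = c(.3, .3, .3, .1)),
              8, 12, dimnames = list(paste0("an", 1:8), map$snp_id))
  d <- tempfile(); dir.create(d)
  write_ped_map(g, map, file.path(d, "r.ped"), file.path(d, "r.map"))
  back <- read_ped_map(file.path(d, "r.ped"), file.path(d, "r.map"))
  expect_equal(back$map$snp_id, map$snp_id)
  expect_equal(back$map$pos_bp, map$pos_bp)
  for (j in seq_len(ncol(g))) {
    a <- back$genotypes[, j]; b <- g[, j]
    expect_equal(is.na(a), is.na(b))
    same <- all(a == b, na.rm = TRUE)
    flipped <- all(a == 2 - b, na.rm = TRUE)
    expect_true(same || flipped)
  }
})

test_that("round trip is exact when no SNP leads with opposite homozygote", {
  map <- make_map(4)
  g <- rbind(a1 = c(2L, 1L, 2L, 1L), a2 = c(0L, 0L, 2L, NA))
  colnames(g) <- map$snp_id
  d <- tempfile(); dir.create(d)
  write_ped_map(g, map, file.path(d, "e.ped"), file.path(d, "e.map"))
  back <- read_ped_map(file.path(d, "e.ped"), file.path(d, "e.map"))
  expect_identical(unname(back$genotypes), unname(g))
})

test_that("write.read reaches a bit-identical fixpoint after one pass", {
  cfg <- sim_config(n_founders = 4, n_generations = 1, n_chrom = 1,
                    snps_per_chrom = 60, chrom_length_mb = 3, seed = 1)
  gd <- gene_drop(simulate_pedigree(cfg), cfg)
  d <- tempfile(); dir.create(d)
  p1 <- file.path(d, "1.ped"); m1 <- file.path(d, "1.map")
  write_ped_map(gd$genotypes, gd$map, p1, m1)
  r1 <- read_ped_map(p1, m1)
  p2 <- file.path(d, "2.ped"); m2 <- file.path(d, "2.map")
  write_ped_map(r1$genotypes, r1$map, p2, m2)
  r2 <- read_ped_map(p2, m2)
  p3 <- file.path(d, "3.ped"); m3 <- file.path(d, "3.map")
  write_ped_map(r2$genotypes, r2$map, p3, m3)
  expect_identical(readLines(p3), readLines(p2))
  expect_identical(readLines(m3), readLines(m2))
})

test_that("empty sample set writes a valid MAP and empty PED", {
  map <- make_map(3)
  g <- matrix(integer(), 0, 3, dimnames = list(NULL, map$snp_id))
  d <- tempfile(); dir.create(d)
  write_ped_map(g, map, file.path(d, "0.ped"), file.path(d, "0.map"))
  expect_length(readLines(file.path(d, "0.ped")), 0)
  expect_length(readLines(file.path(d, "0.map")), 3)
  # a single heterozygous genotype ends with two distinct allele symbols
  g1 <- matrix(1L, 1, 3, dimnames = list("x", map$snp_id))
  write_ped_map(g1, map, file.path(d, "1.ped"), file.path(d, "0.map"))
  fields <- strsplit(readLines(file.path(d, "1.ped")), " ")[[1]]
  expect_false(fields[7] == fields[8])
})

test_that("pedigree reading sorts topologically and adds implicit founders", {
  d <- tempfile(); dir.create(d)
  pf <- file.path(d, "ped.csv")
  writeLines(c("E,C,D", "C,A,B", "D,A,B", "B,0,0"), pf)  # A has no record
  ped <- read_pedigree(pf)
  expect_true("A" %in% ped$id)
  ord <- stats::setNames(seq_len(nrow(ped)), ped$id)
  for (i in seq_len(nrow(ped))) {
    if (!is.na(ped$sire[i])) expect_lt(ord[ped$sire[i]], i)
    if (!is.na(ped$dam[i])) expect_lt(ord[ped$dam[i]], i)
  }
  # single founder triple
  writeLines("A 0 0", pf)
  expect_equal(read_pedigree(pf)$id, "A")
})

test_that("pedigree cycles are detected and reported", {
  d <- tempfile(); dir.create(d)
  pf <- file.path(d, "cyc.txt")
  writeLines(c("B A A", "A B 0"), pf)
  expect_error(read_pedigree(pf), "cycle")
})

test_that("shuffled pedigrees sort to the same order-respecting result", {
  set.seed(4)
  ped <- data.frame(
    id = c("f1", "f2", "c1", "c2", "g1", "g2", "h1", "h2", "h3", "h4"),
    sire = c(NA, NA, "f1", "f1", "c1", "c1", "g1", "g1", "g1", "g1"),
    dam = c(NA, NA, "f2", "f2", "c2", "c2", "g2", "g2", "g2", "g2"),
    stringsAsFactors = FALSE)
  s1 <- sort_pedigree(ped)
  s2 <- sort_pedigree(ped[sample(nrow(ped)), ])
  expect_setequal(s1$id, s2$id)
  # both orders must respect parentage; A-matrix results must agree
  a1 <- pedigree_a_matrix(s1)
  a2 <- pedigree_a_matrix(s2)
  expect_equal(a1[s1$id, s1$id], a2[s1$id, s1$id])
})

test_that("QC removes low-call-rate SNPs then high-missing samples, in order", {
  set.seed(7)
  map <- make_map(100)
  g <- matrix(sample(0:2, 10 * 100, TRUE), 10, 100,
              dimnames = list(paste0("an", 1:10), map$snp_id))
  # SNP missing in 1 of 10 animals: call rate 0.9 < 0.95 -> dropped
  g[1, 1] <- NA
  res <- apply_qc(g, map)
  expect_false("s_1_0001" %in% res$map$snp_id)
  expect_equal(res$report$n_snps_low_call_rate_removed, 1)

  # animal boundary: >15% missing removed, exactly 15% retained
  g2 <- matrix(sample(0:2, 10 * 100, TRUE), 10, 100,
               dimnames = list(paste0("an", 1:10), map$snp_id))
  g2[1, 1:16] <- NA  # 16% -> removed
  g2[2, 1:15] <- NA  # exactly 15% -> retained
  res2 <- apply_qc(g2, map, min_snp_call_rate = 0)
  expect_false("an1" %in% rownames(res2$genotypes))
  expect_true("an2" %in% rownames(res2$genotypes))

  # planted failures: 3 bad SNPs, 2 bad animals; counts reported in order
  g3 <- matrix(sample(0:2, 20 * 100, TRUE), 20, 100,
               dimnames = list(paste0("an", 1:20), map$snp_id))
  g3[1:2, 4:6] <- NA                     # 3 SNPs at call rate 0.9
  g3[3, 7:30] <- NA                      # animal 3: 24 of remaining 97 > 15%
  g3[4, 31:54] <- NA                     # animal 4
  res3 <- apply_qc(g3, map)
  expect_equal(res3$report$n_snps_low_call_rate_removed, 3)
  expect_equal(res3$report$n_samples_high_missing_removed, 2)
})

test_that("QC drops non-autosomal chromosomes and is idempotent", {
  set.seed(8)
  map <- rbind(make_map(50, chrom = "1"), make_map(10, chrom = "X"),
               make_map(5, chrom = "0"))
  map$snp_id <- sprintf("m%03d", seq_len(nrow(map)))
  g <- matrix(sample(c(0:2, NA), 12 * 65, TRUE, prob = c(.3, .3, .3, .1)),
              12, 65, dimnames = list(paste0("an", 1:12), map$snp_id))
  r1 <- apply_qc(g, map)
  expect_false(any(r1$map$chrom %in% c("X", "0")))
  expect_equal(r1$report$n_snps_nonautosomal_removed, 15)
  r2 <- apply_qc(r1$genotypes, r1$map)
  expect_identical(r2$genotypes, r1$genotypes)
  expect_identical(r2$map, r1$map)
  # removed + retained counts add up
  expect_equal(r1$report$n_snps_in,
               r1$report$n_snps_nonautosomal_removed +
                 r1$report$n_snps_low_call_rate_removed +
                 r1$report$n_snps_out)
  expect_equal(r1$report$n_samples_in,
               r1$report$n_samples_high_missing_removed +
                 r1$report$n_samples_out)
  expect_error(apply_qc(g, map, min_snp_call_rate = 1.01), "min_snp_call_rate")
  # all SNPs failing -> explicit empty-panel error
  gna <- g; gna[] <- NA
  expect_error(apply_qc(gna, map), "empty panel")
})

test_that("BED conversion round-trips 1-based inclusive segments", {
  segs <- data.frame(chrom = c("1", "2"), start_bp = c(100, 5000),
                     end_bp = c(900, 9000))
  bed <- runs_to_bed(segs)
  expect_equal(bed$start, c(99, 4999))
  expect_equal(bed$end, c(900, 9000))
  back <- bed_to_runs(bed)
  expect_equal(back$start_bp, segs$start_bp)
  expect_equal(back$end_bp, segs$end_bp)
})
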