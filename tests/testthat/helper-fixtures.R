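# Programmatic fixtures shared across test files.

make_map <- function(n, spacing_bp = 1e5, chrom = "1", start = spacing_bp) {
  data.frame(snp_id = sprintf("s_%s_%04d", chrom, seq_len(n)), chrom = chrom,
             pos_bp = seq(start, by = spacing_bp, length.out = n),
             stringsAsFactors = FALSE)
}

# A random planted-run fixture on one chromosome: irregular spacing, one
# animal, one planted run with a stated number of blemishes.
random_planted_fixture <- function(kind = "hom", n_snps_total = 300,
                                   run_snps = 60, n_opposite = 0,
                                   n_missing = 0) {
  spacing <- sample(50:80, 1) * 1000
  map <- make_map(n_snps_total, spacing_bp = spacing)
  start_i <- sample(2:(n_snps_total - run_snps - 1), 1)
  spec <- data.frame(animal = 1, chrom = "1",
                     start_bp = map$pos_bp[start_i],
                     end_bp = map$pos_bp[start_i + run_snps - 1],
                     kind = kind, n_opposite = n_opposite,
                     n_missing = n_missing)
  list(map = map, spec = spec,
       genotypes = plant_runs(1, map, spec))
}

# Small two-herd style PED/MAP files on disk for IO tests.
write_tiny_ped_map <- function(dir = tempfile("pedmap")) {
  dir.create(dir, showWarnings = FALSE)
  ped <- c("F1 A1 0 0 1 -9 A A A C G G",
           "F1 A2 0 0 2 -9 A A C C 0 0")
  map <- c("1\trs1\t0\t1000", "1\trs2\t0\t2000", "2\trs3\t0\t1500")
  writeLines(ped, file.path(dir, "t.ped"))
  writeLines(map, file.path(dir, "t.map"))
  list(ped = file.path(dir, "t.ped"), map = file.path(dir, "t.map"))
}
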