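# Orchestration: run the whole analysis (QC -> diversity -> ROH -> ROHet ->
# summaries -> islands -> relationships -> comparison -> optional sweeps)
# from a single configuration, writing every artifact plus a manifest.

#' Default pipeline configuration
#'
#' @param ped_path,map_path PLINK PED/MAP input paths.
#' @param pedigree_path optional pedigree file; when `NULL` the pedigree
#'   stage is skipped and the inbreeding comparison excludes pedigree F.
#' @param l_auto_mb autosomal genome length (Mb) used for FROH; when `NULL`
#'   it is taken as the map span (sum over chromosomes of the covered
#'   length).
#' @param qc,roh,rohet,islands,sweeps stage parameter lists; see
#'   [apply_qc()], [roh_params()], [consecutive_params()],
#'   [detect_islands()], [sweep_runs()]. `sweeps = NULL` disables the
#'   sensitivity stage.
#' @return a named list understood by [run_pipeline()].
#' @export
pipeline_config <- function(ped_path, map_path, pedigree_path = NULL,
                            l_auto_mb = NULL,
                            qc = list(), roh = list(), rohet = list(),
                            islands = list(roh_q = 0.999, rohet_t = 0.25),
                            sweeps = NULL) {
  list(ped_path = ped_path, map_path = map_path,
       pedigree_path = pedigree_path, l_auto_mb = l_auto_mb, qc = qc,
       roh = roh, rohet = rohet, islands = islands, sweeps = sweeps)
}

#' Run the full analysis pipeline
#'
#' Stages are executed in a fixed order; every artifact is written into
#' `out_dir` together with a JSON manifest of files and per-stage counts.
#' Outputs are a pure function of the input files and the configuration.
#'
#' @param config a [pipeline_config()] list, or the path to a YAML file
#'   with the same fields.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the main in-memory results.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(files = character(), counts = list())
  emit <- function(name) manifest$files <<- c(manifest$files, name)

  # provenance: the configuration as consumed
  yaml::write_yaml(config, file.path(out_dir, "config.yaml"))
  emit("config.yaml")

  io <- read_ped_map(config$ped_path, config$map_path)
  qc <- do.call(apply_qc, c(list(io$genotypes, io$map), config$qc))
  write_qc_report(qc$report, file.path(out_dir, "qc_report.json"))
  emit("qc_report.json")
  manifest$counts$qc <- qc$report[c("n_snps_out", "n_samples_out")]

  div <- snp_stats(qc$genotypes)
  utils::write.csv(div$per_snp, file.path(out_dir, "snp_stats.csv"),
                   row.names = FALSE)
  emit("snp_stats.csv")
  jsonlite::write_json(div$summary, file.path(out_dir, "diversity_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  emit("diversity_summary.json")
  fis_tab <- fis(qc$genotypes)
  utils::write.csv(fis_tab, file.path(out_dir, "fis.csv"), row.names = FALSE)
  emit("fis.csv")

  l_auto <- config$l_auto_mb
  if (is.null(l_auto))
    l_auto <- sum(tapply(qc$map$pos_bp, qc$map$chrom,
                         function(p) max(p) - min(p))) / 1e6

  rp <- do.call(roh_params, as.list(config$roh))
  roh_set <- detect_roh_sliding(qc$genotypes, qc$map, rp)
  write_runs(roh_set, file.path(out_dir, "roh.tsv"))
  emit("roh.tsv")
  manifest$counts$n_roh <- nrow(roh_set)

  cp <- do.call(consecutive_params, as.list(config$rohet))
  rohet_set <- detect_runs_consecutive(qc$genotypes, qc$map, cp)
  write_runs(rohet_set, file.path(out_dir, "rohet.tsv"))
  emit("rohet.tsv")
  manifest$counts$n_rohet <- nrow(rohet_set)

  classes <- classify_by_size(roh_set)
  utils::write.table(classes, file.path(out_dir, "roh_size_classes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  emit("roh_size_classes.tsv")
  ids <- rownames(qc$genotypes)
  froh_tab <- froh(roh_set, l_auto, animals = ids)
  utils::write.csv(froh_tab, file.path(out_dir, "froh.csv"), row.names = FALSE)
  emit("froh.csv")

  freq_roh <- snp_run_frequency(roh_set, qc$map, length(ids))
  utils::write.table(freq_roh, file.path(out_dir, "snp_roh_freq.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  emit("snp_roh_freq.tsv")
  freq_rohet <- snp_run_frequency(rohet_set, qc$map, length(ids))
  utils::write.table(freq_rohet, file.path(out_dir, "snp_rohet_freq.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  emit("snp_rohet_freq.tsv")

  isl_roh <- detect_islands(freq_roh, "quantile",
                            q = config$islands$roh_q %||% 0.999, kind = "ROH")
  isl_rohet <- detect_islands(freq_rohet, "fixed",
                              t = config$islands$rohet_t %||% 0.25,
                              kind = "ROHet")
  for (nm in c("roh_islands", "rohet_islands")) {
    isl <- if (nm == "roh_islands") isl_roh else isl_rohet
    utils::write.table(isl, file.path(out_dir, paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    emit(paste0(nm, ".tsv"))
    utils::write.table(runs_to_bed(isl)[, c("chrom", "start", "end")],
                       file.path(out_dir, paste0(nm, ".bed")), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    emit(paste0(nm, ".bed"))
  }
  manifest$counts$n_roh_islands <- nrow(isl_roh)
  manifest$counts$n_rohet_islands <- nrow(isl_rohet)

  G <- vanraden_g(qc$genotypes)
  write_relationship(G, file.path(out_dir, "G_matrix.csv"))
  emit("G_matrix.csv")
  R <- NULL
  if (nrow(roh_set)) {
    R <- roh_relationship(roh_set, animals = ids)
    write_relationship(R, file.path(out_dir, "roh_matrix.csv"))
    emit("roh_matrix.csv")
  } else {
    warning("no ROH detected: ROH relationship matrix skipped")
  }

  f_ped <- NULL
  A <- NULL
  if (!is.null(config$pedigree_path)) {
    ped <- read_pedigree(config$pedigree_path)
    A <- pedigree_a_matrix(ped)
    write_relationship(A, file.path(out_dir, "A_matrix.csv"))
    emit("A_matrix.csv")
    f_ped <- attr(A, "F")
  } else {
    warning("no pedigree file: pedigree stage skipped, ",
            "comparison excludes pedigree F")
  }

  cmp <- NULL
  if (!is.null(f_ped)) {
    common <- intersect(names(f_ped), ids)
    if (length(common) >= 3) {
      cmp <- compare_inbreeding(f_ped[common], fis_tab, froh_tab)
      utils::write.csv(cmp$table, file.path(out_dir, "inbreeding_comparison.csv"),
                       row.names = FALSE)
      emit("inbreeding_comparison.csv")
      utils::write.csv(cmp$pearson, file.path(out_dir, "inbreeding_pearson.csv"))
      emit("inbreeding_pearson.csv")
      utils::write.csv(cmp$spearman, file.path(out_dir, "inbreeding_spearman.csv"))
      emit("inbreeding_spearman.csv")
    }
  }

  if (!is.null(config$sweeps)) {
    for (k in seq_along(config$sweeps)) {
      sw <- config$sweeps[[k]]
      res <- sweep_runs(qc$genotypes, qc$map, sw$axis, sw$values,
                        base = if (identical(sw$base, "rohet")) cp else rp,
                        l_auto_mb = l_auto)
      fn <- sprintf("sweep_%s_%s.tsv",
                    if (identical(sw$base, "rohet")) "rohet" else "roh",
                    sw$axis)
      utils::write.table(res, file.path(out_dir, fn), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      emit(fn)
    }
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(qc = qc, diversity = div, fis = fis_tab, roh = roh_set,
                 rohet = rohet_set, froh = froh_tab, classes = classes,
                 islands = list(roh = isl_roh, rohet = isl_rohet),
                 G = G, roh_rel = R, A = A, comparison = cmp,
                 l_auto_mb = l_auto))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
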