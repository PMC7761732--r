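# Parameter-sensitivity sweep engine: rerun a detector along one parameter
# axis and monitor the summary variables (run count, runs per animal, mean
# size, mean FROH).

#' Sweep one run-detection parameter and monitor summary statistics
#'
#' The detector (sliding-window for `roh_params` bases, consecutive for
#' `consecutive_params` bases) is run at each grid point with only the swept
#' axis changed from the base parameters. Monitored per grid point:
#' `n_runs`, `avg_n` (runs per animal, counting every panel animal
#' including those with zero runs), `avg_size_kb`, and — for ROH sweeps
#' only — `avg_froh` (mean per-animal FROH, zero-run animals included).
#' Each row is exactly reproducible by a direct detector call at that
#' parameter point.
#'
#' @param genotypes samples x SNPs matrix coded 0/1/2/NA.
#' @param map sorted marker map aligned with the genotype columns.
#' @param axis parameter to sweep: one of `density_kb_per_snp`, `max_het`,
#'   `max_missing` (sliding-window bases) or `max_opposite`, `max_missing`
#'   (consecutive bases).
#' @param values numeric vector of axis values.
#' @param base base parameter object ([roh_params()] or
#'   [consecutive_params()]).
#' @param l_auto_mb autosomal genome length in Mb (required for ROH sweeps,
#'   where FROH is monitored).
#' @return data.frame: `axis`, `value`, `n_runs`, `avg_n`, `avg_size_kb`
#'   and, for ROH sweeps, `avg_froh`.
#' @export
sweep_runs <- function(genotypes, map, axis, values, base = roh_params(),
                       l_auto_mb = NULL) {
  is_roh <- inherits(base, "roh_params")
  if (!is_roh && !inherits(base, "consecutive_params"))
    stop("base must be roh_params() or consecutive_params()")
  allowed <- if (is_roh) c("density_kb_per_snp", "max_het", "max_missing")
             else c("max_opposite", "max_missing")
  if (!axis %in% allowed)
    stop("axis must be one of: ", paste(allowed, collapse = ", "))
  if (!length(values) || any(!is.finite(values)) || any(values < 0))
    stop("invalid grid values for axis ", axis)
  if (is_roh && is.null(l_auto_mb))
    stop("l_auto_mb is required for ROH sweeps (FROH is monitored)")

  n_animals <- nrow(genotypes)
  ids <- rownames(genotypes)
  if (is.null(ids)) ids <- paste0("S", seq_len(n_animals))
  rows <- lapply(values, function(v) {
    p <- base
    p[[axis]] <- v
    rs <- if (is_roh) detect_roh_sliding(genotypes, map, p)
          else detect_runs_consecutive(genotypes, map, p)
    row <- data.frame(
      axis = axis, value = v, n_runs = nrow(rs),
      avg_n = nrow(rs) / n_animals,
      avg_size_kb = if (nrow(rs)) mean(rs$length_bp) / 1000 else 0,
      stringsAsFactors = FALSE)
    if (is_roh)
      row$avg_froh <- mean(froh(rs, l_auto_mb, animals = ids)$froh_total)
    row
  })
  do.call(rbind, rows)
}
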