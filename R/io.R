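#' Write analysis outputs to a directory
#'
#' Emits a deterministic file set: `results.json` (all incremental
#' cost-effectiveness fields plus per-arm summaries), one tidy trace CSV
#' per arm (`trace_<arm>.csv`: cycle, time, occupancy and discounted
#' streams), optional sweep tables under `sweeps/` and the PSA
#' cost-effectiveness plane under `psa/ce_plane.csv`. Returns a manifest
#' listing every file with its MD5 content hash, so reruns can be checked
#' for bitwise identity.
#'
#' @param base A `base_case` object from [run_base_case()].
#' @param outdir Output directory (created if needed).
#' @param os_sweep,discount_sweep Optional sweep tables
#'   ([os_benefit_sweep()], [drug_discount_sweep()]).
#' @param psa Optional [run_psa()] result.
#' @return A data frame manifest `(file, md5)`, invisibly.
#' @export
write_results <- function(base, outdir, os_sweep = NULL, discount_sweep = NULL,
                          psa = NULL) {
  stopifnot(inherits(base, "base_case"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)

  arm_summary <- function(a) {
    list(arm = a$arm, pre_pd_cost = a$costs$pre_pd, post_pd_cost = a$costs$post_pd,
         total_cost = a$costs$total, qalys = a$qalys$qalys)
  }
  results <- list(
    schema_version = "1.0",
    arms = list(placebo = arm_summary(base$placebo),
                osimertinib = arm_summary(base$osimertinib)),
    cea = unclass(base$cea)
  )
  f <- file.path(outdir, "results.json")
  jsonlite::write_json(results, f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(files, f)

  for (a in list(base$placebo, base$osimertinib)) {
    tr <- as.data.frame(a$trace)
    tr$disc_cost_pre_pd <- a$costs$per_cycle$disc_cost_pre_pd
    tr$disc_cost_post_pd <- a$costs$per_cycle$disc_cost_post_pd
    tr$disc_qaly <- a$qalys$per_cycle$disc_qaly
    f <- file.path(outdir, sprintf("trace_%s.csv", a$arm))
    utils::write.csv(tr, f, row.names = FALSE, quote = FALSE)
    files <- c(files, f)
  }

  if (!is.null(os_sweep)) {
    dir.create(file.path(outdir, "sweeps"), showWarnings = FALSE)
    f <- file.path(outdir, "sweeps", "os_benefit.csv")
    utils::write.csv(os_sweep, f, row.names = FALSE, quote = FALSE)
    files <- c(files, f)
  }
  if (!is.null(discount_sweep)) {
    dir.create(file.path(outdir, "sweeps"), showWarnings = FALSE)
    f <- file.path(outdir, "sweeps", "drug_discount.csv")
    utils::write.csv(discount_sweep, f, row.names = FALSE, quote = FALSE)
    files <- c(files, f)
  }
  if (!is.null(psa)) {
    stopifnot(inherits(psa, "psa_result"))
    dir.create(file.path(outdir, "psa"), showWarnings = FALSE)
    f <- file.path(outdir, "psa", "ce_plane.csv")
    utils::write.csv(psa$draws[, c("draw", "delta_cost", "delta_qaly")], f,
                     row.names = FALSE, quote = FALSE)
    files <- c(files, f)
  }

  manifest <- data.frame(file = files, md5 = unname(tools::md5sum(files)),
                         row.names = NULL)
  f <- file.path(outdir, "manifest.csv")
  utils::write.csv(manifest, f, row.names = FALSE, quote = FALSE)
  invisible(manifest)
}
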