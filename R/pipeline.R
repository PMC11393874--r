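#' Run the full prioritization pipeline and write its outputs
#'
#' Orchestrates the stages end to end: read (and, for multiple VCFs, merge)
#' the annotated cohort, classify every variant through the two-round
#' cascade, summarize the cohort when patient data are available, and write
#' the prioritized variant table, the summary report and a machine-readable
#' run manifest into `out_dir`. Identical inputs and configuration produce
#' identical outputs. On failure, partial outputs are removed.
#'
#' @param variants A variant tibble, or `NULL` to read from `table`/`vcf`.
#' @param table Path to a flat variant table ([read_variant_table()]).
#' @param vcf Character vector of VCF paths; several are cohort-merged.
#' @param panel A panel tibble or a path for [load_panel()]; defaults to the
#'   packaged DNA-repair panel.
#' @param alias_map Optional alias-map path when `panel` is a path.
#' @param patients Patient tibble or TSV path; optional.
#' @param config A [filter_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, `list(calls, summary, manifest)`.
#' @export
run_pipeline <- function(variants = NULL, table = NULL, vcf = NULL,
                         panel = NULL, alias_map = NULL, patients = NULL,
                         config = filter_config(), out_dir = ".") {
  written <- character(0)
  panel_path <- NULL
  on_fail <- function(e) {
    unlink(written)
    abort(paste0("pipeline error (", conditionMessage(e), ")"), parent = e)
  }
  tryCatch({
    if (is.null(panel)) {
      panel_path <- repairsieve_extdata("dna_repair_panel.txt")
      panel <- dna_repair_panel()
    } else if (is.character(panel)) {
      panel_path <- panel
      panel <- load_panel(panel, alias_map)
    }
    if (is.null(variants)) {
      if (!is.null(table)) {
        variants <- read_variant_table(table)
      } else if (!is.null(vcf)) {
        per <- lapply(vcf, read_vcf_variants)
        variants <- if (length(per) == 1) per[[1]] else
          merge_cohort(setNames(per, paste0("S", seq_along(per))))
      } else {
        abort("no input: give variants, table or vcf")
      }
    }
    if (is.character(patients)) patients <- read_patient_table(patients)

    calls <- classify_variants(variants, panel, config)
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    v_out <- prepare_variants(variants)
    out_tab <- dplyr::left_join(
      v_out, tidy(calls)[, c("key", "gene", "retained", "group",
                             "subcategory", "af_class", "rule_trace")],
      by = c("key", "gene")
    )
    prioritized_path <- file.path(out_dir, "prioritized_variants.tsv")
    written <- c(written, prioritized_path)
    write_variant_table(out_tab, prioritized_path)

    summary <- NULL
    if (!is.null(patients)) {
      summary <- summarize_cohort(patients, calls, variants)
      summary_tsv <- file.path(out_dir, "cohort_summary.tsv")
      summary_txt <- file.path(out_dir, "cohort_summary.txt")
      written <- c(written, summary_tsv, summary_txt)
      readr::write_tsv(glance(summary), summary_tsv, progress = FALSE)
      writeLines(utils::capture.output(print(summary)), summary_txt)
    }

    counts <- attr(calls, "stage_counts")
    manifest <- list(
      tool = "repairsieve",
      version = as.character(utils::packageVersion("repairsieve")),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      inputs = list(table = table, vcf = vcf,
                    n_variants = nrow(prepare_variants(variants)),
                    n_patients = if (is.null(patients)) NULL else nrow(patients)),
      panel_checksum = if (!is.null(panel_path))
        unname(tools::md5sum(panel_path)) else NULL,
      config = unclass(config),
      stage_counts = as.list(counts),
      affected_genes = attr(calls, "affected_genes")
    )
    manifest_path <- file.path(out_dir, "run_manifest.json")
    written <- c(written, manifest_path)
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE, null = "null")
    invisible(list(calls = calls, summary = summary, manifest = manifest))
  }, error = on_fail)
}
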