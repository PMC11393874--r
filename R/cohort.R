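#' Read a patient table
#'
#' Reads the tab-separated patient dialect: columns `patient_id`,
#' `lund_negative` (0/1; 1 = no family history under the modified Lund
#' criteria, i.e. qualified by young onset alone), `age1`, `age2` (`NA`
#' unless the patient had bilateral disease, in which case `age2` is the age
#' at the second diagnosis), `triple_negative` (0/1/NA), `histology` (free
#' text) and `variant_ids` (comma-separated variant identifiers: dbSNP
#' rs-numbers, or location strings for variants without one; `NA` = no
#' variants).
#'
#' @param path Path to the TSV.
#' @return A tibble with `ages_at_diagnosis` and `variant_ids` list columns
#'   and a `bilateral` flag (true exactly when two ages are recorded).
#' @export
read_patient_table <- function(path) {
  tab <- readr::read_tsv(path, na = "NA", show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(
                           patient_id = readr::col_character(),
                           lund_negative = readr::col_integer(),
                           age1 = readr::col_integer(),
                           age2 = readr::col_integer(),
                           triple_negative = readr::col_integer(),
                           histology = readr::col_character(),
                           variant_ids = readr::col_character()
                         ))
  if (anyDuplicated(tab$patient_id)) {
    abort(paste0("cohort error: duplicate patient_id: ",
                 tab$patient_id[duplicated(tab$patient_id)][1]))
  }
  bad_age <- !is.na(tab$age1) & (tab$age1 < 15 | tab$age1 > 100)
  if (any(bad_age)) abort("cohort error: ages at diagnosis must lie in [15, 100]")
  tibble(
    patient_id = tab$patient_id,
    lund_negative = tab$lund_negative == 1L,
    ages_at_diagnosis = purrr::map2(tab$age1, tab$age2,
                                    function(a, b) c(a, b)[!is.na(c(a, b))]),
    bilateral = !is.na(tab$age2),
    triple_negative = ifelse(is.na(tab$triple_negative), NA,
                             tab$triple_negative == 1L),
    histology_text = tab$histology,
    variant_ids = purrr::map(tab$variant_ids, function(s) {
      if (is.na(s) || s == "") character(0) else trimws(strsplit(s, ",")[[1]])
    })
  )
}

#' Novelty of a variant
#'
#' A variant counts as novel when it has no dbSNP identifier *and* no allele
#' frequency reported in any of the four reference-population columns. Both
#' conditions are required: a cataloged variant may lack frequencies, and a
#' frequency of 0 is a reported value, so neither alone implies novelty.
#'
#' @param variants Variant tibble.
#' @return Logical vector.
#' @export
is_novel <- function(variants) {
  af <- cbind(variants$af_exome_global, variants$af_genome_global,
              variants$af_exome_fin, variants$af_genome_fin)
  is.na(variants$variant_id) & rowSums(!is.na(af)) == 0
}

#' Variants carried per patient
#'
#' @param patients Patient tibble from [read_patient_table()].
#' @return A tibble `patient_id`, `n_variants`.
#' @export
variants_per_patient <- function(patients) {
  if (anyDuplicated(patients$patient_id)) {
    abort("cohort error: duplicate patient_id")
  }
  tibble(patient_id = patients$patient_id,
         n_variants = purrr::map_int(patients$variant_ids, length))
}

# Resolve the identifiers a patient table uses (rs-numbers, or location
# strings for variants without one) to variant rows. Returns row indices.
resolve_variant_ids <- function(ids, variants) {
  hit <- match(ids, variants$variant_id)
  if ("location" %in% names(variants)) {
    hit2 <- match(ids, variants$location)
    hit[is.na(hit)] <- hit2[is.na(hit)]
  }
  hit3 <- match(ids, variants$key)
  hit[is.na(hit)] <- hit3[is.na(hit)]
  if (any(is.na(hit))) {
    abort(paste0("cohort error: variant id not resolvable: ",
                 paste(ids[is.na(hit)], collapse = ", ")))
  }
  hit
}

#' Cohort summary statistics
#'
#' Aggregates a patient cohort against the retained variants of a
#' prioritization run: carrier structure (patients with / without a retained
#' variant, multi-variant carriers, the per-patient maximum), novelty counts
#' over the retained variants, per-variant carrier counts, age statistics
#' (age at *first* diagnosis; the median uses the lower-middle element for
#' even counts) and the clinical flags.
#'
#' Every variant id a patient carries must resolve to a retained variant;
#' a dangling reference is an error naming the id.
#'
#' @param patients Patient tibble from [read_patient_table()].
#' @param calls `priority_calls` from [classify_variants()].
#' @param variants The variant tibble the calls were computed from.
#' @return A `cohort_summary` object; see [glance.cohort_summary()].
#' @export
summarize_cohort <- function(patients, calls, variants) {
  variants <- prepare_variants(variants)
  retained_keys <- calls$key[calls$retained]
  retained <- variants[variants$key %in% retained_keys, , drop = FALSE]

  counts <- variants_per_patient(patients)
  carrier_idx <- purrr::map(patients$variant_ids, function(ids) {
    if (length(ids) == 0) return(integer(0))
    resolve_variant_ids(ids, retained)
  })
  carrier_counts <- table(factor(unlist(carrier_idx), levels = seq_len(nrow(retained))))
  carriers_per_variant <- setNames(
    as.integer(carrier_counts),
    ifelse(is.na(retained$variant_id),
           if ("location" %in% names(retained)) retained$location else retained$key,
           retained$variant_id)
  )
  first_age <- purrr::map_int(patients$ages_at_diagnosis, function(a) {
    if (length(a) == 0) NA_integer_ else as.integer(a[1])
  })
  novel <- is_novel(retained)
  n_with <- sum(counts$n_variants >= 1)
  ages <- sort(first_age[!is.na(first_age)])
  lower_median <- if (length(ages) == 0) NA_real_ else
    as.numeric(ages[ceiling(length(ages) / 2)])
  structure(
    list(
      n_patients = nrow(patients),
      n_with_variant = n_with,
      n_without_variant = nrow(patients) - n_with,
      n_multi_variant = sum(counts$n_variants >= 2),
      max_variants_per_patient = if (nrow(patients) == 0) 0L else max(counts$n_variants),
      n_retained_variants = nrow(retained),
      n_novel_variants = sum(novel),
      n_known_variants = sum(!novel),
      n_distinct_genes_known = length(unique(retained$gene[!novel])),
      carriers_per_variant = carriers_per_variant,
      variants_per_patient = setNames(counts$n_variants, counts$patient_id),
      min_age = if (length(ages)) min(ages) else NA_real_,
      median_age = lower_median,
      mean_age = if (length(ages)) mean(ages) else NA_real_,
      n_bilateral = sum(patients$bilateral, na.rm = TRUE),
      n_lund_negative = sum(patients$lund_negative, na.rm = TRUE)
    ),
    class = "cohort_summary"
  )
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary>\n")
  cat(sprintf("  %d patients: %d carry >=1 retained variant, %d carry none\n",
              x$n_patients, x$n_with_variant, x$n_without_variant))
  cat(sprintf("  %d multi-variant carriers; per-patient maximum %d\n",
              x$n_multi_variant, x$max_variants_per_patient))
  cat(sprintf("  %d retained variants: %d novel, %d known (in %d genes)\n",
              x$n_retained_variants, x$n_novel_variants, x$n_known_variants,
              x$n_distinct_genes_known))
  cat(sprintf("  age at first diagnosis: min %s, median %s, mean %.2f\n",
              x$min_age, x$median_age, x$mean_age))
  cat(sprintf("  %d bilateral, %d Lund-negative\n",
              x$n_bilateral, x$n_lund_negative))
  invisible(x)
}

#' Tidy and summary methods for cohort summaries
#'
#' `glance()` returns the scalar cohort statistics as one row; `tidy()`
#' returns the per-variant carrier counts.
#'
#' @param x A `cohort_summary` from [summarize_cohort()].
#' @param ... Unused.
#' @method glance cohort_summary
#' @export
glance.cohort_summary <- function(x, ...) {
  scalars <- x[setdiff(names(x), c("carriers_per_variant", "variants_per_patient"))]
  as_tibble(scalars)
}

#' @rdname glance.cohort_summary
#' @method tidy cohort_summary
#' @export
tidy.cohort_summary <- function(x, ...) {
  tibble(variant = names(x$carriers_per_variant),
         n_carriers = as.integer(x$carriers_per_variant))
}

#' @rdname glance.cohort_summary
#' @param object A `cohort_summary`.
#' @method autoplot cohort_summary
#' @export
autoplot.cohort_summary <- function(object, ...) {
  df <- tibble(n = as.integer(object$variants_per_patient))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n)) +
    ggplot2::geom_bar(fill = "steelblue") +
    ggplot2::labs(x = "retained variants carried", y = "patients",
                  title = "Variants per patient") +
    ggplot2::theme_minimal()
}

#' Overlap of index variants with an external validation cohort
#'
#' Matches prioritized (index) variants against the per-patient variant keys
#' of an independent cohort, by variant key so that variants without a dbSNP
#' record remain comparable (with an rs-number fallback when the validation
#' side carries no genomic keys).
#'
#' @param index_variants Variant tibble.
#' @param validation_cohort Named list, patient id -> key tibble (or a
#'   character vector of rs-numbers when keys are unavailable).
#' @return `list(shared = <tibble of shared index variants>,
#'   carrier_counts = <named integer>, patients_hit = <character>)`.
#' @export
validation_overlap <- function(index_variants, validation_cohort) {
  index <- prepare_variants(index_variants)
  per_patient <- purrr::imap(validation_cohort, function(v, pid) {
    if (is.character(v)) {
      idx <- match(v, index$variant_id)
    } else {
      keys <- normalize_variant_keys(as_tibble(v))$key
      idx <- match(keys, index$key)
    }
    unique(idx[!is.na(idx)])
  })
  hits <- unlist(per_patient)
  shared_idx <- sort(unique(hits))
  counts <- table(factor(hits, levels = shared_idx))
  shared <- index[shared_idx, , drop = FALSE]
  names_out <- ifelse(is.na(shared$variant_id), shared$key, shared$variant_id)
  list(
    shared = shared,
    carrier_counts = setNames(as.integer(counts), names_out),
    patients_hit = sort(names(per_patient)[lengths(per_patient) > 0])
  )
}
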