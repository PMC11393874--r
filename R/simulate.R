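#' Configuration for the synthetic cohort generator
#'
#' The generator emulates the statistical structure the cascade assumes: a
#' multi-patient cohort of annotated germline variants with rare and
#' ultra-rare allele frequencies, pathogenicity scores drawn per planted
#' stratum, representation-level missingness (unscored indels lack CADD;
#' non-missense variants lack REVEL), panel and off-panel genes, and
#' heterozygous per-patient genotypes. Every variant is constructed so that
#' its intended fate under [classify_variants()] is guaranteed: attribute
#' values are placed strictly inside the relevant threshold interval with a
#' margin of 1e-6, never on a boundary.
#'
#' Fates: `STRICT_GROUP1` and `STRICT_SUB1` are retained by the strict round;
#' `RELAXED_SUB2` only by the relaxed round (placed in a gene that also
#' hosts a strict-round variant, with either the allele frequency between the
#' strict and relaxed ceilings or the REVEL score between the relaxed and
#' strict floors); `FAIL_REVEL`, `COMMON_AF`, `LOW_CADD` and `OFF_PANEL` are
#' rejected, each by the rule named.
#'
#' @param n_patients Cohort size (the emulated screen used 63).
#' @param n_variants Number of variants to plant.
#' @param fate_fractions Named fractions over the seven fates (summing to 1);
#'   converted to counts by largest remainder.
#' @param fate_counts Named integer counts per fate; overrides
#'   `fate_fractions` when given.
#' @param fraction_missing_cadd Fraction of plantable variants emitted as
#'   unscored indels (CADD absent).
#' @param fraction_missing_revel Fraction of Group-2 strict variants with no
#'   REVEL score.
#' @param fraction_missing_af Fraction of strict-round variants with no
#'   reported frequency at all (ultra-rare).
#' @param fraction_novel Fraction of ultra-rare variants emitted without an
#'   rs-number (exercising novelty detection).
#' @param af_log10_range log10 interval rare frequencies are drawn from
#'   (upper end is capped below the strict ceiling).
#' @param carrier_lambda Mean extra carriers per variant beyond the first
#'   (Poisson; capped at `n_patients`).
#' @param filter A [filter_config()]; thresholds the construction targets.
#' @param seed Integer seed. Per-variant substreams are derived from it and
#'   the variant index, so extending `n_variants` does not reshuffle earlier
#'   variants.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_patients = 63,
                       n_variants = 100,
                       fate_fractions = c(
                         STRICT_GROUP1 = 0.10, STRICT_SUB1 = 0.20,
                         RELAXED_SUB2 = 0.15, FAIL_REVEL = 0.15,
                         COMMON_AF = 0.20, LOW_CADD = 0.10, OFF_PANEL = 0.10
                       ),
                       fate_counts = NULL,
                       fraction_missing_cadd = 0.15,
                       fraction_missing_revel = 0.3,
                       fraction_missing_af = 0.2,
                       fraction_novel = 1,
                       af_log10_range = c(-5, -2.1),
                       carrier_lambda = 0.8,
                       filter = filter_config(),
                       seed = 1L) {
  fates <- c("STRICT_GROUP1", "STRICT_SUB1", "RELAXED_SUB2", "FAIL_REVEL",
             "COMMON_AF", "LOW_CADD", "OFF_PANEL")
  stopifnot(n_patients >= 1, n_variants >= 0)
  if (is.null(fate_counts)) {
    if (abs(sum(fate_fractions) - 1) > 1e-9) {
      abort("sim_config: fate_fractions must sum to 1")
    }
    raw <- fate_fractions[fates]
    raw[is.na(raw)] <- 0
    counts <- floor(raw * n_variants)
    rem <- n_variants - sum(counts)
    if (rem > 0) {
      extra <- order(raw * n_variants - counts, decreasing = TRUE)[seq_len(rem)]
      counts[extra] <- counts[extra] + 1
    }
    fate_counts <- setNames(as.integer(counts), fates)
  } else {
    full <- setNames(integer(length(fates)), fates)
    full[names(fate_counts)] <- as.integer(fate_counts)
    fate_counts <- full
    n_variants <- sum(fate_counts)
  }
  if (fate_counts[["RELAXED_SUB2"]] > 0 &&
      fate_counts[["STRICT_GROUP1"]] + fate_counts[["STRICT_SUB1"]] == 0) {
    abort(paste0("sim_config error: RELAXED_SUB2 variants need a gene hosting ",
                 "a strict-round variant; plant at least one STRICT_* variant"))
  }
  props <- c(fraction_missing_cadd, fraction_missing_revel,
             fraction_missing_af, fraction_novel)
  stopifnot(all(props >= 0 & props <= 1))
  structure(
    list(
      n_patients = as.integer(n_patients),
      n_variants = as.integer(n_variants),
      fate_counts = fate_counts,
      fraction_missing_cadd = fraction_missing_cadd,
      fraction_missing_revel = fraction_missing_revel,
      fraction_missing_af = fraction_missing_af,
      fraction_novel = fraction_novel,
      af_log10_range = af_log10_range,
      carrier_lambda = carrier_lambda,
      filter = filter,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# Per-variant substream: a fixed function of (seed, index) only.
substream <- function(seed, i) {
  set.seed((abs(seed) %% 100003L) * 20011L + i)
}

margin <- 1e-6

#' Generate a synthetic annotated cohort with planted truth
#'
#' Draws `n_variants` annotated variants whose fate under the cascade is
#' fixed by construction (see [sim_config()]), assigns heterozygous carriers
#' among `n_patients` synthetic patients, and returns the truth labels. For
#' a fixed seed the output is reproducible element-for-element.
#'
#' @param config A [sim_config()].
#' @param panel_genes Symbols to draw on-panel genes from; defaults to the
#'   packaged DNA-repair panel.
#' @return `list(variants, patients, truth)`: a variant tibble, a patient
#'   tibble in the [read_patient_table()] shape, and a truth tibble with the
#'   planted `fate` per variant.
#' @export
simulate_cohort <- function(config = sim_config(),
                            panel_genes = NULL) {
  if (is.null(panel_genes)) {
    panel_genes <- load_panel(repairsieve_extdata("dna_repair_panel.txt"))$symbol
  }
  fc <- config$filter
  fates <- rep(names(config$fate_counts), times = config$fate_counts)
  n <- length(fates)
  patients <- paste0("P", sprintf("%03d", seq_len(config$n_patients)))
  if (n == 0) {
    return(list(variants = empty_variant_tbl(),
                patients = empty_patient_tbl(patients, config),
                truth = tibble(key = character(), variant_id = character(),
                               gene = character(), fate = character())))
  }
  # genes hosting strict variants come first so RELAXED_SUB2 can reuse them
  substream(config$seed, 0L)
  strict_idx <- which(fates %in% c("STRICT_GROUP1", "STRICT_SUB1"))
  strict_genes <- sample(panel_genes, max(1, min(length(strict_idx), length(panel_genes))),
                         replace = length(panel_genes) < length(strict_idx))
  bases <- c("A", "C", "G", "T")
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    substream(config$seed, i)
    fate <- fates[i]
    gene <- switch(
      fate,
      OFF_PANEL = paste0("OFFPANEL", i),
      RELAXED_SUB2 = sample(strict_genes, 1),
      STRICT_GROUP1 = ,
      STRICT_SUB1 = strict_genes[(match(i, strict_idx) - 1) %% length(strict_genes) + 1],
      sample(panel_genes, 1)
    )
    chrom <- as.character(sample(1:22, 1))
    pos <- 1000L * i + sample(1:999, 1)
    ref <- sample(bases, 1)
    alt <- sample(setdiff(bases, ref), 1)

    cadd_missing <- fate != "LOW_CADD" && runif(1) < config$fraction_missing_cadd
    if (fate == "LOW_CADD") {
      cadd <- runif(1, 0, fc$cadd_min - margin)
    } else if (cadd_missing) {
      cadd <- NA_real_
      # unscored variants are emitted as indels: CADD leaves many unscored
      alt <- paste0(ref, sample(bases, 1))
    } else {
      cadd <- runif(1, fc$cadd_min + margin, 60)
    }

    ultra <- fate %in% c("STRICT_GROUP1", "STRICT_SUB1") &&
      runif(1) < config$fraction_missing_af
    af <- function(lo, hi) signif(runif(1, lo, hi), 6)
    rare_af <- function(ceiling_af) {
      hi <- min(10^config$af_log10_range[2], ceiling_af - margin)
      signif(10^runif(1, config$af_log10_range[1], log10(hi)), 6)
    }
    afs <- rep(NA_real_, 4)
    if (fate == "COMMON_AF") {
      afs <- rep(af(fc$af_relaxed + margin, 0.5), 4)
    } else if (fate == "RELAXED_SUB2" && runif(1) < 0.5) {
      afs <- rep(af(fc$af_strict + margin, fc$af_relaxed - margin), 4)
      relax_via_af <- TRUE
    } else if (!ultra) {
      afs <- rep(rare_af(fc$af_strict), 4)
    }
    relax_via_af <- fate == "RELAXED_SUB2" && !is.na(afs[1]) && afs[1] >= fc$af_strict

    group1 <- fate == "STRICT_GROUP1"
    consequence <- if (group1) {
      sample(fc$group1_terms, 1)
    } else if (is.na(cadd) && nchar(alt) > 1) {
      "frameshift_variant"
    } else {
      "missense_variant"
    }

    revel <- NA_real_
    if (!group1) {
      revel_missing <- consequence != "missense_variant" ||
        (fate == "STRICT_SUB1" && runif(1) < config$fraction_missing_revel)
      revel <- if (revel_missing) NA_real_ else switch(
        fate,
        STRICT_SUB1 = runif(1, fc$revel_strict + margin, 1),
        RELAXED_SUB2 = if (relax_via_af) runif(1, fc$revel_relaxed + margin, 1)
                       else runif(1, fc$revel_relaxed + margin, fc$revel_strict - margin),
        FAIL_REVEL = runif(1, 0, fc$revel_relaxed - margin),
        runif(1, fc$revel_relaxed + margin, 1)
      )
      # these two fates hinge on a present REVEL score
      if (fate %in% c("RELAXED_SUB2", "FAIL_REVEL") && !relax_via_af && is.na(revel)) {
        revel <- if (fate == "FAIL_REVEL") runif(1, 0, fc$revel_relaxed - margin)
                 else runif(1, fc$revel_relaxed + margin, fc$revel_strict - margin)
      }
      if (fate == "FAIL_REVEL") {
        revel <- runif(1, 0, fc$revel_relaxed - margin)
        consequence <- "missense_variant"
      }
    }
    novel <- ultra && runif(1) < config$fraction_novel
    n_car <- min(config$n_patients, 1L + stats::rpois(1, config$carrier_lambda))
    carriers <- sample(patients, n_car)
    rows[[i]] <- tibble(
      chrom = chrom, pos = pos, ref = ref, alt = alt,
      variant_id = if (novel) NA_character_ else paste0("rs", 5e6 + i),
      gene = gene, gene_id = NA_character_,
      consequence = consequence, canonical = TRUE,
      hgvs_c = NA_character_, hgvs_p = NA_character_,
      sift = NA_real_, polyphen = NA_real_, revel = revel,
      cadd_phred = if (is.na(cadd)) NA_real_ else round(cadd, 2),
      af_exome_global = afs[1], af_genome_global = afs[2],
      af_exome_fin = afs[3], af_genome_fin = afs[4],
      carriers = list(sort(carriers)),
      homozygotes = list(character(0)),
      fate = fate
    )
  }
  variants <- normalize_variant_keys(list_rbind(rows))
  truth <- variants[, c("key", "variant_id", "gene", "fate")]
  variants$fate <- NULL
  pts <- empty_patient_tbl(patients, config)
  # patients carry the retained-fate variants they were assigned
  retained_fates <- c("STRICT_GROUP1", "STRICT_SUB1", "RELAXED_SUB2")
  idx <- which(truth$fate %in% retained_fates)
  ids <- ifelse(is.na(variants$variant_id), variants$key, variants$variant_id)
  pts$variant_ids <- purrr::map(pts$patient_id, function(p) {
    ids[idx][purrr::map_lgl(variants$carriers[idx], function(cc) p %in% cc)]
  })
  list(variants = variants, patients = pts, truth = truth)
}

empty_patient_tbl <- function(patient_ids, config) {
  substream(config$seed, -1L)
  n <- length(patient_ids)
  age1 <- sample(23:40, n, replace = TRUE)
  bilateral <- runif(n) < 0.19
  tibble(
    patient_id = patient_ids,
    lund_negative = runif(n) < 0.286,
    ages_at_diagnosis = purrr::map2(age1, bilateral, function(a, b) {
      if (b) c(a, min(a + sample(0:25, 1), 75)) else a
    }),
    bilateral = bilateral,
    triple_negative = runif(n) < 0.19,
    histology_text = NA_character_,
    variant_ids = rep(list(character(0)), n)
  )
}

#' Expected cascade call for a planted fate
#'
#' The mapping from the generator's truth labels to the calls
#' [classify_variants()] must produce; used to verify planted-fate recovery.
#'
#' @param fate Character vector of fate labels.
#' @return Tibble with expected `retained`, `group`, `subcategory`.
#' @export
fate_expectation <- function(fate) {
  tibble(
    fate = fate,
    retained = fate %in% c("STRICT_GROUP1", "STRICT_SUB1", "RELAXED_SUB2"),
    group = dplyr::case_when(
      fate == "STRICT_GROUP1" ~ "GROUP1",
      fate %in% c("STRICT_SUB1", "RELAXED_SUB2", "FAIL_REVEL") ~ "GROUP2",
      TRUE ~ NA_character_
    ),
    subcategory = dplyr::case_when(
      fate == "STRICT_SUB1" ~ "SUB1",
      fate == "RELAXED_SUB2" ~ "SUB2",
      TRUE ~ "NONE"
    )
  )
}
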