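test_that("CADD rule excludes scores below the floor, retains the unscored", {
  cfg <- filter_config()
  expect_true(cadd_pass(42, cfg))
  expect_true(cadd_pass(20, cfg))       # 'smaller than 20' excluded, 20 kept
  expect_false(cadd_pass(19.999, cfg))
  expect_true(cadd_pass(NA, cfg))
  expect_false(cadd_pass(NA, filter_config(retain_missing_cadd = FALSE)))
  expect_error(cadd_pass(-1, cfg), "negative")
})

test_that("REVEL rule is strictly-greater with missing retained", {
  cfg <- filter_config()
  expect_true(revel_pass(0.884, 0.75, cfg))
  expect_true(revel_pass(0.413, 0.4, cfg))
  expect_false(revel_pass(0.4, 0.4, cfg))
  expect_false(revel_pass(0.75, 0.75, cfg))
  expect_true(revel_pass(NA, 0.75, cfg))
  expect_false(revel_pass(NA, 0.75, filter_config(retain_missing_revel = FALSE)))
  expect_error(revel_pass(1.2, 0.75, cfg), "\\[0, 1\\]")
})

test_that("allele-frequency classing distinguishes rare, ultra-rare, excluded", {
  v <- dplyr::bind_rows(
    make_variant(af_exome_fin = 0.002491, af_genome_fin = 0.003159),
    make_variant(),                                    # all four absent
    make_variant(af_genome_global = 0.5),
    make_variant(af_exome_fin = 0, af_genome_fin = 0), # zero is reported
    make_variant(af_exome_fin = 0.01)                  # boundary: excluded
  )
  expect_equal(af_class(v, 0.01),
               c("RARE", "ULTRA_RARE", "EXCLUDED", "RARE", "EXCLUDED"))
  # every reported frequency must meet the ceiling
  mixed <- make_variant(af_exome_fin = 1e-5, af_genome_fin = 0.02)
  expect_equal(af_class(mixed, 0.01), "EXCLUDED")
  expect_equal(af_class(mixed, 0.05), "RARE")
})

test_that("consequence grouping splits strata with Group 1 precedence", {
  cfg <- filter_config()
  expect_equal(consequence_group("stop_gained", cfg), "GROUP1")
  expect_equal(consequence_group("missense_variant&splice_region_variant", cfg), "GROUP2")
  expect_equal(consequence_group("synonymous_variant", cfg), "OTHER")
  expect_equal(consequence_group("stop_gained&missense_variant", cfg), "GROUP1")
  expect_equal(consequence_group(list(c("frameshift_variant")), cfg), "GROUP2")
})

test_that("transcript choice prefers canonical, keeps non-transcript-only", {
  anns <- tibble::tibble(
    canonical = c(FALSE, TRUE),
    consequence = c("missense_variant", "missense_variant")
  )
  expect_equal(transcript_filter(anns), 2L)
  downstream <- tibble::tibble(canonical = FALSE,
                               consequence = "downstream_gene_variant")
  expect_equal(transcript_filter(downstream), 1L)
  noncanon <- tibble::tibble(canonical = FALSE,
                             consequence = "missense_variant")
  expect_true(is.na(transcript_filter(noncanon)))
  expect_true(is.na(transcript_filter(anns[0, ])))
})

test_that("strict round retains by the published predicate and reports genes", {
  panel <- tiny_panel(c("MSH3", "POLQ"))
  v <- dplyr::bind_rows(
    # MSH3 missense, rare, REVEL 0.884 -> subcategory 1
    make_variant(pos = 1L, variant_id = "rs199791286", gene = "MSH3",
                 revel = 0.884, cadd_phred = 32,
                 af_exome_fin = 0.001294, af_genome_fin = 0.001415),
    # POLQ missense at AF 0.01381 -> strict round must NOT retain it
    make_variant(pos = 2L, variant_id = "rs41540016", gene = "POLQ",
                 consequence = "missense_variant&splice_region_variant",
                 revel = 0.84, cadd_phred = 33,
                 af_exome_fin = 0.01381, af_genome_fin = 0.01208)
  )
  out <- run_strict(v, panel)
  expect_equal(out$calls$variant_id, "rs199791286")
  expect_equal(out$calls$subcategory, "SUB1")
  expect_equal(out$affected_genes, "MSH3")

  empty <- run_strict(v[0, ], panel)
  expect_equal(nrow(empty$calls), 0)
  expect_length(empty$affected_genes, 0)
})

test_that("relaxed round rescues within affected genes only", {
  panel <- tiny_panel(c("POLQ", "MSH3"))
  v <- dplyr::bind_rows(
    make_variant(pos = 2L, variant_id = "rs41540016", gene = "POLQ",
                 revel = 0.84, cadd_phred = 33,
                 af_exome_fin = 0.01381, af_genome_fin = 0.01208),
    # POLQ rare but mid REVEL: strict-fail, relaxed-pass
    make_variant(pos = 3L, variant_id = "rs2306211", gene = "POLQ",
                 revel = 0.571, cadd_phred = 28.8,
                 af_exome_fin = 0.007347, af_genome_fin = 0.006223),
    # same scores in a gene outside the affected set: not evaluated
    make_variant(pos = 4L, variant_id = "rs_other", gene = "MSH3",
                 revel = 0.571, cadd_phred = 28.8,
                 af_exome_fin = 0.007347)
  )
  out <- run_relaxed(v, affected_genes = "POLQ", panel = panel)
  expect_setequal(out$variant_id, c("rs41540016", "rs2306211"))
  expect_true(all(out$subcategory == "SUB2"))
})

test_that("the full cascade reproduces the published screen end to end", {
  calls <- classify_variants(eobc_variants(), dna_repair_panel())
  expect_equal(sum(calls$retained), 72)
  expect_equal(nrow(calls), 72)
  # printed examples
  expect_equal(calls$subcategory[calls$variant_id %in% "rs199791286"], "SUB1")
  expect_equal(calls$subcategory[calls$variant_id %in% "rs41540016"], "SUB2")
  expect_equal(calls$subcategory[calls$variant_id %in% "rs2306211"], "SUB2")
  expect_equal(calls$group[calls$variant_id %in% "rs193219754"], "GROUP1")
  expect_equal(calls$subcategory[calls$variant_id %in% "rs193219754"], "NONE")
  # a Group-1 variant at FIN AF between the two ceilings comes back through
  # the relaxed round
  expect_equal(calls$round[calls$variant_id %in% "rs11571833"], "relaxed")
  expect_equal(calls$group[calls$variant_id %in% "rs11571833"], "GROUP1")
  expect_true(all(nchar(calls$rule_trace) > 0))
})

test_that("a common variant in a panel gene is rejected as EXCLUDED", {
  v <- make_variant(gene = "WRN", revel = 0.99, cadd_phred = 35,
                    af_exome_fin = 0.3)
  calls <- classify_variants(v, tiny_panel())
  expect_false(calls$retained)
  expect_equal(calls$af_class, "EXCLUDED")
})

test_that("a single ultra-rare splice-acceptor variant is retained as Group 1", {
  v <- make_variant(gene = "WRN", consequence = "splice_acceptor_variant",
                    cadd_phred = 34)
  calls <- classify_variants(v, tiny_panel())
  expect_true(calls$retained)
  expect_equal(calls$group, "GROUP1")
  expect_equal(calls$subcategory, "NONE")
  expect_equal(calls$af_class, "ULTRA_RARE")
})

test_that("classification agrees with the brute-force oracle", {
  for (seed in c(11, 42)) {
    v <- random_variants(200, seed)
    got <- classify_variants(v, tiny_panel())
    want <- oracle_classify(v, tiny_panel()$symbol)
    expect_equal(got$retained, want$retained)
    expect_equal(got$group, want$group)
    expect_equal(got$subcategory, want$subcategory)
  }
})

test_that("classification is invariant under input permutation", {
  v <- random_variants(150, 7)
  calls <- classify_variants(v, tiny_panel())
  set.seed(99)
  perm <- sample(nrow(v))
  calls_perm <- classify_variants(v[perm, ], tiny_panel())
  m <- match(calls$key, calls_perm$key)
  expect_equal(calls$retained, calls_perm$retained[m])
  expect_equal(calls$subcategory, calls_perm$subcategory[m])
})

test_that("tightening thresholds never adds retained variants", {
  v <- random_variants(150, 13)
  base_cfg <- filter_config()
  base <- classify_variants(v, tiny_panel(), base_cfg)
  retained_base <- base$key[base$retained]
  harder <- list(
    filter_config(cadd_min = 25),
    filter_config(cadd_min = 35),
    filter_config(af_strict = 0.005, af_relaxed = 0.01),
    filter_config(af_strict = 0.001, af_relaxed = 0.002),
    filter_config(revel_strict = 0.9, revel_relaxed = 0.6)
  )
  for (cfg in harder) {
    calls <- classify_variants(v, tiny_panel(), cfg)
    expect_true(all(calls$key[calls$retained] %in% retained_base))
  }
})

test_that("strict retainees always satisfy the relaxed criteria", {
  v <- random_variants(150, 21)
  calls <- classify_variants(v, tiny_panel())
  strict_keys <- calls$key[calls$round %in% "strict"]
  relaxed_only <- oracle_classify(v, tiny_panel()$symbol,
                                  af_strict = 0.02, revel_strict = 0.4)
  expect_true(all(strict_keys %in% v$key[relaxed_only$retained]))
  expect_length(intersect(calls$key[calls$subcategory == "SUB1"],
                          calls$key[calls$subcategory == "SUB2"]), 0)
})

test_that("duplicate (key, gene) records are evaluated once", {
  v <- make_variant(gene = "WRN", cadd_phred = 30, revel = 0.9,
                    af_exome_fin = 0.001)
  calls <- classify_variants(dplyr::bind_rows(v, v), tiny_panel())
  expect_equal(nrow(calls), 1)
})
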