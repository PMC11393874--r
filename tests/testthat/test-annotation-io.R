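test_that("variant keys normalize contig names and indel spellings", {
  k <- normalize_variant_keys(
    tibble::tibble(chrom = "chr7", pos = 100L, ref = "tca", alt = "TCG")
  )
  expect_equal(k$chrom, "7")
  expect_equal(k$pos, 102L)
  expect_equal(k$ref, "A")
  expect_equal(k$alt, "G")

  # two caller spellings of the same deletion meet at one key
  a <- normalize_variant_keys(tibble::tibble(chrom = "1", pos = 100L, ref = "ATTT", alt = "AT"))
  b <- normalize_variant_keys(tibble::tibble(chrom = "chr1", pos = 100L, ref = "ATT", alt = "A"))
  expect_equal(a$key, b$key)

  expect_error(normalize_variant_keys(
    tibble::tibble(chrom = "1", pos = 0L, ref = "A", alt = "G")), "position")
  expect_error(normalize_variant_keys(
    tibble::tibble(chrom = "1", pos = 5L, ref = "A", alt = "N")), "alleles")
})

test_that("consensus intersection obeys set algebra", {
  keys <- function(pos) tibble::tibble(chrom = "2", pos = as.integer(pos),
                                       ref = "A", alt = "C")
  k123 <- keys(c(10, 20, 30))
  k24 <- keys(c(20, 40))

  expect_equal(consensus_merge(k123, k24)$pos, 20L)
  expect_equal(consensus_merge(k123, k123)$pos, c(10L, 20L, 30L))
  expect_equal(nrow(consensus_merge(keys(1), keys(2))), 0)
  # symmetry and containment
  ab <- consensus_merge(k123, k24)
  ba <- consensus_merge(k24, k123)
  expect_equal(ab$key, ba$key)
  expect_true(all(ab$key %in% normalize_variant_keys(k123)$key))
  expect_true(all(ab$key %in% normalize_variant_keys(k24)$key))
})

test_that("consensus refuses mixed reference builds", {
  a <- tibble::tibble(chrom = "1", pos = 5L, ref = "A", alt = "G")
  b <- a
  attr(a, "build") <- "GRCh38"
  attr(b, "build") <- "GRCh37"
  expect_error(consensus_merge(a, b), "mixed reference builds")
})

test_that("cohort merge unifies shared variants and conserves incidences", {
  v <- make_variant(pos = 500L, gene = "WRN")
  per_patient <- list(
    p1 = dplyr::bind_rows(v, make_variant(pos = 900L, gene = "ATM", variant_id = "rs9")),
    p2 = v,
    p3 = make_variant(pos = 700L, gene = "POLQ", variant_id = "rs7")
  )
  merged <- merge_cohort(per_patient)
  expect_equal(nrow(merged), 3)
  shared <- merged[merged$pos == 500L, ]
  expect_setequal(shared$carriers[[1]], c("p1", "p2"))
  # incidence conservation
  expect_equal(sum(lengths(merged$carriers)),
               sum(vapply(per_patient, nrow, integer(1))))
  expect_equal(nrow(merge_cohort(list())), 0)
})

test_that("cohort merge warns on conflicting annotations and keeps first", {
  v1 <- make_variant(cadd_phred = 30)
  v2 <- make_variant(cadd_phred = 31)
  expect_warning(m <- merge_cohort(list(a = v1, b = v2)), "conflicting")
  expect_equal(m$cadd_phred, 30)
})

test_that("CSQ schema parsing extracts ordered field names", {
  line <- '##INFO=<ID=CSQ,Number=.,Type=String,Description="Consequence annotations from VEP. Format: Consequence|SYMBOL|CANONICAL|REVEL">'
  expect_equal(parse_csq_schema(line),
               c("Consequence", "SYMBOL", "CANONICAL", "REVEL"))

  shuffled <- c("REVEL", "SYMBOL", "gnomADe_AF", "CADD_PHRED", "Consequence",
                "CANONICAL", "HGVSc", "Gene", "SIFT", "PolyPhen", "Allele",
                "gnomADg_AF")
  line2 <- paste0('##INFO=<ID=CSQ,Description="... Format: ',
                  paste(shuffled, collapse = "|"), '">')
  expect_equal(parse_csq_schema(line2), shuffled)

  expect_error(parse_csq_schema('##INFO=<ID=CSQ,Description="Format: Consequence|SYMBOL">'),
               "CANONICAL")
  expect_error(parse_csq_schema('##INFO=<ID=CSQ,Description="no clause here">'),
               "Format")
})

test_that("VCF reading decomposes alleles, maps blanks to NA, fills carriers", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(path, c(
    # single-sample het record; REVEL empty -> absent
    "chr5\t1000\trs100\tA\tG\t.\tPASS\tCSQ=G|missense_variant|WRN|ENSG1|YES|||0.01|0.9||25.0|0.001|||\tGT\t0/1\t0/0",
    # multi-allelic: two ALT alleles, per-allele CSQ entries
    "chr5\t2000\t.\tC\tT,A\t.\tPASS\tCSQ=T|missense_variant|ATM||YES||||||30||||,A|stop_gained|ATM||YES||||||31||||\tGT\t0/1\t0/2"
  ))
  v <- read_vcf_variants(path)
  expect_equal(nrow(v), 3)
  first <- v[v$pos == 1000L, ]
  expect_equal(first$carriers[[1]], "P1")
  expect_true(is.na(first$revel))
  expect_equal(first$cadd_phred, 25)
  expect_equal(first$af_exome_global, 0.001)
  multi <- v[v$pos == 2000L, ]
  expect_equal(nrow(multi), 2)
  expect_setequal(multi$alt, c("T", "A"))
  expect_equal(multi$carriers[[which(multi$alt == "T")]], "P1")
  expect_equal(multi$carriers[[which(multi$alt == "A")]], "P2")
  expect_equal(attr(v, "build"), "GRCh38")
})

test_that("VCF reading applies transcript selection per gene", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(path, c(
    # canonical entry wins over a non-canonical one
    "chr1\t100\trs1\tA\tG\t.\tPASS\tCSQ=G|synonymous_variant|WRN|||||||||||| ,G|missense_variant|WRN||YES||||||22||||\tGT\t0/1\t0/0",
    # non-canonical-only transcript variant is dropped
    "chr1\t200\trs2\tA\tG\t.\tPASS\tCSQ=G|missense_variant|ATM||||||||||||\tGT\t0/1\t0/0",
    # downstream-gene-only annotation is kept without a canonical flag
    "chr1\t300\trs3\tA\tG\t.\tPASS\tCSQ=G|downstream_gene_variant|ERCC1||||||||||||\tGT\t0/1\t0/0"
  ))
  v <- read_vcf_variants(path)
  expect_setequal(v$variant_id, c("rs1", "rs3"))
  expect_equal(v$consequence[v$variant_id == "rs1"], "missense_variant")
  expect_true(v$canonical[v$variant_id == "rs1"])
})

test_that("malformed CSQ entries raise record-level errors", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(path, c(
    "chr1\t100\trs1\tA\tG\t.\tPASS\tCSQ=G|missense_variant|WRN|x|YES|a|b|c|d|e|f|g|h|i|j|EXTRA\tGT\t0/1\t0/0"
  ))
  expect_error(read_vcf_variants(path), "record 1")
})

test_that("flat variant table reading matches the documented dialect", {
  v <- eobc_variants()
  expect_equal(nrow(v), 72)
  expect_equal(sum(is.na(v$variant_id)), 8)

  mlh3 <- v[v$variant_id %in% "rs193219754", ]
  expect_equal(mlh3$gene, "MLH3")
  expect_equal(mlh3$cadd_phred, 42)
  expect_equal(mlh3$af_exome_fin, 0.002491)
  expect_true(is.na(mlh3$revel))
  expect_equal(mlh3$consequence, "stop_gained")

  rnf4 <- v[v$location %in% "chr4:2490336", ]
  expect_true(is.na(rnf4$variant_id))
  expect_true(all(is.na(c(rnf4$af_exome_fin, rnf4$af_genome_fin,
                          rnf4$af_exome_global, rnf4$af_genome_global))))

  # scientific-notation frequencies parse exactly
  rad54l <- v[v$variant_id %in% "rs766240074", ]
  expect_identical(rad54l$af_exome_fin, 4.968e-05)
  expect_identical(rad54l$af_genome_fin, 0)
})

test_that("a header-only table yields an empty variant set", {
  path <- withr::local_tempfile(fileext = ".tsv")
  hdr <- paste(c("variant_id", "gene", "location", "nucleotide_change",
                 "protein_change", "consequence", "subcategory",
                 "af_exome_fin", "af_genome_fin", "af_exome_global",
                 "af_genome_global", "sift", "polyphen", "revel",
                 "cadd_phred"), collapse = "\t")
  writeLines(hdr, path)
  expect_equal(nrow(read_variant_table(path)), 0)
})

test_that("table reading rejects unknown columns and non-numeric scores", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("variant_id\tbogus", "rs1\tx"), path)
  expect_error(read_variant_table(path), "unknown column")

  path2 <- withr::local_tempfile(fileext = ".tsv")
  src <- readr::read_lines(repairsieve_extdata("eobc_variants.tsv"))
  src[2] <- sub("\t42$", "\tforty-two", src[2])
  writeLines(src, path2)
  expect_error(read_variant_table(path2), "non-numeric")
})

test_that("the table dialect round-trips field-for-field", {
  path <- withr::local_tempfile(fileext = ".tsv")
  v <- eobc_variants()
  write_variant_table(v, path)
  reread <- read_variant_table(path)
  expect_equal(as.data.frame(reread), as.data.frame(v))
  expect_identical(readr::read_lines(path),
                   readr::read_lines(repairsieve_extdata("eobc_variants.tsv")))
})
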