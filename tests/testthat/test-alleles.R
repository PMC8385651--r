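test_that("emitted VCF round-trips allele depths through the reader", {
  co <- simulate_cohort(small_cohort_config(seed = 31))
  obs <- dplyr::filter(co$dna, assay == "amplicon")
  path <- withr::local_tempfile(fileext = ".vcf")
  emit_vcf(obs, path)
  back <- read_allele_depths(path)
  merged <- dplyr::inner_join(
    obs, back,
    by = c("chrom", "pos", "ref", "alt", "sample_id"),
    suffix = c("", ".vcf")
  )
  expect_equal(nrow(merged), nrow(obs))
  expect_equal(merged$ref_depth.vcf, merged$ref_depth)
  expect_equal(merged$alt_depth.vcf, merged$alt_depth)
  expect_equal(merged$quality.vcf, merged$quality)
  # sample-name metadata recovered
  expect_equal(merged$individual_id.vcf, merged$individual_id)
  expect_equal(merged$material.vcf, merged$material)
})

test_that("plain and multi-allelic AD fields decompose into ref-vs-alt pairs", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"d\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    "Chr18\t100\t.\tA\tT\t60\tPASS\t.\tGT:AD\t0/1:30,30",
    "Chr18\t200\t.\tG\tA,C\t60\tPASS\t.\tGT:AD\t0/1:20,15,5"
  ), path)
  obs <- read_allele_depths(path)
  expect_equal(nrow(obs), 3)
  bi <- obs[obs$pos == 100, ]
  expect_equal(c(bi$ref_depth, bi$alt_depth), c(30, 30))
  tri <- obs[obs$pos == 200, ]
  expect_equal(tri$alt, c("A", "C"))
  expect_equal(tri$ref_depth, c(20, 20))
  expect_equal(tri$alt_depth, c(15, 5))
})

test_that("a VCF without AD is rejected", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    "Chr18\t100\t.\tA\tT\t60\tPASS\t.\tGT\t0/1"
  ), path)
  expect_error(read_allele_depths(path), "AD")
})

test_that("the quality filter removes sites below Phred 15, inclusively at 15", {
  obs <- tibble::tibble(
    chrom = "Chr18", pos = 1:4, ref = "A", alt = "T",
    quality = c(14.9, 15, 10, 60), ref_depth = 10, alt_depth = 10
  )
  kept <- filter_by_quality(obs)
  expect_equal(kept$quality, c(15, 60))
  expect_equal(filter_by_quality(kept), kept) # idempotent
  expect_equal(nrow(filter_by_quality(obs[0, ])), 0)
  expect_equal(filter_by_quality(obs, min_phred = 0), obs)
})

test_that("a low-QUAL site written to VCF is removed by the default filter", {
  co <- simulate_cohort(small_cohort_config(seed = 17))
  obs <- dplyr::filter(co$dna, assay == "amplicon")
  bad_pos <- obs$pos[1]
  obs$quality[obs$pos == bad_pos] <- 10
  path <- withr::local_tempfile(fileext = ".vcf")
  emit_vcf(obs, path)
  back <- filter_by_quality(read_allele_depths(path))
  expect_false(bad_pos %in% back$pos)
  expect_true(all(setdiff(unique(obs$pos), bad_pos) %in% back$pos))
})

test_that("allelic fractions behave and fail where they must", {
  expect_equal(allelic_fraction(30, 30), 0.5)
  expect_equal(allelic_fraction(10, 90), 0.9)
  expect_error(allelic_fraction(0, 0), "zero total depth")
  # complementarity under allele swap
  set.seed(2)
  r <- sample(1:100, 20)
  a <- sample(1:100, 20)
  expect_equal(allelic_fraction(r, a) + allelic_fraction(a, r), rep(1, 20))
})

test_that("DNA genotyping follows depth, band and homozygosity-test rules", {
  obs <- tibble::tibble(
    material = "DNA",
    ref_depth = c(50, 99, 5, 80),
    alt_depth = c(50, 1, 5, 20)
  )
  calls <- call_genotype_dna(obs)
  # fraction 0.5 inside the het band
  expect_equal(calls$call[1], "het")
  # one minor read in 100 at error rate 1%: exact binomial keeps homozygosity
  expect_equal(calls$call[2], "hom_ref")
  expect_gt(binom.test(1, 100, 0.01)$p.value, 0.05)
  # depth 10 below min_depth 20
  expect_equal(calls$call[3], "undetermined")
  # fraction 0.2 sits on the band edge: het
  expect_equal(calls$call[4], "het")
  # cDNA input is a usage error
  expect_error(
    call_genotype_dna(dplyr::mutate(obs, material = "cDNA")),
    "DNA"
  )
})

test_that("a clean homozygote with excess minor reads is undetermined", {
  obs <- tibble::tibble(ref_depth = 850, alt_depth = 150) # fraction 0.15
  calls <- call_genotype_dna(obs)
  expect_equal(calls$call, "undetermined")
})

test_that("het recall and false-het rate meet targets at 30x", {
  set.seed(123)
  n <- 2000
  het <- sample_allele_depths(0.5, 30, seq_error = 0.005, rho = 0.02, n = n)
  hom <- sample_allele_depths(0, 30, seq_error = 0.005, rho = 0.02, n = n)
  het_calls <- call_genotype_dna(het)
  hom_calls <- call_genotype_dna(hom)
  recall <- mean(het_calls$call == "het")
  false_het <- mean(hom_calls$call == "het")
  expect_gte(recall, 0.95)
  expect_lte(false_het, 0.01)
})
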