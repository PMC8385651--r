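site_obs <- function(ref_reads, alt_reads, pos = 1, individual = "M01",
                     tissue = "leaves") {
  tibble::tibble(
    chrom = "Chr18", pos = pos, ref = "A", alt = "T",
    individual_id = individual, material = "cDNA", tissue = tissue,
    gene_id = "g1", ref_depth = ref_reads, alt_depth = alt_reads
  )
}

het_call <- function(pos = 1, individual = "M01", call = "het") {
  tibble::tibble(
    chrom = "Chr18", pos = pos, ref = "A", alt = "T",
    individual_id = individual, call = call
  )
}

test_that("site classification reads the cDNA fraction against the threshold", {
  out <- classify_site_rna(site_obs(2, 98), het_call())
  expect_equal(out$class, "monoallelic_alt")
  expect_equal(out$cdna_fraction, 0.98)
  expect_equal(classify_site_rna(site_obs(48, 52), het_call())$class, "biallelic")
  expect_equal(classify_site_rna(site_obs(2, 3), het_call())$class, "undetermined")
  # non-het DNA sites are not informative
  expect_equal(nrow(classify_site_rna(site_obs(2, 98),
                                      het_call(call = "hom_ref"))), 0)
})

test_that("site classification is symmetric under ref/alt relabeling", {
  swapped <- classify_site_rna(site_obs(98, 2), het_call())
  expect_equal(swapped$class, "monoallelic_ref")
  straight <- classify_site_rna(site_obs(2, 98), het_call())
  expect_equal(straight$cdna_fraction, 1 - swapped$cdna_fraction)
})

test_that("missing join keys raise an informative error", {
  expect_error(
    classify_site_rna(dplyr::select(site_obs(1, 2), -individual_id), het_call()),
    "individual_id"
  )
})

multi_tissue_sites <- function(classes_by_tissue, individual = "M01") {
  purrr::imap_dfr(classes_by_tissue, function(classes, tissue) {
    tibble::tibble(
      gene_id = "g1", individual_id = individual, sex = "male",
      tissue = tissue, pos = seq_along(classes), class = classes
    )
  })
}

test_that("gene aggregation requires cross-tissue consistency", {
  mono <- rep("monoallelic_alt", 3)
  bi <- rep("biallelic", 3)
  all_mono <- aggregate_gene_ase(multi_tissue_sites(
    list(leaves = mono, catkin_axes = mono, flowers = mono)
  ))
  expect_equal(all_mono$class, "monoallelic")
  expect_equal(all_mono$n_tissues_consistent, 3)
  all_bi <- aggregate_gene_ase(multi_tissue_sites(
    list(leaves = bi, catkin_axes = bi, flowers = bi)
  ))
  expect_equal(all_bi$class, "biallelic")
  mixed <- aggregate_gene_ase(multi_tissue_sites(
    list(leaves = mono, catkin_axes = bi)
  ))
  expect_equal(mixed$class, "undetermined")
})

test_that("gene aggregation needs enough informative sites", {
  one_site <- aggregate_gene_ase(multi_tissue_sites(
    list(leaves = "monoallelic_alt")
  ))
  expect_equal(one_site$class, "undetermined")
  expect_equal(one_site$n_informative_sites, 1)
  nothing <- aggregate_gene_ase(multi_tissue_sites(
    list(leaves = rep("undetermined", 3))
  ))
  expect_equal(nothing$class, "undetermined")
  expect_equal(nothing$n_informative_sites, 0)
  empty <- multi_tissue_sites(list(leaves = "biallelic"))[0, ]
  expect_equal(nrow(aggregate_gene_ase(empty)), 0)
})

test_that("a within-tissue minority of discordant sites is tolerated", {
  sites <- multi_tissue_sites(list(
    leaves = c(rep("monoallelic_alt", 4), "biallelic"),
    flowers = rep("monoallelic_ref", 5)
  ))
  expect_equal(aggregate_gene_ase(sites)$class, "monoallelic")
})

cohort_calls <- function(n_male_mono, n_female_mono, n_male = 10, n_female = 10,
                         gene = "g1") {
  tibble::tibble(
    gene_id = gene,
    individual_id = c(sprintf("M%02d", seq_len(n_male)),
                      sprintf("F%02d", seq_len(n_female))),
    sex = rep(c("male", "female"), c(n_male, n_female)),
    class = c(
      rep(c("monoallelic", "biallelic"), c(n_male_mono, n_male - n_male_mono)),
      rep(c("monoallelic", "biallelic"), c(n_female_mono, n_female - n_female_mono))
    )
  )
}

test_that("a clean 10-vs-0 split gives the exact hypergeometric p", {
  res <- tidy(sex_association(cohort_calls(10, 0)))
  expect_equal(res$p_value, 1 / choose(20, 10), tolerance = 1e-12)
  expect_equal(res$p_value, 5.4128e-6, tolerance = 1e-4)
  expect_equal(res$label, "male_associated_ASE")
  expect_equal(res$direction, "male")
})

test_that("null and weak patterns stay unlabelled", {
  expect_equal(tidy(sex_association(cohort_calls(0, 0)))$label, "none")
  weak <- tidy(sex_association(cohort_calls(1, 0)))
  expect_equal(weak$p_value, 0.5, tolerance = 1e-12)
  expect_equal(weak$label, "none")
})

test_that("female-directed patterns are labelled symmetrically", {
  res <- tidy(sex_association(cohort_calls(0, 10)))
  expect_equal(res$label, "female_associated_ASE")
  expect_equal(res$p_value, 1 / choose(20, 10), tolerance = 1e-12)
})

test_that("undetermined individuals are excluded from the table", {
  calls <- cohort_calls(10, 0)
  calls$class[calls$individual_id == "F01"] <- "undetermined"
  res <- tidy(sex_association(calls))
  expect_equal(res$n_female_bi, 9)
  expect_equal(res$n_undetermined, 1)
  all_und <- dplyr::mutate(cohort_calls(0, 0), class = "undetermined")
  res2 <- tidy(sex_association(all_und))
  expect_true(is.na(res2$p_value))
  expect_equal(res2$label, "none")
})

test_that("duplicate calls per individual are rejected", {
  dup <- dplyr::bind_rows(cohort_calls(1, 1), cohort_calls(1, 1))
  expect_error(sex_association(dup), "at most one call")
})

test_that("the Fisher p matches hypergeometric enumeration for all margins <= 20", {
  for (n_male in c(3, 7, 10)) {
    for (n_female in c(4, 10)) {
      for (a in 0:n_male) {
        for (c_ in 0:n_female) {
          expected <- enumerate_fisher_p(a, n_male - a, c_, n_female - c_)
          got <- fisher.test(
            matrix(c(a, n_male - a, c_, n_female - c_), 2, byrow = TRUE),
            alternative = "greater"
          )$p.value
          expect_equal(got, expected, tolerance = 1e-10)
        }
      }
    }
  }
})

test_that("false-positive rate on null cohorts stays below alpha", {
  set.seed(2024)
  n_rep <- 500
  hits <- 0
  for (r in seq_len(n_rep)) {
    # null: monoallelic calls equally likely (20%) in both sexes
    class <- ifelse(stats::runif(20) < 0.2, "monoallelic", "biallelic")
    calls <- tibble::tibble(
      gene_id = "g1",
      individual_id = sprintf("i%02d", 1:20),
      sex = rep(c("male", "female"), each = 10),
      class = class
    )
    res <- tidy(sex_association(calls))
    hits <- hits + (res$label != "none")
  }
  expect_lte(hits / n_rep, 0.05)
})

test_that("bonferroni correction rescales across the gene panel", {
  calls <- dplyr::bind_rows(
    cohort_calls(7, 1, gene = "g1"), # marginal signal
    cohort_calls(0, 0, gene = "g2"),
    cohort_calls(0, 0, gene = "g3")
  )
  plain <- tidy(sex_association(calls))
  corr <- tidy(sex_association(calls, correction = "bonferroni"))
  expect_equal(corr$p_adjusted, pmin(plain$p_value * 3, 1))
})

test_that("single-individual DNA/cDNA concordance reproduces the sexed patterns", {
  cfg <- truth_config(n_males = 1, n_females = 1, seed = 10)
  co <- simulate_cohort(cfg)
  symbols <- setNames(cfg$genes$symbol, cfg$genes$gene_id)
  for (ind in c("M01", "F01")) {
    dna <- call_genotype_dna(
      dplyr::filter(co$dna, assay == "wgs", individual_id == ind,
                    !is.na(gene_id)),
      min_depth = 10 # WGS depth ~18-26x
    )
    rna <- dplyr::filter(co$rna, assay == "bulk_rna", individual_id == ind)
    tab <- compare_wgs_rna_het_sites(dna, rna, min_depth = 20)
    tab$symbol <- symbols[tab$gene_id]
    expect_setequal(unique(tab$symbol), c("TCP", "CLC", "MET1"))
    if (ind == "M01") {
      expect_true(all(tab$majority[tab$symbol == "CLC"] == "monoallelic"))
      expect_true(all(tab$majority[tab$symbol != "CLC"] == "biallelic"))
    } else {
      expect_true(all(tab$majority == "biallelic"))
    }
  }
  # no overlapping sites yields an empty table
  empty <- compare_wgs_rna_het_sites(
    dplyr::filter(co$dna, assay == "wgs", individual_id == "M01")[0, ] |>
      call_genotype_dna(),
    dplyr::filter(co$rna, individual_id == "M01")
  )
  expect_equal(nrow(empty), 0)
})

test_that("planted truth is recovered across seeds", {
  n_seeds <- 40
  good <- 0
  for (s in seq_len(n_seeds)) {
    co <- simulate_cohort(truth_config(seed = 1000 + s))
    res <- tidy(run_ase_stages(co))
    symbols <- setNames(co$config$genes$symbol, co$config$genes$gene_id)
    res$symbol <- symbols[res$gene_id]
    ok <- all(res$label[res$symbol == "CLC"] == "male_associated_ASE") &&
      all(res$label[res$symbol != "CLC"] == "none")
    good <- good + ok
  }
  expect_gte(good / n_seeds, 0.95)
})
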