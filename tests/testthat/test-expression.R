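toy_counts <- function() {
  tibble::tibble(
    gene_id = sprintf("g%02d", 1:10),
    A = c(100, 200, 300, 50, 80, 120, 60, 90, 500, 40),
    B = c(110, 190, 310, 55, 75, 125, 65, 85, 480, 45)
  )
}

test_that("CPM columns sum to one million and honour the worked example", {
  m <- tibble::tibble(gene_id = c("a", "b", "c"), L1 = c(1, 1, 2))
  expect_equal(unname(cpm(m)[, "L1"]), c(250000, 250000, 500000))
  set.seed(9)
  rand <- tibble::tibble(
    gene_id = sprintf("g%d", 1:50),
    X = rpois(50, 100), Y = rpois(50, 300), Z = rpois(50, 20) + 1
  )
  expect_equal(unname(colSums(cpm(rand))), rep(1e6, 3))
  # unit factors leave CPM unchanged
  f1 <- setNames(rep(1, 3), c("X", "Y", "Z"))
  expect_equal(cpm(rand, f1), cpm(rand))
})

test_that("a zero-total library is reported by name", {
  bad <- tibble::tibble(gene_id = c("a", "b"), L1 = c(1, 2), L2 = c(0, 0))
  expect_error(cpm(bad), "L2")
})

test_that("TMM factors are unity on identical columns and multiply to one", {
  eq <- toy_counts()
  eq$B <- eq$A
  expect_equal(unname(tmm_factors(eq)), c(1, 1))
  # a pure depth doubling is absorbed by the library size, factors stay ~1
  doubled <- toy_counts()
  doubled$B <- doubled$A * 2
  f <- tmm_factors(doubled)
  expect_equal(prod(f), 1, tolerance = 1e-10)
  expect_equal(unname(f["B"] / f["A"]), 1, tolerance = 1e-6)
  set.seed(31)
  rand <- tibble::tibble(
    gene_id = sprintf("g%d", 1:200),
    U = rpois(200, 50), V = rpois(200, 150), W = rpois(200, 80)
  )
  expect_equal(prod(tmm_factors(rand)), 1, tolerance = 1e-10)
  expect_true(all(tmm_factors(rand) > 0))
})

test_that("TMM compensates composition bias from a spiked gene block", {
  set.seed(41)
  base <- rpois(400, 100)
  spiked <- base
  spiked[1:40] <- spiked[1:40] * 20 # 10% of genes massively up in B
  counts <- tibble::tibble(gene_id = sprintf("g%d", seq_along(base)),
                           A = base, B = spiked)
  f <- tmm_factors(counts)
  x <- cpm(counts, f)
  unspiked <- 41:400
  ratio <- median(x[unspiked, "B"] / x[unspiked, "A"])
  expect_equal(ratio, 1, tolerance = 0.05)
  # without factors the unspiked genes appear depleted in B
  x0 <- cpm(counts)
  expect_lt(median(x0[unspiked, "B"] / x0[unspiked, "A"]), 0.85)
})

test_that("the fold-change screen applies the CPM floor and twofold rule", {
  # libraries padded to equal totals of 1e6 so CPM values equal raw counts
  counts <- tibble::tibble(
    gene_id = c("strong", "low", "flat", "filler"),
    A1 = c(1000, 7, 500, 0), A2 = c(1100, 7, 510, 0),
    B1 = c(100, 3, 505, 0), B2 = c(110, 3, 495, 0)
  )
  for (l in c("A1", "A2", "B1", "B2")) {
    counts[[l]][4] <- 1e6 - sum(counts[[l]][1:3])
  }
  hits <- deg_screen(counts, c("A1", "A2"), c("B1", "B2"), use_tmm = FALSE)
  expect_true("strong" %in% hits$gene_id)
  # flat: no fold change; low: CPM 7 vs 3 fails the CPM > 8 floor
  expect_false("flat" %in% hits$gene_id)
  expect_false("low" %in% hits$gene_id)
  expect_equal(unname(hits$fold_change[hits$gene_id == "strong"]), 10,
               tolerance = 0.1)

  # groups with identical expression yield nothing
  mirror <- tibble::tibble(gene_id = c("x", "y"),
                           A1 = c(100, 200), B1 = c(100, 200))
  expect_equal(nrow(deg_screen(mirror, "A1", "B1", use_tmm = FALSE)), 0)
  expect_error(deg_screen(counts, character(0), "B1"), "non-empty")
})

test_that("the screen is symmetric in its groups up to fold direction", {
  set.seed(5)
  counts <- tibble::tibble(
    gene_id = sprintf("g%d", 1:100),
    A1 = rpois(100, 200), A2 = rpois(100, 200),
    B1 = rpois(100, 200), B2 = rpois(100, 200)
  )
  counts$A1[1:5] <- counts$A1[1:5] * 6
  counts$A2[1:5] <- counts$A2[1:5] * 6
  ab <- deg_screen(counts, c("A1", "A2"), c("B1", "B2"))
  ba <- deg_screen(counts, c("B1", "B2"), c("A1", "A2"))
  expect_setequal(ab$gene_id, ba$gene_id)
  both <- dplyr::inner_join(ab, ba, by = "gene_id")
  expect_equal(both$fold_change.x, 1 / both$fold_change.y, tolerance = 1e-10)
})

test_that("overlapping groups are rejected", {
  expect_error(deg_screen(toy_counts(), "A", c("A", "B")), "disjoint")
})

test_that("spearman distance matches a rank-then-pearson oracle", {
  counts <- tibble::tibble(
    gene_id = sprintf("g%d", 1:5),
    L1 = c(5, 10, 20, 40, 80),
    L2 = c(6, 11, 19, 41, 78),
    L3 = c(80, 40, 20, 10, 5)
  )
  d <- spearman_distance(counts, min_mean_cpm = 0, use_tmm = FALSE)
  x <- cpm(counts)
  oracle <- 1 - stats::cor(apply(x, 2, rank))
  expect_equal(unclass(d), oracle, tolerance = 1e-12, ignore_attr = TRUE)
  # duplicate profiles at distance 0, rank-reversed at distance 2
  expect_equal(d["L1", "L2"], 1 - stats::cor(rank(x[, "L1"]), rank(x[, "L2"])))
  dup <- counts
  dup$L2 <- dup$L1
  d2 <- spearman_distance(dup, min_mean_cpm = 0, use_tmm = FALSE)
  expect_equal(d2["L1", "L2"], 0)
  expect_equal(d["L1", "L3"], 2)
})

test_that("distance matrices are symmetric, zero-diagonal and in [0, 2]", {
  set.seed(12)
  for (r in 1:5) {
    counts <- tibble::tibble(gene_id = sprintf("g%d", 1:60))
    for (l in 1:4) counts[[paste0("L", l)]] <- rpois(60, sample(50:500, 1))
    d <- spearman_distance(counts, min_mean_cpm = 0)
    expect_equal(unclass(d), t(unclass(d)), ignore_attr = TRUE)
    expect_equal(unname(diag(d)), rep(0, 4))
    expect_true(all(d >= 0 & d <= 2))
  }
})

test_that("too few genes after the CPM filter is an error", {
  counts <- tibble::tibble(gene_id = c("a", "b"), L1 = c(1, 1e6), L2 = c(1, 1e6))
  expect_error(spearman_distance(counts, min_mean_cpm = 1e5), "pass the mean-CPM filter")
})

test_that("sexes are closer in leaves than in generative tissues", {
  n_rep <- 15
  good <- 0
  for (s in seq_len(n_rep)) {
    co <- simulate_cohort(truth_config(n_males = 1, n_females = 1,
                                       n_background_genes = 800,
                                       seed = 300 + s))
    d <- spearman_distance(co$counts)
    libs <- co$libraries
    lib_of <- function(sex, tissue) {
      libs$library_id[libs$sex == sex & libs$tissue == tissue]
    }
    leaf_d <- d[lib_of("male", "leaves"), lib_of("female", "leaves")]
    flower_d <- d[lib_of("male", "flowers"), lib_of("female", "flowers")]
    good <- good + (leaf_d < flower_d)
  }
  expect_gte(good / n_rep, 0.95)
})
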