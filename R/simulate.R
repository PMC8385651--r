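#' Ground-truth configuration for a synthetic poplar cohort
#'
#' Builds the full generative specification of a synthetic cohort emulating
#' a two-tier study design: one male and one female with ~18x / ~26x whole-genome
#' sequencing and bulk RNA-seq of three tissues (six libraries), plus a deep
#' targeted-amplicon panel over 10 male and 10 female plants sampled as DNA
#' from leaves and cDNA from leaves, catkin axes and flowers (80 samples).
#'
#' @param n_males,n_females Number of individuals per sex (default 10 + 10,
#'   the amplicon panel design).
#' @param tissues Tissue labels for cDNA sampling.
#' @param genes Gene truth tibble as from [gene_truth()]: annotated intervals
#'   plus `expr_rate` (expected RNA-seq counts per library),
#'   `y_fraction_male` (fraction of male transcripts from the Y-haplotype
#'   allele; 0 plants Y-allele silencing, the CLC pattern) and
#'   `allele_fraction_female` (alt-allele expression fraction in females,
#'   default 0.5 = biallelic).
#' @param hemizygous_regions Interval tibble of Y-specific (male-hemizygous)
#'   regions; females have zero coverage there, males one-haplotype coverage.
#' @param n_het_sites_per_gene Heterozygous sites planted per gene.
#' @param wgs_depth_male,wgs_depth_female Mean diploid per-base WGS depth.
#' @param rna_depth Mean allele-informative cDNA depth per site (bulk RNA-seq).
#' @param amplicon_depth Mean depth per site in the amplicon panel (deep by
#'   design).
#' @param seq_error Per-base sequencing error probability in `[0, 0.5)`.
#' @param overdispersion_rho Beta-binomial intra-class correlation in `[0, 1)`;
#'   0 degenerates to binomial sampling.
#' @param qual Phred-scaled site quality written to emitted VCFs (default 60,
#'   so default runs pass the quality filter).
#' @param region Region scanned for hemizygosity, binned at `bin_width`.
#' @param bin_width Coverage bin width in bp.
#' @param n_background_genes Non-SDR genes in the bulk count matrix.
#' @param frac_leaf_biased,frac_generative_biased Fraction of background genes
#'   with a sex-biased expression planted in leaves or in the two generative
#'   tissues respectively.
#' @param bias_fold Fold change applied to sex-biased background genes.
#' @param n_y_sites_per_region Y-specific marker sites per hemizygous region.
#' @param seed Integer seed; all randomness derives from it via stable
#'   per-stream substreams, so adding samples does not perturb existing ones.
#' @return A validated list of class `truth_config`.
#' @export
truth_config <- function(n_males = 10, n_females = 10,
                         tissues = c("leaves", "catkin_axes", "flowers"),
                         genes = gene_truth(),
                         hemizygous_regions = hemizygous_truth_regions(),
                         n_het_sites_per_gene = 6,
                         wgs_depth_male = 18, wgs_depth_female = 26,
                         rna_depth = 100, amplicon_depth = 2000,
                         seq_error = 0.005, overdispersion_rho = 0.02,
                         qual = 60,
                         region = sdr_region(), bin_width = 200,
                         n_background_genes = 2000,
                         frac_leaf_biased = 0.03,
                         frac_generative_biased = 0.15,
                         bias_fold = 4,
                         n_y_sites_per_region = 3,
                         seed = 1) {
  cfg <- structure(
    list(
      n_males = n_males, n_females = n_females, tissues = tissues,
      genes = genes, hemizygous_regions = hemizygous_regions,
      n_het_sites_per_gene = n_het_sites_per_gene,
      wgs_depth_male = wgs_depth_male, wgs_depth_female = wgs_depth_female,
      rna_depth = rna_depth, amplicon_depth = amplicon_depth,
      seq_error = seq_error, overdispersion_rho = overdispersion_rho,
      qual = qual, region = region, bin_width = bin_width,
      n_background_genes = n_background_genes,
      frac_leaf_biased = frac_leaf_biased,
      frac_generative_biased = frac_generative_biased,
      bias_fold = bias_fold,
      n_y_sites_per_region = n_y_sites_per_region,
      seed = seed
    ),
    class = "truth_config"
  )
  validate_truth_config(cfg)
}

validate_truth_config <- function(cfg) {
  counts <- c(cfg$n_males, cfg$n_females, cfg$n_het_sites_per_gene,
              cfg$n_background_genes, cfg$n_y_sites_per_region)
  if (any(counts < 0)) abort("counts must be >= 0")
  if (cfg$n_males + cfg$n_females < 1) abort("cohort must contain at least one individual")
  depths <- c(cfg$wgs_depth_male, cfg$wgs_depth_female, cfg$rna_depth,
              cfg$amplicon_depth)
  if (any(depths <= 0)) abort("all depths must be > 0")
  if (cfg$seq_error < 0 || cfg$seq_error >= 0.5) abort("seq_error must be in [0, 0.5)")
  if (cfg$overdispersion_rho < 0 || cfg$overdispersion_rho >= 1) {
    abort("overdispersion_rho must be in [0, 1)")
  }
  stopifnot(all(c("gene_id", "chrom", "start", "end", "expr_rate",
                  "y_fraction_male", "allele_fraction_female") %in% names(cfg$genes)))
  if (any(cfg$genes$y_fraction_male < 0 | cfg$genes$y_fraction_male > 1) ||
      any(cfg$genes$allele_fraction_female < 0 | cfg$genes$allele_fraction_female > 1)) {
    abort("allele fractions must lie in [0, 1]")
  }
  if (any(cfg$genes$expr_rate < 0)) abort("expr_rate must be >= 0")
  cfg
}

#' Default gene truth for the SDR panel
#'
#' The five annotated SDR genes with the expression pattern observed in the
#' study tissues: TCP, CLC and MET1 transcribed, NB-ARC and the unknown gene
#' silent. The CLC-like gene carries `y_fraction_male = 0` (its Y allele is
#' silenced in males, producing monoallelic male expression); all other
#' genes express both alleles equally.
#'
#' @param expr_rate Expected bulk RNA-seq counts per library for expressed
#'   genes.
#' @return The [sdr_genes()] tibble with truth columns added.
#' @export
gene_truth <- function(expr_rate = 400) {
  g <- sdr_genes()
  g$expr_rate <- ifelse(g$symbol %in% c("TCP", "CLC", "MET1"), expr_rate, 0)
  g$y_fraction_male <- ifelse(g$symbol == "CLC", 0, 0.5)
  g$allele_fraction_female <- 0.5
  g
}

#' Default planted Y-specific (male-hemizygous) regions
#'
#' Two intergenic intervals inside the SDR scan window, aligned to the 200-bp
#' bin grid and overlapping no annotated gene: a 4-kb block (comparable to the
#' shorter Y-hemizygous sequences reported in poplars) and a 2-kb block.
#' Neither is transcribed in the default truth.
#'
#' @return An interval tibble with a `region_id` column.
#' @export
hemizygous_truth_regions <- function() {
  r <- gintervals(
    chrom = c("Chr18", "Chr18"),
    start = c(16240000, 16296000),
    end = c(16244000, 16298000),
    strand = "*"
  )
  r$region_id <- c("YHS_A", "YHS_B")
  r
}

# Stable substream seed: polynomial hash of the key folded with the global
# seed, kept below 2^31 so set.seed() accepts it on any platform.
substream_seed <- function(seed, key) {
  h <- 0
  for (b in utf8ToInt(key)) h <- (h * 31 + b) %% 2147483647
  as.integer((h + (seed %% 2147483647) * 48271) %% 2147483647)
}

#' Draw ref/alt allele depths for one or more sites
#'
#' The generative read model used throughout the simulator: total depth is
#' Poisson with the given mean; the alt count is beta-binomial with mean
#' `p* = f (1 - e) + (1 - f) e` (true fraction `f` convolved with the
#' sequencing error `e`) and intra-class correlation `rho`. `rho = 0`
#' degenerates to binomial sampling. A mean depth of 0 yields `(0, 0)`.
#'
#' @param true_fraction True alt-allele fraction(s) in `[0, 1]`; recycled.
#' @param depth Mean total depth(s); recycled.
#' @param seq_error Per-base error probability.
#' @param rho Beta-binomial intra-class correlation in `[0, 1)`.
#' @param n Number of draws (defaults to the longer of the two inputs).
#' @return A tibble with `ref_depth` and `alt_depth`.
#' @examples
#' set.seed(1)
#' sample_allele_depths(0.5, 100, seq_error = 0.005, rho = 0.02, n = 3)
#' @export
sample_allele_depths <- function(true_fraction, depth, seq_error = 0, rho = 0,
                                 n = max(length(true_fraction), length(depth))) {
  stopifnot(all(true_fraction >= 0 & true_fraction <= 1),
            all(depth >= 0), seq_error >= 0, seq_error < 0.5,
            rho >= 0, rho < 1)
  f <- rep_len(true_fraction, n)
  d <- rep_len(depth, n)
  total <- rpois(n, d)
  p_star <- f * (1 - seq_error) + (1 - f) * seq_error
  if (rho == 0) {
    alt <- rbinom(n, total, p_star)
  } else {
    a <- p_star * (1 - rho) / rho
    b <- (1 - p_star) * (1 - rho) / rho
    p_i <- ifelse(p_star <= 0, 0, ifelse(p_star >= 1, 1, rbeta(n, pmax(a, 1e-12), pmax(b, 1e-12))))
    alt <- rbinom(n, total, p_i)
  }
  tibble(ref_depth = total - alt, alt_depth = alt)
}

#' Simulate a full synthetic cohort with ground truth
#'
#' Emits every data stream the pipeline consumes, each traceable to a truth
#' record:
#' \itemize{
#'   \item `dna`: WGS allele-depth observations for the sequenced pair (first
#'     male and first female) at every planted site, with females at zero
#'     depth over Y-specific sites and males at one-haplotype depth there,
#'     plus deep amplicon DNA observations for every individual over the
#'     expressed-gene panel.
#'   \item `rna`: bulk cDNA allele depths for the pair across tissues and
#'     amplicon cDNA depths for the whole cohort, with per-gene allelic
#'     fractions taken from the gene truth.
#'   \item `wgs_coverage` / `rna_coverage`: per-bin depth tracks over the SDR
#'     scan window.
#'   \item `counts` / `libraries`: a gene-by-library bulk count matrix for the
#'     2-sex x 3-tissue design, SDR genes plus background genes with planted
#'     sex effects concentrated in the generative tissues.
#'   \item `amplicon_samples`: the sample sheet of the amplicon design
#'     (individuals x \{DNA-leaves, cDNA per tissue\}).
#'   \item `truth`: phased site table (which allele rides the Y haplotype),
#'     true hemizygous intervals and true per-gene allelic class per
#'     individual.
#' }
#' Deterministic given `config$seed`; random streams are keyed by
#' (individual, material, tissue) so enlarging the cohort leaves existing
#' samples' draws unchanged.
#'
#' @param config A [truth_config()].
#' @return A list of class `sdr_cohort`.
#' @export
simulate_cohort <- function(config = truth_config()) {
  config <- validate_truth_config(config)
  cfg <- config
  individuals <- cohort_individuals(cfg)
  sites <- plant_sites(cfg)
  y_sites <- plant_y_sites(cfg)

  wgs_pair <- individuals %>%
    group_by(.data$sex) %>%
    dplyr::slice(1) %>%
    ungroup()

  dna_wgs <- simulate_wgs_dna(cfg, wgs_pair, sites, y_sites)
  rna_bulk <- simulate_bulk_rna(cfg, wgs_pair, sites)
  amp <- simulate_amplicon(cfg, individuals, sites)
  cov <- simulate_coverage(cfg, wgs_pair)

  structure(
    list(
      config = cfg,
      individuals = individuals,
      sites = sites,
      y_sites = y_sites,
      dna = bind_rows(dna_wgs, amp$dna),
      rna = bind_rows(rna_bulk, amp$rna),
      amplicon_samples = amp$samples,
      counts = cov$counts,
      libraries = cov$libraries,
      wgs_coverage = cov$wgs,
      rna_coverage = cov$rna,
      truth = cohort_truth(cfg, individuals, sites)
    ),
    class = "sdr_cohort"
  )
}

cohort_individuals <- function(cfg) {
  ids <- c(
    if (cfg$n_males > 0) sprintf("M%02d", seq_len(cfg$n_males)),
    if (cfg$n_females > 0) sprintf("F%02d", seq_len(cfg$n_females))
  )
  tibble(
    individual_id = ids,
    sex = rep(c("male", "female"), c(cfg$n_males, cfg$n_females))
  )
}

# Heterozygous sites planted per gene; the phase column records which allele
# sits on the male Y haplotype.
plant_sites <- function(cfg) {
  set.seed(substream_seed(cfg$seed, "sites"))
  bases <- c("A", "C", "G", "T")
  purrr::pmap_dfr(
    cfg$genes[, c("gene_id", "symbol", "chrom", "start", "end")],
    function(gene_id, symbol, chrom, start, end) {
      pos <- sort(sample.int(end - start, cfg$n_het_sites_per_gene)) + start
      ref <- sample(bases, length(pos), replace = TRUE)
      alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
      tibble(
        site_id = sprintf("%s_%d", symbol, seq_along(pos)),
        gene_id = gene_id, symbol = symbol, chrom = chrom, pos = pos,
        ref = ref, alt = unname(alt),
        y_allele = sample(c("ref", "alt"), length(pos), replace = TRUE),
        quality = cfg$qual
      )
    }
  )
}

# Marker sites inside Y-specific regions: present on the Y haplotype only, so
# males show one-haplotype depth and females none.
plant_y_sites <- function(cfg) {
  if (nrow(cfg$hemizygous_regions) == 0 || cfg$n_y_sites_per_region == 0) {
    return(tibble(
      site_id = character(), region_id = character(), chrom = character(),
      pos = numeric(), ref = character(), alt = character(), quality = numeric()
    ))
  }
  set.seed(substream_seed(cfg$seed, "y_sites"))
  bases <- c("A", "C", "G", "T")
  purrr::pmap_dfr(
    cfg$hemizygous_regions[, c("region_id", "chrom", "start", "end")],
    function(region_id, chrom, start, end) {
      pos <- sort(sample.int(end - start, cfg$n_y_sites_per_region)) + start
      ref <- sample(bases, length(pos), replace = TRUE)
      alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
      tibble(
        site_id = sprintf("%s_%d", region_id, seq_along(pos)),
        region_id = region_id, chrom = chrom, pos = pos,
        ref = ref, alt = unname(alt), quality = cfg$qual
      )
    }
  )
}

# True alt-allele expression fraction at a phased site for a given sex.
true_rna_alt_fraction <- function(y_allele, sex, y_fraction_male,
                                  allele_fraction_female) {
  n <- length(y_allele)
  sex <- rep_len(sex, n)
  male_frac <- ifelse(y_allele == "alt", y_fraction_male, 1 - y_fraction_male)
  ifelse(sex == "male", male_frac, rep_len(allele_fraction_female, n))
}

simulate_wgs_dna <- function(cfg, wgs_pair, sites, y_sites) {
  purrr::pmap_dfr(wgs_pair, function(individual_id, sex) {
    depth <- if (sex == "male") cfg$wgs_depth_male else cfg$wgs_depth_female
    set.seed(substream_seed(cfg$seed, paste("wgs_dna", individual_id)))
    het <- sample_allele_depths(
      0.5, depth, cfg$seq_error, cfg$overdispersion_rho, n = nrow(sites)
    )
    out <- bind_cols(
      sites[, c("site_id", "gene_id", "chrom", "pos", "ref", "alt", "quality")],
      het
    )
    if (nrow(y_sites) > 0) {
      ydepth <- if (sex == "male") depth / 2 else 0
      yd <- sample_allele_depths(
        0, ydepth, cfg$seq_error, cfg$overdispersion_rho, n = nrow(y_sites)
      )
      yobs <- bind_cols(
        y_sites[, c("site_id", "chrom", "pos", "ref", "alt", "quality")],
        yd
      )
      yobs$gene_id <- NA_character_
      out <- bind_rows(out, yobs)
    }
    out$individual_id <- individual_id
    out$sex <- sex
    out$material <- "DNA"
    out$tissue <- "leaves"
    out$assay <- "wgs"
    out$sample_id <- paste(individual_id, "DNA", "leaves", sep = "_")
    out
  })
}

simulate_bulk_rna <- function(cfg, wgs_pair, sites) {
  expressed <- cfg$genes %>% filter(.data$expr_rate > 0)
  esites <- sites %>%
    inner_join(
      expressed[, c("gene_id", "y_fraction_male", "allele_fraction_female")],
      by = "gene_id"
    )
  if (nrow(esites) == 0) return(tibble())
  grid <- tidyr::expand_grid(wgs_pair, tissue = cfg$tissues)
  purrr::pmap_dfr(grid, function(individual_id, sex, tissue) {
    set.seed(substream_seed(cfg$seed, paste("bulk_rna", individual_id, tissue)))
    f <- true_rna_alt_fraction(
      esites$y_allele, sex, esites$y_fraction_male, esites$allele_fraction_female
    )
    d <- sample_allele_depths(f, cfg$rna_depth, cfg$seq_error,
                              cfg$overdispersion_rho, n = nrow(esites))
    out <- bind_cols(
      esites[, c("site_id", "gene_id", "chrom", "pos", "ref", "alt", "quality")],
      d
    )
    out$individual_id <- individual_id
    out$sex <- sex
    out$material <- "cDNA"
    out$tissue <- tissue
    out$assay <- "bulk_rna"
    out$sample_id <- paste(individual_id, "cDNA", tissue, sep = "_")
    out
  })
}

simulate_amplicon <- function(cfg, individuals, sites) {
  panel <- cfg$genes %>% filter(.data$expr_rate > 0)
  psites <- sites %>%
    inner_join(
      panel[, c("gene_id", "y_fraction_male", "allele_fraction_female")],
      by = "gene_id"
    )
  samples <- bind_rows(
    individuals %>% mutate(material = "DNA", tissue = "leaves"),
    tidyr::expand_grid(individuals, material = "cDNA", tissue = cfg$tissues)
  ) %>%
    mutate(sample_id = paste(.data$individual_id, .data$material, .data$tissue,
                             sep = "_")) %>%
    arrange(.data$individual_id, .data$material, .data$tissue)
  if (nrow(psites) == 0) {
    return(list(samples = samples, dna = tibble(), rna = tibble()))
  }
  obs <- purrr::pmap_dfr(samples, function(individual_id, sex, material, tissue,
                                           sample_id) {
    set.seed(substream_seed(cfg$seed, paste("amplicon", sample_id)))
    f <- if (material == "DNA") {
      rep(0.5, nrow(psites))
    } else {
      true_rna_alt_fraction(psites$y_allele, sex, psites$y_fraction_male,
                            psites$allele_fraction_female)
    }
    d <- sample_allele_depths(f, cfg$amplicon_depth, cfg$seq_error,
                              cfg$overdispersion_rho, n = nrow(psites))
    out <- bind_cols(
      psites[, c("site_id", "gene_id", "chrom", "pos", "ref", "alt", "quality")],
      d
    )
    out$individual_id <- individual_id
    out$sex <- sex
    out$material <- material
    out$tissue <- tissue
    out$assay <- "amplicon"
    out$sample_id <- sample_id
    out
  })
  list(
    samples = samples,
    dna = obs %>% filter(.data$material == "DNA"),
    rna = obs %>% filter(.data$material == "cDNA")
  )
}

# Overlap fraction of each bin with a set of intervals (same chromosome).
bin_overlap_fraction <- function(bins, regions) {
  if (nrow(regions) == 0) return(rep(0, nrow(bins)))
  ovl <- rep(0, nrow(bins))
  for (i in seq_len(nrow(regions))) {
    same <- bins$chrom == regions$chrom[i]
    lo <- pmax(bins$start, regions$start[i])
    hi <- pmin(bins$end, regions$end[i])
    ovl <- ovl + ifelse(same, pmax(0, hi - lo), 0)
  }
  pmin(ovl / (bins$end - bins$start), 1)
}

# Binned base counts: Poisson(mean_depth * width) / width, the sufficient
# statistic for per-bin mean depth.
draw_bin_depth <- function(expected, width) {
  rpois(length(expected), expected * width) / width
}

simulate_coverage <- function(cfg, wgs_pair) {
  bins <- bin_interval(cfg$region, cfg$bin_width)
  hemi_frac <- bin_overlap_fraction(bins, cfg$hemizygous_regions)

  wgs <- purrr::pmap_dfr(wgs_pair, function(individual_id, sex) {
    depth <- if (sex == "male") cfg$wgs_depth_male else cfg$wgs_depth_female
    # hemizygous sequence: one haplotype in males, absent in females
    expected <- if (sex == "male") {
      depth * (1 - hemi_frac) + (depth / 2) * hemi_frac
    } else {
      depth * (1 - hemi_frac)
    }
    set.seed(substream_seed(cfg$seed, paste("wgs_cov", individual_id)))
    bins %>% mutate(
      sample_id = individual_id, sex = sex,
      depth = draw_bin_depth(expected, .data$end - .data$start)
    )
  })

  libraries <- tidyr::expand_grid(wgs_pair, tissue = cfg$tissues) %>%
    mutate(library_id = paste(substr(.data$sex, 1, 1), .data$tissue, sep = "_"))

  expressed <- cfg$genes %>% filter(.data$expr_rate > 0)
  expr_frac <- bin_overlap_fraction(bins, expressed)
  rna <- purrr::pmap_dfr(libraries, function(individual_id, sex, tissue,
                                             library_id) {
    set.seed(substream_seed(cfg$seed, paste("rna_cov", library_id)))
    bins %>% mutate(
      library_id = library_id, sample_id = individual_id, sex = sex,
      tissue = tissue,
      depth = draw_bin_depth(cfg$rna_depth * expr_frac, .data$end - .data$start)
    )
  })

  counts <- simulate_bulk_counts(cfg, libraries)
  list(wgs = wgs, rna = rna, libraries = libraries, counts = counts)
}

simulate_bulk_counts <- function(cfg, libraries) {
  set.seed(substream_seed(cfg$seed, "background_genes"))
  nbg <- cfg$n_background_genes
  bg <- tibble(
    gene_id = sprintf("BG%04d", seq_len(nbg)),
    rate = rlnorm(nbg, meanlog = log(50), sdlog = 1),
    leaf_biased = FALSE, generative_biased = FALSE, bias_dir = 1
  )
  if (nbg > 0) {
    n_leaf <- round(cfg$frac_leaf_biased * nbg)
    n_gen <- round(cfg$frac_generative_biased * nbg)
    picks <- sample.int(nbg, min(nbg, n_leaf + n_gen))
    bg$leaf_biased[picks[seq_len(min(n_leaf, length(picks)))]] <- TRUE
    if (length(picks) > n_leaf) {
      bg$generative_biased[picks[(n_leaf + 1):length(picks)]] <- TRUE
    }
    bg$bias_dir <- sample(c(1, -1), nbg, replace = TRUE)
  }
  sdr <- tibble(
    gene_id = cfg$genes$gene_id, rate = cfg$genes$expr_rate,
    leaf_biased = FALSE, generative_biased = FALSE, bias_dir = 1
  )
  genes <- bind_rows(sdr, bg)

  mat <- purrr::pmap(libraries, function(individual_id, sex, tissue, library_id) {
    set.seed(substream_seed(cfg$seed, paste("counts", library_id)))
    lib_factor <- rlnorm(1, 0, 0.1)
    biased <- if (tissue == "leaves") genes$leaf_biased else genes$generative_biased
    sex_sign <- if (sex == "male") 1 else -1
    fold <- ifelse(biased, cfg$bias_fold^(0.5 * sex_sign * genes$bias_dir), 1)
    mu <- genes$rate * fold * lib_factor
    rnbinom(nrow(genes), mu = mu, size = 20)
  })
  counts <- as_tibble(setNames(mat, libraries$library_id))
  bind_cols(tibble(gene_id = genes$gene_id), counts)
}

cohort_truth <- function(cfg, individuals, sites) {
  classes <- tidyr::expand_grid(
    cfg$genes[, c("gene_id", "symbol", "expr_rate", "y_fraction_male",
                  "allele_fraction_female")],
    individuals
  ) %>%
    mutate(
      true_class = case_when(
        .data$expr_rate == 0 ~ "silent",
        .data$sex == "male" &
          (.data$y_fraction_male <= 0 | .data$y_fraction_male >= 1) ~ "monoallelic",
        .data$sex == "female" &
          (.data$allele_fraction_female <= 0 | .data$allele_fraction_female >= 1) ~ "monoallelic",
        TRUE ~ "biallelic"
      )
    ) %>%
    select("gene_id", "symbol", "individual_id", "sex", "true_class")
  structure(
    list(
      individuals = individuals,
      sites = sites,
      hemizygous_regions = cfg$hemizygous_regions,
      gene_classes = classes
    ),
    class = "sdr_truth"
  )
}

#' @export
print.sdr_cohort <- function(x, ...) {
  cat("<sdr_cohort>\n")
  cat("  individuals:      ", nrow(x$individuals), "\n")
  cat("  planted het sites:", nrow(x$sites), "\n")
  cat("  DNA observations: ", nrow(x$dna), "\n")
  cat("  RNA observations: ", nrow(x$rna), "\n")
  cat("  amplicon samples: ", nrow(x$amplicon_samples), "\n")
  cat("  RNA libraries:    ", nrow(x$libraries), "\n")
  invisible(x)
}
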