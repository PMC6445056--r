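test_that("cohort config enforces its invariants", {
  expect_error(cohort_config(drift_F = 0), "drift_F")
  expect_error(cohort_config(chrom_length = 1e5, n_sites = 2e5), "spacing")
  expect_error(cohort_config(chrom_length = 1e5,
                             sweep_interval = c(9e4, 2e5)), "sweep_interval")
})

test_that("background differentiation matches the drift-model expectation", {
  # For two populations drifted independently with parameter F from a
  # common ancestor, E[H_S] = 2p(1-p)(1-F) and E[H_T] = 2p(1-p)(1-F/2),
  # so the expected fixation index is F/(2-F) (~ F/2 for small F).
  cfg <- cohort_config(n_per_pop = 30, chrom_length = 1e6, n_sites = 10000,
                       drift_F = 0.01)
  sim <- simulate_cohort(cfg, seed = 314)
  expected <- 0.01 / (2 - 0.01)
  for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
    fst_true <- window_fst(sim$freq[, pair[1]], sim$freq[, pair[2]])
    expect_equal(fst_true, expected, tolerance = 0.25)  # sampling error
  }
  # per-site fixed difference: selected 1, others 0
  expect_equal(window_fst(1, 0), 1)
})

test_that("simulated frequencies are bounded and genotypes are consistent", {
  cfg <- cohort_config(n_per_pop = 30, chrom_length = 1e6, n_sites = 2000,
                       drift_F = 0.05, sweep_interval = c(4e5, 6e5),
                       sweep_freq = 0.98)
  sim <- simulate_cohort(cfg, seed = 5)
  expect_true(all(sim$freq >= 0 & sim$freq <= 1))
  expect_true(all(sim$genotypes %in% 0:2))
  # sweep override applied to the selected population only
  in_sweep <- sim$positions - 1 >= 4e5 & sim$positions - 1 < 6e5
  expect_true(all(sim$freq[in_sweep, 1] == 0.98))
  expect_false(all(sim$freq[in_sweep, 2] == 0.98))
  # chi-square goodness of fit of allele counts against truth frequencies,
  # aggregated over sites (n_per_pop >= 30)
  for (j in 1:3) {
    cols <- which(sim$manifest$samples$population == sim$config$pop_names[j])
    f <- sim$freq[, j]
    keep <- f > 0.02 & f < 0.98
    obs <- rowSums(sim$genotypes[keep, cols])
    n_all <- 2 * length(cols)
    chi <- sum((obs - n_all * f[keep])^2 / (n_all * f[keep] * (1 - f[keep])))
    p <- pchisq(chi, df = sum(keep), lower.tail = FALSE)
    expect_gt(p, 0.001)
  }
})

test_that("cohort generation is deterministic and VCF round-trips", {
  cfg <- cohort_config(n_per_pop = 4, chrom_length = 5e4, n_sites = 300)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  s1 <- simulate_cohort(cfg, seed = 99, dir = d1)
  s2 <- simulate_cohort(cfg, seed = 99, dir = d2)
  expect_identical(readLines(file.path(d1, "cohort.vcf")),
                   readLines(file.path(d2, "cohort.vcf")))
  expect_false(identical(
    readLines(file.path(d1, "cohort.vcf")),
    {
      d3 <- withr::local_tempdir()
      simulate_cohort(cfg, seed = 100, dir = d3)
      readLines(file.path(d3, "cohort.vcf"))
    }))
  # reading the VCF + manifest recovers exactly the generator's frequencies
  man <- read_manifest(file.path(d1, "manifest.tsv"))
  expect_equal(unname(man$roles["selected"]), "selected")
  tab_vcf <- read_vcf(file.path(d1, "cohort.vcf"), man)
  tab_mem <- cohort_afreq(s1)
  expect_equal(tab_vcf$pos, tab_mem$pos)
  for (p in s1$config$pop_names) {
    expect_equal(tab_vcf[[paste0("f_major_", p)]],
                 tab_mem[[paste0("f_major_", p)]], tolerance = 1e-12)
  }
})

test_that("phenotype simulation recovers noiseless effects exactly", {
  set.seed(8)
  geno <- data.frame(sample = sprintf("s%02d", 1:40),
                     M1 = rbinom(40, 2, 0.5))
  eff <- list(y = list(beta = c(M1 = -3.3), beta_age = 0.5, beta_sex = 1,
                       intercept = 20, noise_sd = 0))
  tab <- simulate_phenotypes(geno, eff, age = rep(2:5, 10),
                             sex = rep(c(0, 1), 20), seed = 1)
  # zero residual variance by construction; lm warns about the perfect fit
  fit <- suppressWarnings(
    fit_association(tab, "M1", "y", "additive", adjust = TRUE))
  expect_equal(fit$beta, -3.3, tolerance = 1e-10)
})

test_that("noisy phenotype estimates follow the OLS sampling distribution", {
  betas <- vapply(1:20, function(s) {
    geno <- tailsweep:::with_seed(1000 + s, {
      data.frame(sample = sprintf("s%03d", 1:116),
                 M1 = rbinom(116, 2, 0.5))
    })
    eff <- list(y = list(beta = c(M1 = -3.3), beta_age = 0.3, beta_sex = 0.5,
                         intercept = 20, noise_sd = 1))
    tab <- simulate_phenotypes(geno, eff, age = rep(2:5, 29),
                               sex = rep(c(0, 1), 58), seed = 2000 + s)
    fit_association(tab, "M1", "y", "additive", adjust = TRUE)$beta
  }, numeric(1))
  # closed-form SE ~ noise_sd / sqrt(n * var(g)); mean of 20 draws should
  # land within 3 SE/sqrt(20) of the truth -- use 3 SE as a loose bound
  se <- 1 / sqrt(116 * 0.5)
  expect_lt(abs(mean(betas) + 3.3), 3 * se)
})

test_that("degenerate and invalid genotype tables are rejected or flagged", {
  geno <- data.frame(sample = c("a", "b", "c", "d", "e", "f", "g", "h"),
                     M1 = rep(1L, 8))
  eff <- list(y = list(beta = c(M1 = 1), noise_sd = 0, intercept = 0))
  tab <- simulate_phenotypes(geno, eff, age = 1:8, sex = rep(0:1, 4),
                             seed = 3)
  fit <- fit_association(tab, "M1", "y", "additive")
  expect_false(fit$estimable)
  expect_true(is.na(fit$beta))

  geno$M1 <- c(0L, 1L, 2L, 3L, 0L, 1L, 2L, 0L)
  expect_error(simulate_phenotypes(geno, eff, age = 1:8, sex = rep(0:1, 4),
                                   seed = 3), "genotype codes")
})

test_that("planted retro-copies carry exact truth records", {
  host <- tailsweep:::with_seed(21, tailsweep:::random_dna(20000))
  gene <- random_gene("G", n_exons = 5, seed = 22)

  # identity 1, spliced -> insert equals the exact exon concatenation
  p <- plant_retrocopy(gene, host, 5000, identity = 1,
                       retain_introns = FALSE, seed = 23)
  mrna <- spliced_sequence(gene)
  expect_equal(substr(p$host, 5001, 5000 + nchar(mrna)), mrna)
  expect_equal(nchar(p$host), nchar(host) + nchar(mrna))
  expect_equal(p$truth$end - p$truth$start, nchar(mrna))

  # intron-retaining insert equals the full gene sequence
  p2 <- plant_retrocopy(gene, host, 0, identity = 1, retain_introns = TRUE,
                        seed = 24)
  expect_equal(substr(p2$host, 1, nchar(gene$sequence)), gene$sequence)

  # substitution rate close to 1 - identity
  p3 <- plant_retrocopy(gene, host, 100, identity = 0.85, seed = 25)
  expect_equal(p3$truth$identity_realized, 0.85, tolerance = 0.03)

  expect_error(plant_retrocopy(gene, host, nchar(host) + 1, seed = 1),
               "outside host")
  expect_error(plant_retrocopy(gene, host, 0, identity = 0.3, seed = 1),
               "identity")
})

test_that("simulated repeat annotation hits coverage targets and round-trips", {
  ann <- simulate_repeat_annotation(1e6, c("LINE/RTE-BovB" = 0.2132), seed = 7)
  cov <- class_coverage(ann, c(0, 1e6))
  expect_equal(cov$covered_bp, 213200, tolerance = 10000 / 213200)
  expect_equal(cov$fraction, 0.2132, tolerance = 0.01 / 0.2132)
  # elements are non-overlapping
  o <- order(ann$start)
  expect_true(all(ann$start[o][-1] >= ann$end[o][-nrow(ann)]))

  tmp <- withr::local_tempfile(fileext = ".out")
  write_repeatmasker_out(ann, tmp)
  back <- parse_repeatmasker_out(tmp)
  for (col in c("seqname", "start", "end", "strand", "name", "class_family")) {
    expect_equal(back[[col]], ann[[col]])
  }

  # empty targets -> header-only file, parsed to zero elements
  tmp2 <- withr::local_tempfile(fileext = ".out")
  empty <- simulate_repeat_annotation(1e5, setNames(numeric(0), character(0)),
                                      seed = 7, path = tmp2)
  expect_equal(nrow(empty), 0)
  expect_equal(nrow(parse_repeatmasker_out(tmp2)), 0)

  # determinism: same seed -> identical file
  t1 <- withr::local_tempfile(); t2 <- withr::local_tempfile()
  simulate_repeat_annotation(2e5, c("SINE/MIR" = 0.05), seed = 9, path = t1)
  simulate_repeat_annotation(2e5, c("SINE/MIR" = 0.05), seed = 9, path = t2)
  expect_identical(readLines(t1), readLines(t2))

  expect_error(simulate_repeat_annotation(1e5, c("SINE/MIR" = 0.9,
                                                 "LINE/L1" = 0.2), seed = 1),
               "sum")
})
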