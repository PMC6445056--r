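#' Simulate phenotypes with additive marker effects and covariates
#'
#' Generates one or more quantitative phenotypes as
#' y = intercept + sum(beta_m * g_m) + beta_age * age + beta_sex * sex +
#' N(0, noise_sd^2), with genotypes coded as counts of the mutated allele
#' (0/1/2).  Sex is coded 0 = male, 1 = female.
#'
#' @param genotypes A data.frame with a `sample` column plus one integer
#'   column per marker (values in 0/1/2 or NA).
#' @param effects A named list, one element per phenotype; each element is a
#'   list with `beta` (named vector of per-marker effects, phenotype units
#'   per allele), `beta_age`, `beta_sex`, `intercept`, `noise_sd`.
#' @param age Positive numeric vector of ages, recycled to the cohort size.
#' @param sex Binary vector (0 = male, 1 = female), recycled likewise.
#' @param seed Integer seed.
#' @return A data.frame with columns sample, age, sex, the phenotypes, and
#'   the marker genotype columns, plus a `truth` attribute recording the
#'   generating parameters.
#' @export
simulate_phenotypes <- function(genotypes, effects, age, sex, seed) {
  stopifnot(is.data.frame(genotypes), "sample" %in% names(genotypes))
  markers <- setdiff(names(genotypes), "sample")
  if (!length(markers)) stop("no marker columns in `genotypes`", call. = FALSE)
  g <- as.matrix(genotypes[markers])
  bad <- !(g %in% c(0L, 1L, 2L)) & !is.na(g)
  if (any(bad)) {
    stop("genotype codes outside {0,1,2,NA}: ",
         paste(unique(g[bad]), collapse = ", "), call. = FALSE)
  }
  n <- nrow(genotypes)
  age <- rep_len(age, n)
  sex <- rep_len(sex, n)
  stopifnot(all(age > 0), all(sex %in% c(0, 1)))
  out <- data.frame(sample = genotypes$sample, age = age, sex = sex,
                    stringsAsFactors = FALSE)
  with_seed(seed, {
    for (ph in names(effects)) {
      e <- effects[[ph]]
      beta <- e$beta
      stopifnot(all(names(beta) %in% markers))
      lin <- (e$intercept %||% 0) +
        as.vector(g[, names(beta), drop = FALSE] %*% beta) +
        (e$beta_age %||% 0) * age + (e$beta_sex %||% 0) * sex
      out[[ph]] <- lin + if ((e$noise_sd %||% 0) > 0) {
        rnorm(n, 0, e$noise_sd)
      } else {
        0
      }
    }
  })
  out <- cbind(out, genotypes[markers])
  attr(out, "truth") <- effects
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a fat- x thin-tailed crossbred genotype-phenotype cohort
#'
#' Emulates a hybrid sheep cohort scored for tail length and width and
#' genotyped at four markers: two markers in the swept intergenic region
#' (generated in complete linkage disequilibrium, i.e. identical genotype
#' columns), one near-sweep gene marker and one unlinked-region marker.
#' Defaults describe a cohort of 116 animals (28 females, 88 males) in which
#' each copy of the swept-region mutated allele shortens the tail by 3.3 cm
#' and widens it by 3.5 cm under an additive model, with age and sex
#' covariate effects and Gaussian noise.
#'
#' @param seed Integer seed.
#' @param n Cohort size.
#' @param n_female Number of females (sex coded 1).
#' @param maf Frequency of the mutated allele at each marker.
#' @param beta_length,beta_width Additive effect of one mutated allele of
#'   the swept-region marker on tail length / width (cm).
#' @param noise_sd_length,noise_sd_width Residual standard deviations (cm).
#' @return A genotype-phenotype data.frame as from [simulate_phenotypes()],
#'   with markers IBH_SNP1, IBH_SNP2, BMP2_SNP, PDGFD_SNP and phenotypes
#'   tail_length_cm, tail_width_cm.
#' @export
simulate_tailcross <- function(seed, n = 116L, n_female = 28L, maf = 0.5,
                               beta_length = -3.3, beta_width = 3.5,
                               noise_sd_length = 2.7, noise_sd_width = 2.0) {
  seed2 <- as.integer((as.numeric(seed) + 1) %% 2147483647)
  seed3 <- as.integer((as.numeric(seed) + 2) %% 2147483647)
  geno <- with_seed(seed, {
    ibh <- rbinom(n, 2L, maf)
    data.frame(sample = sprintf("X%03d", seq_len(n)),
               IBH_SNP1 = ibh,
               IBH_SNP2 = ibh,  # complete LD with IBH_SNP1 by construction
               BMP2_SNP = rbinom(n, 2L, maf),
               PDGFD_SNP = rbinom(n, 2L, maf),
               stringsAsFactors = FALSE)
  })
  covar <- with_seed(seed2, {
    list(age = sample(2:7, n, replace = TRUE),
         sex = sample(rep(c(1, 0), c(n_female, n - n_female))))
  })
  effects <- list(
    tail_length_cm = list(beta = c(IBH_SNP1 = beta_length), beta_age = 0.8,
                          beta_sex = -1.5, intercept = 32,
                          noise_sd = noise_sd_length),
    tail_width_cm = list(beta = c(IBH_SNP1 = beta_width), beta_age = 0.5,
                         beta_sex = -1.0, intercept = 10,
                         noise_sd = noise_sd_width))
  simulate_phenotypes(geno, effects, age = covar$age, sex = covar$sex,
                      seed = seed3)
}
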