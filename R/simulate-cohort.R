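#' Configuration for a three-population cohort simulation
#'
#' Describes a cohort of three populations — a "selected" lineage, its
#' "sister" lineage and an "outgroup" — genotyped at bi-allelic SNVs on one
#' chromosome.  Background differentiation follows the Balding–Nichols
#' model: per site an ancestral derived-allele frequency p is drawn from
#' Uniform(0.05, 0.95) and each population's frequency from
#' Beta(p(1-F)/F, (1-p)(1-F)/F) with that population's drift parameter F.
#' Inside `sweep_interval` the selected population's derived-allele
#' frequency is overridden to `sweep_freq`, planting a localized sweep of
#' near-fixed differentiated alleles while the other populations keep their
#' drifted frequencies.
#'
#' @param n_per_pop Samples per population (recycled to length 3).
#' @param chrom_length Chromosome length in bp.
#' @param n_sites Number of segregating sites.
#' @param drift_F Per-population drift parameter in (0,1); scalar or
#'   length 3 in the order selected, sister, outgroup.
#' @param sweep_interval Half-open interval `c(start, end)` in bp, or NULL
#'   for no sweep.
#' @param sweep_freq Target derived-allele frequency in the selected
#'   population inside the sweep.
#' @param chrom Chromosome name written to output.
#' @param pop_names Labels for the three populations, in role order
#'   (selected, sister, outgroup).
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_per_pop = 30L, chrom_length = 1e7, n_sites = 20000L,
                          drift_F = 0.01,
                          sweep_interval = NULL, sweep_freq = 0.98,
                          chrom = "chr1",
                          pop_names = c("selected", "sister", "outgroup")) {
  n_per_pop <- rep_len(as.integer(n_per_pop), 3L)
  drift_F <- rep_len(drift_F, 3L)
  stopifnot(all(n_per_pop >= 2), chrom_length >= 1, n_sites >= 1,
            length(pop_names) == 3L, !anyDuplicated(pop_names))
  if (any(drift_F <= 0 | drift_F >= 1)) {
    stop("drift_F must lie strictly in (0, 1)", call. = FALSE)
  }
  if (n_sites > chrom_length) {
    stop("n_sites exceeds chrom_length: mean inter-site spacing < 1 bp",
         call. = FALSE)
  }
  if (!is.null(sweep_interval)) {
    stopifnot(length(sweep_interval) == 2L)
    if (sweep_interval[1] < 0 || sweep_interval[2] > chrom_length ||
        sweep_interval[1] >= sweep_interval[2]) {
      stop("sweep_interval must be a non-empty interval within ",
           "[0, chrom_length)", call. = FALSE)
    }
    stopifnot(sweep_freq >= 0, sweep_freq <= 1)
  }
  structure(list(n_per_pop = n_per_pop, chrom_length = chrom_length,
                 n_sites = as.integer(n_sites), drift_F = drift_F,
                 sweep_interval = sweep_interval, sweep_freq = sweep_freq,
                 chrom = chrom, pop_names = pop_names),
            class = "cohort_config")
}

#' Simulate a three-population cohort with an optional planted sweep
#'
#' Draws true per-population allele frequencies under the Balding–Nichols
#' model (see [cohort_config()]), overrides the selected population inside
#' the sweep interval, and samples diploid genotypes as Binomial(2, f) per
#' sample.  The VCF REF allele is the ancestral allele and ALT the derived
#' allele, so the sweep elevates ALT.  The generator is a pure function of
#' (config, seed): the same pair reproduces byte-identical output files.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @param dir Optional output directory; when given, writes `cohort.vcf`,
#'   `manifest.tsv` and `truth.json`.
#' @return A list of class `cohort_sim` with elements `config`, `seed`,
#'   `positions` (1-based), `ref`, `alt`, `freq` (n_sites x 3 matrix of true
#'   derived-allele frequencies), `genotypes` (n_sites x samples ALT-allele
#'   counts), `manifest` (a [read_manifest()]-compatible object), `truth`,
#'   and `paths` when `dir` was given.
#' @export
simulate_cohort <- function(config, seed, dir = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  sim <- with_seed(seed, {
    n_sites <- config$n_sites
    pos <- sort(sample.int(config$chrom_length, n_sites))  # 1-based, unique
    p_anc <- runif(n_sites, 0.05, 0.95)
    freq <- matrix(NA_real_, n_sites, 3L,
                   dimnames = list(NULL, config$pop_names))
    for (j in 1:3) {
      F <- config$drift_F[j]
      freq[, j] <- rbeta(n_sites, p_anc * (1 - F) / F,
                         (1 - p_anc) * (1 - F) / F)
    }
    if (!is.null(config$sweep_interval)) {
      in_sweep <- (pos - 1) >= config$sweep_interval[1] &
        (pos - 1) < config$sweep_interval[2]
      freq[in_sweep, 1L] <- config$sweep_freq
    }
    ref <- sample(c("A", "C", "G", "T"), n_sites, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L),
                  character(1), USE.NAMES = FALSE)
    geno <- matrix(NA_integer_, n_sites, sum(config$n_per_pop))
    col0 <- 0L
    for (j in 1:3) {
      nj <- config$n_per_pop[j]
      geno[, col0 + seq_len(nj)] <-
        rbinom(n_sites * nj, 2L, rep(freq[, j], nj))
      col0 <- col0 + nj
    }
    list(pos = pos, freq = freq, ref = ref, alt = alt, geno = geno)
  })
  samples <- unlist(lapply(1:3, function(j) {
    sprintf("%s_%02d", config$pop_names[j], seq_len(config$n_per_pop[j]))
  }))
  colnames(sim$geno) <- samples
  manifest <- new_manifest(
    data.frame(sample = samples,
               population = rep(config$pop_names, config$n_per_pop),
               stringsAsFactors = FALSE),
    roles = setNames(config$pop_names, c("selected", "sister", "outgroup")))
  truth <- list(sweep_interval = config$sweep_interval,
                sweep_freq = if (is.null(config$sweep_interval)) NULL else
                  config$sweep_freq,
                drift_F = setNames(as.list(config$drift_F), config$pop_names),
                positions = sim$pos,
                freq = sim$freq)
  out <- structure(list(config = config, seed = seed, positions = sim$pos,
                        ref = sim$ref, alt = sim$alt, freq = sim$freq,
                        genotypes = sim$geno, manifest = manifest,
                        truth = truth),
                   class = "cohort_sim")
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(vcf = file.path(dir, "cohort.vcf"),
                  manifest = file.path(dir, "manifest.tsv"),
                  truth = file.path(dir, "truth.json"))
    write_cohort_vcf(out, paths$vcf)
    write.table(manifest$samples, paths$manifest, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    writeLines(truth_json(truth), paths$truth)
    out$paths <- paths
  }
  out
}

## Minimal JSON writer for the truth record (numbers and nested lists only),
## so the generator has no serialization dependency.
truth_json <- function(x) {
  enc <- function(v) {
    if (is.null(v)) return("null")
    if (is.list(v) && !is.null(names(v))) {
      return(paste0("{", paste0("\"", names(v), "\":",
                                vapply(v, enc, character(1)),
                                collapse = ","), "}"))
    }
    if (is.matrix(v)) {
      return(enc(lapply(seq_len(ncol(v)), function(j) v[, j])))
    }
    if (is.list(v)) {
      return(paste0("[", paste(vapply(v, enc, character(1)), collapse = ","),
                    "]"))
    }
    if (is.character(v)) {
      return(if (length(v) == 1) paste0("\"", v, "\"") else
        paste0("[", paste0("\"", v, "\"", collapse = ","), "]"))
    }
    s <- format(v, digits = 15, trim = TRUE, scientific = FALSE)
    if (length(v) == 1) s else paste0("[", paste(s, collapse = ","), "]")
  }
  enc(x)
}

#' Write a cohort simulation as a sorted bi-allelic VCF 4.2
#'
#' @param sim A `cohort_sim` from [simulate_cohort()].
#' @param path Output path (plain text).
#' @return `path`, invisibly.
#' @export
write_cohort_vcf <- function(sim, path) {
  stopifnot(inherits(sim, "cohort_sim"))
  gt_codes <- c("0/0", "0/1", "1/1")
  gt <- matrix(gt_codes[sim$genotypes + 1L], nrow = nrow(sim$genotypes))
  body <- paste(sim$config$chrom, sim$positions, ".", sim$ref, sim$alt,
                ".", "PASS", ".", "GT",
                apply(gt, 1L, paste, collapse = "\t"),
                sep = "\t")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=tailsweep.simulate_cohort",
    sprintf("##contig=<ID=%s,length=%d>", sim$config$chrom,
            as.integer(sim$config$chrom_length)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(sim$genotypes)), collapse = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Allele-frequency table from a simulated cohort's genotypes
#'
#' Computes per-population frequencies directly from the simulated genotype
#' matrix — the same quantities [read_vcf()] recovers from the written VCF —
#' and applies the major/minor convention.
#'
#' @param sim A `cohort_sim`.
#' @param scope Major/minor scope, see [assign_major_minor()].
#' @return An allele-frequency table.
#' @export
cohort_afreq <- function(sim, scope = "global") {
  stopifnot(inherits(sim, "cohort_sim"))
  pops <- sim$config$pop_names
  n_sites <- length(sim$positions)
  f_alt <- matrix(NA_real_, n_sites, 3L)
  n_alleles <- matrix(NA_integer_, n_sites, 3L)
  for (j in 1:3) {
    cols <- which(sim$manifest$samples$population == pops[j])
    n_alleles[, j] <- 2L * length(cols)
    f_alt[, j] <- rowSums(sim$genotypes[, cols, drop = FALSE]) /
      n_alleles[, j]
  }
  tab <- new_afreq(chrom = sim$config$chrom, pos = sim$positions,
                   ref = sim$ref, alt = sim$alt,
                   f_alt = f_alt, n_alleles = n_alleles, pops = pops,
                   roles = sim$manifest$roles)
  assign_major_minor(tab, scope = scope)
}
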