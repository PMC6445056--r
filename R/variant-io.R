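new_manifest <- function(samples, roles = NULL) {
  stopifnot(is.data.frame(samples),
            all(c("sample", "population") %in% names(samples)))
  dup <- duplicated(samples$sample)
  if (any(dup)) {
    stop("duplicated sample id(s) in manifest: ",
         paste(unique(samples$sample[dup]), collapse = ", "), call. = FALSE)
  }
  pops <- unique(samples$population)
  if (!is.null(roles)) {
    stopifnot(setequal(names(roles), c("selected", "sister", "outgroup")))
    missing <- setdiff(roles, pops)
    if (length(missing)) {
      stop("role population(s) absent from manifest: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(samples = samples[c("sample", "population")],
                 populations = pops, roles = roles),
            class = "pop_manifest")
}

#' Read a sample-to-population manifest
#'
#' The manifest is a two-column TSV (sample, population), with or without a
#' header line.  Each sample must map to exactly one population.  For the
#' three-lineage branch-length analysis, the selected / sister / outgroup
#' roles are taken from `roles`; by default the three populations are
#' assigned those roles in order of first appearance in the file.
#'
#' @param path Manifest TSV path.
#' @param roles Named character vector mapping the role names `selected`,
#'   `sister`, `outgroup` to population labels, or NULL to assign roles in
#'   order of first appearance when exactly three populations are present.
#' @return A `pop_manifest` object.
#' @export
read_manifest <- function(path, roles = NULL) {
  raw <- read.table(path, sep = "\t", header = FALSE,
                    col.names = c("sample", "population"),
                    colClasses = "character")
  if (nrow(raw) && identical(tolower(unlist(raw[1, ], use.names = FALSE)),
                             c("sample", "population"))) {
    raw <- raw[-1, , drop = FALSE]
  }
  if (!nrow(raw)) stop("empty manifest: ", path, call. = FALSE)
  if (is.null(roles) && length(unique(raw$population)) == 3L) {
    roles <- setNames(unique(raw$population),
                      c("selected", "sister", "outgroup"))
  }
  new_manifest(raw, roles = roles)
}

#' Read a multi-sample VCF into a per-population allele-frequency table
#'
#' Keeps bi-allelic SNV records only (multi-allelic and non-SNV records are
#' dropped and counted), computes per-population REF/ALT frequencies from
#' called alleles — missing genotypes shrink the denominator, no imputation —
#' and applies the major/minor labelling convention.
#'
#' @param path VCF path (plain or bgzipped; parsed with vcfR).
#' @param manifest A `pop_manifest` from [read_manifest()].
#' @param min_call_rate Minimum fraction of called alleles across the whole
#'   cohort for a site to be kept (default 0, i.e. no filter).
#' @param major_scope Major/minor scope, see [assign_major_minor()].
#' @param unknown_sample What to do when a VCF sample is absent from the
#'   manifest: `"error"` (default) or `"warn"` (sample is then ignored).
#' @return An allele-frequency table (class `afreq_table`), with attributes
#'   `pops`, `roles` and `dropped` (a named count of filtered records).
#' @export
read_vcf <- function(path, manifest, min_call_rate = 0,
                     major_scope = "global",
                     unknown_sample = c("error", "warn")) {
  unknown_sample <- match.arg(unknown_sample)
  stopifnot(inherits(manifest, "pop_manifest"))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  n_in <- nrow(fix)
  if (n_in == 0) stop("VCF contains no records: ", path, call. = FALSE)
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  snv <- !is.na(alt) & nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  multi <- grepl(",", alt, fixed = TRUE)
  keep <- snv & !multi
  dropped <- c(multiallelic = sum(multi), non_snv = sum(!snv & !multi))
  if (!any(keep)) stop("zero bi-allelic SNV records after filtering: ", path,
                       call. = FALSE)
  gt <- vcfR::extract.gt(v)[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]

  vcf_samples <- colnames(gt)
  unknown <- setdiff(vcf_samples, manifest$samples$sample)
  if (length(unknown)) {
    msg <- paste0("VCF sample(s) not in manifest: ",
                  paste(unknown, collapse = ", "))
    if (unknown_sample == "error") stop(msg, call. = FALSE)
    warning(msg, call. = FALSE)
  }

  gtn <- gsub("|", "/", gt, fixed = TRUE)
  alt_count <- matrix(NA_integer_, nrow(gtn), ncol(gtn),
                      dimnames = dimnames(gtn))
  code <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
  known <- gtn %in% c(names(code), "./.", ".")
  if (!all(known | is.na(gtn))) {
    bad <- unique(gtn[!known & !is.na(gtn)])
    stop("unsupported genotype code(s) in VCF: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  called <- !is.na(gtn) & gtn %in% names(code)
  alt_count[called] <- code[gtn[called]]

  pops <- manifest$populations
  n_sites <- nrow(gtn)
  f_alt <- matrix(NA_real_, n_sites, length(pops))
  n_alleles <- matrix(0L, n_sites, length(pops))
  for (j in seq_along(pops)) {
    cols <- intersect(
      manifest$samples$sample[manifest$samples$population == pops[j]],
      vcf_samples)
    cc <- called[, cols, drop = FALSE]
    n_alleles[, j] <- 2L * rowSums(cc)
    ac <- rowSums(alt_count[, cols, drop = FALSE], na.rm = TRUE)
    f_alt[, j] <- ifelse(n_alleles[, j] > 0, ac / n_alleles[, j], NA_real_)
  }
  if (min_call_rate > 0) {
    n_max <- 2L * nrow(manifest$samples)
    ok <- rowSums(n_alleles) / n_max >= min_call_rate
    dropped <- c(dropped, low_call_rate = sum(!ok))
    if (!any(ok)) stop("zero sites pass min_call_rate", call. = FALSE)
    fix <- fix[ok, , drop = FALSE]
    f_alt <- f_alt[ok, , drop = FALSE]
    n_alleles <- n_alleles[ok, , drop = FALSE]
  }
  tab <- new_afreq(chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
                   ref = fix[, "REF"], alt = fix[, "ALT"],
                   f_alt = f_alt, n_alleles = n_alleles,
                   pops = pops, roles = manifest$roles)
  attr(tab, "dropped") <- dropped
  assign_major_minor(tab, scope = major_scope)
}
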