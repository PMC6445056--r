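## Allele-frequency table construction shared by the VCF reader and the
## cohort simulator.  The raw table carries the ALT-allele frequency and the
## called-allele count per population; assign_major_minor() layers the
## major/minor labelling convention on top.

new_afreq <- function(chrom, pos, ref, alt, f_alt, n_alleles, pops,
                      roles = NULL) {
  stopifnot(is.matrix(f_alt), is.matrix(n_alleles),
            ncol(f_alt) == length(pops))
  tab <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                    stringsAsFactors = FALSE)
  for (j in seq_along(pops)) {
    tab[[paste0("f_alt_", pops[j])]] <- f_alt[, j]
    tab[[paste0("n_", pops[j])]] <- n_alleles[, j]
  }
  o <- order(tab$chrom, tab$pos)
  tab <- tab[o, , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "pops") <- pops
  attr(tab, "roles") <- roles
  class(tab) <- c("afreq_table", "data.frame")
  tab
}

afreq_pops <- function(table) attr(table, "pops")

afreq_roles <- function(table) {
  roles <- attr(table, "roles")
  if (is.null(roles)) {
    stop("allele-frequency table has no population roles; ",
         "supply a manifest with selected/sister/outgroup roles",
         call. = FALSE)
  }
  roles
}

#' Assign the major/minor allele convention
#'
#' Labels one allele per site as "major" and computes per-population
#' major-allele frequencies.  Under the default `"global"` scope the major
#' allele is the one whose pooled (all-samples) frequency is >= 0.5 (ties go
#' to REF), and the *same* allele is labelled major in every population, so
#' cross-population products in the between-population distance refer to
#' identical nucleotides.  Under `"per_pop"` each population's own commoner
#' allele is its major allele (no shared identity; `allele_major` is NA).
#'
#' @param table An allele-frequency table from [read_vcf()] or
#'   [cohort_afreq()].
#' @param scope `"global"` (default) or `"per_pop"`.
#' @return The table with columns `allele_major`, `allele_minor` and, per
#'   population, `f_major_<pop>`.
#' @export
assign_major_minor <- function(table, scope = c("global", "per_pop")) {
  scope <- match.arg(scope)
  pops <- afreq_pops(table)
  f_alt <- as.matrix(table[paste0("f_alt_", pops)])
  n <- as.matrix(table[paste0("n_", pops)])
  if (scope == "global") {
    alt_count <- rowSums(f_alt * n, na.rm = TRUE)
    tot <- rowSums(n * !is.na(f_alt))
    pooled_alt <- ifelse(tot > 0, alt_count / tot, NA_real_)
    alt_major <- !is.na(pooled_alt) & pooled_alt > 0.5  # tie -> REF major
    table$allele_major <- ifelse(alt_major, table$alt, table$ref)
    table$allele_minor <- ifelse(alt_major, table$ref, table$alt)
    for (p in pops) {
      fa <- table[[paste0("f_alt_", p)]]
      table[[paste0("f_major_", p)]] <- ifelse(alt_major, fa, 1 - fa)
    }
  } else {
    table$allele_major <- NA_character_
    table$allele_minor <- NA_character_
    for (p in pops) {
      fa <- table[[paste0("f_alt_", p)]]
      table[[paste0("f_major_", p)]] <- pmax(fa, 1 - fa)
    }
  }
  attr(table, "major_scope") <- scope
  table
}

#' Export an allele-frequency table as long-format TSV
#'
#' One row per site x population with columns chrom, pos, allele_major,
#' allele_minor, pop, f_major, f_minor, n_alleles.
#'
#' @param table A major/minor-assigned allele-frequency table.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
export_afreq <- function(table, path) {
  pops <- afreq_pops(table)
  if (is.null(table$allele_major)) table <- assign_major_minor(table)
  rows <- lapply(pops, function(p) {
    data.frame(chrom = table$chrom, pos = table$pos,
               allele_major = table$allele_major,
               allele_minor = table$allele_minor,
               pop = p,
               f_major = table[[paste0("f_major_", p)]],
               f_minor = 1 - table[[paste0("f_major_", p)]],
               n_alleles = table[[paste0("n_", p)]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$pos, out$pop), ]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
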