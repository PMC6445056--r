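## Retro-copy detection: align intron-containing parent genes to a genomic
## region, apply the candidate-duplication thresholds, then classify each
## exon-exon junction as intron-collapsed or intron-retained to separate
## retro-transposed (processed, intron-less) copies from ordinary segmental
## duplicates.

#' Classify intron loss at each exon-exon junction of a candidate locus
#'
#' Each exon of the parent gene is locally aligned inside the candidate
#' locus; for the junction between consecutive aligned exons, the
#' target-side gap between the flanking exon alignments is compared with the
#' parent intron length.  A junction is `collapsed` when the target gap is
#' at most `max_junction_gap` while the parent intron is longer than that
#' gap; `retained` when the target gap is within `retain_tol` (default 20%)
#' of the parent intron length; `ambiguous` otherwise; and `uncalled` when a
#' flanking exon is unaligned or the exons are out of order on the target.
#'
#' @param gene A [gene_model()].
#' @param region Target DNA sequence.
#' @param locus 0-based half-open `c(start, end)` of the candidate locus on
#'   `region`.
#' @param strand Strand of the candidate alignment (`"+"` or `"-"`).
#' @param max_junction_gap Maximum target gap (bp) for a collapsed call
#'   (default 30).
#' @param retain_tol Relative tolerance for a retained call (default 0.2).
#' @param min_exon_cov Minimum fraction of an exon that must align for the
#'   exon to count as aligned (default 0.5).
#' @param min_exon_identity Minimum identity of an exon alignment
#'   (default 0.7).
#' @return A data.frame with one row per junction: `junction`,
#'   `intron_len`, `target_gap`, `status`.
#' @export
detect_intron_loss <- function(gene, region, locus, strand = "+",
                               max_junction_gap = 30L, retain_tol = 0.2,
                               min_exon_cov = 0.5, min_exon_identity = 0.7) {
  stopifnot(inherits(gene, "gene_model"))
  n_ex <- nrow(gene$exons)
  il <- intron_lengths(gene)
  if (n_ex < 2) {
    return(data.frame(junction = integer(0), intron_len = integer(0),
                      target_gap = integer(0), status = character(0)))
  }
  tlen <- nchar(region)
  if (strand == "-") {
    region <- revcomp(region)
    locus <- c(tlen - locus[2], tlen - locus[1])
  }
  margin <- sum(il) + 200L
  w0 <- max(1L, locus[1] + 1L - margin)
  w1 <- min(tlen, locus[2] + margin)
  window <- substr(region, w0, w1)
  window_dna <- Biostrings::DNAString(window)
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3)
  ex_t <- matrix(NA_integer_, n_ex, 2L)
  for (i in seq_len(n_ex)) {
    eseq <- substr(gene$sequence, gene$exons$start[i] + 1L, gene$exons$end[i])
    pal <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(eseq), window_dna, type = "local",
      substitutionMatrix = submat, gapOpening = 5, gapExtension = 2)
    alen <- Biostrings::nchar(pal)
    ident <- if (alen > 0) Biostrings::nmatch(pal) / alen else 0
    if (alen >= min_exon_cov * nchar(eseq) && ident >= min_exon_identity) {
      sr <- pal@subject@range
      ex_t[i, ] <- c(IRanges::start(sr) - 1L, IRanges::end(sr))  # window 0-based
    }
  }
  gap <- ex_t[-1L, 1L] - ex_t[-n_ex, 2L]
  ordered_ok <- !is.na(gap) & gap >= -max_junction_gap
  status <- ifelse(!ordered_ok, "uncalled",
            ifelse(gap <= max_junction_gap & il > max_junction_gap,
                   "collapsed",
            ifelse(abs(gap - il) <= retain_tol * il, "retained",
                   "ambiguous")))
  data.frame(junction = seq_len(n_ex - 1L), intron_len = il,
             target_gap = gap, status = status, stringsAsFactors = FALSE)
}

## Split blocks of one gene into candidate loci by target-side proximity.
split_loci <- function(blocks, locus_gap) {
  if (!nrow(blocks)) return(list())
  blocks <- blocks[order(blocks$t_start), , drop = FALSE]
  hi <- cummax(blocks$t_end)
  grp <- cumsum(c(1L, blocks$t_start[-1L] > hi[-nrow(blocks)] + locus_gap))
  split(blocks, grp)
}

#' Call retro-copies of parent genes in a genomic region
#'
#' Pipeline per gene: the spliced (mRNA-like) sequence is aligned against
#' the region by [chain_alignments()]; blocks are grouped into candidate
#' loci; each locus must pass [candidate_filter()]; passing loci are
#' classified by [detect_intron_loss()] using the intron-containing gene
#' sequence.  Verdicts: `retrocopy` when at least half of the junctions are
#' collapsed; `duplication_with_introns` when at least half are retained;
#' `no_intron_evidence` for single-exon parents or all-uncalled junctions;
#' `ambiguous` otherwise; `no_candidate` when the thresholds are not met.
#'
#' @param genes A [gene_model()] or list of them.
#' @param region Target DNA sequence.
#' @param k,min_chain_score Aligner seeding parameters, see
#'   [chain_alignments()].
#' @param min_aligned,min_identity Candidate thresholds (strict `>`), see
#'   [candidate_filter()].
#' @param max_junction_gap,retain_tol Junction classification parameters,
#'   see [detect_intron_loss()].
#' @return A data.frame of class `retrocopy_calls`, one row per gene x
#'   locus (genes without any locus get a single `no_candidate` row):
#'   `gene`, `t_start`, `t_end`, `strand`, `aligned_bp`, `identity`,
#'   `junctions_total`, `junctions_collapsed`, `junctions_retained`,
#'   `junctions_uncalled`, `verdict`.  Attribute `blocks` holds the
#'   per-call alignment blocks for dot plots.
#' @export
call_retrocopies <- function(genes, region, k = 12L, min_chain_score = 40L,
                             min_aligned = 500, min_identity = 0.80,
                             max_junction_gap = 30L, retain_tol = 0.2) {
  if (inherits(genes, "gene_model")) genes <- list(genes)
  rows <- list(); blocks_out <- list()
  for (gene in genes) {
    stopifnot(inherits(gene, "gene_model"))
    mrna <- spliced_sequence(gene)
    blocks <- chain_alignments(mrna, region, k = k,
                               min_chain_score = min_chain_score)
    loci <- split_loci(blocks, locus_gap = max(10000L, sum(intron_lengths(gene))))
    if (!length(loci)) {
      rows[[length(rows) + 1L]] <- data.frame(
        gene = gene$id, t_start = NA_integer_, t_end = NA_integer_,
        strand = NA_character_, aligned_bp = 0L, identity = NA_real_,
        junctions_total = nrow(gene$exons) - 1L, junctions_collapsed = 0L,
        junctions_retained = 0L, junctions_uncalled = 0L,
        verdict = "no_candidate", stringsAsFactors = FALSE)
      next
    }
    for (lb in loci) {
      cf <- candidate_filter(lb, min_aligned, min_identity)
      t_span <- c(min(lb$t_start), max(lb$t_end))
      strand <- lb$strand[which.max(lb$matches)]
      jt <- nrow(gene$exons) - 1L
      if (!cf$pass) {
        verdict <- "no_candidate"
        jc <- jr <- ju <- 0L
      } else {
        jn <- detect_intron_loss(gene, region, t_span, strand,
                                 max_junction_gap = max_junction_gap,
                                 retain_tol = retain_tol)
        jc <- sum(jn$status == "collapsed")
        jr <- sum(jn$status == "retained")
        ju <- sum(jn$status == "uncalled")
        verdict <- if (jt == 0L || ju == jt) {
          "no_intron_evidence"
        } else if (jc >= ceiling(0.5 * jt)) {
          "retrocopy"
        } else if (jr >= ceiling(0.5 * jt)) {
          "duplication_with_introns"
        } else {
          "ambiguous"
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        gene = gene$id, t_start = t_span[1], t_end = t_span[2],
        strand = strand, aligned_bp = cf$aligned_bp, identity = cf$identity,
        junctions_total = jt, junctions_collapsed = jc,
        junctions_retained = jr, junctions_uncalled = ju,
        verdict = verdict, stringsAsFactors = FALSE)
      blocks_out[[paste0(gene$id, "@", t_span[1])]] <- lb
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(0), t_start = integer(0), t_end = integer(0),
               strand = character(0), aligned_bp = integer(0),
               identity = numeric(0), junctions_total = integer(0),
               junctions_collapsed = integer(0), junctions_retained = integer(0),
               junctions_uncalled = integer(0), verdict = character(0),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "blocks") <- blocks_out
  class(out) <- c("retrocopy_calls", "data.frame")
  out
}

#' Write retro-copy calls as TSV
#'
#' @param calls A `retrocopy_calls` table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_retrocopy_calls <- function(calls, path) {
  write.table(as.data.frame(calls), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
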