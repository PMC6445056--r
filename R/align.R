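## In-package pairwise DNA aligner: exact k-mer seeding, diagonal-band
## collinear chaining, then gapped local extension of each chain with
## Biostrings::pairwiseAlignment.  Replaces an external BLASTN/LASTZ call
## for desk-scale queries (genes) against regions up to a few Mb.

empty_blocks <- function() {
  data.frame(q_start = integer(0), q_end = integer(0),
             t_start = integer(0), t_end = integer(0),
             strand = character(0), length = integer(0),
             matches = integer(0), identity = numeric(0),
             stringsAsFactors = FALSE)
}

seed_hits <- function(qseq, target_dna, k) {
  qlen <- nchar(qseq)
  if (qlen < k) return(NULL)
  starts <- seq_len(qlen - k + 1L)
  kmers <- substring(qseq, starts, starts + k - 1L)
  keep <- !grepl("[^ACGT]", kmers)
  if (!any(keep)) return(NULL)
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(kmers[keep]))
  m <- Biostrings::matchPDict(pd, target_dna)
  tstarts <- Biostrings::startIndex(m)
  n_hits <- lengths(tstarts)
  if (sum(n_hits) == 0) return(NULL)
  data.frame(qpos = rep(starts[keep], n_hits),
             tpos = unlist(tstarts[n_hits > 0]))
}

#' Seed-chain-extend local alignment of a query against a target sequence
#'
#' Exact k-mer matches are grouped into diagonal bands (seeds whose
#' target-minus-query offsets differ by at most `band`), each band scored by
#' the query bases its seeds cover, and bands scoring at least
#' `min_chain_score` are extended by gapped local alignment
#' (Biostrings::pairwiseAlignment) over the banded query/target spans.  Both
#' strands are searched; minus-strand blocks report query coordinates on the
#' original (plus) query orientation.
#'
#' @param query,target DNA sequences over A/C/G/T/N.
#' @param k Exact seed length (default 12, minimum 8).
#' @param min_chain_score Minimum query bases covered by a band's seeds for
#'   the band to be extended (default 40).
#' @param band Diagonal tolerance in bp when grouping seeds (default 50).
#' @return A data.frame of alignment blocks sorted by target position, with
#'   0-based half-open `q_start`/`q_end`, `t_start`/`t_end`, `strand`,
#'   alignment `length` (columns), `matches` and `identity`
#'   (matches/length).  Empty for an all-N query.
#' @export
chain_alignments <- function(query, target, k = 12L, min_chain_score = 40L,
                             band = 50L) {
  if (!nchar(query) || !nchar(target)) {
    stop("empty query or target sequence", call. = FALSE)
  }
  if (k < 8) stop("seed length k must be >= 8", call. = FALSE)
  query <- toupper(query); target <- toupper(target)
  qlen <- nchar(query); tlen <- nchar(target)
  target_dna <- Biostrings::DNAString(target)
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3)
  out <- list()
  for (strand in c("+", "-")) {
    qseq <- if (strand == "+") query else revcomp(query)
    hits <- seed_hits(qseq, target_dna, k)
    if (is.null(hits)) next
    hits$diag <- hits$tpos - hits$qpos
    hits <- hits[order(hits$diag, hits$tpos), ]
    grp <- cumsum(c(1L, diff(hits$diag) > band))
    for (g in split(hits, grp)) {
      cov <- sum(IRanges::width(IRanges::reduce(
        IRanges::IRanges(g$qpos, width = k))))
      if (cov < min_chain_score) next
      q0 <- max(1L, min(g$qpos) - band)
      q1 <- min(qlen, max(g$qpos) + k - 1L + band)
      t0 <- max(1L, min(g$tpos) - 2L * band)
      t1 <- min(tlen, max(g$tpos) + k - 1L + 2L * band)
      pal <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(substr(qseq, q0, q1)),
        Biostrings::subseq(target_dna, t0, t1),
        type = "local", substitutionMatrix = submat,
        gapOpening = 5, gapExtension = 2)
      alen <- Biostrings::nchar(pal)
      if (alen < k) next
      nmat <- Biostrings::nmatch(pal)
      pr <- pal@pattern@range  # 1-based in the q0-trimmed query
      sr <- pal@subject@range
      qs1 <- q0 + IRanges::start(pr) - 1L  # 1-based in qseq
      qe1 <- q0 + IRanges::end(pr) - 1L
      if (strand == "+") {
        q_start <- qs1 - 1L; q_end <- qe1
      } else {
        q_start <- qlen - qe1; q_end <- qlen - qs1 + 1L
      }
      out[[length(out) + 1L]] <- data.frame(
        q_start = q_start, q_end = q_end,
        t_start = t0 + IRanges::start(sr) - 2L,  # to 0-based half-open
        t_end = t0 + IRanges::end(sr) - 1L,
        strand = strand, length = alen, matches = nmat,
        identity = nmat / alen, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty_blocks())
  blocks <- do.call(rbind, out)
  ## Drop blocks nested inside a higher-scoring block on the same strand
  ## (band overlap can produce duplicated extensions of one locus).
  blocks <- blocks[order(-blocks$matches), ]
  keep <- rep(TRUE, nrow(blocks))
  for (i in seq_len(nrow(blocks))[-1]) {
    prior <- which(keep[seq_len(i - 1L)])
    nested <- any(blocks$strand[prior] == blocks$strand[i] &
                    blocks$t_start[prior] <= blocks$t_start[i] &
                    blocks$t_end[prior] >= blocks$t_end[i] &
                    blocks$q_start[prior] <= blocks$q_start[i] &
                    blocks$q_end[prior] >= blocks$q_end[i])
    if (nested) keep[i] <- FALSE
  }
  blocks <- blocks[keep, , drop = FALSE]
  blocks <- blocks[order(blocks$t_start, blocks$t_end), , drop = FALSE]
  rownames(blocks) <- NULL
  blocks
}

#' Candidate duplication filter on alignment blocks
#'
#' A query-target pair is a candidate duplication event when its blocks
#' align strictly more than `min_aligned` bases in total with a
#' length-weighted identity strictly above `min_identity`.
#'
#' @param blocks Alignment blocks from [chain_alignments()] for one
#'   query-target pair (or one locus).
#' @param min_aligned Aligned-bp threshold (default 500, exclusive).
#' @param min_identity Identity threshold (default 0.80, exclusive).
#' @return List with `pass`, `aligned_bp`, `identity`.
#' @export
candidate_filter <- function(blocks, min_aligned = 500, min_identity = 0.80) {
  aligned <- sum(blocks$length)
  ident <- if (aligned > 0) sum(blocks$matches) / aligned else NA_real_
  list(pass = isTRUE(aligned > min_aligned && ident > min_identity),
       aligned_bp = aligned, identity = ident)
}

#' Write alignment blocks as PAF-like TSV (dot-plot input)
#'
#' @param blocks Alignment blocks.
#' @param path Output path.
#' @param query_name,target_name Sequence names for the first columns.
#' @return `path`, invisibly.
#' @export
export_blocks <- function(blocks, path, query_name = "query",
                          target_name = "target") {
  out <- data.frame(query = query_name,
                    q_start = blocks$q_start, q_end = blocks$q_end,
                    strand = blocks$strand, target = target_name,
                    t_start = blocks$t_start, t_end = blocks$t_end,
                    matches = blocks$matches, aln_len = blocks$length,
                    identity = blocks$identity)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
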