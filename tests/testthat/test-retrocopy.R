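test_that("aligner recovers an exact planted copy at identity 1", {
  q <- tailsweep:::with_seed(31, tailsweep:::random_dna(600))
  flank1 <- tailsweep:::with_seed(32, tailsweep:::random_dna(3000))
  flank2 <- tailsweep:::with_seed(33, tailsweep:::random_dna(3000))
  target <- paste0(flank1, q, flank2)
  blocks <- chain_alignments(q, target)
  expect_equal(nrow(blocks), 1)
  expect_equal(blocks$identity, 1)
  expect_gte(blocks$length, 600)
  expect_equal(blocks$t_start, 3000)
  expect_equal(blocks$t_end, 3600)
  expect_equal(blocks$strand, "+")
})

test_that("aligner identity tracks the planted substitution rate", {
  q <- tailsweep:::with_seed(41, tailsweep:::random_dna(800))
  copy <- tailsweep:::with_seed(42, tailsweep:::mutate_sequence(q, 0.15))
  target <- paste0(tailsweep:::with_seed(43, tailsweep:::random_dna(2000)),
                   copy,
                   tailsweep:::with_seed(44, tailsweep:::random_dna(2000)))
  blocks <- chain_alignments(q, target)
  expect_gte(nrow(blocks), 1)
  ident <- sum(blocks$matches) / sum(blocks$length)
  expect_equal(ident, 0.85, tolerance = 0.03 / 0.85)
})

test_that("reverse-complemented copies are found on the minus strand", {
  q <- tailsweep:::with_seed(51, tailsweep:::random_dna(600))
  target <- paste0(tailsweep:::with_seed(52, tailsweep:::random_dna(1500)),
                   tailsweep:::revcomp(q),
                   tailsweep:::with_seed(53, tailsweep:::random_dna(1500)))
  blocks <- chain_alignments(q, target)
  expect_equal(nrow(blocks), 1)
  expect_equal(blocks$strand, "-")
  expect_equal(blocks$identity, 1)
  expect_equal(c(blocks$t_start, blocks$t_end), c(1500, 2100))
})

test_that("aligner input contracts: empty, short-k and all-N sequences", {
  expect_error(chain_alignments("", "ACGT"), "empty")
  expect_error(chain_alignments("ACGTACGTACGT", "ACGT", k = 4), ">= 8")
  n_seq <- paste(rep("N", 100), collapse = "")
  expect_equal(nrow(chain_alignments(n_seq, tailsweep:::with_seed(
    1, tailsweep:::random_dna(1000)))), 0)
})

test_that("candidate thresholds are strict inequalities", {
  mk <- function(len, ident) {
    data.frame(q_start = 0L, q_end = len, t_start = 0L, t_end = len,
               strand = "+", length = len, matches = round(len * ident),
               identity = ident)
  }
  expect_true(candidate_filter(mk(600, 0.85))$pass)
  expect_false(candidate_filter(mk(400, 0.99))$pass)   # too short
  expect_false(candidate_filter(mk(500, 0.85))$pass)   # 500 is not > 500
  expect_true(candidate_filter(mk(501, 0.85))$pass)
  expect_false(candidate_filter(mk(600, 0.80))$pass)   # 0.80 is not > 0.80
  # length-weighted identity across blocks
  two <- rbind(mk(300, 0.95), mk(300, 0.70))
  cf <- candidate_filter(two)
  expect_equal(cf$identity, (round(300 * 0.95) + round(300 * 0.7)) / 600)
})

test_that("junction classification separates collapsed and retained introns", {
  host <- tailsweep:::with_seed(61, tailsweep:::random_dna(30000))
  gene <- random_gene("G", n_exons = 5, seed = 62)

  spliced <- plant_retrocopy(gene, host, 10000, identity = 0.9, seed = 63)
  jn <- detect_intron_loss(gene, spliced$host,
                           c(spliced$truth$start, spliced$truth$end))
  expect_equal(jn$status, rep("collapsed", 4))

  genomic <- plant_retrocopy(gene, host, 10000, identity = 0.9,
                             retain_introns = TRUE, seed = 64)
  jn2 <- detect_intron_loss(gene, genomic$host,
                            c(genomic$truth$start, genomic$truth$end))
  expect_equal(jn2$status, rep("retained", 4))

  # exon 3 replaced by random sequence -> junctions 2-3 and 3-4 uncalled
  mrna <- spliced_sequence(gene)
  ex <- gene$exons
  lens <- ex$end - ex$start
  off <- cumsum(c(0, lens))
  scrambled <- paste0(substr(mrna, 1, off[3]),
                      tailsweep:::with_seed(65, tailsweep:::random_dna(lens[3])),
                      substr(mrna, off[4] + 1, nchar(mrna)))
  target <- paste0(substr(host, 1, 5000), scrambled,
                   substr(host, 5001, nchar(host)))
  jn3 <- detect_intron_loss(gene, target, c(5000, 5000 + nchar(scrambled)))
  expect_equal(jn3$status, c("collapsed", "uncalled", "uncalled", "collapsed"))

  # single-exon parent: no junctions to classify
  g1 <- random_gene("single", n_exons = 1, seed = 66)
  expect_equal(nrow(detect_intron_loss(g1, host, c(0, 1000))), 0)
})

test_that("full pipeline calls planted copies with correct verdicts", {
  host <- tailsweep:::with_seed(71, tailsweep:::random_dna(80000))
  genes <- lapply(1:6, function(i) random_gene(paste0("G", i), seed = 700 + i))
  dup_gene <- random_gene("DUP", seed = 710)
  at <- seq(5000, 75000, length.out = 7)
  region <- host
  for (i in 1:6) {
    p <- plant_retrocopy(genes[[i]], region, round(at[i]),
                         identity = 0.88, seed = 720 + i)
    region <- p$host
  }
  p <- plant_retrocopy(dup_gene, region, round(at[7]), identity = 0.9,
                       retain_introns = TRUE, seed = 730)
  region <- p$host

  calls <- call_retrocopies(c(genes, list(dup_gene)), region)
  expect_equal(sum(calls$verdict == "retrocopy"), 6)
  expect_equal(calls$verdict[calls$gene == "DUP"], "duplication_with_introns")
  expect_true(all(calls$junctions_collapsed[calls$verdict == "retrocopy"] == 4))

  # strand invariance: reverse-complementing the region preserves verdicts
  calls_rc <- call_retrocopies(c(genes, list(dup_gene)),
                               tailsweep:::revcomp(region))
  v1 <- calls$verdict[order(calls$gene)]
  v2 <- calls_rc$verdict[order(calls_rc$gene)]
  expect_equal(v2, v1)
  expect_true(all(calls_rc$strand == "-"))

  # empty gene list -> empty output
  expect_equal(nrow(call_retrocopies(list(), region)), 0)

  # absent gene -> no_candidate row
  absent <- random_gene("ABSENT", seed = 740)
  one <- call_retrocopies(absent, region)
  expect_equal(one$verdict, "no_candidate")
})

test_that("alignment blocks export as PAF-like TSV", {
  q <- tailsweep:::with_seed(81, tailsweep:::random_dna(600))
  target <- paste0(q, tailsweep:::with_seed(82, tailsweep:::random_dna(600)))
  blocks <- chain_alignments(q, target)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  export_blocks(blocks, tmp, "q", "t")
  back <- read.table(tmp, header = TRUE, sep = "\t")
  expect_equal(back$t_start, blocks$t_start)
  expect_equal(back$matches, blocks$matches)
})
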