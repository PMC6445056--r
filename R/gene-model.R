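#' Construct a gene model (sequence plus exon structure)
#'
#' @param id Gene identifier.
#' @param sequence Genomic gene sequence (introns included), A/C/G/T/N.
#' @param exons Data.frame or 2-column matrix of exon `start`, `end` in
#'   0-based half-open coordinates on `sequence`; must be sorted and
#'   non-overlapping with at least one exon.  Introns are the gaps between
#'   consecutive exons.
#' @param strand `"+"` or `"-"` (annotation only; the sequence is stored as
#'   given).
#' @return An object of class `gene_model` with fields `id`, `sequence`,
#'   `exons`, `strand`.
#' @export
gene_model <- function(id, sequence, exons, strand = "+") {
  exons <- as.data.frame(exons)
  names(exons)[1:2] <- c("start", "end")
  stopifnot(nrow(exons) >= 1, strand %in% c("+", "-"))
  o <- order(exons$start)
  exons <- exons[o, , drop = FALSE]
  len <- nchar(sequence)
  if (any(exons$start < 0) || any(exons$end > len) ||
      any(exons$end <= exons$start)) {
    stop("exon intervals must be non-empty and within the gene sequence",
         call. = FALSE)
  }
  if (nrow(exons) > 1 && any(exons$start[-1] < exons$end[-nrow(exons)])) {
    stop("exons overlap", call. = FALSE)
  }
  rownames(exons) <- NULL
  structure(list(id = id, sequence = toupper(sequence), exons = exons,
                 strand = strand),
            class = "gene_model")
}

#' Spliced (mRNA-like) sequence of a gene model
#' @param gene A [gene_model()].
#' @return The concatenated exon sequence.
#' @export
spliced_sequence <- function(gene) {
  stopifnot(inherits(gene, "gene_model"))
  paste(substring(gene$sequence, gene$exons$start + 1, gene$exons$end),
        collapse = "")
}

intron_lengths <- function(gene) {
  ex <- gene$exons
  if (nrow(ex) < 2) return(integer(0))
  ex$start[-1] - ex$end[-nrow(ex)]
}

#' Read exon structures from a TSV or GFF3 file
#'
#' TSV dialect: columns gene, exon_start, exon_end (0-based half-open, with
#' or without header).  GFF3 dialect: `exon` features whose Parent or ID
#' attribute names the gene; 1-based inclusive coordinates are converted.
#'
#' @param path Input file.
#' @param format `"tsv"` or `"gff3"`; guessed from the extension by default.
#' @return Named list of exon data.frames (`start`, `end`), one per gene.
#' @export
read_exon_table <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3" else "tsv"
  }
  if (format == "tsv") {
    raw <- read.table(path, sep = "\t", header = FALSE, colClasses = "character")
    if (identical(tolower(raw[1, 1]), "gene")) raw <- raw[-1, , drop = FALSE]
    df <- data.frame(gene = raw[[1]], start = as.integer(raw[[2]]),
                     end = as.integer(raw[[3]]), stringsAsFactors = FALSE)
  } else {
    lines <- readLines(path)
    lines <- lines[!grepl("^#", lines) & nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    parts <- parts[vapply(parts, length, 1L) >= 9 &
                     vapply(parts, function(p) p[3] == "exon", TRUE)]
    if (!length(parts)) stop("no exon features in ", path, call. = FALSE)
    df <- do.call(rbind, lapply(parts, function(p) {
      attr_str <- p[9]
      m <- regmatches(attr_str, regexec("(?:Parent|ID)=([^;]+)", attr_str))[[1]]
      data.frame(gene = if (length(m) == 2) m[2] else p[1],
                 start = as.integer(p[4]) - 1L, end = as.integer(p[5]),
                 stringsAsFactors = FALSE)
    }))
  }
  lapply(split(df[c("start", "end")], df$gene), function(x) {
    x <- x[order(x$start), ]
    rownames(x) <- NULL
    x
  })
}

#' Generate a random intron-containing gene model
#'
#' Fixture generator: exon and intron lengths are drawn uniformly from the
#' given ranges and the sequence is uniform random DNA.
#'
#' @param id Gene identifier.
#' @param n_exons Number of exons.
#' @param exon_len,intron_len Length ranges `c(min, max)` in bp.
#' @param seed Integer seed.
#' @return A [gene_model()].
#' @export
random_gene <- function(id, n_exons = 5L, exon_len = c(150L, 300L),
                        intron_len = c(300L, 800L), seed) {
  with_seed(seed, {
    el <- sample(exon_len[1]:exon_len[2], n_exons, replace = TRUE)
    il <- if (n_exons > 1) {
      sample(intron_len[1]:intron_len[2], n_exons - 1L, replace = TRUE)
    } else {
      integer(0)
    }
    starts <- cumsum(c(0L, el[-n_exons] + il))
    seq <- random_dna(sum(el) + sum(il))
    gene_model(id, seq, data.frame(start = starts, end = starts + el))
  })
}

#' Plant a retro-copy (or intron-retaining duplicate) of a gene into a host
#'
#' Inserts either the spliced exon concatenation (`retain_introns = FALSE`,
#' emulating a reverse-transcribed mRNA insertion) or the full genomic gene
#' sequence (`retain_introns = TRUE`) at `insert_at`, applying point
#' substitutions at rate (1 - identity) uniformly at random.
#'
#' @param parent A [gene_model()].
#' @param host Host DNA sequence.
#' @param insert_at 0-based insertion offset in `host` (0..nchar).
#' @param identity Target sequence identity of the copy, in [0.5, 1].
#' @param retain_introns Insert the full genomic sequence instead of the
#'   spliced sequence.
#' @param seed Integer seed.
#' @return List with `host` (modified sequence) and `truth` (gene id,
#'   0-based half-open insertion interval, target identity, realized
#'   identity, substitution count, intron flag).
#' @export
plant_retrocopy <- function(parent, host, insert_at, identity = 1,
                            retain_introns = FALSE, seed) {
  stopifnot(inherits(parent, "gene_model"))
  if (identity < 0.5 || identity > 1) {
    stop("identity must lie in [0.5, 1]", call. = FALSE)
  }
  if (insert_at < 0 || insert_at > nchar(host)) {
    stop("insert_at outside host sequence", call. = FALSE)
  }
  ins <- if (retain_introns) parent$sequence else spliced_sequence(parent)
  mut <- with_seed(seed, mutate_sequence(ins, 1 - identity))
  n_sub <- sum(strsplit(ins, "")[[1]] != strsplit(mut, "")[[1]])
  new_host <- paste0(substr(host, 1, insert_at), mut,
                     substr(host, insert_at + 1, nchar(host)))
  list(host = new_host,
       truth = list(gene = parent$id, start = insert_at,
                    end = insert_at + nchar(ins),
                    identity_target = identity,
                    identity_realized = 1 - n_sub / nchar(ins),
                    n_substitutions = n_sub,
                    retain_introns = retain_introns))
}
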