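## Default element names per repeat class/family, mirroring the vocabulary
## RepeatMasker emits for ruminant genomes.
default_repeat_names <- c(
  "LINE/RTE-BovB" = "BovB",
  "LINE/L1" = "L1",
  "LINE/L2" = "L2",
  "SINE/MIR" = "MIR",
  "SINE/tRNA-Core-RTE" = "Bov-tA",
  "LTR/ERVL" = "ERVL",
  "LTR/ERVL-MaLR" = "MLT1",
  "DNA/hAT-Charlie" = "MER1")

#' Simulate a RepeatMasker-style repeat annotation with target coverages
#'
#' Generates non-overlapping repeat elements whose per-class coverage
#' matches the requested fractions to within 1% absolute (the last element
#' of each class is trimmed so the class total hits the target exactly,
#' subject to the 50 bp minimum element length).  Element lengths are drawn
#' from a log-normal distribution; placement is uniform over the free space.
#'
#' @param region_length Region length in bp.
#' @param class_targets Named numeric vector of per-class coverage
#'   fractions (names are class/family strings, e.g. `"LINE/RTE-BovB"`);
#'   fractions must sum to at most 1.  An empty vector yields a header-only
#'   annotation.
#' @param seed Integer seed.
#' @param meanlog,sdlog Element length distribution parameters (log-normal,
#'   truncated below at 50 bp; defaults meanlog = log(800), sdlog = 0.7).
#' @param seqname Sequence name for the annotation rows.
#' @param path Optional output path; when given the annotation is also
#'   written in RepeatMasker `.out` format.
#' @return A `repeat_annotation` data.frame (round-trips through
#'   [parse_repeatmasker_out()] when written).
#' @export
simulate_repeat_annotation <- function(region_length, class_targets, seed,
                                       meanlog = log(800), sdlog = 0.7,
                                       seqname = "region", path = NULL) {
  stopifnot(region_length >= 1)
  if (length(class_targets) && (is.null(names(class_targets)) ||
                                any(!nzchar(names(class_targets))))) {
    stop("class_targets must be a named vector", call. = FALSE)
  }
  if (sum(class_targets) > 1 + 1e-9) {
    stop("class coverage targets sum to more than 1", call. = FALSE)
  }
  ann <- with_seed(seed, {
    rows <- list()
    for (cls in names(class_targets)) {
      target_bp <- round(class_targets[[cls]] * region_length)
      if (target_bp < 50) next
      lens <- integer(0)
      while (sum(lens) < target_bp) {
        l <- max(50L, round(stats::rlnorm(1, meanlog, sdlog)))
        lens <- c(lens, l)
      }
      excess <- sum(lens) - target_bp
      lens[length(lens)] <- lens[length(lens)] - excess
      if (lens[length(lens)] < 50L) lens <- lens[-length(lens)]
      nm <- default_repeat_names[[cls]] %||% sub("^.*/", "", cls)
      rows[[cls]] <- data.frame(class_family = cls, name = nm, len = lens,
                                stringsAsFactors = FALSE)
    }
    if (!length(rows)) {
      data.frame(seqname = character(0), start = integer(0),
                 end = integer(0), strand = character(0),
                 name = character(0), class_family = character(0),
                 divergence = numeric(0), score = numeric(0),
                 stringsAsFactors = FALSE)
    } else {
      el <- do.call(rbind, rows)
      el <- el[sample.int(nrow(el)), , drop = FALSE]  # interleave classes
      total <- sum(el$len)
      free <- region_length - total
      if (free < 0) stop("infeasible packing: elements exceed region",
                         call. = FALSE)
      offsets <- sort(sample.int(free + 1L, nrow(el), replace = TRUE) - 1L)
      starts <- offsets + cumsum(c(0L, el$len[-nrow(el)]))
      data.frame(seqname = seqname, start = starts, end = starts + el$len,
                 strand = sample(c("+", "-"), nrow(el), replace = TRUE),
                 name = el$name, class_family = el$class_family,
                 divergence = round(runif(nrow(el), 5, 30), 1),
                 score = round(runif(nrow(el), 200, 5000)),
                 stringsAsFactors = FALSE)
    }
  })
  ann <- new_repeat_annotation(ann)
  if (!is.null(path)) write_repeatmasker_out(ann, path)
  ann
}
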