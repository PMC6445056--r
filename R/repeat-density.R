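#' Parse a RepeatMasker `.out` annotation file
#'
#' Reads the standard whitespace-delimited 14/15-column body (with the usual
#' 3-line header; a missing header is tolerated with a warning).  The
#' 1-based inclusive query coordinates are converted to 0-based half-open;
#' the "C" strand code is mapped to "-".
#'
#' @param path `.out` file path.
#' @return A data.frame of class `repeat_annotation` with columns `seqname`,
#'   `start`, `end`, `strand`, `name`, `class_family`, `class`, `subclass`,
#'   `divergence`, `score`.
#' @export
parse_repeatmasker_out <- function(path) {
  lines <- readLines(path)
  is_header <- grepl("^\\s*(SW|score|$)", lines[seq_len(min(3, length(lines)))])
  if (length(lines) >= 1 && is_header[1]) {
    lines <- lines[-seq_len(sum(cumprod(is_header)))]
  } else {
    warning("no RepeatMasker header found in ", path, call. = FALSE)
  }
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(new_repeat_annotation(data.frame(
      seqname = character(0), start = integer(0), end = integer(0),
      strand = character(0), name = character(0), class_family = character(0),
      divergence = numeric(0), score = numeric(0))))
  }
  fields <- strsplit(trimws(lines), "\\s+")
  nf <- vapply(fields, length, 1L)
  bad <- which(nf < 14L)
  if (length(bad)) {
    stop("unparseable RepeatMasker row(s) (fewer than 14 fields) at line(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  f <- function(i) vapply(fields, `[[`, character(1), i)
  begin <- as.integer(f(6)); end <- as.integer(f(7))
  if (any(begin > end)) {
    stop("RepeatMasker row(s) with begin > end at line(s): ",
         paste(which(begin > end), collapse = ", "), call. = FALSE)
  }
  new_repeat_annotation(data.frame(
    seqname = f(5), start = begin - 1L, end = end,
    strand = ifelse(f(9) == "C", "-", f(9)),
    name = f(10), class_family = f(11),
    divergence = as.numeric(f(2)), score = as.numeric(f(1)),
    stringsAsFactors = FALSE))
}

new_repeat_annotation <- function(df) {
  cf <- strsplit(df$class_family, "/", fixed = TRUE)
  df$class <- vapply(cf, `[[`, character(1), 1)
  df$subclass <- vapply(cf, function(x) if (length(x) > 1) x[2] else x[1],
                        character(1))
  class(df) <- c("repeat_annotation", "data.frame")
  df
}

#' Write repeat annotation back to RepeatMasker `.out` format
#'
#' Inverse of [parse_repeatmasker_out()] for the fields the package uses;
#' the unused columns are filled with placeholders.
#'
#' @param ann A `repeat_annotation` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_repeatmasker_out <- function(ann, path) {
  header <- c(
    paste("   SW   perc perc perc  query      position in query    ",
          "matching             repeat           position in repeat"),
    paste("score   div. del. ins.  sequence   begin end    (left)  ",
          "repeat               class/family   begin  end    (left)   ID"),
    "")
  body <- if (nrow(ann)) {
    sprintf("%5d %6.1f  0.0  0.0  %-10s %7d %7d (0) %s %-16s %-16s 1 %6d (0) %5d",
            as.integer(ann$score), ann$divergence, ann$seqname,
            ann$start + 1L, ann$end,
            ifelse(ann$strand == "-", "C", "+"),
            ann$name, ann$class_family, ann$end - ann$start,
            seq_len(nrow(ann)))
  } else {
    character(0)
  }
  writeLines(c(header, body), path)
  invisible(path)
}

clip_to_region <- function(ann, region) {
  s <- pmax(ann$start, region[1])
  e <- pmin(ann$end, region[2])
  keep <- e > s
  ann <- ann[keep, , drop = FALSE]
  ann$start <- s[keep]
  ann$end <- e[keep]
  ann
}

union_bp <- function(start, end) {
  if (!length(start)) return(0L)
  sum(IRanges::width(IRanges::reduce(IRanges::IRanges(start + 1L, end))))
}

#' Per-class repeat coverage of a region
#'
#' Elements are clipped to the region; per group, coverage is the union of
#' member intervals (overlapping or nested elements counted once) divided by
#' the region length.
#'
#' @param ann A `repeat_annotation` data.frame.
#' @param region 0-based half-open `c(start, end)` interval.
#' @param grouping Grouping column: `"class_family"` (default), `"class"`,
#'   `"subclass"` or `"name"`.
#' @return A data.frame with `group`, `n_elements`, `covered_bp`,
#'   `fraction`, sorted by decreasing coverage.
#' @export
class_coverage <- function(ann, region,
                           grouping = c("class_family", "class", "subclass",
                                        "name")) {
  grouping <- match.arg(grouping)
  region_len <- region[2] - region[1]
  stopifnot(region_len > 0)
  ann <- clip_to_region(ann, region)
  groups <- split(ann, ann[[grouping]])
  out <- data.frame(
    group = names(groups),
    n_elements = vapply(groups, nrow, 1L),
    covered_bp = vapply(groups, function(g) union_bp(g$start, g$end), 1L),
    stringsAsFactors = FALSE)
  out$fraction <- out$covered_bp / region_len
  out <- out[order(-out$covered_bp), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Sliding-window repeat density across a region
#'
#' Per window, the union-coverage fraction of the supplied elements
#' (subset `ann` beforehand to focus on one class, e.g. BovB).
#'
#' @param ann A `repeat_annotation` data.frame (already filtered to the
#'   elements of interest).
#' @param region 0-based half-open `c(start, end)`.
#' @param window Window size in bp (default 50000).
#' @param step Step in bp (default `window / 2`).
#' @return A data.frame with `start`, `end`, `fraction` (windows positioned
#'   relative to `region[1]`).
#' @export
windowed_density <- function(ann, region, window = 50000L,
                             step = window %/% 2L) {
  region_len <- region[2] - region[1]
  if (window > region_len) stop("window exceeds region length", call. = FALSE)
  ann <- clip_to_region(ann, region)
  win <- tile_windows(region_len, window, step)
  win$start <- win$start + region[1]
  win$end <- win$end + region[1]
  win$fraction <- vapply(seq_len(nrow(win)), function(i) {
    sub <- clip_to_region(ann, c(win$start[i], win$end[i]))
    union_bp(sub$start, sub$end) / (win$end[i] - win$start[i])
  }, numeric(1))
  win[c("start", "end", "fraction")]
}

#' Compare focal-region repeat density against random loci
#'
#' Draws `n` random regions of the focal region's length uniformly over the
#' annotated extent, non-overlapping with each other and with the focal
#' region, and reports per group the focal coverage fraction against the
#' mean and sample standard deviation over the random regions.
#'
#' @param ann Genome-wide `repeat_annotation`.
#' @param genome_length Annotated extent in bp.
#' @param focal 0-based half-open `c(start, end)` focal region.
#' @param n Number of random regions (default 10).
#' @param seed Integer seed.
#' @param grouping Grouping column, see [class_coverage()].
#' @param max_tries Placement attempts before giving up.
#' @return A data.frame with `group`, `focal_fraction`, `random_mean`,
#'   `random_sd`.
#' @export
random_region_comparison <- function(ann, genome_length, focal, n = 10L,
                                     seed, grouping = "class_family",
                                     max_tries = 1000L) {
  if (n < 1) stop("need n >= 1 random regions", call. = FALSE)
  flen <- focal[2] - focal[1]
  if (genome_length < (n + 1) * flen) {
    stop("genome extent too small to place ", n,
         " non-overlapping regions of the focal length", call. = FALSE)
  }
  regions <- with_seed(seed, {
    placed <- list(focal)
    tries <- 0L
    while (length(placed) < n + 1L) {
      tries <- tries + 1L
      if (tries > max_tries) {
        stop("could not place ", n, " non-overlapping random regions",
             call. = FALSE)
      }
      s <- sample.int(genome_length - flen + 1L, 1L) - 1L
      cand <- c(s, s + flen)
      overlaps <- any(vapply(placed, function(r) {
        cand[1] < r[2] && r[1] < cand[2]
      }, TRUE))
      if (!overlaps) placed[[length(placed) + 1L]] <- cand
    }
    placed[-1L]
  })
  focal_cov <- class_coverage(ann, focal, grouping)
  rand_cov <- lapply(regions, function(r) class_coverage(ann, r, grouping))
  groups <- sort(unique(c(focal_cov$group,
                          unlist(lapply(rand_cov, `[[`, "group")))))
  frac_of <- function(cov, g) {
    i <- match(g, cov$group)
    ifelse(is.na(i), 0, cov$fraction[i])
  }
  rand_mat <- vapply(rand_cov, frac_of, numeric(length(groups)), g = groups)
  if (is.null(dim(rand_mat))) rand_mat <- matrix(rand_mat, nrow = length(groups))
  data.frame(group = groups,
             focal_fraction = frac_of(focal_cov, groups),
             random_mean = rowMeans(rand_mat),
             random_sd = apply(rand_mat, 1L, sd),
             stringsAsFactors = FALSE)
}
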