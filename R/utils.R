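#' @keywords internal
"_PACKAGE"

#' @importFrom stats rbeta rbinom rnorm runif quantile sd lm pt coef
#'   complete.cases setNames pchisq
#' @importFrom utils read.table write.table
NULL

## Run code with a private, restorable RNG stream so generators are pure
## functions of (config, seed) and never disturb the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

#' Tile a chromosome with sliding windows
#'
#' Windows are 0-based half-open intervals starting at 0 and advancing by
#' `step`; the trailing partial window at the chromosome end is retained and
#' flagged so terminal features are not silently dropped.
#'
#' @param chrom_length Chromosome length in bp.
#' @param window Window size in bp (default 30000).
#' @param step Step size in bp (default 15000); must not exceed `window`.
#' @return A data.frame with columns `start`, `end`, `partial`.
#' @examples
#' tile_windows(60000)
#' @export
tile_windows <- function(chrom_length, window = 30000L, step = 15000L) {
  stopifnot(chrom_length >= 1, window >= 1, step >= 1)
  if (step > window) stop("`step` must be <= `window`", call. = FALSE)
  starts <- seq(0, chrom_length - 1, by = step)
  ends <- pmin(starts + window, chrom_length)
  data.frame(start = starts, end = ends, partial = (ends - starts) < window)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## Substitute bases uniformly at random at rate `rate`; each hit position is
## replaced by one of the three other bases.
mutate_sequence <- function(seq, rate) {
  if (rate <= 0) return(seq)
  bases <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(bases)) < rate & bases %in% c("A", "C", "G", "T"))
  for (i in hit) {
    bases[i] <- sample(setdiff(c("A", "C", "G", "T"), bases[i]), 1L)
  }
  paste(bases, collapse = "")
}
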