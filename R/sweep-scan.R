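## Per-site numerator/denominator components of the window fixation index.
## "wright": H_T - H_S over H_T with H_T from the mean of the two population
## frequencies and H_S the mean within-population heterozygosity (no sample
## size correction; frequencies are taken as known).
## "hudson": Hudson's estimator with finite-sample correction, which needs
## the called-allele counts and may be negative.
fst_site_components <- function(fa, fb, na = NULL, nb = NULL,
                                estimator = c("wright", "hudson")) {
  estimator <- match.arg(estimator)
  if (estimator == "wright") {
    pbar <- (fa + fb) / 2
    ht <- 2 * pbar * (1 - pbar)
    hs <- (2 * fa * (1 - fa) + 2 * fb * (1 - fb)) / 2
    list(num = ht - hs, den = ht)
  } else {
    if (is.null(na) || is.null(nb)) {
      stop("hudson estimator needs allele counts na, nb", call. = FALSE)
    }
    num <- (fa - fb)^2 - fa * (1 - fa) / (na - 1) - fb * (1 - fb) / (nb - 1)
    den <- fa * (1 - fb) + fb * (1 - fa)
    list(num = num, den = den)
  }
}

#' Window fixation index between two populations
#'
#' Ratio-of-sums window estimator: per-site numerator and denominator
#' components are summed over the window and then divided, so monomorphic
#' sites contribute zero to both sums.  The default `"wright"` form is the
#' frequency-based (H_T - H_S)/H_T with no sample-size correction; the
#' `"hudson"` form applies Hudson's finite-sample correction (needs allele
#' counts, may be negative, not clamped).
#'
#' @param fa,fb Per-site frequencies of a shared allele in the two
#'   populations (major-allele frequencies under the global convention; the
#'   statistic is invariant to which of the two alleles is tracked).
#' @param na,nb Called-allele counts per site (hudson only).
#' @param estimator `"wright"` (default) or `"hudson"`.
#' @return The window fixation index, or NA if no site is informative
#'   (denominator sum zero).
#' @export
window_fst <- function(fa, fb, na = NULL, nb = NULL,
                       estimator = c("wright", "hudson")) {
  estimator <- match.arg(estimator)
  ok <- !is.na(fa) & !is.na(fb)
  if (estimator == "hudson") ok <- ok & !is.na(na) & !is.na(nb) & na > 1 & nb > 1
  if (!any(ok)) return(NA_real_)
  cmp <- fst_site_components(fa[ok], fb[ok], na[ok], nb[ok], estimator)
  den <- sum(cmp$den)
  if (den == 0) return(NA_real_)
  sum(cmp$num) / den
}

#' Lineage-specific branch lengths from three pairwise fixation indices
#'
#' For populations M (selected), T (sister) and E (outgroup), the branch
#' length specific to M is (FI_MT + FI_ME - FI_TE)/2, and symmetrically for
#' T and E.  The three branch lengths always sum to (FI_MT+FI_ME+FI_TE)/2.
#'
#' @param fi_mt,fi_me,fi_te Pairwise window fixation indices (vectorized).
#' @return A data.frame with columns `lsbl_m`, `lsbl_t`, `lsbl_e`; NA inputs
#'   propagate.
#' @export
lsbl <- function(fi_mt, fi_me, fi_te) {
  data.frame(lsbl_m = (fi_mt + fi_me - fi_te) / 2,
             lsbl_t = (fi_mt + fi_te - fi_me) / 2,
             lsbl_e = (fi_me + fi_te - fi_mt) / 2)
}

#' Between-population distance d_xy over a window
#'
#' With per-site major-allele frequencies f_x, f_y of the *same* allele in
#' populations x and y (global major/minor convention), the default
#' `"per_site"` mode averages f_x,major*f_y,minor + f_y,major*f_x,minor over
#' sites — the mean probability that one allele drawn from each population
#' differs at a site.  The `"literal"` mode evaluates the unnormalized
#' window-sum product form
#' sum(f_x,major)*sum(f_y,minor) + sum(f_y,major)*sum(f_x,minor),
#' which scales with the squared site count and is only comparable between
#' equal-n windows.  Both modes are symmetric in (x, y).
#'
#' @param fx,fy Per-site major-allele frequencies in the two populations.
#' @param mode `"per_site"` (default) or `"literal"`.
#' @return The window distance; NA when no site has data in both
#'   populations.
#' @export
window_dxy <- function(fx, fy, mode = c("per_site", "literal")) {
  mode <- match.arg(mode)
  ok <- !is.na(fx) & !is.na(fy)
  if (!any(ok)) return(NA_real_)
  fx <- fx[ok]; fy <- fy[ok]
  if (mode == "per_site") {
    mean(fx * (1 - fy) + fy * (1 - fx))
  } else {
    sum(fx) * sum(1 - fy) + sum(fy) * sum(1 - fx)
  }
}

#' Pooled window heterozygosity H_P
#'
#' H_P = 2*S_maj*S_min / (S_maj + S_min)^2 where S_maj and S_min are the
#' window sums of per-site major- and minor-allele frequencies.  The pooled
#' form is bounded in [0, 0.5] and is the statistic standardized genome-wide
#' into ZH_P.
#'
#' @param f_major Per-site major-allele frequencies in one population.
#' @return H_P, or NA when every frequency is undefined.
#' @export
window_hp <- function(f_major) {
  f_major <- f_major[!is.na(f_major)]
  if (!length(f_major)) return(NA_real_)
  s_maj <- sum(f_major)
  s_min <- sum(1 - f_major)
  2 * s_maj * s_min / (s_maj + s_min)^2
}

#' Genome-wide standardization of window H_P into ZH_P
#'
#' ZH_P = (H_P - mu)/sigma with mu and sigma the mean and standard deviation
#' of H_P over all non-NA windows of one population.
#'
#' @param hp Vector of window H_P values (one population, genome-wide).
#' @param sd_type `"sample"` (default, n-1 denominator) or `"population"`.
#' @return ZH_P values; NAs propagate.  If sigma is zero (or fewer than two
#'   non-NA windows) all values are NA with a warning.
#' @export
standardize_zhp <- function(hp, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  ok <- !is.na(hp)
  if (sum(ok) < 2) {
    warning("fewer than two non-NA windows; ZH_P undefined", call. = FALSE)
    return(rep(NA_real_, length(hp)))
  }
  mu <- mean(hp[ok])
  sigma <- sd(hp[ok])
  if (sd_type == "population") {
    sigma <- sigma * sqrt((sum(ok) - 1) / sum(ok))
  }
  if (sigma == 0) {
    warning("zero variance across windows; ZH_P undefined", call. = FALSE)
    return(rep(NA_real_, length(hp)))
  }
  (hp - mu) / sigma
}

#' Sliding-window selective-sweep scan
#'
#' Tiles each chromosome with sliding windows (default 30 kb with a 15 kb
#' step) and computes per window: the three pairwise fixation indices, the
#' three lineage-specific branch lengths, pairwise d_xy, and per-population
#' pooled heterozygosity H_P; after the sweep over all windows, H_P is
#' standardized genome-wide into ZH_P per population.  d_xy uses the
#' table's (global by default) shared major/minor labelling; H_P uses each
#' population's own per-site commoner allele, so it is depressed wherever
#' that population is near fixation regardless of which allele is fixed.
#' Windows with fewer
#' than `min_sites` sites carry NA statistics; the trailing partial window
#' of each chromosome is retained and flagged.
#'
#' @param table A major/minor-assigned allele-frequency table whose roles
#'   attribute names the selected (M), sister (T) and outgroup (E)
#'   populations.
#' @param window,step Window and step size in bp.
#' @param min_sites Minimum sites for a window's statistics to be computed.
#' @param estimator Fixation-index estimator, see [window_fst()].
#' @param dxy_mode d_xy mode, see [window_dxy()].
#' @param sd_type Standard deviation convention for ZH_P.
#' @param chrom_lengths Optional named vector of chromosome lengths; by
#'   default each chromosome extends to its last site.
#' @return A data.frame of class `window_stats` sorted by (chrom, start)
#'   with columns chrom, start, end, partial, n_sites, fi_mt, fi_me, fi_te,
#'   lsbl_m, lsbl_t, lsbl_e, d_mt, d_me, d_te, hp_m, hp_t, hp_e, zhp_m,
#'   zhp_t, zhp_e.  Windows use 0-based half-open coordinates.
#' @export
scan_genome <- function(table, window = 30000L, step = 15000L,
                        min_sites = 10L,
                        estimator = c("wright", "hudson"),
                        dxy_mode = c("per_site", "literal"),
                        sd_type = c("sample", "population"),
                        chrom_lengths = NULL) {
  estimator <- match.arg(estimator)
  dxy_mode <- match.arg(dxy_mode)
  sd_type <- match.arg(sd_type)
  roles <- afreq_roles(table)
  pm <- roles[["selected"]]; pt <- roles[["sister"]]; pe <- roles[["outgroup"]]
  need <- paste0("f_major_", c(pm, pt, pe))
  if (!all(need %in% names(table))) {
    stop("table lacks major-allele frequencies; run assign_major_minor()",
         call. = FALSE)
  }
  for (p in c(pm, pt, pe)) {
    if (max(table[[paste0("n_", p)]], na.rm = TRUE) < 4L) {
      stop("population `", p, "` has fewer than 2 samples; ",
           "branch-length statistics need >= 2 per population",
           call. = FALSE)
    }
  }
  chroms <- unique(table$chrom)
  res <- lapply(chroms, function(ch) {
    sub <- table[table$chrom == ch, , drop = FALSE]
    clen <- if (!is.null(chrom_lengths) && ch %in% names(chrom_lengths)) {
      chrom_lengths[[ch]]
    } else {
      max(sub$pos)
    }
    win <- tile_windows(clen, window, step)
    fm <- sub[[paste0("f_major_", pm)]]
    ft <- sub[[paste0("f_major_", pt)]]
    fe <- sub[[paste0("f_major_", pe)]]
    nm <- sub[[paste0("n_", pm)]]
    nt <- sub[[paste0("n_", pt)]]
    ne <- sub[[paste0("n_", pe)]]
    pos0 <- sub$pos - 1L  # 0-based for half-open window membership
    stats <- lapply(seq_len(nrow(win)), function(i) {
      idx <- which(pos0 >= win$start[i] & pos0 < win$end[i])
      ns <- length(idx)
      if (ns < min_sites) {
        return(c(n_sites = ns, fi_mt = NA, fi_me = NA, fi_te = NA,
                 d_mt = NA, d_me = NA, d_te = NA,
                 hp_m = NA, hp_t = NA, hp_e = NA))
      }
      c(n_sites = ns,
        fi_mt = window_fst(fm[idx], ft[idx], nm[idx], nt[idx], estimator),
        fi_me = window_fst(fm[idx], fe[idx], nm[idx], ne[idx], estimator),
        fi_te = window_fst(ft[idx], fe[idx], nt[idx], ne[idx], estimator),
        d_mt = window_dxy(fm[idx], ft[idx], dxy_mode),
        d_me = window_dxy(fm[idx], fe[idx], dxy_mode),
        d_te = window_dxy(ft[idx], fe[idx], dxy_mode),
        ## H_P uses each population's own major allele (per-site pmax):
        ## intra-population heterozygosity must be depressed wherever the
        ## population is near-fixed, whichever allele it is fixed for
        hp_m = window_hp(pmax(fm[idx], 1 - fm[idx])),
        hp_t = window_hp(pmax(ft[idx], 1 - ft[idx])),
        hp_e = window_hp(pmax(fe[idx], 1 - fe[idx])))
    })
    cbind(data.frame(chrom = ch, win[c("start", "end", "partial")]),
          as.data.frame(do.call(rbind, stats)))
  })
  out <- do.call(rbind, res)
  out <- cbind(out, lsbl(out$fi_mt, out$fi_me, out$fi_te))
  for (p in c("m", "t", "e")) {
    out[[paste0("zhp_", p)]] <- if (sum(!is.na(out[[paste0("hp_", p)]])) >= 2) {
      standardize_zhp(out[[paste0("hp_", p)]], sd_type)
    } else {
      rep(NA_real_, nrow(out))
    }
  }
  out <- out[order(out$chrom, out$start),
             c("chrom", "start", "end", "partial", "n_sites",
               "fi_mt", "fi_me", "fi_te", "lsbl_m", "lsbl_t", "lsbl_e",
               "d_mt", "d_me", "d_te", "hp_m", "hp_t", "hp_e",
               "zhp_m", "zhp_t", "zhp_e")]
  rownames(out) <- NULL
  class(out) <- c("window_stats", "data.frame")
  out
}

#' Extract top-quantile windows
#'
#' Returns the windows whose value in `column` is at or above the
#' (1 - quantile) empirical quantile of the non-NA values, sorted in
#' descending order; ties at the threshold are all included.
#'
#' @param stats A `window_stats` table from [scan_genome()].
#' @param column Statistic column (default `"lsbl_m"`).
#' @param quantile Upper tail fraction (default 0.005, i.e. the top 0.5%).
#' @return The selected subset of `stats`.
#' @export
top_windows <- function(stats, column = "lsbl_m", quantile = 0.005) {
  if (!nrow(stats)) stop("empty window table", call. = FALSE)
  x <- stats[[column]]
  if (is.null(x)) stop("no column `", column, "` in window table",
                       call. = FALSE)
  if (all(is.na(x))) stop("all values of `", column, "` are NA",
                          call. = FALSE)
  thr <- stats::quantile(x, 1 - quantile, na.rm = TRUE, names = FALSE)
  sel <- which(!is.na(x) & x >= thr)
  stats[sel[order(x[sel], decreasing = TRUE)], , drop = FALSE]
}

#' Write a window-statistics table as BED-compatible TSV
#'
#' @param stats A `window_stats` table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_window_stats <- function(stats, path) {
  write.table(stats, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
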