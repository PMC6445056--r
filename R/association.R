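#' Encode a genotype under a genetic model
#'
#' Genotypes are counts of the mutated allele (0/1/2).  The additive model
#' keeps the count; the dominant model scores carriers (1 if g >= 1); the
#' recessive model scores mutant homozygotes (1 if g == 2).  Missing values
#' propagate.
#'
#' @param g Integer vector of allele counts in {0, 1, 2} (NA allowed).
#' @param model `"additive"`, `"dominant"` or `"recessive"`.
#' @return Numeric vector of encoded genotypes.
#' @export
encode_genotype <- function(g, model = c("additive", "dominant", "recessive")) {
  model <- match.arg(model)
  bad <- !(g %in% c(0L, 1L, 2L)) & !is.na(g)
  if (any(bad)) {
    stop("genotype outside {0,1,2}: ", paste(unique(g[bad]), collapse = ", "),
         call. = FALSE)
  }
  switch(model,
         additive = as.numeric(g),
         dominant = as.numeric(g >= 1),
         recessive = as.numeric(g == 2))
}

#' Marker-phenotype linear association under one genetic model
#'
#' Ordinary least squares of the phenotype on the encoded genotype, with age
#' and sex covariates when `adjust = TRUE`.  Rows with any missing required
#' field are dropped (complete-case); `n_used` reports the retained rows.
#' The genotype coefficient's two-sided t-test gives the p-value.  A
#' genotype column that is constant after missing-data removal yields an
#' "inestimable" result (NA estimates) rather than an error; a
#' rank-deficient design among the covariates is an error naming the
#' collinear columns.
#'
#' @param table Genotype-phenotype data.frame with columns `age`, `sex`
#'   (0 = male, 1 = female), the phenotype and the marker (mutated-allele
#'   counts; which allele is counted must be declared by the table's
#'   producer, never inferred).
#' @param marker,phenotype Column names.
#' @param model Genetic model, see [encode_genotype()].
#' @param adjust Include age and sex covariates (default TRUE).
#' @return One-row data.frame: marker, phenotype, model, adjusted, beta, se,
#'   t, p, n_used, estimable.
#' @export
fit_association <- function(table, marker, phenotype,
                            model = c("additive", "dominant", "recessive"),
                            adjust = TRUE) {
  model <- match.arg(model)
  need <- c(marker, phenotype, if (adjust) c("age", "sex"))
  missing_cols <- setdiff(need, names(table))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  d <- table[need]
  d$g <- encode_genotype(table[[marker]], model)
  d <- d[complete.cases(d), , drop = FALSE]
  base <- data.frame(marker = marker, phenotype = phenotype, model = model,
                     adjusted = adjust, stringsAsFactors = FALSE)
  if (nrow(d) < (if (adjust) 4L else 2L) + 3L) {
    stop("too few complete cases (", nrow(d), ") to fit the model",
         call. = FALSE)
  }
  if (length(unique(d$g)) < 2L) {
    return(cbind(base, data.frame(beta = NA_real_, se = NA_real_,
                                  t = NA_real_, p = NA_real_,
                                  n_used = nrow(d), estimable = FALSE)))
  }
  fml <- if (adjust) {
    stats::reformulate(c("g", "age", "sex"), response = phenotype)
  } else {
    stats::reformulate("g", response = phenotype)
  }
  fit <- lm(fml, data = d)
  cf <- coef(fit)
  if (anyNA(cf)) {
    stop("rank-deficient design; collinear column(s): ",
         paste(names(cf)[is.na(cf)], collapse = ", "), call. = FALSE)
  }
  sm <- summary(fit)$coefficients
  cbind(base, data.frame(beta = sm["g", "Estimate"],
                         se = sm["g", "Std. Error"],
                         t = sm["g", "t value"],
                         p = sm["g", "Pr(>|t|)"],
                         n_used = nrow(d), estimable = TRUE))
}

#' Full association report over markers, phenotypes, models and adjustment
#'
#' One row per marker x phenotype x genetic model x adjusted/unadjusted
#' combination.  P-values are reported without multiple-testing adjustment.
#'
#' @param table Genotype-phenotype table, see [fit_association()].
#' @param markers,phenotypes Column name vectors.
#' @param models Genetic models to fit.
#' @param adjust Logical vector of adjustment settings to run.
#' @return A data.frame of stacked [fit_association()] rows.
#' @export
association_report <- function(table, markers, phenotypes,
                               models = c("additive", "dominant", "recessive"),
                               adjust = c(TRUE, FALSE)) {
  grid <- expand.grid(marker = markers, phenotype = phenotypes,
                      model = models, adjusted = adjust,
                      stringsAsFactors = FALSE)
  if (!nrow(grid)) {
    return(data.frame(marker = character(0), phenotype = character(0),
                      model = character(0), adjusted = logical(0),
                      beta = numeric(0), se = numeric(0), t = numeric(0),
                      p = numeric(0), n_used = integer(0),
                      estimable = logical(0)))
  }
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    fit_association(table, grid$marker[i], grid$phenotype[i],
                    grid$model[i], grid$adjusted[i])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
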