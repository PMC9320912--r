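#' Balanced two-way factorial ANOVA for one trait
#'
#' Fixed-effects genotype x temperature ANOVA with interaction on the
#' replicate-level values of a single trait. The closed-form decomposition
#' requires a balanced design (equal replication in every cell) and at
#' least two replicates per cell for a residual term.
#'
#' @param ds a [phenotype_dataset()].
#' @param trait name of the trait to analyse.
#' @return a data frame with rows `G`, `T`, `GxT`, `Residuals` and columns
#'   `df`, `ss`, `ms`, `F`, `p`. When every value is identical all sums of
#'   squares are zero and `F`/`p` are `NA`.
#' @examples
#' sim <- simulate_phenotypes(generator_config(seed = 1, n_genotypes = 5,
#'                                             traits = "SL"))
#' factorial_anova(sim$dataset, "SL")
#' @export
factorial_anova <- function(ds, trait) {
  stopifnot(inherits(ds, "phenotype_dataset"))
  sub <- ds$data[ds$data$trait == trait, , drop = FALSE]
  if (nrow(sub) == 0L) stop("trait '", trait, "' not in dataset",
                            call. = FALSE)
  counts <- table(sub$genotype, sub$treatment)
  if (length(unique(as.vector(counts))) != 1L) {
    stop("unbalanced design for trait '", trait,
         "': the factorial decomposition requires equal replication in ",
         "every genotype x treatment cell", call. = FALSE)
  }
  if (counts[1L] < 2L) {
    stop("need at least 2 replicates per cell for a residual term",
         call. = FALSE)
  }
  sub$genotype <- factor(sub$genotype)
  sub$treatment <- factor(sub$treatment)
  fit <- stats::aov(value ~ genotype * treatment, data = sub)
  tab <- summary(fit)[[1L]]
  out <- data.frame(
    term = c("G", "T", "GxT", "Residuals"),
    df = tab[["Df"]],
    ss = tab[["Sum Sq"]],
    ms = tab[["Mean Sq"]],
    F = c(tab[["F value"]][1:3], NA_real_),
    p = c(tab[["Pr(>F)"]][1:3], NA_real_),
    stringsAsFactors = FALSE)
  if (isTRUE(all.equal(stats::var(sub$value), 0))) {
    out$F <- NA_real_   # degenerate: no variation anywhere
    out$p <- NA_real_
    out$ss <- 0
    out$ms <- 0
  }
  out
}

#' Pearson correlation structure of trait means
#'
#' Pairwise Pearson correlations across genotypes between all traits under
#' one treatment, with two-sided p-values from
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` and counts of trait pairs
#' significant at 0.05 and 0.01 (uncorrected, matching the raw-threshold
#' screening convention).
#'
#' @param means a `trait_means` table from [replicate_means()].
#' @param treatment treatment level to correlate within.
#' @return a `trait_correlation` object: list with `r` and `p` matrices,
#'   `n` (genotype count), `n_sig_05`, `n_sig_01` (counts over distinct
#'   pairs). Zero-variance traits yield `NA` correlations with a warning.
#' @export
correlation_matrix <- function(means, treatment) {
  stopifnot(inherits(means, "trait_means"))
  m <- means_matrix(means, treatment)
  n <- nrow(m)
  if (n < 3L) stop("need at least 3 genotypes", call. = FALSE)
  sds <- apply(m, 2L, stats::sd)
  if (any(sds == 0)) {
    warning("zero-variance trait(s), correlations undefined: ",
            paste(colnames(m)[sds == 0], collapse = ", "), call. = FALSE)
  }
  r <- suppressWarnings(stats::cor(m))
  tstat <- r * sqrt(n - 2) / sqrt(pmax(0, 1 - r^2))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  diag(p) <- 0
  upper <- upper.tri(r)
  structure(list(r = r, p = p, n = n,
                 n_sig_05 = sum(p[upper] < 0.05, na.rm = TRUE),
                 n_sig_01 = sum(p[upper] < 0.01, na.rm = TRUE)),
            class = "trait_correlation")
}

#' @export
print.trait_correlation <- function(x, ...) {
  cat("Pearson correlations over", x$n, "genotypes,",
      ncol(x$r), "traits\n")
  cat("Significant pairs: ", x$n_sig_05, " at p < 0.05, ",
      x$n_sig_01, " at p < 0.01\n", sep = "")
  invisible(x)
}

#' Correlation-matrix PCA of trait means
#'
#' Principal component analysis on standardised trait values (an
#' eigendecomposition of the Pearson correlation matrix), with the
#' eigenvalue > 1 retention rule. The default scope pools genotype x
#' treatment rows (one observation per genotype per treatment), matching a
#' joint two-temperature analysis; per-treatment and resistance-coefficient
#' scopes are available since published analyses differ.
#'
#' @param means a `trait_means` table from [replicate_means()].
#' @param scope `"pooled"` (default), `"control"`, `"stress"`, or `"crc"`
#'   (rows are genotypes, values the stress/control ratios).
#' @return a `trait_pca` object: list with `eigenvalues` (descending),
#'   `percent` (percent of total variance per component, summing to 100),
#'   `cumulative`, `loadings` (trait x component eigenvector matrix), and
#'   `n_retained` (components with eigenvalue strictly greater than 1).
#' @export
pca_traits <- function(means, scope = c("pooled", "control", "stress",
                                        "crc")) {
  scope <- match.arg(scope)
  stopifnot(inherits(means, "trait_means"))
  treatments <- attr(means, "treatments")
  x <- switch(scope,
    pooled = rbind(means_matrix(means, treatments["control"]),
                   means_matrix(means, treatments["stress"])),
    control = means_matrix(means, treatments["control"]),
    stress = means_matrix(means, treatments["stress"]),
    crc = cold_resistance_coefficients(means)$crc)
  if (ncol(x) < 2L) stop("need at least 2 traits", call. = FALSE)
  if (nrow(x) < 2L) stop("need more than one observation row",
                         call. = FALSE)
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("constant trait(s), standardisation undefined: ",
         paste(colnames(x)[sds == 0], collapse = ", "), call. = FALSE)
  }
  eig <- eigen(stats::cor(x), symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  pct <- ev / sum(ev) * 100
  loadings <- eig$vectors
  dimnames(loadings) <- list(colnames(x),
                             paste0("PC", seq_along(ev)))
  structure(list(eigenvalues = ev,
                 percent = pct,
                 cumulative = cumsum(pct),
                 loadings = loadings,
                 n_retained = sum(ev > 1),
                 scope = scope),
            class = "trait_pca")
}

#' @export
print.trait_pca <- function(x, ...) {
  k <- min(5L, length(x$eigenvalues))
  cat("Correlation-matrix PCA (scope: ", x$scope, ")\n", sep = "")
  print(data.frame(eigenvalue = round(x$eigenvalues[seq_len(k)], 3),
                   percent = round(x$percent[seq_len(k)], 3),
                   cumulative = round(x$cumulative[seq_len(k)], 3)))
  cat("Components retained (eigenvalue > 1):", x$n_retained, "\n")
  invisible(x)
}
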