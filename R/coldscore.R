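#' Comprehensive cold-resistance evaluation of a genotype panel
#'
#' Fits the full multi-trait evaluation to a two-temperature phenotype
#' dataset: replicate means, cold-resistance coefficients
#' (stress/control ratio per genotype and trait), direction-aware fuzzy
#' membership values, the comprehensive per-genotype score `U_j` (mean
#' membership over traits), per-trait rate change, genetic coefficients of
#' variation under each treatment, and a Ward hierarchical classification
#' of the panel into `k` ordered resistance types.
#'
#' @param data a [phenotype_dataset()], or a tidy data frame / CSV path
#'   accepted by it.
#' @param registry trait registry; defaults to the dataset's own.
#' @param traits optional character vector restricting the comprehensive
#'   score to a trait subset (all measured traits by default).
#' @param k number of resistance types to cut the dendrogram into.
#' @param linkage,metric clustering options, see [classify_genotypes()].
#' @param sd_type standard-deviation convention for [genetic_cv()].
#' @param control,stress treatment labels, used when `data` is not already
#'   a `phenotype_dataset`.
#' @return an object of class `coldscore`: list with elements `means`,
#'   `crc`, `membership`, `rc` (genotype x trait rate-change matrix),
#'   `rc_summary` (per trait: mean of per-genotype rate changes and the
#'   rate change of the grand means, which differ slightly), `cvg`
#'   (per trait x treatment genetic CVs), `u_cv` (CV of the `U_j` scores,
#'   percent), `types` (a [classify_genotypes()] result), `registry`, and
#'   `call`.
#' @examples
#' sim <- simulate_phenotypes(generator_config(seed = 1, n_genotypes = 10))
#' fit <- coldscore(sim$dataset, k = 4)
#' fit
#' head(sort(coef(fit), decreasing = TRUE))
#' @export
coldscore <- function(data, registry = NULL, traits = NULL, k = 4L,
                      linkage = "ward", metric = "euclidean",
                      sd_type = "sample",
                      control = "CK", stress = "LT") {
  cl <- match.call()
  if (is.character(data) && length(data) == 1L) {
    data <- load_phenotypes(data,
                            registry = if (is.null(registry))
                              default_trait_registry() else registry,
                            control = control, stress = stress)
  } else if (!inherits(data, "phenotype_dataset")) {
    data <- phenotype_dataset(data,
                              registry = if (is.null(registry))
                                default_trait_registry() else registry,
                              control = control, stress = stress)
  }
  if (is.null(registry)) registry <- data$registry
  if (!is.null(traits)) {
    unknown <- setdiff(traits, data$traits)
    if (length(unknown) > 0L) {
      stop("trait(s) not in dataset: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    data$data <- data$data[data$data$trait %in% traits, , drop = FALSE]
    data$traits <- sort(traits)
  }

  means <- replicate_means(data)
  crc <- cold_resistance_coefficients(means)
  mm <- membership_values(crc, registry)
  rc <- (crc$crc - 1) * 100                    # CRC = 1 + RC/100 cell-wise

  treatments <- data$treatments
  ck <- means_matrix(means, treatments["control"])
  lt <- means_matrix(means, treatments["stress"])
  rc_summary <- data.frame(
    trait = colnames(rc),
    mean_rc = colMeans(rc),
    rc_of_means = rate_change(colMeans(lt), colMeans(ck)),
    row.names = NULL, stringsAsFactors = FALSE)

  cvg <- data.frame(
    trait = rep(colnames(ck), 2L),
    treatment = rep(unname(treatments[c("control", "stress")]),
                    each = ncol(ck)),
    cvg = c(apply(ck, 2L, genetic_cv, sd_type = sd_type),
            apply(lt, 2L, genetic_cv, sd_type = sd_type)),
    row.names = NULL, stringsAsFactors = FALSE)

  types <- classify_genotypes(mm, k = k, linkage = linkage, metric = metric)

  structure(list(
    means = means,
    crc = crc,
    membership = mm,
    rc = rc,
    rc_summary = rc_summary,
    cvg = cvg,
    u_cv = genetic_cv(mm$u_j, sd_type = sd_type),
    types = types,
    registry = registry,
    treatments = treatments,
    call = cl
  ), class = "coldscore")
}

#' @export
print.coldscore <- function(x, ...) {
  cat("Multi-trait cold-resistance evaluation\n")
  cat("  ", nrow(x$crc$crc), " genotypes, ", x$membership$n_traits,
      " traits (", x$treatments["control"], " control vs ",
      x$treatments["stress"], " stress)\n", sep = "")
  cat("  U_j range: [", format(min(x$membership$u_j), digits = 3), ", ",
      format(max(x$membership$u_j), digits = 3), "], CV ",
      format(x$u_cv, digits = 3), "%\n", sep = "")
  cat("  Resistance types:",
      paste(sprintf("%s (n=%d)", x$types$summary$type,
                    x$types$summary$n_genotypes), collapse = ", "), "\n")
  invisible(x)
}

#' @export
#' @describeIn coldscore comprehensive resistance scores `U_j`, named by
#'   genotype.
coef.coldscore <- function(object, ...) {
  object$membership$u_j
}

#' @export
summary.coldscore <- function(object, ...) {
  ranking <- data.frame(
    genotype = names(object$membership$u_j),
    u_j = unname(object$membership$u_j),
    type = as.character(object$types$type[names(object$membership$u_j)]),
    stringsAsFactors = FALSE)
  ranking <- ranking[order(-ranking$u_j), ]
  rownames(ranking) <- NULL
  out <- list(ranking = ranking,
              u_cv = object$u_cv,
              rc_summary = object$rc_summary,
              cvg = object$cvg,
              types = object$types$summary)
  class(out) <- "summary.coldscore"
  out
}

#' @export
print.summary.coldscore <- function(x, ...) {
  cat("Genotype ranking by comprehensive score U_j",
      " (CV ", format(x$u_cv, digits = 3), "%):\n", sep = "")
  print(utils::head(x$ranking, 10L), digits = 3)
  if (nrow(x$ranking) > 10L) cat("  ... ", nrow(x$ranking) - 10L,
                                 " more genotypes\n", sep = "")
  cat("\nResistance types:\n")
  print(x$types, digits = 3)
  cat("\nLargest mean rate changes under stress:\n")
  ord <- order(-abs(x$rc_summary$mean_rc))
  print(utils::head(x$rc_summary[ord, ], 5L), digits = 3)
  invisible(x)
}

#' @export
plot.coldscore <- function(x, which = c("dendrogram", "scores"), ...) {
  which <- match.arg(which)
  if (which == "dendrogram") {
    graphics::plot(x$types$hclust,
                   main = "Genotype classification on membership profiles",
                   xlab = "", sub = "", ...)
  } else {
    u <- sort(x$membership$u_j, decreasing = TRUE)
    graphics::barplot(u, las = 2, ylab = "Comprehensive score U_j",
                      main = "Cold-resistance ranking",
                      cex.names = 0.6, ...)
  }
  invisible(x)
}
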