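#' Classify genotypes into ordered resistance types
#'
#' Agglomeratively clusters genotypes on their membership-value profiles
#' (rows of `U_ij`), cuts the tree into `k` clusters, and orders the
#' clusters by descending mean comprehensive score so that type I is the
#' most resistant group and type `k` the most sensitive.
#'
#' Ward's criterion on Euclidean distances (the `"ward.D2"` method of
#' [stats::hclust()], which operates on untransformed distances) is the
#' default; alternative linkages and metrics are exposed for sensitivity
#' analysis. Clusters with identical mean scores are ordered by the lowest
#' genotype index they contain, for determinism.
#'
#' @param mm a `membership_matrix` from [membership_values()].
#' @param k number of resistance types (default 4); `1 <= k <=` number of
#'   genotypes.
#' @param linkage one of `"ward"`, `"average"`, `"complete"`, `"single"`.
#' @param metric one of `"euclidean"`, `"manhattan"`, `"correlation"`
#'   (distance `1 - r` between profile rows).
#' @return a `cold_types` object: list with `hclust` (the dendrogram),
#'   `cluster` (integer cluster ids), `type` (ordered factor, levels
#'   `"I"` strongest downward), `u_j`, and `summary` (per-type genotype
#'   count and score range).
#' @examples
#' sim <- simulate_phenotypes(generator_config(seed = 1, n_genotypes = 12))
#' mm <- membership_values(
#'   cold_resistance_coefficients(replicate_means(sim$dataset)),
#'   sim$config$registry)
#' classify_genotypes(mm, k = 4)
#' @export
classify_genotypes <- function(mm, k = 4L,
                               linkage = c("ward", "average", "complete",
                                           "single"),
                               metric = c("euclidean", "manhattan",
                                          "correlation")) {
  stopifnot(inherits(mm, "membership_matrix"))
  linkage <- match.arg(linkage)
  metric <- match.arg(metric)
  n <- nrow(mm$u)
  if (k < 1L) stop("k must be at least 1", call. = FALSE)
  if (k > n) {
    stop("k (", k, ") exceeds the number of genotypes (", n, ")",
         call. = FALSE)
  }
  d <- switch(metric,
              euclidean = stats::dist(mm$u, method = "euclidean"),
              manhattan = stats::dist(mm$u, method = "manhattan"),
              correlation = stats::as.dist(1 - stats::cor(t(mm$u))))
  method <- if (linkage == "ward") "ward.D2" else linkage
  hc <- stats::hclust(d, method = method)
  cluster <- stats::cutree(hc, k = k)

  cl_mean <- tapply(mm$u_j, cluster, mean)
  cl_first <- tapply(seq_len(n), cluster, min)
  ord <- order(-cl_mean, cl_first)            # strongest first; tie -> lower index
  rank_of <- integer(length(ord))
  rank_of[as.integer(names(cl_mean))[ord]] <- seq_along(ord)
  type_levels <- as.character(utils::as.roman(seq_len(k)))
  type <- factor(type_levels[rank_of[cluster]], levels = type_levels,
                 ordered = TRUE)
  names(type) <- rownames(mm$u)

  summ <- data.frame(
    type = type_levels,
    n_genotypes = as.integer(table(type)[type_levels]),
    u_min = tapply(mm$u_j, type, min)[type_levels],
    u_max = tapply(mm$u_j, type, max)[type_levels],
    u_mean = tapply(mm$u_j, type, mean)[type_levels],
    row.names = NULL, stringsAsFactors = FALSE)

  structure(list(hclust = hc, cluster = cluster, type = type,
                 u_j = mm$u_j, k = k, linkage = linkage, metric = metric,
                 summary = summ),
            class = "cold_types")
}

#' @export
print.cold_types <- function(x, ...) {
  cat("Resistance types (", x$k, " clusters, ", x$linkage, " linkage, ",
      x$metric, " distance):\n", sep = "")
  print(x$summary, digits = 3)
  invisible(x)
}

#' Export the classification dendrogram in Newick format
#'
#' @param ct a `cold_types` object.
#' @param path optional file path; when `NULL` the Newick string is
#'   returned.
#' @return the Newick string, invisibly when written to `path`.
#' @export
dendrogram_newick <- function(ct, path = NULL) {
  stopifnot(inherits(ct, "cold_types"))
  hc <- ct$hclust
  build <- function(i) {
    if (i < 0) return(hc$labels[-i])
    left <- build(hc$merge[i, 1L])
    right <- build(hc$merge[i, 2L])
    h <- hc$height[i]
    child_h <- function(j) if (j < 0) 0 else hc$height[j]
    paste0("(", left, ":", format(h - child_h(hc$merge[i, 1L])), ",",
           right, ":", format(h - child_h(hc$merge[i, 2L])), ")")
  }
  nwk <- paste0(build(nrow(hc$merge)), ";")
  if (is.null(path)) return(nwk)
  writeLines(nwk, path)
  invisible(nwk)
}
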