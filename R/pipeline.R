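#' Run the full evaluation pipeline and write a report bundle
#'
#' Orchestrates the end-to-end analysis — evaluation ([coldscore()]),
#' per-trait factorial ANOVA, correlation screening, PCA, classification,
#' and optional qPCR fold changes — and writes every tabular product as CSV
#' plus a single `report.json` summary to `out_dir`. Outputs are
#' deterministic functions of the inputs and options; running twice on
#' identical inputs reproduces the bundle byte for byte. Each written file
#' is recorded in the report with its MD5 checksum.
#'
#' @param phenotypes a [phenotype_dataset()], tidy data frame, or CSV path.
#' @param out_dir output directory (created if absent).
#' @param registry trait registry; default registry when `NULL`.
#' @param qpcr optional tidy Ct table (data frame or CSV path) with columns
#'   `gene,genotype,treatment,replicate,ct`.
#' @param reference_gene reference gene for the qPCR stage (required when
#'   `qpcr` is given).
#' @param k,linkage,metric classification options.
#' @param pca_scope PCA observation scope, see [pca_traits()].
#' @param sd_type standard-deviation convention for [genetic_cv()].
#' @param control,stress treatment labels.
#' @return the report list, invisibly; files under `out_dir`:
#'   `crc.csv`, `membership.csv` (wide `U_ij`), `scores.csv`,
#'   `rc_summary.csv`, `cvg.csv`, `anova.csv`, `corr_r_<treatment>.csv`,
#'   `corr_p_<treatment>.csv`, `pca_eigen.csv`, `pca_loadings.csv`,
#'   `types.csv`, `linkage.csv`, optionally `qpcr_fold.csv`, and
#'   `report.json`.
#' @export
run_pipeline <- function(phenotypes, out_dir,
                         registry = NULL, qpcr = NULL,
                         reference_gene = NULL,
                         k = 4L, linkage = "ward", metric = "euclidean",
                         pca_scope = "pooled", sd_type = "sample",
                         control = "CK", stress = "LT") {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  fit <- coldscore(phenotypes, registry = registry, k = k,
                   linkage = linkage, metric = metric, sd_type = sd_type,
                   control = control, stress = stress)
  ds_traits <- colnames(fit$crc$crc)

  ds <- if (inherits(phenotypes, "phenotype_dataset")) phenotypes else
    phenotype_dataset(if (is.character(phenotypes))
      utils::read.csv(phenotypes, stringsAsFactors = FALSE) else phenotypes,
      registry = fit$registry, control = control, stress = stress)
  # per-trait factorial ANOVA needs within-cell replication; single-
  # replicate cohorts (e.g. tables of published means) skip the stage
  reps <- table(ds$data$genotype, ds$data$treatment, ds$data$trait)
  anova_tabs <- NULL
  if (min(reps) >= 2L) {
    anova_tabs <- do.call(rbind, lapply(ds_traits, function(tr) {
      cbind(trait = tr, factorial_anova(ds, tr))
    }))
  }

  treatments <- fit$treatments
  corr <- lapply(treatments, function(tr) correlation_matrix(fit$means, tr))
  pca <- pca_traits(fit$means, scope = pca_scope)

  out <- function(f) file.path(out_dir, f)
  wcsv <- function(x, f, rn = FALSE) {
    utils::write.csv(x, out(f), row.names = rn)
    f
  }
  files <- c(
    wcsv(fit$crc$crc, "crc.csv", rn = TRUE),
    wcsv(fit$membership$u, "membership.csv", rn = TRUE),
    wcsv(data.frame(genotype = names(fit$membership$u_j),
                    u_j = unname(fit$membership$u_j),
                    type = as.character(fit$types$type)),
         "scores.csv"),
    wcsv(fit$rc_summary, "rc_summary.csv"),
    wcsv(fit$cvg, "cvg.csv"),
    wcsv(corr[["control"]]$r, paste0("corr_r_", treatments["control"],
                                     ".csv"), rn = TRUE),
    wcsv(corr[["control"]]$p, paste0("corr_p_", treatments["control"],
                                     ".csv"), rn = TRUE),
    wcsv(corr[["stress"]]$r, paste0("corr_r_", treatments["stress"],
                                    ".csv"), rn = TRUE),
    wcsv(corr[["stress"]]$p, paste0("corr_p_", treatments["stress"],
                                    ".csv"), rn = TRUE),
    wcsv(data.frame(component = seq_along(pca$eigenvalues),
                    eigenvalue = pca$eigenvalues,
                    percent = pca$percent,
                    cumulative = pca$cumulative),
         "pca_eigen.csv"),
    wcsv(pca$loadings, "pca_loadings.csv", rn = TRUE),
    wcsv(data.frame(genotype = names(fit$types$type),
                    cluster = unname(fit$types$cluster),
                    type = as.character(fit$types$type),
                    u_j = unname(fit$membership$u_j)),
         "types.csv"),
    wcsv(cbind(as.data.frame(fit$types$hclust$merge),
               height = fit$types$hclust$height),
         "linkage.csv"))
  if (!is.null(anova_tabs)) {
    files <- c(files, wcsv(anova_tabs, "anova.csv"))
  }

  qpcr_res <- NULL
  if (!is.null(qpcr)) {
    if (is.null(reference_gene)) {
      stop("reference_gene is required when a qPCR table is supplied",
           call. = FALSE)
    }
    ct <- if (is.character(qpcr)) utils::read.csv(qpcr,
                                                  stringsAsFactors = FALSE)
          else qpcr
    qpcr_res <- relative_expression(ct, reference_gene,
                                    control = control, stress = stress)
    files <- c(files, wcsv(qpcr_res, "qpcr_fold.csv"))
  }

  report <- list(
    n_genotypes = nrow(fit$crc$crc),
    n_traits = fit$membership$n_traits,
    treatments = as.list(treatments),
    rc_summary = fit$rc_summary,
    cvg = fit$cvg,
    u_j = as.list(fit$membership$u_j),
    u_cv = fit$u_cv,
    types = fit$types$summary,
    type_assignments = as.list(stats::setNames(
      as.character(fit$types$type), names(fit$types$type))),
    anova = anova_tabs,
    correlation = list(
      control = list(n_sig_05 = corr[["control"]]$n_sig_05,
                     n_sig_01 = corr[["control"]]$n_sig_01),
      stress = list(n_sig_05 = corr[["stress"]]$n_sig_05,
                    n_sig_01 = corr[["stress"]]$n_sig_01),
      pooled_n_sig_05 = corr[["control"]]$n_sig_05 +
        corr[["stress"]]$n_sig_05),
    pca = list(eigenvalues = pca$eigenvalues, percent = pca$percent,
               cumulative = pca$cumulative, n_retained = pca$n_retained,
               scope = pca_scope),
    qpcr = qpcr_res,
    options = list(k = k, linkage = linkage, metric = metric,
                   pca_scope = pca_scope, sd_type = sd_type),
    files = as.list(stats::setNames(
      unname(tools::md5sum(file.path(out_dir, files))), files))
  )
  jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(report)
}
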