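#' Derived seedling traits
#'
#' Scalar helpers for the four derived traits measured in two-temperature
#' cold-screening trials. All are vectorised over their arguments.
#'
#' * `root_shoot_ratio()`: root fresh weight over seedling fresh weight.
#' * `membrane_stability_index()`: `100 * (1 - c1/c2)` from paired
#'   electrolyte-leakage conductivities, `c1` after 40 degC incubation and
#'   `c2` after boiling; 100 means fully intact membranes, 0 full leakage.
#' * `water_use_efficiency()`: net photosynthetic rate over transpiration
#'   rate, `Pn/Tr`.
#' * `rubisco_proxy()`: `Pn/Ci`, a carboxylation-efficiency surrogate from
#'   gas exchange.
#'
#' @param rfw,sfw root and seedling fresh weight (g); `sfw > 0`.
#' @param c1,c2 conductivities in the same units; `0 <= c1 <= c2`, `c2 > 0`.
#' @param pn net photosynthetic rate (uM m-2 s-1).
#' @param tr transpiration rate; must be positive.
#' @param ci intercellular CO2 concentration; must be positive.
#' @return numeric vector of the derived trait.
#' @examples
#' root_shoot_ratio(1.38, 4.6)
#' membrane_stability_index(1, 4)   # 75% stability
#' water_use_efficiency(5.52, 2.4)
#' rubisco_proxy(5.52, 240)
#' @name derived_traits
NULL

#' @rdname derived_traits
#' @export
root_shoot_ratio <- function(rfw, sfw) {
  if (any(sfw <= 0)) {
    stop("seedling fresh weight must be positive", call. = FALSE)
  }
  rfw / sfw
}

#' @rdname derived_traits
#' @export
membrane_stability_index <- function(c1, c2) {
  if (any(c2 <= 0)) {
    stop("boiled-sample conductivity c2 must be positive", call. = FALSE)
  }
  if (any(c1 < 0) || any(c1 > c2)) {
    stop("conductivity c1 must satisfy 0 <= c1 <= c2", call. = FALSE)
  }
  (1 - c1 / c2) * 100
}

#' @rdname derived_traits
#' @export
water_use_efficiency <- function(pn, tr) {
  if (any(tr <= 0)) {
    stop("transpiration rate must be positive", call. = FALSE)
  }
  pn / tr
}

#' @rdname derived_traits
#' @export
rubisco_proxy <- function(pn, ci) {
  if (any(ci <= 0)) {
    stop("intercellular CO2 concentration must be positive", call. = FALSE)
  }
  pn / ci
}

#' Relative expression by the 2^-ddCt method
#'
#' Computes the Livak fold change of a target gene under a stress condition
#' relative to a control condition, each normalised to a reference gene.
#' Replicate Ct values are averaged per condition before the double
#' difference is taken:
#' `ddCt = (Ct_target - Ct_ref)_stress - (Ct_target - Ct_ref)_control`,
#' fold change `2^-ddCt`. A condition used as its own calibrator therefore
#' has fold change exactly 1.
#'
#' @param target_stress,ref_stress,target_control,ref_control numeric
#'   vectors of replicate Ct values for the target and reference gene under
#'   the stress and control conditions.
#' @return a list with elements `fold` (the 2^-ddCt fold change), `ddct`,
#'   and `per_replicate` (fold changes recomputed per stress replicate
#'   against the mean control calibrator, for dispersion bars; `NULL` when
#'   the target/reference replicate counts differ).
#' @examples
#' delta_delta_ct(22, 20, 25, 20)$fold  # one gene, 8-fold induction
#' @export
delta_delta_ct <- function(target_stress, ref_stress,
                           target_control, ref_control) {
  vals <- list(target_stress = target_stress, ref_stress = ref_stress,
               target_control = target_control, ref_control = ref_control)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (length(v) == 0L || !all(is.finite(v))) {
      stop("Ct values for ", nm, " must be a non-empty finite vector",
           call. = FALSE)
    }
  }
  dct_stress <- mean(target_stress) - mean(ref_stress)
  dct_control <- mean(target_control) - mean(ref_control)
  ddct <- dct_stress - dct_control
  per_rep <- NULL
  if (length(target_stress) == length(ref_stress)) {
    per_rep <- 2^(-((target_stress - ref_stress) - dct_control))
  }
  list(fold = 2^(-ddct), ddct = ddct, per_replicate = per_rep)
}

#' Relative expression for a tidy Ct table
#'
#' Applies [delta_delta_ct()] to every (gene, genotype) pair of a tidy qPCR
#' table with columns `gene,genotype,treatment,replicate,ct`, using one
#' named reference gene and the declared control/stress labels.
#'
#' @param ct data frame with columns `gene`, `genotype`, `treatment`,
#'   `replicate`, `ct`.
#' @param reference_gene name of the internal reference gene; must be
#'   present for every genotype x treatment condition.
#' @param control,stress treatment labels (defaults `"CK"`, `"LT"`).
#' @return data frame with one row per target gene x genotype: columns
#'   `gene`, `genotype`, `ddct`, `fold`, `fold_sd` (standard deviation of
#'   per-replicate fold changes, `NA` when unavailable).
#' @export
relative_expression <- function(ct, reference_gene,
                                control = "CK", stress = "LT") {
  required <- c("gene", "genotype", "treatment", "replicate", "ct")
  missing_cols <- setdiff(required, names(ct))
  if (length(missing_cols) > 0L) {
    stop("Ct table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!reference_gene %in% ct$gene) {
    stop("reference gene '", reference_gene, "' not found in Ct table",
         call. = FALSE)
  }
  targets <- setdiff(unique(ct$gene), reference_gene)
  genotypes <- unique(ct$genotype)
  pick <- function(g, geno, treat) {
    v <- ct$ct[ct$gene == g & ct$genotype == geno & ct$treatment == treat]
    if (length(v) == 0L) {
      stop("no Ct values for gene '", g, "', genotype '", geno,
           "', treatment '", treat, "'", call. = FALSE)
    }
    v
  }
  out <- do.call(rbind, lapply(targets, function(g) {
    do.call(rbind, lapply(genotypes, function(geno) {
      res <- delta_delta_ct(pick(g, geno, stress),
                            pick(reference_gene, geno, stress),
                            pick(g, geno, control),
                            pick(reference_gene, geno, control))
      data.frame(gene = g, genotype = geno, ddct = res$ddct,
                 fold = res$fold,
                 fold_sd = if (is.null(res$per_replicate)) NA_real_
                           else stats::sd(res$per_replicate),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}
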