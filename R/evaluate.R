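#' Rate change of a trait under stress
#'
#' Percent change of the stress-treatment mean relative to the control
#' mean, `(mean_lt - mean_ck)/mean_ck * 100`. Vectorised.
#'
#' @param mean_lt trait mean under the stress treatment.
#' @param mean_ck trait mean under the control treatment; must be positive.
#' @return percent rate change.
#' @examples
#' rate_change(5, 10)  # -50
#' @export
rate_change <- function(mean_lt, mean_ck) {
  if (any(mean_ck <= 0)) {
    stop("control mean must be positive", call. = FALSE)
  }
  (mean_lt - mean_ck) / mean_ck * 100
}

#' Cold-resistance coefficients
#'
#' For every trait i and genotype j, the ratio of the genotype's
#' stress-treatment mean to its control mean, `CRC_ij = T_LT / T_CK`,
#' together with the per-trait extrema used by the membership transform.
#' The identity `CRC = 1 + RC/100` holds cell-wise with the rate change.
#'
#' @param means a `trait_means` table from [replicate_means()].
#' @return a `crc_matrix` object: list with `crc` (genotype x trait
#'   matrix), `trait_min`, `trait_max` (named per-trait extrema over
#'   genotypes), and the treatment roles.
#' @export
cold_resistance_coefficients <- function(means) {
  stopifnot(inherits(means, "trait_means"))
  treatments <- attr(means, "treatments")
  ck <- means_matrix(means, treatments["control"])
  lt <- means_matrix(means, treatments["stress"])
  if (anyNA(ck) || anyNA(lt)) {
    stop("means table has missing (genotype, treatment, trait) cells",
         call. = FALSE)
  }
  if (any(ck <= 0)) {
    bad <- which(ck <= 0, arr.ind = TRUE)[1L, ]
    stop("control mean must be positive; offending genotype '",
         rownames(ck)[bad[1L]], "', trait '", colnames(ck)[bad[2L]], "'",
         call. = FALSE)
  }
  crc <- lt / ck
  structure(list(crc = crc,
                 trait_min = apply(crc, 2L, min),
                 trait_max = apply(crc, 2L, max),
                 treatments = treatments),
            class = "crc_matrix")
}

#' @export
print.crc_matrix <- function(x, ...) {
  cat("Cold-resistance coefficients:", nrow(x$crc), "genotypes x",
      ncol(x$crc), "traits\n")
  cat("Per-trait range: [", format(min(x$trait_min), digits = 3), ",",
      format(max(x$trait_max), digits = 3), "]\n")
  invisible(x)
}

#' Fuzzy membership values and comprehensive resistance score
#'
#' Min-max normalises each trait's cold-resistance coefficients across
#' genotypes to the unit interval. For traits positively associated with
#' resistance (`direction = +1`) the membership is
#' `(CRC - min)/(max - min)`; for damage-indicating traits
#' (`direction = -1`) it is one minus that quantity, so that larger
#' membership always means more resistant. The comprehensive score `U_j`
#' of a genotype is the unweighted mean of its memberships over traits.
#'
#' A trait whose coefficients are constant across genotypes carries no
#' ranking information; its memberships are set to 0.5 with a warning so
#' it does not pull `U_j` toward either extreme.
#'
#' @param crc a `crc_matrix` from [cold_resistance_coefficients()].
#' @param registry trait registry supplying `direction` for every trait in
#'   `crc`.
#' @return a `membership_matrix` object: list with `u` (genotype x trait
#'   membership matrix), `u_j` (named per-genotype score vector),
#'   `n_traits`, and `degenerate` (names of constant traits, if any).
#' @export
membership_values <- function(crc, registry = default_trait_registry()) {
  stopifnot(inherits(crc, "crc_matrix"))
  validate_registry(registry)
  traits <- colnames(crc$crc)
  missing_traits <- setdiff(traits, registry$name)
  if (length(missing_traits) > 0L) {
    stop("trait(s) missing from registry: ",
         paste(missing_traits, collapse = ", "), call. = FALSE)
  }
  direction <- registry$direction[match(traits, registry$name)]
  rng <- crc$trait_max[traits] - crc$trait_min[traits]
  degenerate <- traits[rng == 0]
  u <- crc$crc
  for (i in seq_along(traits)) {
    if (rng[i] == 0) {
      u[, i] <- 0.5
      next
    }
    norm <- (crc$crc[, i] - crc$trait_min[traits[i]]) / rng[i]
    u[, i] <- if (direction[i] > 0) norm else 1 - norm
  }
  if (length(degenerate) > 0L) {
    warning("trait(s) with constant resistance coefficients set to ",
            "membership 0.5: ", paste(degenerate, collapse = ", "),
            call. = FALSE)
  }
  structure(list(u = u,
                 u_j = rowMeans(u),
                 n_traits = length(traits),
                 degenerate = degenerate),
            class = "membership_matrix")
}

#' @export
print.membership_matrix <- function(x, ...) {
  cat("Membership matrix:", nrow(x$u), "genotypes x", x$n_traits,
      "traits\n")
  cat("Comprehensive score U_j range: [",
      format(min(x$u_j), digits = 3), ",",
      format(max(x$u_j), digits = 3), "]\n")
  invisible(x)
}

#' Genetic coefficient of variation
#'
#' Coefficient of variation of one trait's genotype means within a single
#' treatment, `SD / mean * 100`. The default uses the sample (n-1)
#' standard deviation, treating the panel as a sample of germplasm; set
#' `sd_type = "population"` for the n-denominator convention.
#'
#' @param values numeric vector, one genotype mean per genotype (length
#'   >= 2, non-zero mean).
#' @param sd_type `"sample"` (default) or `"population"`.
#' @return the coefficient of variation in percent.
#' @examples
#' genetic_cv(c(1, 2, 3))  # 50
#' @export
genetic_cv <- function(values, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  if (length(values) < 2L) {
    stop("need at least two genotypes", call. = FALSE)
  }
  m <- mean(values)
  if (m == 0) stop("mean is zero; CV undefined", call. = FALSE)
  s <- stats::sd(values)
  if (sd_type == "population") {
    s <- s * sqrt((length(values) - 1) / length(values))
  }
  s / m * 100
}
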