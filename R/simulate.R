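#' Configuration for the synthetic cohort generator
#'
#' Bundles the design and calibration of a simulated two-temperature
#' screening trial: cohort size, replication, per-trait control baselines,
#' per-trait cold-effect multipliers, per-trait genotype-effect dispersions,
#' and the two noise scales. Defaults reproduce the reference study design:
#' 39 genotypes x 29 traits x 2 treatments x 3 replicates, cold-effect
#' multipliers `1 + cold_effect_pct/100` (e.g. 0.514 for seedling length,
#' 3.219 for MDA, 4.118 for proline) and genotype-effect CVs equal to the
#' published control-condition genetic coefficients of variation.
#'
#' @param seed integer seed; the generator is fully deterministic given the
#'   configuration and seed.
#' @param n_genotypes number of genotypes (default 39, minimum 2).
#' @param n_replicates replicates per genotype x treatment (default 3).
#' @param registry calibrated trait registry: must carry columns `name`,
#'   `direction`, `cold_effect_pct`, `cvg_ck`, `baseline_ck` (see
#'   [default_trait_registry()] with `calibrated = TRUE`).
#' @param traits optional character vector restricting the simulation to a
#'   subset of registry traits.
#' @param interaction_cv coefficient of variation of the genotype x
#'   temperature interaction multiplier (default 0.05). The interaction is
#'   tied monotonically to a latent per-genotype resistance score, so more
#'   resistant genotypes respond less on damage traits and hold their values
#'   better on resistance-supporting traits.
#' @param residual_cv replicate-level residual CV (default 0.03).
#' @param control,stress treatment labels.
#' @return a `generator_config` list.
#' @export
generator_config <- function(seed,
                             n_genotypes = 39L,
                             n_replicates = 3L,
                             registry = default_trait_registry(calibrated = TRUE),
                             traits = NULL,
                             interaction_cv = 0.05,
                             residual_cv = 0.03,
                             control = "CK", stress = "LT") {
  needed <- c("name", "direction", "cold_effect_pct", "cvg_ck", "baseline_ck")
  missing_cols <- setdiff(needed, names(registry))
  if (length(missing_cols) > 0L) {
    stop("registry lacks calibration column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!is.null(traits)) {
    unknown <- setdiff(traits, registry$name)
    if (length(unknown) > 0L) {
      stop("trait(s) not in registry: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    registry <- registry[registry$name %in% traits, , drop = FALSE]
  }
  if (n_genotypes < 2L) stop("n_genotypes must be >= 2", call. = FALSE)
  if (n_replicates < 1L) stop("n_replicates must be >= 1", call. = FALSE)
  if (interaction_cv < 0 || residual_cv < 0 || any(registry$cvg_ck < 0)) {
    stop("coefficients of variation must be non-negative", call. = FALSE)
  }
  multipliers <- 1 + registry$cold_effect_pct / 100
  if (any(multipliers <= 0)) {
    stop("cold-effect multipliers must be positive", call. = FALSE)
  }
  if (any(registry$baseline_ck <= 0)) {
    stop("baselines must be positive", call. = FALSE)
  }
  structure(list(
    seed = as.integer(seed),
    n_genotypes = as.integer(n_genotypes),
    n_replicates = as.integer(n_replicates),
    registry = registry,
    interaction_cv = interaction_cv,
    residual_cv = residual_cv,
    control = control, stress = stress
  ), class = "generator_config")
}

# log-normal sdlog giving a multiplicative factor with mean 1 and the
# requested coefficient of variation
lognorm_sdlog <- function(cv) sqrt(log1p(cv^2))

#' Simulate a two-temperature phenotype cohort
#'
#' Draws a replicate-level phenotype table under a multiplicative log-normal
#' model: `value = baseline_i * G(g,i) * [m_i * I(g,i)]^(stress) * eps`,
#' where `G` is a mean-one log-normal genotype effect at the configured
#' per-trait CV, `m_i` the cold-effect multiplier, `I` a mean-one
#' interaction multiplier `exp(d_i * sigma_I * z_g - sigma_I^2/2)` driven by
#' a latent resistance score `z_g` (signed by the trait direction `d_i`, so
#' high-`z` genotypes are pulled toward the favourable end on every trait),
#' and `eps` a mean-one log-normal replicate residual. The latent scores are
#' drawn normal and standardised to exact mean zero and unit variance across
#' the cohort, so the configured multipliers are realised cohort-level
#' effects rather than expectations, and per-trait mean rate change tracks
#' `100 * (m_i - 1)` closely at any cohort size.
#'
#' Draws occur in a fixed order — genotype effects trait by trait, then the
#' latent scores, then residuals in the row order of the returned table —
#' so a seed identifies one cohort exactly.
#'
#' @param cfg a [generator_config()].
#' @return a list with elements `dataset` (a validated
#'   [phenotype_dataset()]), `truth` (list: `latent` named score vector,
#'   `genotype_effects` and `interaction` genotype x trait matrices), and
#'   `config`.
#' @examples
#' sim <- simulate_phenotypes(generator_config(seed = 1, n_genotypes = 5,
#'                                             traits = c("SL", "MDA")))
#' head(sim$dataset$data)
#' @export
simulate_phenotypes <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  reg <- cfg$registry
  n_g <- cfg$n_genotypes
  n_t <- nrow(reg)
  n_r <- cfg$n_replicates
  genotypes <- sprintf("G%02d", seq_len(n_g))
  set.seed(cfg$seed)

  sd_g <- lognorm_sdlog(reg$cvg_ck / 100)
  g_eff <- matrix(1, n_g, n_t, dimnames = list(genotypes, reg$name))
  for (i in seq_len(n_t)) {
    g_eff[, i] <- exp(stats::rnorm(n_g, 0, sd_g[i]) - sd_g[i]^2 / 2)
  }
  # the latent gradient is a cohort-level design property: standardise the
  # realised scores so the configured multipliers are exact cohort effects
  z <- stats::rnorm(n_g)
  z <- (z - mean(z)) / stats::sd(z)
  names(z) <- genotypes
  sd_i <- lognorm_sdlog(cfg$interaction_cv)
  inter <- exp(outer(z, reg$direction * sd_i) - sd_i^2 / 2)
  dimnames(inter) <- list(genotypes, reg$name)

  grid <- expand.grid(replicate = seq_len(n_r),
                      treatment = c(cfg$control, cfg$stress),
                      genotype = genotypes,
                      trait = reg$name,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  idx_t <- match(grid$trait, reg$name)
  idx_g <- match(grid$genotype, genotypes)
  stressed <- grid$treatment == cfg$stress
  m <- 1 + reg$cold_effect_pct / 100
  mu <- reg$baseline_ck[idx_t] * g_eff[cbind(idx_g, idx_t)] *
    ifelse(stressed, m[idx_t] * inter[cbind(idx_g, idx_t)], 1)
  sd_e <- lognorm_sdlog(cfg$residual_cv)
  eps <- exp(stats::rnorm(nrow(grid), 0, sd_e) - sd_e^2 / 2)
  grid$value <- mu * eps

  ds <- phenotype_dataset(grid[, c("genotype", "treatment", "replicate",
                                   "trait", "value")],
                          registry = reg,
                          control = cfg$control, stress = cfg$stress)
  list(dataset = ds,
       truth = list(latent = z, genotype_effects = g_eff,
                    interaction = inter),
       config = cfg)
}

#' Simulate a qPCR Ct table
#'
#' Emits a tidy Ct table (`gene,genotype,treatment,replicate,ct`) for a set
#' of target genes with known fold changes under stress plus a reference
#' gene whose Ct is constant in expectation across conditions. The target
#' Ct under stress is shifted by `-log2(fold)` relative to control, so
#' [relative_expression()] recovers the configured fold changes.
#'
#' @param fold_changes data frame with columns `gene`, `genotype`, `fold`
#'   (one row per target gene x genotype; folds must be positive).
#' @param n_replicates replicates per condition (default 3).
#' @param ct_noise_sd standard deviation of additive Ct noise (cycles).
#' @param seed integer seed.
#' @param reference_gene name of the reference gene row to emit.
#' @param base_ct_target,base_ct_ref expected control-condition Ct of the
#'   target and reference genes.
#' @param control,stress treatment labels.
#' @return tidy data frame of Ct values.
#' @export
simulate_qpcr <- function(fold_changes, n_replicates = 3L,
                          ct_noise_sd = 0.1, seed = 1L,
                          reference_gene = "ref",
                          base_ct_target = 26, base_ct_ref = 20,
                          control = "CK", stress = "LT") {
  required <- c("gene", "genotype", "fold")
  missing_cols <- setdiff(required, names(fold_changes))
  if (length(missing_cols) > 0L) {
    stop("fold_changes is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(fold_changes$fold <= 0)) {
    stop("fold changes must be positive", call. = FALSE)
  }
  set.seed(seed)
  genotypes <- unique(fold_changes$genotype)
  rows <- list()
  for (geno in genotypes) {
    sub <- fold_changes[fold_changes$genotype == geno, , drop = FALSE]
    for (k in seq_len(nrow(sub))) {
      for (treat in c(control, stress)) {
        shift <- if (treat == stress) -log2(sub$fold[k]) else 0
        rows[[length(rows) + 1L]] <- data.frame(
          gene = sub$gene[k], genotype = geno, treatment = treat,
          replicate = seq_len(n_replicates),
          ct = base_ct_target + shift +
            stats::rnorm(n_replicates, 0, ct_noise_sd),
          stringsAsFactors = FALSE)
      }
    }
    for (treat in c(control, stress)) {
      rows[[length(rows) + 1L]] <- data.frame(
        gene = reference_gene, genotype = geno, treatment = treat,
        replicate = seq_len(n_replicates),
        ct = base_ct_ref + stats::rnorm(n_replicates, 0, ct_noise_sd),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
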