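#' Construct a replicate-level phenotype dataset
#'
#' Validates a tidy table of trait measurements against a trait registry and
#' a declared pair of treatment levels, and returns a `phenotype_dataset`
#' object used by all downstream stages.
#'
#' @param data data frame with columns `genotype`, `treatment`, `replicate`,
#'   `trait`, `value` (one measurement per row).
#' @param registry trait registry data frame (see [default_trait_registry()]);
#'   every trait in `data` must appear in it.
#' @param control,stress the two treatment labels, control first. Defaults
#'   `"CK"` (22 degC normal temperature) and `"LT"` (10 degC chilling).
#' @param on_missing what to do when a genotype lacks a (treatment, trait)
#'   cell: `"error"` (default) or `"drop"` to remove that genotype listwise.
#'   The comprehensive score averages over a fixed trait set, so incomplete
#'   genotypes cannot be scored.
#' @return an object of class `phenotype_dataset`: a list with elements
#'   `data` (the validated tidy table), `registry`, `genotypes`,
#'   `treatments` (named vector with elements `control` and `stress`), and
#'   `traits`.
#' @examples
#' df <- expand.grid(genotype = c("g1", "g2"), treatment = c("CK", "LT"),
#'                   replicate = 1:3, trait = "SL")
#' df$value <- 10 + seq_len(nrow(df))
#' ds <- phenotype_dataset(df, default_trait_registry())
#' ds
#' @export
phenotype_dataset <- function(data, registry = default_trait_registry(),
                              control = "CK", stress = "LT",
                              on_missing = c("error", "drop")) {
  on_missing <- match.arg(on_missing)
  validate_registry(registry)
  required <- c("genotype", "treatment", "replicate", "trait", "value")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0L) {
    stop("phenotype table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  data <- as.data.frame(data)[required]
  data$genotype <- as.character(data$genotype)
  data$treatment <- as.character(data$treatment)
  data$trait <- as.character(data$trait)

  bad_treat <- setdiff(unique(data$treatment), c(control, stress))
  if (length(bad_treat) > 0L) {
    stop("unknown treatment label(s): ", paste(bad_treat, collapse = ", "),
         "; declared levels are control = '", control,
         "', stress = '", stress, "'", call. = FALSE)
  }
  unknown_traits <- setdiff(unique(data$trait), registry$name)
  if (length(unknown_traits) > 0L) {
    stop("trait(s) absent from registry: ",
         paste(unknown_traits, collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(data$value)) {
    suppressWarnings(num <- as.numeric(data$value))
    if (anyNA(num)) {
      stop("non-numeric value(s) at row(s): ",
           paste(utils::head(which(is.na(num)), 5L), collapse = ", "),
           call. = FALSE)
    }
    data$value <- num
  }
  if (!all(is.finite(data$value))) {
    stop("non-finite value(s) at row(s): ",
         paste(utils::head(which(!is.finite(data$value)), 5L),
               collapse = ", "), call. = FALSE)
  }
  pos_traits <- registry$name[registry$strictly_positive]
  neg <- data$trait %in% pos_traits & data$value <= 0
  if (any(neg)) {
    stop("non-positive value(s) for strictly positive trait(s) at row(s): ",
         paste(utils::head(which(neg), 5L), collapse = ", "), call. = FALSE)
  }

  # completeness: every genotype must carry every observed (treatment, trait)
  traits <- sort(unique(data$trait))
  genotypes <- unique(data$genotype)
  cells <- unique(data[c("genotype", "treatment", "trait")])
  n_cells <- table(cells$genotype)
  expected <- 2L * length(traits)
  incomplete <- names(n_cells)[n_cells < expected]
  also_missing <- setdiff(genotypes, names(n_cells))
  incomplete <- union(incomplete, also_missing)
  if (length(incomplete) > 0L) {
    if (on_missing == "error") {
      stop("genotype(s) with missing (treatment, trait) cells: ",
           paste(incomplete, collapse = ", "),
           "; use on_missing = 'drop' to exclude them", call. = FALSE)
    }
    warning("dropping incomplete genotype(s): ",
            paste(incomplete, collapse = ", "), call. = FALSE)
    data <- data[!data$genotype %in% incomplete, , drop = FALSE]
    genotypes <- setdiff(genotypes, incomplete)
    if (length(genotypes) == 0L) {
      stop("no complete genotype remains after dropping", call. = FALSE)
    }
  }

  structure(list(
    data = data,
    registry = registry,
    genotypes = genotypes,
    treatments = c(control = control, stress = stress),
    traits = traits
  ), class = "phenotype_dataset")
}

#' Load a tidy phenotype CSV
#'
#' Reads a UTF-8 CSV with header `genotype,treatment,replicate,trait,value`
#' and validates it into a [phenotype_dataset()].
#'
#' @inheritParams phenotype_dataset
#' @param path path to the CSV file.
#' @return a `phenotype_dataset`.
#' @export
load_phenotypes <- function(path, registry = default_trait_registry(),
                            control = "CK", stress = "LT",
                            on_missing = c("error", "drop")) {
  data <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = c(value = "character"))
  phenotype_dataset(data, registry, control = control, stress = stress,
                    on_missing = on_missing)
}

#' Write a phenotype dataset back to tidy CSV
#'
#' @param ds a `phenotype_dataset`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(ds, path) {
  stopifnot(inherits(ds, "phenotype_dataset"))
  utils::write.csv(ds$data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.phenotype_dataset <- function(x, ...) {
  reps <- table(x$data$genotype, x$data$treatment) /
    max(1L, length(unique(x$data$trait)))
  cat("Phenotype dataset:",
      length(x$genotypes), "genotypes x",
      length(x$traits), "traits x 2 treatments (",
      x$treatments["control"], "control /",
      x$treatments["stress"], "stress )\n")
  cat("Replicates per cell:",
      paste(range(round(reps, 2)), collapse = "-"), "\n")
  invisible(x)
}

#' Replicate means per genotype x treatment x trait
#'
#' Collapses replicate-level measurements to their arithmetic mean, the
#' quantity the cold-resistance coefficient and rate change are defined on.
#'
#' @param ds a `phenotype_dataset`.
#' @return a `trait_means` object: data frame with columns `genotype`,
#'   `treatment`, `trait`, `mean`, `n_replicates`, carrying the registry and
#'   treatment roles as attributes.
#' @export
replicate_means <- function(ds) {
  stopifnot(inherits(ds, "phenotype_dataset"))
  agg <- stats::aggregate(value ~ genotype + treatment + trait,
                          data = ds$data, FUN = mean)
  cnt <- stats::aggregate(value ~ genotype + treatment + trait,
                          data = ds$data, FUN = length)
  names(agg)[names(agg) == "value"] <- "mean"
  agg$n_replicates <- cnt$value[match(
    paste(agg$genotype, agg$treatment, agg$trait),
    paste(cnt$genotype, cnt$treatment, cnt$trait))]
  agg <- agg[order(agg$trait, agg$genotype, agg$treatment), ]
  rownames(agg) <- NULL
  structure(agg,
            registry = ds$registry,
            treatments = ds$treatments,
            genotypes = ds$genotypes,
            class = c("trait_means", "data.frame"))
}

# genotype x trait matrix of means for one treatment level
means_matrix <- function(means, treatment) {
  stopifnot(inherits(means, "trait_means"))
  sub <- means[means$treatment == treatment, , drop = FALSE]
  genotypes <- attr(means, "genotypes")
  traits <- sort(unique(means$trait))
  m <- matrix(NA_real_, nrow = length(genotypes), ncol = length(traits),
              dimnames = list(genotypes, traits))
  m[cbind(match(sub$genotype, genotypes), match(sub$trait, traits))] <- sub$mean
  m
}
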