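#' Default maize seedling trait registry
#'
#' Returns the registry of the 29 seedling traits used for two-temperature
#' (22 degC control vs 10 degC chilling) cold-resistance screening of maize
#' panels: seven growth parameters, ten photosynthetic performances, two
#' membrane characteristics, two reactive-oxygen-species levels, four
#' antioxidant enzyme activities, one osmotic substance and three polyamine
#' concentrations.
#'
#' The `direction` column drives the membership-function transform: `+1`
#' means a larger trait value indicates greater cold resistance (the plain
#' min-max membership is used), `-1` means the trait marks damage (MDA,
#' superoxide production, H2O2, intercellular CO2) and the membership is
#' inverted. The field literature does not publish a canonical assignment,
#' so the registry is fully overridable; the default encodes the reading
#' that only the four damage markers are negatively associated.
#'
#' When `calibrated = TRUE` three extra columns are attached for use by
#' [simulate_phenotypes()]: `cold_effect_pct`, the percent rate change of
#' the trait mean under chilling (e.g. -48.6 for seedling length, +221.9
#' for MDA); `cvg_ck` and `cvg_lt`, the genetic coefficients of variation
#' (percent) of the genotype means under control and chilling; and
#' `baseline_ck`, a control-condition cohort mean in the trait's units.
#'
#' @param calibrated logical; attach generator calibration columns.
#' @return A data frame with columns `name`, `long_name`, `category`,
#'   `units`, `direction`, `strictly_positive`, and, when requested, the
#'   calibration columns described above.
#' @seealso [read_trait_registry()] for loading a custom registry from CSV.
#' @examples
#' reg <- default_trait_registry()
#' table(reg$category)
#' subset(reg, direction == -1)$name
#' @export
default_trait_registry <- function(calibrated = FALSE) {
  reg <- data.frame(
    name = c("SL", "RL", "RN", "SFW", "RFW", "PB", "RSR",
             "Chl_a", "Chl_b", "Chl_ab", "Chl_ratio",
             "Pn", "Ci", "Gs", "Tr", "WUE", "Rubisco",
             "MDA", "MSI", "O2", "H2O2",
             "SOD", "POD", "CAT", "APX", "Pro", "Put", "Spd", "Spm"),
    long_name = c(
      "seedling length", "root length", "root number",
      "seedling fresh weight", "root fresh weight", "plant biomass",
      "root-shoot ratio",
      "chlorophyll a content", "chlorophyll b content",
      "chlorophyll a+b content", "chlorophyll a:b ratio",
      "net photosynthetic rate", "intercellular CO2 concentration",
      "stomatal conductance", "transpiration rate", "water use efficiency",
      "ribulose-1,5-bisphosphate carboxylase activity",
      "malondialdehyde content", "membrane stability index",
      "superoxide production rate", "hydrogen peroxide content",
      "superoxide dismutase activity", "peroxidase activity",
      "catalase activity", "ascorbate peroxidase activity",
      "proline content", "putrescine concentration",
      "spermidine concentration", "spermine concentration"),
    category = c(rep("growth", 7),
                 rep("photosynthetic", 10),
                 rep("membrane", 2), rep("ROS", 2),
                 rep("antioxidant", 4), "osmotic", rep("polyamine", 3)),
    units = c("cm", "cm", "count", "g", "g", "g", "ratio",
              "mg g-1 FW", "mg g-1 FW", "mg g-1 FW", "ratio",
              "uM m-2 s-1", "uM M-1", "mol m-2 s-1", "mM m-2 s-1",
              "ratio", "M m-2 s-1",
              "uM g-1 FW", "%", "uM min-1 g-1 FW", "uM g-1 FW",
              "Unit g-1 protein", "Unit g-1 protein",
              "uM min-1 g-1 protein", "uM min-1 g-1 protein",
              "ug g-1 FW", "nM g-1 FW", "nM g-1 FW", "nM g-1 FW"),
    direction = 1L,
    strictly_positive = TRUE,
    stringsAsFactors = FALSE
  )
  # damage markers: increase under chilling indicates injury, not resistance
  reg$direction[reg$name %in% c("MDA", "O2", "H2O2", "Ci")] <- -1L
  if (calibrated) {
    reg$cold_effect_pct <- c(
      -48.6, -39.0, -10.2, -28.1, -21.1, -24.2, 9.9,
      -18.6, -21.7, -20.3, 3.3,
      -19.7, 7.2, -12.0, -2.8, -17.1, -25.1,
      221.9, -19.5, 163.4, 159.2,
      42.7, 144.4, 101.1, 65.8, 311.8, 183.7, 69.2, 56.6)
    reg$cvg_ck <- c(
      20.58, 22.55, 16.96, 27.29, 21.08, 26.54, 24.15,
      10.88, 15.46, 11.49, 13.45,
      21.44, 8.67, 6.52, 9.19, 13.16, 32.15,
      18.72, 5.76, 11.82, 15.20,
      7.43, 14.56, 37.59, 15.35, 9.69, 8.87, 8.32, 4.59)
    reg$cvg_lt <- c(
      27.56, 24.66, 23.99, 28.38, 34.54, 27.92, 31.21,
      16.75, 17.90, 16.07, 12.02,
      18.63, 9.21, 11.82, 10.87, 8.43, 29.16,
      27.18, 14.07, 16.49, 19.74,
      34.85, 24.27, 40.13, 27.81, 22.48, 12.72, 20.02, 15.62)
    # control-condition cohort means; where the chilled-cohort mean is
    # published (MSI, enzymes, chlorophylls, Pn, polyamines) the control
    # baseline is that value back-transformed through the cold multiplier,
    # otherwise a realistic round figure in the trait's units
    reg$baseline_ck <- c(
      25, 18, 4.5, 4.6, 1.38, 6.0, 0.30,
      0.442, 0.511, 0.953, 0.865,
      6.87, 220, 0.15, 2.40, 2.86, 8.77,
      4.0, 82.1, 2.0, 3.0,
      1.71, 0.675, 0.323, 3.29, 30, 96.9, 31.1, 29.3)
  }
  reg
}

#' Read a trait registry from CSV
#'
#' The CSV must carry the header
#' `name,long_name,category,units,direction,strictly_positive`. `direction`
#' must be +1 or -1; trait names must be unique.
#'
#' @param path path to the registry CSV.
#' @return a validated registry data frame.
#' @export
read_trait_registry <- function(path) {
  reg <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("name", "long_name", "category", "units",
                "direction", "strictly_positive")
  missing_cols <- setdiff(required, names(reg))
  if (length(missing_cols) > 0L) {
    stop("registry file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  reg$direction <- as.integer(reg$direction)
  reg$strictly_positive <- as.logical(reg$strictly_positive)
  validate_registry(reg)
  reg
}

validate_registry <- function(registry) {
  if (!is.data.frame(registry) || nrow(registry) == 0L) {
    stop("registry must be a non-empty data frame", call. = FALSE)
  }
  if (anyDuplicated(registry$name)) {
    dup <- unique(registry$name[duplicated(registry$name)])
    stop("duplicated trait name(s) in registry: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  if (!all(registry$direction %in% c(-1L, 1L))) {
    bad <- registry$name[!registry$direction %in% c(-1L, 1L)]
    stop("trait direction must be +1 or -1; offending trait(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(registry)
}
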