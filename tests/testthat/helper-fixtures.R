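# Shared fixtures, built in code.

# minimal registry: traits named A, B, ... with the given directions
tiny_registry <- function(directions) {
  n <- length(directions)
  data.frame(name = LETTERS[seq_len(n)],
             long_name = paste("trait", LETTERS[seq_len(n)]),
             category = "growth", units = "u",
             direction = as.integer(directions),
             strictly_positive = TRUE,
             stringsAsFactors = FALSE)
}

# tidy table from per-treatment genotype x trait matrices of cell means,
# emitted as single-replicate rows (replicate means are then those values)
tidy_from_means <- function(ck, lt) {
  stopifnot(identical(dimnames(ck), dimnames(lt)))
  grid <- expand.grid(genotype = rownames(ck), trait = colnames(ck),
                      stringsAsFactors = FALSE)
  rbind(
    data.frame(genotype = grid$genotype, treatment = "CK", replicate = 1L,
               trait = grid$trait, value = ck[cbind(grid$genotype, grid$trait)]),
    data.frame(genotype = grid$genotype, treatment = "LT", replicate = 1L,
               trait = grid$trait, value = lt[cbind(grid$genotype, grid$trait)]))
}

# 2 genotypes x 2 treatments x 3 replicates x 2 traits (24 rows) with
# hand-checkable replicate means
fixture_tidy_24 <- function() {
  rows <- expand.grid(replicate = 1:3, treatment = c("CK", "LT"),
                      genotype = c("g1", "g2"), trait = c("A", "B"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  base <- c(A.g1.CK = 10, A.g1.LT = 6, A.g2.CK = 20, A.g2.LT = 14,
            B.g1.CK = 4, B.g1.LT = 5, B.g2.CK = 8, B.g2.LT = 6)
  key <- paste(rows$trait, rows$genotype, rows$treatment, sep = ".")
  rows$value <- base[key] + (rows$replicate - 2)  # reps mean to base exactly
  rows[c("genotype", "treatment", "replicate", "trait", "value")]
}

# hand-evaluated 4-genotype x 3-trait cohort (traits A, B positive, C
# damage-indicating); frozen spreadsheet arithmetic:
#   CRC A: .5 .6 .8 .9   -> U: 0 .25 .75 1
#   CRC B: .8 .9 .6 .7   -> U: 2/3 1 0 1/3
#   CRC C: 3 2 1 2.5     -> U: 0 .5 1 .25
#   U_j: 2/9, 7/12, 7/12, 19/36
fixture_hand_cohort <- function() {
  genotypes <- paste0("g", 1:4)
  ck <- matrix(10, 4, 3, dimnames = list(genotypes, c("A", "B", "C")))
  lt <- matrix(c(5, 6, 8, 9,      # A
                 8, 9, 6, 7,      # B
                 30, 20, 10, 25), # C
               4, 3, dimnames = dimnames(ck))
  list(tidy = tidy_from_means(ck, lt),
       registry = tiny_registry(c(1, 1, -1)),
       u = cbind(A = c(0, .25, .75, 1),
                 B = c(2 / 3, 1, 0, 1 / 3),
                 C = c(0, .5, 1, .25)),
       u_j = c(g1 = 2 / 9, g2 = 7 / 12, g3 = 7 / 12, g4 = 19 / 36))
}

# noise-free generator configuration helpers
flat_registry <- function(traits = c("SL", "MDA")) {
  reg <- default_trait_registry(calibrated = TRUE)
  reg <- reg[reg$name %in% traits, , drop = FALSE]
  reg$cvg_ck <- 0
  reg$cold_effect_pct <- 0
  reg
}
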