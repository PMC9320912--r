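test_that("rate change follows its definition and domain", {
  expect_equal(rate_change(10, 10), 0)
  expect_equal(rate_change(5, 10), -50)
  expect_equal(rate_change(c(11, 9), c(10, 10)), c(10, -10))
  expect_error(rate_change(5, 0), "positive")
})

test_that("resistance coefficients are stress/control ratios with row extrema", {
  genotypes <- paste0("g", 1:3)
  ck <- matrix(c(10, 10, 10, 4, 5, 8), 3, 2,
               dimnames = list(genotypes, c("A", "B")))
  lt <- matrix(c(5, 7.5, 10, 2, 6, 4), 3, 2, dimnames = dimnames(ck))
  m <- replicate_means(phenotype_dataset(tidy_from_means(ck, lt),
                                         tiny_registry(c(1, 1))))
  crc <- cold_resistance_coefficients(m)
  expect_equal(crc$crc[, "A"], c(g1 = 0.5, g2 = 0.75, g3 = 1))
  expect_equal(crc$crc[, "B"], c(g1 = 0.5, g2 = 1.2, g3 = 0.5))
  expect_equal(crc$trait_min, c(A = 0.5, B = 0.5))
  expect_equal(crc$trait_max, c(A = 1, B = 1.2))
  # cell-wise identity with rate change
  expect_equal(crc$crc, 1 + rate_change(lt, ck) / 100)

  lt_eq <- ck
  crc_eq <- cold_resistance_coefficients(
    replicate_means(phenotype_dataset(tidy_from_means(ck, lt_eq),
                                      tiny_registry(c(1, 1)))))
  expect_true(all(crc_eq$crc == 1))
})

test_that("control means of zero are rejected with the offending cell named", {
  df <- data.frame(genotype = "g1", treatment = c("CK", "LT"),
                   replicate = 1L, trait = "A", value = c(10, 5))
  reg <- tiny_registry(1)
  reg$strictly_positive <- FALSE
  df$value[1] <- -2
  m <- replicate_means(phenotype_dataset(df, reg))
  expect_error(cold_resistance_coefficients(m), "g1.*A|A.*g1")
})

test_that("membership normalisation hits its endpoints and flips with direction", {
  genotypes <- paste0("g", 1:3)
  ck <- matrix(4, 3, 1, dimnames = list(genotypes, "A"))
  lt <- matrix(c(2, 3, 4), 3, 1, dimnames = dimnames(ck))
  m <- replicate_means(phenotype_dataset(tidy_from_means(ck, lt),
                                         tiny_registry(1)))
  crc <- cold_resistance_coefficients(m)   # CRC row {0.5, 0.75, 1.0}
  pos <- membership_values(crc, tiny_registry(1))
  expect_equal(unname(pos$u[, "A"]), c(0, 0.5, 1))
  neg <- membership_values(crc, tiny_registry(-1))
  expect_equal(unname(neg$u[, "A"]), c(1, 0.5, 0))
  expect_equal(pos$u[, "A"] + neg$u[, "A"], c(g1 = 1, g2 = 1, g3 = 1))
})

test_that("membership matches a brute-force min-max oracle on random matrices", {
  for (rep in 1:10) {
    set.seed(100 + rep)
    crc_vals <- matrix(exp(stats::rnorm(25, 0, 0.4)), 5, 5,
                       dimnames = list(paste0("g", 1:5), LETTERS[1:5]))
    directions <- sample(c(-1, 1), 5, replace = TRUE)
    ck <- matrix(1, 5, 5, dimnames = dimnames(crc_vals))
    m <- replicate_means(phenotype_dataset(tidy_from_means(ck, crc_vals),
                                           tiny_registry(directions)))
    got <- membership_values(cold_resistance_coefficients(m),
                             tiny_registry(directions))
    # independent oracle: explicit per-column normalisation
    expected <- crc_vals
    for (j in 1:5) {
      col <- crc_vals[, j]
      norm <- (col - min(col)) / (max(col) - min(col))
      expected[, j] <- if (directions[j] > 0) norm else 1 - norm
    }
    expect_equal(got$u, expected)
    expect_equal(got$u_j, rowMeans(expected))
    # normalisation endpoints are exact per trait
    expect_equal(unname(apply(got$u, 2, min)), rep(0, 5))
    expect_equal(unname(apply(got$u, 2, max)), rep(1, 5))
    expect_true(all(got$u_j >= 0 & got$u_j <= 1))
  }
})

test_that("degenerate constant traits get membership 0.5 with a warning", {
  ck <- matrix(4, 3, 2, dimnames = list(paste0("g", 1:3), c("A", "B")))
  lt <- ck; lt[, "A"] <- c(2, 3, 4)      # B is constant across genotypes
  m <- replicate_means(phenotype_dataset(tidy_from_means(ck, lt),
                                         tiny_registry(c(1, 1))))
  crc <- cold_resistance_coefficients(m)
  expect_warning(mm <- membership_values(crc, tiny_registry(c(1, 1))), "B")
  expect_equal(unname(mm$u[, "B"]), rep(0.5, 3))
  expect_identical(mm$degenerate, "B")
})

test_that("scores are invariant to unit rescaling and genotype relabeling", {
  sim <- simulate_phenotypes(generator_config(seed = 3, n_genotypes = 8,
                                              traits = c("SL", "MDA", "Pro")))
  df <- sim$dataset$data
  reg <- sim$config$registry
  base <- coldscore(df, registry = reg)

  scaled <- df
  scaled$value[scaled$trait == "SL"] <- scaled$value[scaled$trait == "SL"] * 1000
  fit_scaled <- coldscore(scaled, registry = reg)
  expect_equal(coef(fit_scaled), coef(base))

  relabeled <- df
  map <- c(G01 = "zz", G02 = "aa", G03 = "mm", G04 = "bb",
           G05 = "qq", G06 = "cc", G07 = "rr", G08 = "dd")
  relabeled$genotype <- unname(map[relabeled$genotype])
  fit_rel <- coldscore(relabeled, registry = reg)
  expect_equal(unname(sort(coef(fit_rel))), unname(sort(coef(base))))
  expect_equal(unname(coef(fit_rel)[map]), unname(coef(base)[names(map)]))
})

test_that("genetic CV matches hand arithmetic, scales, and translates", {
  expect_equal(genetic_cv(c(2, 2, 2)), 0)
  expect_equal(genetic_cv(c(1, 2, 3)), 50)   # sample SD 1, mean 2
  expect_equal(genetic_cv(c(1, 2, 3) * 7), 50)          # scale-invariant
  expect_false(isTRUE(all.equal(genetic_cv(c(1, 2, 3) + 10), 50)))
  expect_equal(genetic_cv(c(1, 2, 3), sd_type = "population"),
               50 * sqrt(2 / 3))
  expect_error(genetic_cv(5), "two")
  expect_error(genetic_cv(c(-1, 1)), "zero")
})

test_that("the hand-evaluated cohort reproduces its frozen score table", {
  fx <- fixture_hand_cohort()
  fit <- coldscore(fx$tidy, registry = fx$registry, k = 2)
  expect_equal(unname(fit$membership$u), unname(fx$u))
  expect_equal(fit$membership$u_j, fx$u_j)
  expect_equal(fit$u_cv, genetic_cv(fx$u_j))
})

test_that("noise-free unit multipliers give a fully degenerate evaluation", {
  reg <- flat_registry(c("SL", "MDA"))
  cfg <- generator_config(seed = 1, n_genotypes = 4, registry = reg,
                          interaction_cv = 0, residual_cv = 0)
  sim <- simulate_phenotypes(cfg)
  expect_warning(fit <- coldscore(sim$dataset, registry = reg, k = 1),
                 "constant")
  expect_true(all(fit$crc$crc == 1))
  expect_true(all(fit$rc == 0))
  expect_true(all(fit$membership$u == 0.5))
})

test_that("a genotype dominating every favourable extreme scores exactly one", {
  genotypes <- paste0("g", 1:4)
  ck <- matrix(10, 4, 2, dimnames = list(genotypes, c("A", "B")))
  # g1 has the largest CRC for positive trait A and smallest for damage B
  lt <- cbind(A = c(9, 5, 6, 7), B = c(12, 30, 25, 20))
  dimnames(lt) <- dimnames(ck)
  fit <- coldscore(tidy_from_means(ck, lt),
                   registry = tiny_registry(c(1, -1)), k = 2)
  expect_equal(unname(coef(fit)["g1"]), 1)
})
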