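anova_fixture <- function() {
  data.frame(
    genotype = rep(c("g1", "g2"), each = 4),
    treatment = rep(rep(c("CK", "LT"), each = 2), 2),
    replicate = rep(1:2, 4),
    trait = "A",
    value = c(10, 12, 6, 8, 20, 22, 16, 18))
}

test_that("two-way ANOVA reproduces the hand sums-of-squares oracle", {
  ds <- phenotype_dataset(anova_fixture(), tiny_registry(1))
  tab <- factorial_anova(ds, "A")
  expect_equal(tab$term, c("G", "T", "GxT", "Residuals"))
  expect_equal(tab$ss, c(200, 32, 0, 8))
  expect_equal(tab$df, c(1, 1, 1, 4))
  expect_equal(tab$F[1:3], c(100, 16, 0))   # MS_res = 2
  expect_equal(tab$p[1:3],
               stats::pf(c(100, 16, 0), 1, 4, lower.tail = FALSE))
})

test_that("ANOVA decomposition is exact on random balanced designs", {
  for (rep in 1:5) {
    set.seed(200 + rep)
    df <- expand.grid(genotype = paste0("g", 1:4),
                      treatment = c("CK", "LT"), replicate = 1:3,
                      stringsAsFactors = FALSE)
    df$trait <- "A"
    df$value <- exp(stats::rnorm(nrow(df), 1, 0.3))
    ds <- phenotype_dataset(df, tiny_registry(1))
    tab <- factorial_anova(ds, "A")
    ss_total <- sum((df$value - mean(df$value))^2)
    expect_equal(sum(tab$ss), ss_total, tolerance = 1e-9)
    expect_true(all(tab$ss >= 0))
  }
})

test_that("degenerate and malformed ANOVA inputs are handled", {
  df <- anova_fixture()
  df$value <- 5
  tab <- factorial_anova(phenotype_dataset(df, tiny_registry(1)), "A")
  expect_equal(tab$ss, rep(0, 4))
  expect_true(all(is.na(tab$F)))

  unbalanced <- anova_fixture()[-1, ]
  expect_error(
    factorial_anova(phenotype_dataset(unbalanced, tiny_registry(1),
                                      on_missing = "error"), "A"),
    "balanced|equal replication")

  single <- anova_fixture()[anova_fixture()$replicate == 1, ]
  expect_error(factorial_anova(phenotype_dataset(single, tiny_registry(1)),
                               "A"), "2 replicates")
  ds <- phenotype_dataset(anova_fixture(), tiny_registry(1))
  expect_error(factorial_anova(ds, "B"), "not in dataset")
})

test_that("correlations match hand computation and perfect-linearity cases", {
  genotypes <- paste0("g", 1:5)
  a <- c(1, 2, 3, 4, 5)
  ck <- cbind(A = a, B = 2 * a, C = 6 - a, D = c(2, 1, 4, 3, 6))
  rownames(ck) <- genotypes
  m <- replicate_means(phenotype_dataset(tidy_from_means(ck, ck * 0.5),
                                         tiny_registry(rep(1, 4))))
  res <- correlation_matrix(m, "CK")
  expect_equal(unname(res$r["A", "B"]), 1)
  expect_equal(unname(res$r["A", "C"]), -1)
  expect_lt(res$p["A", "B"], 1e-10)
  # hand: Sxy = 10, Sxx = 10, Syy = 14.8 -> r = 10/sqrt(148)
  expect_equal(unname(res$r["A", "D"]), 10 / sqrt(148), tolerance = 1e-6)
  expect_true(isSymmetric(res$r))
  expect_equal(unname(diag(res$r)), rep(1, 4))
})

test_that("correlation p-values decrease in |r| at fixed n", {
  n <- 10
  p_of_r <- function(r) {
    t <- r * sqrt(n - 2) / sqrt(1 - r^2)
    2 * stats::pt(abs(t), n - 2, lower.tail = FALSE)
  }
  rs <- seq(0.1, 0.9, by = 0.1)
  expect_true(all(diff(p_of_r(rs)) < 0))
  # and the package reports those same p-values on data with known r
  set.seed(42)
  x <- stats::rnorm(n) + 5
  y <- stats::rnorm(n) + 5
  ck <- cbind(A = x, B = y)
  rownames(ck) <- paste0("g", 1:n)
  m <- replicate_means(phenotype_dataset(tidy_from_means(ck, ck * 0.5),
                                         tiny_registry(c(1, 1))))
  res <- correlation_matrix(m, "CK")
  expect_equal(unname(res$p["A", "B"]),
               stats::cor.test(x, y)$p.value, tolerance = 1e-12)
})

test_that("zero-variance traits yield missing correlations with a warning", {
  ck <- cbind(A = c(1, 2, 3), B = c(5, 5, 5))
  rownames(ck) <- paste0("g", 1:3)
  m <- replicate_means(phenotype_dataset(tidy_from_means(ck, ck),
                                         tiny_registry(c(1, 1))))
  expect_warning(res <- correlation_matrix(m, "CK"), "B")
  expect_true(is.na(res$r["A", "B"]))
})

test_that("two standardised variables give eigenvalues 1 +/- r", {
  x <- c(1, 2, 3, 4, 5)
  e <- c(1, -2, 1, 0, 0)                  # orthogonal to centred x
  xs <- (x - mean(x)) / stats::sd(x)
  es <- (e - mean(e)) / stats::sd(e)
  y <- 0.6 * xs + sqrt(1 - 0.36) * es + 10
  ck <- cbind(A = x, B = y)
  rownames(ck) <- paste0("g", 1:5)
  m <- replicate_means(phenotype_dataset(tidy_from_means(ck, ck * 2),
                                         tiny_registry(c(1, 1))))
  res <- pca_traits(m, scope = "control")
  expect_equal(res$eigenvalues, c(1.6, 0.4))
  expect_equal(res$percent, c(80, 20))
  expect_equal(res$n_retained, 1L)
})

test_that("PCA matches an independent eigendecomposition and reconstructs", {
  set.seed(11)
  x <- matrix(exp(stats::rnorm(40)), 10, 4,
              dimnames = list(paste0("g", 1:10), LETTERS[1:4]))
  m <- replicate_means(phenotype_dataset(tidy_from_means(x, x * 0.8),
                                         tiny_registry(rep(1, 4))))
  res <- pca_traits(m, scope = "control")
  # oracle: singular values of the standardised matrix
  z <- scale(x)
  sv <- svd(z)$d
  expect_equal(res$eigenvalues, sv^2 / (nrow(x) - 1), tolerance = 1e-10)
  expect_equal(sum(res$percent), 100)
  expect_true(all(diff(res$cumulative) >= 0))
  # loadings orthonormal; reconstruction reproduces the correlation matrix
  expect_equal(crossprod(res$loadings), diag(4), ignore_attr = TRUE)
  expect_equal(res$loadings %*% diag(res$eigenvalues) %*% t(res$loadings),
               stats::cor(z), ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("PCA scopes and degenerate traits behave as documented", {
  sim <- simulate_phenotypes(generator_config(seed = 2, n_genotypes = 8,
                                              traits = c("SL", "MDA", "Pro")))
  m <- replicate_means(sim$dataset)
  pooled <- pca_traits(m)                  # 16 observation rows
  expect_equal(length(pooled$eigenvalues), 3L)
  crc_scope <- pca_traits(m, scope = "crc")
  expect_equal(sum(crc_scope$percent), 100)

  ck <- cbind(A = c(1, 2, 3), B = c(5, 5, 5))
  rownames(ck) <- paste0("g", 1:3)
  mc <- replicate_means(phenotype_dataset(tidy_from_means(ck, ck * 2),
                                          tiny_registry(c(1, 1))))
  expect_error(pca_traits(mc, scope = "control"), "B")
})
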