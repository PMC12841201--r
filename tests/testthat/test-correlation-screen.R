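test_that("pearson_r reproduces hand-evaluated coefficients", {
  expect_equal(pearson_r(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(pearson_r(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_equal(pearson_r(c(1, 2, 4), c(2, 3, 7)), 0.98974331861, tolerance = 1e-10)
})

test_that("pearson_r matches the explicit-sums oracle and stays in [-1, 1]", {
  set.seed(31)
  for (i in 1:300) {
    n <- sample(3:8, 1)
    x <- rnorm(n); y <- rnorm(n)
    r <- pearson_r(x, y)
    expect_equal(r, pearson_oracle(x, y), tolerance = 1e-12)
    expect_lte(abs(r), 1)
  }
})

test_that("pearson_r is affine-invariant and flips sign under negation", {
  set.seed(17)
  x <- rnorm(5); y <- rnorm(5)
  r <- pearson_r(x, y)
  expect_equal(pearson_r(2.5 * x + 3, y), r)
  expect_equal(pearson_r(x, 0.1 * y - 7), r)
  expect_equal(pearson_r(-x, y), -r)
})

test_that("degenerate variance is an error, duplicated values are legal", {
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), class = "degenerate_variance_error")
  expect_error(pearson_r(c(1, 2, 3), c(4, 4, 4)), class = "degenerate_variance_error")
  expect_error(pearson_r(c(1, 2), c(1, 2)), class = "validation_error")
  # duplicated x short of constancy (the published Cept1 abundances)
  expect_silent(pearson_r(c(16.4, 16.4, 16.2), c(1, 2, 3)))
})

test_that("correlation p-values follow the t transform on n-2 df", {
  expect_equal(correlation_pvalue(0, 10), 1)
  expect_equal(correlation_pvalue(1, 3), 0)
  expect_equal(correlation_pvalue(-1, 5), 0)
  # n = 3 gives 1 df: t is standard Cauchy, p = (2/pi) * atan(1/|t|)
  r <- 0.963
  t <- r * sqrt(1 / (1 - r^2))
  expect_equal(correlation_pvalue(r, 3), (2 / pi) * atan(1 / t), tolerance = 1e-12)
  expect_equal(correlation_pvalue(r, 3), 0.1737, tolerance = 1e-3)
  expect_lt(correlation_pvalue(0.999999, 3), 1e-3)
})

test_that("the 3-of-4 rule on the published grid selects Cept1 and Slc44a1", {
  cfg <- screen_config()
  sel <- cholscreen:::select_from_grid(fixtures$correlations, cfg)
  expect_setequal(sel, c("Cept1", "Slc44a1"))
  # Cept1 is strong in 4/4 cells, Slc44a1 in 3/4, Aldh7a1 in 0/4
  strong <- tapply(fixtures$correlations$r > 0.7, fixtures$correlations$gene, sum)
  expect_equal(as.vector(strong[c("Aldh7a1", "Cept1", "Slc44a1")]), c(0, 4, 3))
})

test_that("the threshold is strict and the absolute mode is never stricter", {
  grid <- data.frame(gene = "g", region = rep(c("forebrain", "brainstem"), 2),
                     dose = rep(c(100, 250), each = 2),
                     r = c(0.7, 0.7, 0.7, 0.7))
  expect_length(cholscreen:::select_from_grid(grid, screen_config()), 0L)

  set.seed(8)
  for (i in 1:50) {
    g <- data.frame(gene = "g", region = "forebrain", dose = c(100, 250, 100, 250),
                    r = runif(4, -1, 1))
    signed <- cholscreen:::select_from_grid(g, screen_config(min_conditions = 2))
    absolute <- cholscreen:::select_from_grid(
      g, screen_config(min_conditions = 2, use_absolute_r = TRUE))
    expect_true(all(signed %in% absolute))
  }
})

test_that("screen_correlations drops strains missing either measurement", {
  params <- sim_params(seed = 41, noise_sd = 1)
  sim <- simulate_panel(params)
  obs <- simulate_celldeath(params, sim$proteome)
  m <- build_reduction_matrix(obs, convention = "REDUCTION")
  res <- screen_correlations(sim$proteome, m, sim$truth$planted,
                             screen_config(convention = "REDUCTION"))
  # the strain without proteome coverage cannot contribute
  expect_true(all(res$grid$n == length(sim$truth$proteome_strains)))
  expect_equal(nrow(res$grid), 4L)

  # cutting the phenotype down to 2 strains starves the screen
  small <- m[1:2, , drop = FALSE]
  class(small) <- class(m); attr(small, "convention") <- attr(m, "convention")
  expect_error(screen_correlations(sim$proteome, small, sim$truth$planted,
                                   screen_config()),
               class = "insufficient_strains_error")
})

test_that("a planted noiseless linear link yields |r| = 1 and selection", {
  params <- sim_params(seed = 23, noise_sd = 0, beta_forebrain = 80,
                       beta_brainstem = 80)
  sim <- simulate_panel(params)
  obs <- simulate_celldeath(params, sim$proteome)
  m <- build_reduction_matrix(obs, convention = "REDUCTION")
  res <- screen_correlations(sim$proteome, m, sim$truth$planted,
                             screen_config(convention = "REDUCTION"))
  expect_equal(res$grid$r, rep(1, 4))
  expect_identical(res$selected, sim$truth$planted)

  # under the complementary phenotype convention the trend flips sign
  m2 <- build_reduction_matrix(obs, convention = "REMAINING")
  res2 <- screen_correlations(sim$proteome, m2, sim$truth$planted,
                              screen_config(convention = "REMAINING"))
  expect_equal(res2$grid$r, rep(-1, 4))
  expect_identical(screen_correlations(
    sim$proteome, m2, sim$truth$planted,
    screen_config(convention = "REMAINING", use_absolute_r = TRUE))$selected,
    sim$truth$planted)
})
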