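make_obs <- function(...) {
  rows <- list(...)
  celldeath_obs(do.call(rbind, lapply(rows, function(r)
    data.frame(strain = r[[1]], region = r[[2]], treatment = r[[3]],
               choline_dose = as.numeric(r[[4]]), litter_id = r[[5]],
               litter_mean = as.numeric(r[[6]]), stringsAsFactors = FALSE))))
}

test_that("litter means aggregate to strain-condition means", {
  obs <- make_obs(
    list("B6", "brainstem", "ETOH", 0, "L1", 10),
    list("B6", "brainstem", "ETOH", 0, "L2", 20),
    list("B6", "brainstem", "ETOH", 0, "L3", 30),
    list("B6", "forebrain", "ETOH", 0, "L1", 12.5))
  means <- litter_to_strain_means(obs)
  bs <- means[means$region == "brainstem", ]
  expect_equal(bs$mean_cell_death, 20)
  expect_equal(bs$n_litters, 3L)
  fb <- means[means$region == "forebrain", ]
  expect_equal(fb$mean_cell_death, 12.5)
  expect_equal(fb$n_litters, 1L)
})

test_that("aggregation is invariant to litter order", {
  params <- sim_params(seed = 5)
  sim <- simulate_panel(params)
  obs <- simulate_celldeath(params, sim$proteome)
  shuffled <- obs[sample(nrow(obs)), ]
  expect_equal(litter_to_strain_means(obs), litter_to_strain_means(shuffled))
})

test_that("control pooling is litter-weighted across choline doses", {
  obs <- make_obs(
    list("B6", "brainstem", "MD", 0, "L1", 20),
    list("B6", "brainstem", "MD", 0, "L2", 20),
    list("B6", "brainstem", "MD", 100, "L1", 24))
  means <- litter_to_strain_means(obs)
  expect_equal(pool_controls(means, "B6", "brainstem"), 64 / 3)

  only0 <- litter_to_strain_means(make_obs(
    list("B6", "brainstem", "MD", 0, "L1", 18),
    list("B6", "brainstem", "MD", 0, "L2", 22)))
  expect_equal(pool_controls(only0, "B6", "brainstem"), 20)

  expect_error(pool_controls(means, "B6", "forebrain"),
               class = "missing_group_error")
})

test_that("percent reduction follows the control-normalized ratio", {
  expect_equal(percent_reduction(20, 40, 20, "REDUCTION"), 100)  # full rescue
  expect_equal(percent_reduction(40, 40, 20, "REDUCTION"), 0)    # no rescue
  expect_equal(percent_reduction(25, 40, 20, "REMAINING"), 25)
  expect_equal(percent_reduction(25, 40, 20, "REDUCTION"), 75)
  expect_error(percent_reduction(25, 20, 20), class = "degenerate_denominator_error")
})

test_that("REMAINING and REDUCTION conventions sum to 100 exactly", {
  set.seed(42)
  for (i in 1:50) {
    md <- runif(1, 5, 30); e0 <- md + runif(1, 1, 40); ce <- runif(1, 0, 60)
    expect_equal(percent_reduction(ce, e0, md, "REMAINING") +
                   percent_reduction(ce, e0, md, "REDUCTION"), 100,
                 tolerance = 1e-12)
  }
})

test_that("percent reduction is invariant under positive affine rescaling", {
  set.seed(7)
  for (i in 1:25) {
    ce <- runif(1, 0, 50); md <- runif(1, 5, 30); e0 <- md + runif(1, 1, 40)
    a <- runif(1, 0.1, 10); b <- runif(1, -5, 5)
    expect_equal(percent_reduction(a * ce + b, a * e0 + b, a * md + b),
                 percent_reduction(ce, e0, md))
  }
})

test_that("the reduction matrix covers strains x region-dose cells", {
  params <- sim_params(seed = 9, n_strains = 2, noise_sd = 1)
  sim <- simulate_panel(params)
  obs <- simulate_celldeath(params, sim$proteome)
  m <- build_reduction_matrix(obs)
  expect_equal(dim(m), c(2L, 4L))
  expect_setequal(colnames(m), c("forebrain_100", "forebrain_250",
                                 "brainstem_100", "brainstem_250"))
  expect_true(all(is.finite(m)))
  expect_identical(attr(m, "convention"), "REMAINING")
})

test_that("strains lacking a required group get NA cells with a logged reason", {
  params <- sim_params(seed = 9, n_strains = 2, noise_sd = 1)
  sim <- simulate_panel(params)
  obs <- simulate_celldeath(params, sim$proteome)
  cut <- obs[!(obs$strain == "BXD01" & obs$treatment == "ETOH" &
                 obs$choline_dose == 250), ]
  m <- build_reduction_matrix(celldeath_obs(cut))
  expect_true(all(is.na(m["BXD01", c("forebrain_250", "brainstem_250")])))
  expect_true(all(is.finite(m["B6", ])))
  dr <- attr(m, "dropped")
  expect_true(any(dr$strain == "BXD01" & grepl("dose 250", dr$reason)))
})

test_that("noiseless simulation with a fixed rescue fraction gives constant cells", {
  params <- sim_params(seed = 2, noise_sd = 0, beta_forebrain = 0,
                       beta_brainstem = 0, rho_base = 0.4)
  sim <- simulate_panel(params)
  obs <- simulate_celldeath(params, sim$proteome)
  m <- build_reduction_matrix(obs, convention = "REDUCTION")
  expect_equal(unname(unclass(m)[is.finite(m)]),
               rep(60, sum(is.finite(m))))
})

test_that("zero ethanol effect in the observed groups is a degenerate denominator", {
  obs <- make_obs(
    list("B6", "brainstem", "MD", 0, "L1", 20),
    list("B6", "brainstem", "ETOH", 0, "L1", 20),
    list("B6", "brainstem", "ETOH", 100, "L1", 20))
  err <- tryCatch(build_reduction_matrix(obs), condition = function(e) e)
  expect_s3_class(err, "degenerate_denominator_error")
  expect_identical(err$strain, "B6")
})
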