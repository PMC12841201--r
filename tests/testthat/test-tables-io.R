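test_that("bundled tables load with the published shapes and cells", {
  expect_s3_class(fixtures$haplotypes, "haplotype_table")
  expect_equal(dim(fixtures$haplotypes), c(22L, 4L))
  expect_identical(colnames(fixtures$haplotypes), c("B6", "BXD51", "BXD73", "BXD2"))
  expect_identical(fixtures$haplotypes["Aldh7a1", "BXD2"], "D2")
  expect_identical(fixtures$haplotypes["Slc44a5", "BXD51"], "R")

  expect_equal(dim(fixtures$proteome), c(5L, 4L))
  expect_true(all(is.na(unclass(fixtures$proteome)[, "BXD2"])))
  expect_equal(unclass(fixtures$proteome)["Slc44a1", "BXD73"], 12.9)
  expect_equal(unclass(fixtures$proteome)["Cept1", "B6"], 16.4)

  grid <- fixtures$correlations
  expect_equal(nrow(grid), 12L)
  expect_equal(grid$r[grid$gene == "Cept1" & grid$region == "brainstem" &
                        grid$dose == 100], 0.996)
  expect_equal(grid$r[grid$gene == "Slc44a1" & grid$region == "forebrain" &
                        grid$dose == 100], 0.521)

  expect_equal(nrow(fixtures$snps$Cept1), 53L)
  expect_equal(nrow(fixtures$snps$Slc44a1), 78L)
  expect_true(all(fixtures$snps$Cept1$category == "UNASSIGNED"))
})

test_that("haplotype reader validates codes and accepts minimal input", {
  one <- write_tmp(c("gene\tB6", "Chka\tB6"))
  tab <- read_haplotype_table(one)
  expect_equal(dim(tab), c(1L, 1L))
  expect_identical(tab["Chka", "B6"], "B6")

  bad <- write_tmp(c("gene\tB6\tBXD51", "Chka\tB6\tX2"))
  expect_error(read_haplotype_table(bad), class = "validation_error")
  expect_error(read_haplotype_table(bad), "X2")

  mixed_nv <- write_tmp(c("gene\tB6\tBXD51", "Chka\tNV\tB6"))
  expect_error(read_haplotype_table(mixed_nv), class = "validation_error")

  expect_error(read_haplotype_table(tempfile()), class = "format_error")
})

test_that("proteome reader maps n/a to missing and rejects bad numerics", {
  hdr <- "gene\tB6\tBXD51\tBXD73"
  tab <- read_proteome_table(write_tmp(c(hdr, "Cept1\t16.4\tn/a\t16.2")))
  expect_true(is.na(unclass(tab)["Cept1", "BXD51"]))
  expect_equal(unclass(tab)["Cept1", "B6"], 16.4)

  empty <- read_proteome_table(write_tmp(hdr))
  expect_equal(nrow(empty), 0L)

  comma <- write_tmp(c(hdr, "Cept1\t12,7\t16.4\t16.2"))
  expect_error(read_proteome_table(comma), class = "format_error")
  expect_error(read_proteome_table(comma), "12,7")
})

test_that("cell-death reader enforces record validity and flags odd doses", {
  hdr <- "strain\tregion\ttreatment\tcholine_dose\tlitter_id\tlitter_mean"
  obs <- read_celldeath_table(write_tmp(c(hdr, "B6\tbrainstem\tETOH\t0\tL1\t12.5")))
  expect_equal(nrow(obs), 1L)
  expect_equal(obs$litter_mean, 12.5)

  expect_error(
    read_celldeath_table(write_tmp(c(hdr, "B6\tbrainstem\tETOH\t0\tL1\t-3"))),
    class = "validation_error")
  expect_error(
    read_celldeath_table(write_tmp(c(hdr,
      "B6\tbrainstem\tETOH\t0\tL1\t12.5", "B6\tbrainstem\tETOH\t0\tL1\t13"))),
    class = "validation_error")
  expect_message(
    read_celldeath_table(write_tmp(c(hdr, "B6\tbrainstem\tETOH\t75\tL1\t12.5"))),
    "outside the 0/100/250 design")
})

test_that("GWAS reader normalizes typeset scientific notation", {
  expect_equal(fixtures$snps$Cept1$p_value[1], 0.0301)  # published as 3.01 x 10^-2
  expect_equal(min(fixtures$snps$Cept1$p_value), 3e-21)

  path <- write_tmp(c("variant\tphenotype\tp",
                      "rs1\theight\t2.36 \u00d7 10^\u22125^",
                      "rs2\theight\t0.0301"))
  rec <- read_gwas_table(path)
  expect_equal(rec$p_value, c(2.36e-5, 0.0301))

  expect_error(read_gwas_table(write_tmp(c("variant\tphenotype\tp",
                                           "rs1\theight\t1.5"))),
               class = "validation_error")
})

test_that("scientific-notation pre-pass is idempotent", {
  raw <- c("3.01 \u00d7 10^\u22122^", "4.00 x 10^-10", "0.05", "1e-3")
  once <- normalize_scientific(raw)
  expect_identical(normalize_scientific(once), once)
  expect_equal(as.numeric(once), c(3.01e-2, 4e-10, 0.05, 1e-3))
})

test_that("write-then-read round-trips tables exactly", {
  hp <- tempfile(fileext = ".tsv")
  write_haplotype_table(fixtures$haplotypes, hp)
  expect_identical(unclass(read_haplotype_table(hp)), unclass(fixtures$haplotypes))

  pp <- tempfile(fileext = ".tsv")
  write_proteome_table(fixtures$proteome, pp)
  expect_equal(unclass(read_proteome_table(pp)), unclass(fixtures$proteome))

  params <- sim_params(seed = 11)
  sim <- simulate_panel(params)
  obs <- simulate_celldeath(params, sim$proteome)
  cp <- tempfile(fileext = ".tsv")
  write_celldeath_table(obs, cp)
  back <- read_celldeath_table(cp)
  expect_equal(back$litter_mean, obs$litter_mean)
  expect_identical(back$strain, obs$strain)

  gw <- simulate_gwas(params, 50)
  gp <- tempfile(fileext = ".tsv")
  write_gwas_table(gw, gp)
  expect_equal(read_gwas_table(gp)$p_value, gw$p_value)
})

test_that("generator-written cell-death files carry one row per litter", {
  params <- sim_params(seed = 3, litters_min = 5, litters_max = 5)
  sim <- simulate_panel(params)
  obs <- simulate_celldeath(params, sim$proteome)
  grp <- table(obs$strain, obs$region, obs$treatment, obs$choline_dose)
  expect_true(all(grp[grp > 0] == 5))
})
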