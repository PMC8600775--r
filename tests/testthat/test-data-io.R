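test_that("delimited round trip preserves a well-formed dataset", {
  dat <- tiny_covariates()
  dat$eq5d <- c(1, 0.883, 0.516, -0.181, 0.725, 0.62)
  path <- withr::local_tempfile(fileext = ".csv")
  write_mapping_data(dat, path)
  back <- read_mapping_data(path)
  expect_equal(nrow(back), nrow(dat))
  expect_equal(back$eq5d, dat$eq5d)
  expect_equal(back$global_health, dat$global_health)
})

test_that("schema and range violations are rejected", {
  dat <- tiny_covariates()
  dat$eq5d <- 0.5
  path <- withr::local_tempfile(fileext = ".csv")

  write_mapping_data(dat[, setdiff(names(dat), "global_health")], path)
  expect_error(read_mapping_data(path), "global_health")

  bad <- dat
  bad$physical_f[2] <- 105
  write_mapping_data(bad, path)
  expect_error(read_mapping_data(path), "out of \\[0, 100\\]")

  bad <- dat
  bad$eq5d[1] <- 0.95 # inside the infeasible gap
  write_mapping_data(bad, path)
  expect_error(read_mapping_data(path), "feasible")

  txt <- readr::read_file(path)
  writeLines(sub("0.95", "abc", txt), path)
  expect_error(read_mapping_data(path), "non-numeric|feasible")
})

test_that("missing values survive the round trip as NA", {
  dat <- tiny_covariates()
  dat$eq5d <- 0.6
  dat$fatigue[3] <- NA
  dat$eq5d[5] <- NA
  path <- withr::local_tempfile(fileext = ".csv")
  write_mapping_data(dat, path)
  back <- read_mapping_data(path)
  expect_true(is.na(back$fatigue[3]))
  expect_true(is.na(back$eq5d[5]))
})

test_that("column_map renames file columns to canonical names", {
  dat <- tiny_covariates()
  dat$eq5d <- 0.7
  names(dat)[names(dat) == "global_health"] <- "QL"
  path <- withr::local_tempfile(fileext = ".csv")
  write_mapping_data(dat, path)
  back <- read_mapping_data(path, column_map = c(global_health = "QL"))
  expect_true("global_health" %in% names(back))
})

test_that("complete-case filter drops exactly the incomplete rows", {
  dat <- tiny_covariates(10L)
  dat$eq5d <- seq(0.1, 0.8, length.out = 10)
  dat$fatigue[4] <- NA
  res <- filter_complete_cases(dat)
  expect_equal(res$report$n_dropped, 1L)
  expect_equal(res$report$pct_dropped, 10)
  expect_equal(nrow(res$data), 9L)
  # retained rows are bit-identical
  expect_identical(res$data, dat[-4, ])

  res2 <- filter_complete_cases(dat[-4, ])
  expect_equal(res2$report$n_dropped, 0L)
  expect_equal(res2$report$pct_dropped, 0)
  expect_identical(res2$data, dat[-4, ])

  all_na <- dat
  all_na$eq5d <- NA_real_
  expect_warning(filter_complete_cases(all_na), "no complete cases")
})

test_that("design matrices implement the /100 rescaling and blocks", {
  dat <- tiny_covariates(3L)
  for (s in qlq_scales()) dat[[s]] <- c(0, 50, 100)
  dat$age <- c(54, 60, 70)
  dat$eq5d <- c(0.2, 0.5, 0.8)
  d <- build_design(dat)
  expect_equal(unname(d$X[1, ]), c(1, rep(0, 15), 54))
  expect_equal(unname(d$Z[2, ]), c(1, 0.5, 0.25))
  expect_equal(unname(d$Z[3, ]), c(1, 1, 1))
  expect_equal(unname(d$X2[, "age_sq"]), dat$age^2)
  expect_equal(ncol(d$X), 17L)
  expect_equal(ncol(d$Z), 3L)
  expect_equal(ncol(d$X2), 18L)
  # rescaling is exactly score/100
  expect_equal(d$X[, "pain"], dat$pain / 100, ignore_attr = TRUE)
})

test_that("constant covariate columns trigger a collinearity warning", {
  dat <- tiny_covariates(4L)
  dat$diarrhoea <- 5
  dat$eq5d <- 0.5
  expect_warning(build_design(dat), "constant covariate")
})
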