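test_that("the default benchmark grid yields 40 tagged observations", {
  suite <- make_grid_suite(seed = 1, sample_times = c(0, 50, 100),
                          cparams = chemostat_params(volume = 1,
                                                     inoculum = 1e5))
  expect_length(suite$observations, 40)
  expect_equal(nrow(suite$design), 40)
  # every observation is tagged with its generating model and truth
  for (rec in suite$observations[c(1, 20, 40)]) {
    expect_true(rec$model %in% c("wf", "chemo"))
    expect_true(rec$delta_c %in% c(1e-5, 1e-7))
    expect_true(rec$s_c %in% c(0.001, 0.1))
    expect_s3_class(rec$trajectory, "cnv_trajectory")
  }
  # counting contract and determinism
  s1 <- make_grid_suite(models = "wf", n_rep = 1, seed = 4,
                        sample_times = c(0, 100))
  expect_length(s1$observations, 4)
  s2 <- make_grid_suite(models = "wf", n_rep = 1, seed = 4,
                        sample_times = c(0, 100))
  expect_identical(lapply(s1$observations, `[[`, "trajectory"),
                   lapply(s2$observations, `[[`, "trajectory"))
})

test_that("DFE suites record their drawn truths and clip extreme draws", {
  d <- gamma_dfe(1, 0.1)
  suite <- make_dfe_suite(d, 1e-5, seed = 7)
  expect_length(suite$observations, 11)
  s_drawn <- sample_dfe(d, 11, seed = 7)
  expect_equal(sapply(suite$observations, `[[`, "s_c"),
               pmin(pmax(s_drawn, 1e-4), 0.4))
  # a wide DFE triggers the support clip with a warning
  expect_warning(make_dfe_suite(gamma_dfe(5, 0.5), 1e-5, seed = 8),
                 "clipped")
})

test_that("the pseudo-empirical bundle reproduces the study layout", {
  dir <- tempfile("bundle")
  files <- make_pseudo_empirical_bundle(dir, seed = 5)
  expect_equal(files$name, c(sprintf("gln_%02d", 1:9), "bc01", "bc02"))
  expect_true(all(file.exists(files$csv)))
  expect_true(all(file.exists(files$truth)))
  # round trip through the CSV reader, invariants intact
  tr <- read_trajectory(files$csv[1])
  expect_equal(nrow(tr), 25)
  expect_equal(max(tr$generation), 267)
  expect_true(all(tr$proportion >= 0 & tr$proportion <= 1))
  # truth sidecars match the generating parameters, never in the CSV
  truth <- jsonlite::read_json(files$truth[1], simplifyVector = TRUE)
  expect_equal(truth$delta_c, 10^-4.3)
  expect_false("s_c" %in% names(read.csv(files$csv[1])))
  # truncation keeps only the early grid points
  cut <- truncate_trajectory(tr, 116)
  expect_true(all(cut$generation <= 116))
  expect_gt(nrow(cut), 3)
  # regeneration with the same seed is byte-identical
  dir2 <- tempfile("bundle2")
  files2 <- make_pseudo_empirical_bundle(dir2, seed = 5)
  expect_identical(readLines(files$csv[3]), readLines(files2$csv[3]))
})
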