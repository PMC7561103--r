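test_that("titration tables round-trip through CSV bit-exactly", {
  lanes <- sim_lanes(seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_titration(lanes, path)
  back <- read_titration(path)
  expect_equal(back, lanes)
  expect_tibble_rows(back, 15)
})

test_that("schema and lane validation name the offending column or row", {
  lanes <- sim_lanes(seed = 5)
  expect_error(validate_titration(dplyr::select(lanes, -"band2")),
               regexp = "band2", class = "emsacoop_schema_error")
  bad <- lanes
  bad$band0[4] <- -1
  expect_error(validate_titration(bad), regexp = "4",
               class = "emsacoop_validation_error")
  zero <- lanes
  zero[7, c("band0", "band1", "band2")] <- 0
  expect_error(validate_titration(zero), regexp = "7",
               class = "emsacoop_validation_error")
  expect_error(read_titration(file.path(tempdir(), "nope.csv")),
               class = "emsacoop_io_error")
})

test_that("lane normalization gives scale-invariant fractions summing to 1", {
  lane <- tibble::tibble(condition = "x", conc_nM = 40, replicate = 1,
                         band0 = 30, band1 = 50, band2 = 20)
  n <- normalize_lanes(lane)
  expect_equal(c(n$p0, n$p1, n$p2), c(0.3, 0.5, 0.2))
  only_free <- dplyr::mutate(lane, band0 = 7, band1 = 0, band2 = 0)
  expect_equal(unlist(normalize_lanes(only_free)[, c("p0", "p1", "p2")]),
               c(p0 = 1, p1 = 0, p2 = 0))
  uneven <- dplyr::mutate(lane, band0 = 1, band1 = 1, band2 = 2)
  expect_equal(unlist(normalize_lanes(uneven)[, c("p0", "p1", "p2")]),
               c(p0 = 0.25, p1 = 0.25, p2 = 0.5))
  for (k in c(0.01, 3, 1e5)) {
    scaled <- dplyr::mutate(lane, dplyr::across(dplyr::starts_with("band"),
                                                ~ .x * k))
    expect_equal(normalize_lanes(scaled)[, c("p0", "p1", "p2")],
                 n[, c("p0", "p1", "p2")])
  }
})

test_that("replicate summaries average normalized fractions per concentration", {
  two_reps <- tibble::tibble(
    condition = "x", conc_nM = 40, replicate = 1:2,
    band0 = c(0.2, 0.4) * 100, band1 = c(0.5, 0.5) * 100,
    band2 = c(0.3, 0.1) * 100
  )
  s <- summarize_replicates(two_reps)
  expect_equal(c(s$mean0, s$mean1, s$mean2), c(0.3, 0.5, 0.2))
  expect_equal(s$mean0 + s$mean1 + s$mean2, 1, tolerance = 1e-9)
  expect_equal(s$sd1, 0)
  expect_false(s$single_replicate)

  single <- dplyr::filter(two_reps, replicate == 1)
  s1 <- summarize_replicates(single)
  expect_true(s1$single_replicate)
  expect_equal(c(s1$sd0, s1$sd1, s1$sd2), c(0, 0, 0))

  identical_reps <- dplyr::mutate(two_reps, band0 = 20, band1 = 50,
                                  band2 = 30)
  s2 <- summarize_replicates(identical_reps)
  expect_equal(c(s2$sd0, s2$sd1, s2$sd2), c(0, 0, 0))

  expect_error(summarize_replicates(two_reps[0, ]),
               class = "emsacoop_validation_error")
  multi <- dplyr::mutate(two_reps, condition = c("a", "b"))
  expect_error(summarize_replicates(multi),
               class = "emsacoop_validation_error")
})

test_that("XLSX adapter applies column mappings before validation", {
  skip_if_not_installed("readxl")
  # readxl cannot write; exercise the mapping/validation path via mocking
  sheet_data <- tibble::tibble(
    probe = "wt", `RBPj (nM)` = c(2.5, 10, 40), rep = 1,
    free = c(90, 60, 20), shift1 = c(8, 30, 40), shift2 = c(2, 10, 40)
  )
  local_mocked_bindings(
    read_excel = function(path, sheet = 1, ...) sheet_data,
    .package = "readxl"
  )
  path <- withr::local_tempfile(fileext = ".xlsx")
  file.create(path)
  got <- read_titration_xlsx(
    path,
    mapping = c(condition = "probe", conc_nM = "RBPj (nM)", replicate = "rep",
                band0 = "free", band1 = "shift1", band2 = "shift2")
  )
  expect_tibble_rows(got, 3)
  expect_named(got, c("condition", "conc_nM", "replicate",
                      "band0", "band1", "band2"))
  expect_error(read_titration_xlsx(path, mapping = c(band2 = "absent")),
               class = "emsacoop_schema_error")
})
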