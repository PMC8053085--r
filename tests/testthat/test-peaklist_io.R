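test_that("sparky peak lists parse row by row", {
  path <- write_sparky_fixture(c(" Assignment  w1  w2  Height",
                                 "G27N-H 108.200 8.450 5.1e6",
                                 "A12N-H 122.900 7.900 4.0e6"))
  pl <- read_peak_list(path)
  expect_s3_class(pl, "peak_list")
  expect_equal(nrow(pl$peaks), 2)
  g27 <- pl$peaks[pl$peaks$residue_id == 27, ]
  expect_equal(g27$shift_n, 108.2)
  expect_equal(g27$shift_h, 8.45)
  expect_equal(g27$intensity, 5.1e6)
  expect_equal(g27$atom_group, "bb")
})

test_that("empty files, bad rows and duplicate assignments are handled", {
  empty <- write_sparky_fixture(character())
  expect_warning(pl <- read_peak_list(empty), "empty")
  expect_equal(nrow(pl$peaks), 0)

  dup <- write_sparky_fixture(c("G27N-H 108.2 8.45 5.1e6",
                                "G27N-H 108.3 8.40 2.0e6"))
  expect_error(read_peak_list(dup), "duplicate")

  bad <- write_sparky_fixture(c("G27N-H 108.2 8.45 5.1e6",
                                "A12N-H 108.2 oops 5.1e6"))
  expect_error(read_peak_list(bad), ":2")
  expect_error(read_peak_list(tempfile()), "not found")
})

test_that("side-chain peaks are carried with their atom group", {
  path <- write_sparky_fixture(c("W84NE1-HE1 129.500 10.100 3.0e6",
                                 "W84N-H 120.000 8.000 3.0e6"))
  pl <- read_peak_list(path)
  expect_setequal(pl$peaks$atom_group, c("bb", "sc"))
  expect_equal(pl$peaks$residue_id, c(84L, 84L))
})

test_that("read/write/read round trips preserve shifts and intensities", {
  pl <- random_pl(30, seed = 7)
  for (dialect in c("sparky", "csv")) {
    path <- tempfile()
    write_peak_list(pl, path, dialect)
    back <- read_peak_list(path, dialect)
    expect_equal(round(back$peaks$shift_n, 3), round(pl$peaks$shift_n, 3))
    expect_equal(round(back$peaks$shift_h, 3), round(pl$peaks$shift_h, 3))
    expect_equal(signif(back$peaks$intensity, 6), signif(pl$peaks$intensity, 6))
    # a second round trip is exact: the format is now a fixed point
    path2 <- tempfile()
    write_peak_list(back, path2, dialect)
    again <- read_peak_list(path2, dialect)
    expect_identical(again$peaks$shift_n, back$peaks$shift_n)
  }
})

test_that("match_peaks pairs identical lists with zero distance", {
  pl <- random_pl(20, seed = 3)
  m <- match_peaks(pl, pl)
  expect_true(all(m$matched))
  expect_equal(m$distance, rep(0, 20))
  expect_equal(m$residue_id, pl$peaks$residue_id)
})

test_that("match_peaks positional matching honours the tolerance box", {
  ref <- make_pl(1, shift_n = 115, shift_h = 8.0, intensity = 1e6)
  # displaced unassigned query peak inside (0.05, 0.5) tolerances
  q <- suppressWarnings(peak_list(data.frame(
    residue_id = NA_integer_, atom_group = "bb",
    shift_n = 115.1, shift_h = 8.02, intensity = 9e5)))
  m <- match_peaks(ref, q)
  expect_true(m$matched)
  expect_equal(m$distance, sqrt(0.02^2 + (0.1 / 5)^2))

  # and outside the box: flagged absent, not an error
  q_far <- suppressWarnings(peak_list(data.frame(
    residue_id = NA_integer_, atom_group = "bb",
    shift_n = 116, shift_h = 8.02, intensity = 9e5)))
  m2 <- match_peaks(ref, q_far)
  expect_false(m2$matched)
  expect_true(is.na(m2$qry_intensity))
})

test_that("greedy matching never reuses a reference peak", {
  set.seed(11)
  ref <- random_pl(10, seed = 5)
  # two unassigned query peaks near the same reference position
  q <- suppressWarnings(peak_list(data.frame(
    residue_id = NA_integer_, atom_group = "bb",
    shift_n = ref$peaks$shift_n[1] + c(0.01, 0.03),
    shift_h = ref$peaks$shift_h[1] + c(0.005, 0.01),
    intensity = c(1e6, 2e6))))
  m <- match_peaks(ref, q)
  expect_lte(sum(m$matched), 1)
  # closest candidate wins
  expect_equal(m$qry_intensity[m$matched], 1e6)
})

test_that("series manifests read, sort and validate", {
  dir <- tempfile(); dir.create(dir)
  tt <- c(0, 0.5, 1, 1.5, 2)
  files <- sprintf("s%d.list", seq_along(tt))
  for (f in files) {
    writeLines("G27N-H 108.200 8.450 5.1e6", file.path(dir, f))
  }
  manifest <- file.path(dir, "manifest.yaml")
  # deliberately out of order: the series must come back sorted
  yaml::write_yaml(list(series = list(time_hours = rev(tt),
                                      files = rev(files))), manifest)
  s <- read_series(manifest)
  expect_length(s, 5)
  expect_equal(s$time_hours, tt)

  yaml::write_yaml(list(series = list(time_hours = c(0, 0.5, 0.5),
                                      files = files[1:3])), manifest)
  expect_error(read_series(manifest), "duplicate")

  yaml::write_yaml(list(series = list(time_hours = c(0, 0.5),
                                      files = c(files[1], "absent.list"))),
                   manifest)
  expect_error(read_series(manifest), "0.5")
})

test_that("write_series and read_series are inverse", {
  g <- generate_kinetics_series(kinetics_sim_spec(seed = 2))
  dir <- tempfile()
  manifest <- write_series(g$series, dir)
  back <- read_series(manifest)
  expect_equal(back$time_hours, g$series$time_hours)
  for (i in seq_along(back$time_hours)) {
    expect_equal(nrow(back$peak_lists[[i]]$peaks),
                 nrow(g$series$peak_lists[[i]]$peaks))
  }
})
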