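test_that("Bonn ASCII reader parses one integer per line", {
  path <- tempfile()
  writeLines(c("12", "-5", "7"), path)
  r <- read_bonn_ascii(path, "healthy")
  expect_identical(r$amplitudes, c(12L, -5L, 7L))
  expect_equal(r$sampling_rate, 173.61)
  expect_identical(r$class_label, "healthy")
  unlink(path)
})

test_that("reader tolerates blank lines and whitespace", {
  path <- tempfile()
  writeLines(c("  12 ", "", "-5", "7", ""), path)
  expect_identical(read_bonn_ascii(path, "ictal")$amplitudes,
                   c(12L, -5L, 7L))
  unlink(path)
})

test_that("reader reports the offending line and rejects empty files", {
  path <- tempfile()
  writeLines(c("abc", "5"), path)
  expect_error(read_bonn_ascii(path, "healthy"), "line 1")
  writeLines(c("5", "", "1.5"), path)
  expect_error(read_bonn_ascii(path, "healthy"), "line 3")
  writeLines(character(0), path)
  expect_error(read_bonn_ascii(path, "healthy"), "empty")
  expect_error(read_bonn_ascii(tempfile(), "healthy"), "not found")
  unlink(path)
})

test_that("write/read round-trip is exact for generated records", {
  for (s in 1:3) {
    ds <- generate_synthetic_dataset(tiny_config(records_per_class = 1,
                                                 seed = s))
    path <- tempfile()
    write_bonn_ascii(ds[[1]], path)
    back <- read_bonn_ascii(path, ds[[1]]$class_label)
    expect_identical(back$amplitudes, ds[[1]]$amplitudes)
    unlink(path)
  }
  # minimal record
  path <- tempfile()
  write_bonn_ascii(eeg_record(0, "healthy"), path)
  expect_identical(readLines(path), "0")
  unlink(path)
})

test_that("synthetic dataset has the requested shape and is seed-deterministic", {
  cfg <- tiny_config(records_per_class = 3, record_length = 512)
  ds <- generate_synthetic_dataset(cfg)
  expect_length(ds, 6)
  expect_true(all(vapply(ds, function(r) length(r$amplitudes), 1L) == 512L))
  labs <- vapply(ds, function(r) r$class_label, "")
  expect_identical(sum(labs == "healthy"), 3L)
  ds2 <- generate_synthetic_dataset(cfg)
  expect_identical(ds, ds2)
  ds3 <- generate_synthetic_dataset(tiny_config(records_per_class = 3,
                                                record_length = 512,
                                                seed = 99))
  expect_false(identical(ds, ds3))
  expect_error(synthetic_config(ictal_amplitude_ratio = 0.5), "ratio")
  expect_error(synthetic_config(healthy_band = c(8, 200)), "Nyquist")
})

test_that("synthetic classes separate by >= 3 pooled SDs on spread features", {
  ds <- generate_synthetic_dataset(tiny_config(records_per_class = 20,
                                               record_length = 1024))
  per_record <- function(stat) vapply(ds, function(r) stat(r$amplitudes), 1)
  labs <- vapply(ds, function(r) r$class_label, "")
  for (stat in list(sd, function(x) diff(range(x)))) {
    v <- per_record(stat)
    h <- v[labs == "healthy"]; i <- v[labs == "ictal"]
    pooled <- sqrt((stats::var(h) + stats::var(i)) / 2)
    expect_gt(abs(mean(i) - mean(h)) / pooled, 3)
  }
})

test_that("dataset directory layout round-trips with a manifest", {
  root <- tempfile()
  ds <- generate_synthetic_dataset(tiny_config(records_per_class = 2,
                                               record_length = 128))
  write_bonn_dataset(ds, root)
  expect_true(file.exists(file.path(root, "manifest.json")))
  manifest <- jsonlite::read_json(file.path(root, "manifest.json"),
                                  simplifyVector = TRUE)
  expect_identical(nrow(manifest), 4L)
  back <- read_bonn_dataset(root)
  expect_length(back, 4)
  amp <- function(d) lapply(d, `[[`, "amplitudes")
  expect_setequal(vapply(back, function(r) r$record_id, ""),
                  vapply(ds, function(r) r$record_id, ""))
  ids <- vapply(back, function(r) r$record_id, "")
  for (r in ds) expect_identical(back[[which(ids == r$record_id)]]$amplitudes,
                                 r$amplitudes)
  unlink(root, recursive = TRUE)
})
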