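test_that("waveform matrices round-trip through delimited text", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "waves.csv")
  set.seed(61)
  M <- matrix(rnorm(5 * 64), 5, 64)
  write_waveform_matrix(M, f)
  M2 <- read_waveform_matrix(f)
  expect_equal(dim(M2), c(5L, 64L))
  expect_equal(M2, M, tolerance = 1e-6)
  # tab-separated is autodetected
  ft <- file.path(dir, "waves.tsv")
  write_waveform_matrix(M, ft, sep = "\t")
  expect_equal(read_waveform_matrix(ft), M, tolerance = 1e-6)
  # empty file and ragged rows are format errors naming the problem
  fe <- file.path(dir, "empty.csv")
  writeLines(character(0), fe)
  expect_error(read_waveform_matrix(fe), "no spikes")
  fr <- file.path(dir, "ragged.csv")
  writeLines(c("1,2,3", "4,5"), fr)
  expect_error(read_waveform_matrix(fr), "row 2")
})

test_that("sort results round-trip through JSON", {
  bank <- make_templates(3, "low", seed = 62)
  ws <- generate_waveform_set(bank, 40, noise_level = 0.1, seed = 63)
  res <- lda_dp_sort(ws$waves)
  dir <- withr::local_tempdir()
  f <- file.path(dir, "result.json")
  write_sort_result(res, f)
  res2 <- read_sort_result(f)
  expect_equal(res2$labels, res$labels)
  expect_equal(res2$pre_merge_labels, res$pre_merge_labels)
  expect_equal(res2$n_clusters, res$n_clusters)
  expect_equal(res2$iterations, res$iterations)
  expect_equal(res2$converged, res$converged)
  expect_equal(nrow(res2$merge_report$merges), nrow(res$merge_report$merges))
  expect_equal(res2$config$alpha, res$config$alpha)
  expect_equal(as.matrix(res2$W), unclass(res$W), ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("run configurations round-trip through JSON", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "config.json")
  cfg <- run_config(K_init = 5, t = 0.012, alpha = 1.8)
  write_run_config(cfg, f)
  cfg2 <- read_run_config(f)
  expect_equal(cfg2, cfg)
})

test_that("wave_clus-style MAT files round-trip with ground truth", {
  bank <- make_templates(2, "low", seed = 64)
  rec <- generate_recording(bank, rates = 5, duration = 2,
                            noise_level = 0.1, seed = 65)
  dir <- withr::local_tempdir()
  f <- file.path(dir, "rec.mat")
  write_waveclus_dataset(rec, f)
  rec2 <- suppressMessages(read_waveclus_dataset(f))
  expect_equal(rec2$trace, rec$trace, tolerance = 1e-12)
  expect_identical(rec2$gt_times, rec$gt_times)
  expect_identical(rec2$gt_labels, rec$gt_labels)
  expect_equal(rec2$fs, rec$fs)
})

test_that("the wave_clus reader enforces the field contract", {
  dir <- withr::local_tempdir()
  # missing spike_class: labels simply absent, no error
  f1 <- file.path(dir, "noclass.mat")
  write_mat5(list(data = matrix(rnorm(100), 1),
                  spike_times = matrix(c(10, 50), 1)), f1)
  b1 <- suppressMessages(read_waveclus_dataset(f1))
  expect_null(b1$gt_labels)
  expect_equal(b1$gt_times, c(10L, 50L))
  # missing data field is a format error naming the field
  f2 <- file.path(dir, "nodata.mat")
  write_mat5(list(trace = matrix(rnorm(10), 1)), f2)
  expect_error(read_waveclus_dataset(f2), "'data'")
  # mismatched ground-truth lengths are a consistency error
  f3 <- file.path(dir, "mismatch.mat")
  write_mat5(list(data = matrix(rnorm(100), 1),
                  spike_times = matrix(1:10, 1),
                  spike_class = matrix(1:9, 1)), f3)
  expect_error(suppressMessages(read_waveclus_dataset(f3)), "consistency")
  # millisecond convention is converted to samples
  f4 <- file.path(dir, "ms.mat")
  write_mat5(list(data = matrix(rnorm(100), 1), sr = matrix(1000, 1, 1),
                  spike_times = matrix(c(10, 20), 1)), f4)
  b4 <- suppressMessages(read_waveclus_dataset(f4, time_units = "ms"))
  expect_equal(b4$gt_times, c(10L, 20L))
  expect_equal(b4$fs, 1000)
})

test_that("the MAT v5 codec handles plain and compressed numeric arrays", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "vars.mat")
  vars <- list(a = matrix(1:6 / 7, 2, 3), b = matrix(-1.5, 1, 1))
  write_mat5(vars, f)
  got <- read_mat5(f)
  expect_equal(got$a, vars$a)
  expect_equal(got$b, vars$b)
  # compressed element (the MATLAB default) via an in-memory zlib stream
  raw_el <- ldadp:::mat5_matrix_raw("z", matrix(4:1, 1))
  comp <- memCompress(raw_el, "gzip")
  con <- file(file.path(dir, "comp.mat"), "wb")
  desc <- charToRaw(formatC("MATLAB 5.0 MAT-file, test", width = -116))
  writeBin(desc[1:116], con)
  writeBin(raw(8), con)
  writeBin(as.integer(256), con, size = 2, endian = "little")
  writeBin(charToRaw("IM"), con)
  writeBin(as.integer(c(15, length(comp))), con, size = 4, endian = "little")
  writeBin(comp, con)
  close(con)
  got2 <- read_mat5(file.path(dir, "comp.mat"))
  expect_equal(as.numeric(got2$z), 4:1)
})
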