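test_that("RWL round trip is exact, including zero widths and decade splits", {
  set.seed(101)
  for (rep in 1:5) {
    n_series <- sample(2:4, 1)
    series <- lapply(seq_len(n_series), function(j) {
      n <- sample(15:60, 1)
      w <- round(runif(n, 0, 6), 2)
      w[sample(n, 2)] <- 0  # locally absent rings
      ring_series(sprintf("SER%02d%d", j, rep), w,
                  first_year = sample(1800:1990, 1))
    })
    tf <- tempfile(fileext = ".rwl")
    write_rwl(series, tf)
    back <- read_rwl(tf)
    expect_length(back, n_series)
    for (s in series) {
      expect_identical(back[[s$series_id]]$widths, s$widths)
      expect_identical(back[[s$series_id]]$first_year, s$first_year)
    }
    unlink(tf)
  }
})

test_that("a single decadal row parses per the format definition", {
  tf <- tempfile(fileext = ".rwl")
  writeLines("ABC01   2000   100   110   120   999", tf)
  out <- read_rwl(tf)
  expect_length(out, 1L)
  expect_equal(out$ABC01$widths, c(1.00, 1.10, 1.20))
  expect_identical(out$ABC01$first_year, 2000L)
  unlink(tf)
})

test_that("rows split at decade boundaries on write", {
  s <- ring_series("DEC01", round(seq(0.5, 1.6, length.out = 12), 2), 1995)
  tf <- tempfile(fileext = ".rwl")
  write_rwl(s, tf)
  lines <- readLines(tf)
  starts <- as.integer(vapply(strsplit(lines, "\\s+"), `[[`, "", 2))
  expect_equal(starts, c(1995L, 2000L))  # 1995-1999 then 2000-2006 (+marker)
  unlink(tf)
})

test_that("the 0.001 mm dialect with -9999 marker is auto-detected", {
  s <- ring_series("THO01", c(0.57, 9.99, 0.2), 1950)  # 999 units in 0.001 mm
  tf <- tempfile(fileext = ".rwl")
  write_rwl(s, tf, dialect = "thousandths")
  back <- read_rwl(tf)
  expect_equal(back$THO01$widths, s$widths)
  unlink(tf)
})

test_that("malformed rows, duplicates and oversized widths are errors; empty file warns", {
  tf <- tempfile(fileext = ".rwl")
  writeLines(c("ABC01   2000   100   abc   999"), tf)
  expect_error(read_rwl(tf), "malformed decade row at line 1")
  writeLines(c("ABC01   2000   100   999",
               "ABC01   2005   100   999"), tf)
  expect_error(read_rwl(tf), "duplicate series code")
  writeLines(character(), tf)
  expect_warning(out <- read_rwl(tf), "empty RWL")
  expect_length(out, 0L)
  big <- ring_series("BIG01", c(1, 12.5), 2000)  # 1250 > 998 hundredths
  expect_error(write_rwl(big, tf), "dialect maximum")
  unlink(tf)
})

test_that("ring_series enforces its invariants", {
  expect_error(ring_series("A", numeric(0), 2000), "nonempty")
  expect_error(ring_series("A", c(1, -0.5), 2000), ">= 0")
  expect_error(ring_series("A", 0.1234, 2000), "resolution")
})

make_qc_series <- function(seed = 3, n = 120, n_series = 2, flip = FALSE) {
  set.seed(seed)
  signal <- rnorm(n, 0, 0.12)
  lapply(seq_len(n_series), function(j) {
    e <- if (flip && j == 2) -signal else signal
    ring_series(sprintf("QC%02d", j), round(pmax(1.5 * (1 + e), 0.01), 2), 1890)
  })
}

test_that("identical series correlate perfectly with the leave-one-out master", {
  rep <- crossdate_qc(make_qc_series(), window_length = 30)
  expect_equal(rep$QC01$overall_r, 1.0, tolerance = 1e-10)
  expect_equal(rep$QC02$overall_r, 1.0, tolerance = 1e-10)
  expect_true(all(rep$QC01$windows$r >= -1 & rep$QC01$windows$r <= 1))
})

test_that("a mirrored series anti-correlates with the master", {
  rep <- crossdate_qc(make_qc_series(flip = TRUE), window_length = 30)
  expect_lt(rep$QC02$overall_r, -0.95)
  expect_true(length(rep$QC02$flags) > 0)  # negative windows are flagged
})

test_that("crossdating is invariant to a common positive scaling", {
  series <- make_qc_series(seed = 9, n_series = 3)
  scaled <- lapply(series, function(s) {
    s$widths <- s$widths * 4
    s
  })
  r1 <- crossdate_qc(series, window_length = 30)
  r2 <- crossdate_qc(scaled, window_length = 30)
  for (id in names(r1)) {
    expect_equal(r1[[id]]$overall_r, r2[[id]]$overall_r, tolerance = 1e-9)
    expect_equal(r1[[id]]$windows$r, r2[[id]]$windows$r, tolerance = 1e-9)
  }
})

test_that("independent white-noise series show low master correlations", {
  set.seed(77)
  series <- lapply(1:20, function(j) {
    ring_series(sprintf("WN%02d", j),
                round(pmax(rnorm(200, 1.5, 0.25), 0.01), 2), 1800)
  })
  rep <- crossdate_qc(series, window_length = 50)
  rs <- vapply(rep, `[[`, numeric(1), "overall_r")
  expect_lt(mean(abs(rs)), 0.2)
  expect_true(all(abs(rs) <= 1))
})

test_that("series with insufficient overlap are skipped with a warning", {
  s1 <- ring_series("OV01", round(runif(80, 1, 2), 2), 1900)
  s2 <- ring_series("OV02", round(runif(80, 1, 2), 2), 1900)
  s3 <- ring_series("OV03", round(runif(30, 1, 2), 2), 2050)  # no overlap
  expect_warning(rep <- crossdate_qc(list(s1, s2, s3), window_length = 40),
                 "skipped")
  expect_named(rep, c("OV01", "OV02"))
})

test_that("crossdate_table flattens reports for export", {
  tab <- crossdate_table(crossdate_qc(make_qc_series(), window_length = 30))
  expect_true(all(c("series_id", "overall_r", "window_r", "flagged") %in%
                    names(tab)))
  expect_true(all(tab$window_r >= -1 & tab$window_r <= 1))
})

test_that("the shipped synthetic example files load", {
  rwl <- system.file("extdata", "synthetic_example.rwl",
                     package = "dendrogrowth")
  series <- read_rwl(rwl)
  expect_gte(length(series), 2L)
  expect_true(all(vapply(series, function(s) all(s$widths >= 0), logical(1))))
  meta <- read_tree_meta(system.file("extdata", "synthetic_example_meta.csv",
                                     package = "dendrogrowth"))
  expect_setequal(meta$tree_id, names(series))
})
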