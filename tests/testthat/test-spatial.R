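grid10 <- grid_spec(0, 0, 1, 10, 10)

test_that("a single point yields a constant surface at its value", {
  s <- idw_interpolate(3.2, 4.1, 17, grid10)
  expect_equal(as.vector(s$values), rep(17, 100))
})

test_that("cells at sample locations take the sample value exactly", {
  # points placed exactly on two cell centers
  s <- idw_interpolate(c(0.5, 7.5), c(0.5, 2.5), c(5, 50), grid10, power = 3.7)
  expect_identical(s$values[10, 1], 5)    # (0.5, 0.5): bottom-left, north-up
  expect_identical(s$values[8, 8], 50)    # (7.5, 2.5)
})

test_that("an equidistant cell averages two points for any power", {
  g <- grid_spec(0, 0, 1, 1, 1)  # single cell centered at (0.5, 0.5)
  for (p in c(1, 2, 4)) {
    s <- idw_interpolate(c(0.5, 0.5), c(2, -1), c(10, 20), g, power = p)
    expect_equal(s$values[1, 1], 15)
  }
})

test_that("IDW stays inside the convex hull of point values", {
  set.seed(9)
  x <- runif(25, 0, 10); y <- runif(25, 0, 10); v <- rnorm(25, 100, 30)
  s <- idw_interpolate(x, y, v, grid10, power = 2)
  expect_true(all(s$values >= min(v) - 1e-9 & s$values <= max(v) + 1e-9))
})

test_that("vectorized IDW matches the naive double-loop oracle", {
  set.seed(21)
  x <- runif(20, 0, 10); y <- runif(20, 0, 10); v <- runif(20, 0, 500)
  for (p in c(1, 2)) {
    s <- idw_interpolate(x, y, v, grid10, power = p)
    expect_equal(s$values, naive_idw(x, y, v, grid10, power = p),
                 tolerance = 1e-10)
  }
})

test_that("neighborhood restriction uses only the k nearest points", {
  # one far-away outlier must not influence cells when k excludes it
  x <- c(1, 2, 100); y <- c(1, 2, 100); v <- c(10, 20, 1e6)
  g <- grid_spec(0, 0, 1, 3, 3)
  s <- idw_interpolate(x, y, v, g, k_neighbors = 2)
  expect_true(all(s$values >= 10 & s$values <= 20))
  # k = all points reduces to the unrestricted surface
  s_all <- idw_interpolate(x, y, v, g, k_neighbors = 3)
  expect_equal(s_all$values, idw_interpolate(x, y, v, g)$values)
})

test_that("coincident points are averaged before weighting", {
  s <- idw_interpolate(c(2, 2, 8), c(2, 2, 8), c(10, 30, 50), grid10)
  o <- idw_interpolate(c(2, 8), c(2, 8), c(20, 50), grid10)
  expect_equal(s$values, o$values)
  expect_error(idw_interpolate(numeric(0), numeric(0), numeric(0), grid10),
               "empty")
})

test_that("risk surfaces classify the interpolated PRI cellwise", {
  refs <- element_references()
  low <- make_samples(lapply(stats::setNames(refs$background, refs$element),
                             function(b) rep(b, 6)))
  rs <- risk_surface(low, grid10)
  expect_equal(as.vector(rs$surface$values), rep(63, 100))
  expect_true(all(rs$classes$values == 1L))  # every cell "Low risk"
  expect_equal(rs$classes$labels[1], "Low risk")

  # classification of the surface == cellwise classify of its values
  cls <- classify(classification_scheme("pri"), as.vector(rs$surface$values))
  expect_equal(as.vector(rs$classes$values), as.integer(cls))
})

test_that("a high-risk cluster dominates its own neighborhood", {
  refs <- element_references()
  lowv <- refs$background
  highv <- refs$background * 20
  n_low <- 12; n_high <- 6
  s <- data.frame(sample_id = sprintf("P%02d", 1:(n_low + n_high)),
                  area = "A",
                  x = c(runif(n_low, 0, 4), runif(n_high, 7, 9)),
                  y = c(runif(n_low, 0, 4), runif(n_high, 7, 9)),
                  stringsAsFactors = FALSE)
  for (j in seq_along(refs$element)) {
    s[[refs$element[j]]] <- c(rep(lowv[j], n_low), rep(highv[j], n_high))
  }
  rs <- risk_surface(s, grid10)
  top <- which(rs$surface$values == max(rs$surface$values), arr.ind = TRUE)[1, ]
  cx <- rs$surface$grid$x_min + (top["col"] - 0.5)
  cy <- rs$surface$grid$y_min + (rs$surface$grid$n_rows - top["row"] + 0.5)
  expect_true(cx >= 7 && cx <= 9 && cy >= 7 && cy <= 9)
})

test_that("ESRI ASCII export writes a parseable north-up grid", {
  set.seed(2)
  s <- idw_interpolate(runif(5, 0, 10), runif(5, 0, 10), runif(5), grid10)
  f <- withr::local_tempfile(fileext = ".asc")
  write_esri_ascii(s, f)
  lines <- readLines(f)
  expect_equal(lines[1], "ncols 10")
  expect_equal(lines[2], "nrows 10")
  expect_equal(lines[3], "xllcorner 0")
  expect_equal(lines[4], "yllcorner 0")
  expect_equal(lines[5], "cellsize 1")
  expect_equal(lines[6], "NODATA_value -9999")
  vals <- as.matrix(utils::read.table(f, skip = 6))
  dimnames(vals) <- NULL
  expect_equal(vals, s$values, tolerance = 1e-6)
})
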