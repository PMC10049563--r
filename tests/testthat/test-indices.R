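test_that("geo-accumulation index matches hand-computed values", {
  expect_equal(compute_igeo(1.5 * 11.2, 11.2), 0)
  # log2(106.91 / (1.5 * 11.2)) and log2(107.87 / (1.5 * 19.4))
  expect_equal(compute_igeo(106.91, 11.2), 2.66986366607, tolerance = 1e-10)
  expect_equal(compute_igeo(107.87, 19.4), 1.89020263078, tolerance = 1e-10)
  expect_error(compute_igeo(0, 11.2), "positive")
  expect_error(compute_igeo(10, -1), "positive")
})

test_that("single-factor pollution index is the background ratio", {
  expect_equal(compute_pi(19.4, 19.4), 1)
  expect_equal(round(compute_pi(107.87, 19.4), 2), 5.56)
  expect_equal(round(compute_pi(73.09, 11.2), 2), 6.53)
  expect_equal(compute_pi(0, 19.4), 0)  # zero concentration is legal here
  expect_error(compute_pi(10, 0), "positive")
})

test_that("risk coefficient is the toxicity-weighted ratio", {
  expect_equal(compute_eri(11.2, 11.2, 10), 10)
  expect_equal(compute_eri(106.91, 11.2, 10), 95.4553571429, tolerance = 1e-10)
  expect_equal(compute_eri(0.03, 0.02, 40), 60)
  expect_error(compute_eri(1, 1, 0.5), ">= 1")
})

test_that("summed risk index reproduces the worked composite cases", {
  # every concentration at background: PRI = sum of toxicity coefficients
  base <- compute_pri(background_vector())
  expect_equal(base$pri, 63)
  expect_equal(as.character(base$class), "Low risk")

  worked <- compute_pri(area_mean_vector("A"))
  expect_equal(worked$pri, 189.79476358, tolerance = 1e-9)
  expect_equal(as.character(worked$class), "Considerable risk")

  halved <- compute_pri(area_mean_vector("A") / 2)
  expect_equal(halved$pri, worked$pri / 2)  # linearity of the sum

  expect_error(compute_pri(background_vector()[-(2:3)]), "Cu, Cr")
})

test_that("indices are linear / log-linear in concentration", {
  set.seed(11)
  conc <- runif(50, 0.5, 200)
  bg <- runif(50, 0.5, 80)
  expect_equal(compute_pi(3 * conc, bg), 3 * compute_pi(conc, bg))
  expect_equal(compute_eri(3 * conc, bg, 5), 3 * compute_eri(conc, bg, 5))
  expect_equal(compute_igeo(2 * conc, bg), compute_igeo(conc, bg) + 1)
  expect_equal(compute_eri(conc, bg, 7), 7 * compute_pi(conc, bg))
})

test_that("index table matches an independent loop-based recomputation", {
  samples <- big_draw("B", n = 100, seed = 5)
  refs <- element_references()
  tbl <- build_index_table(samples, refs)

  # naive per-sample, per-element loop as the oracle
  k <- 0
  for (i in seq_len(nrow(samples))) {
    pri_acc <- 0
    for (j in seq_along(refs$element)) {
      k <- k + 1
      el <- refs$element[j]
      conc <- samples[[el]][i]
      row <- tbl$elements[k, ]
      expect_identical(row$sample_id, samples$sample_id[i])
      expect_identical(row$element, el)
      expect_equal(row$igeo, log2(conc / (1.5 * refs$background[j])),
                   tolerance = 1e-12)
      expect_equal(row$pi, conc / refs$background[j], tolerance = 1e-12)
      expect_equal(row$eri, refs$toxicity[j] * conc / refs$background[j],
                   tolerance = 1e-12)
      pri_acc <- pri_acc + refs$toxicity[j] * conc / refs$background[j]
    }
    expect_equal(tbl$samples$pri[i], pri_acc, tolerance = 1e-12)
  }
  # row-level identity Er_i = T_i * P_i (shared background)
  expect_equal(tbl$elements$eri,
               tbl$elements$pi *
                 refs$toxicity[match(tbl$elements$element, refs$element)],
               tolerance = 1e-12)
})

test_that("sample validation names the offending sample", {
  s <- make_samples(list(Zn = c(10, 10, 10)))
  s$Pb[2] <- -1
  expect_error(build_index_table(s), "S02")
  s2 <- make_samples(list(Zn = c(10, 10)))
  s2$Hg <- NULL
  expect_error(build_index_table(s2), "Hg")
  expect_error(build_index_table(make_samples(list(Zn = c(1, 1, 1)))[0, ]),
               "empty")
})

test_that("samples and index tables round-trip through CSV", {
  s <- generate_area(area_generator_config("A", n = 8), seed = 3)
  f <- withr::local_tempfile(fileext = ".csv")
  write_samples(s, f)
  s2 <- read_samples(f)
  expect_equal(s2[, names(s2)], as.data.frame(s)[, names(s2)],
               tolerance = 1e-12)

  tbl <- build_index_table(s)
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_index_table(tbl, f2)
  long <- utils::read.csv(f2)
  expect_equal(nrow(long), 48)  # 8 samples x 6 elements
  expect_true(all(c("igeo", "pi", "eri", "pri", "pri_class") %in% names(long)))
  expect_equal(unique(long$pri[long$sample_id == s$sample_id[1]]),
               tbl$samples$pri[1], tolerance = 1e-9)
})
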