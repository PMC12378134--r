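test_that("database means and SDs match hand-computed values", {
  # identical profiles: mean is the profile, SD exactly 0
  cohort <- make_cohort(matrix(rep(fixture_profile(), 4), 4, byrow = TRUE))
  ndb <- build_ndb(cohort)
  expect_equal(ndb$mean, fixture_profile())
  expect_equal(ndb$sd, rep(0, 17))
  expect_equal(ndb$n, 4L)

  # two subjects, segment 1 at 60 and 80: mean 70, sample SD 10 * sqrt(2)
  two <- make_cohort(rbind(c(60, rep(70, 16)), c(80, rep(70, 16))))
  ndb2 <- build_ndb(two)
  expect_equal(ndb2$mean[1], 70)
  expect_equal(ndb2$sd[1], sqrt(200))   # sqrt(((60-70)^2+(80-70)^2)/(2-1))

  expect_error(build_ndb(two[1, , drop = FALSE]), "at least 2")
  mixed <- two; mixed$phase <- c("early", "late")
  expect_error(build_ndb(mixed), "one phase")
})

test_that("subject-level pooling equals building on the concatenation", {
  set.seed(3)
  a <- make_cohort(matrix(runif(17 * 5, 40, 100), 5), population = "Jp")
  b <- make_cohort(matrix(runif(17 * 3, 40, 100), 3), population = "It",
                   prefix = "T")
  pooled <- combine_ndbs(a, b)
  direct <- build_ndb(rbind(a, b), label = "JpIt")
  expect_equal(pooled$mean, direct$mean)
  expect_equal(pooled$sd, direct$sd)
  expect_equal(pooled$n, 8L)
  expect_identical(pooled$population, "JpIt")

  # associativity via concatenation
  c3 <- make_cohort(matrix(runif(17 * 4, 40, 100), 4), population = "Xx",
                    prefix = "U")
  nested <- combine_ndbs(a, rbind(b, c3))
  flat <- build_ndb(rbind(a, b, c3), label = nested$population)
  expect_equal(nested$mean, flat$mean)
  expect_equal(nested$sd, flat$sd)

  # two single-subject cohorts, segment 1 at 60 and 80 -> pooled mean 70
  one_a <- make_cohort(matrix(c(60, rep(70, 16)), 1))
  one_b <- make_cohort(matrix(c(80, rep(70, 16)), 1), prefix = "T")
  expect_equal(combine_ndbs(one_a, one_b)$mean[1], 70)
})

test_that("mean deviation converts to SD by the normal closed form", {
  expect_equal(md_to_sd(0), 0)
  expect_equal(md_to_sd(1), sqrt(pi / 2))
  expect_error(md_to_sd(-0.1), "non-negative")
  # Monte-Carlo: empirical MAD-about-mean times sqrt(pi/2) recovers the SD
  set.seed(4)
  x <- rnorm(2e5, 50, 7)
  expect_equal(md_to_sd(mean(abs(x - mean(x)))), sd(x), tolerance = 0.02)
})

test_that("summary-statistics ANOVA agrees with raw-data ANOVA", {
  set.seed(5)
  raw <- lapply(c(20, 15, 25), function(n)
    matrix(rnorm(17 * n, 75, 6), n) + rnorm(1, 0, 2))
  ndbs <- lapply(seq_along(raw), function(g)
    build_ndb(make_cohort(raw[[g]], population = paste0("G", g))))
  cmp <- compare_ndbs(ndbs)
  for (s in c(1, 9, 17)) {
    vals <- unlist(lapply(raw, function(m) m[, s]))
    grp <- factor(rep(seq_along(raw), vapply(raw, nrow, integer(1))))
    a <- anova(lm(vals ~ grp))
    expect_equal(cmp$F[s], a$`F value`[1])
    expect_equal(cmp$p[s], a$`Pr(>F)`[1])
  }
})

test_that("two-group comparison reduces to the pooled-variance t test", {
  set.seed(6)
  x <- matrix(rnorm(17 * 12, 80, 5), 12)
  y <- matrix(rnorm(17 * 9, 76, 6), 9)
  cmp <- compare_ndbs(list(build_ndb(make_cohort(x, population = "A")),
                           build_ndb(make_cohort(y, population = "B"))))
  for (s in c(2, 11)) {
    tt <- t.test(x[, s], y[, s], var.equal = TRUE)
    expect_equal(cmp$F[s], unname(tt$statistic)^2)
    expect_equal(cmp$p[s], tt$p.value)
  }
  # identical summaries: F = 0, p = 1
  same <- build_ndb(make_cohort(x, population = "A"))
  expect_equal(compare_ndbs(list(same, same))$F, rep(0, 17))
  expect_equal(compare_ndbs(list(same, same))$p, rep(1, 17))
})

test_that("database CSV round trip is bit-exact and converts mean deviations", {
  set.seed(7)
  ndb <- build_ndb(make_cohort(matrix(runif(17 * 6, 40, 100), 6)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_ndb(ndb, path)
  back <- read_ndb(path)
  expect_identical(back$mean, ndb$mean)
  expect_identical(back$sd, ndb$sd)
  expect_identical(back$n, ndb$n)
  expect_false(back$md_converted)

  # sidecar declaring mean-deviation dispersion triggers conversion + flag
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  meta$dispersion <- "mean_deviation"
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  conv <- read_ndb(path)
  expect_true(conv$md_converted)
  expect_equal(conv$sd, ndb$sd * sqrt(pi / 2))
})
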