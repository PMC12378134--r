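test_that("the generator is deterministic under a fixed seed", {
  cfg <- default_generator_config()
  a <- simulate_normal(cfg, 10, "Jp", seed = 123)
  b <- simulate_normal(cfg, 10, "Jp", seed = 123)
  expect_identical(a, b)
  c <- simulate_normal(cfg, 10, "Jp", seed = 124)
  expect_false(identical(a, c))
})

test_that("zero noise collapses every subject onto the stratum mean", {
  cfg <- default_generator_config()
  cfg$sds$Jp <- rep(1e-12, 17)   # degenerate-dispersion limit
  cfg$hmr$noise_sd <- 0
  cohort <- simulate_normal(cfg, 5, "Jp", sex = "F", seed = 1)
  early <- as.matrix(cohort[cohort$phase == "early", sprintf("seg%02d", 1:17)])
  expect_equal(unname(early),
               matrix(cfg$means[["Jp.F.early"]], 5, 17, byrow = TRUE),
               tolerance = 1e-9)
  expect_equal(unique(cohort$hmr), unname(cfg$hmr$normal_mean))
})

test_that("population and sex offsets shape the stratum means as configured", {
  cfg <- default_generator_config()
  expect_equal(cfg$means[["Jp.F.early"]][4] - cfg$means[["Jp.M.early"]][4],
               cfg$male_inferior_decrement)
  expect_equal(cfg$means[["Jp.F.early"]][1] - cfg$means[["It.F.early"]][1],
               cfg$it_anterior_decrement)
  # anterior segments are untouched by the male offset
  expect_equal(cfg$means[["Jp.M.early"]][1], cfg$means[["Jp.F.early"]][1])
  # and the late phase is a uniform shift of the early phase
  expect_equal(cfg$means[["Jp.F.early"]] - cfg$means[["Jp.F.late"]],
               rep(2, 17))
})

test_that("a focal lesion subtracts its depth on exactly one territory", {
  cfg <- default_generator_config()
  # with equal RNG consumption, zero depth reproduces the same draws, so
  # the difference to a lesioned run isolates the territory effect exactly
  cfg0 <- cfg; cfg0$depth <- NULL
  cfg0$cad$depth_range <- c(0, 0)
  base <- simulate_cad(cfg0, 6, sex = "F", seed = 42)
  cfg40 <- cfg; cfg40$cad$depth_range <- c(40, 40)
  lesioned <- simulate_cad(cfg40, 6, sex = "F", seed = 42)
  segs <- sprintf("seg%02d", 1:17)
  diff_mat <- as.matrix(base[, segs]) - as.matrix(lesioned[, segs])
  set.seed(42)
  territories <- sample(c("LAD", "RCA", "LCx"), 6, replace = TRUE)
  for (i in seq_len(6)) {
    expected <- rep(0, 17)
    expected[territory_segments(territories[i])] <- 40
    expect_equal(unname(diff_mat[2 * i - 1, ]), expected)  # early row
    expect_equal(unname(diff_mat[2 * i, ]), expected)      # late row
  }
  # zero depth (and normal HMR model) is distributionally the normal model
  expect_true(all(base$label == "CAD"))
})

test_that("a diffuse decrement shifts all 17 segments equally", {
  cfg <- default_generator_config()
  cfg$dcm$decrement_range <- c(20, 20)
  cfg$dcm$noise_inflation <- 1
  cfg0 <- cfg; cfg0$dcm$decrement_range <- c(0, 0)
  base <- simulate_dcm(cfg0, 5, sex = "M", seed = 7)
  shifted <- simulate_dcm(cfg, 5, sex = "M", seed = 7)
  segs <- sprintf("seg%02d", 1:17)
  expect_equal(unname(as.matrix(base[, segs]) - as.matrix(shifted[, segs])),
               matrix(20, 10, 17))
})

test_that("database building on simulated normals recovers generator truth", {
  cfg <- default_generator_config()
  cohort <- simulate_normal(cfg, 200, "It", sex = "M", seed = 21)
  ndb <- build_ndb(cohort, phase = "early", sex = "M")
  truth_m <- cfg$means[["It.M.early"]]
  truth_s <- cfg$sds$It
  expect_lt(max(abs(ndb$mean - truth_m) / truth_m), 4 * 8 / sqrt(200) / 70)
  expect_lt(max(abs(ndb$sd - truth_s) / truth_s), 0.20)
})

test_that("the study wrapper assembles labeled cohorts of the right size", {
  study <- simulate_study(n_jp = 8, n_it = 6, n_cad = 4, n_dcm = 3,
                          n_control = 2, seed = 5)
  expect_equal(nrow(study$jp_normals), 16)   # early + late per subject
  expect_equal(nrow(study$it_normals), 12)
  expect_equal(table(study$validation$label[study$validation$phase == "late"]),
               table(factor(rep(c("CAD", "DCM", "none"), c(4, 3, 2)))))
  expect_true(all(study$validation$hmr >= 1))
})
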