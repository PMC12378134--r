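test_that("visual banding rule and its boundaries are exact", {
  expect_identical(visual_score_segment(72), 0L)
  expect_identical(visual_score_segment(45), 3L)
  expect_identical(visual_score_segment(35), 4L)
  # closed boundaries: >= 70 is normal, < 40 is absent
  expect_identical(visual_score_segment(c(70, 69.999, 60, 59.999, 50,
                                          49.999, 40, 39.999, 0)),
                   c(0L, 1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L))
  expect_error(visual_score_segment(-1), "non-negative")
})

test_that("automated score counts SD thresholds below the database mean", {
  ndb <- build_ndb(make_cohort(rbind(fixture_profile() - 5,
                                     fixture_profile() + 5)))
  # sd is 5 * sqrt(2) everywhere; uptake at the mean scores 0
  expect_equal(auto_score_segment(ndb$mean, ndb), rep(0L, 17))
  # 3.5 SD below the mean crosses thresholds 2 and 3 -> score 2
  expect_equal(auto_score_segment(ndb$mean - 3.5 * ndb$sd, ndb), rep(2L, 17))
  # deep defect hits the cap of 4
  expect_equal(auto_score_segment(rep(0, 17), ndb), rep(4L, 17))
  # uptake above the mean is never penalized
  expect_equal(auto_score_segment(ndb$mean + 10, ndb), rep(0L, 17))
  # zero-SD segments fall back to the floor, with a warning
  flat <- build_ndb(make_cohort(rbind(rep(80, 17), rep(80, 17))))
  expect_warning(s <- auto_score_segment(rep(78, 17), flat), "floor")
  expect_equal(s, rep(3L, 17))   # 2% below mean = 4 floor-SDs -> score 3
})

test_that("both scoring rules are monotone: less uptake never lowers a score", {
  ndb <- build_ndb(make_cohort(rbind(fixture_profile() - 5,
                                     fixture_profile() + 5)))
  u <- seq(0, 120, by = 0.5)
  vis <- visual_score_segment(u)
  expect_true(all(diff(vis) <= 0))
  aut <- auto_score_segment(u, ndb, segments = rep(1L, length(u)))
  expect_true(all(diff(aut) <= 0))
})

test_that("summed score is the plain segment sum with range 0..68", {
  expect_identical(summed_score(rep(0L, 17)), 0L)
  expect_identical(summed_score(rep(4L, 17)), 68L)
  set.seed(8)
  for (k in 1:5) {
    v <- sample(0:4, 17, replace = TRUE)
    total <- 0L
    for (x in v) total <- total + x
    expect_identical(summed_score(v), total)
  }
  expect_error(summed_score(rep(1L, 16)), "17")
  expect_error(summed_score(c(rep(1L, 16), 5L)), "0..4")
})

test_that("cohort scoring wires profiles, methods and metadata together", {
  profiles <- rbind(fixture_profile(), rep(80, 17), rep(30, 17))
  cohort <- make_cohort(profiles, label = c("none", "none", "CAD"))
  vis <- score_cohort(cohort, "visual_rule")
  expect_equal(vis$summed,
               apply(profiles, 1, function(p) sum(visual_score_segment(p))))
  expect_identical(unique(vis$method), "visual_rule")

  set.seed(9)
  normals <- make_cohort(matrix(rnorm(17 * 30, 80, 5), 30))
  ndb <- build_ndb(normals)
  auto <- score_cohort(cohort, "ndb_auto", ndb)
  expect_identical(auto$ndb_id[1], ndb$population)
  expect_equal(auto$summed[3], 68L)  # uptake 30 is > 5 SD below everywhere
  expect_true(all(sprintf("seg%02d", 1:17) %in% names(auto)))
  expect_error(score_cohort(cohort, "ndb_auto"), "normal_database")
})

test_that("scoring the database's own mean profile yields all zeros", {
  set.seed(10)
  ndb <- build_ndb(make_cohort(matrix(rnorm(17 * 25, 78, 6), 25)))
  self <- score_cohort(make_cohort(matrix(ndb$mean, 1)), "ndb_auto", ndb)
  expect_equal(self$summed, 0L)
})
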