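test_that("planted simulation respects the declared structure and types", {
  ft <- dplyr::bind_rows(
    tibble::tibble(feature = c("n1", "n2"), view = 1L, dtype = "numerical",
                   feature_cluster = 1L),
    tibble::tibble(feature = c("c1"), view = 2L, dtype = "categorical",
                   feature_cluster = 1L),
    tibble::tibble(feature = c("i1"), view = 2L, dtype = "integer",
                   feature_cluster = 2L))
  bl <- dplyr::bind_rows(
    tibble::tibble(view = 1L, feature_cluster = 1L, subject_cluster = 1:2,
                   mean = c(-1, 1), sd = 1, probs = list(NULL, NULL), rate = NA_real_),
    tibble::tibble(view = 2L, feature_cluster = 1L, subject_cluster = 1L,
                   mean = NA_real_, sd = NA_real_, probs = list(c(.5, .5)),
                   rate = NA_real_),
    tibble::tibble(view = 2L, feature_cluster = 2L, subject_cluster = 1L,
                   mean = NA_real_, sd = NA_real_, probs = list(NULL), rate = 4))
  st <- planted_structure(20, ft, list(rep(1:2, each = 10), rep(1L, 20)), bl,
                          missing_rate = 0, seed = 9)
  sim <- simulate_planted(st)

  # no missing entries at rate zero
  expect_false(anyNA(as.matrix(sim$data$values[, -1])))
  # exclusive feature-to-view partition
  expect_setequal(sim$truth$feature_views$feature, ft$feature)
  expect_equal(anyDuplicated(sim$truth$feature_views$feature), 0L)
  # declared types respected
  expect_true(all(sim$data$values$c1 %in% c("1", "2")))
  expect_true(all(sim$data$values$i1 >= 0 &
                    sim$data$values$i1 == round(sim$data$values$i1)))
  # bit-identical under a fixed seed
  sim2 <- simulate_planted(st)
  expect_identical(sim$data$values, sim2$data$values)
})

test_that("empirical block moments converge to the planted parameters", {
  n <- 10000
  ft <- dplyr::bind_rows(
    tibble::tibble(feature = "g", view = 1L, dtype = "numerical", feature_cluster = 1L),
    tibble::tibble(feature = "p", view = 1L, dtype = "integer", feature_cluster = 2L),
    tibble::tibble(feature = "c", view = 1L, dtype = "categorical", feature_cluster = 3L))
  bl <- dplyr::bind_rows(
    tibble::tibble(view = 1L, feature_cluster = 1L, subject_cluster = 1L,
                   mean = 0, sd = 1, probs = list(NULL), rate = NA_real_),
    tibble::tibble(view = 1L, feature_cluster = 2L, subject_cluster = 1L,
                   mean = NA_real_, sd = NA_real_, probs = list(NULL), rate = 3),
    tibble::tibble(view = 1L, feature_cluster = 3L, subject_cluster = 1L,
                   mean = NA_real_, sd = NA_real_, probs = list(c(.2, .8)),
                   rate = NA_real_))
  sim <- simulate_planted(planted_structure(n, ft, list(rep(1L, n)), bl, seed = 5))
  # Gaussian mean within 4 standard errors of 0
  expect_lt(abs(mean(sim$data$values$g)), 4 / sqrt(n))
  # Poisson mean within 4 se of 3
  expect_lt(abs(mean(sim$data$values$p) - 3), 4 * sqrt(3 / n))
  # categorical level frequency within 4 se of 0.8
  expect_lt(abs(mean(sim$data$values$c == "2") - 0.8), 4 * sqrt(.2 * .8 / n))
})

test_that("invalid planted configurations are rejected", {
  ft <- tibble::tibble(feature = "x", view = 1L, dtype = "numerical",
                       feature_cluster = 1L)
  bad_sd <- tibble::tibble(view = 1L, feature_cluster = 1L, subject_cluster = 1L,
                           mean = 0, sd = 0, probs = list(NULL), rate = NA_real_)
  expect_error(planted_structure(5, ft, list(rep(1L, 5)), bad_sd),
               class = "mvcoclust_config_error")
  ftc <- tibble::tibble(feature = "c", view = 1L, dtype = "categorical",
                        feature_cluster = 1L)
  bad_p <- tibble::tibble(view = 1L, feature_cluster = 1L, subject_cluster = 1L,
                          mean = NA_real_, sd = NA_real_, probs = list(c(.5, .6)),
                          rate = NA_real_)
  expect_error(planted_structure(5, ftc, list(rep(1L, 5)), bad_p),
               class = "mvcoclust_config_error")
})

test_that("simulated ROI series reproduce the target correlation", {
  # independent ROIs: empirical correlation near 0
  ts <- simulate_roi_timeseries(2, 10000, seed = 3)
  r <- cor(ts$series[[1]][1, ], ts$series[[1]][2, ])
  expect_lt(abs(r), 4 / sqrt(10000))

  # duplicated ROI (off-diagonal 1): correlation exactly 1
  tgt <- matrix(c(1, 1, 1, 1), 2)
  ts2 <- simulate_roi_timeseries(2, 100, target_cor = tgt, seed = 4)
  expect_equal(cor(ts2$series[[1]][1, ], ts2$series[[1]][2, ]), 1,
               tolerance = 1e-10)

  # moderate correlation within Fisher-z sampling error
  tgt3 <- matrix(c(1, .5, .5, 1), 2)
  ts3 <- simulate_roi_timeseries(2, 50000, target_cor = tgt3, seed = 5)
  z <- atanh(cor(ts3$series[[1]][1, ], ts3$series[[1]][2, ]))
  expect_lt(abs(z - atanh(0.5)), 4 / sqrt(50000 - 3))

  # non-PSD target rejected
  bad <- matrix(c(1, 2, 2, 1), 2)
  expect_error(simulate_roi_timeseries(2, 100, target_cor = bad),
               class = "mvcoclust_config_error")
})

test_that("study fixture defaults give 134 subjects split 67/67", {
  sim <- simulate_depression_study(study_fixture_config(
    n_fc_features = 40, n_questionnaire_features = 30))
  expect_equal(nrow(sim$data$values), 134)
  expect_equal(sum(sim$data$labels$label == "control"), 67)
  expect_equal(sum(sim$data$labels$label == "depressed"), 67)
  # planted D clusters present with subtype naming
  expect_setequal(unique(sim$truth$subtype$subtype),
                  c("C1", "C2", "D1", "D2", "D3"))
  # outcome defined for depressed subjects only
  dep <- sim$data$labels$label == "depressed"
  expect_true(all(is.na(sim$outcome$outcome[!dep])))
  expect_false(anyNA(sim$outcome$outcome[dep]))
})

test_that("study fixture feature budget matches the configuration", {
  cfg <- study_fixture_config(n_fc_features = 50, n_questionnaire_features = 25,
                              n_categorical = 6, n_integer = 2)
  sim <- simulate_depression_study(cfg)
  sp <- sim$data$specs
  expect_equal(sum(sp$group == "FC"), 50)
  expect_equal(sum(sp$group == "questionnaire" & sp$dtype == "numerical") +
                 sum(sp$group == "questionnaire" & sp$dtype == "categorical"),
               25 + 6 - 2)  # 4 MINI items are categorical questionnaire
  expect_equal(sum(sp$dtype == "categorical"), 6)
  expect_equal(sum(sp$dtype == "integer"), 2)
})

test_that("zero effect size plants identical depressed-cluster profiles", {
  cfg <- study_fixture_config(effect_size = 0, n_fc_features = 30,
                              n_questionnaire_features = 25, missing_rate = 0)
  sim <- simulate_depression_study(cfg)
  bl <- sim$truth$structure$blocks
  num1 <- bl[bl$view == 1 & !is.na(bl$mean), ]
  for (g in unique(num1$feature_cluster)) {
    m <- num1$mean[num1$feature_cluster == g & num1$subject_cluster %in% 3:5]
    expect_equal(max(m) - min(m), 0)
  }
})
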