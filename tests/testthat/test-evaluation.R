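test_that("framewise confusion counts follow the definitions", {
  p <- c(TRUE, TRUE, FALSE, FALSE); r <- c(TRUE, FALSE, TRUE, FALSE)
  expect_equal(framewise_confusion(p, r),
               c(TP = 1L, FP = 1L, TN = 1L, FN = 1L))
  same <- runif(50) < 0.5
  cc <- framewise_confusion(same, same)
  expect_equal(cc[["FP"]], 0L); expect_equal(cc[["FN"]], 0L)
  cc2 <- framewise_confusion(same, !same)
  expect_equal(cc2[["TP"]], 0L); expect_equal(cc2[["TN"]], 0L)
  expect_error(framewise_confusion(p, r[1:3]), "equal length")
})

test_that("performance statistics match their formulas and flag undefined", {
  s <- performance_stats(c(TP = 90, FP = 10, TN = 890, FN = 10))
  expect_equal(s$precision, 0.9)
  expect_equal(s$recall, 0.9)
  expect_equal(s$f1, 0.9)
  expect_equal(s$specificity, 890 / 900)

  # identical prediction gives all statistics 1
  v <- runif(100) < 0.4
  s1 <- performance_stats(framewise_confusion(v, v))
  expect_equal(c(s1$precision, s1$recall, s1$f1, s1$specificity),
               rep(1, 4))

  # swapping pred and ref swaps precision/recall and FP/FN
  set.seed(9)
  a <- runif(200) < 0.5; b <- runif(200) < 0.5
  sab <- performance_stats(framewise_confusion(a, b))
  sba <- performance_stats(framewise_confusion(b, a))
  expect_equal(sab$precision, sba$recall)
  expect_equal(sab$FP, sba$FN)
  expect_equal(sab$f1, sba$f1)

  # zero denominators are undefined, not zero
  s0 <- performance_stats(c(TP = 0, FP = 0, TN = 10, FN = 5))
  expect_true(is.na(s0$precision))
  expect_true("precision" %in% s0$undefined)

  expect_equal(f1_score(0.9, 0.9), 0.9)
  expect_true(is.na(f1_score(0, 0)))
})

test_that("inter-rater reports quantify agreement against a reference", {
  v <- bouts_to_vector(cbind(c(10L, 60L), c(39L, 89L)), 120L)  # two 30-frame bouts
  identical3 <- list(a = v, b = v, c = v)
  rep1 <- interrater_report(identical3)
  expect_equal(rep1$per_rater$f1, rep(1, 3))
  expect_true(all(rep1$agreement %in% c(0, 1)))

  # a rater shifted 2 frames misses 2 frames per 30-frame bout
  shifted <- bouts_to_vector(cbind(c(12L, 62L), c(41L, 91L)), 120L)
  rep2 <- interrater_report(list(ref = v, shifted = shifted), reference = "ref")
  r <- rep2$per_rater[rep2$per_rater$rater == "shifted", ]
  expect_equal(r$TP, 56)          # 28 overlapping frames per bout
  expect_equal(r$recall, 56 / 60)
  expect_equal(r$FN, 4)

  # agreement fractions over 3 raters live on {0, 1/3, 2/3, 1}
  set.seed(4)
  r3 <- interrater_report(list(a = runif(60) < 0.5, b = runif(60) < 0.5,
                               c = runif(60) < 0.5))
  expect_true(all(r3$agreement %in% c(0, 1 / 3, 2 / 3, 1)))
  expect_true(isSymmetric(r3$disagreement))
  expect_error(interrater_report(list(a = v)), "at least 2")
  expect_error(interrater_report(list(a = v, b = v[1:10])), "frame count")
})

test_that("threshold sweeps score every cell and pick the F1 argmax", {
  ses <- cached_freezing()
  # a 1x1 grid equals a direct validation run at those parameters
  one <- sweep_optimize(ses$metrics, ses$truth, "freezing_velocity",
                        axes = list(back_velocity_max = 0.59))
  direct <- validate_detection(
    detect_freezing_velocity(ses$metrics, freezing_params(ses$params$fps)),
    ses$truth)
  expect_equal(one$grid$f1, direct$f1)

  grid <- sweep_optimize(ses$metrics, ses$truth, "freezing_velocity",
                         axes = list(back_velocity_max = c(0.2, 0.59, 2, 6),
                                     head_angular_velocity_max = c(5, 15, 60)))
  expect_equal(nrow(grid$grid), 12L)
  # the argmax dominates every cell, including the defaults
  expect_true(all(grid$best$f1 >= grid$grid$f1, na.rm = TRUE))
  expect_gte(grid$best$f1, direct$f1)

  # two-stage sweep (velocity axes then window/count axes) is deterministic
  p2 <- freezing_params(ses$params$fps,
                        back_velocity_max = grid$best$back_velocity_max,
                        head_angular_velocity_max =
                          grid$best$head_angular_velocity_max)
  stage2a <- sweep_optimize(ses$metrics, ses$truth, "freezing_velocity",
                            axes = list(window_width = c(25L, 45L),
                                        count_threshold = c(9L, 15L)),
                            base_params = p2)
  stage2b <- sweep_optimize(ses$metrics, ses$truth, "freezing_velocity",
                            axes = list(window_width = c(25L, 45L),
                                        count_threshold = c(9L, 15L)),
                            base_params = p2)
  expect_identical(stage2a$grid, stage2b$grid)
  expect_gte(stage2a$best$f1, grid$best$f1 - 1e-12)

  # ties break to the lexicographically smallest parameter tuple
  flat <- sweep_optimize(ses$metrics, ses$truth, "freezing_velocity",
                         axes = list(back_velocity_max = c(7, 8, 9)))
  expect_equal(flat$best$back_velocity_max, 7)
})

test_that("focused exploration separates classes and balances frames", {
  set.seed(6)
  n <- 2000
  metric_a <- runif(n, 0, 4)
  metric_b <- rnorm(n)
  label <- metric_a < 1.5   # perfectly separable on metric_a
  df <- data.frame(va = metric_a, vb = metric_b)
  # perfect separation makes glm.fit warn about 0/1 probabilities; the
  # separability is the point of this fixture
  em <- suppressWarnings(explore_focused(df, label, "va", "vb", seed = 3))
  expect_gte(em$accuracy, 0.99)
  expect_equal(em$stats$n[1], em$stats$n[2])   # balanced downsampling
  # the 0.5 probability contour sits near the true threshold
  surf <- em$surface
  near <- surf[abs(surf$b - median(metric_b)) ==
                 min(abs(surf$b - median(metric_b))), ]
  cross <- near$a[which.min(abs(near$probability - 0.5))]
  expect_lt(abs(cross - 1.5), 0.3)

  # label independent of both metrics: near-chance accuracy, small weights
  label0 <- runif(n) < 0.5
  em0 <- explore_focused(df, label0, "va", "vb", seed = 3)
  expect_lt(abs(em0$accuracy - 0.5), 0.08)
  expect_true(all(abs(em0$weights) < 0.25))

  expect_error(explore_focused(df, c(rep(TRUE, 5), rep(FALSE, n - 5)),
                               "va", "vb"), "fewer than 10")
})

test_that("broad exploration ranks planted signals first and prunes noise", {
  set.seed(12)
  n <- 12000   # null z-scale weights ~ N(0, ~0.03): prune test has power
  back_velocity <- runif(n, 0, 3)
  # probabilistic label driven only by back velocity (perfectly separable
  # labels would make the logistic fit degenerate)
  label <- runif(n) < plogis(4 * (0.8 - back_velocity))
  df <- data.frame(back_velocity = back_velocity,
                   noise1 = rnorm(n), noise2 = rnorm(n), noise3 = rnorm(n))
  em <- explore_broad(df, label, weight_prune_threshold = 0.1, seed = 2)
  expect_equal(em$ranking$metric[1], "back_velocity")
  expect_true("back_velocity" %in% em$kept)
  expect_true(all(c("noise1", "noise2", "noise3") %in% em$dropped))
  # pruning never increases the metric count
  expect_lte(length(em$kept), ncol(df))
  # duplicated metrics are dropped with a warning
  df2 <- cbind(df, dup = df$back_velocity * 2)
  expect_warning(explore_broad(df2, label, seed = 2), "duplicated")
})

test_that("discrimination index matches its formula", {
  expect_equal(discrimination_index(50, 50), 0)
  expect_equal(discrimination_index(60, 20), 0.5)
  expect_equal(discrimination_index(0, 40), -1)
  expect_warning(di <- discrimination_index(0, 0), "undefined")
  expect_true(is.na(di))
})

test_that("spatiotemporal filtering restricts behavior to windows and zones", {
  fps <- 10
  v <- rep(c(TRUE, FALSE), 100)   # 50% uniformly
  b <- behavior_result("beh", v)
  one <- apply_spatiotemporal_filter(b, list(c(0, 10)), fps)
  expect_equal(one$pct_time, 50)

  # two windows partitioning the session conserve total behavior time
  both <- apply_spatiotemporal_filter(b, list(c(0, 10), c(10, 20)), fps)
  expect_equal(sum(both$behavior_frames), sum(v))

  # behavior confined to a zone
  zone <- c(rep(TRUE, 100), rep(FALSE, 100))
  vz <- zone & rep(TRUE, 200)
  rz <- apply_spatiotemporal_filter(behavior_result("beh", vz),
                                    list(c(0, 20)), fps,
                                    zone_membership = zone)
  expect_equal(rz$pct_time, 100)
  rz2 <- apply_spatiotemporal_filter(behavior_result("beh", vz),
                                     list(c(0, 20)), fps,
                                     zone_membership = !zone)
  expect_equal(rz2$pct_time, 0)

  expect_warning(apply_spatiotemporal_filter(b, list(c(5, 5)), fps), "empty")
})
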