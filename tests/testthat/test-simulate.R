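test_that("the reference preset reproduces the study composition exactly", {
  ss <- generate_scene_set(scene_set_config(), seed = 1)
  expect_equal(ss$n_scenes, 53)
  expect_equal(ss$n_hazard_scenes, 26)
  expect_equal(ss$n_normal_scenes, 27)
  expect_equal(ss$n_hazard_points, 42)
  expect_equal(ss$n_events, 30)
  expect_equal(sum(is.na(ss$hazard_areas$event_id)), 6)
  class_counts <- table(ss$hazard_areas$event_class)
  expect_equal(
    as.integer(class_counts[c(
      "tumbling", "falling", "patient_injury", "finger_caught",
      "tube_removal", "device_damage", "attention_lapse"
    )]),
    c(14L, 5L, 7L, 4L, 4L, 2L, 6L)
  )
  # events per class: 10 tumbling, 5 falling, 5 patient injuries, 4+4+2 others
  ev <- unique(ss$hazard_areas$event_id[!is.na(ss$hazard_areas$event_id)])
  expect_equal(
    as.integer(table(sub("_[0-9]+$", "", ev))[c(
      "tumbling", "falling", "patient_injury", "finger_caught",
      "tube_removal", "device_damage"
    )]),
    c(10L, 5L, 5L, 4L, 4L, 2L)
  )
  per_scene <- table(ss$hazard_areas$scene_id)
  expect_true(all(per_scene >= 1 & per_scene <= 3))
  region_counts <- table(ss$scenes$region_label)
  expect_equal(
    as.integer(region_counts[REGION_LABELS]),
    c(4L, 9L, 11L, 3L, 9L, 11L, 6L)
  )
})

test_that("generation is deterministic under a fixed seed", {
  cfg <- scene_set_config()
  a <- generate_scene_set(cfg, seed = 5)
  b <- generate_scene_set(cfg, seed = 5)
  expect_identical(a, b)
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_scene_set(a, p1)
  write_scene_set(b, p2)
  expect_identical(readLines(p1), readLines(p2)) # byte-identical serialization
  expect_false(identical(a, generate_scene_set(cfg, seed = 6)))
})

test_that("hazard circles are non-overlapping and inside the image", {
  for (seed in 1:5) {
    ss <- generate_scene_set(scene_set_config(), seed = seed)
    a <- ss$hazard_areas
    idx <- match(a$scene_id, ss$scenes$scene_id)
    expect_true(all(a$center_x - a$radius >= 0))
    expect_true(all(a$center_x + a$radius <= ss$scenes$width[idx]))
    expect_true(all(a$center_y - a$radius >= 0))
    expect_true(all(a$center_y + a$radius <= ss$scenes$height[idx]))
    for (sid in unique(a$scene_id)) {
      s <- a[a$scene_id == sid, ]
      if (nrow(s) < 2) next
      for (i in seq_len(nrow(s) - 1)) {
        for (j in seq(i + 1, nrow(s))) {
          d <- sqrt((s$center_x[i] - s$center_x[j])^2 + (s$center_y[i] - s$center_y[j])^2)
          expect_gte(d, s$radius[i] + s$radius[j])
        }
      }
    }
  }
})

test_that("the custom preset honours its configuration", {
  cfg <- scene_set_config("custom",
    n_hazard_scenes = 5, n_normal_scenes = 3,
    points_per_scene = c(2, 4), width = 2000, height = 1500
  )
  ss <- generate_scene_set(cfg, seed = 8)
  expect_equal(ss$n_hazard_scenes, 5)
  expect_equal(ss$n_normal_scenes, 3)
  per_scene <- table(ss$hazard_areas$scene_id)
  expect_true(all(per_scene >= 2 & per_scene <= 4))
  # attention-lapse points carry no event id, all others do
  a <- ss$hazard_areas
  expect_true(all(is.na(a$event_id) == (a$event_class == "attention_lapse")))

  # an all-normal set is legal and downstream sensitivity is undefined
  ss0 <- generate_scene_set(
    scene_set_config("custom", n_hazard_scenes = 0, n_normal_scenes = 4),
    seed = 1
  )
  expect_equal(ss0$n_hazard_points, 0)
  sc <- score_response(ss0, observer_response("o"))
  expect_error(sensitivity_points(sc, ss0), "no hazard points")
})

test_that("impossible circle packing fails with a helpful error", {
  cfg <- scene_set_config("custom",
    n_hazard_scenes = 1, n_normal_scenes = 0,
    points_per_scene = c(8, 8), width = 120, height = 120,
    radius_range = c(50, 60)
  )
  expect_error(generate_scene_set(cfg, seed = 1), "non-overlapping")
})

test_that("extreme observer models force the expected responses", {
  ss <- generate_scene_set(scene_set_config(), seed = 2)
  perfect <- simulate_response(ss, observer_model(p_detect = 1, fp_rate = 0), seed = 3)
  sc <- score_response(ss, perfect)
  expect_equal(sc$tp_count, 42)
  expect_equal(sc$fp_count, 0)
  expect_equal(sensitivity_points(sc, ss), 1)
  expect_equal(specificity_scenes(sc, ss), 1)
  expect_equal(afroc_fom(rating_data(sc, ss)), 1)

  blind <- simulate_response(ss, observer_model(p_detect = 0, fp_rate = 0), seed = 3)
  expect_equal(nrow(blind$marks), 0)
})

test_that("simulated responses are deterministic and within binomial support", {
  ss <- generate_scene_set(scene_set_config(), seed = 2)
  model <- observer_model(p_detect = 0.5, fp_rate = 0.5)
  r1 <- simulate_response(ss, model, seed = 11)
  r2 <- simulate_response(ss, model, seed = 11)
  expect_identical(r1, r2)
  sc <- score_response(ss, r1)
  expect_lte(sc$tp_count, 42)
  expect_false(identical(r1, simulate_response(ss, model, seed = 12)))
})

test_that("the Monte-Carlo oracle hits the analytic extremes", {
  ss <- generate_scene_set(scene_set_config(), seed = 2)
  top <- oracle_fom(ss, observer_model(p_detect = 1, fp_rate = 0),
    n_replicates = 5, seed = 1
  )
  expect_equal(top$mean, 1)
  expect_equal(top$sd, 0)
  bottom <- oracle_fom(ss, observer_model(p_detect = 0, fp_rate = 0),
    n_replicates = 5, seed = 1
  )
  expect_equal(bottom$mean, 0)
})

test_that("with no FPs the expected FOM is the detection probability", {
  ss <- generate_scene_set(scene_set_config(), seed = 2)
  oc <- oracle_fom(ss, observer_model(p_detect = 0.7, fp_rate = 0),
    n_replicates = 300, seed = 9
  )
  # each replicate's theta is k/42 with k ~ Binomial(42, 0.7)
  expect_true(all(abs(oc$foms * 42 - round(oc$foms * 42)) < 1e-9))
  expect_lt(abs(oc$mean - 0.7), 4 * sqrt(0.7 * 0.3 / 42 / 300))
})

test_that("the oracle mean is monotone in skill", {
  ss <- generate_scene_set(scene_set_config(), seed = 2)
  lo <- oracle_fom(ss, kyt_observer_model(p_detect = 0.3), n_replicates = 120, seed = 4)
  hi <- oracle_fom(ss, kyt_observer_model(p_detect = 0.8), n_replicates = 120, seed = 4)
  expect_gt(hi$mean, lo$mean)
  clean <- oracle_fom(ss, kyt_observer_model(fp_rate = 0), n_replicates = 120, seed = 4)
  noisy <- oracle_fom(ss, kyt_observer_model(fp_rate = 2), n_replicates = 120, seed = 4)
  expect_gt(clean$mean, noisy$mean)
})

test_that("simulated sensitivities and specificities stay on the k/42 and k/27 grids", {
  ss <- generate_scene_set(scene_set_config(), seed = 6)
  model <- kyt_observer_model(fp_rate = 1)
  withr::with_seed(12, {
    for (i in 1:10) {
      sc <- score_response(ss, simulate_response(ss, model, seed = NULL))
      sp <- sensitivity_points(sc, ss) * 42
      sn <- specificity_scenes(sc, ss) * 27
      expect_equal(sp, round(sp))
      expect_equal(sn, round(sn))
    }
  })
})
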