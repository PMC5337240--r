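test_that("marks are classified TP/suppressed/FP by the circular hit rule", {
  ss <- fixture_scene_set()
  # hp1 at (100,100) r=50: distances 22.4 and 11.2 inside, 141.4 outside
  r <- observer_response("o1", marks = marks_df(
    list("H1", 120, 110, 0.6),
    list("H1", 90, 95, 0.4),
    list("H1", 200, 200, 0.3)
  ))
  sc <- score_response(ss, r)
  expect_equal(sc$marks$label, c("TP", "suppressed", "FP"))
  expect_equal(sc$marks$matched_hazard_point_id, c("hp1", "hp1", NA))
  expect_equal(sc$tp_count, 1)
  expect_equal(sc$fp_count, 1)
  expect_equal(sc$detected_hazard_point_ids, "hp1")
})

test_that("the hit test is boundary inclusive", {
  ss <- fixture_scene_set()
  # (150, 100) is exactly radius 50 from hp1's center (100, 100)
  sc <- score_response(ss, observer_response("o", marks = marks_df(list("H1", 150, 100, 0.9))))
  expect_equal(sc$marks$label, "TP")
  expect_equal(sc$marks$matched_hazard_point_id, "hp1")
  # one pixel further out is an FP
  sc2 <- score_response(ss, observer_response("o", marks = marks_df(list("H1", 151, 100, 0.9))))
  expect_equal(sc2$marks$label, "FP")
})

test_that("zero marks score to empty results", {
  ss <- fixture_scene_set()
  sc <- score_response(ss, observer_response("o"))
  expect_equal(sc$tp_count, 0)
  expect_equal(sc$fp_count, 0)
  expect_length(sc$detected_hazard_point_ids, 0)
  expect_length(sc$marked_scene_ids, 0)
  expect_equal(specificity_scenes(sc, ss), 1)
  expect_equal(sensitivity_points(sc, ss), 0)
  expect_equal(sensitivity_events(sc, ss), 0)
})

test_that("equal-rated duplicate hits keep exactly one TP, earliest entry wins", {
  ss <- fixture_scene_set()
  r <- observer_response("o", marks = marks_df(
    list("H1", 110, 100, 0.5),
    list("H1", 95, 100, 0.5)
  ))
  sc <- score_response(ss, r)
  expect_equal(sc$marks$label, c("TP", "suppressed"))
  # reversed entry order flips which mark is labeled, never the counts
  r2 <- observer_response("o", marks = r$marks[2:1, ])
  sc2 <- score_response(ss, r2)
  expect_equal(sc2$marks$label, c("TP", "suppressed"))
  expect_equal(sc2$tp_count, 1)
})

test_that("scoring is permutation-stable in counts and detected sets", {
  ss <- generate_scene_set(scene_set_config(), seed = 4)
  model <- kyt_observer_model(fp_rate = 1)
  withr::with_seed(42, {
    for (i in 1:10) {
      r <- simulate_response(ss, model, seed = NULL)
      perm <- sample(nrow(r$marks))
      r2 <- observer_response(r$observer_id, r$group_label, r$session_label,
        marks = r$marks[perm, ]
      )
      sc <- score_response(ss, r)
      sc2 <- score_response(ss, r2)
      expect_equal(sc2$tp_count, sc$tp_count)
      expect_equal(sc2$fp_count, sc$fp_count)
      expect_equal(sc2$detected_hazard_point_ids, sc$detected_hazard_point_ids)
      expect_equal(sc2$marked_scene_ids, sc$marked_scene_ids)
    }
  })
})

test_that("a mark inside overlapping areas goes to the nearest center", {
  ss <- scene_set(
    scenes = data.frame(
      scene_id = "H1", has_hazard = TRUE, width = 400, height = 300,
      region_label = "chest", stringsAsFactors = FALSE
    ),
    hazard_areas = data.frame(
      hazard_point_id = c("hpA", "hpB"), scene_id = "H1",
      center_x = c(100, 160), center_y = 100, radius = 50,
      event_id = c("e1", "e2"), event_class = "tumbling",
      stringsAsFactors = FALSE
    )
  )
  sc <- score_response(ss, observer_response("o", marks = marks_df(list("H1", 120, 100, 0.5))))
  expect_equal(sc$marks$matched_hazard_point_id, "hpA") # 20 px vs 40 px
  # equidistant point: lowest hazard_point_id wins
  sc2 <- score_response(ss, observer_response("o", marks = marks_df(list("H1", 130, 100, 0.5))))
  expect_equal(sc2$marks$matched_hazard_point_id, "hpA")
})

test_that("sensitivities and specificity are the expected fractions", {
  ss <- generate_scene_set(scene_set_config(), seed = 9)
  a <- ss$hazard_areas
  # hit the first 19 hazard points dead center, and put one FP on 13 of the
  # 27 normal scenes -> sensitivity 19/42, specificity 14/27
  hit <- a[order(a$hazard_point_id), ][1:19, ]
  normal <- sort(ss$scenes$scene_id[!ss$scenes$has_hazard])[1:13]
  marks <- rbind(
    data.frame(
      scene_id = hit$scene_id, x = hit$center_x, y = hit$center_y,
      rating = 0.8, stringsAsFactors = FALSE
    ),
    data.frame(scene_id = normal, x = 1, y = 1, rating = 0.3, stringsAsFactors = FALSE)
  )
  sc <- score_response(ss, observer_response("o", marks = marks))
  expect_equal(sensitivity_points(sc, ss), 19 / 42)
  expect_equal(round_half_up(100 * sensitivity_points(sc, ss), 1), 45.2)
  expect_equal(specificity_scenes(sc, ss), 14 / 27)
  expect_equal(round_half_up(100 * specificity_scenes(sc, ss), 1), 51.9)
})

test_that("event sensitivity counts an event on any detected member point", {
  ss <- fixture_scene_set()
  # hp1 and hp2 share event e1; detecting only hp1 detects e1 (1 of 2 events)
  sc <- score_response(ss, observer_response("o", marks = marks_df(list("H1", 100, 100, 0.5))))
  expect_equal(sensitivity_events(sc, ss), 1 / 2)
  expect_equal(sensitivity_points(sc, ss), 1 / 4)
  # the attention-lapse point hp4 has no event: detecting it moves point
  # sensitivity but not event sensitivity
  sc2 <- score_response(ss, observer_response("o", marks = marks_df(list("H2", 50, 50, 0.5))))
  expect_equal(sensitivity_events(sc2, ss), 0)
  expect_equal(sensitivity_points(sc2, ss), 1 / 4)
  # detecting every point detects every event
  a <- ss$hazard_areas
  all_hits <- observer_response("o", marks = data.frame(
    scene_id = a$scene_id, x = a$center_x, y = a$center_y, rating = 0.9,
    stringsAsFactors = FALSE
  ))
  expect_equal(sensitivity_events(score_response(ss, all_hits), ss), 1)
})

test_that("per-event identity: event sensitivity >= mean per-event detected fraction", {
  ss <- generate_scene_set(scene_set_config(), seed = 13)
  a <- ss$hazard_areas[!is.na(ss$hazard_areas$event_id), ]
  model <- kyt_observer_model(fp_rate = 0.5)
  withr::with_seed(99, {
    for (i in 1:20) {
      sc <- score_response(ss, simulate_response(ss, model, seed = NULL))
      det <- a$hazard_point_id %in% sc$detected_hazard_point_ids
      frac <- vapply(split(det, a$event_id), mean, numeric(1))
      expect_gte(
        sensitivity_events(sc, ss) * ss$n_events + 1e-12,
        sum(frac)
      )
    }
  })
})

test_that("degenerate scene sets give undefined-quantity errors", {
  no_normal <- scene_set(
    scenes = data.frame(
      scene_id = "H1", has_hazard = TRUE, width = 400, height = 300,
      region_label = "chest", stringsAsFactors = FALSE
    ),
    hazard_areas = data.frame(
      hazard_point_id = "hp1", scene_id = "H1", center_x = 100, center_y = 100,
      radius = 50, event_id = NA_character_, event_class = "attention_lapse",
      stringsAsFactors = FALSE
    )
  )
  sc <- score_response(no_normal, observer_response("o"))
  expect_error(specificity_scenes(sc, no_normal), "no no-hazard scenes")
  expect_error(sensitivity_events(sc, no_normal), "no events")

  all_normal <- scene_set(scenes = data.frame(
    scene_id = "N1", has_hazard = FALSE, width = 400, height = 300,
    region_label = "head", stringsAsFactors = FALSE
  ))
  sc2 <- score_response(all_normal, observer_response("o"))
  expect_error(sensitivity_points(sc2, all_normal), "no hazard points")
})

test_that("suppressed marks never reach counts, rating data or curves", {
  ss <- fixture_scene_set()
  r <- observer_response("o", marks = marks_df(
    list("H1", 100, 100, 0.9),
    list("H1", 101, 100, 0.8), # duplicate hit, lower rating -> suppressed
    list("N1", 10, 10, 0.85)
  ))
  sc <- score_response(ss, r)
  expect_equal(sum(sc$marks$label == "suppressed"), 1)
  expect_equal(sc$fp_count, 1)
  rd <- rating_data(sc, ss)
  expect_equal(unname(rd$lesion_ratings["hp1"]), 0.9)
  expect_false(0.8 %in% unlist(rd)) # the suppressed rating appears nowhere
})
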