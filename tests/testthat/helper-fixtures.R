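# Shared fixtures and independent oracles, built in code at test time.

# Small scene set: 2 hazardous scenes (3 event-bearing points in 2 events +
# 1 attention-lapse point), 2 normal scenes, 400 x 300 px.
fixture_scene_set <- function() {
  scene_set(
    scenes = data.frame(
      scene_id = c("H1", "H2", "N1", "N2"),
      has_hazard = c(TRUE, TRUE, FALSE, FALSE),
      width = 400, height = 300,
      region_label = c("chest", "abdomen", "head", "patient_movement"),
      stringsAsFactors = FALSE
    ),
    hazard_areas = data.frame(
      hazard_point_id = c("hp1", "hp2", "hp3", "hp4"),
      scene_id = c("H1", "H1", "H2", "H2"),
      center_x = c(100, 300, 200, 50),
      center_y = c(100, 100, 150, 50),
      radius = c(50, 40, 60, 30),
      event_id = c("e1", "e1", "e2", NA),
      event_class = c("tumbling", "tumbling", "falling", "attention_lapse"),
      stringsAsFactors = FALSE
    )
  )
}

marks_df <- function(...) {
  rows <- list(...)
  data.frame(
    scene_id = vapply(rows, function(r) as.character(r[[1]]), character(1)),
    x = vapply(rows, function(r) as.numeric(r[[2]]), numeric(1)),
    y = vapply(rows, function(r) as.numeric(r[[3]]), numeric(1)),
    rating = vapply(rows, function(r) as.numeric(r[[4]]), numeric(1)),
    stringsAsFactors = FALSE
  )
}

# Build a rating_data container directly (fields as documented).
mk_rating_data <- function(lesion, fpmax, n_lesions, n_fp_scenes,
                           variant = "normal_only") {
  structure(
    list(
      observer_id = "fixture", session_label = "",
      lesion_ratings = lesion, normal_fp_max = fpmax,
      n_lesions = n_lesions, n_fp_scenes = n_fp_scenes, variant = variant
    ),
    class = "rating_data"
  )
}

# Independent brute-force Wilcoxon statistic: explicit double loop over all
# (hazard point, FP scene) pairs with the psi kernel.
theta_brute <- function(rd) {
  r <- c(rd$lesion_ratings, rep(-Inf, rd$n_lesions - length(rd$lesion_ratings)))
  m <- c(rd$normal_fp_max, rep(-Inf, rd$n_fp_scenes - length(rd$normal_fp_max)))
  s <- 0
  for (ri in r) {
    for (mi in m) {
      if (ri > mi) {
        s <- s + 1
      } else if (is.finite(ri) && is.finite(mi) && ri == mi) {
        s <- s + 0.5
      }
    }
  }
  s / (rd$n_lesions * rd$n_fp_scenes)
}

# Random rating data on a coarse rating grid (to exercise ties).
rand_rating_data <- function(complete = TRUE, max_n = 8) {
  n_l <- sample(1:max_n, 1)
  n_s <- sample(1:max_n, 1)
  grid <- seq(0.05, 1, by = 0.05)
  k_l <- if (complete) n_l else sample(0:n_l, 1)
  k_s <- if (complete) n_s else sample(0:n_s, 1)
  nm <- function(prefix, k) if (k) paste0(prefix, seq_len(k)) else character(0)
  mk_rating_data(
    lesion = stats::setNames(sample(grid, k_l, replace = TRUE), nm("hp", k_l)),
    fpmax = stats::setNames(sample(grid, k_s, replace = TRUE), nm("n", k_s)),
    n_lesions = n_l, n_fp_scenes = n_s
  )
}
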