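#' Scene-set generator configuration
#'
#' Describes a synthetic scene set. The default `preset = "kyt"` reproduces
#' the composition of the reference hazard-prediction study exactly: 26
#' hazardous and 27 normal scenes, 42 hazard points of which 36 belong to 30
#' events (10 tumbling events with 14 points, 5 falling with 5, 5 patient
#' injuries with 7, 4 caught fingers, 4 tube removals, 2 device damages) and
#' 6 are attention-lapse points without an event; one to three points per
#' hazardous scene; region labels 4 head, 9 chest, 11 abdomen, 3 pelvis, 9
#' upper-extremity, 11 lower-extremity and 6 patient-movement scenes. Only
#' the geometry (circle centers and radii, label assignment) is random.
#' `preset = "custom"` generates free composition from the remaining
#' arguments, each hazard point forming its own singleton event unless its
#' class is `attention_lapse`.
#'
#' @param preset `"kyt"` (reference composition) or `"custom"`.
#' @param n_hazard_scenes,n_normal_scenes scene counts (custom preset).
#' @param points_per_scene integer range `c(min, max)` of hazard points per
#'   hazardous scene (custom preset).
#' @param width,height image dimensions in pixels.
#' @param radius_range range `c(min, max)` of hazard-circle radii in pixels.
#' @param event_class_mix named probabilities over [EVENT_CLASSES] for the
#'   custom preset; default uniform.
#' @return An object of class `scene_set_config`.
#' @export
scene_set_config <- function(preset = c("kyt", "custom"),
                             n_hazard_scenes = 26, n_normal_scenes = 27,
                             points_per_scene = c(1, 3),
                             width = 1024, height = 768,
                             radius_range = c(30, 80),
                             event_class_mix = NULL) {
  preset <- match.arg(preset)
  stopifnot(
    n_hazard_scenes >= 0, n_normal_scenes >= 0,
    length(points_per_scene) == 2, points_per_scene[1] >= 1,
    points_per_scene[1] <= points_per_scene[2],
    width > 0, height > 0,
    length(radius_range) == 2, radius_range[1] > 0,
    radius_range[1] <= radius_range[2]
  )
  if (is.null(event_class_mix)) {
    event_class_mix <- stats::setNames(
      rep(1 / length(EVENT_CLASSES), length(EVENT_CLASSES)), EVENT_CLASSES
    )
  }
  stopifnot(
    all(names(event_class_mix) %in% EVENT_CLASSES),
    all(event_class_mix >= 0), sum(event_class_mix) > 0
  )
  out <- list(
    preset = preset, n_hazard_scenes = n_hazard_scenes,
    n_normal_scenes = n_normal_scenes, points_per_scene = points_per_scene,
    width = width, height = height, radius_range = radius_range,
    event_class_mix = event_class_mix / sum(event_class_mix)
  )
  class(out) <- "scene_set_config"
  out
}

# Fixed point/event packing of the reference composition: which hazard scene
# carries which events and how many points each event contributes there.
# Totals: 42 points, 30 events + 6 no-event attention-lapse points, 1-2
# points per scene (within the study's 1-3 constraint).
kyt_layout <- function() {
  two_point <- data.frame(
    scene = 1:6,
    event_id = c(paste0("tumbling_", sprintf("%02d", 1:4)), "patient_injury_01", "patient_injury_02"),
    event_class = c(rep("tumbling", 4), rep("patient_injury", 2)),
    n_points = 2, stringsAsFactors = FALSE
  )
  with_attention <- data.frame(
    scene = rep(7:12, each = 2),
    event_id = as.vector(rbind(paste0("tumbling_", sprintf("%02d", 5:10)), NA_character_)),
    event_class = rep(c("tumbling", "attention_lapse"), 6),
    n_points = 1, stringsAsFactors = FALSE
  )
  paired_singletons <- data.frame(
    scene = rep(13:16, each = 2),
    event_id = c(
      "falling_01", "falling_02", "falling_03", "falling_04",
      "falling_05", "patient_injury_03", "patient_injury_04", "patient_injury_05"
    ),
    event_class = c(rep("falling", 5), rep("patient_injury", 3)),
    n_points = 1, stringsAsFactors = FALSE
  )
  lone_singletons <- data.frame(
    scene = 17:26,
    event_id = c(
      paste0("finger_caught_", sprintf("%02d", 1:4)),
      paste0("tube_removal_", sprintf("%02d", 1:4)),
      "device_damage_01", "device_damage_02"
    ),
    event_class = c(
      rep("finger_caught", 4), rep("tube_removal", 4),
      rep("device_damage", 2)
    ),
    n_points = 1, stringsAsFactors = FALSE
  )
  rbind(two_point, with_attention, paired_singletons, lone_singletons)
}

kyt_region_multiset <- function() {
  rep(
    c(
      "head", "chest", "abdomen", "pelvis",
      "upper_extremity", "lower_extremity", "patient_movement"
    ),
    times = c(4, 9, 11, 3, 9, 11, 6)
  )
}

# Place k non-overlapping circles fully inside [0,w]x[0,h].
place_circles <- function(k, width, height, radius_range, max_tries = 200) {
  cx <- cy <- r <- numeric(k)
  for (i in seq_len(k)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      ri <- stats::runif(1, radius_range[1], radius_range[2])
      if (2 * ri > min(width, height)) next
      xi <- stats::runif(1, ri, width - ri)
      yi <- stats::runif(1, ri, height - ri)
      if (i == 1 || all(sqrt((cx[seq_len(i - 1)] - xi)^2 + (cy[seq_len(i - 1)] - yi)^2) >=
        r[seq_len(i - 1)] + ri)) {
        cx[i] <- xi
        cy[i] <- yi
        r[i] <- ri
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("could not place non-overlapping hazard circles after ", max_tries,
        " attempts; use a larger image or smaller radii",
        call. = FALSE
      )
    }
  }
  data.frame(center_x = cx, center_y = cy, radius = r)
}

#' Generate a synthetic scene set
#'
#' Builds a [scene_set()] from a [scene_set_config()]: the composition comes
#' from the preset (see [scene_set_config()]), hazard circles are placed
#' non-overlapping and fully inside the image bounds, and all randomness is
#' governed by `seed` (the same config and seed give a byte-identical
#' serialization).
#'
#' @param config a [scene_set_config()].
#' @param seed integer seed.
#' @return A [scene_set()].
#' @examples
#' ss <- generate_scene_set(scene_set_config(), seed = 1)
#' ss # 53 scenes, 42 hazard points, 30 events
#' @export
generate_scene_set <- function(config = scene_set_config(), seed = 1) {
  stopifnot(inherits(config, "scene_set_config"))
  with_seed(seed, {
    if (config$preset == "kyt") {
      layout <- kyt_layout()
      n_hazard <- 26
      n_normal <- 27
      regions <- sample(kyt_region_multiset())
    } else {
      n_hazard <- config$n_hazard_scenes
      n_normal <- config$n_normal_scenes
      k_range <- config$points_per_scene
      layout <- NULL
      regions <- sample(REGION_LABELS, n_hazard + n_normal, replace = TRUE)
    }
    hazard_ids <- sprintf("H%02d", seq_len(n_hazard))
    normal_ids <- sprintf("N%02d", seq_len(n_normal))
    scenes <- data.frame(
      scene_id = c(hazard_ids, normal_ids),
      has_hazard = rep(c(TRUE, FALSE), c(n_hazard, n_normal)),
      width = config$width, height = config$height,
      region_label = regions[seq_len(n_hazard + n_normal)],
      stringsAsFactors = FALSE
    )
    areas <- empty_hazard_areas()
    hp_counter <- 0L
    for (i in seq_len(n_hazard)) {
      if (config$preset == "kyt") {
        rows <- layout[layout$scene == i, , drop = FALSE]
        event_id <- rep(rows$event_id, rows$n_points)
        event_class <- rep(rows$event_class, rows$n_points)
      } else {
        k <- sample(seq(k_range[1], k_range[2]), 1)
        event_class <- sample(names(config$event_class_mix), k,
          replace = TRUE, prob = config$event_class_mix
        )
        event_id <- ifelse(
          event_class == "attention_lapse", NA_character_,
          sprintf("%s_%s_ev%d", event_class, hazard_ids[i], seq_len(k))
        )
      }
      k <- length(event_id)
      geom <- place_circles(k, config$width, config$height, config$radius_range)
      areas <- rbind(areas, data.frame(
        hazard_point_id = sprintf("HP%02d", hp_counter + seq_len(k)),
        scene_id = hazard_ids[i],
        geom,
        event_id = event_id,
        event_class = event_class,
        stringsAsFactors = FALSE
      ))
      hp_counter <- hp_counter + k
    }
    scene_set(scenes, areas, emulation = config$preset == "kyt")
  })
}

#' Synthetic observer model
#'
#' A stochastic reader with known skill, used to simulate mark-rating
#' responses: each hazard point is detected with probability `p_detect`
#' (optionally overridden per event class), detected points get a TP mark
#' uniformly inside their circle with a rating drawn from a beta distribution
#' clipped to \[0.01, 1\]; each scene additionally receives a Poisson number
#' of FP marks placed uniformly outside all hazard circles, rated from a
#' second beta distribution.
#'
#' `sos_factor` models within-scene satisfaction of search: once the observer
#' has detected one hazard point in a scene, the detection probability of the
#' remaining points in that scene is multiplied by `sos_factor` (1 =
#' independent detections). See [kyt_observer_model()] for defaults that
#' emulate the reference study's readers.
#'
#' @param p_detect baseline detection probability in \[0, 1\].
#' @param p_detect_class optional named numeric vector of per-event-class
#'   detection probabilities overriding `p_detect` (names from
#'   [EVENT_CLASSES]).
#' @param tp_rating_shape,fp_rating_shape `c(shape1, shape2)` of the beta
#'   rating distributions for TP and FP marks.
#' @param fp_rate mean number of FP marks per scene (Poisson).
#' @param sos_factor multiplier in \[0, 1\] applied to detection probabilities
#'   after the first detection within a scene.
#' @param seed default seed used by [simulate_response()] when none is given.
#' @return An object of class `observer_model`.
#' @export
observer_model <- function(p_detect = 0.5, p_detect_class = NULL,
                           tp_rating_shape = c(2, 2), fp_rate = 0.5,
                           fp_rating_shape = c(2, 2), sos_factor = 1,
                           seed = NULL) {
  stopifnot(
    p_detect >= 0, p_detect <= 1, fp_rate >= 0,
    length(tp_rating_shape) == 2, all(tp_rating_shape > 0),
    length(fp_rating_shape) == 2, all(fp_rating_shape > 0),
    sos_factor >= 0, sos_factor <= 1
  )
  if (!is.null(p_detect_class)) {
    stopifnot(
      all(names(p_detect_class) %in% EVENT_CLASSES),
      all(p_detect_class >= 0), all(p_detect_class <= 1)
    )
  }
  out <- list(
    p_detect = p_detect, p_detect_class = p_detect_class,
    tp_rating_shape = tp_rating_shape, fp_rate = fp_rate,
    fp_rating_shape = fp_rating_shape, sos_factor = sos_factor, seed = seed
  )
  class(out) <- "observer_model"
  out
}

#' Reference-study observer model
#'
#' An [observer_model()] whose defaults emulate the readers of the reference
#' hazard-prediction study: baseline detection probability 0.65 with
#' attention-lapse points at 0.2 (these points were by far the most often
#' overlooked), a satisfaction-of-search factor of 0.35 (observers tended to
#' overlook further hazard points in a scene once they had found one), TP
#' ratings Beta(4, 2), 0.2 FP marks per scene rated Beta(2, 4). Under these
#' settings simulated point sensitivities and scene specificities fall in the
#' ranges the study reported.
#'
#' @param p_detect,fp_rate,sos_factor,seed overrides of the defaults above.
#' @param ... passed on to [observer_model()].
#' @return An [observer_model()].
#' @export
kyt_observer_model <- function(p_detect = 0.65, fp_rate = 0.2, sos_factor = 0.35,
                               seed = NULL, ...) {
  observer_model(
    p_detect = p_detect,
    p_detect_class = c(attention_lapse = 0.2),
    tp_rating_shape = c(4, 2), fp_rate = fp_rate,
    fp_rating_shape = c(2, 4), sos_factor = sos_factor, seed = seed, ...
  )
}

clip_rating <- function(x) pmin(1, pmax(0.01, x))

#' Simulate a mark-rating response
#'
#' Draws one observer's free response on a scene set from an
#' [observer_model()]. Scenes are visited in `scene_id` order and hazard
#' points within a scene in `hazard_point_id` order, so results are
#' platform-stable; all randomness comes from one stream seeded by `seed`.
#' FP marks are rejection-sampled uniformly outside every hazard circle of
#' their scene.
#'
#' @param scene_set a [scene_set()].
#' @param model an [observer_model()].
#' @param observer_id,group_label,session_label labels for the resulting
#'   response.
#' @param seed integer seed; defaults to `model$seed`.
#' @return An [observer_response()].
#' @export
simulate_response <- function(scene_set, model, observer_id = "sim",
                              group_label = "simulated", session_label = "",
                              seed = model$seed) {
  stopifnot(inherits(scene_set, "scene_set"), inherits(model, "observer_model"))
  with_seed(seed, {
    marks <- list()
    add_mark <- function(scene_id, x, y, rating) {
      marks[[length(marks) + 1]] <<- data.frame(
        scene_id = scene_id, x = x, y = y, rating = rating,
        stringsAsFactors = FALSE
      )
    }
    p_for <- function(cls) {
      if (!is.null(model$p_detect_class) && cls %in% names(model$p_detect_class)) {
        model$p_detect_class[[cls]]
      } else {
        model$p_detect
      }
    }
    for (sid in sort(scene_set$scenes$scene_id)) {
      srow <- scene_set$scenes[scene_set$scenes$scene_id == sid, ]
      a <- scene_set$hazard_areas[scene_set$hazard_areas$scene_id == sid, , drop = FALSE]
      a <- a[order(a$hazard_point_id), , drop = FALSE]
      found_one <- FALSE
      for (j in seq_len(nrow(a))) {
        p <- p_for(a$event_class[j]) * if (found_one) model$sos_factor else 1
        if (stats::runif(1) < p) {
          found_one <- TRUE
          ang <- stats::runif(1, 0, 2 * pi)
          rad <- a$radius[j] * sqrt(stats::runif(1))
          add_mark(
            sid,
            a$center_x[j] + rad * cos(ang), a$center_y[j] + rad * sin(ang),
            clip_rating(stats::rbeta(1, model$tp_rating_shape[1], model$tp_rating_shape[2]))
          )
        }
      }
      n_fp <- stats::rpois(1, model$fp_rate)
      for (f in seq_len(n_fp)) {
        ok <- FALSE
        for (try in seq_len(200)) {
          x <- stats::runif(1, 0, srow$width)
          y <- stats::runif(1, 0, srow$height)
          if (!nrow(a) || all(sqrt((a$center_x - x)^2 + (a$center_y - y)^2) > a$radius)) {
            ok <- TRUE
            break
          }
        }
        if (!ok) {
          stop("could not place an FP mark outside the hazard circles of scene ", sid,
            call. = FALSE
          )
        }
        add_mark(
          sid, x, y,
          clip_rating(stats::rbeta(1, model$fp_rating_shape[1], model$fp_rating_shape[2]))
        )
      }
    }
    observer_response(
      observer_id = observer_id, group_label = group_label,
      session_label = session_label,
      marks = if (length(marks)) {
        do.call(rbind, marks)
      } else {
        data.frame(
          scene_id = character(), x = numeric(), y = numeric(),
          rating = numeric(), stringsAsFactors = FALSE
        )
      }
    )
  })
}

#' Monte-Carlo oracle for the expected figure of merit
#'
#' Brute-force estimate of an observer model's expected AFROC figure of
#' merit on a scene set: repeatedly simulate a response, score it and compute
#' \eqn{\theta}, then average. `sd` is the Monte-Carlo spread of a single
#' simulated observer's \eqn{\theta} (the scale on which one simulated
#' reader's FOM varies); `se` is the standard error of the reported mean.
#'
#' @param scene_set a [scene_set()].
#' @param model an [observer_model()].
#' @param n_replicates number of simulated readings (>= 1).
#' @param seed integer seed for the replicate stream.
#' @param variant FOM variant, see [rating_data()].
#' @return An object of class `oracle_fom`: `mean`, `sd`, `se`,
#'   `n_replicates` and the vector `foms`.
#' @export
oracle_fom <- function(scene_set, model, n_replicates = 1000, seed = 1,
                       variant = c("normal_only", "all_scenes")) {
  stopifnot(n_replicates >= 1)
  variant <- match.arg(variant)
  foms <- with_seed(seed, {
    vapply(seq_len(n_replicates), function(i) {
      r <- simulate_response(scene_set, model,
        observer_id = sprintf("mc%05d", i),
        seed = NULL
      )
      afroc_fom(rating_data(score_response(scene_set, r), scene_set, variant))
    }, numeric(1))
  })
  out <- list(
    mean = mean(foms),
    sd = if (n_replicates > 1) stats::sd(foms) else 0,
    se = if (n_replicates > 1) stats::sd(foms) / sqrt(n_replicates) else 0,
    n_replicates = n_replicates,
    foms = foms
  )
  class(out) <- "oracle_fom"
  out
}

#' @export
print.oracle_fom <- function(x, ...) {
  cat(sprintf(
    "<oracle_fom> mean theta = %.4f (sd %.4f, se %.5f) over %d replicates\n",
    x$mean, x$sd, x$se, x$n_replicates
  ))
  invisible(x)
}
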