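#' Event classes and scene region labels
#'
#' Controlled vocabularies for hazard-point event classes and for the body
#' region (or activity) a scene depicts.
#'
#' @format Character vectors.
#' @name vocabularies
NULL

#' @rdname vocabularies
#' @export
EVENT_CLASSES <- c(
  "tumbling", "falling", "patient_injury", "finger_caught",
  "tube_removal", "device_damage", "attention_lapse"
)

#' @rdname vocabularies
#' @export
REGION_LABELS <- c(
  "head", "chest", "abdomen", "pelvis",
  "upper_extremity", "lower_extremity", "patient_movement"
)

empty_scenes <- function() {
  data.frame(
    scene_id = character(), has_hazard = logical(),
    width = numeric(), height = numeric(), region_label = character(),
    stringsAsFactors = FALSE
  )
}

empty_hazard_areas <- function() {
  data.frame(
    hazard_point_id = character(), scene_id = character(),
    center_x = numeric(), center_y = numeric(), radius = numeric(),
    event_id = character(), event_class = character(),
    stringsAsFactors = FALSE
  )
}

#' Construct a scene set
#'
#' A scene set is the ground truth of a free-response hazard-prediction
#' observer study: the scenes shown to observers and, for hazardous scenes,
#' the circular hazard areas an observer must hit for a mark to count as a
#' true positive. Hazard points may be grouped into events (a potential
#' incident such as a fall, possibly caused by more than one hazard point);
#' points with `event_id = NA` are hazard points without an associated event
#' (e.g. staff looking away from the patient).
#'
#' Coordinates are continuous pixels, origin at the top-left corner, x
#' rightward and y downward.
#'
#' @param scenes data.frame with columns `scene_id`, `has_hazard`, `width`,
#'   `height`, `region_label`.
#' @param hazard_areas data.frame with columns `hazard_point_id`, `scene_id`,
#'   `center_x`, `center_y`, `radius`, `event_id` (NA allowed), `event_class`.
#' @param emulation logical; if `TRUE`, additionally enforce the reference
#'   study composition constraint that every hazardous scene carries one to
#'   three hazard areas.
#' @return An object of class `scene_set`: a list with elements `scenes`,
#'   `hazard_areas` and derived counts `n_scenes`, `n_hazard_scenes`,
#'   `n_normal_scenes`, `n_hazard_points`, `n_events`.
#' @seealso [read_scene_set()], [generate_scene_set()]
#' @export
scene_set <- function(scenes = empty_scenes(), hazard_areas = empty_hazard_areas(),
                      emulation = FALSE) {
  scenes <- as.data.frame(scenes, stringsAsFactors = FALSE)
  hazard_areas <- as.data.frame(hazard_areas, stringsAsFactors = FALSE)

  need_s <- c("scene_id", "has_hazard", "width", "height", "region_label")
  need_a <- c(
    "hazard_point_id", "scene_id", "center_x", "center_y", "radius",
    "event_id", "event_class"
  )
  if (!all(need_s %in% names(scenes))) {
    stop("scenes is missing column(s): ",
      paste(setdiff(need_s, names(scenes)), collapse = ", "),
      call. = FALSE
    )
  }
  if (!all(need_a %in% names(hazard_areas))) {
    stop("hazard_areas is missing column(s): ",
      paste(setdiff(need_a, names(hazard_areas)), collapse = ", "),
      call. = FALSE
    )
  }
  scenes <- scenes[need_s]
  hazard_areas <- hazard_areas[need_a]
  scenes$scene_id <- as.character(scenes$scene_id)
  hazard_areas$scene_id <- as.character(hazard_areas$scene_id)
  hazard_areas$hazard_point_id <- as.character(hazard_areas$hazard_point_id)
  hazard_areas$event_id <- as.character(hazard_areas$event_id)

  if (anyDuplicated(scenes$scene_id)) {
    stop("duplicate scene_id: ",
      paste(unique(scenes$scene_id[duplicated(scenes$scene_id)]), collapse = ", "),
      call. = FALSE
    )
  }
  if (anyDuplicated(hazard_areas$hazard_point_id)) {
    stop("duplicate hazard_point_id: ",
      paste(unique(hazard_areas$hazard_point_id[duplicated(hazard_areas$hazard_point_id)]),
        collapse = ", "
      ),
      call. = FALSE
    )
  }
  bad_region <- setdiff(unique(scenes$region_label), REGION_LABELS)
  if (length(bad_region)) {
    stop("unknown region_label: ", paste(bad_region, collapse = ", "), call. = FALSE)
  }
  bad_class <- setdiff(unique(hazard_areas$event_class), EVENT_CLASSES)
  if (length(bad_class)) {
    stop("unknown event_class: ", paste(bad_class, collapse = ", "), call. = FALSE)
  }
  if (nrow(scenes) && any(!is.finite(scenes$width) | scenes$width <= 0 |
    !is.finite(scenes$height) | scenes$height <= 0)) {
    stop("scene width and height must be positive", call. = FALSE)
  }

  if (nrow(hazard_areas)) {
    if (any(!is.finite(hazard_areas$radius) | hazard_areas$radius <= 0)) {
      bad <- hazard_areas$hazard_point_id[!is.finite(hazard_areas$radius) |
        hazard_areas$radius <= 0]
      stop("radius must be positive for hazard point(s): ",
        paste(bad, collapse = ", "),
        call. = FALSE
      )
    }
    unknown <- setdiff(hazard_areas$scene_id, scenes$scene_id)
    if (length(unknown)) {
      stop("hazard areas reference unknown scene(s): ",
        paste(unknown, collapse = ", "),
        call. = FALSE
      )
    }
    idx <- match(hazard_areas$scene_id, scenes$scene_id)
    if (any(!scenes$has_hazard[idx])) {
      stop("hazard areas placed on scene(s) flagged has_hazard = FALSE: ",
        paste(unique(hazard_areas$scene_id[!scenes$has_hazard[idx]]), collapse = ", "),
        call. = FALSE
      )
    }
    inside <- hazard_areas$center_x - hazard_areas$radius >= 0 &
      hazard_areas$center_x + hazard_areas$radius <= scenes$width[idx] &
      hazard_areas$center_y - hazard_areas$radius >= 0 &
      hazard_areas$center_y + hazard_areas$radius <= scenes$height[idx]
    if (any(!inside)) {
      stop("hazard circle(s) extend outside the image bounds: ",
        paste(hazard_areas$hazard_point_id[!inside], collapse = ", "),
        call. = FALSE
      )
    }
  }

  n_per_scene <- table(factor(hazard_areas$scene_id, levels = scenes$scene_id))
  flagged <- scenes$has_hazard
  empty_flagged <- scenes$scene_id[flagged & n_per_scene[scenes$scene_id] == 0]
  if (length(empty_flagged)) {
    stop("scene(s) flagged has_hazard = TRUE but carry no hazard area: ",
      paste(empty_flagged, collapse = ", "),
      call. = FALSE
    )
  }
  if (emulation) {
    too_many <- scenes$scene_id[n_per_scene[scenes$scene_id] > 3]
    if (length(too_many)) {
      stop("emulation mode requires 1-3 hazard areas per hazardous scene; ",
        "violated by scene(s): ", paste(too_many, collapse = ", "),
        call. = FALSE
      )
    }
  }

  out <- list(
    scenes = scenes,
    hazard_areas = hazard_areas,
    n_scenes = nrow(scenes),
    n_hazard_scenes = sum(scenes$has_hazard),
    n_normal_scenes = sum(!scenes$has_hazard),
    n_hazard_points = nrow(hazard_areas),
    n_events = length(unique(hazard_areas$event_id[!is.na(hazard_areas$event_id)]))
  )
  class(out) <- "scene_set"
  out
}

#' @export
print.scene_set <- function(x, ...) {
  cat(sprintf(
    "<scene_set> %d scenes (%d hazardous, %d normal), %d hazard points in %d events\n",
    x$n_scenes, x$n_hazard_scenes, x$n_normal_scenes, x$n_hazard_points, x$n_events
  ))
  invisible(x)
}

#' Construct an observer response
#'
#' One observer's free-response marks for one reading session: each mark is a
#' clicked location in a scene plus a continuous confidence rating in
#' (0, 1] ("possibly hazardous" to "definitely hazardous"). A scene may carry
#' any number of marks, including none; mark order is preserved because it
#' breaks rating ties during scoring.
#'
#' @param observer_id,group_label,session_label identifying strings;
#'   `group_label` is free text (e.g. an experience band or occupation) and
#'   `session_label` distinguishes repeated readings (e.g. "before"/"after").
#' @param marks data.frame with columns `scene_id`, `x`, `y`, `rating`.
#' @return An object of class `observer_response`.
#' @export
observer_response <- function(observer_id, group_label = "", session_label = "",
                              marks = data.frame(
                                scene_id = character(), x = numeric(),
                                y = numeric(), rating = numeric()
                              )) {
  marks <- as.data.frame(marks, stringsAsFactors = FALSE)
  need <- c("scene_id", "x", "y", "rating")
  if (!all(need %in% names(marks))) {
    stop("marks is missing column(s): ", paste(setdiff(need, names(marks)), collapse = ", "),
      call. = FALSE
    )
  }
  marks <- marks[need]
  marks$scene_id <- as.character(marks$scene_id)
  if (nrow(marks)) {
    if (any(!is.finite(marks$x) | !is.finite(marks$y))) {
      stop("mark coordinates must be finite numbers", call. = FALSE)
    }
    bad <- !is.finite(marks$rating) | marks$rating <= 0 | marks$rating > 1
    if (any(bad)) {
      stop("rating outside (0, 1] for mark(s) at row(s): ",
        paste(which(bad), collapse = ", "),
        call. = FALSE
      )
    }
  }
  rownames(marks) <- NULL
  out <- list(
    observer_id = as.character(observer_id),
    group_label = as.character(group_label),
    session_label = as.character(session_label),
    marks = marks
  )
  class(out) <- "observer_response"
  out
}

#' @export
print.observer_response <- function(x, ...) {
  cat(sprintf(
    "<observer_response> %s [%s/%s]: %d marks on %d scenes\n",
    x$observer_id, x$group_label, x$session_label,
    nrow(x$marks), length(unique(x$marks$scene_id))
  ))
  invisible(x)
}

#' Validate observer responses against a scene set
#'
#' Cross-checks loaded responses against the ground truth before scoring:
#' marks must reference known scenes and lie inside the image bounds, and
#' each (observer, session) pair must appear once. Any reported error is a
#' hard error; [run_scoring()] refuses to score while the report is
#' non-empty.
#'
#' @param scene_set a [scene_set()].
#' @param responses a list of [observer_response()] objects.
#' @return A data.frame of class `validation_report` with columns
#'   `observer_id`, `session_label`, `scene_id`, `error`; zero rows when the
#'   study is clean.
#' @export
validate_study <- function(scene_set, responses) {
  stopifnot(inherits(scene_set, "scene_set"))
  if (inherits(responses, "observer_response")) responses <- list(responses)
  rows <- list()
  add <- function(obs, ses, scn, msg) {
    rows[[length(rows) + 1]] <<- data.frame(
      observer_id = obs, session_label = ses, scene_id = scn, error = msg,
      stringsAsFactors = FALSE
    )
  }
  keys <- vapply(responses, function(r) paste(r$observer_id, r$session_label, sep = "\r"),
    character(1)
  )
  for (k in unique(keys[duplicated(keys)])) {
    parts <- strsplit(k, "\r", fixed = TRUE)[[1]]
    add(parts[1], parts[2], NA_character_, "duplicate observer/session pair")
  }
  for (r in responses) {
    m <- r$marks
    if (!nrow(m)) next
    idx <- match(m$scene_id, scene_set$scenes$scene_id)
    for (i in which(is.na(idx))) {
      add(
        r$observer_id, r$session_label, m$scene_id[i],
        sprintf("mark %d references unknown scene", i)
      )
    }
    ok <- !is.na(idx)
    out_of_bounds <- ok & (m$x < 0 | m$x > scene_set$scenes$width[idx] |
      m$y < 0 | m$y > scene_set$scenes$height[idx])
    for (i in which(out_of_bounds)) {
      add(
        r$observer_id, r$session_label, m$scene_id[i],
        sprintf("mark %d at (%g, %g) lies outside the image bounds", i, m$x[i], m$y[i])
      )
    }
  }
  report <- if (length(rows)) {
    do.call(rbind, rows)
  } else {
    data.frame(
      observer_id = character(), session_label = character(),
      scene_id = character(), error = character(), stringsAsFactors = FALSE
    )
  }
  class(report) <- c("validation_report", "data.frame")
  report
}

#' @export
print.validation_report <- function(x, ...) {
  if (!nrow(x)) {
    cat("<validation_report> clean: no errors\n")
  } else {
    cat(sprintf("<validation_report> %d hard error(s):\n", nrow(x)))
    print.data.frame(x)
  }
  invisible(x)
}
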