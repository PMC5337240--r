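#' Score an observer's marks against the ground truth
#'
#' Implements the localization scoring rule of the free-response paradigm
#' with circular acceptance regions:
#'
#' * a mark is *inside* a hazard area iff its Euclidean distance from the
#'   area's center is at most the radius (boundary inclusive);
#' * a mark inside two overlapping areas is assigned to the area whose center
#'   is nearest (ties broken by lowest `hazard_point_id`);
#' * among all inside-marks of one hazard point, the one with the highest
#'   rating is the true positive (`TP`); an exact rating tie is broken in
#'   favour of the earliest-entered mark. The remaining inside-marks are
#'   `suppressed` and excluded from every downstream count and curve;
#' * every other mark — outside all areas, or on a scene without hazard
#'   points — is a false positive (`FP`).
#'
#' @param scene_set a [scene_set()].
#' @param response an [observer_response()]. It must pass [validate_study()]
#'   against `scene_set`; scoring stops on the first hard error.
#' @return An object of class `scored_response`: the marks with `label`
#'   (`"TP"`, `"FP"`, `"suppressed"`) and `matched_hazard_point_id` columns,
#'   plus `tp_count`, `fp_count`, `detected_hazard_point_ids` and
#'   `marked_scene_ids`.
#' @examples
#' ss <- scene_set(
#'   scenes = data.frame(
#'     scene_id = c("H1", "N1"), has_hazard = c(TRUE, FALSE),
#'     width = 400, height = 300, region_label = "chest"
#'   ),
#'   hazard_areas = data.frame(
#'     hazard_point_id = "hp1", scene_id = "H1", center_x = 100,
#'     center_y = 100, radius = 50, event_id = "e1", event_class = "falling"
#'   )
#' )
#' r <- observer_response("obs1", marks = data.frame(
#'   scene_id = c("H1", "H1", "H1"), x = c(120, 90, 200),
#'   y = c(110, 95, 200), rating = c(0.6, 0.4, 0.3)
#' ))
#' score_response(ss, r)
#' @export
score_response <- function(scene_set, response) {
  stopifnot(inherits(scene_set, "scene_set"), inherits(response, "observer_response"))
  report <- validate_study(scene_set, list(response))
  if (nrow(report)) {
    stop("response fails validation against the scene set: ",
      paste(report$error, collapse = "; "),
      call. = FALSE
    )
  }
  m <- response$marks
  n <- nrow(m)
  label <- character(n)
  matched <- rep(NA_character_, n)

  areas <- scene_set$hazard_areas
  if (n) {
    assigned <- rep(NA_character_, n)
    for (i in seq_len(n)) {
      a <- areas[areas$scene_id == m$scene_id[i], , drop = FALSE]
      if (!nrow(a)) next
      d <- sqrt((a$center_x - m$x[i])^2 + (a$center_y - m$y[i])^2)
      inside <- d <= a$radius
      if (!any(inside)) next
      cand <- which(inside)
      pick <- cand[order(d[cand], a$hazard_point_id[cand])][1]
      assigned[i] <- a$hazard_point_id[pick]
    }
    label[is.na(assigned)] <- "FP"
    for (hp in unique(assigned[!is.na(assigned)])) {
      idx <- which(assigned == hp)
      win <- idx[order(-m$rating[idx], idx)][1]
      label[win] <- "TP"
      label[setdiff(idx, win)] <- "suppressed"
      matched[idx] <- hp
    }
  }

  m$label <- label
  m$matched_hazard_point_id <- matched
  out <- list(
    observer_id = response$observer_id,
    group_label = response$group_label,
    session_label = response$session_label,
    marks = m,
    tp_count = sum(label == "TP"),
    fp_count = sum(label == "FP"),
    detected_hazard_point_ids = sort(unique(matched[label == "TP"])),
    marked_scene_ids = sort(unique(m$scene_id))
  )
  class(out) <- "scored_response"
  out
}

#' @export
print.scored_response <- function(x, ...) {
  cat(sprintf(
    "<scored_response> %s [%s]: %d TP, %d FP, %d suppressed\n",
    x$observer_id, x$session_label, x$tp_count, x$fp_count,
    sum(x$marks$label == "suppressed")
  ))
  invisible(x)
}

#' Point-based sensitivity
#'
#' Fraction of all hazard points in the scene set that the observer detected
#' (marked with a true positive), the per-lesion sensitivity of a
#' free-response study.
#'
#' @param scored a [score_response()] result.
#' @param scene_set the [scene_set()] it was scored against.
#' @return A fraction in \[0, 1\].
#' @export
sensitivity_points <- function(scored, scene_set) {
  stopifnot(inherits(scored, "scored_response"), inherits(scene_set, "scene_set"))
  if (scene_set$n_hazard_points == 0) {
    stop_undefined("point-based sensitivity", "the scene set has no hazard points")
  }
  length(scored$detected_hazard_point_ids) / scene_set$n_hazard_points
}

#' Event-based sensitivity
#'
#' Fraction of events detected, where an event counts as detected as soon as
#' at least one of its hazard points is detected. Hazard points without an
#' event (`event_id` NA) are excluded from both numerator and denominator.
#' Because several hazard points can cause the same event, this is the
#' per-case recomputation of sensitivity on events rather than points.
#'
#' @inheritParams sensitivity_points
#' @return A fraction in \[0, 1\].
#' @export
sensitivity_events <- function(scored, scene_set) {
  stopifnot(inherits(scored, "scored_response"), inherits(scene_set, "scene_set"))
  if (scene_set$n_events == 0) {
    stop_undefined("event-based sensitivity", "the scene set has no events")
  }
  a <- scene_set$hazard_areas
  a <- a[!is.na(a$event_id), , drop = FALSE]
  detected <- a$hazard_point_id %in% scored$detected_hazard_point_ids
  sum(vapply(split(detected, a$event_id), any, logical(1))) / scene_set$n_events
}

#' Scene-based specificity
#'
#' Fraction of no-hazard scenes the observer correctly identified as such,
#' i.e. left entirely unmarked. Any mark on a no-hazard scene (necessarily a
#' false positive) makes that scene incorrect.
#'
#' @inheritParams sensitivity_points
#' @return A fraction in \[0, 1\].
#' @export
specificity_scenes <- function(scored, scene_set) {
  stopifnot(inherits(scored, "scored_response"), inherits(scene_set, "scene_set"))
  if (scene_set$n_normal_scenes == 0) {
    stop_undefined("scene-based specificity", "the scene set has no no-hazard scenes")
  }
  normal <- scene_set$scenes$scene_id[!scene_set$scenes$has_hazard]
  sum(!(normal %in% scored$marked_scene_ids)) / scene_set$n_normal_scenes
}
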