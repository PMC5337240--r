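#' Read and write scene-set ground truth (JSON)
#'
#' The scene-set file is a JSON document with a single `scenes` array; each
#' scene object carries `scene_id`, `has_hazard`, `width`, `height`,
#' `region_label` and a (possibly empty) `hazard_areas` array of objects with
#' `hazard_point_id`, `center_x`, `center_y`, `radius`, `event_id` (null for
#' hazard points without an event) and `event_class`. Numbers are written at
#' full precision so that a write/read cycle reproduces the object exactly.
#'
#' @param path file path.
#' @param emulation passed to [scene_set()]; enforce the 1-3 areas-per-scene
#'   reference composition when `TRUE`.
#' @return `read_scene_set()` returns a [scene_set()]; `write_scene_set()`
#'   returns `path` invisibly.
#' @export
read_scene_set <- function(path, emulation = FALSE) {
  if (!file.exists(path)) stop("scene-set file not found: ", path, call. = FALSE)
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) stop("cannot parse scene-set JSON ", path, ": ", conditionMessage(e), call. = FALSE)
  )
  if (is.null(doc$scenes)) {
    stop("scene-set file ", path, ": missing top-level field 'scenes'", call. = FALSE)
  }
  scn <- function(field, record, i, coerce, allow_null = FALSE) {
    v <- record[[field]]
    if (is.null(v)) {
      if (allow_null) {
        return(NA)
      }
      stop(sprintf("scene-set file %s: scene record %d is missing field '%s'", path, i, field),
        call. = FALSE
      )
    }
    coerce(v)
  }
  scenes <- empty_scenes()
  areas <- list(empty_hazard_areas())
  for (i in seq_along(doc$scenes)) {
    s <- doc$scenes[[i]]
    scenes <- rbind(scenes, data.frame(
      scene_id = scn("scene_id", s, i, as.character),
      has_hazard = scn("has_hazard", s, i, as.logical),
      width = scn("width", s, i, as.numeric),
      height = scn("height", s, i, as.numeric),
      region_label = scn("region_label", s, i, as.character),
      stringsAsFactors = FALSE
    ))
    for (j in seq_along(s$hazard_areas)) {
      a <- s$hazard_areas[[j]]
      fld <- function(field, coerce, allow_null = FALSE) {
        v <- a[[field]]
        if (is.null(v)) {
          if (allow_null) {
            return(NA)
          }
          stop(sprintf(
            "scene-set file %s: hazard area %d of scene record %d is missing field '%s'",
            path, j, i, field
          ), call. = FALSE)
        }
        coerce(v)
      }
      areas[[length(areas) + 1]] <- data.frame(
        hazard_point_id = fld("hazard_point_id", as.character),
        scene_id = scenes$scene_id[nrow(scenes)],
        center_x = fld("center_x", as.numeric),
        center_y = fld("center_y", as.numeric),
        radius = fld("radius", as.numeric),
        event_id = fld("event_id", as.character, allow_null = TRUE),
        event_class = fld("event_class", as.character),
        stringsAsFactors = FALSE
      )
    }
  }
  scene_set(scenes, do.call(rbind, areas), emulation = emulation)
}

#' @rdname read_scene_set
#' @param x a [scene_set()].
#' @export
write_scene_set <- function(x, path) {
  stopifnot(inherits(x, "scene_set"))
  scenes <- lapply(seq_len(nrow(x$scenes)), function(i) {
    s <- x$scenes[i, ]
    a <- x$hazard_areas[x$hazard_areas$scene_id == s$scene_id, , drop = FALSE]
    list(
      scene_id = s$scene_id, has_hazard = s$has_hazard,
      width = s$width, height = s$height, region_label = s$region_label,
      hazard_areas = lapply(seq_len(nrow(a)), function(j) {
        list(
          hazard_point_id = a$hazard_point_id[j],
          center_x = a$center_x[j], center_y = a$center_y[j],
          radius = a$radius[j],
          event_id = if (is.na(a$event_id[j])) NULL else a$event_id[j],
          event_class = a$event_class[j]
        )
      })
    )
  })
  jsonlite::write_json(list(scenes = scenes), path,
    auto_unbox = TRUE, digits = I(17), null = "null", pretty = TRUE
  )
  invisible(path)
}

#' Read and write observer mark-rating responses (CSV)
#'
#' The response file is a long-format CSV with header
#' `observer_id,group_label,session_label,scene_id,x,y,rating`, one row per
#' mark, UTF-8, `.` decimal separator. Rows are grouped into one
#' [observer_response()] per (observer_id, session_label) pair in file
#' order; group labels must be constant within a pair. Ratings must lie in
#' (0, 1]. Coordinates and ratings are written with 17 significant digits so
#' a write/read cycle is exact.
#'
#' @param path file path.
#' @return `read_responses()` returns a list of [observer_response()]
#'   objects; `write_responses()` returns `path` invisibly.
#' @export
read_responses <- function(path) {
  if (!file.exists(path)) stop("response file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character", fileEncoding = "UTF-8")
  need <- c("observer_id", "group_label", "session_label", "scene_id", "x", "y", "rating")
  if (!all(need %in% names(df))) {
    stop("response file ", path, " is missing column(s): ",
      paste(setdiff(need, names(df)), collapse = ", "),
      call. = FALSE
    )
  }
  if (!nrow(df)) {
    return(list())
  }
  num <- function(col) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v))
    if (length(bad)) {
      stop(sprintf(
        "response file %s: non-numeric '%s' at data row(s) %s",
        path, col, paste(bad, collapse = ", ")
      ), call. = FALSE)
    }
    v
  }
  x <- num("x")
  y <- num("y")
  rating <- num("rating")
  bad <- which(rating <= 0 | rating > 1)
  if (length(bad)) {
    stop(sprintf(
      "response file %s: rating outside (0, 1] at data row(s) %s (scale starts at 0.01)",
      path, paste(bad, collapse = ", ")
    ), call. = FALSE)
  }
  key <- paste(df$observer_id, df$session_label, sep = "\r")
  out <- lapply(unique(key), function(k) {
    sel <- key == k
    grp <- unique(df$group_label[sel])
    if (length(grp) > 1) {
      stop(sprintf(
        "response file %s: observer/session %s carries conflicting group labels (%s)",
        path, sub("\r", "/", k, fixed = TRUE), paste(grp, collapse = ", ")
      ), call. = FALSE)
    }
    observer_response(
      observer_id = df$observer_id[sel][1],
      group_label = grp,
      session_label = df$session_label[sel][1],
      marks = data.frame(
        scene_id = df$scene_id[sel], x = x[sel], y = y[sel], rating = rating[sel],
        stringsAsFactors = FALSE
      )
    )
  })
  out
}

#' @rdname read_responses
#' @param responses a list of [observer_response()] objects (or a single one).
#' @export
write_responses <- function(responses, path) {
  if (inherits(responses, "observer_response")) responses <- list(responses)
  rows <- lapply(responses, function(r) {
    if (!nrow(r$marks)) {
      return(NULL)
    }
    data.frame(
      observer_id = r$observer_id, group_label = r$group_label,
      session_label = r$session_label, scene_id = r$marks$scene_id,
      x = sprintf("%.17g", r$marks$x), y = sprintf("%.17g", r$marks$y),
      rating = sprintf("%.17g", r$marks$rating),
      stringsAsFactors = FALSE
    )
  })
  df <- do.call(rbind, c(rows, list(data.frame(
    observer_id = character(), group_label = character(), session_label = character(),
    scene_id = character(), x = character(), y = character(), rating = character(),
    stringsAsFactors = FALSE
  ))))
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write scored marks to CSV
#'
#' One row per mark with its scoring label, header
#' `observer_id,session_label,scene_id,x,y,rating,label,matched_hazard_point_id`.
#'
#' @param scored a [score_response()] result or list of them.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_scored_marks <- function(scored, path) {
  if (inherits(scored, "scored_response")) scored <- list(scored)
  rows <- lapply(scored, function(s) {
    if (!nrow(s$marks)) {
      return(NULL)
    }
    data.frame(
      observer_id = s$observer_id, session_label = s$session_label,
      scene_id = s$marks$scene_id,
      x = sprintf("%.17g", s$marks$x), y = sprintf("%.17g", s$marks$y),
      rating = sprintf("%.17g", s$marks$rating),
      label = s$marks$label,
      matched_hazard_point_id = s$marks$matched_hazard_point_id,
      stringsAsFactors = FALSE
    )
  })
  df <- do.call(rbind, c(rows, list(data.frame(
    observer_id = character(), session_label = character(), scene_id = character(),
    x = character(), y = character(), rating = character(), label = character(),
    matched_hazard_point_id = character(), stringsAsFactors = FALSE
  ))))
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}
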