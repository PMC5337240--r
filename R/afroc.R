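#' Reduce a scored response to AFROC rating data
#'
#' The sufficient statistic for the AFROC figure of merit: per hazard point,
#' the rating of its true-positive mark (absent if undetected), and per
#' FP-contributing scene, the highest false-positive rating on that scene
#' (absent if the scene carries no FP). Suppressed marks never contribute.
#'
#' @param scored a [score_response()] result.
#' @param scene_set the [scene_set()] it was scored against.
#' @param variant which scenes contribute FP maxima: `"normal_only"` (default)
#'   uses the no-hazard scenes only; `"all_scenes"` uses every scene. The two
#'   agree whenever the observer places no FP on hazardous scenes.
#' @return An object of class `rating_data`: named numeric vectors
#'   `lesion_ratings` (by hazard_point_id) and `normal_fp_max` (by scene_id),
#'   plus the denominators `n_lesions` and `n_fp_scenes` and the `variant`.
#' @export
rating_data <- function(scored, scene_set, variant = c("normal_only", "all_scenes")) {
  stopifnot(inherits(scored, "scored_response"), inherits(scene_set, "scene_set"))
  variant <- match.arg(variant)
  m <- scored$marks

  tp <- m[m$label == "TP", , drop = FALSE]
  lesion_ratings <- stats::setNames(tp$rating, tp$matched_hazard_point_id)

  fp_scenes <- if (variant == "normal_only") {
    scene_set$scenes$scene_id[!scene_set$scenes$has_hazard]
  } else {
    scene_set$scenes$scene_id
  }
  fp <- m[m$label == "FP" & m$scene_id %in% fp_scenes, , drop = FALSE]
  normal_fp_max <- if (nrow(fp)) {
    vapply(split(fp$rating, fp$scene_id), max, numeric(1))
  } else {
    stats::setNames(numeric(0), character(0))
  }

  out <- list(
    observer_id = scored$observer_id,
    session_label = scored$session_label,
    lesion_ratings = lesion_ratings,
    normal_fp_max = normal_fp_max,
    n_lesions = scene_set$n_hazard_points,
    n_fp_scenes = length(fp_scenes),
    variant = variant
  )
  class(out) <- "rating_data"
  out
}

# Pad the observed ratings out to the full denominators, absences as -Inf.
rating_vectors <- function(rd) {
  r <- c(rd$lesion_ratings, rep(-Inf, rd$n_lesions - length(rd$lesion_ratings)))
  m <- c(rd$normal_fp_max, rep(-Inf, rd$n_fp_scenes - length(rd$normal_fp_max)))
  list(r = unname(r), m = unname(m))
}

#' Wilcoxon-type AFROC figure of merit
#'
#' The figure of merit \eqn{\theta} is the probability that a randomly chosen
#' hazard point's TP rating exceeds a randomly chosen FP-scene's highest FP
#' rating:
#' \deqn{\theta = \frac{1}{N_L N_S} \sum_{\ell=1}^{N_L} \sum_{s=1}^{N_S}
#'   \psi(r_\ell, m_s)}
#' with \eqn{\psi = 1} if \eqn{r_\ell > m_s}, \eqn{1/2} if both ratings are
#' present and equal, and 0 otherwise. An undetected hazard point and an
#' unmarked scene enter as \eqn{-\infty}; the (undetected, unmarked) pair
#' scores 0, so an observer who marks nothing scores 0 and one who detects
#' every point without any FP scores 1. \eqn{\theta} equals the trapezoidal
#' area under the empirical AFROC curve whenever every hazard point and every
#' FP scene has a finite rating, and is the definition of record otherwise.
#'
#' @param rd a [rating_data()] object.
#' @return \eqn{\theta} in \[0, 1\].
#' @export
afroc_fom <- function(rd) {
  stopifnot(inherits(rd, "rating_data"))
  if (rd$n_lesions < 1) stop_undefined("figure of merit", "no hazard points (n_lesions = 0)")
  if (rd$n_fp_scenes < 1) stop_undefined("figure of merit", "no FP-contributing scenes (n_fp_scenes = 0)")
  v <- rating_vectors(rd)
  gt <- outer(v$r, v$m, ">")
  eq <- outer(v$r, v$m, "==") & outer(is.finite(v$r), is.finite(v$m), "&")
  (sum(gt) + 0.5 * sum(eq)) / (rd$n_lesions * rd$n_fp_scenes)
}

#' Empirical AFROC curve
#'
#' Operating points of the alternative free-response ROC curve: at each
#' threshold (the distinct ratings present, descending) the lesion
#' localization fraction LLF (hazard points whose TP rating meets the
#' threshold, over all hazard points) is plotted against the false-positive
#' fraction FPF (FP scenes whose highest FP rating meets the threshold, over
#' all FP-contributing scenes). The polyline is anchored at (0, 0) and
#' extended to (1, 1) for display.
#'
#' The authoritative area (`area`) is the Wilcoxon statistic [afroc_fom()],
#' which handles undetected points and unmarked scenes unambiguously;
#' `polyline_area` is the trapezoidal area of the displayed polyline and
#' equals `area` exactly when all ratings are finite.
#'
#' @param rd a [rating_data()] object.
#' @return An object of class `afroc_curve`: `points` (data.frame
#'   `threshold`, `fpf`, `llf`, endpoints carrying `NA` thresholds), `area`,
#'   `polyline_area`, `n_lesions`, `n_fp_scenes`.
#' @export
afroc_curve <- function(rd) {
  stopifnot(inherits(rd, "rating_data"))
  theta <- afroc_fom(rd)
  thr <- sort(unique(c(rd$lesion_ratings, rd$normal_fp_max)), decreasing = TRUE)
  v <- rating_vectors(rd)
  pts <- data.frame(
    threshold = thr,
    fpf = vapply(thr, function(t) sum(v$m >= t) / rd$n_fp_scenes, numeric(1)),
    llf = vapply(thr, function(t) sum(v$r >= t) / rd$n_lesions, numeric(1))
  )
  pts <- rbind(
    data.frame(threshold = NA_real_, fpf = 0, llf = 0),
    pts,
    data.frame(threshold = NA_real_, fpf = 1, llf = 1)
  )
  rownames(pts) <- NULL
  out <- list(
    observer_id = rd$observer_id,
    session_label = rd$session_label,
    points = pts,
    area = theta,
    polyline_area = trapezoid(pts$fpf, pts$llf),
    n_lesions = rd$n_lesions,
    n_fp_scenes = rd$n_fp_scenes
  )
  class(out) <- "afroc_curve"
  out
}

#' @export
print.afroc_curve <- function(x, ...) {
  cat(sprintf(
    "<afroc_curve> %d operating points; FOM (Wilcoxon area) = %.4f\n",
    nrow(x$points) - 2L, x$area
  ))
  invisible(x)
}

# LLF of the display polyline at arbitrary FPF values: the value at the top
# of any vertical jump, linear interpolation elsewhere.
curve_llf_at <- function(curve, fpf) {
  x <- curve$points$fpf
  y <- curve$points$llf
  vapply(fpf, function(g) {
    j <- findInterval(g, x) # largest j with x[j] <= g
    if (x[j] == g || j == length(x)) {
      y[j]
    } else {
      y[j] + (y[j + 1] - y[j]) * (g - x[j]) / (x[j + 1] - x[j])
    }
  }, numeric(1))
}

#' Reader-averaged AFROC curve
#'
#' Vertical (LLF) average of several observers' display polylines on an
#' evenly spaced FPF grid, the usual way a group's average AFROC curve is
#' plotted. The `area` of the averaged polyline is reported separately from
#' `mean_fom`, the arithmetic mean of the member figures of merit — group
#' FOMs are always averaged as numbers, never read off the averaged curve.
#'
#' @param curves a non-empty list of [afroc_curve()] objects.
#' @param grid_size number of grid intervals on \[0, 1\] (default 100, i.e.
#'   101 FPF sample points).
#' @return An object of class `afroc_curve` (points carry `NA` thresholds)
#'   with extra fields `mean_fom` and `n_curves`.
#' @export
average_afroc_curves <- function(curves, grid_size = 100) {
  if (inherits(curves, "afroc_curve")) curves <- list(curves)
  stopifnot(length(curves) >= 1, all(vapply(curves, inherits, logical(1), "afroc_curve")))
  stopifnot(grid_size >= 1)
  grid <- seq(0, 1, length.out = grid_size + 1)
  llf <- rowMeans(vapply(curves, curve_llf_at, numeric(length(grid)), fpf = grid))
  pts <- data.frame(threshold = NA_real_, fpf = grid, llf = llf)
  out <- list(
    observer_id = NA_character_,
    session_label = NA_character_,
    points = pts,
    area = trapezoid(grid, llf),
    polyline_area = trapezoid(grid, llf),
    mean_fom = mean(vapply(curves, function(cv) cv$area, numeric(1))),
    n_curves = length(curves),
    n_lesions = curves[[1]]$n_lesions,
    n_fp_scenes = curves[[1]]$n_fp_scenes
  )
  class(out) <- c("afroc_curve_avg", "afroc_curve")
  out
}

#' @export
print.afroc_curve_avg <- function(x, ...) {
  cat(sprintf(
    "<afroc_curve_avg> average of %d curves; polyline area = %.4f, mean FOM = %.4f\n",
    x$n_curves, x$area, x$mean_fom
  ))
  invisible(x)
}

#' Plot AFROC curves
#'
#' @param curves a named list of [afroc_curve()] objects (names become the
#'   legend labels), or a single curve.
#' @param title optional plot title.
#' @return A ggplot object with FPF on \[0, 1\] against LLF on \[0, 1\].
#' @export
plot_afroc <- function(curves, title = "AFROC curves") {
  if (inherits(curves, "afroc_curve")) curves <- list(curve = curves)
  if (is.null(names(curves))) names(curves) <- paste0("curve", seq_along(curves))
  df <- do.call(rbind, lapply(names(curves), function(nm) {
    p <- curves[[nm]]$points
    data.frame(label = nm, fpf = p$fpf, llf = p$llf, stringsAsFactors = FALSE)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = fpf, y = llf, colour = label)) +
    ggplot2::geom_line() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted", colour = "grey50") +
    ggplot2::coord_fixed(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = "False-positive fraction (FPF)",
      y = "Lesion localization fraction (LLF)",
      colour = NULL, title = title
    ) +
    ggplot2::theme_minimal()
}
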