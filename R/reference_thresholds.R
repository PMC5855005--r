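# The three fixed-threshold comparison methods. Each yields one constant
# threshold per channel and the usual on/off-ground rule (force >= T).

#' Body-weight-fraction threshold (Mariani method)
#'
#' A constant threshold at 5% of body weight: `0.05 * mass_kg * g` newtons.
#' Runs in real time but does not adapt to walking speed, and requires the
#' wearer's mass.
#'
#' @param mass_kg Body mass in kilograms (> 0).
#' @param g Gravitational acceleration in m/s^2 (default 9.81).
#' @return Threshold in newtons.
#' @examples
#' mariani_threshold(67.3)
#' @export
mariani_threshold <- function(mass_kg, g = 9.81) {
  if (!is.numeric(mass_kg) || length(mass_kg) != 1L || !is.finite(mass_kg) ||
      mass_kg <= 0) {
    stop("`mass_kg` must be a single positive number", call. = FALSE)
  }
  0.05 * mass_kg * g
}

#' Global-extrema span threshold (timing-analysis-module method)
#'
#' A post-processing threshold at 10% of the recording's global force span:
#' `T_min + (T_max - T_min) * 10/100`, computed severally per channel per
#' trial. On a constant trace the span collapses and the threshold equals
#' the constant.
#'
#' @param rec A [gcf_recording()] or numeric force vector.
#' @return Threshold in newtons.
#' @examples
#' tam_threshold(c(0, 40, 100, 30))
#' @export
tam_threshold <- function(rec) {
  f <- if (inherits(rec, "gcf_recording")) rec$f else as.numeric(rec)
  if (length(f) == 0L) stop("recording is empty", call. = FALSE)
  mn <- min(f)
  mx <- max(f)
  mn + (mx - mn) * 10 / 100
}

#' Per-cycle extrema of a force trace
#'
#' Segments the trace into maximal runs at-or-above and below a split level
#' and takes one local maximum per above-run and one local minimum per
#' below-run. Leading or trailing incomplete half-cycles contribute an
#' extremum only to their own list, so the counts `k` (maxima) and `l`
#' (minima) may differ by one — exactly the situation an incomplete gait
#' cycle creates.
#'
#' @param rec A [gcf_recording()] or numeric force vector.
#' @param split_level Level separating stance lobes from swing valleys, in
#'   newtons; must lie within the data range. A natural self-contained
#'   choice is [tam_threshold()] of the same recording.
#' @return A list of class `extrema_summary` with fields `local_maxima`,
#'   `local_minima`, `global_max`, `global_min`, `k`, `l`.
#' @examples
#' find_cycle_extrema(rep(c(500, 0), times = 3, each = 10), split_level = 50)
#' @export
find_cycle_extrema <- function(rec, split_level) {
  f <- if (inherits(rec, "gcf_recording")) rec$f else as.numeric(rec)
  if (length(f) == 0L) stop("recording is empty", call. = FALSE)
  if (!is.finite(split_level) || split_level < min(f) ||
      split_level > max(f)) {
    stop("`split_level` must lie within the data range", call. = FALSE)
  }
  above <- f >= split_level
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  maxima <- numeric(0)
  minima <- numeric(0)
  for (q in seq_along(r$values)) {
    seg <- f[starts[q]:ends[q]]
    if (r$values[q]) {
      maxima <- c(maxima, max(seg))
    } else {
      minima <- c(minima, min(seg))
    }
  }
  structure(
    list(
      local_maxima = maxima, local_minima = minima,
      global_max = max(f), global_min = min(f),
      k = length(maxima), l = length(minima)
    ),
    class = "extrema_summary"
  )
}

#' @export
print.extrema_summary <- function(x, ...) {
  cat(sprintf(
    "<extrema_summary> k=%d maxima (mean %.2f N), l=%d minima (mean %.2f N), global [%.2f, %.2f] N\n",
    x$k, if (x$k) mean(x$local_maxima) else NA_real_,
    x$l, if (x$l) mean(x$local_minima) else NA_real_,
    x$global_min, x$global_max
  ))
  invisible(x)
}

#' Averaged per-cycle extrema threshold (Lopez--Meyer method)
#'
#' A post-processing threshold placed a proportion `alpha` of the way from
#' the mean of the per-cycle minima to the mean of the per-cycle maxima:
#' `TMIN + alpha * (TMAX - TMIN)` with `TMAX = mean(local_maxima)` and
#' `TMIN = mean(local_minima)`. `alpha` compensates for interindividual
#' variability in pressure levels; 0.084 is the conventional setting.
#'
#' @param ext An `extrema_summary` from [find_cycle_extrema()], or a
#'   [gcf_recording()] / numeric vector (in which case extrema are found
#'   with [find_cycle_extrema()] at the [tam_threshold()] split level).
#' @param alpha Proportional factor in (0, 1), default 0.084.
#' @return Threshold in newtons.
#' @examples
#' lopez_meyer_threshold(list(local_maxima = c(300, 500),
#'                            local_minima = c(0, 10)))
#' @export
lopez_meyer_threshold <- function(ext, alpha = 0.084) {
  if (inherits(ext, "gcf_recording") || is.numeric(ext)) {
    ext <- find_cycle_extrema(ext, split_level = tam_threshold(ext))
  }
  if (length(ext$local_maxima) == 0L || length(ext$local_minima) == 0L) {
    stop("need at least one local maximum and one local minimum",
         call. = FALSE)
  }
  TMAX <- mean(ext$local_maxima)
  TMIN <- mean(ext$local_minima)
  TMIN + alpha * (TMAX - TMIN)
}

#' Classify every sample of a recording against a constant threshold
#'
#' @param rec A [gcf_recording()] or numeric force vector.
#' @param t Threshold in newtons; a sample exactly at `t` is on-ground.
#' @return Character vector of `"on_ground"` / `"off_ground"`.
#' @examples
#' classify_with_threshold(c(10, 33, 50), 33)
#' @export
classify_with_threshold <- function(rec, t) {
  f <- if (inherits(rec, "gcf_recording")) rec$f else as.numeric(rec)
  if (length(f) == 0L) stop("recording is empty", call. = FALSE)
  classify_sample(f, t)
}
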