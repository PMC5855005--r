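# Gait phase detection algorithm (GPDA): map per-sample (heel, ball)
# contact statuses to phases and events by the four-row rule table
#
#   heel        ball        label        category
#   on-ground   on-ground   stance       phase
#   off-ground  off-ground  swing        phase
#   on-ground   off-ground  heel_strike  event
#   off-ground  on-ground   heel_off     event

#' The four gait labels and their categories
#'
#' @return A data frame with columns `label` and `category` giving the
#'   complete label set: `stance` and `swing` are phases; `heel_strike` and
#'   `heel_off` are events (event labels persist over every sample of the
#'   combined status that defines them).
#' @export
gait_label_levels <- function() {
  data.frame(
    label = c("stance", "swing", "heel_strike", "heel_off"),
    category = c("phase", "phase", "event", "event")
  )
}

#' Label one sample (or a vector of samples) from its contact statuses
#'
#' Total over the four status combinations: both sensors on-ground is
#' stance, both off-ground is swing, heel only is heel-strike, ball only is
#' heel-off.
#'
#' @param heel,ball Character vectors of `"on_ground"` / `"off_ground"`.
#' @return Character vector of gait labels.
#' @examples
#' label_sample("on_ground", "off_ground")
#' @export
label_sample <- function(heel, ball) {
  if (length(heel) != length(ball)) {
    stop("`heel` and `ball` must have equal length", call. = FALSE)
  }
  ok <- c("on_ground", "off_ground")
  if (!all(heel %in% ok) || !all(ball %in% ok)) {
    stop("statuses must be \"on_ground\" or \"off_ground\"", call. = FALSE)
  }
  h <- heel == "on_ground"
  b <- ball == "on_ground"
  out <- character(length(h))
  out[h & b] <- "stance"
  out[!h & !b] <- "swing"
  out[h & !b] <- "heel_strike"
  out[!h & b] <- "heel_off"
  out
}

# Merge runs shorter than min_run samples into the preceding run's value
# (the leading run is kept regardless). Used to debounce noisy statuses.
.debounce_runs <- function(x, min_run) {
  if (min_run <= 1L) return(x)
  r <- rle(x)
  if (length(r$lengths) > 1L) {
    for (q in 2:length(r$lengths)) {
      if (r$lengths[q] < min_run) r$values[q] <- r$values[q - 1L]
    }
  }
  inverse.rle(r)
}

#' Label a status sequence and extract gait events
#'
#' Applies [label_sample()] per sample and emits one discrete event at the
#' first sample of each maximal run labelled `heel_strike` or `heel_off`.
#' Events are indexed by cycle, a cycle starting at each heel-strike.
#'
#' @param heel_statuses,ball_statuses Equal-length character vectors of
#'   `"on_ground"` / `"off_ground"`.
#' @param time_s Optional numeric vector of sample times; defaults to
#'   `(0, 1, 2, ...) / fs`.
#' @param fs Sampling rate used when `time_s` is absent (default 1, i.e.
#'   event times in sample units).
#' @param min_run_samples Optional debounce: status runs shorter than this
#'   many samples are merged into the preceding run before labelling
#'   (default 0, no debouncing).
#' @return A list of class `gpda_result` with `labels` (character, one per
#'   sample) and `events` (data frame `label,t,cycle_index`, times strictly
#'   increasing).
#' @examples
#' heel <- c("off_ground", "on_ground", "on_ground", "off_ground", "off_ground")
#' ball <- c("off_ground", "off_ground", "on_ground", "on_ground", "off_ground")
#' detect_sequence(heel, ball)
#' @export
detect_sequence <- function(heel_statuses, ball_statuses, time_s = NULL,
                            fs = 1, min_run_samples = 0) {
  n <- length(heel_statuses)
  if (length(ball_statuses) != n) {
    stop("status sequences must have equal length", call. = FALSE)
  }
  if (n == 0L) stop("status sequences are empty", call. = FALSE)
  if (is.null(time_s)) {
    time_s <- (seq_len(n) - 1) / fs
  } else if (length(time_s) != n) {
    stop("`time_s` must match the status sequences in length", call. = FALSE)
  }
  if (min_run_samples > 0) {
    heel_statuses <- .debounce_runs(heel_statuses, min_run_samples)
    ball_statuses <- .debounce_runs(ball_statuses, min_run_samples)
  }
  labels <- label_sample(heel_statuses, ball_statuses)

  r <- rle(labels)
  starts <- cumsum(r$lengths) - r$lengths + 1L
  is_event <- r$values %in% c("heel_strike", "heel_off")
  ev_label <- r$values[is_event]
  ev_t <- time_s[starts[is_event]]
  cycle_index <- cumsum(ev_label == "heel_strike")
  structure(
    list(
      labels = labels,
      events = data.frame(
        label = ev_label, t = ev_t, cycle_index = as.integer(cycle_index)
      )
    ),
    class = "gpda_result"
  )
}

#' @export
print.gpda_result <- function(x, ...) {
  tab <- table(factor(x$labels, levels = gait_label_levels()$label))
  cat(sprintf("<gpda_result> %d samples, %d events\n",
              length(x$labels), nrow(x$events)))
  print(tab)
  invisible(x)
}
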