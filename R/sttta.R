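# Self-tuning triple-threshold algorithm (STTTA): an online per-channel
# state machine that tracks each gait cycle's force extrema and recomputes
# its low/middle/high thresholds once per cycle.
#
# Within one cycle the machine visits, in order (letters follow the
# customary annotation of the force trace):
#   b: upward crossing of t_m  -> t_l update from the just-completed minimum
#   c: upward crossing of t_h  -> open the maximum search region
#   d: downward crossing of t_h -> leave the region (may re-enter before e)
#   e: downward crossing of t_m -> finalize T_max(j); t_h update
#   f: downward crossing of t_l -> t_m update; open the minimum search region
#   g: upward crossing of t_l  -> cycle i ends (region may re-open before h)
#   h: upward crossing of t_m  -> same point as b of the next cycle
# Encoding this order in the state machine makes the one-update-per-cycle
# guarantee structural: once t_h has been recomputed at e, later excursions
# above t_h cannot re-open the maximum region until the cycle completes.

#' Parameters of the self-tuning triple-threshold algorithm
#'
#' @param beta Proportion placing the high threshold between the previous
#'   low threshold and the cycle maximum (default 0.071).
#' @param gamma Proportion placing the middle threshold likewise (default
#'   0.042). Must satisfy `0 < gamma < beta < 1` so the recomputed
#'   thresholds keep their ordering.
#' @param lam Mixing proportion of the low-threshold update,
#'   `t_l <- lam * T_min + (1 - lam) * t_m` (default 0.5).
#' @param t_l0,t_m0,t_h0 Initial thresholds in newtons (defaults 15, 20,
#'   25 N), required to satisfy `t_l0 < t_m0 < t_h0`. Any triple strictly
#'   between the expected per-cycle minima and maxima works; the defaults
#'   suit adult level walking where per-cycle maxima run 300--1300 N and
#'   minima 0--5 N.
#' @return An object of class `sttta_params`.
#' @examples
#' sttta_params()
#' @export
sttta_params <- function(beta = 0.071, gamma = 0.042, lam = 0.5,
                         t_l0 = 15, t_m0 = 20, t_h0 = 25) {
  for (nm in c("beta", "gamma", "lam", "t_l0", "t_m0", "t_h0")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("`", nm, "` must be a single finite number", call. = FALSE)
    }
  }
  if (!(gamma > 0 && beta > gamma && beta < 1)) {
    stop("need 0 < gamma < beta < 1", call. = FALSE)
  }
  if (!(lam > 0 && lam < 1)) {
    stop("need 0 < lam < 1", call. = FALSE)
  }
  if (!(t_l0 < t_m0 && t_m0 < t_h0)) {
    stop("initial thresholds must satisfy t_l0 < t_m0 < t_h0", call. = FALSE)
  }
  structure(
    list(beta = beta, gamma = gamma, lam = lam,
         t_l0 = t_l0, t_m0 = t_m0, t_h0 = t_h0),
    class = "sttta_params"
  )
}

#' @export
print.sttta_params <- function(x, ...) {
  cat(sprintf(
    "<sttta_params> beta=%g gamma=%g lam=%g init (t_l, t_m, t_h) = (%g, %g, %g) N\n",
    x$beta, x$gamma, x$lam, x$t_l0, x$t_m0, x$t_h0
  ))
  invisible(x)
}

#' An ordered low/middle/high threshold triple
#'
#' @param t_l,t_m,t_h Thresholds in newtons, `t_l < t_m < t_h`.
#' @return An object of class `threshold_triple`.
#' @export
threshold_triple <- function(t_l, t_m, t_h) {
  if (!(is.finite(t_l) && is.finite(t_m) && is.finite(t_h))) {
    stop("thresholds must be finite", call. = FALSE)
  }
  if (!(t_l < t_m && t_m < t_h)) {
    stop("thresholds must satisfy t_l < t_m < t_h", call. = FALSE)
  }
  structure(list(t_l = t_l, t_m = t_m, t_h = t_h), class = "threshold_triple")
}

#' @export
print.threshold_triple <- function(x, ...) {
  cat(sprintf("<threshold_triple> (t_l, t_m, t_h) = (%.3f, %.3f, %.3f) N\n",
              x$t_l, x$t_m, x$t_h))
  invisible(x)
}

#' Initialize a fresh per-channel STTTA state
#'
#' @param params An [sttta_params()] object.
#' @return An object of class `sttta_state` holding the current thresholds,
#'   the running maximum/minimum accumulators (`NA` until their search
#'   region opens), the most recent finalized cycle extrema, the cycle-point
#'   phase, and the completed-cycle counter `i` and completed-maximum
#'   counter `j` (`i` and `j` may differ when incomplete cycles occur).
#' @examples
#' init_state(sttta_params())
#' @export
init_state <- function(params = sttta_params()) {
  if (!inherits(params, "sttta_params")) {
    params <- do.call(sttta_params, as.list(params))
  }
  structure(
    list(
      t_l = params$t_l0, t_m = params$t_m0, t_h = params$t_h0,
      max_acc = NA_real_, min_acc = NA_real_,
      last_tmax = NA_real_, last_tmin = NA_real_,
      phase_point = "UNSYNCED",
      i = 0L, j = 0L,
      tm_pending = FALSE,   # t_m update owed from the last finalized maximum
      i_counted = FALSE,    # cycle i already counted at the first g crossing
      prev_f = NA_real_,
      params = params
    ),
    class = "sttta_state"
  )
}

#' @export
print.sttta_state <- function(x, ...) {
  cat(sprintf(
    "<sttta_state> phase=%s thresholds=(%.3f, %.3f, %.3f) N i=%d j=%d\n",
    x$phase_point, x$t_l, x$t_m, x$t_h, x$i, x$j
  ))
  invisible(x)
}

#' Classify one force sample against the high threshold
#'
#' The high threshold is the main threshold: a sensor is on-ground when its
#' force is at or above it, off-ground otherwise (the boundary sample counts
#' as on-ground).
#'
#' @param f Force(s) in newtons (vectorized).
#' @param t_h High threshold in newtons.
#' @return Character vector of `"on_ground"` / `"off_ground"`.
#' @examples
#' classify_sample(c(24.999, 25, 30), 25)
#' @export
classify_sample <- function(f, t_h) {
  if (anyNA(f) || any(!is.finite(f)) || !is.finite(t_h)) {
    stop("forces and threshold must be finite", call. = FALSE)
  }
  ifelse(f >= t_h, "on_ground", "off_ground")
}

# Attempt a threshold update; on an ordering violation keep the previous
# value and record a warning (robustness: a live detector must not halt).
.apply_update <- function(st, which, new_value) {
  cand <- c(t_l = st$t_l, t_m = st$t_m, t_h = st$t_h)
  cand[[which]] <- new_value
  if (!(cand[["t_l"]] < cand[["t_m"]] && cand[["t_m"]] < cand[["t_h"]])) {
    warning(sprintf(
      "rejected %s update to %.3f N (would break t_l < t_m < t_h); keeping %.3f N",
      which, new_value, st[[which]]
    ), call. = FALSE)
    return(list(st = st, event = NULL))
  }
  old <- st[[which]]
  st[[which]] <- new_value
  list(st = st, event = list(threshold = which, old = old, new = new_value))
}

# Advance the state machine by one sample. Returns list(st, status, events)
# where events is a list of threshold-update records fired at this sample.
.sttta_advance <- function(st, f) {
  if (!is.finite(f)) {
    stop("force sample must be finite", call. = FALSE)
  }
  fp <- st$prev_f
  if (is.na(fp)) fp <- -Inf  # cold start: the first sample can cross upward
  events <- list()
  p <- st$params

  up <- function(thr) f >= thr && fp < thr
  down_strict <- function(thr) f < thr && fp >= thr   # t_h, t_m exits
  down_le <- function(thr) f <= thr && fp > thr       # t_l entry (Eq-style <=)
  up_tl_exit <- function() f > st$t_l && fp <= st$t_l

  repeat {
    moved <- FALSE
    ph <- st$phase_point

    if (ph == "UNSYNCED") {
      if (up(st$t_m)) {
        # point b with no completed minimum yet: no t_l update possible
        st$phase_point <- "ABOVE_TM_RISING"
        moved <- TRUE
      }
    } else if (ph == "ABOVE_TM_RISING") {
      if (up(st$t_h)) {
        if (is.na(st$max_acc)) st$max_acc <- f
        st$phase_point <- "IN_MAX_REGION"
        moved <- TRUE
      } else if (down_le(st$t_l)) {
        # the trace fell straight through t_l; recover the minimum search
        if (st$tm_pending && !is.na(st$last_tmax)) {
          upd <- .apply_update(
            st, "t_m", p$gamma * (st$last_tmax - st$t_l) + st$t_l)
          st <- upd$st
          if (!is.null(upd$event)) events[[length(events) + 1L]] <- upd$event
          st$tm_pending <- FALSE
        }
        if (is.na(st$min_acc)) st$min_acc <- f
        st$phase_point <- "IN_MIN_REGION"
        moved <- TRUE
      }
    } else if (ph == "IN_MAX_REGION") {
      if (down_strict(st$t_h)) {
        st$phase_point <- "AFTER_MAX"
        moved <- TRUE
      }
    } else if (ph == "AFTER_MAX") {
      if (up(st$t_h)) {
        # re-entry before e continues the same maximum search (no reset)
        st$phase_point <- "IN_MAX_REGION"
        moved <- TRUE
      } else if (down_strict(st$t_m)) {
        # point e: finalize T_max(j), recompute t_h for the next cycle
        st$last_tmax <- st$max_acc
        st$max_acc <- NA_real_
        st$j <- st$j + 1L
        upd <- .apply_update(
          st, "t_h", p$beta * (st$last_tmax - st$t_l) + st$t_l)
        st <- upd$st
        if (!is.null(upd$event)) events[[length(events) + 1L]] <- upd$event
        st$tm_pending <- TRUE
        st$phase_point <- "BELOW_TM"
        moved <- TRUE
      }
    } else if (ph == "BELOW_TM") {
      if (down_le(st$t_l)) {
        # point f: recompute t_m, open the minimum search region
        if (st$tm_pending && !is.na(st$last_tmax)) {
          upd <- .apply_update(
            st, "t_m", p$gamma * (st$last_tmax - st$t_l) + st$t_l)
          st <- upd$st
          if (!is.null(upd$event)) events[[length(events) + 1L]] <- upd$event
          st$tm_pending <- FALSE
        }
        if (is.na(st$min_acc)) st$min_acc <- f
        st$phase_point <- "IN_MIN_REGION"
        moved <- TRUE
      } else if (up(st$t_m)) {
        # incomplete cycle: the trace turned back up without reaching t_l
        st$phase_point <- "ABOVE_TM_RISING"
        moved <- TRUE
      }
    } else if (ph == "IN_MIN_REGION") {
      if (up_tl_exit()) {
        # point g: the present cycle ends (the region may still re-open
        # below t_l before h, continuing the same minimum search)
        if (!st$i_counted) {
          st$i <- st$i + 1L
          st$i_counted <- TRUE
        }
        st$phase_point <- "AFTER_MIN"
        moved <- TRUE
      }
    } else if (ph == "AFTER_MIN") {
      if (down_le(st$t_l)) {
        st$phase_point <- "IN_MIN_REGION"
        moved <- TRUE
      } else if (up(st$t_m)) {
        # point h (= b of the next cycle): finalize T_min(j), update t_l
        st$last_tmin <- st$min_acc
        st$min_acc <- NA_real_
        if (!is.na(st$last_tmin)) {
          upd <- .apply_update(
            st, "t_l", p$lam * st$last_tmin + (1 - p$lam) * st$t_m)
          st <- upd$st
          if (!is.null(upd$event)) events[[length(events) + 1L]] <- upd$event
        }
        st$i_counted <- FALSE
        st$phase_point <- "ABOVE_TM_RISING"
        moved <- TRUE
      }
    }

    if (!moved) break
  }

  # in-region extremum accumulation for the present sample
  if (st$phase_point == "IN_MAX_REGION" && f >= st$t_h) {
    st$max_acc <- max(st$max_acc, f)
  } else if (st$phase_point == "IN_MIN_REGION" && f <= st$t_l) {
    st$min_acc <- min(st$min_acc, f)
  }

  st$prev_f <- f
  status <- if (f >= st$t_h) "on_ground" else "off_ground"
  list(st = st, status = status, events = events)
}

#' Advance the STTTA state machine by one sample
#'
#' Feeds a single force sample to the online detector: the contact status is
#' decided against the current high threshold, threshold-crossing events
#' advance the cycle-point machine, and any threshold recomputation due at
#' this sample takes effect immediately. Folding [step()] over a trace gives
#' exactly the same statuses and threshold trajectory as [run_sttta()] on
#' the whole trace.
#'
#' @param state An `sttta_state` from [init_state()] or a previous [step()].
#' @param f One force sample in newtons.
#' @return A list with elements `state` (the advanced state), `status`
#'   (`"on_ground"` / `"off_ground"`), and `events` (a list, usually empty,
#'   of threshold updates fired at this sample, each with fields
#'   `threshold`, `old`, `new`).
#' @examples
#' s <- init_state(sttta_params())
#' step(s, 100)$status
#' @export
step <- function(state, f) {
  stopifnot(inherits(state, "sttta_state"))
  if (!is.numeric(f) || length(f) != 1L) {
    stop("`f` must be a single numeric force sample", call. = FALSE)
  }
  out <- .sttta_advance(state, f)
  list(state = out$st, status = out$status, events = out$events)
}

#' Run the STTTA over a whole recording
#'
#' Folds the per-sample state machine over the trace and records, for every
#' sample, the thresholds in effect, together with a log of every threshold
#' update event (which threshold, old and new value, the completed-cycle
#' counter at firing). Ball and heel channels are independent: run one
#' `run_sttta()` per channel.
#'
#' @param rec A [gcf_recording()] or a bare numeric force vector.
#' @param params An [sttta_params()] object.
#' @return A list of class `sttta_result` with elements:
#'   \describe{
#'     \item{status}{character vector of per-sample contact statuses;}
#'     \item{thresholds}{data frame `time_s,t_l,t_m,t_h` of the values in
#'       effect after each sample (piecewise constant between updates);}
#'     \item{events}{data frame `time_s,threshold,old_N,new_N,cycle_i` of
#'       update events;}
#'     \item{state}{the final `sttta_state`.}
#'   }
#' @examples
#' f <- rep(c(0, 500), each = 50, times = 3)
#' res <- run_sttta(f, sttta_params())
#' tail(res$thresholds, 1)
#' @export
run_sttta <- function(rec, params = sttta_params()) {
  if (inherits(rec, "gcf_recording")) {
    f <- rec$f
    t <- rec$t
  } else {
    f <- as.numeric(rec)
    t <- seq_along(f) - 1
  }
  n <- length(f)
  if (n == 0L) stop("recording is empty", call. = FALSE)

  st <- init_state(params)
  status <- character(n)
  thr <- matrix(NA_real_, nrow = n, ncol = 3L)
  ev_t <- numeric(0); ev_thr <- character(0)
  ev_old <- numeric(0); ev_new <- numeric(0); ev_i <- integer(0)

  for (k in seq_len(n)) {
    out <- .sttta_advance(st, f[k])
    st <- out$st
    status[k] <- out$status
    thr[k, 1L] <- st$t_l; thr[k, 2L] <- st$t_m; thr[k, 3L] <- st$t_h
    if (length(out$events)) {
      for (ev in out$events) {
        ev_t <- c(ev_t, t[k])
        ev_thr <- c(ev_thr, ev$threshold)
        ev_old <- c(ev_old, ev$old)
        ev_new <- c(ev_new, ev$new)
        ev_i <- c(ev_i, st$i)
      }
    }
  }

  structure(
    list(
      status = status,
      thresholds = data.frame(
        time_s = t, t_l = thr[, 1L], t_m = thr[, 2L], t_h = thr[, 3L]
      ),
      events = data.frame(
        time_s = ev_t, threshold = ev_thr, old_N = ev_old, new_N = ev_new,
        cycle_i = ev_i
      ),
      state = st
    ),
    class = "sttta_result"
  )
}

#' @export
print.sttta_result <- function(x, ...) {
  cat(sprintf(
    "<sttta_result> %d samples, %d threshold updates, %d completed cycles, final (t_l, t_m, t_h) = (%.3f, %.3f, %.3f) N\n",
    length(x$status), nrow(x$events), x$state$i,
    x$state$t_l, x$state$t_m, x$state$t_h
  ))
  invisible(x)
}

#' Stationary thresholds for constant per-cycle extrema
#'
#' When every cycle has the same maximum `M` and minimum `m`, the three
#' per-cycle update rules have a unique fixed point, found by solving the
#' linear system
#' `t_h = beta*(M - t_l) + t_l`, `t_m = gamma*(M - t_l) + t_l`,
#' `t_l = lam*m + (1 - lam)*t_m`. The online detector converges to this
#' triple within a few cycles on strictly periodic input, which makes the
#' closed form a convenient oracle for convergence and adaptation tests.
#'
#' @param M,m Per-cycle maximum and minimum force in newtons, `m < M`.
#' @param params An [sttta_params()] object.
#' @return A [threshold_triple()].
#' @examples
#' fixed_point_thresholds(1000, 0, sttta_params())
#' @export
fixed_point_thresholds <- function(M, m, params = sttta_params()) {
  if (!is.finite(M) || !is.finite(m)) {
    stop("`M` and `m` must be finite", call. = FALSE)
  }
  if (m >= M) stop("need m < M", call. = FALSE)
  stopifnot(inherits(params, "sttta_params"))
  g <- params$gamma; b <- params$beta; l <- params$lam
  # t_l = l*m + (1-l)*(g*(M - t_l) + t_l)
  t_l <- (l * m + (1 - l) * g * M) / (1 - (1 - l) * (1 - g))
  t_m <- g * (M - t_l) + t_l
  t_h <- b * (M - t_l) + t_l
  threshold_triple(t_l, t_m, t_h)
}

#' Export a threshold trace and its update events to CSV
#'
#' @param result An `sttta_result` from [run_sttta()].
#' @param trace_path Optional path for the per-sample trace
#'   (`time_s,t_l,t_m,t_h`).
#' @param events_path Optional path for the update log
#'   (`time_s,threshold,old_N,new_N,cycle_i`).
#' @return `result`, invisibly.
#' @export
write_threshold_trace <- function(result, trace_path = NULL,
                                  events_path = NULL) {
  stopifnot(inherits(result, "sttta_result"))
  if (!is.null(trace_path)) {
    utils::write.csv(result$thresholds, trace_path, row.names = FALSE,
                     quote = FALSE)
  }
  if (!is.null(events_path)) {
    utils::write.csv(result$events, events_path, row.names = FALSE,
                     quote = FALSE)
  }
  invisible(result)
}
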