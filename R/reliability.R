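# Reliability scoring: per-sample gait-label agreement between a test
# method and a reference method, and grid search over the beta/gamma
# tuning proportions for maximum mean reliability.

#' Per-sample label computation for one detection method
#'
#' Runs one of the four contact-detection methods on a ball/heel recording
#' pair and maps the statuses to gait labels with [detect_sequence()].
#'
#' @param ball,heel [gcf_recording()]s of equal length on one time base.
#' @param method One of `"sttta"`, `"mariani"`, `"tam"`, `"lopez_meyer"`.
#' @param params [sttta_params()] used when `method = "sttta"`.
#' @param mass_kg Body mass, required for `method = "mariani"`.
#' @param alpha Proportional factor for `method = "lopez_meyer"`.
#' @param g Gravitational acceleration for `method = "mariani"`.
#' @return A list with `labels` (per-sample gait labels), `events` (data
#'   frame from [detect_sequence()]), `ball_status`, `heel_status`, and
#'   `thresholds` (a named list; per-channel constants for the reference
#'   methods, final adaptive triples for the online method).
#' @export
method_labels <- function(ball, heel,
                          method = c("sttta", "mariani", "tam",
                                     "lopez_meyer"),
                          params = sttta_params(), mass_kg = NULL,
                          alpha = 0.084, g = 9.81) {
  method <- match.arg(method)
  stopifnot(inherits(ball, "gcf_recording"), inherits(heel, "gcf_recording"))
  if (length(ball) != length(heel)) {
    stop("ball and heel recordings must have equal length", call. = FALSE)
  }
  thresholds <- list()
  if (method == "sttta") {
    rb <- run_sttta(ball, params)
    rh <- run_sttta(heel, params)
    ball_status <- rb$status
    heel_status <- rh$status
    thresholds <- list(
      ball = with(rb$state, c(t_l = t_l, t_m = t_m, t_h = t_h)),
      heel = with(rh$state, c(t_l = t_l, t_m = t_m, t_h = t_h))
    )
  } else {
    thr <- switch(method,
      mariani = {
        if (is.null(mass_kg)) {
          stop("`mass_kg` is required for the mariani method", call. = FALSE)
        }
        tt <- mariani_threshold(mass_kg, g = g)
        list(ball = tt, heel = tt)
      },
      tam = list(ball = tam_threshold(ball), heel = tam_threshold(heel)),
      lopez_meyer = list(
        ball = lopez_meyer_threshold(ball, alpha = alpha),
        heel = lopez_meyer_threshold(heel, alpha = alpha)
      )
    )
    ball_status <- classify_with_threshold(ball, thr$ball)
    heel_status <- classify_with_threshold(heel, thr$heel)
    thresholds <- thr
  }
  det <- detect_sequence(heel_status, ball_status, time_s = ball$t)
  list(labels = det$labels, events = det$events,
       ball_status = ball_status, heel_status = heel_status,
       thresholds = thresholds)
}

#' Per-sample agreement between two gait label sequences
#'
#' The reliability metric: the percentage of samples on which the two
#' label sequences agree, with the full 4x4 confusion table. Symmetric up
#' to transposition of the confusion matrix; 100 exactly when the
#' sequences are identical.
#'
#' @param labels_a,labels_b Equal-length non-empty character vectors of
#'   gait labels.
#' @param methods Length-2 character vector naming the two methods (used
#'   for reporting only).
#' @return An object of class `reliability_report` with fields
#'   `percent_agreement` (in \[0, 100\]), `n_samples`, `confusion`
#'   (4x4 table, rows = `methods[1]`), and `methods`.
#' @examples
#' agreement(c("stance", "swing"), c("stance", "swing"))$percent_agreement
#' @export
agreement <- function(labels_a, labels_b, methods = c("a", "b")) {
  n <- length(labels_a)
  if (n == 0L || length(labels_b) != n) {
    stop("label sequences must be non-empty and of equal length",
         call. = FALSE)
  }
  lv <- gait_label_levels()$label
  fa <- factor(labels_a, levels = lv)
  fb <- factor(labels_b, levels = lv)
  if (anyNA(fa) || anyNA(fb)) {
    stop("labels must be one of: ", paste(lv, collapse = ", "),
         call. = FALSE)
  }
  confusion <- table(fa, fb, dnn = methods)
  structure(
    list(
      percent_agreement = 100 * sum(diag(confusion)) / n,
      n_samples = n,
      confusion = confusion,
      methods = methods
    ),
    class = "reliability_report"
  )
}

#' @export
print.reliability_report <- function(x, ...) {
  cat(sprintf("<reliability_report> %s vs %s: %.2f%% over %d samples\n",
              x$methods[1], x$methods[2], x$percent_agreement, x$n_samples))
  print(x$confusion)
  invisible(x)
}

# index of the first sample to score after discarding burn_in_cycles
# complete cycles, judged by the reference labels' heel-strike events
.burn_in_start <- function(ref_events, ref_times, burn_in_cycles) {
  if (burn_in_cycles <= 0) return(1L)
  hs <- ref_events$t[ref_events$label == "heel_strike"]
  if (length(hs) <= burn_in_cycles) {
    stop("fewer reference cycles than `burn_in_cycles`", call. = FALSE)
  }
  which(ref_times >= hs[burn_in_cycles + 1L])[1L]
}

#' Compare two detection methods on one recording pair
#'
#' Runs both methods with [method_labels()] and scores their per-sample
#' agreement, optionally discarding an initial burn-in (in complete cycles
#' of the reference method, `method_b`) during which the adaptive
#' thresholds are still converging from their initial values.
#'
#' @inheritParams method_labels
#' @param method_a,method_b Method names as in [method_labels()];
#'   `method_b` is treated as the reference.
#' @param burn_in_cycles Number of initial reference cycles to exclude
#'   from scoring (default 0).
#' @return A `reliability_report` (see [agreement()]).
#' @export
compare_methods <- function(ball, heel, method_a = "sttta",
                            method_b = "tam", params = sttta_params(),
                            mass_kg = NULL, alpha = 0.084, g = 9.81,
                            burn_in_cycles = 0) {
  la <- method_labels(ball, heel, method_a, params = params,
                      mass_kg = mass_kg, alpha = alpha, g = g)
  lb <- method_labels(ball, heel, method_b, params = params,
                      mass_kg = mass_kg, alpha = alpha, g = g)
  start <- .burn_in_start(lb$events, ball$t, burn_in_cycles)
  idx <- start:length(la$labels)
  agreement(la$labels[idx], lb$labels[idx],
            methods = c(method_a, method_b))
}

#' Grid search over the beta/gamma tuning proportions
#'
#' For every admissible pair on the grid (only `gamma < beta` keeps the
#' recomputed thresholds ordered), runs the online detector plus the phase
#' labeller on every recording pair, scores each against the reference
#' method's labels, and averages. Ties are broken toward the smallest
#' `beta`, then the smallest `gamma`.
#'
#' @param recordings A list of recording pairs, each a list with elements
#'   `ball` and `heel` ([gcf_recording()]s).
#' @param reference `"tam"` or `"lopez_meyer"` (the post-processing
#'   reference methods).
#' @param beta_grid,gamma_grid Numeric vectors of candidate proportions in
#'   (0, 1). Defaults cover 0.02--0.30 in steps of 0.02 (refine around the
#'   optimum with a finer grid if needed).
#' @param lam Fixed low-threshold mixing proportion (default 0.5; the
#'   middle and low updates feed each other, so one of the two proportions
#'   is held fixed while the other two are searched).
#' @param init Length-3 vector of initial thresholds `(t_l0, t_m0, t_h0)`.
#' @param alpha Proportional factor of the Lopez--Meyer reference.
#' @param burn_in_cycles Initial reference cycles excluded from scoring.
#' @return An object of class `grid_search_result` with `best_beta`,
#'   `best_gamma`, `best_reliability`, and `surface` (data frame
#'   `beta,gamma,reliability_pct`).
#' @export
grid_search <- function(recordings, reference = c("tam", "lopez_meyer"),
                        beta_grid = seq(0.02, 0.30, by = 0.02),
                        gamma_grid = seq(0.02, 0.30, by = 0.02),
                        lam = 0.5, init = c(15, 20, 25), alpha = 0.084,
                        burn_in_cycles = 0) {
  reference <- match.arg(reference)
  if (length(recordings) == 0L) {
    stop("`recordings` must be non-empty", call. = FALSE)
  }
  if (length(beta_grid) == 0L || length(gamma_grid) == 0L) {
    stop("grids must be non-empty", call. = FALSE)
  }
  cells <- expand.grid(gamma = gamma_grid, beta = beta_grid)
  cells <- cells[cells$gamma < cells$beta, c("beta", "gamma")]
  if (nrow(cells) == 0L) {
    stop("no admissible (beta, gamma) pair with gamma < beta", call. = FALSE)
  }

  # reference labels are fixed across grid cells: compute once
  ref <- lapply(recordings, function(rp) {
    method_labels(rp$ball, rp$heel, reference, alpha = alpha)
  })

  score_cell <- function(beta, gamma) {
    p <- sttta_params(beta = beta, gamma = gamma, lam = lam,
                      t_l0 = init[1], t_m0 = init[2], t_h0 = init[3])
    vals <- vapply(seq_along(recordings), function(q) {
      rp <- recordings[[q]]
      la <- method_labels(rp$ball, rp$heel, "sttta", params = p)
      start <- .burn_in_start(ref[[q]]$events, rp$ball$t, burn_in_cycles)
      idx <- start:length(la$labels)
      agreement(la$labels[idx], ref[[q]]$labels[idx])$percent_agreement
    }, numeric(1))
    mean(vals)
  }

  cells$reliability_pct <- mapply(score_cell, cells$beta, cells$gamma)
  ord <- order(-cells$reliability_pct, cells$beta, cells$gamma)
  best <- cells[ord[1L], ]
  structure(
    list(
      best_beta = best$beta,
      best_gamma = best$gamma,
      best_reliability = best$reliability_pct,
      reference = reference,
      surface = cells[order(cells$beta, cells$gamma), ]
    ),
    class = "grid_search_result"
  )
}

#' @export
print.grid_search_result <- function(x, ...) {
  cat(sprintf(
    "<grid_search_result> best beta=%.3f gamma=%.3f: %.2f%% mean agreement vs %s over %d cells\n",
    x$best_beta, x$best_gamma, x$best_reliability, x$reference,
    nrow(x$surface)
  ))
  invisible(x)
}
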