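#' Magnetic-tweezers trace container
#'
#' A (time, force, bead-height) series sampled uniformly (200 Hz by
#' default). Stored as a data frame with columns `time_s`, `force_pN`,
#' `height_nm` plus a `sampling_rate` attribute and free-form metadata
#' (protocol, construct, seed, hold windows for jump cycles).
#'
#' @param time_s strictly increasing time in s
#' @param force_pN force per sample in pN
#' @param height_nm bead height per sample in nm
#' @param sampling_rate sampling rate in Hz
#' @param metadata named list of free-form metadata
#' @return an object of class `mt_trace` (also a data frame)
#' @export
mt_trace <- function(time_s, force_pN, height_nm, sampling_rate = 200,
                     metadata = list()) {
  n <- length(time_s)
  if (length(force_pN) != n || length(height_nm) != n)
    stop("time, force and height channels must have equal length")
  if (n > 1 && any(diff(time_s) <= 0))
    stop("'time_s' must be strictly increasing")
  structure(data.frame(time_s = time_s, force_pN = force_pN,
                       height_nm = height_nm),
            sampling_rate = sampling_rate, metadata = metadata,
            class = c("mt_trace", "data.frame"))
}

#' @export
print.mt_trace <- function(x, ...) {
  cat(sprintf("<mt_trace> %d samples @ %g Hz, %.2f-%.2f s, force %.3g-%.3g pN\n",
              nrow(x), attr(x, "sampling_rate"),
              min(x$time_s), max(x$time_s), min(x$force_pN), max(x$force_pN)))
  invisible(x)
}

#' @export
plot.mt_trace <- function(x, ...) {
  graphics::plot(x$time_s, x$height_nm, type = "l", col = "grey60",
                 xlab = "time (s)", ylab = "bead height (nm)", ...)
  invisible(x)
}

#' Smooth the height channel of a trace
#'
#' Low-pass smoothing of the bead-height channel. The default `"fft"`
#' method retains frequencies below `sampling_rate / (2 * window)` in the
#' discrete Fourier transform (the n-point-FFT smoothing convention used in
#' single-molecule trace displays); `"ma"` is a centred moving average of
#' the same window.
#'
#' @param trace an [mt_trace()]
#' @param window smoothing window in samples (>= 1; 10 by default)
#' @param method `"fft"` or `"ma"`
#' @return a smoothed `mt_trace` of the same length
#' @export
smooth_trace <- function(trace, window = 10, method = c("fft", "ma")) {
  method <- match.arg(method)
  stopifnot(inherits(trace, "mt_trace"))
  n <- nrow(trace)
  if (window < 1) stop("'window' must be >= 1")
  if (window > n) stop("'window' exceeds the trace length")
  h <- trace$height_nm
  if (window == 1) return(trace)
  if (method == "fft") {
    X <- stats::fft(h)
    # keep DC and bins with |frequency index| < n/(2*window)
    kmax <- floor(n / (2 * window))
    keep <- rep(FALSE, n)
    keep[1] <- TRUE
    if (kmax >= 1) {
      keep[1 + seq_len(kmax)] <- TRUE        # positive frequencies
      keep[n + 1 - seq_len(kmax)] <- TRUE    # negative frequencies
    }
    X[!keep] <- 0
    sm <- Re(stats::fft(X, inverse = TRUE)) / n
  } else {
    sm <- as.numeric(stats::filter(h, rep(1 / window, window), sides = 2))
    # pad filter edges with the nearest computed value
    idx <- which(!is.na(sm))
    sm[seq_len(idx[1] - 1)] <- sm[idx[1]]
    sm[seq((idx[length(idx)] + 1), length.out = n - idx[length(idx)])] <-
      sm[idx[length(idx)]]
  }
  out <- trace
  out$height_nm <- sm
  out
}

# Segment cost machinery for change-point detection: cost of fitting one
# mean to h[i..j] is sum((h - mean)^2), computed from cumulative sums.
seg_cost_fun <- function(h) {
  cs <- cumsum(h); cs2 <- cumsum(h^2)
  function(i, j) {
    s <- cs[j] - if (i > 1) cs[i - 1] else 0
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    s2 - s^2 / (j - i + 1)
  }
}

# Best single split of h[lo..hi]; returns list(split, gain)
best_split <- function(h, lo, hi, cost, min_len = 2L) {
  if (hi - lo + 1 < 2 * min_len) return(list(split = NA, gain = -Inf))
  ss <- (lo + min_len - 1):(hi - min_len)
  cs <- cumsum(h); cs2 <- cumsum(h^2)
  base <- if (lo > 1) cs[lo - 1] else 0
  base2 <- if (lo > 1) cs2[lo - 1] else 0
  nl <- ss - lo + 1
  sl <- cs[ss] - base
  costl <- (cs2[ss] - base2) - sl^2 / nl
  nr <- hi - ss
  sr <- cs[hi] - cs[ss]
  costr <- (cs2[hi] - cs2[ss]) - sr^2 / nr
  gain <- cost(lo, hi) - costl - costr
  k <- which.max(gain)
  list(split = ss[k], gain = gain[k])
}

#' Detect step transitions in a bead-height trace
#'
#' Fits a piecewise-constant level sequence to the height channel and
#' returns the step events between successive levels. The default
#' change-point method is greedy binary segmentation: the split with the
#' largest residual-sum-of-squares reduction is accepted while the
#' reduction exceeds a BIC-style penalty (`penalty_mult * sigma^2 * log(n)`
#' with a robust noise estimate `sigma` from successive differences).
#' Adjacent levels closer than `min_step` are then merged. The `"hmm"`
#' method fits a Gaussian-emission hidden Markov model with at most
#' `max_states` levels (suited to two-state hopping traces) and takes the
#' Viterbi path as the level sequence.
#'
#' Detection is invariant to adding a constant offset to the height
#' channel. A trace with no resolvable level change yields an empty event
#' table, not an error.
#'
#' @param trace an [mt_trace()]
#' @param min_step minimal accepted level change in nm (default 10, suited
#'   to rupture/unfolding steps; use ~2 for hopping traces)
#' @param max_states maximal number of HMM levels (ignored by the
#'   change-point method)
#' @param method `"cp"` (change-point, default) or `"hmm"`
#' @param penalty_mult multiplier of the BIC penalty (change-point method)
#' @param min_dwell_samples minimal segment length in samples
#' @return an object of class `step_fit`: list with `events` (data frame
#'   `time_s`, `force_pN`, `step_nm`, `index`), `levels` (fitted level per
#'   sample), `segments` (data frame `start`, `end`, `level_nm`,
#'   `dwell_s`) and the noise estimate `sigma`
#' @export
detect_steps <- function(trace, min_step = 10, max_states = 6,
                         method = c("cp", "hmm"), penalty_mult = 2,
                         min_dwell_samples = 2L) {
  method <- match.arg(method)
  stopifnot(inherits(trace, "mt_trace"))
  h <- trace$height_nm
  n <- length(h)
  sigma <- stats::mad(diff(h)) / sqrt(2)
  if (method == "cp") {
    cost <- seg_cost_fun(h)
    penalty <- penalty_mult * max(sigma, 1e-12)^2 * log(n)
    bounds <- c(0L, n)  # segment k is (bounds[k]+1):bounds[k+1]
    repeat {
      best <- list(gain = -Inf)
      for (k in seq_len(length(bounds) - 1L)) {
        sp <- best_split(h, bounds[k] + 1L, bounds[k + 1L], cost,
                         min_dwell_samples)
        if (sp$gain > best$gain) best <- sp
      }
      if (!is.finite(best$gain) || best$gain <= penalty) break
      bounds <- sort(c(bounds, best$split))
    }
  } else {
    hm <- gaussian_hmm(h, K = max_states)
    path <- hm$path
    bounds <- c(0L, which(diff(path) != 0), n)
  }
  # level means and merging of sub-threshold steps
  seg_mean <- function(bounds) {
    vapply(seq_len(length(bounds) - 1L), function(k)
      mean(h[(bounds[k] + 1L):bounds[k + 1L]]), numeric(1))
  }
  means <- seg_mean(bounds)
  while (length(means) > 1L) {
    d <- abs(diff(means))
    if (all(d >= min_step)) break
    k <- which.min(d)                 # merge across the smallest sub-threshold step
    bounds <- bounds[-(k + 1L)]
    means <- seg_mean(bounds)
  }
  starts <- bounds[-length(bounds)] + 1L
  ends <- bounds[-1]
  segments <- data.frame(start = starts, end = ends, level_nm = means,
                         dwell_s = trace$time_s[ends] - trace$time_s[starts])
  levels <- rep(means, times = ends - starts + 1L)
  if (length(means) > 1L) {
    b <- bounds[c(-1, -length(bounds))]
    events <- data.frame(
      time_s = (trace$time_s[b] + trace$time_s[b + 1L]) / 2,
      force_pN = trace$force_pN[b + 1L],
      step_nm = diff(means),
      index = b)
  } else {
    events <- data.frame(time_s = numeric(), force_pN = numeric(),
                         step_nm = numeric(), index = integer())
  }
  structure(list(events = events, segments = segments, levels = levels,
                 sigma = sigma, method = method, trace = trace),
            class = "step_fit")
}

#' @export
print.step_fit <- function(x, ...) {
  cat(sprintf("<step_fit> %d level(s), %d step event(s); noise sigma %.3g nm (%s)\n",
              nrow(x$segments), nrow(x$events), x$sigma, x$method))
  if (nrow(x$events)) print(utils::head(x$events, 10))
  invisible(x)
}

#' @export
plot.step_fit <- function(x, ...) {
  graphics::plot(x$trace$time_s, x$trace$height_nm, type = "l", col = "grey70",
                 xlab = "time (s)", ylab = "bead height (nm)", ...)
  graphics::lines(x$trace$time_s, x$levels, col = "red3", lwd = 2)
  invisible(x)
}

#' Extract dwell times from force-jump-cycle traces
#'
#' For each clamped hold window the dwell time is the interval from the
#' start of the hold to the first detected step of at least `min_step` nm;
#' holds ending without a qualifying step are kept as right-censored
#' records at the hold duration (discarding them would bias the lifetime
#' estimate). Events inside the initial `transient_blank` after the jump
#' are ignored (bead re-orientation artifacts).
#'
#' Hold windows are taken from each trace's metadata (`metadata$holds`, a
#' data frame with `start_s`, `end_s`, `force_pN` -- the synthetic
#' generator writes these) and validated against the jump protocol.
#'
#' @param traces an `mt_trace` or list of them
#' @param protocol a jump [force_protocol()]
#' @param min_step qualifying step size in nm
#' @param transient_blank ignore events within this interval after the jump
#'   (s)
#' @param ... passed to [detect_steps()]
#' @return a data frame of class `dwell_records` with columns `force_pN`,
#'   `dwell_s`, `censored`
#' @export
extract_dwell_times <- function(traces, protocol, min_step = 20,
                                transient_blank = 0.3, ...) {
  stopifnot(inherits(protocol, "force_protocol"))
  if (protocol$kind != "jump") stop("'protocol' must be a jump protocol")
  if (inherits(traces, "mt_trace")) traces <- list(traces)
  if (length(traces) == 0L) return(dwell_records(numeric(), numeric(), logical()))
  rows <- lapply(traces, function(tr) {
    holds <- attr(tr, "metadata")$holds
    if (is.null(holds))
      stop("trace metadata lacks hold-phase boundaries ('holds')")
    out <- vector("list", nrow(holds))
    for (i in seq_len(nrow(holds))) {
      sel <- tr$time_s >= holds$start_s[i] & tr$time_s <= holds$end_s[i]
      sub <- mt_trace(tr$time_s[sel], tr$force_pN[sel], tr$height_nm[sel],
                      attr(tr, "sampling_rate"))
      fit <- detect_steps(sub, min_step = min_step, ...)
      ev <- fit$events
      ev <- ev[abs(ev$step_nm) >= min_step &
               ev$time_s >= holds$start_s[i] + transient_blank, , drop = FALSE]
      if (nrow(ev)) {
        out[[i]] <- data.frame(force_pN = holds$force_pN[i],
                               dwell_s = ev$time_s[1] - holds$start_s[i],
                               censored = FALSE)
      } else {
        out[[i]] <- data.frame(force_pN = holds$force_pN[i],
                               dwell_s = holds$end_s[i] - holds$start_s[i],
                               censored = TRUE)
      }
    }
    do.call(rbind, out)
  })
  out <- do.call(rbind, rows)
  dwell_records(out$force_pN, out$dwell_s, out$censored)
}

#' Dwell-record table
#'
#' @param force_pN clamp force per record
#' @param dwell_s dwell time in s (> 0)
#' @param censored logical; `TRUE` if the hold ended without rupture
#' @return a data frame of class `dwell_records`
#' @export
dwell_records <- function(force_pN, dwell_s, censored = FALSE) {
  if (length(censored) == 1L) censored <- rep(censored, length(dwell_s))
  if (any(dwell_s <= 0)) stop("dwell times must be positive")
  structure(data.frame(force_pN = force_pN, dwell_s = dwell_s,
                       censored = censored),
            class = c("dwell_records", "data.frame"))
}

#' Rupture events from a force-ramp trace
#'
#' Detects steps during a monotone force scan and reads the force at each
#' step from the force channel at the step sample.
#'
#' @param trace an [mt_trace()] covering the scan
#' @param loading_rate nominal loading rate in pN/s (sign sets the expected
#'   force direction)
#' @param min_step minimal step size in nm
#' @param ... passed to [detect_steps()]
#' @return data frame with columns `force_pN`, `step_nm`, `time_s`, ordered
#'   in time
#' @export
rupture_events_from_ramp <- function(trace, loading_rate, min_step = 10, ...) {
  stopifnot(inherits(trace, "mt_trace"))
  df <- diff(trace$force_pN)
  if (loading_rate > 0 && any(df < -1e-9) ||
      loading_rate < 0 && any(df > 1e-9))
    stop("force channel is not monotone in the scan region")
  fit <- detect_steps(trace, min_step = min_step, ...)
  ev <- fit$events[abs(fit$events$step_nm) >= min_step, , drop = FALSE]
  data.frame(force_pN = ev$force_pN, step_nm = ev$step_nm, time_s = ev$time_s)
}

#' Classify measured steps against theoretical predictions
#'
#' Assigns each event the transition whose predicted step size at the
#' event's force is nearest to the measured size (nearest-prediction rule).
#'
#' @param events data frame with `force_pN` and `step_nm`
#' @param construct a [construct_spec()]
#' @param transitions candidate transitions (default [standard_transitions()])
#' @param env a [polymer_env()]
#' @return `events` with added columns `label` and `predicted_nm`
#' @export
classify_events <- function(events, construct,
                            transitions = standard_transitions(construct),
                            env = polymer_env()) {
  if (nrow(events) == 0L) {
    events$label <- character(0); events$predicted_nm <- numeric(0)
    return(events)
  }
  events$label <- NA_character_
  events$predicted_nm <- NA_real_
  for (r in seq_len(nrow(events))) {
    tab <- predicted_step_table(construct, transitions,
                                forces = events$force_pN[r], env = env)
    k <- which.min(abs(tab$step_nm - events$step_nm[r]))
    events$label[r] <- tab$transition[k]
    events$predicted_nm[r] <- tab$step_nm[k]
  }
  events
}
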