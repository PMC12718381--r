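# assign frames to mixture components with midpoint thresholds and
# +/- 1 sd hysteresis, then merge dwells shorter than min_dwell
.assign_states <- function(e, comp, min_dwell) {
  k <- nrow(comp)
  mu <- comp$mean
  sig <- comp$sd
  nearest <- function(v) max.col(-abs(outer(v, mu, "-")), ties.method = "first")
  raw <- nearest(e)
  st <- integer(length(e))
  st[1L] <- raw[1L]
  for (t in seq_along(e)[-1L]) {
    cur <- st[t - 1L]
    cand <- raw[t]
    if (cand == cur) { st[t] <- cur; next }
    # boundary between current and candidate, in the direction of travel
    if (cand > cur) {
      b <- (mu[cur + 1L] + mu[cur]) / 2
      ok <- e[t] > b + sig[cur + 1L]
      st[t] <- if (ok) cur + 1L else cur
    } else {
      b <- (mu[cur] + mu[cur - 1L]) / 2
      ok <- e[t] < b - sig[cur - 1L]
      st[t] <- if (ok) cur - 1L else cur
    }
  }
  if (min_dwell > 1L) {
    r <- rle(st)
    keep <- r$lengths >= min_dwell
    if (!any(keep)) return(rep.int(st[1L], length(st)))
    if (!all(keep)) {
      # merge short dwells into the previous surviving run
      vals <- r$values
      for (i in seq_along(vals)) {
        if (!keep[i]) vals[i] <- if (i == 1L) vals[which(keep)[1L]]
                                 else vals[i - 1L]
      }
      st <- inverse.rle(list(lengths = r$lengths, values = vals))
      r2 <- rle(st)
      st <- inverse.rle(r2)
    }
  }
  st
}

#' Count FRET state transitions in a time window
#'
#' Assigns each frame of each molecule's FRET series to a mixture
#' component using thresholds at the midpoints between adjacent component
#' means, with a hysteresis band of one s.d. of the nearer component, and
#' counts changes of assigned component that persist for at least
#' `min_dwell` frames. Counts are restricted to the first
#' `window_seconds` of each trace, the windowing used to compare
#' conformational dynamics between constructs (e.g. the rare clamp
#' switching of membrane-anchored full-length STIM1 versus its frequent
#' switching in the soluble cytosolic fragment).
#'
#' @param series list of `fret_series` objects (or a [qc_filter()]
#'   result).
#' @param fit a [fit_mixture()] result with at least 2 components
#'   (with 1 component all counts are 0).
#' @param window_seconds analysis window in seconds (default 5).
#' @param min_dwell minimum frames a new state must persist to count as a
#'   transition (default 3).
#' @return An object of class `transition_stats`: list with
#'   `per_molecule_counts` (named integer vector), `window_seconds`,
#'   `frequency_distribution` (data.frame `count`, `probability`,
#'   summing to 1), and `excluded` (ids of molecules shorter than the
#'   window).
#' @export
count_transitions <- function(series, fit, window_seconds = 5,
                              min_dwell = 3) {
  stopifnot(inherits(fit, "fret_mixture"))
  if (inherits(series, "qc_result"))
    series <- lapply(series$accepted, `[[`, "fret")
  if (inherits(series, "fret_series")) series <- list(series)
  if (window_seconds <= 0) stop("'window_seconds' must be > 0")
  counts <- integer(0)
  excluded <- character(0)
  for (s in series) {
    n_window <- floor(window_seconds / s$frame_interval)
    e <- s$efficiency
    e <- e[is.finite(e)]
    if (length(e) < n_window) {
      excluded <- c(excluded, s$molecule_id)
      next
    }
    e <- e[seq_len(n_window)]
    cnt <- if (fit$k < 2L) 0L else {
      st <- .assign_states(e, fit$components, min_dwell)
      sum(diff(st) != 0L)
    }
    counts[s$molecule_id] <- cnt
  }
  if (length(counts) == 0L)
    stop("no molecule has at least ", window_seconds, " s of usable frames")
  tab <- table(factor(counts, levels = 0:max(counts)))
  dist <- data.frame(count = as.integer(names(tab)),
                     probability = as.numeric(tab) / length(counts))
  structure(list(per_molecule_counts = counts,
                 window_seconds = window_seconds,
                 frequency_distribution = dist,
                 excluded = excluded),
            class = "transition_stats")
}

#' @export
print.transition_stats <- function(x, ...) {
  cat("Transitions in first", x$window_seconds, "s:",
      length(x$per_molecule_counts), "molecules, mean",
      format(mean(x$per_molecule_counts), digits = 3), "per molecule\n")
  if (length(x$excluded))
    cat(length(x$excluded), "molecules shorter than the window excluded\n")
  invisible(x)
}
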