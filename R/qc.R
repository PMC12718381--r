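# --- change-point detection -------------------------------------------------

# SSE of segment [a, b] from cumulative sums; vectorized over a or b
.seg_sse <- function(cs, cs2, a, b) {
  n <- b - a + 1
  s <- cs[b + 1L] - cs[a]
  (cs2[b + 1L] - cs2[a]) - s * s / n
}

# best split of x[a..b]: returns c(split_first_frame_of_right, gain)
.best_split <- function(cs, cs2, a, b, min_segment) {
  lo <- a + min_segment - 1L   # last index of left segment candidates
  hi <- b - min_segment
  if (lo > hi) return(NULL)
  left <- .seg_sse(cs, cs2, a, lo:hi)
  right <- .seg_sse(cs, cs2, (lo:hi) + 1L, b)
  total <- .seg_sse(cs, cs2, a, b)
  gain <- total - (left + right)
  i <- which.max(gain)
  c((lo:hi)[i] + 1L, gain[i])
}

#' Detect intensity steps in a single channel
#'
#' Least-squares change-point detection by binary segmentation with an L2
#' cost, followed by a one-pass local refinement of each change point
#' holding the others fixed. A split is accepted only when it reduces the
#' within-segment squared error by more than a penalty calibrated on the
#' noise level estimated from first differences. Designed for the large,
#' single-step intensity drops of fluorophore photobleaching.
#'
#' @param x numeric intensity series (length >= `2 * min_segment`).
#' @param max_steps maximum number of change points to return (>= 1).
#' @param min_segment minimum frames per segment (default 4).
#' @param penalty cost-reduction threshold for accepting a step;
#'   `NULL` (default) uses `3 * sigma^2 * log(n)` with `sigma` the robust
#'   (MAD-based) noise s.d. from first differences.
#' @return A data.frame with columns `frame` (1-based index of the first
#'   frame after the change) and `step_size` (signed mean-level change),
#'   ordered by frame; zero rows when no step improves the penalized cost.
#' @examples
#' x <- c(rep(200, 100), rep(50, 60))
#' detect_steps(x)  # one step of -150 at frame 101
#' @export
detect_steps <- function(x, max_steps = 3, min_segment = 4, penalty = NULL) {
  n <- length(x)
  if (max_steps < 1L) stop("'max_steps' must be >= 1")
  if (n < 2L * min_segment)
    stop("series shorter than 2 * min_segment (", 2L * min_segment, " frames)")
  if (is.null(penalty)) {
    sigma <- stats::mad(diff(x)) / sqrt(2)
    penalty <- 3 * sigma^2 * log(n)
  }
  cs <- c(0, cumsum(x))
  cs2 <- c(0, cumsum(x * x))
  bounds <- c(1L, n + 1L)  # segment starts, plus sentinel end
  repeat {
    if (length(bounds) - 1L > max_steps) break
    best <- NULL
    starts <- bounds[-length(bounds)]
    ends <- bounds[-1L] - 1L
    for (s in seq_along(starts)) {
      sp <- .best_split(cs, cs2, starts[s], ends[s], min_segment)
      if (!is.null(sp) && (is.null(best) || sp[2L] > best[2L])) best <- sp
    }
    if (is.null(best) || best[2L] <= penalty) break
    bounds <- sort(c(bounds, as.integer(best[1L])))
    if (length(bounds) - 2L >= max_steps) break
  }
  cps <- bounds[-c(1L, length(bounds))]
  if (length(cps) > 0L) {
    # local refinement: re-optimize each change point between its neighbours
    for (pass in 1:2) {
      for (i in seq_along(cps)) {
        a <- if (i == 1L) 1L else cps[i - 1L]
        b <- if (i == length(cps)) n else cps[i + 1L] - 1L
        sp <- .best_split(cs, cs2, a, b, min_segment)
        if (!is.null(sp)) cps[i] <- as.integer(sp[1L])
      }
      cps <- sort(unique(cps))
    }
  }
  if (length(cps) == 0L)
    return(data.frame(frame = integer(), step_size = numeric()))
  seg_bounds <- c(1L, cps, n + 1L)
  means <- vapply(seq_len(length(seg_bounds) - 1L), function(i)
    mean(x[seg_bounds[i]:(seg_bounds[i + 1L] - 1L)]), numeric(1))
  data.frame(frame = cps, step_size = diff(means))
}

# --- bleach events ----------------------------------------------------------

#' Locate photobleaching events in a two-color trace
#'
#' Runs [detect_steps()] on both channels and interprets downward steps as
#' candidate bleaching events: the acceptor bleach is the acceptor
#' channel's downward step, the donor bleach the donor channel's downward
#' step (the donor channel typically also shows an upward step at the
#' acceptor bleach, which is ignored here). Because single-step bleaching
#' is irreversible and falls to background, a downward step counts as a
#' bleach only if it is the channel's last step and drops the channel to
#' its minimal segment level (within a noise tolerance); this guards
#' against occasional spurious steps being mistaken for bleaching, which
#' would corrupt the background estimate. Bleach calling also uses a
#' stricter default penalty than generic step detection. Counts of
#' downward steps per channel are retained for QC.
#'
#' @param trace a `fret_trace`.
#' @param max_steps,min_segment passed to [detect_steps()].
#' @param penalty passed to [detect_steps()]; the default here is
#'   `6 * sigma^2 * log(n)` (twice the generic default) to keep the
#'   false-bleach rate low.
#' @return An object of class `bleach_events`: list with
#'   `acceptor_bleach_frame` and `donor_bleach_frame` (1-based first frame
#'   after the drop, or `NA`), the per-channel step tables, and downward
#'   step counts.
#' @export
find_bleach_events <- function(trace, max_steps = 3, min_segment = 4,
                               penalty = NULL) {
  bleach_of <- function(x) {
    if (is.null(penalty)) {
      sigma <- stats::mad(diff(x)) / sqrt(2)
      pen <- 6 * sigma^2 * log(length(x))
    } else pen <- penalty
    st <- detect_steps(x, max_steps, min_segment, penalty = pen)
    down <- st[st$step_size < 0, , drop = FALSE]
    bleach <- NA_integer_
    if (nrow(st) > 0L && nrow(down) > 0L) {
      last <- st$frame[nrow(st)]
      if (st$step_size[nrow(st)] < 0) {
        bounds <- c(1L, st$frame, length(x) + 1L)
        seg_means <- vapply(seq_len(length(bounds) - 1L), function(i)
          mean(x[bounds[i]:(bounds[i + 1L] - 1L)]), numeric(1))
        sigma <- stats::mad(diff(x)) / sqrt(2)
        if (seg_means[length(seg_means)] <= min(seg_means) + 3 * sigma + 1e-9)
          bleach <- last
      }
    }
    list(steps = st, bleach = bleach, n_down = nrow(down))
  }
  a <- bleach_of(trace$acceptor)
  d <- bleach_of(trace$donor)
  structure(list(
    acceptor_bleach_frame = a$bleach,
    donor_bleach_frame = d$bleach,
    acceptor_steps = a$steps, donor_steps = d$steps,
    n_acceptor_down = a$n_down, n_donor_down = d$n_down),
    class = "bleach_events")
}

# --- gamma ------------------------------------------------------------------

#' Estimate the per-molecule gamma correction
#'
#' gamma is estimated from the intensity steps at acceptor photobleaching:
#' the ratio of the acceptor-channel drop to the donor-channel rise,
#' `gamma = |dI_A| / dI_D`, using mean levels over `window` frames on
#' either side of the acceptor bleach frame. When the trace has no usable
#' acceptor bleach, or the donor does not rise, the estimate falls back to
#' a supplied ensemble value and is flagged.
#'
#' @param trace a `fret_trace`.
#' @param bleach a [find_bleach_events()] result.
#' @param window number of frames averaged on each side of the bleach.
#' @param fallback_gamma ensemble fallback (e.g. the ensemble median of
#'   per-molecule estimates); `NA` if unavailable.
#' @return An object of class `gamma_estimate`: list with `gamma`,
#'   `method` (`"per-molecule-step"` or `"ensemble-fallback"`),
#'   `delta_acceptor`, `delta_donor`.
#' @export
estimate_gamma <- function(trace, bleach, window = 10, fallback_gamma = NA) {
  fallback <- function() structure(
    list(gamma = fallback_gamma, method = "ensemble-fallback",
         delta_acceptor = NA_real_, delta_donor = NA_real_),
    class = "gamma_estimate")
  ba <- bleach$acceptor_bleach_frame
  n <- length(trace$donor)
  if (is.na(ba) || ba - window < 1L || ba + window - 1L > n) return(fallback())
  post_end <- ba + window - 1L
  bd <- bleach$donor_bleach_frame
  if (!is.na(bd) && bd > ba) post_end <- min(post_end, bd - 1L)
  if (post_end < ba) return(fallback())
  pre <- (ba - window):(ba - 1L)
  post <- ba:post_end
  d_a <- mean(trace$acceptor[pre]) - mean(trace$acceptor[post])
  d_d <- mean(trace$donor[post]) - mean(trace$donor[pre])
  if (!is.finite(d_d) || d_d <= 0 || d_a <= 0) return(fallback())
  structure(list(gamma = d_a / d_d, method = "per-molecule-step",
                 delta_acceptor = d_a, delta_donor = d_d),
            class = "gamma_estimate")
}

#' @export
print.gamma_estimate <- function(x, ...) {
  cat("gamma =", format(x$gamma, digits = 4), "(", x$method, ")\n")
  invisible(x)
}

# --- FRET series ------------------------------------------------------------

#' Compute a gamma-corrected FRET time series
#'
#' E = I_A / (I_A + gamma * I_D) per frame after background subtraction.
#' Frames where the denominator is not positive are excluded (set `NA`)
#' and counted. Values are clipped to \[-0.1, 1.1\] for storage; the raw
#' values are retained.
#'
#' @param trace a `fret_trace`.
#' @param gamma a [estimate_gamma()] result or a positive number.
#' @param window integer vector of frame indices (1-based) forming the
#'   analysis window, which must end before the acceptor bleach; `NULL`
#'   uses the whole trace.
#' @param background per-channel baseline to subtract; scalar or
#'   `c(donor, acceptor)`.
#' @return An object of class `fret_series`: list with `molecule_id`,
#'   `efficiency` (clipped), `raw`, `window` (`c(start, end)` half-open is
#'   reported as inclusive 1-based start/end), `gamma_used`, `n_excluded`,
#'   `frame_interval`.
#' @examples
#' tr <- simulate_trace(state_model(0.5), photo_model(noise_sd = 0),
#'                      n_frames = 20, seed = 1)
#' fs <- compute_fret(tr, gamma = 1)
#' stopifnot(all(abs(fs$efficiency - 0.5) < 1e-12))
#' @export
compute_fret <- function(trace, gamma, window = NULL, background = 0) {
  g <- if (inherits(gamma, "gamma_estimate")) gamma$gamma else as.numeric(gamma)
  if (!is.finite(g) || g <= 0) stop("gamma must be finite and > 0")
  n <- length(trace$donor)
  if (is.null(window)) window <- seq_len(n)
  window <- as.integer(window)
  if (any(window < 1L | window > n)) stop("window outside trace bounds")
  background <- rep_len(as.numeric(background), 2L)
  i_d <- trace$donor[window] - background[1L]
  i_a <- trace$acceptor[window] - background[2L]
  denom <- i_a + g * i_d
  bad <- !is.finite(denom) | denom <= 0
  raw <- ifelse(bad, NA_real_, i_a / denom)
  structure(list(molecule_id = trace$molecule_id,
                 efficiency = pmin(pmax(raw, -0.1), 1.1),
                 raw = raw,
                 window = c(min(window), max(window)),
                 gamma_used = g,
                 n_excluded = sum(bad),
                 frame_interval = trace$frame_interval),
            class = "fret_series")
}

#' @export
print.fret_series <- function(x, ...) {
  cat("FRET series", x$molecule_id, "-", length(x$efficiency),
      "frames, gamma =", format(x$gamma_used, digits = 3),
      if (x$n_excluded) paste0("(", x$n_excluded, " frames excluded)"), "\n")
  invisible(x)
}

# --- QC policy and filter ---------------------------------------------------

#' QC thresholds for molecule selection
#'
#' @param min_pre_frames minimum frames before the acceptor bleach.
#' @param max_anticorrelation maximum allowed Pearson correlation between
#'   donor and acceptor over the pre-bleach window (traces with at least
#'   two states should anticorrelate; default -0.2).
#' @param single_state_sd E s.d. below which a trace is treated as
#'   single-state and the anticorrelation test is waived.
#' @param gamma_window frames averaged on each side of the acceptor bleach
#'   for gamma estimation.
#' @param background per-channel fallback baseline used when a trace has
#'   no post-donor-bleach segment to estimate it from.
#' @return A list of class `qc_policy`.
#' @export
qc_policy <- function(min_pre_frames = 10, max_anticorrelation = -0.2,
                      single_state_sd = 0.05, gamma_window = 10,
                      background = 0) {
  structure(list(min_pre_frames = min_pre_frames,
                 max_anticorrelation = max_anticorrelation,
                 single_state_sd = single_state_sd,
                 gamma_window = gamma_window,
                 background = rep_len(as.numeric(background), 2L)),
            class = "qc_policy")
}

#' Quality-control filter for an ensemble of traces
#'
#' Implements the single-molecule selection behind ensemble analyses:
#' accepts molecules with exactly one acceptor bleach step and at most one
#' donor bleach step, acceptor bleaching first, a pre-bleach window of at
#' least `min_pre_frames`, and donor/acceptor anticorrelation over the
#' pre-bleach window (waived for single-state traces by a variance test).
#' Background is taken from the post-donor-bleach segment when one exists,
#' else from the policy. gamma is estimated per molecule from the bleach
#' steps; molecules where that fails receive the ensemble median gamma and
#' are flagged.
#'
#' @param traces list of `fret_trace` objects.
#' @param policy a [qc_policy()].
#' @return A list of class `qc_result`: `accepted` (list of traces, each
#'   with `$bleach`, `$gamma`, `$fret` attached), and `report` (data.frame
#'   with `molecule_id`, `accepted`, `reason`, `gamma`, `gamma_method`,
#'   `acceptor_bleach_frame`, `donor_bleach_frame`).
#' @export
qc_filter <- function(traces, policy = qc_policy()) {
  stopifnot(inherits(policy, "qc_policy"))
  n <- length(traces)
  bleaches <- lapply(traces, find_bleach_events)
  gammas <- mapply(function(tr, bl)
    estimate_gamma(tr, bl, window = policy$gamma_window),
    traces, bleaches, SIMPLIFY = FALSE)
  per_mol <- vapply(gammas, function(g)
    if (g$method == "per-molecule-step") g$gamma else NA_real_, numeric(1))
  fallback <- stats::median(per_mol, na.rm = TRUE)

  accepted <- list()
  report <- vector("list", n)
  for (i in seq_len(n)) {
    tr <- traces[[i]]
    bl <- bleaches[[i]]
    ge <- gammas[[i]]
    if (ge$method == "ensemble-fallback") ge$gamma <- fallback
    reason <- NA_character_
    if (is.na(bl$acceptor_bleach_frame)) reason <- "no-acceptor-bleach"
    else if (bl$n_acceptor_down > 1L) reason <- "multiple-acceptor-steps"
    else if (bl$n_donor_down > 1L) reason <- "multiple-donor-steps"
    else if (!is.na(bl$donor_bleach_frame) &&
             bl$donor_bleach_frame <= bl$acceptor_bleach_frame)
      reason <- "donor-first"
    else if (bl$acceptor_bleach_frame - 1L < policy$min_pre_frames)
      reason <- "short-pre-bleach"
    else if (!is.finite(ge$gamma) || ge$gamma <= 0)
      reason <- "no-gamma"

    fs <- NULL
    if (is.na(reason)) {
      bg <- policy$background
      if (!is.na(bl$donor_bleach_frame) &&
          bl$donor_bleach_frame + 2L <= length(tr$donor)) {
        post <- bl$donor_bleach_frame:length(tr$donor)
        bg <- c(mean(tr$donor[post]), mean(tr$acceptor[post]))
      }
      pre <- seq_len(bl$acceptor_bleach_frame - 1L)
      fs <- compute_fret(tr, ge, window = pre, background = bg)
      rho <- suppressWarnings(stats::cor(tr$donor[pre], tr$acceptor[pre]))
      e_sd <- stats::sd(fs$efficiency, na.rm = TRUE)
      single_state <- is.finite(e_sd) && e_sd < policy$single_state_sd
      if (!single_state &&
          (!is.finite(rho) || rho > policy$max_anticorrelation))
        reason <- "not-anticorrelated"
    }
    if (is.na(reason)) {
      tr$bleach <- bl
      tr$gamma <- ge
      tr$fret <- fs
      accepted[[length(accepted) + 1L]] <- tr
    }
    report[[i]] <- data.frame(
      molecule_id = tr$molecule_id,
      accepted = is.na(reason),
      reason = ifelse(is.na(reason), "", reason),
      gamma = ge$gamma, gamma_method = ge$method,
      acceptor_bleach_frame = bl$acceptor_bleach_frame,
      donor_bleach_frame = bl$donor_bleach_frame)
  }
  structure(list(accepted = accepted, report = do.call(rbind, report)),
            class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  n <- nrow(x$report)
  cat("QC:", length(x$accepted), "of", n, "molecules accepted\n")
  rej <- x$report$reason[!x$report$accepted]
  if (length(rej)) print(table(rej))
  invisible(x)
}
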