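#' Define a conformational state model
#'
#' A state model holds the true FRET efficiency of each conformational
#' state, the per-second switching rates between states, and the
#' initial/equilibrium occupancy of each state. It is the generative
#' counterpart of the (peak FRET, fractional area) parameters recovered by
#' [fit_mixture()] from an amplitude histogram.
#'
#' @param fret numeric vector of true FRET efficiencies, one per state,
#'   each in \[0, 1\].
#' @param rates square numeric matrix of per-second switching rates
#'   (off-diagonal entries, s^-1, all >= 0). The diagonal is ignored. A
#'   single number 0 (the default) means a static model.
#' @param probs initial/equilibrium state occupancies; must sum to 1.
#'   Default: uniform.
#' @return An object of class `state_model`.
#' @examples
#' # the two-state resting/activated model of the 242:242' dye pair in Ca2+
#' sm <- state_model(fret = c(0.28, 0.68), probs = c(0.70, 0.30))
#' @export
state_model <- function(fret, rates = 0, probs = NULL) {
  fret <- as.numeric(fret)
  k <- length(fret)
  if (k < 1L) stop("state model must have at least one state")
  if (any(!is.finite(fret)) || any(fret < 0) || any(fret > 1))
    stop("state FRET efficiencies must be finite and in [0, 1]")
  if (is.null(probs)) probs <- rep(1 / k, k)
  probs <- as.numeric(probs)
  if (length(probs) != k)
    stop("'probs' must have one entry per state")
  if (abs(sum(probs) - 1) > 1e-9)
    stop("state probabilities must sum to 1")
  if (any(probs < 0)) stop("state probabilities must be >= 0")
  if (identical(rates, 0)) rates <- matrix(0, k, k)
  rates <- as.matrix(rates)
  if (!all(dim(rates) == c(k, k)))
    stop("'rates' must be a ", k, "x", k, " matrix")
  if (any(rates[row(rates) != col(rates)] < 0))
    stop("off-diagonal switching rates must be >= 0")
  diag(rates) <- 0
  structure(list(fret = fret, rates = rates, probs = probs, k = k),
            class = "state_model")
}

#' Define a photophysical model
#'
#' Collects the intensity, noise, detection-correction and photobleaching
#' parameters used when simulating a two-color trace. `gamma` is the
#' per-molecule correction for unequal detection efficiency and quantum
#' yield between the donor and acceptor channels, so that
#' E = I_A / (I_A + gamma * I_D) recovers the true efficiency.
#'
#' @param total_intensity mean summed two-channel intensity before
#'   acceptor bleaching (counts/frame).
#' @param gamma detection-efficiency/quantum-yield correction (> 0).
#' @param noise_sd additive Gaussian noise s.d. per channel
#'   (counts/frame). The default 20 is the shot-noise scale of a
#'   ~500 counts/frame molecule, giving per-frame FRET scatter of about
#'   0.03.
#' @param acceptor_bleach_rate,donor_bleach_rate per-frame single-step
#'   bleaching hazards, each in \[0, 1\]. 0 disables bleaching.
#' @param background per-channel baseline (counts/frame); scalar or a
#'   length-2 vector `c(donor, acceptor)`.
#' @return An object of class `photo_model`.
#' @export
photo_model <- function(total_intensity = 500, gamma = 1, noise_sd = 20,
                        acceptor_bleach_rate = 0, donor_bleach_rate = 0,
                        background = 0) {
  if (!is.finite(gamma) || gamma <= 0) stop("'gamma' must be > 0")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  for (r in c(acceptor_bleach_rate, donor_bleach_rate))
    if (!is.finite(r) || r < 0 || r > 1)
      stop("bleach rates are per-frame hazards in [0, 1]")
  background <- rep_len(as.numeric(background), 2L)
  structure(list(total_intensity = total_intensity, gamma = gamma,
                 noise_sd = noise_sd,
                 acceptor_bleach_rate = acceptor_bleach_rate,
                 donor_bleach_rate = donor_bleach_rate,
                 background = background),
            class = "photo_model")
}

# first frame (1-based) at which a per-frame hazard has fired; Inf if never
.bleach_frame <- function(rate, n_frames) {
  if (rate <= 0) return(Inf)
  if (rate >= 1) return(1L)
  f <- stats::rgeom(1L, rate) + 1L
  if (f > n_frames) Inf else f
}

# discrete-frame Markov path: per-frame leave probability 1 - exp(-r_i * dt),
# destination chosen proportionally to the off-diagonal rates
.simulate_path <- function(model, n_frames, frame_interval) {
  k <- model$k
  s0 <- sample.int(k, 1L, prob = model$probs)
  if (k == 1L || all(model$rates == 0)) return(rep.int(s0, n_frames))
  exit <- rowSums(model$rates)
  p_leave <- 1 - exp(-exit * frame_interval)
  path <- integer(n_frames)
  path[1L] <- s0
  u <- stats::runif(n_frames)
  for (t in seq_len(n_frames - 1L)) {
    s <- path[t]
    if (u[t] < p_leave[s]) {
      dest <- model$rates[s, ] / exit[s]
      path[t + 1L] <- sample.int(k, 1L, prob = dest)
    } else path[t + 1L] <- s
  }
  path
}

#' Simulate a two-color smFRET trace
#'
#' Generates donor and acceptor intensity time series for one molecule:
#' hidden-Markov switching between conformational states, single-step
#' irreversible acceptor and donor photobleaching, and additive Gaussian
#' noise. Before any bleaching the noiseless expectations are
#' `acceptor = background + total * E` and
#' `donor = background + total * (1 - E) / gamma`, so the ratio formula
#' E = I_A / (I_A + gamma * I_D) recovers the state FRET exactly. After
#' acceptor bleaching the acceptor falls to background and the donor rises
#' to `background + total / gamma`; after donor bleaching both channels
#' are background.
#'
#' @param model a [state_model()].
#' @param photo a [photo_model()].
#' @param n_frames number of frames (>= 1).
#' @param frame_interval seconds per frame (> 0).
#' @param seed integer seed; identical inputs and seed give identical
#'   traces. `NULL` uses the current RNG state.
#' @param molecule_id identifier stored in the trace.
#' @return An object of class `fret_trace`: a list with elements
#'   `molecule_id`, `frame_interval`, `donor`, `acceptor` and `truth`
#'   (state path, bleach frames, gamma).
#' @examples
#' tr <- simulate_trace(state_model(0.4), photo_model(noise_sd = 0),
#'                      n_frames = 50, seed = 1)
#' e <- with(tr, acceptor / (acceptor + donor))
#' stopifnot(all(abs(e - 0.4) < 1e-12))
#' @export
simulate_trace <- function(model, photo, n_frames, frame_interval = 0.1,
                           seed = NULL, molecule_id = "mol1") {
  stopifnot(inherits(model, "state_model"), inherits(photo, "photo_model"))
  if (model$k < 1L) stop("empty state model")
  n_frames <- as.integer(n_frames)
  if (is.na(n_frames) || n_frames < 1L) stop("'n_frames' must be >= 1")
  if (!is.finite(frame_interval) || frame_interval <= 0)
    stop("'frame_interval' must be > 0")
  if (!is.null(seed)) set.seed(as.integer(seed))

  path <- .simulate_path(model, n_frames, frame_interval)
  b_a <- .bleach_frame(photo$acceptor_bleach_rate, n_frames)
  b_d <- .bleach_frame(photo$donor_bleach_rate, n_frames)

  t_idx <- seq_len(n_frames)
  e <- model$fret[path]
  total <- photo$total_intensity
  g <- photo$gamma
  bg_d <- photo$background[1L]
  bg_a <- photo$background[2L]

  live <- t_idx < pmin(b_a, b_d)          # FRET-active frames
  donor_only <- !live & t_idx < b_d & b_a <= b_d  # acceptor dark, donor alive
  acceptor <- ifelse(live, bg_a + total * e, bg_a)
  donor <- ifelse(live, bg_d + total * (1 - e) / g,
                  ifelse(donor_only, bg_d + total / g, bg_d))
  if (photo$noise_sd > 0) {
    donor <- donor + stats::rnorm(n_frames, 0, photo$noise_sd)
    acceptor <- acceptor + stats::rnorm(n_frames, 0, photo$noise_sd)
  }
  structure(list(molecule_id = molecule_id,
                 frame_interval = frame_interval,
                 donor = donor, acceptor = acceptor,
                 truth = list(path = path,
                              acceptor_bleach_frame = b_a,
                              donor_bleach_frame = b_d,
                              gamma = g,
                              state_fret = model$fret)),
            class = "fret_trace")
}

#' @export
print.fret_trace <- function(x, ...) {
  cat("smFRET trace", x$molecule_id, "-", length(x$donor), "frames @",
      x$frame_interval, "s/frame\n")
  invisible(x)
}

#' Simulate an ensemble of smFRET traces
#'
#' Draws `n_molecules` independent traces from a shared state model.
#' Per-molecule gamma factors are drawn from a log-normal population
#' (median `exp(gamma_meanlog)`), emulating the empirical per-molecule
#' gamma measurement. `fret_jitter_sd` adds per-molecule static
#' heterogeneity: each molecule's true state FRET values are jittered by a
#' Gaussian of this s.d., which is what gives ensemble amplitude
#' histograms their component width.
#'
#' @inheritParams simulate_trace
#' @param n_molecules number of molecules (>= 1).
#' @param seed master seed; per-molecule seeds are derived from it
#'   deterministically.
#' @param gamma_meanlog,gamma_sdlog log-normal population of per-molecule
#'   gamma. `gamma_sdlog = 0` fixes gamma at the photo model's value times
#'   `exp(gamma_meanlog)`.
#' @param fret_jitter_sd s.d. of per-molecule jitter applied to the state
#'   FRET values (clipped to \[-0.05, 1.05\]); 0 disables it.
#' @return A list of [simulate_trace()] results (class `fret_ensemble`).
#' @export
simulate_ensemble <- function(model, photo, n_molecules, n_frames,
                              frame_interval = 0.1, seed = 1,
                              gamma_meanlog = 0, gamma_sdlog = 0.2,
                              fret_jitter_sd = 0) {
  stopifnot(inherits(model, "state_model"), inherits(photo, "photo_model"))
  n_molecules <- as.integer(n_molecules)
  if (is.na(n_molecules) || n_molecules < 1L)
    stop("'n_molecules' must be >= 1")
  set.seed(as.integer(seed))
  mol_seeds <- sample.int(.Machine$integer.max, n_molecules)
  gammas <- if (gamma_sdlog > 0)
    stats::rlnorm(n_molecules, gamma_meanlog, gamma_sdlog)
  else rep(photo$gamma * exp(gamma_meanlog), n_molecules)
  jitter <- if (fret_jitter_sd > 0)
    matrix(stats::rnorm(n_molecules * model$k, 0, fret_jitter_sd),
           n_molecules, model$k)
  else matrix(0, n_molecules, model$k)

  traces <- vector("list", n_molecules)
  for (i in seq_len(n_molecules)) {
    ph <- photo
    ph$gamma <- gammas[i]
    sm <- model
    sm$fret <- pmin(pmax(model$fret + jitter[i, ], -0.05), 1.05)
    traces[[i]] <- simulate_trace(sm, ph, n_frames, frame_interval,
                                  seed = mol_seeds[i],
                                  molecule_id = sprintf("mol%04d", i))
  }
  structure(traces, class = c("fret_ensemble", "list"))
}

#' @export
print.fret_ensemble <- function(x, ...) {
  cat("smFRET ensemble:", length(x), "molecules,",
      length(x[[1L]]$donor), "frames each\n")
  invisible(x)
}
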