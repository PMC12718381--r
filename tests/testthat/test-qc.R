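# ---- step detection --------------------------------------------------------

test_that("a noiseless level shift is located exactly with its signed size", {
  x <- c(rep(200, 100), rep(50, 60))
  st <- detect_steps(x)
  expect_equal(st$frame, 101L)  # first frame of the new level
  expect_equal(st$step_size, -150)
})

test_that("constant and too-short series are handled", {
  expect_equal(nrow(detect_steps(rep(7, 50))), 0L)
  set.seed(1)
  expect_equal(nrow(detect_steps(rnorm(100, 100, 5))), 0L)
  expect_error(detect_steps(rnorm(6), min_segment = 4), "min_segment")
})

test_that("two-step staircases match the exhaustive least-squares oracle", {
  set.seed(42)
  for (rep in 1:12) {
    n <- sample(40:200, 1)
    c1 <- sample(5:(n - 12), 1)
    c2 <- sample((c1 + 4):(n - 4), 1)
    levels <- cumsum(c(300, sample(c(-1, 1), 2, TRUE) * runif(2, 100, 250)))
    x <- c(rep(levels[1], c1 - 1), rep(levels[2], c2 - c1),
           rep(levels[3], n - c2 + 1)) + rnorm(n, 0, 5)
    st <- detect_steps(x, max_steps = 2)
    orc <- oracle_changepoints(x, 2)
    expect_equal(st$frame, orc$frames,
                 info = sprintf("rep %d n=%d cp=(%d,%d)", rep, n, c1, c2))
  }
})

test_that("single large steps match the oracle over random placements", {
  set.seed(99)
  for (rep in 1:10) {
    n <- sample(30:200, 1)
    c1 <- sample(5:(n - 4), 1)
    x <- c(rep(120, c1 - 1), rep(260, n - c1 + 1)) + rnorm(n, 0, 5)
    st <- detect_steps(x, max_steps = 1)
    orc <- oracle_changepoints(x, 1)
    expect_equal(st$frame, orc$frames)
  }
})

# ---- gamma -----------------------------------------------------------------

test_that("gamma is the acceptor drop over the donor rise at acceptor bleach", {
  # acceptor 100 -> 0, donor 50 -> 150: equal magnitudes, gamma 1
  tr <- structure(list(molecule_id = "g1", frame_interval = 0.1,
                       donor = c(rep(50, 40), rep(150, 40)),
                       acceptor = c(rep(100, 40), rep(0, 40)), truth = NULL),
                  class = "fret_trace")
  bl <- find_bleach_events(tr)
  g <- estimate_gamma(tr, bl)
  expect_equal(g$gamma, 1.0)
  expect_equal(g$method, "per-molecule-step")

  # acceptor 120 -> 20, donor 40 -> 90: 100 / 50 = 2
  tr2 <- structure(list(molecule_id = "g2", frame_interval = 0.1,
                        donor = c(rep(40, 40), rep(90, 40)),
                        acceptor = c(rep(120, 40), rep(20, 40)), truth = NULL),
                   class = "fret_trace")
  g2 <- estimate_gamma(tr2, find_bleach_events(tr2))
  expect_equal(g2$gamma, 2.0)
})

test_that("gamma recovery from noisy traces is accurate and scale-invariant", {
  tr <- make_trace(e = 0.5, gamma = 1.4, total = 500, n = 120,
                   bleach_a = 60, bleach_d = Inf, noise = 5, seed = 8)
  g <- estimate_gamma(tr, find_bleach_events(tr), window = 10)
  expect_lt(abs(g$gamma - 1.4), 0.1)

  tr_scaled <- tr
  tr_scaled$donor <- tr$donor * 3.7
  tr_scaled$acceptor <- tr$acceptor * 3.7
  g_s <- estimate_gamma(tr_scaled, find_bleach_events(tr_scaled), window = 10)
  expect_equal(g_s$gamma, g$gamma, tolerance = 1e-10)
})

test_that("traces without a usable acceptor bleach fall back and are flagged", {
  tr <- make_trace(e = 0.5, n = 80, noise = 3, seed = 2)  # no bleach at all
  g <- estimate_gamma(tr, find_bleach_events(tr), fallback_gamma = 1.11)
  expect_equal(g$method, "ensemble-fallback")
  expect_equal(g$gamma, 1.11)
})

# ---- FRET series -----------------------------------------------------------

test_that("the ratio formula evaluates the stated examples", {
  tr <- structure(list(molecule_id = "f", frame_interval = 0.1,
                       donor = c(50, 80, 20), acceptor = c(50, 0, 60),
                       truth = NULL), class = "fret_trace")
  e1 <- compute_fret(tr, gamma = 1, window = 1)
  expect_equal(e1$efficiency, 0.5)
  e2 <- compute_fret(tr, gamma = 1, window = 2)
  expect_equal(e2$efficiency, 0)
  e3 <- compute_fret(tr, gamma = 2, window = 3)
  expect_equal(e3$efficiency, 60 / (60 + 40))
})

test_that("non-positive denominators are excluded and counted", {
  tr <- structure(list(molecule_id = "f", frame_interval = 0.1,
                       donor = c(50, -60, 50), acceptor = c(50, 10, 50),
                       truth = NULL), class = "fret_trace")
  fs <- compute_fret(tr, gamma = 1)
  expect_equal(fs$n_excluded, 1L)
  expect_true(is.na(fs$efficiency[2]))
  expect_equal(fs$efficiency[c(1, 3)], c(0.5, 0.5))
})

test_that("FRET values are clipped for storage with raw values retained", {
  tr <- structure(list(molecule_id = "f", frame_interval = 0.1,
                       donor = c(-10), acceptor = c(100), truth = NULL),
                  class = "fret_trace")
  fs <- compute_fret(tr, gamma = 1)
  expect_equal(fs$efficiency, 1.1)
  expect_equal(fs$raw, 100 / 90)
})

test_that("compute_fret after simulate_trace reproduces state FRET exactly", {
  sm <- state_model(c(0.25, 0.8), rates = matrix(c(0, 1, 1, 0), 2),
                    probs = c(0.5, 0.5))
  tr <- simulate_trace(sm, photo_model(gamma = 1.6, noise_sd = 0), 120,
                       seed = 4)
  fs <- compute_fret(tr, gamma = 1.6)
  expect_equal(fs$efficiency, sm$fret[tr$truth$path], tolerance = 1e-12)
})

# ---- QC filter -------------------------------------------------------------

test_that("a clean single-bleach ensemble is fully accepted", {
  set.seed(31)
  traces <- lapply(1:100, function(i)
    make_trace(e = runif(1, 0.2, 0.8), gamma = runif(1, 0.8, 1.25),
               total = 500, n = 150, bleach_a = sample(40:80, 1),
               bleach_d = sample(110:140, 1), noise = 5,
               id = sprintf("m%03d", i)))
  qc <- qc_filter(traces)
  expect_equal(nrow(qc$report), 100L)
  expect_true(all(qc$report$accepted))
  expect_true(all(qc$report$gamma_method == "per-molecule-step"))
})

test_that("rejection reasons identify donor-first and missing bleaching", {
  donor_first <- make_trace(e = 0.5, n = 150, bleach_a = 100, bleach_d = 50,
                            noise = 4, seed = 1)
  no_bleach <- make_trace(e = 0.5, n = 150, noise = 4, seed = 2)
  short_pre <- make_trace(e = 0.5, n = 150, bleach_a = 6, bleach_d = 100,
                          noise = 4, seed = 3)
  qc <- qc_filter(list(donor_first, no_bleach, short_pre))
  expect_equal(qc$report$reason,
               c("donor-first", "no-acceptor-bleach", "short-pre-bleach"))
  expect_length(qc$accepted, 0)
})

test_that("dynamic traces must anticorrelate; static traces are waived", {
  # static trace with substantial uncorrelated channel noise on E scale:
  # donor and acceptor vary independently -> correlation near 0, but the
  # E s.d. is small, so the variance waiver applies
  static <- make_trace(e = 0.5, n = 150, bleach_a = 90, bleach_d = 130,
                       noise = 8, seed = 21)
  qc1 <- qc_filter(list(static))
  expect_true(qc1$report$accepted)

  # rapidly toggling channels, faster than the minimum step segment, so
  # no bleach-like steps are called in the pre-bleach window
  toggle <- rep(c(-100, -100, 100, 100), length.out = 89)
  base <- function(sign_d) {
    tr <- make_trace(e = 0.3, n = 150, bleach_a = 90, bleach_d = 130,
                     noise = 20, seed = 23)
    tr$donor[1:89] <- 350 + sign_d * toggle
    tr$acceptor[1:89] <- 150 + toggle
    tr
  }
  # in-phase fluctuation: E swings but channels correlate -> rejected
  qc2 <- qc_filter(list(base(+1)))
  expect_false(qc2$report$accepted[1])
  expect_equal(qc2$report$reason[1], "not-anticorrelated")
  # anticorrelated fluctuation (real state switching signature) -> accepted
  qc3 <- qc_filter(list(base(-1)))
  expect_true(qc3$report$accepted[1])
})
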