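# ---- shared study conditions ----------------------------------------------
# generator settings used for ensemble-level recovery checks: per-frame
# shot-noise scale 20 counts and 0.063 per-molecule jitter combine to a
# histogram component width of ~0.07
study_photo <- function(gamma = 1)
  photo_model(total_intensity = 500, gamma = gamma, noise_sd = 20,
              acceptor_bleach_rate = 0.02, donor_bleach_rate = 0.005)

study_jitter <- 0.063

# printed reference mixture fits used as generators: peak FRET values,
# fractional areas and molecule counts per condition
reference_fits <- list(
  ca_2mm     = list(mu = c(0.28, 0.68), w = c(0.70, 0.30), n = 361),
  egta       = list(mu = c(0.29, 0.65, 0.88), w = c(0.25, 0.67, 0.08), n = 437),
  tm_ct      = list(mu = c(0.30, 0.75), w = c(0.59, 0.41), n = 203),
  mbp_tm_ct  = list(mu = c(0.32, 0.59, 0.78), w = c(0.92, 0.04, 0.04), n = 234),
  pc_only    = list(mu = c(0.36, 0.72, 0.88), w = c(0.33, 0.60, 0.06), n = 184),
  four_ka    = list(mu = c(0.25, 0.58, 0.81), w = c(0.17, 0.47, 0.36), n = 243))

# run the full qc -> histogram -> mixture pipeline on one simulated ensemble
recover_condition <- function(cond, seed, k = length(cond$mu)) {
  sm <- state_model(cond$mu, probs = cond$w / sum(cond$w))
  ens <- simulate_ensemble(sm, study_photo(), cond$n, n_frames = 100,
                           seed = seed, fret_jitter_sd = study_jitter)
  qc <- qc_filter(ens)
  fit <- fit_mixture(build_histogram(qc), k_range = k, seed = 1,
                     equal_widths = TRUE, weighting = "poisson")
  fit
}

# build a trace directly with prescribed levels and bleach frames
make_trace <- function(e = 0.4, gamma = 1, total = 500, n = 150,
                       bleach_a = Inf, bleach_d = Inf, noise = 0,
                       background = 0, id = "m1", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t_idx <- seq_len(n)
  live <- t_idx < pmin(bleach_a, bleach_d)
  donly <- !live & t_idx < bleach_d & bleach_a <= bleach_d
  acc <- ifelse(live, background + total * e, background)
  don <- ifelse(live, background + total * (1 - e) / gamma,
                ifelse(donly, background + total / gamma, background))
  if (noise > 0) {
    don <- don + rnorm(n, 0, noise)
    acc <- acc + rnorm(n, 0, noise)
  }
  structure(list(molecule_id = id, frame_interval = 0.1,
                 donor = don, acceptor = acc, truth = NULL),
            class = "fret_trace")
}

# ---- independent oracles ---------------------------------------------------

# exhaustive least-squares change-point search for exactly k in {0, 1, 2}
# steps; returns list(frames, sse)
oracle_changepoints <- function(x, k, min_segment = 4) {
  n <- length(x)
  sse <- function(a, b) {
    v <- x[a:b]
    sum((v - mean(v))^2)
  }
  if (k == 0) return(list(frames = integer(0), sse = sse(1, n)))
  if (k == 1) {
    cand <- (min_segment + 1L):(n - min_segment + 1L)
    tot <- vapply(cand, function(c) sse(1, c - 1L) + sse(c, n), numeric(1))
    return(list(frames = cand[which.min(tot)], sse = min(tot)))
  }
  best <- NULL
  for (c1 in (min_segment + 1L):(n - 2L * min_segment + 1L)) {
    for (c2 in (c1 + min_segment):(n - min_segment + 1L)) {
      tot <- sse(1, c1 - 1L) + sse(c1, c2 - 1L) + sse(c2, n)
      if (is.null(best) || tot < best$sse)
        best <- list(frames = c(c1, c2), sse = tot)
    }
  }
  best
}

# invert the Forster relation by bisection (independent of the closed form)
oracle_invert_fret <- function(e_target, r0, tol = 1e-12) {
  lo <- 1e-6
  hi <- r0 * 100
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    e_mid <- 1 / (1 + (mid / r0)^6)
    if (e_mid > e_target) lo <- mid else hi <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

# random pairing of a labelled subunit pool, counting heterodimers
oracle_pairing <- function(n1, n2, seed) {
  set.seed(seed)
  pool <- sample(rep(c(1L, 2L), c(n1, n2)))
  odd <- pool[seq(1L, length(pool), by = 2L)]
  even <- pool[seq(2L, length(pool), by = 2L)]
  sum(odd != even)
}

# ---- toy structure fixtures ------------------------------------------------

# write a PDB file from a data.frame(chain, resno, elety, x, y, z)
write_toy_pdb <- function(atoms, path = tempfile(fileext = ".pdb")) {
  lines <- character(nrow(atoms))
  for (i in seq_len(nrow(atoms))) {
    a <- atoms[i, ]
    elem <- substr(gsub("[0-9]", "", a$elety), 1L, 1L)
    lines[i] <- sprintf(
      "ATOM  %5d  %-3s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      i, a$elety, "ALA", a$chain, a$resno, a$x, a$y, a$z, 1, 0, elem)
  }
  writeLines(c(lines, "END"), path)
  path
}

# two-chain toy model: n_res residues per chain along x, CA/CB pairs
toy_dimer_pdb <- function(n_res = 10, spacing = 5, chain_offset = 50) {
  rows <- list()
  for (ch in c("A", "B")) {
    z0 <- if (ch == "A") 0 else chain_offset
    for (r in seq_len(n_res)) {
      rows[[length(rows) + 1L]] <- data.frame(
        chain = ch, resno = r, elety = c("CA", "CB"),
        x = r * spacing, y = c(0, 1.5), z = z0)
    }
  }
  write_toy_pdb(do.call(rbind, rows))
}

# a single labelled residue (CB at the origin, optionally with CA) plus
# arbitrary extra obstacle atoms given as data.frame(x, y, z)
toy_site_pdb <- function(extra = NULL, include_ca = FALSE) {
  atoms <- data.frame(chain = "A", resno = 1, elety = "CB",
                      x = 0, y = 0, z = 0)
  if (include_ca)
    atoms <- rbind(atoms, data.frame(chain = "A", resno = 1, elety = "CA",
                                     x = 0, y = 0, z = -1.5))
  if (!is.null(extra)) {
    extra <- data.frame(chain = "A", resno = seq_len(nrow(extra)) + 1,
                        elety = "O", x = extra$x, y = extra$y, z = extra$z)
    atoms <- rbind(atoms, extra)
  }
  write_toy_pdb(atoms)
}
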