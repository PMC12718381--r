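# --- structural model -------------------------------------------------------

#' Load a structural model from a PDB file
#'
#' Reads a (possibly dimeric) structural model and exposes its heavy-atom
#' coordinates by chain, author residue number and atom name, so that
#' intra- vs inter-subunit dye pairs (the prime convention: "A:B'" pairs
#' site A on one chain with site B on the other) are addressable.
#'
#' @param path PDB-format file.
#' @return An object of class `structural_model`: list with `atoms`
#'   (data.frame `chain`, `resno`, `elety`, `x`, `y`, `z`; hydrogens
#'   excluded), `chains`, `path`.
#' @export
load_model <- function(path) {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  heavy <- !(toupper(trimws(at$elesy)) %in% "H") &
    !grepl("^[0-9]*H", trimws(at$elety))
  at <- at[heavy & at$type %in% c("ATOM", "HETATM"), , drop = FALSE]
  atoms <- data.frame(chain = at$chain, resno = at$resno,
                      elety = trimws(at$elety),
                      x = at$x, y = at$y, z = at$z,
                      stringsAsFactors = FALSE)
  structure(list(atoms = atoms, chains = unique(atoms$chain), path = path),
            class = "structural_model")
}

#' @export
print.structural_model <- function(x, ...) {
  cat("Structural model:", length(x$chains), "chain(s) (",
      paste(x$chains, collapse = ", "), "),",
      length(unique(paste(x$atoms$chain, x$atoms$resno))), "residues,",
      nrow(x$atoms), "heavy atoms\n")
  invisible(x)
}

#' Look up an atom's coordinates
#'
#' @param model a [load_model()] result.
#' @param chain chain identifier.
#' @param resno author residue number.
#' @param atom atom name (e.g. `"CB"`); with `fallback`, `"CA"` is used
#'   when the requested atom is absent from the residue.
#' @param fallback fall back to CA when the atom is missing.
#' @return Numeric xyz (Angstrom).
#' @export
lookup_atom <- function(model, chain, resno, atom = "CB", fallback = TRUE) {
  res <- model$atoms[model$atoms$chain == chain &
                     model$atoms$resno == resno, , drop = FALSE]
  if (nrow(res) == 0L)
    stop("residue ", resno, " on chain ", chain, " not found in model")
  hit <- res[res$elety == atom, , drop = FALSE]
  if (nrow(hit) == 0L && fallback) hit <- res[res$elety == "CA", , drop = FALSE]
  if (nrow(hit) == 0L)
    stop("atom ", atom, " (and CA fallback) missing at ", chain, ":", resno)
  as.numeric(hit[1L, c("x", "y", "z")])
}

#' Define a dye labeling site
#'
#' Accessible-volume parameters follow standard single-radius (AV1)
#' conventions for maleimide dyes on cysteine-substituted residues; the
#' attachment atom defaults to the residue's C-beta (falling back to
#' C-alpha when absent).
#'
#' @param chain chain identifier.
#' @param resno author residue number (1-based, as in the PDB).
#' @param atom attachment atom name (default `"CB"`).
#' @param linker_length dye linker length in Angstrom (default 20).
#' @param linker_width linker diameter in Angstrom (default 4.5).
#' @param dye_radius dye radius in Angstrom (default 3.5).
#' @return An object of class `label_site`.
#' @export
label_site <- function(chain, resno, atom = "CB", linker_length = 20,
                       linker_width = 4.5, dye_radius = 3.5) {
  if (linker_length <= 0) stop("'linker_length' must be > 0")
  structure(list(chain = chain, resno = resno, atom = atom,
                 linker_length = linker_length, linker_width = linker_width,
                 dye_radius = dye_radius),
            class = "label_site")
}

# min distance from each point (rows of p) to any obstacle (rows of obs),
# computed in chunks to bound memory
.min_dist_to <- function(p, obs) {
  if (nrow(obs) == 0L) return(rep(Inf, nrow(p)))
  out <- numeric(nrow(p))
  obs2 <- rowSums(obs^2)
  chunk <- 5000L
  for (i in seq(1L, nrow(p), by = chunk)) {
    j <- i:min(i + chunk - 1L, nrow(p))
    pj <- p[j, , drop = FALSE]
    d2 <- outer(rowSums(pj^2), obs2, "+") - 2 * (pj %*% t(obs))
    out[j] <- sqrt(pmax(apply(d2, 1L, min), 0))
  }
  out
}

# shared accessibility test: clash clearance at the dye center plus
# straight-line linker clearance back to the attachment atom
.allowed_positions <- function(cand, attach, obs, site, clash_distance) {
  keep <- .min_dist_to(cand, obs) >= site$dye_radius + clash_distance
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) == 0L) return(cand)
  half_w <- site$linker_width / 2
  n_path <- 8L
  fr <- seq_len(n_path) / (n_path + 1L)
  ok <- rep(TRUE, nrow(cand))
  for (f in fr) {
    pts <- sweep(cand * f, 2L, attach * (1 - f), "+")
    ok <- ok & (.min_dist_to(pts, obs) >= half_w)
    if (!any(ok)) break
  }
  cand[ok, , drop = FALSE]
}

#' Simulate an accessible-volume dye cloud
#'
#' Enumerates candidate dye-center positions on a cubic grid within
#' `linker_length` of the attachment atom and keeps those that (a) keep
#' at least `dye_radius + clash_distance` from every model heavy atom and
#' (b) have straight-line linker clearance of `linker_width / 2` back to
#' the attachment atom. The attachment atom itself is not treated as an
#' obstacle. This geometric accessible-volume construction stands in for
#' explicit dye-position simulation on the structure; the cloud centroid
#' is the model-implied mean dye position.
#'
#' @param model a [load_model()] result.
#' @param site a [label_site()].
#' @param grid_spacing grid step in Angstrom (default 1).
#' @param clash_distance extra clearance beyond the dye radius (default 1).
#' @return An object of class `dye_cloud`: list with `positions` (matrix,
#'   Angstrom), `mean_position`, `n_samples` (candidates in the linker
#'   ball), `n_allowed`, `attachment`, `site`.
#' @export
simulate_dye_cloud <- function(model, site, grid_spacing = 1,
                               clash_distance = 1) {
  stopifnot(inherits(model, "structural_model"), inherits(site, "label_site"))
  if (grid_spacing <= 0) stop("'grid_spacing' must be > 0")
  attach <- lookup_atom(model, site$chain, site$resno, site$atom)
  a <- model$atoms
  self <- a$chain == site$chain & a$resno == site$resno &
    a$elety == site$atom
  # nearest-neighbour coordinate match also drops a CA used as fallback
  if (!any(self)) {
    d <- sqrt((a$x - attach[1])^2 + (a$y - attach[2])^2 + (a$z - attach[3])^2)
    self <- d < 1e-6
  }
  obs <- as.matrix(a[!self, c("x", "y", "z"), drop = FALSE])
  L <- site$linker_length
  reach <- L + site$dye_radius + clash_distance
  if (nrow(obs) > 0L) {
    d_attach <- sqrt(colSums((t(obs) - attach)^2))
    obs <- obs[d_attach <= reach, , drop = FALSE]
  }
  g <- seq(-L, L, by = grid_spacing)
  cand <- as.matrix(expand.grid(x = g, y = g, z = g))
  cand <- cand[rowSums(cand^2) <= L^2, , drop = FALSE]
  cand <- sweep(cand, 2L, attach, "+")
  n_samples <- nrow(cand)
  allowed <- .allowed_positions(cand, attach, obs, site, clash_distance)
  if (nrow(allowed) == 0L)
    stop("site fully occluded: no allowed dye position at ",
         site$chain, ":", site$resno)
  structure(list(positions = allowed,
                 mean_position = colMeans(allowed),
                 n_samples = n_samples, n_allowed = nrow(allowed),
                 attachment = attach, site = site),
            class = "dye_cloud")
}

#' Monte-Carlo accessible-volume sampler
#'
#' Rejection-sampling counterpart of [simulate_dye_cloud()]: candidate
#' positions are drawn uniformly in the linker ball instead of enumerated
#' on a grid, with the identical accessibility test. Used to cross-check
#' the grid enumeration (the allowed-volume fractions of the two samplers
#' agree within sampling error).
#'
#' @inheritParams simulate_dye_cloud
#' @param n_samples number of uniform draws in the linker ball.
#' @param seed integer seed.
#' @return A `dye_cloud` (with `n_samples = n_samples`).
#' @export
sample_dye_cloud_mc <- function(model, site, n_samples = 20000,
                                clash_distance = 1, seed = 1) {
  stopifnot(inherits(model, "structural_model"), inherits(site, "label_site"))
  set.seed(as.integer(seed))
  attach <- lookup_atom(model, site$chain, site$resno, site$atom)
  a <- model$atoms
  self <- a$chain == site$chain & a$resno == site$resno & a$elety == site$atom
  if (!any(self)) {
    d <- sqrt((a$x - attach[1])^2 + (a$y - attach[2])^2 + (a$z - attach[3])^2)
    self <- d < 1e-6
  }
  obs <- as.matrix(a[!self, c("x", "y", "z"), drop = FALSE])
  L <- site$linker_length
  if (nrow(obs) > 0L) {
    d_attach <- sqrt(colSums((t(obs) - attach)^2))
    obs <- obs[d_attach <= L + site$dye_radius + clash_distance, , drop = FALSE]
  }
  # uniform in the ball: uniform direction, radius ~ L * U^(1/3)
  u <- matrix(stats::rnorm(3L * n_samples), ncol = 3L)
  u <- u / sqrt(rowSums(u^2))
  r <- L * stats::runif(n_samples)^(1 / 3)
  cand <- sweep(u * r, 2L, attach, "+")
  allowed <- .allowed_positions(cand, attach, obs, site, clash_distance)
  if (nrow(allowed) == 0L)
    stop("site fully occluded: no allowed dye position at ",
         site$chain, ":", site$resno)
  structure(list(positions = allowed,
                 mean_position = colMeans(allowed),
                 n_samples = n_samples, n_allowed = nrow(allowed),
                 attachment = attach, site = site),
            class = "dye_cloud")
}

#' @export
print.dye_cloud <- function(x, ...) {
  cat("Dye cloud at", x$site$chain, ":", x$site$resno, "-",
      x$n_allowed, "of", x$n_samples, "positions allowed (",
      sprintf("%.1f%%", 100 * allowed_fraction(x)), ")\n")
  invisible(x)
}

#' Allowed-volume fraction of a dye cloud
#' @param cloud a `dye_cloud`.
#' @return `n_allowed / n_samples`.
#' @export
allowed_fraction <- function(cloud) cloud$n_allowed / cloud$n_samples

#' Inter-dye distance between two dye clouds
#'
#' `"mean-position"` returns the distance between cloud centroids.
#' `"fret-averaged"` averages the Förster efficiency over sampled
#' position pairs and returns the distance whose efficiency equals that
#' mean, which is what a FRET measurement of a flexible dye reports. For
#' single-position clouds the two modes coincide exactly.
#'
#' @param cloud_a,cloud_b `dye_cloud` objects.
#' @param mode `"mean-position"` or `"fret-averaged"`.
#' @param r0 Förster radius in nm (fret-averaged mode).
#' @param n_pairs position pairs sampled in fret-averaged mode.
#' @param seed seed for pair sampling.
#' @return Distance in nm (coordinates are Angstrom; 10 A = 1 nm).
#' @export
interdye_distance <- function(cloud_a, cloud_b,
                              mode = c("mean-position", "fret-averaged"),
                              r0 = 5.8, n_pairs = 10000, seed = 1) {
  mode <- match.arg(mode)
  for (cl in list(cloud_a, cloud_b))
    if (!inherits(cl, "dye_cloud") || cl$n_allowed == 0L)
      stop("empty dye cloud")
  if (mode == "mean-position")
    return(sqrt(sum((cloud_a$mean_position - cloud_b$mean_position)^2)) / 10)
  set.seed(as.integer(seed))
  na <- nrow(cloud_a$positions)
  nb <- nrow(cloud_b$positions)
  i <- sample.int(na, n_pairs, replace = TRUE)
  j <- sample.int(nb, n_pairs, replace = TRUE)
  r_nm <- sqrt(rowSums((cloud_a$positions[i, , drop = FALSE] -
                        cloud_b$positions[j, , drop = FALSE])^2)) / 10
  e_mean <- mean(1 / (1 + (r_nm / r0)^6))
  fret_to_distance(min(max(e_mean, 1e-12), 1 - 1e-12), r0)
}
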