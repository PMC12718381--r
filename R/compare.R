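# parse a pair label like "242:431'" -> residues + primed flag
.parse_pair_label <- function(label) {
  parts <- strsplit(label, ":", fixed = TRUE)[[1L]]
  if (length(parts) != 2L) stop("pair label must be 'resA:resB[\\']': ", label)
  primed <- grepl("'$", parts[2L])
  list(res_a = as.integer(parts[1L]),
       res_b = as.integer(sub("'$", "", parts[2L])),
       primed = primed)
}

#' Compare model-implied and smFRET-derived inter-dye distances
#'
#' For each dye pair, simulates accessible-volume dye clouds on the
#' structural model, computes the model-implied inter-dye distance, and
#' pairs it with the smFRET-derived distance (peak FRET values are
#' converted through the Förster relation). Pair labels use the dimer
#' convention: `"242:431'"` pairs residue 242 on one chain with 431 on
#' the adjacent chain (prime), while an unprimed `"242:417"` is resolved
#' as the minimum over the two same-chain pairings and the chain used is
#' reported.
#'
#' @param model a [load_model()] result with two chains (a dimer) for
#'   primed pairs.
#' @param fret_table data.frame with columns `pair` (labels as above) and
#'   either `E` (peak FRET) or `distance_nm`.
#' @param r0 Förster radius in nm.
#' @param site_params list of [label_site()] arguments applied to every
#'   residue (`atom`, `linker_length`, `linker_width`, `dye_radius`).
#' @param mode distance mode passed to [interdye_distance()].
#' @param grid_spacing,clash_distance passed to [simulate_dye_cloud()].
#' @return An object of class `distance_comparison`: `table` (data.frame
#'   `pair`, `smfret_nm`, `model_nm`, `chains`) and `summary` (list with
#'   `rmsd_nm`, `mean_signed_nm` (model minus smFRET), `pearson_r`,
#'   `n_pairs`, `skipped`). Unresolvable pairs are skipped with a
#'   warning.
#' @export
compare_distances <- function(model, fret_table, r0 = 5.8,
                              site_params = list(),
                              mode = "mean-position",
                              grid_spacing = 1, clash_distance = 1) {
  stopifnot(inherits(model, "structural_model"))
  if (!"pair" %in% names(fret_table))
    stop("'fret_table' needs a 'pair' column")
  if (!any(c("E", "distance_nm") %in% names(fret_table)))
    stop("'fret_table' needs an 'E' or 'distance_nm' column")
  chains <- model$chains
  cloud_cache <- new.env(parent = emptyenv())
  get_cloud <- function(chain, resno) {
    key <- paste0(chain, "_", resno)
    if (!is.null(cloud_cache[[key]])) return(cloud_cache[[key]])
    site <- do.call(label_site, c(list(chain = chain, resno = resno),
                                  site_params))
    cl <- simulate_dye_cloud(model, site, grid_spacing, clash_distance)
    cloud_cache[[key]] <- cl
    cl
  }
  rows <- list()
  skipped <- character(0)
  for (i in seq_len(nrow(fret_table))) {
    lab <- fret_table$pair[i]
    smfret <- if ("distance_nm" %in% names(fret_table) &&
                  is.finite(fret_table$distance_nm[i]))
      fret_table$distance_nm[i]
    else fret_to_distance(fret_table$E[i], r0)
    res <- try({
      p <- .parse_pair_label(lab)
      if (p$primed) {
        if (length(chains) < 2L)
          stop("primed pair on a single-chain model: ", lab)
        d <- interdye_distance(get_cloud(chains[1L], p$res_a),
                               get_cloud(chains[2L], p$res_b),
                               mode = mode, r0 = r0)
        used <- paste0(chains[1L], ":", chains[2L])
      } else {
        ds <- vapply(chains, function(ch)
          interdye_distance(get_cloud(ch, p$res_a), get_cloud(ch, p$res_b),
                            mode = mode, r0 = r0), numeric(1))
        d <- min(ds)
        used <- paste0(chains[which.min(ds)], ":", chains[which.min(ds)])
      }
      list(d = d, used = used)
    }, silent = TRUE)
    if (inherits(res, "try-error")) {
      warning("pair ", lab, " skipped: ",
              conditionMessage(attr(res, "condition")))
      skipped <- c(skipped, lab)
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      pair = lab, smfret_nm = smfret, model_nm = res$d, chains = res$used)
  }
  if (length(rows) == 0L) stop("no pair could be resolved on the model")
  tab <- do.call(rbind, rows)
  dev <- tab$model_nm - tab$smfret_nm
  structure(list(
    table = tab,
    summary = list(
      rmsd_nm = sqrt(mean(dev^2)),
      mean_signed_nm = mean(dev),
      pearson_r = if (nrow(tab) >= 3L)
        stats::cor(tab$smfret_nm, tab$model_nm) else NA_real_,
      n_pairs = nrow(tab), skipped = skipped)),
    class = "distance_comparison")
}

#' @export
print.distance_comparison <- function(x, digits = 3, ...) {
  cat("smFRET vs model inter-dye distances (", x$summary$n_pairs, "pairs )\n")
  print(format(x$table, digits = digits), row.names = FALSE)
  cat(sprintf("RMSD %.2f nm, mean signed deviation %+.2f nm, Pearson r %s\n",
              x$summary$rmsd_nm, x$summary$mean_signed_nm,
              ifelse(is.na(x$summary$pearson_r), "NA",
                     sprintf("%.3f", x$summary$pearson_r))))
  if (length(x$summary$skipped))
    cat("skipped:", paste(x$summary$skipped, collapse = ", "), "\n")
  invisible(x)
}
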