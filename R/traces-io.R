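#' Write traces to a tidy CSV store
#'
#' Traces are stored long-form with columns `molecule_id`, `frame`
#' (0-based), `donor`, `acceptor`; time is `frame * frame_interval`.
#' Simulation truth (gamma, bleach frames, state path, state FRET) is
#' written to an optional sidecar CSV so round-trips are lossless.
#'
#' @param traces a list of `fret_trace` objects (e.g. from
#'   [simulate_ensemble()]).
#' @param path output CSV path.
#' @param truth_path optional sidecar CSV path for truth metadata;
#'   `NULL` (default) writes `<path>.truth.csv` when any trace carries
#'   truth, and nothing otherwise.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path, truth_path = NULL) {
  if (length(traces) == 0L) {
    utils::write.csv(
      data.frame(molecule_id = character(), frame = integer(),
                 donor = numeric(), acceptor = numeric()),
      path, row.names = FALSE)
    return(invisible(path))
  }
  rows <- do.call(rbind, lapply(traces, function(tr) {
    data.frame(molecule_id = tr$molecule_id,
               frame = seq_along(tr$donor) - 1L,
               donor = tr$donor, acceptor = tr$acceptor,
               frame_interval = tr$frame_interval)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  has_truth <- vapply(traces, function(tr) !is.null(tr$truth), logical(1))
  if (any(has_truth)) {
    if (is.null(truth_path)) truth_path <- paste0(path, ".truth.csv")
    tru <- do.call(rbind, lapply(traces[has_truth], function(tr) {
      data.frame(molecule_id = tr$molecule_id,
                 gamma = tr$truth$gamma,
                 acceptor_bleach_frame = tr$truth$acceptor_bleach_frame,
                 donor_bleach_frame = tr$truth$donor_bleach_frame,
                 path = paste(tr$truth$path, collapse = ";"),
                 state_fret = paste(tr$truth$state_fret, collapse = ";"))
    }))
    utils::write.csv(tru, truth_path, row.names = FALSE)
  }
  invisible(path)
}

#' Read traces from a CSV store
#'
#' @param path CSV written by [write_traces()] (columns `molecule_id`,
#'   `frame`, `donor`, `acceptor`, optionally `frame_interval`).
#' @param truth_path optional truth sidecar; `NULL` looks for
#'   `<path>.truth.csv` and reads it if present.
#' @param frame_interval fallback seconds/frame when the file has no
#'   `frame_interval` column.
#' @return A list of `fret_trace` objects (class `fret_ensemble`); empty
#'   input reads back as an empty list.
#' @export
read_traces <- function(path, truth_path = NULL, frame_interval = 0.1) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("molecule_id", "frame", "donor", "acceptor")
  if (!all(need %in% names(df)))
    stop("trace store must have columns ", paste(need, collapse = ", "))
  if (nrow(df) == 0L) return(structure(list(), class = c("fret_ensemble", "list")))
  if (anyNA(df$donor) || anyNA(df$acceptor)) {
    bad <- df$molecule_id[which(is.na(df$donor) | is.na(df$acceptor))[1L]]
    stop("malformed intensity values for molecule '", bad, "'")
  }
  truth <- NULL
  if (is.null(truth_path)) {
    cand <- paste0(path, ".truth.csv")
    if (file.exists(cand)) truth_path <- cand
  }
  if (!is.null(truth_path) && file.exists(truth_path))
    truth <- utils::read.csv(truth_path, stringsAsFactors = FALSE)

  ids <- unique(df$molecule_id)
  traces <- lapply(ids, function(id) {
    sub <- df[df$molecule_id == id, , drop = FALSE]
    sub <- sub[order(sub$frame), , drop = FALSE]
    if (!identical(as.integer(sub$frame), seq_len(nrow(sub)) - 1L))
      stop("unequal-length or gapped channels for molecule '", id, "'")
    fi <- if ("frame_interval" %in% names(sub)) sub$frame_interval[1L]
          else frame_interval
    tr <- list(molecule_id = id, frame_interval = fi,
               donor = sub$donor, acceptor = sub$acceptor, truth = NULL)
    if (!is.null(truth) && id %in% truth$molecule_id) {
      t1 <- truth[truth$molecule_id == id, , drop = FALSE][1L, ]
      tr$truth <- list(
        path = as.integer(strsplit(t1$path, ";", fixed = TRUE)[[1L]]),
        acceptor_bleach_frame = t1$acceptor_bleach_frame,
        donor_bleach_frame = t1$donor_bleach_frame,
        gamma = t1$gamma,
        state_fret = as.numeric(strsplit(t1$state_fret, ";", fixed = TRUE)[[1L]]))
    }
    structure(tr, class = "fret_trace")
  })
  structure(traces, class = c("fret_ensemble", "list"))
}
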