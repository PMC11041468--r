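#' Extract alarm episodes from a categorical status stream
#'
#' Maximal runs of asserted status codes become half-open episodes. Codes in
#' the artifact set (e.g. `5` for sensor-off) are never treated as
#' assertions; codes outside the known vocabulary trigger a warning.
#'
#' @param stream a categorical [vs_stream()] of alarm-status codes.
#' @param asserted codes (coerced to character) that count as an asserted
#'   alarm.
#' @param known full vocabulary of expected codes.
#' @return data.frame of episodes (`start`, `end`, `kind`, `source`).
#' @examples
#' s <- vs_stream(c(0, 1, 1, 0, 1), "SpO2Alarm", sampling_rate = 1)
#' episodes_from_status(s, asserted = 1)
#' @export
episodes_from_status <- function(stream, asserted = 1,
                                 known = c(0, 1, 5)) {
  asserted <- as.character(asserted)
  known <- unique(c(as.character(known), asserted))
  unknown <- setdiff(unique(stream$value), known)
  if (length(unknown)) {
    warning("unknown alarm-status code(s): ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  mask <- stream$value %in% asserted
  mask_to_episodes(mask, stream$timestamp, stream$sampling_rate,
                   source = stream$data_type)
}

#' Match alarm episodes against ground-truth events
#'
#' An episode matches a true event when their intervals overlap after the
#' event is widened by `tolerance` seconds on both sides. A true event
#' counts as detected (TP) when at least one episode matches it, and each
#' event is counted at most once; undetected events are FN; episodes
#' matching no event are FP. Intervals are half-open.
#'
#' @param episodes data.frame with `start`, `end` (seconds).
#' @param truth data.frame of non-overlapping true-event intervals with
#'   `start`, `end`.
#' @param tolerance matching slack in seconds (default 10).
#' @return List of class `eval_counts` with `tp`, `fp`, `fn`.
#' @examples
#' eps <- data.frame(start = c(150, 300), end = c(170, 310))
#' tru <- data.frame(start = 100, end = 160)
#' categorize(eps, tru, tolerance = 10)
#' @export
categorize <- function(episodes, truth, tolerance = 10) {
  stopifnot(tolerance >= 0)
  nt <- nrow(truth)
  if (nt > 1) {
    o <- order(truth$start)
    if (any(truth$start[o][-1] < truth$end[o][-nt])) {
      stop("ground-truth events must be mutually disjoint", call. = FALSE)
    }
  }
  ne <- if (is.null(episodes)) 0L else nrow(episodes)
  hit_truth <- logical(nt)
  hit_ep <- logical(ne)
  if (ne > 0 && nt > 0) {
    for (i in seq_len(ne)) {
      ov <- episodes$start[i] < truth$end + tolerance &
            episodes$end[i] > truth$start - tolerance
      if (any(ov)) {
        hit_ep[i] <- TRUE
        hit_truth <- hit_truth | ov
      }
    }
  }
  structure(list(tp = sum(hit_truth), fp = sum(!hit_ep),
                 fn = sum(!hit_truth)),
            class = "eval_counts")
}

#' @export
print.eval_counts <- function(x, ...) {
  cat(sprintf("<eval_counts> TP %d  FP %d  FN %d\n", x$tp, x$fp, x$fn))
  invisible(x)
}

# internal: pool several eval_counts
pool_counts <- function(counts) {
  structure(list(tp = sum(vapply(counts, `[[`, 0, "tp")),
                 fp = sum(vapply(counts, `[[`, 0, "fp")),
                 fn = sum(vapply(counts, `[[`, 0, "fn"))),
            class = "eval_counts")
}

#' Sensitivity and false alarm rate
#'
#' `sensitivity` is the percentage of true events detected,
#' `100 * TP / (TP + FN)`. `far` is the percentage of issued alarm episodes
#' that are false, `100 * FP / (TP + FP)`.
#'
#' @param counts an `eval_counts` from [categorize()].
#' @return Percentage in `[0, 100]`.
#' @export
sensitivity <- function(counts) {
  if (counts$tp + counts$fn == 0) {
    stop("sensitivity undefined: no true events", call. = FALSE)
  }
  100 * counts$tp / (counts$tp + counts$fn)
}

#' @rdname sensitivity
#' @export
far <- function(counts) {
  if (counts$tp + counts$fp == 0) {
    stop("false alarm rate undefined: no alarm episodes", call. = FALSE)
  }
  100 * counts$fp / (counts$tp + counts$fp)
}

#' Percent change of a metric relative to the monitor's reference value
#'
#' Reported as `100 * (metric - reference) / reference`, truncated toward
#' zero at one decimal place (so -5.88 reports as -5.8 and 8.69 as 8.6).
#' Negative values indicate a reduction relative to the bedside monitor.
#'
#' @param metric the pipeline's metric (%).
#' @param oem_metric the monitor's reference metric (%); must be positive.
#' @return Signed percent change, one truncated decimal.
#' @examples
#' percent_change(80, 85)  # -5.8
#' percent_change(50, 46)  #  8.6
#' @export
percent_change <- function(metric, oem_metric) {
  if (oem_metric <= 0) stop("reference metric must be positive", call. = FALSE)
  x <- 100 * (metric - oem_metric) / oem_metric
  trunc(round(x * 10, 6)) / 10
}

# internal: grid of tunables for a preset
default_grid <- function(cdss) {
  g <- list(ced_dt = c(5, 10, 12, 15, 20, 30, 60))
  if (cdss %in% c(2, 4)) g$med_ww <- c(5, 10, 20, 25, 30, 35, 60)
  if (cdss %in% c(3, 4)) g$sq_thresh <- c(6, 12, 18)
  expand.grid(g)
}

#' Leave-one-out cross-validated tuning of a preset pipeline
#'
#' For each fold, one patient is held out; on the remaining patients every
#' grid point is evaluated with pooled counts, and the point minimizing
#' training FAR subject to training sensitivity at or above `sn_floor` is
#' selected (ties broken toward smaller `ced_dt`, then smaller `med_ww`,
#' then smaller `sq_thresh`). The selected pipeline is then scored on the
#' held-out patient, and fold metrics are averaged without weighting. When
#' no grid point reaches the sensitivity floor on a fold's training set, the
#' best-sensitivity point is used and the fold is flagged.
#'
#' @param cohort list of patients, each a list with `streams` (named 1 Hz
#'   [vs_stream()] list) and `truth` (data.frame of true desaturation
#'   intervals), as produced by [simulate_cohort()] + [acquire()] or
#'   [prepare_cohort()].
#' @param cdss preset number, 1-4.
#' @param grid data.frame of tunable combinations; defaults to the study
#'   grids (`ced_dt` in `{5,10,12,15,20,30,60}`, `med_ww` in
#'   `{5,10,20,25,30,35,60}` where applicable, `sq_thresh` in `{6,12,18}`
#'   where applicable).
#' @param sn_floor training sensitivity constraint (%), typically 75 or 80.
#' @param tolerance episode/event matching slack in seconds.
#' @param ced named list of [ced_config()] overrides applied at every grid
#'   point.
#' @return List of class `cdss_loocv`: `folds` (per-fold data.frame with the
#'   selected tunables and held-out metrics), `mean_sn`, `mean_far`,
#'   `pooled` counts over held-out patients.
#' @export
loocv <- function(cohort, cdss, grid = default_grid(cdss), sn_floor = 80,
                  tolerance = 10, ced = list()) {
  np <- length(cohort)
  stopifnot(np >= 2, nrow(grid) >= 1)
  # score every (patient, grid point) once; folds reuse the counts
  counts <- vector("list", np)
  for (p in seq_len(np)) {
    counts[[p]] <- vector("list", nrow(grid))
    for (g in seq_len(nrow(grid))) {
      args <- c(list(cdss = cdss, ced = ced), as.list(grid[g, , drop = FALSE]))
      run <- run_graph(do.call(preset, args), cohort[[p]]$streams)
      counts[[p]][[g]] <- categorize(run$episodes, cohort[[p]]$truth,
                                     tolerance)
    }
  }
  tie_cols <- intersect(c("ced_dt", "med_ww", "sq_thresh"), names(grid))
  folds <- NULL
  held_counts <- list()
  for (p in seq_len(np)) {
    train <- setdiff(seq_len(np), p)
    sn_tr <- far_tr <- numeric(nrow(grid))
    for (g in seq_len(nrow(grid))) {
      pc <- pool_counts(lapply(train, function(q) counts[[q]][[g]]))
      sn_tr[g] <- if (pc$tp + pc$fn > 0) sensitivity(pc) else 0
      far_tr[g] <- if (pc$tp + pc$fp > 0) far(pc) else Inf
    }
    feasible <- which(sn_tr >= sn_floor)
    fallback <- length(feasible) == 0
    cand <- if (fallback) which(sn_tr == max(sn_tr)) else feasible
    ord <- do.call(order, c(list(far_tr[cand]),
                            lapply(tie_cols, function(cl) grid[cand, cl])))
    sel <- cand[ord[1]]
    hc <- counts[[p]][[sel]]
    held_counts[[p]] <- hc
    fold <- data.frame(patient = p, grid[sel, , drop = FALSE],
                       train_sn = sn_tr[sel], train_far = far_tr[sel],
                       sn = if (hc$tp + hc$fn > 0) sensitivity(hc) else NA_real_,
                       far = if (hc$tp + hc$fp > 0) far(hc) else NA_real_,
                       fallback = fallback, row.names = NULL)
    folds <- rbind(folds, fold)
  }
  structure(list(folds = folds,
                 mean_sn = mean(folds$sn, na.rm = TRUE),
                 mean_far = mean(folds$far, na.rm = TRUE),
                 pooled = pool_counts(held_counts),
                 cdss = cdss, sn_floor = sn_floor),
            class = "cdss_loocv")
}

#' @export
print.cdss_loocv <- function(x, ...) {
  cat(sprintf("<cdss_loocv> preset #%d, Sn floor %g%%: mean Sn %.1f%%, mean FAR %.1f%%\n",
              x$cdss, x$sn_floor, x$mean_sn, x$mean_far))
  print(x$folds, row.names = FALSE)
  invisible(x)
}
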