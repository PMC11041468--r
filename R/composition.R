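#' Build a pipeline composition graph
#'
#' A composition wires acquisition outputs through artifact-detection
#' operators into the alarm generator. Nodes are component instances; each
#' declares named input channels (`"<producer>.<data_type>"`, with the
#' pseudo-producer `"pda"` for acquisition outputs), the channels it
#' provides, the SQ type it requires on its inputs and declares on its
#' outputs, and its parameters. Edges are implied by channel references.
#'
#' @param nodes named list of node descriptions (see [preset()] for the
#'   four study formulations, which are the intended entry point).
#' @param tunables named list of tunable parameters recorded on the graph.
#' @return A list of class `cdss_graph`.
#' @export
cdss_graph <- function(nodes, tunables = list()) {
  structure(list(nodes = nodes, tunables = tunables), class = "cdss_graph")
}

#' @export
print.cdss_graph <- function(x, ...) {
  cat(sprintf("<cdss_graph> %d node(s)\n", length(x$nodes)))
  for (nm in names(x$nodes)) {
    nd <- x$nodes[[nm]]
    cat(sprintf("  %-10s %-8s in: %-40s out: %s\n", nm, nd$type,
                paste(unlist(nd$inputs), collapse = ", "),
                paste(nd$outputs, collapse = ", ")))
  }
  if (length(x$tunables)) {
    cat("  tunables:",
        paste(names(x$tunables), unlist(x$tunables), sep = "=", collapse = " "),
        "\n")
  }
  invisible(x)
}

# internal: make a node description
graph_node <- function(type, inputs, outputs, params = list(),
                       sq_in = NULL, sq_out = NULL) {
  list(type = type, inputs = inputs, outputs = outputs, params = params,
       sq_in = sq_in, sq_out = sq_out)
}

#' Check interface compatibility of a composition graph
#'
#' Static checks before execution: every required input channel is provided
#' by exactly one node (or by acquisition), the graph is acyclic, and the SQ
#' type declared on each provision matches what the consuming node requires.
#' Violations are returned, not raised.
#'
#' @param graph a [cdss_graph()].
#' @return character vector of violations; empty when the graph is runnable.
#' @export
check_compatibility <- function(graph) {
  out <- character(0)
  nodes <- graph$nodes
  producers <- list()   # channel -> node name
  sq_of <- list()       # channel -> declared sq_type
  for (nm in names(nodes)) {
    for (ch in nodes[[nm]]$outputs) {
      if (!is.null(producers[[ch]])) {
        out <- c(out, sprintf("channel '%s' provided by both '%s' and '%s'",
                              ch, producers[[ch]], nm))
      }
      producers[[ch]] <- nm
      sq_of[[ch]] <- nodes[[nm]]$sq_out
    }
  }
  for (nm in names(nodes)) {
    nd <- nodes[[nm]]
    for (ch in unlist(nd$inputs)) {
      src <- sub("\\..*$", "", ch)
      if (src != "pda" && is.null(producers[[ch]])) {
        out <- c(out, sprintf("node '%s' requires unprovided channel '%s'",
                              nm, ch))
      }
      want <- nd$sq_in
      have <- if (src == "pda") "binary" else sq_of[[ch]]
      if (!is.null(want) && !is.null(have) && !have %in% want) {
        out <- c(out, sprintf(
          "node '%s' requires sq_type %s on '%s' but it provides '%s'",
          nm, paste0("{", paste(want, collapse = ","), "}"), ch, have))
      }
    }
  }
  # cycle check: Kahn's algorithm over node dependencies
  deps <- lapply(nodes, function(nd) {
    src <- unique(sub("\\..*$", "", unlist(nd$inputs)))
    intersect(src, names(nodes))
  })
  done <- character(0)
  remaining <- names(nodes)
  repeat {
    ready <- remaining[vapply(remaining, function(nm)
      all(deps[[nm]] %in% done), logical(1))]
    if (!length(ready)) break
    done <- c(done, ready)
    remaining <- setdiff(remaining, ready)
  }
  if (length(remaining)) {
    out <- c(out, sprintf("cyclic wiring among node(s): %s",
                          paste(remaining, collapse = ", ")))
  }
  out
}

# internal: standard de-interlacer node
dil_node <- function(data_type, art_syms = c("NaN", "^^", "5")) {
  graph_node("dil",
             inputs = list(x = paste0("pda.", data_type)),
             outputs = paste0("%ID%.", data_type),
             params = list(art_syms = art_syms, sqi_match = 0),
             sq_in = c("binary", "rank"), sq_out = "binary")
}

#' Preset pipeline compositions
#'
#' The four study formulations, in increasing order of artifact-detection
#' sophistication:
#' \describe{
#'   \item{#1}{de-interlace the SpO2 and SpO2-alarm streams, min-fuse their
#'     SQ streams onto SpO2, alarm with the CED.}
#'   \item{#2}{#1 plus a quality-masked median filter on SpO2 (window
#'     `med_ww`) before the CED.}
#'   \item{#3}{de-interlace HR, PR, SpO2 and SpO2-alarm; min-fuse
#'     SpO2/alarm quality onto SpO2; derive a binary SQ stream from the
#'     |HR-PR| disagreement (single threshold `sq_thresh`, attached to PR
#'     since PR and SpO2 share the optical sensor); min-fuse it with the
#'     SpO2 quality; alarm with the CED.}
#'   \item{#4}{#3 plus the median filter before the CED.}
#' }
#'
#' @param cdss preset number, 1-4.
#' @param ced_dt alarm annunciation delay in seconds.
#' @param med_ww median filter window (presets 2 and 4 only).
#' @param sq_thresh HR-PR disagreement threshold in bpm (presets 3 and 4
#'   only; the study grid is `{6, 12, 18}`).
#' @param ced named list of further [ced_config()] overrides (e.g.
#'   `list(floor = 65)`).
#' @return A [cdss_graph()].
#' @examples
#' preset(2, ced_dt = 10, med_ww = 10)
#' @export
preset <- function(cdss, ced_dt = 10, med_ww = NULL, sq_thresh = NULL,
                   ced = list()) {
  stopifnot(cdss %in% 1:4)
  if (!is.null(med_ww) && !cdss %in% c(2, 4)) {
    stop("med_ww is only tunable in presets #2 and #4", call. = FALSE)
  }
  if (!is.null(sq_thresh) && !cdss %in% c(3, 4)) {
    stop("sq_thresh is only tunable in presets #3 and #4", call. = FALSE)
  }
  if (cdss %in% c(2, 4) && is.null(med_ww)) med_ww <- 10
  if (cdss %in% c(3, 4) && is.null(sq_thresh)) sq_thresh <- 18
  nodes <- list(
    dil_spo2  = dil_node("SpO2"),
    dil_alarm = dil_node("SpO2Alarm")
  )
  nodes$fuse1 <- graph_node(
    "fuse",
    inputs = list(a = "dil_alarm.SpO2Alarm", b = "dil_spo2.SpO2"),
    outputs = "fuse1.SpO2",
    params = list(operator = "min", forward = "SpO2"),
    sq_in = "binary", sq_out = "binary")
  spo2_ch <- "fuse1.SpO2"
  if (cdss %in% c(3, 4)) {
    nodes$dil_hr <- dil_node("HR")
    nodes$dil_pr <- dil_node("PR")
    nodes$diff <- graph_node(
      "diff",
      inputs = list(a = "dil_hr.HR", b = "dil_pr.PR"),
      outputs = "diff.PR",
      params = list(thresholds = sq_thresh, sq_values = 1, sqi_default = 0),
      sq_in = "binary", sq_out = "binary")
    nodes$fuse2 <- graph_node(
      "fuse",
      inputs = list(a = "fuse1.SpO2", b = "diff.PR"),
      outputs = "fuse2.SpO2",
      params = list(operator = "min", forward = "SpO2"),
      sq_in = "binary", sq_out = "binary")
    spo2_ch <- "fuse2.SpO2"
  }
  if (cdss %in% c(2, 4)) {
    nodes$medfilt <- graph_node(
      "medfilt",
      inputs = list(x = spo2_ch),
      outputs = "medfilt.SpO2Med",
      params = list(med_ww = med_ww),
      sq_in = c("binary", "rank"), sq_out = "binary")
    spo2_ch <- "medfilt.SpO2Med"
  }
  nodes$ced <- graph_node(
    "ced",
    inputs = list(spo2 = spo2_ch),
    outputs = character(0),
    params = c(list(ced_dt = ced_dt), ced),
    sq_in = c("binary", "rank"), sq_out = NULL)
  # stamp node ids into the dil output channel names
  for (nm in names(nodes)) {
    nodes[[nm]]$outputs <- sub("%ID%", nm, nodes[[nm]]$outputs, fixed = TRUE)
  }
  tun <- list(cdss = cdss, ced_dt = ced_dt)
  if (!is.null(med_ww)) tun$med_ww <- med_ww
  if (!is.null(sq_thresh)) tun$sq_thresh <- sq_thresh
  cdss_graph(nodes, tun)
}

#' Execute a composition graph on a patient's streams
#'
#' Runs the graph in topological order, materializing every provision
#' channel so intermediate streams can be inspected. Execution is a pure
#' function of the graph and the inputs; every operator is causal, so the
#' same graph supports sample-at-a-time streaming.
#'
#' @param graph a [cdss_graph()] passing [check_compatibility()].
#' @param streams named list of 1 Hz [vs_stream()] keyed by data type, as
#'   returned by [acquire()] (each must carry an SQ annotation).
#' @return List of class `cdss_run`: `episodes` (data.frame), `mask`,
#'   `channels` (named list of every materialized stream), `tunables`.
#' @export
run_graph <- function(graph, streams) {
  viol <- check_compatibility(graph)
  if (length(viol)) {
    stop("graph fails compatibility check: ", paste(viol, collapse = "; "),
         call. = FALSE)
  }
  chans <- list()
  for (dt in names(streams)) chans[[paste0("pda.", dt)]] <- streams[[dt]]
  fetch <- function(ch, node) {
    if (is.null(chans[[ch]])) {
      stop("node '", node, "': required input stream '", ch, "' is missing",
           call. = FALSE)
    }
    chans[[ch]]
  }
  # topological order (check_compatibility guarantees one exists)
  nodes <- graph$nodes
  done <- character(0)
  order <- character(0)
  while (length(order) < length(nodes)) {
    for (nm in setdiff(names(nodes), order)) {
      src <- unique(sub("\\..*$", "", unlist(nodes[[nm]]$inputs)))
      if (all(setdiff(src, "pda") %in% order)) order <- c(order, nm)
    }
  }
  result <- NULL
  for (nm in order) {
    nd <- nodes[[nm]]
    p <- nd$params
    if (nd$type == "dil") {
      s <- ad_dil(fetch(nd$inputs$x, nm), p$art_syms, p$sqi_match)
      chans[[nd$outputs]] <- s
    } else if (nd$type == "fuse") {
      ins <- lapply(unlist(nd$inputs), fetch, node = nm)
      s <- ad_fuse_sqi(ins, operator = p$operator, forward = p$forward)
      if (inherits(s, "vs_stream")) s <- stats::setNames(list(s), s$data_type)
      for (k in seq_along(s)) {
        chans[[nd$outputs[k]]] <- s[[k]]
      }
    } else if (nd$type == "diff") {
      s <- ad_diff(fetch(nd$inputs$a, nm), fetch(nd$inputs$b, nm),
                   thresholds = p$thresholds, sq_values = p$sq_values,
                   sqi_default = p$sqi_default)
      chans[[nd$outputs]] <- s
    } else if (nd$type == "medfilt") {
      chans[[nd$outputs]] <- ad_medfilt(fetch(nd$inputs$x, nm), p$med_ww)
    } else if (nd$type == "ced") {
      cfg <- do.call(ced_config, p[setdiff(names(p), character(0))])
      result <- generate_alarms(fetch(nd$inputs$spo2, nm), cfg)
    } else {
      stop("unknown node type: ", nd$type, call. = FALSE)
    }
  }
  structure(list(episodes = if (is.null(result)) NULL else result$episodes,
                 mask = if (is.null(result)) NULL else result$mask,
                 channels = chans, tunables = graph$tunables),
            class = "cdss_run")
}

#' @export
print.cdss_run <- function(x, ...) {
  cat(sprintf("<cdss_run> %d episode(s), %d channel(s) materialized\n",
              if (is.null(x$episodes)) 0L else nrow(x$episodes),
              length(x$channels)))
  if (!is.null(x$episodes) && nrow(x$episodes)) {
    print(x$episodes, row.names = FALSE)
  }
  invisible(x)
}
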