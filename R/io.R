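#' Write / read spike-train event lists as CSV
#'
#' Event lists have columns \code{source_id} (1-based integer) and
#' \code{t_ms}.
#'
#' @param events data.frame with \code{source_id}, \code{t_ms}.
#' @param path file path.
#' @export
write_spike_trains <- function(events, path) {
  stopifnot(all(c("source_id", "t_ms") %in% names(events)))
  utils::write.csv(events[, c("source_id", "t_ms")], path, row.names = FALSE)
}

#' @rdname write_spike_trains
#' @return \code{read_spike_trains} returns the event data.frame.
#' @export
read_spike_trains <- function(path) {
  ev <- utils::read.csv(path)
  stopifnot(all(c("source_id", "t_ms") %in% names(ev)))
  ev
}

#' Write a per-step adaptation log
#'
#' CSV with columns \code{t_ms, neuron_id, R_ohm, tau_m_ms, y_khz}, one row
#' per recorded step, suitable for plotting parameter-learning trajectories.
#'
#' @param run an \code{"ip_run"} with recorded trajectories.
#' @param path file path.
#' @param neuron_id id to record in the log.
#' @export
write_adaptation_log <- function(run, path, neuron_id = 1L) {
  stopifnot(inherits(run, "ip_run"), !is.null(run$traj_R))
  utils::write.csv(data.frame(t_ms = seq_along(run$traj_R),
                              neuron_id = neuron_id,
                              R_ohm = run$traj_R,
                              tau_m_ms = run$traj_tau,
                              y_khz = run$rates),
                   path, row.names = FALSE)
}

#' Write recorded rate traces of a network simulation
#'
#' CSV with columns \code{t_ms, neuron_id, y_khz} (long format).
#'
#' @param sim a \code{"network_sim"} object.
#' @param path file path.
#' @param neurons neuron ids to include (default all).
#' @export
write_trace <- function(sim, path, neurons = seq_len(nrow(sim$rates))) {
  stopifnot(inherits(sim, "network_sim"))
  long <- do.call(rbind, lapply(neurons, function(i)
    data.frame(t_ms = seq_len(sim$n_steps) * sim$cfg$dt,
               neuron_id = i, y_khz = sim$rates[i, ])))
  utils::write.csv(long, path, row.names = FALSE)
}

#' Serialize a network as an edge list plus JSON header
#'
#' Writes \code{<prefix>_edges.csv} (columns \code{pre_id, post_id, weight,
#' type}; input lines appear as negative \code{pre_id}) and
#' \code{<prefix>_header.json} (builder, seed, sizes, spec when present).
#'
#' @param net a \code{"spiking_network"}.
#' @param prefix path prefix for the two files.
#' @return Invisibly, the two file paths.
#' @export
write_network <- function(net, prefix) {
  stopifnot(inherits(net, "spiking_network"))
  rec <- which(net$W != 0, arr.ind = TRUE)
  type <- if (is.null(net$type)) {
    rep(NA_character_, nrow(rec))
  } else {
    paste0(net$type[rec[, 1]], net$type[rec[, 2]])
  }
  edges <- data.frame(pre_id = rec[, 1], post_id = rec[, 2],
                      weight = net$W[rec], type = type)
  if (net$n_inputs > 0) {
    ein <- which(net$Win != 0, arr.ind = TRUE)
    if (nrow(ein)) {
      edges <- rbind(edges,
                     data.frame(pre_id = -ein[, 1], post_id = ein[, 2],
                                weight = net$Win[ein],
                                type = rep("input", nrow(ein))))
    }
  }
  ecsv <- paste0(prefix, "_edges.csv")
  hjson <- paste0(prefix, "_header.json")
  utils::write.csv(edges, ecsv, row.names = FALSE)
  hdr <- list(builder = net$builder, n = net$n, n_inputs = net$n_inputs,
              seed = net$seed,
              params = unclass(net$params))
  if (!is.null(net$extra$spec)) hdr$spec <- unclass(net$extra$spec)
  jsonlite::write_json(hdr, hjson, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(ecsv, hjson))
}
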