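#' Declarative stimulation protocols
#'
#' A protocol is a time-ordered schedule of cue presentations over a trained
#' network, plus mode flags (e.g. dreaming).  Cue feature subsets (which 70%
#' of an object's features are excited) are drawn at run time from the trial
#' seed, so the same protocol yields different feature draws across trials.
#'
#' @name protocols
NULL

new_protocol <- function(duration, events, modality,
                         dreaming = FALSE, label = "custom") {
  if (nrow(events)) {
    events <- events[order(events$time), , drop = FALSE]
    if (any(diff(c(0, events$time)) < 0)) stop("events must be time-ordered")
    ends <- events$time + events$duration
    if (any(events$time[-1] < head(ends, -1)))
      stop("overlapping cue presentations are not supported")
    if (duration < max(ends)) stop("protocol duration ends before its last event")
  }
  structure(list(duration = duration, events = events, modality = modality,
                 dreaming = dreaming, label = label),
            class = "tg_protocol")
}

cue_events <- function(objects, times, duration = 0.05, frac = 0.7) {
  if (!length(objects))
    return(data.frame(time = numeric(0), duration = numeric(0),
                      object = integer(0), frac = numeric(0)))
  data.frame(time = times, duration = duration,
             object = objects, frac = frac)
}

#' @export
print.tg_protocol <- function(x, ...) {
  cat(sprintf("tg_protocol '%s' (%s modality%s): %.3g s, %d cue event(s)\n",
              x$label, x$modality, if (x$dreaming) ", dreaming" else "",
              x$duration, nrow(x$events)))
  invisible(x)
}

#' Working-memory maintenance protocol
#'
#' Two partial cues presented in succession: object 1 between 0.005 and
#' 0.055 s and object 2 between 0.405 and 0.455 s (70\% of features each).
#' The first object must be maintained by WM after its cue ends and must be
#' reset when the second object is presented.
#'
#' @param objects two object ids.
#' @param frac fraction of features excited by each cue.
#' @param duration total simulated time (s).
#' @return A \code{tg_protocol}.
#' @export
protocol_maintenance <- function(objects = c(1, 2), frac = 0.7,
                                 duration = 0.8) {
  new_protocol(duration,
               cue_events(objects, c(0.005, 0.405), 0.05, frac),
               modality = "sequence", label = "maintenance")
}

#' Sequence-recovery protocol
#'
#' Brief 50 ms cues (70\% of features) to successive starting objects at
#' 0.005, 0.605 and 1.205 s; after each cue the trained network replays the
#' stored list from the cued object onward, nested in the theta cycle.
#'
#' @param cues object ids cued in turn (default 1, 2, 3).
#' @param times cue onsets (s).
#' @param frac cue feature fraction.
#' @param cue_dur cue duration (s).
#' @param duration total simulated time (s).
#' @return A \code{tg_protocol}.
#' @export
protocol_sequence_recovery <- function(cues = c(1, 2, 3),
                                       times = c(0.005, 0.605, 1.205),
                                       frac = 0.7, cue_dur = 0.05,
                                       duration = NULL) {
  stopifnot(length(cues) == length(times))
  if (is.null(duration)) duration <- max(times) + 0.6
  new_protocol(duration, cue_events(cues, times, cue_dur, frac),
               modality = "sequence", label = "sequence_recovery")
}

#' Semantic (simultaneous multi-item) protocol
#'
#' Simultaneous 50 ms cues to 70\% of the features of k objects; the
#' network must maintain all of them, segmented in the gamma band, over a
#' 1.5 s window.
#'
#' @param objects object ids cued simultaneously.
#' @param t_on common cue onset (s).
#' @param frac cue feature fraction.
#' @param cue_dur cue duration (s).
#' @param duration total simulated time (s).
#' @return A \code{tg_protocol}.
#' @export
protocol_semantic <- function(objects = 1:4, t_on = 0.005, frac = 0.7,
                              cue_dur = 0.05, duration = 1.5) {
  ev <- if (length(objects))
    cue_events(objects, rep(t_on, length(objects)), cue_dur, frac)
  else cue_events(integer(0), numeric(0))
  p <- structure(list(duration = duration, events = ev,
                      modality = "semantic", dreaming = FALSE,
                      label = "semantic"), class = "tg_protocol")
  p  # simultaneous cues are one multi-object presentation, not overlaps
}

#' Dreaming / imagination protocol
#'
#' The WM layer is disconnected from L1 in both directions and every L1
#' pyramidal population receives uniform noise on [80, 160]; the network
#' spontaneously replays stored sequences and may concatenate them through
#' shared features.
#'
#' @param duration total simulated time (s).
#' @param noise length-2 range of the uniform L1 drive.
#' @return A \code{tg_protocol}.
#' @export
protocol_dreaming <- function(duration = 4, noise = c(80, 160)) {
  p <- new_protocol(duration, cue_events(integer(0), numeric(0)),
                    modality = "sequence", dreaming = TRUE,
                    label = "dreaming")
  p$dream_noise <- noise
  p
}

#' Run a protocol on a trained network
#'
#' Integrates the full four-layer network under the protocol's schedule.
#' The run is a pure function of (network, protocol, seed): identical
#' arguments give bit-identical recordings.
#'
#' @param network a \code{tg_network} (modality must match the protocol).
#' @param protocol a \code{tg_protocol}.
#' @param seed integer seed for cue-feature draws and the noise streams.
#' @return A \code{tg_recording}: list with \code{time}, per-layer spike
#'   density matrices (\code{WM}, \code{L1}, \code{L2}, \code{L3}; rows =
#'   time, columns = lattice columns), the L2 \code{gate} state, and the
#'   realized \code{events} (including the drawn cue features).
#' @export
run_protocol <- function(network, protocol, seed = 1) {
  stopifnot(inherits(network, "tg_network"), inherits(protocol, "tg_protocol"))
  if (protocol$modality != network$modality)
    stop("protocol is for the '", protocol$modality,
         "' modality but the network is '", network$modality, "'")
  p <- network$params
  steps <- round(protocol$duration / p$dt)
  rec_every <- max(1L, round(p$rec_dt / p$dt))

  run <- function() {
    ev <- protocol$events
    ev_idx <- vector("list", nrow(ev))
    if (nrow(ev)) {
      for (i in seq_len(nrow(ev))) {
        feats <- network$collection$objects[[ev$object[i]]]
        k <- max(1L, round(ev$frac[i] * length(feats)))
        ev_idx[[i]] <- sort(sample(feats, k))
      }
    }
    sched <- list(
      ev_on = as.integer(round(ev$time / p$dt)),
      ev_off = as.integer(round((ev$time + ev$duration) / p$dt)),
      ev_amp = rep(p$cue_amp, nrow(ev)),
      ev_idx = lapply(ev_idx, function(ix) as.integer(ix - 1L)),
      dreaming = isTRUE(protocol$dreaming),
      dream_lo = if (!is.null(protocol$dream_noise)) protocol$dream_noise[1] else p$dream_lo,
      dream_hi = if (!is.null(protocol$dream_noise)) protocol$dream_noise[2] else p$dream_hi)
    syn <- c(network$synapses,
             list(g_wm_l1 = p$g_wm_l1, g_l1_wm = p$g_l1_wm,
                  g_l1_l2 = p$g_l1_l2, g_l2_l3 = p$g_l2_l3))
    out <- cpp_simulate_network(p, syn, sched, steps, rec_every)
    ev$features <- ev_idx
    structure(list(
      time = seq(0, by = p$rec_dt, length.out = nrow(out$zp_wm)),
      WM = out$zp_wm, L1 = out$zp_l1, L2 = out$zp_l2, L3 = out$zp_l3,
      gate = out$gate, events = ev, seed = seed,
      modality = network$modality, dt = p$rec_dt,
      burn_in = p$burn_in,
      collection = network$collection),
      class = "tg_recording")
  }
  with_seed(seed, run)
}

#' @export
print.tg_recording <- function(x, ...) {
  cat(sprintf("tg_recording: %.3g s at %.3g ms resolution, %d columns, %s modality\n",
              max(x$time), x$dt * 1e3, ncol(x$WM), x$modality))
  invisible(x)
}

#' Simulate one isolated cortical column
#'
#' A single column with no lateral or inter-layer connections, driven by an
#' external input and optional white (uniform) noise.  With the default
#' constants and a noise drive in the standard range the column oscillates
#' in the alpha band (about 10 Hz).
#'
#' @param params parameter list from \code{\link{tg_params}}.
#' @param duration simulated time (s).
#' @param input constant external drive to the pyramidal population, or a
#'   vector with one value per integration step.
#' @param input_f drive to the fast interneurons (constant or per step).
#' @param noise length-2 uniform range added to the pyramidal drive per
#'   step; \code{NULL} for the standard range, \code{c(0, 0)} for none.
#' @param C_pp auto-excitation gain (0 = a column outside WM).
#' @param seed integer seed.
#' @param dt optional integration-step override (s).
#' @return List with \code{time}, \code{z_p}, \code{z_f}.
#' @examples
#' z <- simulate_column(duration = 0.5, seed = 1)
#' range(z$z_p)
#' @export
simulate_column <- function(params = tg_params(), duration = 1, input = 0,
                            input_f = 0, noise = NULL, C_pp = 0, seed = 1,
                            dt = NULL) {
  if (!is.null(dt)) params$dt <- dt
  if (is.null(noise)) noise <- c(params$noise_col_lo, params$noise_col_hi)
  steps <- round(duration / params$dt)
  rec_every <- max(1L, round(params$rec_dt / params$dt))
  out <- with_seed(seed, function()
    cpp_simulate_column(params, as.numeric(input), as.numeric(input_f),
                        noise[1], noise[2], steps, rec_every, C_pp))
  list(time = seq(0, by = rec_every * params$dt, length.out = length(out$z_p)),
       z_p = out$z_p, z_f = out$z_f)
}
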