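#' Per-object mean activity traces
#'
#' Averages the pyramidal spike density over each object's member columns.
#' On the 0..5 activity scale a trace value of 5 means every feature of the
#' object is fully active, 4 means about 80\% are, and 3.5 corresponds to a
#' 70\% cue.
#'
#' @param recording a \code{tg_recording}.
#' @param layer \code{"WM"}, \code{"L1"}, \code{"L2"} or \code{"L3"}.
#' @param collection optional \code{tg_collection} (defaults to the one the
#'   recording was made with).
#' @param drop_burn_in discard the initial transient before averaging.
#' @return List with \code{time} and \code{traces} (time x objects matrix).
#' @export
object_traces <- function(recording, layer = "L3", collection = NULL,
                          drop_burn_in = TRUE) {
  stopifnot(inherits(recording, "tg_recording"))
  if (is.null(collection)) collection <- recording$collection
  if (max(unlist(collection$objects)) > ncol(recording[[layer]]))
    stop("collection does not match the recording lattice")
  keep <- if (drop_burn_in) recording$time >= recording$burn_in
          else rep(TRUE, length(recording$time))
  zz <- recording[[layer]][keep, , drop = FALSE]
  tr <- vapply(collection$objects,
               function(ft) rowMeans(zz[, ft, drop = FALSE]),
               numeric(sum(keep)))
  list(time = recording$time[keep], traces = tr,
       gate = recording$gate[keep])
}

#' Dominant frequency of a trace
#'
#' Frequency of the maximum of a smoothed periodogram within a band.  If the
#' band maximum does not exceed \code{min_ratio} times the spectral median
#' of the band, the trace is considered arrhythmic and \code{NA} is
#' returned.
#'
#' @param x numeric trace.
#' @param fs sampling rate (Hz).
#' @param band length-2 frequency band (Hz); defaults: theta-alpha c(2, 12),
#'   use c(15, 100) for gamma.
#' @param min_ratio peak-over-median criterion for declaring a rhythm.
#' @return Peak frequency in Hz, or \code{NA} if no rhythm.
#' @examples
#' t <- seq(0, 2, by = 1e-3)
#' dominant_frequency(sin(2 * pi * 10 * t), 1000, c(2, 12))
#' @export
dominant_frequency <- function(x, fs, band = c(2, 12), min_ratio = 3) {
  x <- x - mean(x)
  if (length(x) < 2 * fs / band[1])
    stop("trace shorter than two periods of the band's lower edge")
  if (sd(x) < 1e-9) return(NA_real_)
  # smooth the periodogram over roughly 1 Hz
  df <- fs / length(x)
  span <- max(3, 2 * floor(0.5 / df) + 1)
  sp <- spec.pgram(ts(x, frequency = fs), spans = c(span, span), taper = 0.1,
                   plot = FALSE, detrend = TRUE)
  sel <- sp$freq >= band[1] & sp$freq <= band[2]
  if (!any(sel)) return(NA_real_)
  pk <- which.max(sp$spec[sel])
  if (sp$spec[sel][pk] < min_ratio * median(sp$spec[sel])) return(NA_real_)
  sp$freq[sel][pk]
}

#' Detect exclusive recognition events
#'
#' An event for object k opens when its trace crosses \code{high} while
#' every other object is below \code{low}, and closes when the trace falls
#' back below \code{low}.  Events of the same object closer than
#' \code{min_gap} seconds are merged.  The \code{high} default of 4
#' corresponds to at least ~80\% of the object's features being active; the
#' \code{low} default enforces exclusivity against all other objects.
#'
#' @param traces time x objects matrix (from \code{\link{object_traces}}).
#' @param time time base (s).
#' @param high activation threshold opening an event.
#' @param low exclusivity/closing threshold.
#' @param min_gap minimum separation between events of one object (s).
#' @return data.frame with \code{object}, \code{onset}, \code{offset},
#'   \code{peak}.
#' @export
detect_recognitions <- function(traces, time, high = 4, low = 1,
                                min_gap = 0.005) {
  stopifnot(nrow(traces) == length(time))
  n_obj <- ncol(traces)
  out <- list()
  for (k in seq_len(n_obj)) {
    others <- traces[, -k, drop = FALSE]
    ok_excl <- if (ncol(others)) apply(others, 1, max) < low
               else rep(TRUE, nrow(traces))
    open <- traces[, k] >= high & ok_excl
    closed <- traces[, k] < low
    state <- FALSE
    onset <- NA_real_
    peak <- -Inf
    ev <- list()
    for (i in seq_along(time)) {
      if (!state && open[i]) { state <- TRUE; onset <- time[i]; peak <- traces[i, k] }
      else if (state) {
        peak <- max(peak, traces[i, k])
        if (closed[i]) {
          ev[[length(ev) + 1]] <- c(onset, time[i], peak)
          state <- FALSE
        }
      }
    }
    if (state) ev[[length(ev) + 1]] <- c(onset, time[length(time)], peak)
    if (length(ev)) {
      m <- do.call(rbind, ev)
      # merge events separated by less than min_gap
      if (nrow(m) > 1) {
        keep <- c(TRUE, m[-1, 1] - m[-nrow(m), 2] >= min_gap)
        grp <- cumsum(keep)
        m <- do.call(rbind, lapply(split(seq_len(nrow(m)), grp), function(ix)
          c(m[ix[1], 1], m[ix[length(ix)], 2], max(m[ix, 3]))))
      }
      out[[k]] <- data.frame(object = k, onset = m[, 1], offset = m[, 2],
                             peak = m[, 3])
    }
  }
  if (!length(out))
    return(data.frame(object = integer(0), onset = numeric(0),
                      offset = numeric(0), peak = numeric(0)))
  res <- do.call(rbind, out)
  res[order(res$onset), , drop = FALSE]
}

#' Decode the per-cycle object sequence
#'
#' Within each theta ON phase (gate-open interval of the recording), returns
#' the ordered list of recognized object ids by event onset.  In the
#' sequence-ordering modality this is the replayed item list nested in each
#' theta cycle.
#'
#' @param recording a \code{tg_recording} (sequence modality).
#' @param layer layer to decode (default \code{"L3"}).
#' @param high,low recognition thresholds (see
#'   \code{\link{detect_recognitions}}).
#' @param min_cycle minimum gate-open duration (s) to count as a cycle.
#' @return List with one integer vector of object ids per theta cycle, with
#'   attributes \code{onsets} (cycle start times).
#' @export
decode_sequence <- function(recording, layer = "L3", high = 4, low = 1,
                            min_cycle = 0.02) {
  tr <- object_traces(recording, layer)
  ev <- detect_recognitions(tr$traces, tr$time, high = high, low = low)
  g <- as.logical(tr$gate)
  starts <- tr$time[which(diff(c(FALSE, g)) == 1)]
  ends <- tr$time[which(diff(c(g, FALSE)) == -1)]
  cyc <- data.frame(start = starts, end = ends)
  cyc <- cyc[cyc$end - cyc$start >= min_cycle, , drop = FALSE]
  out <- lapply(seq_len(nrow(cyc)), function(i) {
    sel <- ev$onset >= cyc$start[i] & ev$onset < cyc$end[i]
    ev$object[sel][order(ev$onset[sel])]
  })
  attr(out, "onsets") <- cyc$start
  attr(out, "ends") <- cyc$end
  out
}

#' Theta-phase of one object's bursts across shifting cues
#'
#' For a fixed object present in the replayed list of several cues, computes
#' the mean onset phase of its recognition burst within the theta cycle
#' (0 = cycle start, 1 = cycle end), per cue epoch, and the least-squares
#' slope of phase against cue index.  Phase precession shows as a negative
#' slope: the object fires earlier in the cycle as the cue advances towards
#' it.
#'
#' @param recording a sequence-recovery \code{tg_recording} with several
#'   cues.
#' @param object the tracked object id.
#' @param cue_times cue onset times; defaults to the recording's events.
#' @param layer decoded layer.
#' @return List with \code{phase} (mean phase per cue), \code{slope}
#'   (NA if fewer than two cue epochs have data).
#' @export
phase_precession_stat <- function(recording, object, cue_times = NULL,
                                  layer = "L3") {
  if (is.null(cue_times)) cue_times <- recording$events$time
  cyc <- decode_sequence(recording, layer)
  onsets <- attr(cyc, "onsets"); ends <- attr(cyc, "ends")
  tr <- object_traces(recording, layer)
  ev <- detect_recognitions(tr$traces, tr$time)
  ev <- ev[ev$object == object, , drop = FALSE]
  epochs <- c(cue_times, max(recording$time) + 1)
  phase <- rep(NA_real_, length(cue_times))
  for (e in seq_along(cue_times)) {
    ph <- c()
    for (i in seq_along(onsets)) {
      if (onsets[i] < epochs[e] + 0.05 || onsets[i] >= epochs[e + 1]) next
      sel <- ev$onset >= onsets[i] & ev$onset < ends[i]
      if (any(sel))
        ph <- c(ph, (min(ev$onset[sel]) - onsets[i]) / (ends[i] - onsets[i]))
    }
    if (length(ph)) phase[e] <- mean(ph)
  }
  ok <- !is.na(phase)
  slope <- if (sum(ok) >= 2)
    unname(coef(lm(phase[ok] ~ seq_along(phase)[ok]))[2]) else NA_real_
  list(phase = phase, slope = slope)
}

#' Success statistics over a battery of semantic trials
#'
#' Runs \code{n_trials} independent semantic simulations (new random object
#' placements and new noise per trial), cueing \code{n_objects} objects
#' simultaneously, and aggregates: the percentage of trials in which every
#' cued object is recognized at least twice (and at least once) within the
#' window, the mean gamma frequency of the summed L3 activity, and the
#' min/max/mean time at which all objects have been recognized twice.
#'
#' @param n_objects number of simultaneously cued objects.
#' @param A_max strength scale of the ultrafast cross-object synapses.
#' @param pattern \code{"orthogonal_fixed"} or \code{"orthogonal_variable"}.
#' @param n_trials number of trials.
#' @param seed battery seed; trial seeds are derived from it.
#' @param duration simulation window per trial (s).
#' @param n_store number of stored objects (the collection size).
#' @param collection optional fixed collection reused across trials (default:
#'   a fresh collection per trial).
#' @return One-row data.frame: \code{n_objects}, \code{A_max},
#'   \code{pattern}, \code{pct_success_2x}, \code{pct_success_1x},
#'   \code{gamma_frequency}, \code{T_min}, \code{T_max}, \code{T_mean},
#'   \code{n_trials}.
#' @export
table2_battery <- function(n_objects, A_max = 0.15,
                           pattern = c("orthogonal_fixed",
                                       "orthogonal_variable"),
                           n_trials = 20, seed = 1, duration = 1.5,
                           n_store = 9, collection = NULL) {
  pattern <- match.arg(pattern)
  if (n_objects == 0)
    return(data.frame(n_objects = 0, A_max = A_max, pattern = pattern,
                      pct_success_2x = 100, pct_success_1x = 100,
                      gamma_frequency = NA_real_, T_min = NA_real_,
                      T_max = NA_real_, T_mean = NA_real_,
                      n_trials = n_trials))
  succ2 <- succ1 <- logical(n_trials)
  gam <- t2 <- rep(NA_real_, n_trials)
  for (tr in seq_len(n_trials)) {
    tseed <- seed * 1000L + tr
    co <- if (is.null(collection))
      generate_collection(pattern, n_objects = n_store, seed = tseed)
    else collection
    net <- build_network(co, "semantic")
    net <- train_network(net, A_max = A_max)
    rec <- run_protocol(net, protocol_semantic(seq_len(n_objects),
                                               duration = duration),
                        seed = tseed)
    res <- trial_success(rec, seq_len(n_objects))
    succ2[tr] <- res$ok2; succ1[tr] <- res$ok1
    gam[tr] <- res$gamma; t2[tr] <- res$t_all2
  }
  data.frame(n_objects = n_objects, A_max = A_max, pattern = pattern,
             pct_success_2x = 100 * mean(succ2),
             pct_success_1x = 100 * mean(succ1),
             gamma_frequency = mean(gam, na.rm = TRUE),
             T_min = if (any(!is.na(t2))) min(t2, na.rm = TRUE) else NA_real_,
             T_max = if (any(!is.na(t2))) max(t2, na.rm = TRUE) else NA_real_,
             T_mean = mean(t2, na.rm = TRUE),
             n_trials = n_trials)
}

# Success, gamma frequency and time-to-double-recognition of one semantic
# trial.
trial_success <- function(recording, cued, high = 4, low = 1) {
  tr <- object_traces(recording, "L3")
  sub <- tr$traces[, cued, drop = FALSE]
  ev <- detect_recognitions(sub, tr$time, high = high, low = low)
  counts <- tabulate(ev$object, nbins = length(cued))
  ok2 <- all(counts >= 2); ok1 <- all(counts >= 1)
  t_all2 <- NA_real_
  if (ok2) {
    second <- vapply(seq_along(cued), function(k)
      sort(ev$onset[ev$object == k])[2], numeric(1))
    t_all2 <- max(second)
  }
  gamma <- dominant_frequency(rowSums(sub), fs = 1 / diff(tr$time[1:2]),
                              band = c(15, 100), min_ratio = 2)
  list(ok2 = ok2, ok1 = ok1, t_all2 = t_all2, gamma = gamma)
}

#' Decode spontaneous burst sequences (dreaming mode)
#'
#' In the noise-driven (dreaming) regime there is no cue-locked theta gate
#' to segment time, so recognized bursts are grouped into episodes split at
#' silent gaps longer than \code{gap}; consecutive repeats of the same
#' object are merged.
#'
#' @param recording a \code{tg_recording}.
#' @param layer decoded layer.
#' @param gap minimum silent interval separating episodes (s).
#' @param high,low recognition thresholds.
#' @return List of integer object-id sequences (one per episode).
#' @export
decode_bursts <- function(recording, layer = "L3", gap = 0.15,
                          high = 4, low = 1) {
  tr <- object_traces(recording, layer)
  ev <- detect_recognitions(tr$traces, tr$time, high = high, low = low)
  if (!nrow(ev)) return(list())
  ev <- ev[order(ev$onset), ]
  brk <- c(TRUE, ev$onset[-1] - ev$offset[-nrow(ev)] > gap)
  split(ev$object, cumsum(brk)) |>
    lapply(function(s) s[c(TRUE, diff(s) != 0)]) |>
    unname()
}

#' Classify the transitions of spontaneously replayed sequences
#'
#' Checks every transition between successive distinct objects of the
#' decoded episodes against the trained lists: a transition is a
#' \emph{within-list} step if the two objects are consecutive in one trained
#' list, and a \emph{concatenation} if it jumps from one list into another
#' one (the mechanism the overlapping features provide).  Everything else is
#' counted as illegal.
#'
#' @param sequences list of decoded episodes (from
#'   \code{\link{decode_bursts}}).
#' @param lists the trained ordered lists (list of integer vectors).
#' @return List with counts \code{within}, \code{concat}, \code{illegal} and
#'   the fraction \code{legal}.
#' @export
classify_transitions <- function(sequences, lists) {
  list_of <- function(x) which(vapply(lists, function(l) x %in% l, TRUE))[1]
  succ <- list()
  for (l in lists) for (k in seq_len(length(l) - 1))
    succ[[as.character(l[k])]] <- c(succ[[as.character(l[k])]], l[k + 1])
  within <- concat <- illegal <- 0L
  for (s in sequences) {
    if (length(s) < 2) next
    for (k in seq_len(length(s) - 1)) {
      a <- s[k]; b <- s[k + 1]
      if (b %in% succ[[as.character(a)]]) within <- within + 1L
      else if (!identical(list_of(a), list_of(b))) concat <- concat + 1L
      else illegal <- illegal + 1L
    }
  }
  tot <- within + concat + illegal
  list(within = within, concat = concat, illegal = illegal,
       legal = if (tot) (within + concat) / tot else NA_real_)
}
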