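#' Model parameters
#'
#' Returns the full parameter set of the model: the cortical-column constants
#' (sigmoid, synaptic kernels, internal couplings), the fixed inter-layer
#' gains of the chosen operating modality, the theta-gate constants, the
#' noise ranges, and the training configuration.
#'
#' All columns in all layers share the same constants; the only exception is
#' the pyramidal auto-excitation \code{C_pp}, which is nonzero in layer WM
#' only and implements working-memory maintenance.  The three long-range
#' synapse classes have characteristic times of about 7.7 ms (W, excitatory
#' pyramidal-to-pyramidal), 6.8 ms (K, pyramidal onto fast interneurons) and
#' under 1 ms (A, ultrafast pyramidal onto fast interneurons).
#'
#' In the \code{"semantic"} modality the WM-to-L1 gain is three times its
#' \code{"sequence"} value, which drives L1 to tonic saturation and removes
#' the theta rhythm; the L3-to-L2 hetero-associative synapses are only
#' trained in the \code{"sequence"} modality.
#'
#' @param modality \code{"sequence"} (ordered recall, theta-gamma nesting) or
#'   \code{"semantic"} (simultaneous multi-item maintenance, gamma
#'   segmentation only).
#' @param ... named overrides for any parameter.
#' @return A named list of parameters.
#' @examples
#' p <- tg_params("sequence")
#' p$e0 * 2   # saturation of the population spike density
#' @export
tg_params <- function(modality = c("sequence", "semantic"), ...) {
  modality <- match.arg(modality)
  p <- list(
    ## sigmoid activation: spike density in (0, 2*e0)
    e0 = 2.5,           # half-saturation spike density
    r = 0.56,           # steepness (1/mV)
    v0 = 6,             # half-activation potential (mV)

    ## intra-column second-order synaptic kernels (gain mV, rate 1/s)
    G_e = 3.25,  om_e = 100,   # glutamatergic
    G_s = 22,    om_s = 40,    # slow GABAergic
    G_f = 40,    om_f = 250,   # fast GABAergic

    ## long-range kernel classes
    G_W = 3.25,  om_W = 130,   # excitatory, tau ~ 7.7 ms
    G_K = 3.25,  om_K = 147,   # onto fast interneurons, tau ~ 6.8 ms
    G_A = 0.5,   tau_A = 8e-4, # ultrafast, first order, tau < 1 ms

    ## internal couplings C_post,pre
    C_ep = 135, C_pe = 108,     # pyramidal <-> excitatory interneurons
    C_sp = 33.75, C_ps = 33.75, # pyramidal <-> slow GABA
    C_fp = 40.5,  C_pf = 108,   # pyramidal <-> fast GABA
    C_fs = 13.5,                # slow GABA -> fast GABA
    C_ff = 18,                  # fast GABA auto-inhibition
    C_pp = 250,                 # WM pyramidal auto-excitation (WM layer only)

    ## fixed inter-layer gains (spike-density multipliers)
    g_wm_l1 = if (modality == "semantic") 225 else 75,
    g_l1_wm = 50,
    g_l1_l2 = 240,
    g_l2_l3 = 260,

    ## lattice
    L = 20, M = 20,

    ## synapse normalization targets (incoming sums)
    W_sum = 90,     # L1 auto-associative excitation
    K_sum = 200,    # within-object reciprocal inhibition (L2, L3)
    W23_sum = 700,  # L3 -> L2 hetero-associative (sequence modality)
    A_max = 0.12,   # per-synapse ultrafast cross-object inhibition

    ## theta gate on L2 (threshold set from the collection at build time
    ## as gate_frac * 2*e0 * mean object size; hysteresis closes at
    ## gate_hyst * threshold)
    gate_frac = 0.5,
    gate_thr = NA_real_,
    gate_hyst = 0.9,
    gate_clamp = 250,

    ## uniform noise: per column, redrawn every noise_dt (band-limited so
    ## its effective strength does not depend on the integration step)
    noise_dt = 1e-3,
    noise_wm_lo = 0,  noise_wm_hi = 40,
    noise_bg_lo = 0,  noise_bg_hi = 150,
    ## isolated-column white-noise drive
    noise_col_lo = 200, noise_col_hi = 400,
    ## dreaming-mode drive to L1
    dream_lo = 80, dream_hi = 160,

    ## stimulation
    cue_amp = 2000,     # drive used for cue presentations
    train_amp = 6000,   # drive used during training (saturates the
                        # columns even against their own fast inhibition)

    ## training configuration
    epochs_step_i = 2000,
    epochs_step_ii = 1000,
    lr_hebb = 0.01,     # per-epoch Hebbian rate (fraction of the cap)
    w_cap = 1,          # saturation level of a single synapse before
                        # normalization
    act_thr = 2.5,      # active/silent threshold on the 0..5 scale

    ## integration
    dt = 1e-4,          # s
    rec_dt = 1e-3,      # recording resolution, s
    burn_in = 0.05      # s discarded by the metrics
  )
  p$modality <- modality
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(p))
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    p <- modifyList(p, dots)
  }
  p
}

#' Population activation function
#'
#' Sigmoid transduction from the average membrane potential of a population
#' to its average spike density.  Output lies strictly between 0 and
#' \code{2 * e0} (0 and 5 with the default constants) and is strictly
#' increasing; \code{v = v0} gives exactly \code{e0}.
#'
#' @param v membrane potential (mV); vectorized.
#' @param e0 half-saturation spike density.
#' @param r steepness (1/mV).
#' @param v0 half-activation potential (mV).
#' @return Spike density, same shape as \code{v}.
#' @examples
#' activation(6)           # e0 = 2.5 at the midpoint
#' activation(c(-1e3, 1e3))
#' @export
activation <- function(v, e0 = 2.5, r = 0.56, v0 = 6) {
  if (any(!is.finite(v))) stop("non-finite membrane potential")
  stopifnot(e0 > 0, r > 0)
  2 * e0 / (1 + exp(-r * (v - v0)))
}

#' One Euler step of a second-order synaptic kernel
#'
#' The kernel is the standard alpha function \eqn{h(t) = G \omega t
#' e^{-\omega t}}, realized as \eqn{\dot y = x}, \eqn{\dot x = G \omega u -
#' 2 \omega x - \omega^2 y}.  Its impulse response peaks at \eqn{t =
#' 1/\omega} and its DC gain is \eqn{G/\omega}.
#'
#' @param state numeric length-2 vector \code{c(y, x)}.
#' @param input presynaptic drive \code{u} for this step.
#' @param gain kernel gain \code{G} (mV).
#' @param tau kernel time constant \code{1/omega} (s).
#' @param dt step size (s); must be well below \code{tau}.
#' @return Updated \code{c(y, x)}.
#' @export
kernel_step <- function(state, input, gain, tau, dt) {
  stopifnot(length(state) == 2, dt > 0, tau > 0)
  if (dt >= tau)
    stop("dt = ", dt, " is not below the kernel time constant ", tau)
  om <- 1 / tau
  x_new <- state[2] + dt * (gain * om * input - 2 * om * state[2] - om^2 * state[1])
  c(state[1] + dt * state[2], x_new)
}
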