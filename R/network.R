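#' Assemble the four-layer network
#'
#' Builds the WM, L1, L2, L3 layers over the collection's lattice, installs
#' the fixed feedforward/feedback gains of the chosen modality, the theta
#' gate on L2, and empty (untrained) synapse matrices.  Columns are indexed
#' by flattening the L x M lattice; column i represents the same feature in
#' every layer.  Only WM columns carry the pyramidal auto-excitation
#' \code{C_pp}.
#'
#' @param collection a \code{tg_collection}.
#' @param modality \code{"sequence"} or \code{"semantic"}; defaults to the
#'   modality of \code{params}.
#' @param params parameter list from \code{\link{tg_params}}.
#' @return A \code{tg_network}.
#' @examples
#' co <- generate_collection("orthogonal_fixed", seed = 1)
#' net <- build_network(co, "sequence")
#' @export
build_network <- function(collection, modality = NULL, params = NULL) {
  stopifnot(inherits(collection, "tg_collection"))
  if (is.null(params)) params <- tg_params(if (is.null(modality)) "sequence"
                                           else modality)
  if (is.null(modality)) modality <- params$modality
  modality <- match.arg(modality, c("sequence", "semantic"))
  if (modality != params$modality)
    params <- tg_params(modality)
  if (params$L != collection$L || params$M != collection$M) {
    if (!is.null(collection$L)) { params$L <- collection$L; params$M <- collection$M }
  }
  n <- collection$L * collection$M
  if (is.na(params$gate_thr)) {
    mean_size <- mean(vapply(collection$objects, length, 1L))
    params$gate_thr <- params$gate_frac * 2 * params$e0 * mean_size
  }
  z <- matrix(0, n, n)
  structure(list(
    collection = collection,
    modality = modality,
    params = params,
    n = n,
    synapses = list(W1 = z, K2 = z, A2 = z, K3 = z, A3 = z, W23 = z),
    trained = FALSE,
    sequence_trained = FALSE,
    sequences = list()
  ), class = "tg_network")
}

#' @export
print.tg_network <- function(x, ...) {
  cat(sprintf("tg_network: %d columns/layer, modality '%s', %s\n",
              x$n, x$modality,
              if (x$sequence_trained) "trained (objects + sequence)"
              else if (x$trained) "trained (objects)"
              else "untrained"))
  invisible(x)
}

#' Normalize incoming synapses
#'
#' Scales every row (the set of synapses entering one column) of a
#' non-negative matrix so its sum equals \code{target}; all-zero rows are
#' left untouched.  This keeps the total excitation (or inhibition) entering
#' a column independent of the object size, so objects of different
#' dimensions oscillate at the same frequency.  \code{target} may be a
#' scalar or a per-row vector.
#'
#' @param mat non-negative matrix, rows = postsynaptic columns.
#' @param target desired incoming sum (scalar or per-row).
#' @return Rescaled matrix.
#' @export
normalize_incoming <- function(mat, target) {
  if (any(mat < 0)) stop("negative synapse values")
  rs <- rowSums(mat)
  sc <- ifelse(rs > 0, target / rs, 0)
  mat * sc
}

#' Clamped steady state under a training drive
#'
#' During training, objects are presented with inputs so strong that the
#' stimulated columns reach saturation and do not oscillate; the learning
#' rules are applied to this steady state.  The steady state is computed
#' algebraically by damped fixed-point iteration on the DC equations of the
#' column (each kernel replaced by its DC gain).
#'
#' @param params parameter list.
#' @param drive_p external drive to the pyramidal population.
#' @param drive_f external drive to the fast interneurons (through the
#'   K-class kernel).
#' @param C_pp auto-excitation (0 outside WM).
#' @return List with steady spike densities \code{z_p}, \code{z_e},
#'   \code{z_s}, \code{z_f}.
#' @export
column_steady_state <- function(params, drive_p = 0, drive_f = 0, C_pp = 0) {
  p <- params
  dc_e <- p$G_e / p$om_e; dc_s <- p$G_s / p$om_s; dc_f <- p$G_f / p$om_f
  dc_W <- p$G_W / p$om_W; dc_K <- p$G_K / p$om_K
  zp <- ze <- zs <- zf <- rep(p$e0, max(length(drive_p), length(drive_f)))
  mix <- 0.3
  for (it in 1:400) {
    yp <- dc_e * zp; ye <- dc_e * ze; ys <- dc_s * zs; yf <- dc_f * zf
    vp <- p$C_pe * ye - p$C_ps * ys - p$C_pf * yf + C_pp * yp + dc_W * drive_p
    ve <- p$C_ep * yp
    vs <- p$C_sp * yp
    vf <- p$C_fp * yp - p$C_ff * yf - p$C_fs * ys + dc_K * drive_f
    zp_n <- activation(vp, p$e0, p$r, p$v0); ze_n <- activation(ve, p$e0, p$r, p$v0)
    zs_n <- activation(vs, p$e0, p$r, p$v0); zf_n <- activation(vf, p$e0, p$r, p$v0)
    d <- max(abs(zp_n - zp), abs(ze_n - ze), abs(zs_n - zs), abs(zf_n - zf))
    zp <- (1 - mix) * zp + mix * zp_n; ze <- (1 - mix) * ze + mix * ze_n
    zs <- (1 - mix) * zs + mix * zs_n; zf <- (1 - mix) * zf + mix * zf_n
    if (d < 1e-12) break
  }
  list(z_p = zp, z_e = ze, z_s = zs, z_f = zf)
}

#' Clamped activities for one training presentation
#'
#' Presents one object for training: its pyramidal columns are driven to
#' saturation in L1, and both the pyramidal columns and the fast
#' interneurons in L2 and L3.  Returns the clamped spike densities used by
#' the learning rules.
#'
#' @param network a \code{tg_network}.
#' @param object integer vector of feature indices (or an object id).
#' @return List with per-layer clamped \code{z_p} and \code{z_f} vectors.
#' @export
present_for_training <- function(network, object) {
  if (length(object) == 1 && object <= length(network$collection$objects))
    object <- network$collection$objects[[object]]
  object <- as.integer(object)
  if (!length(object)) stop("empty object")
  if (any(object < 1 | object > network$n)) stop("feature index out of range")
  p <- network$params
  on_p <- column_steady_state(p, drive_p = p$train_amp, drive_f = 0)
  on_pf <- column_steady_state(p, drive_p = p$train_amp, drive_f = p$train_amp)
  off <- column_steady_state(p, drive_p = 0, drive_f = 0)
  mk <- function(on_val, off_val) {
    v <- rep(off_val, network$n); v[object] <- on_val; v
  }
  list(
    L1 = list(z_p = mk(on_p$z_p, off$z_p), z_f = mk(on_p$z_f, off$z_f)),
    L2 = list(z_p = mk(on_pf$z_p, off$z_p), z_f = mk(on_pf$z_f, off$z_f)),
    L3 = list(z_p = mk(on_pf$z_p, off$z_p), z_f = mk(on_pf$z_f, off$z_f))
  )
}

#' Save / load a network snapshot
#'
#' Serializes the complete network (collection, parameters, all synapse
#' matrices, modality and training state) so that a loaded copy is
#' bit-identical to the saved one.
#'
#' @param network a \code{tg_network}.
#' @param path file path (conventionally \code{.rds}).
#' @return \code{load_network} returns the \code{tg_network};
#'   \code{save_network} returns \code{path} invisibly.
#' @export
save_network <- function(network, path) {
  stopifnot(inherits(network, "tg_network"))
  saveRDS(network, path)
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  net <- readRDS(path)
  if (!inherits(net, "tg_network")) stop("not a network snapshot: ", path)
  net
}
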