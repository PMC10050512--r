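# Hebbian / anti-Hebbian training of the lateral and feedback synapses.
#
# All rules operate on clamped steady-state activities (the columns are
# driven to saturation during training, so activities are essentially
# bimodal).  A single synapse saturates at w_cap; one epoch moves it a
# fraction lr_hebb of the remaining headroom.  After the epochs, incoming
# sums are normalized, which makes the trained network independent of the
# epoch count once the rules have saturated.

# normalized "activity" in [0, 1]: fraction above the active threshold
.h_act <- function(z, p) pmax(z - p$act_thr, 0) / (2 * p$e0 - p$act_thr)
# normalized "silence" in [0, 1]
.h_sil <- function(z, p) pmax(p$act_thr - z, 0) / p$act_thr

#' Single-epoch Hebbian update of the L1 excitatory synapses
#'
#' Potentiates \code{W[i, j]} when presynaptic pyramidal population j and
#' postsynaptic pyramidal population i are both active in the clamped state;
#' self-connections stay zero.  The increment saturates at \code{w_cap}.
#'
#' @param W current matrix.
#' @param clamp clamp state from \code{\link{present_for_training}}.
#' @param params parameter list.
#' @return Updated matrix.
#' @export
hebb_update_W_L1 <- function(W, clamp, params) {
  h <- .h_act(clamp$L1$z_p, params)
  W_new <- W + params$lr_hebb * outer(h, h) * (params$w_cap - W)
  diag(W_new) <- 0
  W_new
}

#' Single-epoch Hebbian update of the within-object K synapses
#'
#' As \code{\link{hebb_update_W_L1}}, but the postsynaptic population is the
#' fast inhibitory interneuron of the target column (both are driven during
#' training in L2/L3).
#'
#' @param K current matrix.
#' @param clamp clamp state.
#' @param layer \code{"L2"} or \code{"L3"}.
#' @param params parameter list.
#' @return Updated matrix.
#' @export
hebb_update_K <- function(K, clamp, layer, params) {
  post <- .h_act(clamp[[layer]]$z_f, params)
  pre <- .h_act(clamp[[layer]]$z_p, params)
  K_new <- K + params$lr_hebb * outer(post, pre) * (params$w_cap - K)
  diag(K_new) <- 0
  K_new
}

#' Single-epoch anti-Hebbian update of the cross-object A synapses
#'
#' Potentiates \code{A[i, j]} when the presynaptic pyramidal population j is
#' active while the postsynaptic fast interneuron i is silent; when both are
#' active the synapse is instead depressed towards zero (so features shared
#' between two objects do not build fast inhibition onto either of them).
#'
#' @param A current matrix.
#' @param clamp clamp state.
#' @param layer \code{"L2"} or \code{"L3"}.
#' @param params parameter list.
#' @return Updated matrix.
#' @export
antihebb_update_A <- function(A, clamp, layer, params) {
  pre <- .h_act(clamp[[layer]]$z_p, params)
  post_sil <- .h_sil(clamp[[layer]]$z_f, params)
  post_act <- .h_act(clamp[[layer]]$z_f, params)
  A_new <- A + params$lr_hebb * outer(post_sil, pre) * (params$w_cap - A)
  A_new <- A_new * (1 - outer(post_act, pre))   # co-activity resets
  diag(A_new) <- 0
  pmax(A_new, 0)
}

#' Train the network on its object collection (step i)
#'
#' Presents every object of the collection separately to layers L1, L2, L3
#' in clamped (saturated) state for \code{epochs_step_i} epochs, forming the
#' auto-associative W synapses in L1 and the K (within-object, Hebbian) and
#' A (cross-object, anti-Hebbian) synapses in L2 and L3.  Afterwards the
#' incoming sums are normalized: W rows to \code{W_sum}, K rows to
#' \code{K_sum}, and A rows so the mean nonzero incoming synapse equals
#' \code{A_max}.
#'
#' Because the clamped activities are constant across epochs, the saturating
#' per-epoch recurrence has a closed form, which is used here; it is
#' identical (to rounding) to iterating the single-epoch rules and makes
#' training time independent of the epoch count.
#'
#' @param network a \code{tg_network}.
#' @param epochs number of step-i epochs (default from params).
#' @param A_max override for the A normalization scale.
#' @return The trained \code{tg_network}.
#' @export
train_network <- function(network, epochs = NULL, A_max = NULL) {
  p <- network$params
  if (!is.null(epochs)) p$epochs_step_i <- epochs
  if (!is.null(A_max)) p$A_max <- A_max
  n <- network$n
  E <- p$epochs_step_i

  # accumulated per-pair potentiation exponents and co-activity reset masks
  expW <- expK2 <- expK3 <- expA2 <- expA3 <- matrix(0, n, n)
  resetA2 <- resetA3 <- matrix(FALSE, n, n)
  for (ob in network$collection$objects) {
    cl <- present_for_training(network, ob)
    h1 <- .h_act(cl$L1$z_p, p)
    expW <- expW + outer(h1, h1)
    for (ly in c("L2", "L3")) {
      hp <- .h_act(cl[[ly]]$z_p, p)
      hf <- .h_act(cl[[ly]]$z_f, p)
      sf <- .h_sil(cl[[ly]]$z_f, p)
      if (ly == "L2") {
        expK2 <- expK2 + outer(hf, hp)
        expA2 <- expA2 + outer(sf, hp)
        resetA2 <- resetA2 | (outer(hf, hp) > 0.5)
      } else {
        expK3 <- expK3 + outer(hf, hp)
        expA3 <- expA3 + outer(sf, hp)
        resetA3 <- resetA3 | (outer(hf, hp) > 0.5)
      }
    }
  }
  sat <- function(expo) p$w_cap * (1 - (1 - p$lr_hebb)^(E * expo))
  W1 <- sat(expW); K2 <- sat(expK2); K3 <- sat(expK3)
  A2 <- sat(expA2); A2[resetA2] <- 0
  A3 <- sat(expA3); A3[resetA3] <- 0
  diag(W1) <- diag(K2) <- diag(K3) <- diag(A2) <- diag(A3) <- 0
  # A forms among feature-coding columns of different objects; columns that
  # belong to no object receive none
  nonmember <- setdiff(seq_len(n), unlist(network$collection$objects))
  A2[nonmember, ] <- 0
  A3[nonmember, ] <- 0

  norm_a <- function(A) {
    nnz <- rowSums(A > 1e-12)
    normalize_incoming(A, p$A_max * nnz)
  }
  network$synapses$W1 <- normalize_incoming(W1, p$W_sum)
  network$synapses$K2 <- normalize_incoming(K2, p$K_sum)
  network$synapses$K3 <- normalize_incoming(K3, p$K_sum)
  network$synapses$A2 <- norm_a(A2)
  network$synapses$A3 <- norm_a(A3)
  network$params <- p
  network$trained <- TRUE
  network
}

#' Train an ordered object sequence (step ii)
#'
#' Only meaningful in the sequence-ordering modality.  For every consecutive
#' pair of the list, object k-1 is presented to layer L3 and object k to
#' layer L2 (pyramidal populations only), and the hetero-associative
#' excitatory synapses from L3 to L2 are potentiated by the Hebb rule, then
#' normalized so the incoming sum per recruited L2 column equals
#' \code{W23_sum}.  Several lists may be trained by calling this repeatedly
#' or passing a list of vectors.
#'
#' @param network a step-i-trained \code{tg_network}.
#' @param sequence integer vector of object ids in order, or list of such
#'   vectors.
#' @param epochs number of step-ii epochs (default from params).
#' @return The updated \code{tg_network}.
#' @export
train_sequence <- function(network, sequence, epochs = NULL) {
  if (network$modality != "sequence")
    stop("hetero-associative L3->L2 synapses are zero in the semantic modality; ",
         "build the network with modality = 'sequence'")
  if (!network$trained) stop("run train_network() (step i) first")
  p <- network$params
  if (!is.null(epochs)) p$epochs_step_ii <- epochs
  seqs <- if (is.list(sequence)) sequence else list(sequence)
  n <- network$n
  expo <- matrix(0, n, n)
  for (s in seqs) {
    s <- as.integer(s)
    if (any(s < 1 | s > length(network$collection$objects)))
      stop("sequence refers to an object outside the collection")
    if (any(diff(s) == 0)) stop("repeated adjacent items in the sequence")
    if (length(s) < 2) next
    for (k in 2:length(s)) {
      cl3 <- present_for_training(network, s[k - 1])   # Obj_(k-1) in L3
      cl2 <- present_for_training(network, s[k])       # Obj_k in L2
      post <- .h_act(cl2$L2$z_p, p)
      pre <- .h_act(cl3$L3$z_p, p)
      expo <- expo + outer(post, pre)
    }
  }
  raw <- p$w_cap * (1 - (1 - p$lr_hebb)^(p$epochs_step_ii * expo))
  diag(raw) <- 0
  network$synapses$W23 <- normalize_incoming(raw, p$W23_sum)
  network$params <- p
  network$sequence_trained <- TRUE
  network$sequences <- c(network$sequences, seqs)
  network
}

#' Apply a pathological perturbation
#'
#' \code{"cff_quarter"} reduces the auto-inhibition of the fast GABAergic
#' interneurons (\code{C_ff}) to 1/4 of its normal level in all columns;
#' \code{"a_quarter"} reduces the strength of the ultrafast A synapses to
#' 1/4 of their trained value.  Returns a modified copy.
#'
#' @param network a \code{tg_network}.
#' @param kind \code{"cff_quarter"} or \code{"a_quarter"}.
#' @param factor scale factor (default 0.25).
#' @return A perturbed copy of the network.
#' @export
apply_pathology <- function(network, kind = c("cff_quarter", "a_quarter"),
                            factor = 0.25) {
  kind <- match.arg(kind)
  if (kind == "cff_quarter") {
    network$params$C_ff <- network$params$C_ff * factor
  } else {
    network$synapses$A2 <- network$synapses$A2 * factor
    network$synapses$A3 <- network$synapses$A3 * factor
  }
  network
}
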