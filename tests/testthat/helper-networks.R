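# Shared fixtures, built once per session.  The miniature 8x8 lattice keeps
# unit tests fast; full 20x20 networks are reserved for the acceptance suite.

.tg_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.tg_cache[[key]])) .tg_cache[[key]] <- force(expr)
  .tg_cache[[key]]
}

mini_collection <- function() cached("mini_co",
  generate_collection("orthogonal_fixed", n_objects = 4, sizes = 6,
                      L = 8, M = 8, seed = 3))

mini_overlap_collection <- function() cached("mini_ov",
  generate_collection("overlapping", n_objects = 4, sizes = 6,
                      overlap_pairs = list(c(2, 4)), overlap_frac = 1 / 3,
                      L = 8, M = 8, seed = 4))

mini_seq_net <- function() cached("mini_seq",
  train_sequence(train_network(build_network(mini_collection(), "sequence")),
                 1:4))

mini_sem_net <- function() cached("mini_sem",
  train_network(build_network(mini_collection(), "semantic"), A_max = 0.15))

full_collection <- function() cached("full_co",
  generate_collection("orthogonal_variable", seed = 1))

full_seq_net <- function() cached("full_seq",
  train_sequence(train_network(build_network(full_collection(), "sequence")),
                 1:9))

# Synthetic recording with hand-built per-column activity, for metrics tests.
synthetic_recording <- function(z_by_layer, collection, dt = 1e-3,
                                gate = NULL) {
  nt <- nrow(z_by_layer[[1]])
  if (is.null(gate)) gate <- rep(TRUE, nt)
  structure(list(
    time = seq(0, by = dt, length.out = nt),
    WM = z_by_layer$WM, L1 = z_by_layer$L1,
    L2 = z_by_layer$L2, L3 = z_by_layer$L3,
    gate = gate,
    events = data.frame(), seed = 0, modality = "sequence",
    dt = dt, burn_in = 0, collection = collection),
    class = "tg_recording")
}
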