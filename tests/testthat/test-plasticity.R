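# Co-activity oracle: expected support of each trained matrix computed by
# direct set logic over the collection, independently of the learning code.
same_object_pairs <- function(co) {
  n <- co$L * co$M
  m <- matrix(FALSE, n, n)
  for (ob in co$objects) m[ob, ob] <- TRUE
  diag(m) <- FALSE
  m
}

test_that("step-i training produces the expected block structure", {
  net <- mini_seq_net()
  co <- mini_collection()
  sup <- same_object_pairs(co)
  s <- net$synapses
  expect_true(all((s$W1 > 1e-9) == sup))
  expect_true(all((s$K2 > 1e-9) == sup))
  expect_true(all((s$K3 > 1e-9) == sup))
  # anti-Hebbian support: cross-object pairs only (complement, off lattice
  # cells excluded because their clamped activity never crosses threshold)
  members <- unlist(co$objects)
  cross <- matrix(FALSE, net$n, net$n)
  cross[members, members] <- TRUE
  cross[sup] <- FALSE
  diag(cross) <- FALSE
  expect_true(all((s$A2 > 1e-9) == cross))
  expect_true(all(diag(s$W1) == 0), all(diag(s$A2) == 0))
})

test_that("W is symmetric and K/A have disjoint support", {
  s <- mini_seq_net()$synapses
  expect_equal(s$W1, t(s$W1))
  expect_identical(sum(s$K2 > 0 & s$A2 > 0), 0L)
  expect_identical(sum(s$K3 > 0 & s$A3 > 0), 0L)
})

test_that("incoming-sum normalization is exact and homogeneous", {
  set.seed(1)
  m <- matrix(runif(100), 10, 10) * rbinom(100, 1, 0.5)
  nm <- normalize_incoming(m, 7)
  rs <- rowSums(nm)
  expect_true(all(abs(rs[rowSums(m) > 0] - 7) < 1e-10))
  expect_equal(normalize_incoming(3.7 * m, 7), nm)  # scale invariance
  expect_error(normalize_incoming(-m, 7), "negative")
  # trained network: all recruited columns receive identical totals even
  # though object sizes differ, so objects oscillate at the same frequency
  net <- train_network(build_network(
    generate_collection("orthogonal_variable", n_objects = 2,
                        sizes = c(8, 20), L = 10, M = 10, seed = 2),
    "sequence"))
  rw <- rowSums(net$synapses$W1)
  expect_lt(max(abs(rw[rw > 0] - net$params$W_sum)), 1e-9)
  rk <- rowSums(net$synapses$K2)
  expect_lt(max(abs(rk[rk > 0] - net$params$K_sum)), 1e-9)
})

test_that("training is idempotent in the epoch count after normalization", {
  co <- mini_collection()
  a <- train_network(build_network(co, "sequence"), epochs = 2000)
  b <- train_network(build_network(co, "sequence"), epochs = 4000)
  expect_equal(a$synapses$W1, b$synapses$W1, tolerance = 1e-6)
  expect_equal(a$synapses$A2, b$synapses$A2, tolerance = 1e-6)
})

test_that("closed-form training equals iterating the single-epoch rules", {
  co <- generate_collection("orthogonal_fixed", n_objects = 2, sizes = 3,
                            L = 4, M = 4, seed = 9)
  net <- build_network(co, "sequence")
  E <- 50
  tr <- train_network(net, epochs = E)
  p <- net$params
  W <- K <- A <- matrix(0, net$n, net$n)
  for (e in seq_len(E)) for (ob in co$objects) {
    cl <- present_for_training(net, ob)
    W <- hebb_update_W_L1(W, cl, p)
    K <- hebb_update_K(K, cl, "L2", p)
    A <- antihebb_update_A(A, cl, "L2", p)
  }
  expect_equal(normalize_incoming(W, p$W_sum), tr$synapses$W1, tolerance = 1e-6)
  expect_equal(normalize_incoming(K, p$K_sum), tr$synapses$K2, tolerance = 1e-6)
  # train_network additionally restricts A to feature-coding columns
  A[setdiff(seq_len(net$n), unlist(co$objects)), ] <- 0
  nnz <- rowSums(A > 1e-12)
  expect_equal(normalize_incoming(A, p$A_max * nnz), tr$synapses$A2,
               tolerance = 1e-6)
})

test_that("clamped presentation saturates the object and leaves the rest at baseline", {
  net <- mini_seq_net()
  cl <- present_for_training(net, 2)
  ob <- mini_collection()$objects[[2]]
  expect_true(all(cl$L1$z_p[ob] > 4.8))
  expect_true(all(cl$L2$z_f[ob] > 4.8))
  expect_true(all(cl$L1$z_p[-ob] < 0.5))
  expect_true(all(cl$L2$z_f[-ob] < 0.5))
  expect_error(present_for_training(net, integer(0)), "empty")
  expect_error(present_for_training(net, 10 * net$n), "range")
})

test_that("sequence training encodes consecutive pairs and their order", {
  co <- mini_collection()
  net0 <- train_network(build_network(co, "sequence"))
  net <- train_sequence(net0, 1:4)
  W23 <- net$synapses$W23
  for (k in 2:4) {
    pre <- co$objects[[k - 1]]; post <- co$objects[[k]]
    expect_true(all(W23[post, pre] > 0))
  }
  expect_true(all(W23[co$objects[[1]], co$objects[[2]]] == 0)) # no reverse
  # single-item list trains nothing
  expect_true(all(train_sequence(net0, 1)$synapses$W23 == 0))
  expect_error(train_sequence(net0, c(1, 1, 2)), "repeated")
  sem <- train_network(build_network(co, "semantic"))
  expect_error(train_sequence(sem, 1:4), "semantic")
  # shuffling the list permutes the blocks accordingly (equivariance)
  net_r <- train_sequence(net0, c(3, 1, 4, 2))
  W23r <- net_r$synapses$W23
  expect_true(all(W23r[co$objects[[1]], co$objects[[3]]] > 0))
  expect_true(all(W23r[co$objects[[4]], co$objects[[1]]] > 0))
  expect_true(all(W23r[co$objects[[2]], co$objects[[1]]] == 0))
  # two independently trained lists give the union of their blocks
  co2 <- generate_collection("orthogonal_fixed", n_objects = 6, sizes = 5,
                             L = 8, M = 8, seed = 12)
  nn <- train_network(build_network(co2, "sequence"))
  both <- train_sequence(nn, list(1:3, 4:6))
  expect_true(all(both$synapses$W23[co2$objects[[2]], co2$objects[[1]]] > 0))
  expect_true(all(both$synapses$W23[co2$objects[[5]], co2$objects[[4]]] > 0))
  expect_true(all(both$synapses$W23[co2$objects[[4]], co2$objects[[3]]] == 0))
})

test_that("shared features build no fast inhibition onto their own objects", {
  co <- mini_overlap_collection()
  net <- train_network(build_network(co, "sequence"))
  shared <- intersect(co$objects[[2]], co$objects[[4]])
  expect_gt(length(shared), 0)
  others2 <- setdiff(co$objects[[2]], shared)
  others4 <- setdiff(co$objects[[4]], shared)
  expect_true(all(net$synapses$A2[others2, shared] == 0))
  expect_true(all(net$synapses$A2[others4, shared] == 0))
  # but ordinary cross-object inhibition still forms
  expect_true(all(net$synapses$A2[co$objects[[1]], shared] > 0))
})

test_that("single-object collection trains no anti-Hebbian synapses", {
  co <- generate_collection("orthogonal_fixed", n_objects = 1, sizes = 5,
                            L = 6, M = 6, seed = 2)
  net <- train_network(build_network(co, "sequence"))
  expect_true(all(net$synapses$A2 == 0))
  expect_true(all(net$synapses$A3 == 0))
})

test_that("pathological perturbations scale the right quantities and invert", {
  net <- mini_seq_net()
  pc <- apply_pathology(net, "cff_quarter")
  expect_equal(pc$params$C_ff, net$params$C_ff / 4)
  expect_equal(pc$synapses$A2, net$synapses$A2)     # untouched
  pa <- apply_pathology(net, "a_quarter")
  expect_equal(pa$synapses$A2, net$synapses$A2 / 4)
  expect_equal(pa$params$C_ff, net$params$C_ff)
  back <- apply_pathology(pa, "a_quarter", factor = 4)
  expect_lt(max(abs(back$synapses$A3 - net$synapses$A3)), 1e-12)
})
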