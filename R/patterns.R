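#' Generate a collection of binary feature patterns ("objects")
#'
#' Each object is a set of features, one feature per cortical column of the
#' L x M lattice.  Three kinds are supported: \code{"orthogonal_fixed"}
#' (equal sizes, no shared features), \code{"orthogonal_variable"}
#' (different sizes, no shared features), and \code{"overlapping"} (equal
#' sizes with a stated fraction of shared features on designated pairs;
#' by default 20\% shared between objects 2/10 and 4/6).
#'
#' Feature placement is uniformly random over the lattice (positions carry no
#' meaning for the dynamics); with \code{connected = TRUE} each object is
#' grown as a connected blob instead, which is only cosmetic.
#'
#' @param kind one of \code{"orthogonal_fixed"}, \code{"orthogonal_variable"},
#'   \code{"overlapping"}.
#' @param n_objects number of objects (default 9; 10 for overlapping).
#' @param sizes integer vector of object sizes, recycled; defaults: 16 for
#'   fixed/overlapping, 8..24 spread for variable.
#' @param overlap_pairs list of index pairs that share features
#'   (overlapping kind only).
#' @param overlap_frac fraction of features shared within each pair.
#' @param L,M lattice dimensions.
#' @param seed optional integer seed (local to this call).
#' @param connected grow spatially connected objects (visual only).
#' @return A \code{tg_collection}: list with \code{objects} (list of integer
#'   feature-index vectors, 1-based), \code{L}, \code{M}, \code{kind}.
#' @examples
#' co <- generate_collection("orthogonal_variable", seed = 1)
#' overlap_table(co)
#' @export
generate_collection <- function(kind = c("orthogonal_fixed",
                                         "orthogonal_variable",
                                         "overlapping"),
                                n_objects = NULL, sizes = NULL,
                                overlap_pairs = list(c(2, 10), c(4, 6)),
                                overlap_frac = 0.2,
                                L = 20, M = 20, seed = NULL,
                                connected = FALSE) {
  kind <- match.arg(kind)
  if (is.null(n_objects))
    n_objects <- if (kind == "overlapping") 10L else 9L
  stopifnot(n_objects >= 1)
  if (is.null(sizes))
    sizes <- switch(kind,
      orthogonal_fixed = rep(16L, n_objects),
      orthogonal_variable = as.integer(round(seq(8, 24, length.out = n_objects))),
      overlapping = rep(16L, n_objects))
  sizes <- rep_len(as.integer(sizes), n_objects)
  if (any(sizes < 1)) stop("object sizes must be positive")

  n_shared <- 0L
  if (kind != "overlapping") overlap_pairs <- list()
  if (length(overlap_pairs)) {
    ids <- unlist(overlap_pairs)
    if (anyDuplicated(ids) || any(ids > n_objects))
      stop("inconsistent overlap specification")
    n_shared <- as.integer(ceiling(overlap_frac *
                                     min(sizes[unlist(overlap_pairs)])))
  }
  total <- sum(sizes) - n_shared * length(overlap_pairs)
  if (total > L * M)
    stop("requested ", total, " distinct features but the lattice has only ",
         L * M)

  gen <- function() {
    pool <- sample.int(L * M)
    take <- function(k) {
      if (connected) grow_blob(pool, k, L, M)
      else { out <- pool[seq_len(k)]; pool <<- pool[-seq_len(k)]; out }
    }
    if (connected) {
      used <- integer(0)
      take <- function(k) {
        out <- grow_blob(setdiff(seq_len(L * M), used), k, L, M)
        used <<- c(used, out)
        out
      }
    }
    objects <- lapply(sizes, take)
    for (pr in overlap_pairs) {
      a <- pr[1]; b <- pr[2]
      shared <- objects[[a]][seq_len(n_shared)]
      # replace the first n_shared features of b with a's, return b's own
      objects[[b]] <- c(shared, objects[[b]][-seq_len(n_shared)])
    }
    objects
  }
  objects <- if (is.null(seed)) gen() else with_seed(seed, gen)

  structure(list(objects = lapply(objects, sort),
                 ids = seq_len(n_objects),
                 L = as.integer(L), M = as.integer(M), kind = kind),
            class = "tg_collection")
}

# Minimal local-seed helper (keeps the global RNG state untouched).
with_seed <- function(seed, fun) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fun()
}

# Random connected blob of k cells on the L x M grid, restricted to `avail`.
grow_blob <- function(avail, k, L, M) {
  if (length(avail) < k) stop("not enough free lattice cells")
  blob <- sample(avail, 1)
  while (length(blob) < k) {
    frontier <- unique(unlist(lapply(blob, function(i) {
      row <- (i - 1) %% L + 1; col <- (i - 1) %/% L + 1
      nb <- c(if (row > 1) i - 1, if (row < L) i + 1,
              if (col > 1) i - L, if (col < M) i + L)
      nb
    })))
    frontier <- setdiff(intersect(frontier, avail), blob)
    if (!length(frontier)) { # boxed in: restart from scratch
      blob <- sample(avail, 1); next
    }
    blob <- c(blob, sample(frontier, 1))
  }
  blob
}

#' @export
print.tg_collection <- function(x, ...) {
  cat(sprintf("tg_collection: %d objects on a %dx%d lattice (%s)\n",
              length(x$objects), x$L, x$M, x$kind))
  ov <- overlap_table(x)
  n_ov <- sum(ov[upper.tri(ov)] > 0)
  cat(sprintf("  sizes: %s; overlapping pairs: %d\n",
              paste(vapply(x$objects, length, 1L), collapse = ","), n_ov))
  invisible(x)
}

#' Pairwise shared-feature counts
#'
#' @param collection a \code{tg_collection}.
#' @return Symmetric integer matrix of pairwise intersection sizes (diagonal
#'   holds the object sizes).
#' @export
overlap_table <- function(collection) {
  n <- length(collection$objects)
  out <- matrix(0L, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    out[i, j] <- length(intersect(collection$objects[[i]],
                                  collection$objects[[j]]))
  out
}

#' Write / read a collection as structured text (JSON)
#'
#' Lossless round trip; feature indices are stored 1-based.
#'
#' @param collection a \code{tg_collection}.
#' @param path file path.
#' @return \code{read_collection} returns a \code{tg_collection};
#'   \code{write_collection} returns \code{path} invisibly.
#' @export
write_collection <- function(collection, path) {
  stopifnot(inherits(collection, "tg_collection"))
  obj <- list(L = collection$L, M = collection$M, kind = collection$kind,
              indexing = 1L,
              objects = lapply(seq_along(collection$objects), function(i)
                list(id = i, features = collection$objects[[i]])))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_collection
#' @export
read_collection <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop("cannot parse collection file '",
                                           path, "': ", conditionMessage(e)))
  for (f in c("L", "M", "kind", "objects"))
    if (is.null(obj[[f]])) stop("collection file lacks field '", f, "'")
  feats <- obj$objects$features
  if (is.null(feats)) feats <- lapply(obj$objects, `[[`, "features")
  feats <- lapply(feats, as.integer)
  rng <- range(unlist(feats))
  if (rng[1] < 1 || rng[2] > obj$L * obj$M)
    stop("feature index out of range [1, ", obj$L * obj$M, "]")
  if (any(vapply(feats, anyDuplicated, 1L) > 0))
    stop("duplicated feature index within an object")
  structure(list(objects = lapply(feats, sort),
                 ids = seq_along(feats),
                 L = as.integer(obj$L), M = as.integer(obj$M),
                 kind = obj$kind),
            class = "tg_collection")
}

#' Render a collection as character grids
#'
#' One L x M character matrix per object: \code{"#"} marks a feature of the
#' object, \code{"."} an empty cell.
#'
#' @param collection a \code{tg_collection}.
#' @return List of character matrices.
#' @export
render_collection <- function(collection) {
  lapply(collection$objects, function(ft) {
    g <- matrix(".", collection$L, collection$M)
    g[ft] <- "#"
    g
  })
}
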