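# Finite domain structures: a point space plus a set of generating
# transformations, with the transformation group computed by closure.
#
# Conventions (internal, tested in tests/testthat/test-structures.R):
#   * point indices are 0..n-1;
#   * a transformation's mapping is an integer vector m with m[i + 1] = t(i);
#   * composition is right-to-left: (f o g)(i) = f(g(i)).

#' Identity permutation on n points
#' @param n number of points
#' @return integer vector of length `n`, the identity mapping on 0..n-1
#' @keywords internal
perm_identity <- function(n) {
  seq_len(n) - 1L
}

#' Compose two permutations (right-to-left)
#' @param f,g integer mappings on 0..n-1
#' @return the mapping of f o g, i.e. i -> f(g(i))
#' @keywords internal
perm_compose <- function(f, g) {
  f[g + 1L]
}

#' Invert a permutation
#' @param f integer mapping on 0..n-1
#' @keywords internal
perm_inverse <- function(f) {
  order(f) - 1L
}

perm_is_bijection <- function(m, n) {
  length(m) == n && !anyNA(m) && setequal(m, seq_len(n) - 1L)
}

perm_key <- function(m) paste(m, collapse = ",")

#' Create a transformation of a finite point space
#'
#' A transformation is a bijection of the point indices `0..n-1` onto
#' themselves, carried as an index array together with a human-readable label.
#'
#' @param mapping integer vector; `mapping[i + 1]` is the image of point `i`
#' @param label free-text label, e.g. `"reversal"`, `"rotation-half"`
#' @return an object of class `symcat_transformation`
#' @export
transformation <- function(mapping, label = "") {
  mapping <- as.integer(mapping)
  if (!perm_is_bijection(mapping, length(mapping))) {
    stop("`mapping` must be a bijection of 0..n-1 onto itself", call. = FALSE)
  }
  structure(list(mapping = mapping, label = label),
            class = "symcat_transformation")
}

#' @export
print.symcat_transformation <- function(x, ...) {
  cat("<transformation", if (nzchar(x$label)) paste0("'", x$label, "'") else "",
      "on", length(x$mapping), "points>\n")
  invisible(x)
}

new_space <- function(topology, points, adjacency, axis_angles = NULL) {
  stopifnot(topology %in% c("interval", "cycle", "feature"))
  structure(
    list(topology = topology, points = points, adjacency = adjacency,
         axis_angles = axis_angles),
    class = "symcat_space"
  )
}

#' @export
print.symcat_space <- function(x, ...) {
  cat("<space:", x$topology, "topology,", nrow(x$points), "points,",
      nrow(x$adjacency), "edges>\n")
  invisible(x)
}

# Path adjacency on 0..n-1 (edges stored once, i < j, 0-based).
adjacency_path <- function(n) {
  if (n < 2) return(matrix(integer(0), ncol = 2))
  cbind(0:(n - 2L), 1:(n - 1L))
}

# Single-cycle adjacency on 0..n-1.
adjacency_cycle <- function(n) {
  rbind(adjacency_path(n), c(0L, n - 1L))
}

space_n <- function(space) nrow(space$points)

# Neighbour list (1-based list over 0-based indices) used by connectivity
# checks; feature topology has no adjacency and every subset is connected.
space_neighbours <- function(space) {
  n <- space_n(space)
  nb <- vector("list", n)
  adj <- space$adjacency
  if (nrow(adj) > 0) {
    for (r in seq_len(nrow(adj))) {
      i <- adj[r, 1]; j <- adj[r, 2]
      nb[[i + 1L]] <- c(nb[[i + 1L]], j)
      nb[[j + 1L]] <- c(nb[[j + 1L]], i)
    }
  }
  nb
}

#' Construct one of the canonical domain structures
#'
#' Builds a finite discretization of one of the four canonical structures —
#' a space plus the transformation generators acting on it — and computes the
#' full transformation group by closure.
#'
#' \describe{
#'   \item{`linear`}{An unbisected one-dimensional continuum (temperature,
#'     life stages) sampled at `size` points (`size` even, so that no sample
#'     point sits at an accidental centre). Generator: the reversal that
#'     inverts the dimension.}
#'   \item{`bisected_linear`}{A one-dimensional continuum with a privileged
#'     central point that must belong to a category ("today" separating past
#'     from future). `size` must be odd so the centre is a real sample point.
#'     Generator: reversal about the centre.}
#'   \item{`bisected_circular`}{A cycle bisected by a privileged axis
#'     (solstices; east--west). Points are sampled at angles
#'     `(i + 1/2)/size` turns so no sample point lies on the axis or its
#'     perpendicular; the two privileged points are carried as edge markers
#'     (`axis_angles`). Generators: reflection in the privileged axis and
#'     rotation by half a turn.}
#'   \item{`binary_feature`}{A discrete space of `2^size` feature bundles
#'     over `size` binary features (sibling kin types, etc.); no adjacency.
#'     Generators: one value swap per feature.}
#' }
#'
#' @param kind one of `"linear"`, `"bisected_linear"`, `"bisected_circular"`,
#'   `"binary_feature"`
#' @param size number of sample points (linear kinds), or the number of
#'   binary features `k` (so the space has `2^k` points)
#' @param closure_cap passed to [generate_group()]
#' @return an object of class `symcat_structure` with components `kind`,
#'   `resolution`, `space`, `generators`, `group`
#' @examples
#' s <- make_structure("bisected_circular", 8)
#' s$group$order  # 4: reflection, half-turn rotation, their product, identity
#' @export
make_structure <- function(kind = c("linear", "bisected_linear",
                                    "bisected_circular", "binary_feature"),
                           size, closure_cap = 10000L) {
  kind <- match.arg(kind)
  size <- as.integer(size)

  if (kind == "linear") {
    if (size < 2L || size %% 2L != 0L) {
      stop("linear structures require an even size >= 2: an odd sample ",
           "count creates a spurious central fixed point", call. = FALSE)
    }
    points <- tibble::tibble(
      index = 0:(size - 1L),
      coord = (0:(size - 1L)) / (size - 1),
      privileged = FALSE
    )
    space <- new_space("interval", points, adjacency_path(size))
    gens <- list(transformation(rev(0:(size - 1L)), "reversal"))
  } else if (kind == "bisected_linear") {
    if (size < 3L || size %% 2L != 1L) {
      stop("bisected_linear structures require an odd size >= 3 so the ",
           "privileged central point is a sample point", call. = FALSE)
    }
    centre <- (size - 1L) %/% 2L
    points <- tibble::tibble(
      index = 0:(size - 1L),
      coord = (0:(size - 1L)) / (size - 1),
      privileged = (0:(size - 1L)) == centre
    )
    space <- new_space("interval", points, adjacency_path(size))
    gens <- list(transformation(rev(0:(size - 1L)), "reversal"))
  } else if (kind == "bisected_circular") {
    if (size < 4L || size %% 2L != 0L) {
      stop("bisected_circular structures require an even size >= 4 so arcs ",
           "pair up under the half-turn rotation", call. = FALSE)
    }
    # Offset sampling: point i sits at angle (i + 1/2)/size turns, so neither
    # privileged axis endpoint (angles 0 and 1/2) is a sample point; the
    # privileged points are edge markers on the axis.
    points <- tibble::tibble(
      index = 0:(size - 1L),
      coord = ((0:(size - 1L)) + 0.5) / size,
      privileged = FALSE
    )
    space <- new_space("cycle", points, adjacency_cycle(size),
                       axis_angles = c(0, 0.5))
    reflect <- rev(0:(size - 1L))             # angle theta -> -theta
    rotate  <- (0:(size - 1L) + size %/% 2L) %% size
    gens <- list(transformation(reflect, "reflection-axis"),
                 transformation(rotate, "rotation-half"))
  } else { # binary_feature
    k <- size
    if (k < 1L || k > 10L) {
      stop("binary_feature structures support 1 <= k <= 10 features ",
           "(the space has 2^k points)", call. = FALSE)
    }
    n <- bitwShiftL(1L, k)
    bits <- vapply(0:(n - 1L), function(i) {
      paste(rev(as.integer(intToBits(i))[seq_len(k)]), collapse = "")
    }, character(1))
    points <- tibble::tibble(
      index = 0:(n - 1L),
      coord = bits,
      privileged = FALSE
    )
    space <- new_space("feature", points, matrix(integer(0), ncol = 2))
    gens <- lapply(seq_len(k) - 1L, function(j) {
      transformation(bitwXor(0:(n - 1L), bitwShiftL(1L, j)),
                     paste0("swap-feature-", j + 1L))
    })
  }

  group <- generate_group(gens, space_n(space), cap = closure_cap)
  out <- structure(
    list(kind = kind, resolution = size, space = space,
         generators = gens, group = group),
    class = "symcat_structure"
  )
  validate_structure(out)
  out
}

#' @export
print.symcat_structure <- function(x, ...) {
  cat("<structure:", x$kind, "| resolution", x$resolution, "|",
      space_n(x$space), "points | group order", x$group$order, ">\n")
  invisible(x)
}

# Structural invariants: every group element preserves adjacency and fixes
# the privileged point set setwise. Called by make_structure(); also the
# entry point for validating user-defined custom structures.
validate_structure <- function(struct) {
  space <- struct$space
  n <- space_n(space)
  adj <- space$adjacency
  edge_keys <- function(a) {
    paste(pmin(a[, 1], a[, 2]), pmax(a[, 1], a[, 2]), sep = "-")
  }
  ek <- sort(edge_keys(adj))
  priv <- space$points$index[space$points$privileged]
  for (el in struct$group$elements) {
    m <- el$mapping
    if (nrow(adj) > 0) {
      img <- cbind(m[adj[, 1] + 1L], m[adj[, 2] + 1L])
      if (!identical(sort(edge_keys(img)), ek)) {
        stop("group element does not preserve the adjacency relation",
             call. = FALSE)
      }
    }
    if (length(priv) > 0 && !setequal(m[priv + 1L], priv)) {
      stop("group element does not fix the privileged point set",
           call. = FALSE)
    }
  }
  invisible(struct)
}

#' Close a generator set under composition
#'
#' Computes the transformation group generated by a set of bijections of
#' `0..n-1`, by breadth-first closure under composition. Because the
#' generators are permutations of a finite set, the closure automatically
#' contains the identity and all inverses.
#'
#' @param generators list of [transformation()] objects (or bare integer
#'   mappings)
#' @param n number of points
#' @param cap maximum allowed group order; closure beyond this aborts
#'   (guards against malformed custom generator sets)
#' @return an object of class `symcat_group`: list with `elements`
#'   (transformations, identity first), `generators`, and `order`
#' @examples
#' g <- generate_group(list(transformation(c(1, 0, 3, 2))), 4)
#' g$order  # 2
#' @export
generate_group <- function(generators, n, cap = 10000L) {
  n <- as.integer(n)
  gens <- lapply(generators, function(g) {
    if (inherits(g, "symcat_transformation")) g else transformation(g)
  })
  for (g in gens) {
    if (!perm_is_bijection(g$mapping, n)) {
      stop("generator is not a bijection of 0..", n - 1L, call. = FALSE)
    }
  }

  id <- transformation(perm_identity(n), "identity")
  elements <- list(id)
  seen <- new.env(parent = emptyenv())
  assign(perm_key(id$mapping), TRUE, envir = seen)

  frontier <- list(id)
  while (length(frontier) > 0) {
    nxt <- list()
    for (el in frontier) {
      for (g in gens) {
        m <- perm_compose(g$mapping, el$mapping)
        key <- perm_key(m)
        if (!exists(key, envir = seen, inherits = FALSE)) {
          assign(key, TRUE, envir = seen)
          lab <- if (identical(el$label, "identity")) g$label else
            paste(g$label, el$label, sep = " . ")
          t_new <- transformation(m, lab)
          elements <- c(elements, list(t_new))
          nxt <- c(nxt, list(t_new))
          if (length(elements) > cap) {
            stop("group closure exceeded cap of ", cap,
                 " elements; malformed generator set?", call. = FALSE)
          }
        }
      }
    }
    frontier <- nxt
  }

  structure(
    list(elements = elements, generators = gens,
         order = length(elements)),
    class = "symcat_group"
  )
}

#' @export
print.symcat_group <- function(x, ...) {
  cat("<transformation group | order", x$order, "|",
      length(x$generators), "generators>\n")
  invisible(x)
}

#' Build a custom structure from explicit points, adjacency and generators
#'
#' Escape hatch for structures beyond the four canonical kinds: supply the
#' point set, an adjacency relation, optional privileged points, and the
#' generator permutations. The group is closed under composition and the
#' structural invariants (adjacency preservation, privileged set fixed
#' setwise) are enforced.
#'
#' @param n number of points (indexed 0..n-1)
#' @param adjacency two-column matrix of 0-based index pairs (may have zero
#'   rows, giving a feature-like disconnected space)
#' @param generators list of generator mappings or [transformation()]s
#' @param privileged integer vector of privileged point indices
#' @param topology declared topology; checked only in that `interval` must
#'   be a path and `cycle` a single cycle
#' @param closure_cap passed to [generate_group()]
#' @return a `symcat_structure` of kind `"custom"`
#' @export
custom_structure <- function(n, adjacency, generators,
                             privileged = integer(0),
                             topology = c("feature", "interval", "cycle"),
                             closure_cap = 10000L) {
  topology <- match.arg(topology)
  n <- as.integer(n)
  adjacency <- matrix(as.integer(adjacency), ncol = 2)
  if (nrow(adjacency) > 0 &&
      (min(adjacency) < 0 || max(adjacency) > n - 1L)) {
    stop("adjacency refers to point indices outside 0..n-1", call. = FALSE)
  }
  degs <- tabulate(adjacency + 1L, nbins = n)
  if (topology == "interval" &&
      !(sum(degs == 1L) == 2L && all(degs <= 2L) &&
        nrow(adjacency) == n - 1L)) {
    stop("interval topology requires the adjacency to be a path",
         call. = FALSE)
  }
  if (topology == "cycle" &&
      !(all(degs == 2L) && nrow(adjacency) == n)) {
    stop("cycle topology requires the adjacency to be a single cycle",
         call. = FALSE)
  }
  points <- tibble::tibble(
    index = 0:(n - 1L),
    coord = (0:(n - 1L)) / max(1L, n - 1L),
    privileged = (0:(n - 1L)) %in% privileged
  )
  space <- new_space(topology, points, adjacency)
  gens <- lapply(generators, function(g) {
    if (inherits(g, "symcat_transformation")) g else transformation(g)
  })
  group <- generate_group(gens, n, cap = closure_cap)
  out <- structure(
    list(kind = "custom", resolution = n, space = space,
         generators = gens, group = group),
    class = "symcat_structure"
  )
  validate_structure(out)
  out
}

#' Read a custom structure declaration from a JSON document
#'
#' The document lists `n`, `adjacency` (array of index pairs), `generators`
#' (array of permutations as index arrays), and optionally `privileged` and
#' `topology`; see [custom_structure()].
#'
#' @param path path to a JSON file
#' @return a `symcat_structure`
#' @export
read_structure_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  adjacency <- if (is.null(doc$adjacency) || length(doc$adjacency) == 0) {
    matrix(integer(0), ncol = 2)
  } else {
    matrix(as.integer(as.matrix(doc$adjacency)), ncol = 2)
  }
  gens <- if (is.matrix(doc$generators)) {
    lapply(seq_len(nrow(doc$generators)), function(i) doc$generators[i, ])
  } else {
    doc$generators
  }
  custom_structure(
    n = doc$n,
    adjacency = adjacency,
    generators = gens,
    privileged = if (is.null(doc$privileged)) integer(0) else doc$privileged,
    topology = if (is.null(doc$topology)) "feature" else doc$topology
  )
}
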