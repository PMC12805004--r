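test_that("is_connected follows the adjacency relation of each topology", {
  lin6 <- make_structure("linear", 6)
  expect_false(is_connected(c(0, 5), lin6$space))  # both ends, no middle
  expect_true(is_connected(3, lin6$space))
  expect_true(is_connected(c(1, 2, 3), lin6$space))

  bc8 <- make_structure("bisected_circular", 8)
  expect_true(is_connected(c(7, 0, 1), bc8$space))  # wrap-around arc
  expect_false(is_connected(c(0, 4), bc8$space))

  bf3 <- make_structure("binary_feature", 3)
  expect_true(is_connected(c(0, 7), bf3$space))  # vacuous for feature spaces

  expect_error(is_connected(integer(0), lin6$space), "nonempty")
  expect_error(is_connected(c(0, 99), lin6$space), "subset")
})

test_that("is_symmetric implements the same-category relation invariance", {
  bl5 <- make_structure("bisected_linear", 5)
  # mirror split with the centre in the left block: centre is fixed by the
  # reversal but its co-members map across the cut
  expect_false(is_symmetric(category_system(c(1, 1, 1, 2, 2)), bl5))
  # palindromic (1, 3, 1) system
  expect_true(is_symmetric(category_system(c(1, 2, 2, 2, 3)), bl5))
  # one-block system is symmetric on any structure
  expect_true(is_symmetric(category_system(rep(1, 5)), bl5))

  expect_error(
    is_symmetric(category_system(c(1, 2)), bl5),
    "different numbers of points"
  )
})

test_that("induced_block_permutation returns block images or failure", {
  bc8 <- make_structure("bisected_circular", 8)
  rot <- bc8$generators[[2]]
  # Western-seasons style four arcs: rotation pairs opposite arcs (2-cycles)
  seasons <- category_system(c(1, 1, 2, 2, 3, 3, 4, 4))
  res <- induced_block_permutation(seasons, rot)
  expect_true(res$success)
  expect_equal(res$permutation, c(3, 4, 1, 2))

  lin4 <- make_structure("linear", 4)
  reversal <- lin4$generators[[1]]
  # asymmetric (3, 1) split: the image of the 3-block is not a block
  expect_false(induced_block_permutation(
    category_system(c(1, 1, 1, 2)), reversal)$success)
  # symmetric (1, 2, 1): outer blocks swap, the middle is fixed
  res2 <- induced_block_permutation(category_system(c(1, 2, 2, 3)), reversal)
  expect_true(res2$success)
  expect_equal(res2$permutation, c(3, 2, 1))
})

test_that("connected-partition counts match closed forms and the brute-force oracle", {
  lin4 <- make_structure("linear", 4)
  expect_length(enumerate_connected_partitions(lin4), 8)  # 2^(n-1)

  bc4 <- make_structure("bisected_circular", 4)
  expect_length(enumerate_connected_partitions(bc4), 12)  # 1 + sum C(4,k)

  bf2 <- make_structure("binary_feature", 2)
  expect_length(enumerate_connected_partitions(bf2), 15)  # Bell(4)

  # against the independent set-partition filter, as relations
  for (struct in list(lin4, bc4, make_structure("linear", 6),
                      make_structure("bisected_circular", 6))) {
    got <- sort(vapply(enumerate_connected_partitions(struct),
                       function(s) paste(s$assignment, collapse = ","),
                       character(1)))
    want <- sort(vapply(oracle_connected_partitions(struct),
                        function(a) paste(a, collapse = ","), character(1)))
    expect_equal(got, want)
  }

  # max_size truncates by block count
  expect_length(enumerate_connected_partitions(lin4, max_size = 2), 4)
})

test_that("symmetric-system inventories match brute force on the canonical structures", {
  lin4 <- make_structure("linear", 4)
  expect_equal(system_sizes(enumerate_symmetric_systems(lin4)), c(1, 2, 3, 4))

  bl5 <- make_structure("bisected_linear", 5)
  expect_equal(system_sizes(enumerate_symmetric_systems(bl5)), c(1, 3, 3, 5))

  bf2 <- make_structure("binary_feature", 2)
  sizes <- system_sizes(enumerate_symmetric_systems(bf2))
  expect_equal(sizes, c(1, 2, 2, 2, 4))  # three 2-systems, never 3
  expect_false(3 %in% sizes)
})

test_that("symmetric systems on the linear structure are the palindromic compositions", {
  for (n in c(4L, 6L, 8L)) {
    struct <- make_structure("linear", n)
    syms <- enumerate_symmetric_systems(struct)
    # composition of each system read left to right along the path
    comps <- lapply(syms, function(s) as.integer(rle(s$assignment)$lengths))
    keys <- sort(vapply(comps, paste, character(1), collapse = ","))
    want <- sort(vapply(oracle_palindromic_compositions(n), paste,
                        character(1), collapse = ","))
    expect_equal(keys, want)
  }
})

test_that("the half-turn rotation acts as a fixed-point-free involution on blocks", {
  for (n in c(4L, 8L, 12L)) {
    struct <- make_structure("bisected_circular", n)
    rot <- struct$generators[[2]]
    syms <- enumerate_symmetric_systems(struct)
    for (s in syms) {
      if (s$size == 1L) next
      res <- induced_block_permutation(s, rot)
      expect_true(res$success)
      expect_true(all(res$permutation != seq_along(res$permutation)))
      p2 <- res$permutation[res$permutation]
      expect_equal(p2, seq_along(res$permutation))
    }
  }
})

test_that("parity verdicts reproduce the theorem table for all four structures", {
  expect_equal(classify_parity("linear", c(4, 6, 8))$verdict, "both")
  expect_equal(classify_parity("bisected_linear", c(5, 7, 9))$verdict, "odd")
  expect_equal(classify_parity("bisected_circular", c(8, 12))$verdict, "even")
  expect_equal(classify_parity("binary_feature", c(2, 3))$verdict, "even")
  # defaults agree
  expect_equal(classify_parity("bisected_linear")$verdict, "odd")
})

test_that("parity verdicts exclude the trivial system and carry witnesses", {
  v <- classify_parity("bisected_circular", c(4, 8))
  expect_true(v$trivial_excluded)
  expect_equal(v$parities_attested, "even")
  expect_equal(v$witnesses$even$size, 2)  # smallest nontrivial witness

  v2 <- classify_parity("linear", c(4, 6))
  expect_setequal(v2$parities_attested, c("odd", "even"))
  expect_equal(v2$witnesses$odd$size, 3)
  expect_equal(v2$witnesses$even$size, 2)
})

test_that("category systems support holes with an invariant unassigned set", {
  bl5 <- make_structure("bisected_linear", 5)
  # labels at hole positions are ignored; the endpoint hole pair is
  # reversal-invariant so the remaining (3)-system stays symmetric
  sys <- category_system(c(9, 1, 1, 1, 9), holes = c(0, 4))
  expect_equal(sys$size, 1)
  expect_true(is_symmetric(sys, bl5))
  # an asymmetric hole set breaks symmetry
  sys2 <- category_system(c(9, 1, 1, 1, 1), holes = 0)
  expect_false(is_symmetric(sys2, bl5))
})

test_that("verdict JSON export carries witnesses as block lists", {
  v <- classify_parity("binary_feature", c(2, 3))
  path <- withr::local_tempfile(fileext = ".json")
  parity_verdict_json(v, path)
  back <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  expect_equal(back$verdict, "even")
  expect_equal(back$witnesses$even$size, 2)
  expect_length(back$witnesses$even$blocks, 2)
})
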