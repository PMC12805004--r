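write_records_csv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  writeLines(c("language,glottocode,family,domain,size", lines), path)
  path
}

test_that("system records read, validate and flag missing glottocodes", {
  path <- write_records_csv(c(
    "Alpha,alph1234,FamA,seasons,4",
    "Beta,beta1234,FamA,seasons,3",
    "Gamma,gamm1234,FamB,seasons,2"
  ))
  recs <- read_system_records(path)
  expect_equal(nrow(recs), 3)
  expect_equal(recs$parity, c("even", "odd", "even"))
  expect_false(any(recs$excluded_from_regression))

  bad <- write_records_csv("Alpha,alph1234,FamA,seasons,4.5")
  expect_error(read_system_records(bad), "row")

  nocode <- write_records_csv(c(
    "Alpha,alph1234,FamA,seasons,4",
    "Natleba,,FamB,seasons,5"
  ))
  recs2 <- read_system_records(nocode)
  expect_equal(nrow(recs2), 2)  # retained ...
  expect_equal(recs2$excluded_from_regression, c(FALSE, TRUE))  # ... flagged

  missingcol <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("language,size", "Alpha,4"), missingcol)
  expect_error(read_system_records(missingcol), "missing required column")
})

test_that("glottocode dedupe keeps the record contradicting the predicted parity", {
  recs <- tibble::tibble(
    language = c("A1", "A2", "B"),
    glottocode = c("waja1257", "waja1257", "bbbb1234"),
    family = "Fam", domain = "cardinal",
    size = c(4L, 3L, 4L)
  )
  out <- dedupe_by_glottocode(recs, "even")
  expect_equal(nrow(out), 2)
  expect_equal(out$size[out$glottocode == "waja1257"], 3)  # odd kept

  out_odd <- dedupe_by_glottocode(recs, "odd")
  expect_equal(out_odd$size[out_odd$glottocode == "waja1257"], 4)

  # agreeing parities: first record kept
  agree <- tibble::tibble(
    language = c("A1", "A2"), glottocode = "cccc1234",
    family = "Fam", domain = "seasons", size = c(2L, 4L)
  )
  kept <- dedupe_by_glottocode(agree, "even")
  expect_equal(nrow(kept), 1)
  expect_equal(kept$size, 2)

  # no duplicates: unchanged
  solo <- tibble::tibble(language = "A", glottocode = "dddd1234",
                         family = "F", domain = "d", size = 3L)
  expect_equal(nrow(dedupe_by_glottocode(solo, "even")), 1)

  # mixed parities without a predicted parity warns and keeps the first
  expect_warning(dedupe_by_glottocode(recs, "none"), "keeping the first")
})

test_that("dedupe matches independent per-glottocode selection on random fixtures", {
  set.seed(71)
  for (rep in 1:20) {
    n <- sample(5:25, 1)
    recs <- tibble::tibble(
      language = sprintf("lang%02d", seq_len(n)),
      glottocode = sprintf("gc%02d0000", sample.int(max(2, n %/% 2), n,
                                                    replace = TRUE)),
      family = "Fam", domain = "d",
      size = sample(1:9, n, replace = TRUE)
    )
    predicted <- sample(c("odd", "even"), 1)
    got <- dedupe_by_glottocode(recs, predicted)
    want <- oracle_dedupe(as.data.frame(recs), predicted)
    expect_equal(got$language, want$language)
    expect_equal(got$size, want$size)
    # parity summaries agree too
    expect_equal(parity_summary(got)$n_odd, sum(want$size %% 2 == 1))
  }
})

test_that("largest_per_language keeps the single largest system, ties first", {
  recs <- tibble::tibble(
    language = c("Alyawarr", "Alyawarr", "Alyawarr", "Kariera", "Tie", "Tie"),
    glottocode = c("alya1234", "alya1234", "alya1234", "kari1234",
                   "tiee1234", "tiee1234"),
    family = "PamaNyungan", domain = "social",
    size = c(4L, 4L, 8L, 4L, 4L, 4L),
    source = c("s1", "s2", "s3", "s1", "first", "second")
  )
  out <- largest_per_language(recs)
  expect_equal(nrow(out), 3)
  expect_equal(out$size[out$language == "Alyawarr"], 8)
  expect_equal(out$source[out$language == "Tie"], "first")
  expect_equal(nrow(largest_per_language(recs[4, ])), 1)
})

test_that("colour consensus counting applies the inclusive threshold", {
  # 10 participants; a term used by exactly 6 on one chip counts at 0.6
  naming <- tibble::tibble(
    participant = sprintf("p%02d", 1:10),
    chip = "chip001",
    term = c(rep("red", 6), rep("other", 4))
  )
  expect_equal(count_color_terms(naming, 0.6), 1)  # boundary inclusive
  naming5 <- naming
  naming5$term <- c(rep("red", 5), rep("blue", 5))
  expect_equal(count_color_terms(naming5, 0.6), 0)

  # planted consensus matrix recovers its ground truth
  mat <- simulate_color_matrix(n_participants = 10, n_chips = 20,
                               n_consensus_terms = 4, seed = 5)
  expect_equal(count_color_terms(mat, 0.6), 4)

  expect_error(count_color_terms(naming[0, ], 0.6), "empty")
  dup <- rbind(naming, naming[1, ])
  expect_error(count_color_terms(dup, 0.6), "at most one term")
})

test_that("colour counts are order-invariant and monotone in the threshold", {
  mat <- simulate_color_matrix(n_participants = 12, n_chips = 15,
                               n_consensus_terms = 3, seed = 9)
  base <- count_color_terms(mat, 0.6)
  shuffled <- mat[rev(seq_len(nrow(mat))), ]
  expect_equal(count_color_terms(shuffled, 0.6), base)

  thresholds <- c(0.2, 0.4, 0.6, 0.8, 1.0)
  counts <- vapply(thresholds, function(th) count_color_terms(mat, th),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("parity summaries report histograms, counts and the powers-of-two flag", {
  s <- parity_summary(c(2L, 4L, 8L, 4L))
  expect_equal(s$n_even, 4)
  expect_equal(s$n_odd, 0)
  expect_true(s$all_powers_of_two)
  expect_equal(s$size_histogram, c("2" = 1L, "4" = 2L, "8" = 1L))

  s2 <- parity_summary(c(3L, 5L))
  expect_equal(s2$n_odd, 2)
  expect_false(s2$all_powers_of_two)

  s3 <- parity_summary(1L)  # 1 = 2^0: documented corner case
  expect_equal(s3$n_odd, 1)
  expect_true(s3$all_powers_of_two)

  expect_error(parity_summary(integer(0)), "no records")
  expect_equal(s$n_odd + s$n_even, sum(s$size_histogram))
})

test_that("parity counts are invariant under record permutation", {
  set.seed(13)
  sizes <- sample(1:9, 40, replace = TRUE)
  s1 <- parity_summary(sizes)
  s2 <- parity_summary(sample(sizes))
  expect_equal(s1$n_odd, s2$n_odd)
  expect_equal(s1$size_histogram, s2$size_histogram)
})
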