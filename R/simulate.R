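# Synthetic cross-linguistic data: surveys of category-system records with
# languages nested in families and a logit-scale parity preference, plus
# kin-term tables and colour matrices, so the full pipeline runs and is
# testable without any field-data download.

#' Configuration for a synthetic cross-linguistic survey
#'
#' The generator draws, for each language, an even/odd parity from a
#' hierarchical logistic model — `logit(theta_even)` plus a family-level and
#' a language-level normal deviation — and then a system size from a
#' sawtooth weight map matched to the drawn parity (probability mass
#' alternating between adjacent odd and even sizes, the signature shape of a
#' parity-preferring domain).
#'
#' @param n_families number of language families
#' @param languages_per_family languages in each family: a single count, or
#'   a vector of length `n_families` (an over-dispersed profile mimics real
#'   surveys, which are typically dominated by one large family)
#' @param theta_even marginal probability that a system is even, in (0, 1)
#' @param sigma_family,sigma_language logit-scale SDs of the family and
#'   language deviations
#' @param even_size_weights named numeric vector: probabilities over even
#'   sizes (names are sizes; must sum to 1)
#' @param odd_size_weights named numeric vector over odd sizes
#' @param duplicates_per_language records per language (>= 1; duplicates
#'   share the language's deviation, mimicking multiple sources)
#' @param domain domain label stamped on the records
#' @param seed integer seed; the generator is a pure function of it
#' @return an object of class `symcat_survey_config`
#' @export
survey_sim_config <- function(n_families = 30L,
                              languages_per_family = 5L,
                              theta_even = 0.7,
                              sigma_family = 0.5,
                              sigma_language = 0,
                              even_size_weights = c("2" = 0.25, "4" = 0.5,
                                                    "6" = 0.2, "8" = 0.05),
                              odd_size_weights = c("3" = 0.3, "5" = 0.45,
                                                   "7" = 0.2, "9" = 0.05),
                              duplicates_per_language = 1L,
                              domain = "synthetic",
                              seed = 1L) {
  check_weights <- function(w, par, lab) {
    sizes <- as.integer(names(w))
    if (anyNA(sizes) || any(sizes %% 2L != par)) {
      stop("`", lab, "` must be named by ",
           if (par == 0L) "even" else "odd", " sizes", call. = FALSE)
    }
    if (abs(sum(w) - 1) > 1e-8 || any(w < 0)) {
      stop("`", lab, "` must be nonnegative and sum to 1", call. = FALSE)
    }
  }
  check_weights(even_size_weights, 0L, "even_size_weights")
  check_weights(odd_size_weights, 1L, "odd_size_weights")
  if (!(theta_even > 0 && theta_even < 1)) {
    stop("`theta_even` must be in (0, 1)", call. = FALSE)
  }
  n_families <- as.integer(n_families)
  lpf <- as.integer(languages_per_family)
  if (length(lpf) == 1L) lpf <- rep(lpf, n_families)
  if (length(lpf) != n_families || any(lpf < 1L)) {
    stop("`languages_per_family` must be a count or a vector of length ",
         "`n_families`", call. = FALSE)
  }
  stopifnot(sigma_family >= 0, sigma_language >= 0,
            duplicates_per_language >= 1L)
  structure(
    list(n_families = n_families, languages_per_family = lpf,
         theta_even = theta_even, sigma_family = sigma_family,
         sigma_language = sigma_language,
         even_size_weights = even_size_weights,
         odd_size_weights = odd_size_weights,
         duplicates_per_language = as.integer(duplicates_per_language),
         domain = domain, seed = as.integer(seed)),
    class = "symcat_survey_config"
  )
}

#' Draw system sizes of a given parity from a weight map
#'
#' @param n number of draws
#' @param parity `"odd"` or `"even"`
#' @param weights named numeric vector of probabilities over sizes of the
#'   requested parity (names are sizes, values sum to 1)
#' @return integer vector of sizes, all of the requested parity
#' @export
simulate_sizes <- function(n, parity = c("odd", "even"), weights) {
  parity <- match.arg(parity)
  sizes <- as.integer(names(weights))
  want <- if (parity == "even") 0L else 1L
  if (anyNA(sizes) || any(sizes %% 2L != want)) {
    stop("`weights` must be named by ", parity, " sizes", call. = FALSE)
  }
  if (abs(sum(weights) - 1) > 1e-8 || any(weights < 0)) {
    stop("`weights` must be nonnegative and sum to 1", call. = FALSE)
  }
  sample(sizes, n, replace = TRUE, prob = weights)
}

#' Generate a synthetic cross-linguistic survey
#'
#' Emits one system record per language x duplicate: parity drawn
#' `Bernoulli(plogis(qlogis(theta_even) + family deviation + language
#' deviation))`, size drawn from the parity-matched weight map. Output is
#' byte-identical for identical configs (the seed is part of the config).
#'
#' @param config a [survey_sim_config()]
#' @return a system-record tibble (see [validate_system_records()]) with
#'   columns `language`, `glottocode`, `family`, `domain`, `size`,
#'   `source`, `parity`, `excluded_from_regression`
#' @export
simulate_survey <- function(config) {
  stopifnot(inherits(config, "symcat_survey_config"))
  set.seed(config$seed)
  base <- stats::qlogis(config$theta_even)

  rows <- list()
  lang_id <- 0L
  for (f in seq_len(config$n_families)) {
    u <- stats::rnorm(1, 0, config$sigma_family)
    for (l in seq_len(config$languages_per_family[f])) {
      lang_id <- lang_id + 1L
      v <- stats::rnorm(1, 0, config$sigma_language)
      p <- stats::plogis(base + u + v)
      for (d in seq_len(config$duplicates_per_language)) {
        even <- stats::rbinom(1, 1, p) == 1L
        size <- if (even) {
          simulate_sizes(1, "even", config$even_size_weights)
        } else {
          simulate_sizes(1, "odd", config$odd_size_weights)
        }
        rows[[length(rows) + 1L]] <- tibble::tibble(
          language = sprintf("lang%04d", lang_id),
          glottocode = sprintf("syn%04d1234", lang_id),
          family = sprintf("family%02d", f),
          domain = config$domain,
          size = size,
          source = sprintf("simulated-source-%d", d)
        )
      }
    }
  }
  validate_system_records(dplyr::bind_rows(rows))
}

#' Named domain presets for the survey generator
#'
#' Qualitative presets for the kinds of size distributions seen across
#' domains: `day_names` (odd-preferring, modal size 5 — two days either
#' side of 'today'), `seasons` (even-preferring, modal size 4),
#' `kinship` (even-preferring, modal sizes 2 and 4), and `balanced`
#' (no preference). These are test fixtures shaped on qualitative
#' descriptions, not estimates fitted to archived field data.
#'
#' @param preset preset name
#' @param ... overrides passed on to [survey_sim_config()]
#' @return a [survey_sim_config()]
#' @export
survey_preset <- function(preset = c("day_names", "seasons", "kinship",
                                     "balanced"), ...) {
  preset <- match.arg(preset)
  args <- switch(preset,
    day_names = list(
      theta_even = 0.15,
      odd_size_weights = c("3" = 0.3, "5" = 0.45, "7" = 0.2, "9" = 0.05),
      even_size_weights = c("2" = 0.2, "4" = 0.45, "6" = 0.25, "8" = 0.1),
      domain = "day_names"
    ),
    seasons = list(
      theta_even = 0.85,
      even_size_weights = c("2" = 0.3, "4" = 0.5, "6" = 0.15, "8" = 0.05),
      odd_size_weights = c("3" = 0.5, "5" = 0.35, "7" = 0.15),
      domain = "seasons"
    ),
    kinship = list(
      theta_even = 0.8,
      even_size_weights = c("2" = 0.45, "4" = 0.4, "6" = 0.1, "8" = 0.05),
      odd_size_weights = c("3" = 0.6, "5" = 0.3, "7" = 0.1),
      domain = "kinship"
    ),
    balanced = list(theta_even = 0.5, domain = "balanced")
  )
  do.call(survey_sim_config, utils::modifyList(args, list(...)))
}

#' Generate a synthetic kin-term extension table
#'
#' Given a target partition of a kin-type inventory into categories, emits
#' `n_synonyms` terms per category, each term's extension being exactly its
#' category's block; [extract_category_system()] on the output recovers the
#' number of blocks by construction.
#'
#' @param partition named list of character vectors: each element is one
#'   category's block of kin codes; blocks must be nonempty and disjoint
#' @param n_synonyms terms per category (>= 1)
#' @param language language label for the emitted rows
#' @param seed seed controlling term-name shuffling (output row order is
#'   deterministic given the seed)
#' @return tibble with columns `language`, `glottocode`, `term`, `kin_type`
#'   (one row per term x kin-type pair)
#' @export
simulate_kin_table <- function(partition, n_synonyms = 1L,
                               language = "synthlang", seed = 1L) {
  if (length(partition) == 0) stop("`partition` must be nonempty",
                                   call. = FALSE)
  blocks <- lapply(partition, as.character)
  if (any(lengths(blocks) == 0)) {
    stop("partition blocks must be nonempty", call. = FALSE)
  }
  all_types <- unlist(blocks)
  if (anyDuplicated(all_types)) {
    stop("partition blocks must be disjoint", call. = FALSE)
  }
  set.seed(seed)
  labels <- names(partition) %||% paste0("cat", seq_along(blocks))
  rows <- lapply(seq_along(blocks), function(b) {
    terms <- sprintf("%s_t%d", labels[b], seq_len(n_synonyms))
    tibble::tibble(
      language = language,
      glottocode = "synt1234",
      term = rep(terms, each = length(blocks[[b]])),
      kin_type = rep(blocks[[b]], times = n_synonyms)
    )
  })
  out <- dplyr::bind_rows(rows)
  out[sample.int(nrow(out)), , drop = FALSE]
}

#' Generate a synthetic colour-naming matrix with planted consensus terms
#'
#' Builds a participant x chip term table in which exactly
#' `n_consensus_terms` terms reach the consensus threshold on at least one
#' chip, and every other term stays strictly below it on every chip; used
#' to exercise [count_color_terms()] with a known ground truth.
#'
#' @param n_participants number of participants (>= 5)
#' @param n_chips number of chips; must be at least
#'   `n_consensus_terms + 1`
#' @param n_consensus_terms number of terms planted at or above threshold
#' @param threshold the consensus fraction the planted terms meet
#' @param seed seed
#' @return tibble with columns `participant`, `chip`, `term`
#' @export
simulate_color_matrix <- function(n_participants = 10L, n_chips = 20L,
                                  n_consensus_terms = 4L, threshold = 0.6,
                                  seed = 1L) {
  stopifnot(n_participants >= 5L, n_chips >= n_consensus_terms + 1L)
  need <- ceiling(threshold * n_participants)
  if (need < 2L) stop("threshold too low: every term would reach consensus",
                      call. = FALSE)
  set.seed(seed)
  grid <- expand.grid(participant = sprintf("p%02d", seq_len(n_participants)),
                      chip = sprintf("chip%03d", seq_len(n_chips)),
                      stringsAsFactors = FALSE)
  # noise terms assigned cyclically so no noise term is used by more than
  # `need - 1` participants on any chip
  n_groups <- ceiling(n_participants / (need - 1L))
  pid <- as.integer(sub("^p", "", grid$participant))
  grid$term <- sprintf("noise%02d", (pid - 1L) %% n_groups + 1L)
  # plant each consensus term on its own chip for exactly `need` users
  for (k in seq_len(n_consensus_terms)) {
    idx <- which(grid$chip == sprintf("chip%03d", k))
    grid$term[idx[seq_len(need)]] <- sprintf("consensus%02d", k)
  }
  # shuffle row order (the counting rule must not depend on it)
  grid <- grid[sample.int(nrow(grid)), , drop = FALSE]
  tibble::as_tibble(grid)
}
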