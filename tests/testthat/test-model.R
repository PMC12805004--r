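test_that("dataset and config constructors enforce their invariants", {
  expect_error(parity_dataset(c(0, 2), family = c("a", "b")), "binary")
  expect_error(parity_dataset(c(0, 1), family = "a"), "equal length")
  expect_error(sampler_config(chains = 1), "chains")
  expect_error(sampler_config(iterations = 100, warmup = 100), "warmup")
  expect_error(prior_spec(sd_scale = -1), "sd_scale > 0")
  expect_error(
    fit_parity_model(parity_dataset(1L, family = "a")),
    "degenerate"
  )
})

test_that("maximally even data force the credible interval above 0.5", {
  d <- parity_dataset(rep(1L, 100),
                      family = rep(sprintf("f%02d", 1:10), each = 10))
  f <- suppressWarnings(
    fit_parity_model(d, config = sampler_config(iterations = 2000,
                                                warmup = 1000, seed = 7)))
  expect_gt(f$ci95[1], 0.5)
  expect_equal(classify_preference(f$ci95), "even_preferring")
})

test_that("balanced data leave the credible interval straddling 0.5", {
  d <- parity_dataset(rep(c(0L, 1L), 50),
                      family = rep(sprintf("f%02d", 1:10), each = 10))
  f <- fit_parity_model(d, config = sampler_config(iterations = 2000,
                                                   warmup = 1000, seed = 7))
  expect_lt(f$ci95[1], 0.5)
  expect_gt(f$ci95[2], 0.5)
  expect_lt(abs(f$prob_even_mean - 0.5), 0.1)
})

test_that("with one family and shrunk group SDs the posterior matches the Beta posterior", {
  set.seed(20)
  y <- rbinom(200, 1, 0.65)
  d <- parity_dataset(y, family = rep("only", 200))
  f <- fit_parity_model(
    d,
    priors = prior_spec(sd_scale = 1e-6),
    config = sampler_config(iterations = 3000, warmup = 1500, seed = 8)
  )
  # flat-ish t prior on the logit ~ uniform-ish on p: Beta(y+1, n-y+1)
  beta_mean <- (sum(y) + 1) / (length(y) + 2)
  expect_lt(abs(f$prob_even_mean - beta_mean), 0.03)
})

test_that("relabelling families leaves the posterior draws identical", {
  set.seed(30)
  y <- rbinom(60, 1, 0.7)
  fam <- rep(sprintf("f%02d", 1:12), each = 5)
  cfg <- sampler_config(iterations = 1200, warmup = 600, seed = 10)
  f1 <- suppressWarnings(fit_parity_model(parity_dataset(y, fam),
                                          config = cfg))
  # bijective relabelling (reverse the name map), same grouping structure
  relabel <- setNames(sprintf("g%02d", 12:1), sprintf("f%02d", 1:12))
  f2 <- suppressWarnings(fit_parity_model(parity_dataset(y, relabel[fam]),
                                          config = cfg))
  expect_identical(f1$draws$p_even, f2$draws$p_even)
})

test_that("duplicate languages require (and get) a language random intercept", {
  y <- rep(c(0L, 1L), 30)
  fam <- rep(sprintf("f%02d", 1:6), each = 10)
  lang <- rep(sprintf("l%02d", 1:30), each = 2)  # two sources per language
  d <- parity_dataset(y, fam, lang)
  expect_error(fit_parity_model(d, language_effects = FALSE),
               "language random")
  f <- suppressWarnings(
    fit_parity_model(d, config = sampler_config(iterations = 1200,
                                                warmup = 600, seed = 4)))
  expect_true(f$language_effects)
  expect_true("sigma_language" %in% names(f$draws))
  expect_true("sigma_language" %in% names(f$rhat))
})

test_that("prob_even applies the logistic transform to the intercept draws", {
  skeleton <- suppressWarnings(fit_parity_model(
    parity_dataset(rep(c(0L, 1L), 20), family = rep(c("a", "b"), 20)),
    config = sampler_config(iterations = 600, warmup = 300, seed = 2)
  ))
  with_alpha <- function(alpha) {
    f <- skeleton
    f$draws <- data.frame(alpha = alpha, p_even = plogis(alpha))
    f$prob_even_mean <- mean(f$draws$p_even)
    f$ci95 <- unname(quantile(f$draws$p_even, c(0.025, 0.975)))
    f
  }
  # alpha draws all zero -> estimate exactly 0.5
  pe <- prob_even(with_alpha(rep(0, 100)))
  expect_equal(pe$estimate, 0.5)
  expect_equal(pe$ci95, c(0.5, 0.5))

  # very large alpha draws -> estimate approaches 1
  expect_gt(prob_even(with_alpha(rep(50, 100)))$estimate, 0.999)

  # standard-normal alpha draws -> interval ~ plogis(+-1.96) by
  # equivariance of quantiles under monotone maps
  set.seed(40)
  pe2 <- prob_even(with_alpha(rnorm(40000)))
  expect_lt(abs(pe2$ci95[1] - plogis(-1.96)), 0.01)
  expect_lt(abs(pe2$ci95[2] - plogis(1.96)), 0.01)
})

test_that("the preference rule reads the interval position against 0.5", {
  expect_equal(classify_preference(c(0.2, 0.4)), "odd_preferring")
  expect_equal(classify_preference(c(0.6, 0.9)), "even_preferring")
  expect_equal(classify_preference(c(0.45, 0.7)), "inconclusive")
  expect_error(classify_preference(c(0.7, 0.2)), "lower <= upper")
  expect_error(classify_preference(c(0, 0.5)), "lower")
})

test_that("shifting an interval upward never moves the verdict towards odd", {
  rank_of <- c(odd_preferring = 1, inconclusive = 2, even_preferring = 3)
  set.seed(50)
  for (i in 1:200) {
    lo <- runif(1, 0.01, 0.9)
    hi <- runif(1, lo, 0.95)
    shift <- runif(1, 0, 0.98 - hi)
    v1 <- rank_of[classify_preference(c(lo, hi))]
    v2 <- rank_of[classify_preference(c(lo + shift, hi + shift))]
    expect_gte(v2, v1)
  }
})

test_that("the frequentist analogue reports proportions, Wald intervals and separation", {
  d <- parity_dataset(c(rep(1L, 30), rep(0L, 10)), family = rep("f", 40))
  g <- fit_parity_glm(d)
  expect_equal(g$estimate, 0.75, tolerance = 1e-6)
  expect_false(g$separation)
  expect_true(g$ci95[1] < 0.75 && g$ci95[2] > 0.75)

  d2 <- parity_dataset(rep(c(1L, 0L), 20), family = rep("f", 40))
  g2 <- fit_parity_glm(d2)
  expect_equal(g2$estimate, 0.5, tolerance = 1e-6)
  expect_equal(g2$ci95[1] + g2$ci95[2], 1, tolerance = 1e-6)  # symmetric

  g3 <- fit_parity_glm(parity_dataset(rep(1L, 20), family = rep("f", 20)))
  expect_true(g3$separation)
  expect_equal(g3$estimate, 1)
  expect_gt(g3$ci95[1], 0.8)  # one-sided lower bound
})

test_that("split R-hat separates mixed chains from divergent ones", {
  set.seed(60)
  good <- matrix(rnorm(4000), ncol = 4)
  expect_lt(split_rhat(good), 1.01)
  bad <- good + rep(c(0, 0, 0, 5), each = 1000)
  expect_gt(split_rhat(bad), 1.5)
})

test_that("posterior matches an independent Gibbs implementation (JAGS)", {
  cfg <- survey_sim_config(theta_even = 0.65, n_families = 20,
                           languages_per_family = 4, sigma_family = 0.6,
                           seed = 21)
  recs <- simulate_survey(cfg)
  y <- as.integer(recs$parity == "even")
  fam <- match(recs$family, unique(recs$family))
  f <- fit_parity_model(parity_dataset(y, recs$family),
                        config = sampler_config(seed = 9))

  library(rjags)
  model_str <- "
    model {
      for (i in 1:N) { y[i] ~ dbern(ilogit(alpha + u[fam[i]])) }
      for (j in 1:F) { u[j] ~ dnorm(0, tauf) }
      alpha ~ dt(0, 0.16, 3)          # scale 2.5 -> precision 1/2.5^2
      sigmaf ~ dt(0, 0.16, 3) T(0,)
      tauf <- pow(sigmaf, -2)
    }"
  jm <- jags.model(textConnection(model_str),
                   data = list(y = y, fam = fam, N = length(y), F = max(fam)),
                   n.chains = 3, n.adapt = 1000, quiet = TRUE,
                   inits = list(.RNG.name = "base::Mersenne-Twister",
                                .RNG.seed = 99))
  update(jm, 2000, progress.bar = "none")
  sm <- coda.samples(jm, c("alpha", "sigmaf"), n.iter = 6000,
                     progress.bar = "none")
  a <- unlist(lapply(sm, function(ch) as.numeric(ch[, "alpha"])))
  sg <- unlist(lapply(sm, function(ch) as.numeric(ch[, "sigmaf"])))

  expect_lt(abs(f$prob_even_mean - mean(plogis(a))), 0.03)
  expect_lt(abs(f$ci95[1] - quantile(plogis(a), 0.025)), 0.05)
  expect_lt(abs(f$ci95[2] - quantile(plogis(a), 0.975)), 0.05)
  expect_lt(abs(mean(f$draws$sigma_family) - mean(sg)), 0.15)
})

test_that("the point estimate agrees with a frequentist mixed model (glmer)", {
  cfg <- survey_sim_config(theta_even = 0.75, n_families = 25,
                           languages_per_family = 6, sigma_family = 0.5,
                           seed = 33)
  recs <- simulate_survey(cfg)
  y <- as.integer(recs$parity == "even")
  f <- suppressWarnings(fit_parity_model(parity_dataset(y, recs$family),
                                         config = sampler_config(seed = 3)))
  suppressMessages({
    gm <- lme4::glmer(y ~ 1 + (1 | fam),
                      data = data.frame(y = y, fam = recs$family),
                      family = binomial())
  })
  p_glmer <- plogis(unname(lme4::fixef(gm)[1]))
  expect_lt(abs(f$prob_even_mean - p_glmer), 0.08)
})
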