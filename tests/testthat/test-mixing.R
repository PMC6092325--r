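test_that("mixture moments combine sources and TEF correctly", {
  # single source: mean = mu + c, sd = sqrt(omega^2 + tau^2)
  src1 <- tibble::tibble(source = "a", d13C_mean = -20, d13C_sd = 0.5,
                         d15N_mean = 4, d15N_sd = 0.4)
  tef <- tibble::tibble(isotope = c("d13C", "d15N"), mean = c(2, 3.2),
                        sd = c(0.3, 0.1))
  m <- mixture_moments(1, src1, tef)
  expect_equal(m$mean, c(-18, 7.2))
  expect_equal(m$sd, c(sqrt(0.5^2 + 0.3^2), sqrt(0.4^2 + 0.1^2)))

  # symmetric two-source blend with no spread
  m2 <- mixture_moments(c(0.5, 0.5), two_sources(0, 10, sd = 0), zero_tef())
  expect_equal(m2$mean, c(5, 5))
  expect_equal(m2$sd, c(0, 0))

  # direct arithmetic: sd = sqrt(0.3^2 * 1 + 0.7^2 * 1)
  m3 <- mixture_moments(c(0.3, 0.7), two_sources(0, 10, sd = 1), zero_tef())
  expect_equal(m3$mean, c(7, 7))
  expect_equal(m3$sd, rep(sqrt(0.58), 2), tolerance = 1e-12)

  expect_error(mixture_moments(c(0.5, 0.5, 0), two_sources(), zero_tef()),
               "sources")
})

test_that("log posterior matches the closed-form normal density", {
  # one source with omega = 1, tau = 0, sigma = 1: total variance 2 per isotope
  src <- tibble::tibble(source = "a", d13C_mean = 0, d13C_sd = 1,
                        d15N_mean = 0, d15N_sd = 1)
  cons <- tibble::tibble(d13C = 0, d15N = 0)   # exactly at the mixture mean
  lp <- log_posterior(p = 1, sigma = c(1, 1), cons, src, zero_tef(),
                      sigma_scale = c(1, 1))
  prior_p <- lgamma(1)
  prior_s <- 2 * (log(2) - log(sqrt(2 * pi)) - 0.5)
  expect_equal(lp - prior_p - prior_s, 2 * (-0.5 * log(2 * pi * 2)),
               tolerance = 1e-12)

  # i.i.d. additivity: doubling identical records doubles the likelihood term
  cons2 <- cons[c(1, 1), ]
  lp2 <- log_posterior(1, c(1, 1), cons2, src, zero_tef(), sigma_scale = c(1, 1))
  expect_equal(lp2 - prior_p - prior_s, 2 * (lp - prior_p - prior_s),
               tolerance = 1e-12)

  # off-simplex -> -Inf, not an exception
  expect_identical(log_posterior(c(0.7, 0.7), c(1, 1), cons, two_sources(),
                                 zero_tef(), sigma_scale = c(1, 1)), -Inf)
  expect_identical(log_posterior(1, c(-1, 1), cons, src, zero_tef(),
                                 sigma_scale = c(1, 1)), -Inf)
})

test_that("posterior draws respect the simplex and the draw-count contract", {
  withr::with_seed(2, {
    cons <- tibble::tibble(d13C = rnorm(20, 5, 0.5), d15N = rnorm(20, 5, 0.5))
  })
  fit <- sample_posterior(cons, two_sources(0, 10, sd = 0.5), zero_tef(),
                          chains = 2, iterations = 2000, burnin = 1000,
                          thin = 5, seed = 9)
  p <- as.matrix(fit$draws[, c("p_a", "p_b")])
  expect_true(all(abs(rowSums(p) - 1) < 1e-10))
  expect_true(all(p >= 0))
  expect_true(all(fit$draws$sigma_d13C > 0))
  expect_identical(nrow(fit$draws), 2L * (2000L - 1000L) %/% 5L)
  expect_identical(nrow(fit$draws), nrow(dplyr::distinct(fit$draws[, c("chain", "draw")])))
})

test_that("single-source model is degenerate at p = 1", {
  src1 <- tibble::tibble(source = "only", d13C_mean = 0, d13C_sd = 0.5,
                         d15N_mean = 0, d15N_sd = 0.5)
  cons <- tibble::tibble(d13C = c(0.1, -0.2), d15N = c(0.3, 0))
  fit <- sample_posterior(cons, src1, zero_tef(), chains = 2,
                          iterations = 1000, burnin = 500, seed = 3)
  expect_true(all(fit$draws$p_only == 1))
})

test_that("symmetric two-source problem centres p at one half", {
  withr::with_seed(14, {
    cons <- tibble::tibble(d13C = rnorm(50, 5, 0.1), d15N = rnorm(50, 5, 0.1))
  })
  fit <- sample_posterior(cons, two_sources(0, 10, sd = 0.01), zero_tef(),
                          seed = 14)
  td <- tidy(fit)
  expect_equal(td$mean[td$term == "p_a"], 0.5, tolerance = 0.03)
})

test_that("with zero consumers the posterior reduces to the Dirichlet prior", {
  cons0 <- tibble::tibble(d13C = numeric(0), d15N = numeric(0))
  fit <- sample_posterior(cons0, default_sources(), default_tef(),
                          chains = 2, iterations = 6000, burnin = 3000,
                          seed = 21, sigma_scale = c(1, 1))
  td <- tidy(fit)
  means <- td$mean[td$kind == "proportion"]
  expect_equal(means, rep(1 / 3, 3), tolerance = 0.05)
})

test_that("permuting source order permutes the posterior summaries", {
  withr::with_seed(8, {
    iso <- gen_isotopes(c(0.45, 0.40, 0.15), seed = 81)
  })
  cons <- iso[iso$group == "consumer", ]
  fit1 <- sample_posterior(cons, default_sources(), default_tef(),
                           chains = 2, iterations = 6000, burnin = 3000, seed = 5)
  fit2 <- sample_posterior(cons, default_sources()[c(3, 1, 2), ], default_tef(),
                           chains = 2, iterations = 6000, burnin = 3000, seed = 6)
  t1 <- tidy(fit1); t2 <- tidy(fit2)
  for (s in default_sources()$source) {
    expect_equal(t1$mean[t1$term == paste0("p_", s)],
                 t2$mean[t2$term == paste0("p_", s)], tolerance = 0.05)
  }
})

test_that("posterior summaries follow the quantile rule and conserve the simplex", {
  grid <- seq(0.1, 1.0, by = 0.1)
  fake <- list(draws = tibble::tibble(chain = 1L, draw = seq_along(grid), p_a = grid),
               rhat = c(p_a = NA_real_), config = list(chains = 1))
  class(fake) <- "mixing_fit"
  s <- summarize_posterior(fake, level = 0.80)
  expect_equal(c(s$lower, s$upper),
               unname(quantile(grid, c(0.1, 0.9))))  # type-7 rule: [0.19, 0.91]
  expect_equal(s$lower, 0.19)
  expect_equal(s$upper, 0.91)

  const <- list(draws = tibble::tibble(chain = 1L, draw = 1:5, p_a = rep(0.4, 5)),
                rhat = c(p_a = NA_real_), config = list(chains = 1))
  class(const) <- "mixing_fit"
  sc <- summarize_posterior(const)
  expect_equal(sc$lower, sc$upper)
  expect_equal(sc$median, 0.4)

  withr::with_seed(31, {
    iso <- gen_isotopes(c(0.5, 0.3, 0.2), seed = 32)
  })
  fit <- sample_posterior(iso[iso$group == "consumer", ], default_sources(),
                          default_tef(), chains = 2, iterations = 4000,
                          burnin = 2000, seed = 7)
  td <- tidy(fit)
  expect_equal(sum(td$mean[td$kind == "proportion"]), 1, tolerance = 1e-6)
  expect_true(all(td$lower <= td$median & td$median <= td$upper))
  # single chain: R-hat unavailable
  fit1 <- sample_posterior(iso[iso$group == "consumer", ], default_sources(),
                           default_tef(), chains = 1, iterations = 2000,
                           burnin = 1000, seed = 7)
  expect_true(all(is.na(fit1$rhat)))
})

test_that("the run records the configured TEF values", {
  withr::with_seed(41, {
    iso <- gen_isotopes(c(0.45, 0.40, 0.15), seed = 42)
  })
  fit <- sample_posterior(iso[iso$group == "consumer", ], default_sources(),
                          default_tef(), chains = 2, iterations = 2000,
                          burnin = 1000, seed = 8)
  expect_equal(fit$tef$mean, c(2, 3.2))
  expect_equal(fit$tef$sd, c(0.3, 0.1))
  g <- glance(fit)
  expect_identical(g$chains, 2)
  expect_true(g$acceptance > 0 && g$acceptance < 1)
})
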