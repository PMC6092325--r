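test_that("generators are deterministic per seed", {
  e1 <- gen_environment(seed = 4); e2 <- gen_environment(seed = 4)
  expect_identical(e1, e2)
  e3 <- gen_environment(seed = 5)
  expect_false(identical(e1$copepods, e3$copepods))

  d1 <- gen_stomachs(e1, seed = 6); d2 <- gen_stomachs(e1, seed = 6)
  expect_identical(d1, d2)

  f1 <- gen_fa_profiles(seed = 7); f2 <- gen_fa_profiles(seed = 7)
  expect_identical(f1, f2)
  # byte-identical CSV for the same seed
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_table_csv(f1, p1); write_table_csv(f2, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("environment generator respects profiles", {
  flat <- tibble::tibble(month = paper_months(), copepods = 500, pteropods = 50)
  env0 <- gen_environment(flat, cv = 0, seed = 1)
  expect_equal(unique(env0$copepods), 500)  # no noise, constant profile

  # configured May:Nov ratio 2:1 recovered in expectation
  prof <- tibble::tibble(month = c("Nov", "May"), copepods = c(400, 800))
  draws <- purrr::map_dfr(1:100, function(s) gen_environment(prof, cv = 0.2, seed = s))
  ratio <- mean(draws$copepods[draws$month == "May"]) /
    mean(draws$copepods[draws$month == "Nov"])
  expect_equal(ratio, 2, tolerance = 0.1)

  expect_error(gen_environment(tibble::tibble(month = character(0))), "taxon")
})

test_that("stomach generator reweights availability by selectivity", {
  env <- gen_environment(seed = 10)
  # zero-availability taxon never appears
  env$furcilia <- 0
  diet <- gen_stomachs(env, n_predators = 30, seed = 11)
  expect_true(all(diet$furcilia == 0))

  # neutral weights: diet share approximates availability share
  flat <- tibble::tibble(month = "May", A = 600, B = 400)
  envf <- gen_environment(flat, cv = 0, seed = 1)
  dietn <- gen_stomachs(envf, n_predators = 400, mean_total = 30, seed = 12)
  share <- sum(dietn$A) / sum(dietn$A + dietn$B)
  expect_equal(share, 0.6, tolerance = 0.02)

  # weight 2 on A with availability p_A: expected share 2p/(1+p)
  dietw <- gen_stomachs(envf, weights = c(A = 2), n_predators = 400,
                        mean_total = 30, seed = 13)
  sharew <- sum(dietw$A) / sum(dietw$A + dietw$B)
  expect_equal(sharew, 2 * 0.6 / (1 + 0.6), tolerance = 0.02)

  expect_error(gen_stomachs(envf, weights = c(A = -1)), "> 0")
})

test_that("isotope generator reproduces analytic mixture moments", {
  # all variances zero: consumers sit exactly at the mixture mean
  src0 <- tibble::tibble(source = c("a", "b"),
                         d13C_mean = c(0, 10), d13C_sd = 0,
                         d15N_mean = c(0, 10), d15N_sd = 0)
  iso0 <- gen_isotopes(c(0.25, 0.75), src0, zero_tef(), n_consumers = 5,
                       resid_sd = 0, seed = 3)
  cons0 <- iso0[iso0$group == "consumer", ]
  expect_equal(cons0$d15N, rep(7.5, 5))

  # p = (1, 0, 0): centred at source 1 plus TEF
  iso1 <- gen_isotopes(c(1, 0, 0), n_consumers = 2000, resid_sd = 0.05, seed = 4)
  cons1 <- iso1[iso1$group == "consumer", ]
  src <- default_sources(); tef <- default_tef()
  expect_equal(mean(cons1$d15N), src$d15N_mean[1] + tef$mean[tef$isotope == "d15N"],
               tolerance = 0.05)

  # CLT check at n = 10000 against the analytic mixture mean
  p <- c(0.45, 0.40, 0.15)
  mom <- mixture_moments(p, src, tef)
  iso2 <- gen_isotopes(p, n_consumers = 10000, resid_sd = 0.3, seed = 5)
  cons2 <- iso2[iso2$group == "consumer", ]
  for (j in 1:2) {
    tot_sd <- sqrt(mom$sd[j]^2 + 0.3^2)
    expect_lt(abs(mean(cons2[[mom$isotope[j]]]) - mom$mean[j]),
              3 * tot_sd / sqrt(10000))
  }
  expect_error(gen_isotopes(c(0.5, 0.6), src0, zero_tef()), "simplex")
})

test_that("FA generator produces a balanced layout with the tissue effect", {
  fa <- gen_fa_profiles(n_per_cell = 2, seed = 9)
  cells <- dplyr::count(fa, month, sex, tissue)
  expect_true(all(cells$n == 2))
  expect_identical(nrow(fa), 8L * 2L * 2L * 2L)

  # multiplier 1 (and no reproductive boost): tissues indistinguishable
  fa1 <- gen_fa_profiles(n_per_cell = 6, gonad_multiplier = 1,
                         month_amplitude = 0,
                         female_peak_months = character(0), seed = 10)
  s <- fa_summary(fa1)
  pv <- stats::t.test(log(s$total[s$tissue == "gonad"]),
                      log(s$total[s$tissue == "soma"]))$p.value
  expect_gt(pv, 0.01)

  # multiplier 10 recovered over ~200 samples
  fa10 <- gen_fa_profiles(n_per_cell = 13, gonad_multiplier = 10, seed = 11)
  r <- fa_tissue_contrast(fa10)$ratio[1]
  expect_equal(r, 10, tolerance = 0.15)
})

test_that("every generated dataset passes its own reader validation", {
  dir <- withr::local_tempdir()
  paths <- synth_paper_like(dir, seed = 77)
  rep <- validate_inputs(list(diet = paths$diet, env = paths$env,
                              isotopes = paths$isotopes, fa = paths$fa))
  expect_true(all(rep$ok))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(truth$seed, 77)
  expect_equal(sum(unlist(truth$true_p)), 1, tolerance = 1e-9)
})
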