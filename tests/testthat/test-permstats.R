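test_that("distance matrices match hand computations", {
  x <- rbind(c(1, 2), c(1, 2))
  expect_equal(as.numeric(distance_matrix(x, "bray")), 0)

  disjoint <- rbind(c(1, 0), c(0, 2))
  expect_equal(as.numeric(distance_matrix(disjoint, "bray")), 1)

  xy <- rbind(c(1, 2), c(3, 0))
  expect_equal(as.numeric(distance_matrix(xy, "bray")), 4 / 6, tolerance = 1e-12)
  expect_equal(as.numeric(distance_matrix(xy, "euclidean")), sqrt(8))

  expect_error(distance_matrix(rbind(c(-1, 0), c(1, 1)), "bray"), "non-negative")
  expect_warning(d0 <- distance_matrix(rbind(c(0, 0), c(0, 0)), "bray"), "zero")
  expect_equal(as.numeric(d0), 0)

  # transform applied before the metric
  dt <- distance_matrix(rbind(0, exp(1) - 1), "euclidean", transform = "log1p")
  expect_equal(as.numeric(dt), 1)
})

test_that("one-way Euclidean PERMANOVA equals classical ANOVA (oracle)", {
  # fixed dataset {0,1 | 2,3}: F = 8, exhaustive p = 2/6
  d <- distance_matrix(data.frame(y = c(0, 1, 2, 3)), "euclidean")
  fit <- permanova(d, data.frame(g = c("A", "A", "B", "B")), permutations = "exact")
  tab <- tidy(fit)
  expect_equal(tab$pseudo_F[tab$term == "g"], 8, tolerance = 1e-10)
  expect_equal(tab$p[tab$term == "g"], 2 / 6, tolerance = 1e-12)
  expect_equal(tab$SS[tab$term == "g"], 4, tolerance = 1e-10)
  expect_equal(tab$SS[tab$term == "Residual"], 1, tolerance = 1e-10)
  expect_equal(tab$df[1:2], c(1, 2))

  # random univariate datasets against aov
  withr::with_seed(19, {
    for (i in 1:100) {
      y <- rnorm(9)
      g <- factor(rep(letters[1:3], each = 3))
      f_perm <- permanova(distance_matrix(data.frame(y), "euclidean"),
                          data.frame(g), permutations = 99, seed = i)
      f_aov <- summary(aov(y ~ g))[[1]]$`F value`[1]
      expect_equal(tidy(f_perm)$pseudo_F[1], f_aov, tolerance = 1e-10)
    }
  })
})

test_that("multivariate PERMANOVA agrees with an independent implementation", {
  withr::with_seed(23, {
    x <- matrix(rexp(60), 12, 5)
    design <- data.frame(g = rep(c("A", "B", "C"), each = 4))
  })
  d <- distance_matrix(x, "bray", transform = "log1p")
  mine <- tidy(permanova(d, design, permutations = 999, seed = 1))
  ref <- vegan::adonis2(d ~ g, data = design, permutations = 999)
  expect_equal(mine$pseudo_F[1], ref$F[1], tolerance = 1e-10)
  expect_equal(mine$SS[mine$term == "g"], ref$SumOfSqs[1], tolerance = 1e-10)
  expect_equal(mine$df[1:2], ref$Df[1:2])
})

test_that("three-way crossed designs partition df and SS additively", {
  withr::with_seed(29, {
    design <- tidyr::expand_grid(a = c("x", "y"), b = c("u", "v"),
                                 c = c("p", "q"), rep = 1:2)
    x <- matrix(rexp(16 * 4), 16, 4) +
      2 * (design$a == "x") + 1 * (design$b == "u")
  })
  d <- distance_matrix(x, "euclidean")
  fit <- permanova(d, design[, c("a", "b", "c")], permutations = 199, seed = 5)
  tab <- tidy(fit)
  expect_equal(sum(tab$df[tab$term != "Total"]), 15)
  expect_equal(sum(tab$SS[tab$term != "Total"]),
               tab$SS[tab$term == "Total"], tolerance = 1e-6)
  expect_identical(tab$term[1:3], c("a", "b", "c"))
  expect_true("a:b:c" %in% tab$term)

  # unbalanced multiway is refused with direction to one-way
  expect_error(permanova(d, design[c(1:15, 1), c("a", "b")],
                         permutations = 199),
               "balance|one-way|Unbalanced")
  expect_error(permanova(d, design[, "a", drop = FALSE], permutations = 9),
               "99")
})

test_that("Monte-Carlo p agrees with exhaustive enumeration", {
  withr::with_seed(37, {
    y <- rnorm(6)
    g <- rep(c("A", "B"), each = 3)
  })
  d <- distance_matrix(data.frame(y), "euclidean")
  p_exact <- tidy(permanova(d, data.frame(g), permutations = "exact"))$p[1]
  p_mc <- tidy(permanova(d, data.frame(g), permutations = 9999, seed = 4))$p[1]
  se <- sqrt(p_exact * (1 - p_exact) / 9999)
  expect_lt(abs(p_mc - p_exact), 3 * se + 1e-4)
})

test_that("identical samples give a flagged zero-SS result", {
  x <- matrix(1, 6, 3)
  d <- distance_matrix(x, "euclidean")
  expect_warning(fit <- permanova(d, data.frame(g = rep(c("A", "B"), 3)),
                                  permutations = 99), "zero")
  expect_true(all(is.na(tidy(fit)$pseudo_F)))
})

test_that("SIMPER decomposes average Bray-Curtis dissimilarity exactly", {
  # one variable: everything attributed to it
  s1 <- simper(matrix(c(1, 3), 2, 1), c("A", "B"))
  expect_equal(s1$contrib_pct, 100)

  # only v1 differs
  s2 <- simper(rbind(c(1, 1), c(3, 1)), c("A", "B"))
  expect_equal(s2$average[s2$variable == "V1"], 2 / 6, tolerance = 1e-12)
  expect_equal(s2$contrib_pct, c(100, 0))
  expect_equal(unique(s2$overall), 2 / 6, tolerance = 1e-12)

  # decomposition identity on random data, multiple groups
  withr::with_seed(41, {
    x <- matrix(rexp(48), 12, 4, dimnames = list(NULL, paste0("V", 1:4)))
    g <- rep(c("A", "B", "C"), each = 4)
  })
  sim <- simper(x, g)
  for (pair in split(sim, paste(sim$group_a, sim$group_b))) {
    expect_equal(sum(pair$average), pair$overall[1], tolerance = 1e-12)
    expect_equal(sum(pair$contrib_pct), 100, tolerance = 1e-6)
    expect_true(all(diff(pair$cumulative_pct) >= -1e-9))
    # overall equals the mean pairwise Bray-Curtis distance across groups
    ia <- which(g == pair$group_a[1]); ib <- which(g == pair$group_b[1])
    dmat <- as.matrix(distance_matrix(x, "bray"))
    expect_equal(pair$overall[1], mean(dmat[ia, ib]), tolerance = 1e-12)
  }

  # against the independent vegan implementation
  ref <- vegan::simper(x, g, permutations = 0)
  mine_ab <- sim[sim$group_a == "A" & sim$group_b == "B", ]
  ref_ab <- summary(ref)$A_B
  expect_equal(mine_ab$average[match(rownames(ref_ab), mine_ab$variable)],
               ref_ab$average, tolerance = 1e-10)

  expect_error(simper(x, rep("A", 12)), "two groups")
})
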