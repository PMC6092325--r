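# Bayesian stable-isotope mixing model.
#
# Consumers are modelled as normal draws around a mixture of K sources whose
# signatures are shifted by a trophic enrichment factor (TEF):
#   mean_j  = sum_k p_k (mu_jk + c_jk)
#   var_j   = sum_k p_k^2 (omega_jk^2 + tau_jk^2) + sigma_j^2
# per isotope j, with p on the simplex, a Dirichlet(1,...,1) prior on p and
# half-normal priors on the per-isotope residual scales sigma_j. Inference is
# by random-walk Metropolis on (softmax-parameterized p, log sigma).

isotope_names <- c("d13C", "d15N")

# Collect sources and TEF tibbles into aligned matrices (J isotopes x K
# sources). TEF may be global (one row per isotope) or per-source.
mixing_matrices <- function(sources, tef, isotopes = isotope_names) {
  K <- nrow(sources)
  if (K < 1L) abort("Need at least one source")
  need <- c(paste0(isotopes, "_mean"), paste0(isotopes, "_sd"))
  if (!all(need %in% names(sources))) {
    abort(sprintf("sources must have columns: source, %s", paste(need, collapse = ", ")))
  }
  mu <- t(as.matrix(sources[, paste0(isotopes, "_mean")]))
  omega <- t(as.matrix(sources[, paste0(isotopes, "_sd")]))
  if (any(omega < 0)) abort("Source sds must be >= 0")

  if (!all(c("isotope", "mean", "sd") %in% names(tef))) {
    abort("tef must have columns isotope, mean, sd (optionally source)")
  }
  if ("source" %in% names(tef) && any(!is.na(tef$source))) {
    cmat <- taumat <- matrix(0, length(isotopes), K)
    for (j in seq_along(isotopes)) for (k in seq_len(K)) {
      row <- tef[tef$isotope == isotopes[j] & tef$source == sources$source[k], ]
      if (nrow(row) != 1L) abort("Per-source TEF must cover every isotope x source")
      cmat[j, k] <- row$mean; taumat[j, k] <- row$sd
    }
  } else {
    cvec <- tauvec <- numeric(length(isotopes))
    for (j in seq_along(isotopes)) {
      row <- tef[tef$isotope == isotopes[j], ]
      if (nrow(row) != 1L) abort(sprintf("TEF missing for isotope %s", isotopes[j]))
      cvec[j] <- row$mean; tauvec[j] <- row$sd
    }
    cmat <- matrix(cvec, length(isotopes), K)
    taumat <- matrix(tauvec, length(isotopes), K)
  }
  if (any(taumat < 0)) abort("TEF sds must be >= 0")
  dimnames(mu) <- dimnames(omega) <- dimnames(cmat) <- dimnames(taumat) <-
    list(isotopes, sources$source)
  list(mu = mu, omega = omega, tef_mean = cmat, tef_sd = taumat,
       sources = sources$source, isotopes = isotopes)
}

#' Moments of the TEF-shifted source mixture
#'
#' For diet proportions `p` on the simplex, the per-isotope mean and sd of
#' the mixture signal before residual error:
#' mean_j = sum_k p_k (mu_jk + c_jk), sd_j = sqrt(sum_k p_k^2 (omega_jk^2 +
#' tau_jk^2)).
#'
#' @param p Numeric simplex vector, one entry per source.
#' @param sources Tibble with `source`, `d13C_mean`, `d13C_sd`, `d15N_mean`,
#'   `d15N_sd` (per-mil).
#' @param tef Tibble with `isotope`, `mean`, `sd` (optionally per `source`).
#' @param isotopes Isotope columns to use.
#' @return Tibble with `isotope`, `mean`, `sd`.
#' @export
mixture_moments <- function(p, sources, tef, isotopes = isotope_names) {
  mats <- mixing_matrices(sources, tef, isotopes)
  if (length(p) != length(mats$sources)) {
    abort(sprintf("p has %d entries but there are %d sources",
                  length(p), length(mats$sources)))
  }
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8) abort("p must lie on the simplex")
  m <- as.numeric((mats$mu + mats$tef_mean) %*% p)
  v <- as.numeric((mats$omega^2 + mats$tef_sd^2) %*% p^2)
  tibble(isotope = mats$isotopes, mean = m, sd = sqrt(v))
}

# Sufficient statistics of the consumer records: per isotope, n, sum y,
# sum y^2 (the normal likelihood depends on the data only through these).
consumer_stats <- function(consumers, isotopes = isotope_names) {
  if (!all(isotopes %in% names(consumers))) {
    abort(sprintf("consumers must have columns %s", paste(isotopes, collapse = ", ")))
  }
  y <- as.matrix(consumers[, isotopes, drop = FALSE])
  if (any(!is.finite(y))) abort("Non-finite consumer isotope values")
  list(n = nrow(y), Sy = colSums(y), Sy2 = colSums(y^2))
}

# Core unnormalized-by-nothing log posterior in natural parameters.
# stats: from consumer_stats(); mats: from mixing_matrices();
# sigma_scale: half-normal scale per isotope.
log_posterior_core <- function(p, sigma, stats, mats, sigma_scale) {
  K <- length(mats$sources)
  if (any(p < -1e-12) || abs(sum(p) - 1) > 1e-8) return(-Inf)
  if (any(sigma <= 0)) return(-Inf)
  m <- as.numeric((mats$mu + mats$tef_mean) %*% p)
  v <- as.numeric((mats$omega^2 + mats$tef_sd^2) %*% p^2) + sigma^2
  ll <- sum(-0.5 * stats$n * log(2 * pi * v) -
              (stats$Sy2 - 2 * m * stats$Sy + stats$n * m^2) / (2 * v))
  lp_p <- lgamma(K)                                  # Dirichlet(1,...,1)
  lp_s <- sum(log(2) - log(sigma_scale * sqrt(2 * pi)) -
                sigma^2 / (2 * sigma_scale^2))       # half-normal
  ll + lp_p + lp_s
}

#' Log posterior density of the mixing model
#'
#' Normal likelihood over consumers and isotopes with mean and variance from
#' [mixture_moments()] plus the residual variance `sigma^2`, a flat
#' Dirichlet(1,...,1) prior on `p`, and independent half-normal priors on
#' each `sigma`. Out-of-support parameters return `-Inf`.
#'
#' @param p Simplex of source proportions.
#' @param sigma Per-isotope residual sds (> 0).
#' @param consumers Tibble of consumer records with isotope columns.
#' @inheritParams mixture_moments
#' @param sigma_scale Half-normal prior scale per isotope; defaults to the
#'   observed consumer sd (or 1 for a single consumer).
#' @return Scalar log density (`-Inf` off support).
#' @export
log_posterior <- function(p, sigma, consumers, sources, tef,
                          sigma_scale = NULL, isotopes = isotope_names) {
  mats <- mixing_matrices(sources, tef, isotopes)
  stats <- consumer_stats(consumers, isotopes)
  if (is.null(sigma_scale)) sigma_scale <- default_sigma_scale(consumers, isotopes)
  if (length(p) != length(mats$sources)) return(-Inf)
  log_posterior_core(p, sigma, stats, mats, sigma_scale)
}

default_sigma_scale <- function(consumers, isotopes = isotope_names) {
  vapply(isotopes, function(j) {
    s <- if (nrow(consumers) > 1) sd(consumers[[j]]) else 1
    if (!is.finite(s) || s <= 0) 1 else s
  }, numeric(1))
}

softmax_p <- function(z) {
  e <- exp(c(z, 0) - max(c(z, 0)))
  e / sum(e)
}

# Log target on the unconstrained scale (softmax proportions, log sigmas),
# including the change-of-variables terms.
make_log_target <- function(stats, mats, sigma_scale) {
  K <- length(mats$sources)
  J <- length(mats$isotopes)
  nz <- K - 1L
  function(th) {
    p <- if (nz > 0) softmax_p(th[seq_len(nz)]) else 1
    sigma <- exp(th[nz + seq_len(J)])
    lp <- log_posterior_core(p, sigma, stats, mats, sigma_scale)
    if (!is.finite(lp)) return(-Inf)
    # change of variables: softmax (sum log p) and log-sigma (sum log sigma)
    jac <- (if (nz > 0) sum(log(p)) else 0) + sum(log(sigma))
    lp + jac
  }
}

# Posterior mode and curvature-based proposal scales (Laplace
# preconditioning for the random-walk proposal).
map_precondition <- function(lt_of, nz, J, sigma_scale) {
  init <- c(rep(0, nz), log(pmax(sigma_scale, 1e-3)))
  npar <- length(init)
  fit <- tryCatch(
    stats::optim(init, function(th) -lt_of(th), method = "BFGS",
                 hessian = TRUE, control = list(maxit = 500)),
    error = function(e) NULL)
  if (is.null(fit) || !is.finite(fit$value)) {
    return(list(mode = init, prop_sd = rep(0.1, npar)))
  }
  prop_sd <- rep(0.1, npar)
  ok <- tryCatch({
    cov <- solve(fit$hessian)
    dg <- diag(cov)
    all(is.finite(dg)) && all(dg > 0)
  }, error = function(e) FALSE)
  if (ok) prop_sd <- sqrt(diag(solve(fit$hessian)))
  prop_sd <- pmin(pmax(prop_sd, 1e-3), 5)
  list(mode = fit$par, prop_sd = prop_sd)
}

# One Metropolis chain; returns draws in natural parameters plus acceptance.
run_chain <- function(stats, mats, sigma_scale, iterations, burnin, thin,
                      seed, pre) {
  K <- length(mats$sources)
  J <- length(mats$isotopes)
  nz <- K - 1L
  npar <- nz + J
  lt_of <- make_log_target(stats, mats, sigma_scale)

  withr::with_seed(seed, {
    # overdispersed start around the mode
    theta <- pre$mode + rnorm(npar, 0, 2 * pre$prop_sd)
    if (!is.finite(lt_of(theta))) theta <- pre$mode
    lt <- lt_of(theta)
    step <- 2.4 / sqrt(npar) * pre$prop_sd
    scale <- 1
    keep_from <- burnin + 1L
    kept_idx <- seq(keep_from, iterations, by = thin)
    draws <- matrix(NA_real_, length(kept_idx), K + J)
    acc_post <- 0L; n_post <- 0L
    acc_win <- 0L; win <- 50L
    ki <- 1L
    for (it in seq_len(iterations)) {
      prop <- theta + rnorm(npar, 0, scale * step)
      lt_prop <- lt_of(prop)
      if (is.finite(lt_prop) && log(runif(1)) < lt_prop - lt) {
        theta <- prop; lt <- lt_prop
        acc_win <- acc_win + 1L
        if (it > burnin) acc_post <- acc_post + 1L
      }
      if (it <= burnin && it %% win == 0L) {
        rate <- acc_win / win
        scale <- scale * exp(0.5 * (rate - 0.3))   # adapt toward 20-40%
        acc_win <- 0L
      }
      if (it > burnin) n_post <- n_post + 1L
      if (ki <= length(kept_idx) && it == kept_idx[ki]) {
        p <- if (nz > 0) softmax_p(theta[seq_len(nz)]) else 1
        draws[ki, ] <- c(p, exp(theta[nz + seq_len(J)]))
        ki <- ki + 1L
      }
    }
    list(draws = draws, acceptance = acc_post / max(n_post, 1L))
  })
}

#' Sample the mixing-model posterior
#'
#' Random-walk Metropolis on the softmax-parameterized source proportions
#' and log residual scales. The proposal scale adapts toward a 20-40%
#' acceptance rate during burn-in only, so the kept chain is a valid
#' fixed-kernel Metropolis sample. Reproducible for a fixed seed.
#'
#' @inheritParams log_posterior
#' @param chains Number of independent chains (default 4).
#' @param iterations Iterations per chain (default 20000).
#' @param burnin Burn-in iterations discarded per chain (default half).
#' @param thin Keep every `thin`-th post-burn-in draw (default 5).
#' @param seed Integer seed; chain c uses a derived child seed.
#' @return A `mixing_fit` object: `draws` tibble (chain, draw, one `p_`
#'   column per source, one `sigma_` column per isotope), per-chain
#'   `acceptance`, `rhat` per parameter, and the inputs echoed back.
#' @export
sample_posterior <- function(consumers, sources, tef,
                             chains = 4, iterations = 20000,
                             burnin = floor(iterations / 2), thin = 5,
                             seed = 1, isotopes = isotope_names,
                             sigma_scale = NULL) {
  if (iterations <= burnin) abort("iterations must exceed burnin")
  mats <- mixing_matrices(sources, tef, isotopes)
  stats <- consumer_stats(consumers, isotopes)
  # n = 0 is allowed: the posterior then reduces to the prior
  if (is.null(sigma_scale)) sigma_scale <- default_sigma_scale(consumers, isotopes)

  lt_of <- make_log_target(stats, mats, sigma_scale)
  pre <- map_precondition(lt_of, length(mats$sources) - 1L,
                          length(mats$isotopes), sigma_scale)
  res <- purrr::map(seq_len(chains), function(ch) {
    run_chain(stats, mats, sigma_scale, iterations, burnin, thin,
              seed = child_seed(seed, ch), pre = pre)
  })
  par_names <- c(paste0("p_", mats$sources), paste0("sigma_", mats$isotopes))
  draws <- purrr::imap(res, function(r, ch) {
    d <- as_tibble(r$draws, .name_repair = "minimal")
    names(d) <- par_names
    bind_cols(tibble(chain = ch, draw = seq_len(nrow(d))), d)
  }) |> bind_rows()

  rhat <- rhat_by_param(draws, par_names)
  out <- list(
    draws = draws,
    acceptance = vapply(res, `[[`, numeric(1), "acceptance"),
    rhat = rhat,
    converged = if (chains > 1) all(rhat < 1.1, na.rm = TRUE) else NA,
    sources = sources, tef = tef, isotopes = mats$isotopes,
    source_names = mats$sources,
    config = list(chains = chains, iterations = iterations, burnin = burnin,
                  thin = thin, seed = seed, sigma_scale = sigma_scale),
    n_consumers = stats$n
  )
  class(out) <- "mixing_fit"
  if (isFALSE(out$converged)) {
    warn(sprintf("MCMC convergence flagged: max R-hat = %.3f", max(rhat, na.rm = TRUE)))
  }
  out
}

# Gelman-Rubin potential scale reduction across chains (NA for one chain or
# a degenerate parameter).
rhat_by_param <- function(draws, par_names) {
  chains <- unique(draws$chain)
  vapply(par_names, function(pn) {
    if (length(chains) < 2) return(NA_real_)
    by_chain <- split(draws[[pn]], draws$chain)
    n <- min(lengths(by_chain))
    by_chain <- lapply(by_chain, function(x) x[seq_len(n)])
    means <- vapply(by_chain, mean, numeric(1))
    vars <- vapply(by_chain, var, numeric(1))
    W <- mean(vars)
    B <- n * var(means)
    if (!is.finite(W) || W <= 0) return(NA_real_)
    sqrt(((n - 1) / n * W + B / n) / W)
  }, numeric(1))
}

#' Summarize posterior draws
#'
#' Posterior mean, median and equal-tailed credibility interval per
#' parameter, with Gelman-Rubin R-hat (reported as `NA` for a single chain).
#'
#' @param fit A `mixing_fit` from [sample_posterior()].
#' @param level Credibility level (default 0.95).
#' @return Tibble with one row per parameter.
#' @export
summarize_posterior <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "mixing_fit"))
  pars <- setdiff(names(fit$draws), c("chain", "draw"))
  a <- (1 - level) / 2
  rows <- purrr::map(pars, function(pn) {
    x <- fit$draws[[pn]]
    q <- quantile(x, c(a, 0.5, 1 - a), names = FALSE)
    tibble(parameter = pn, mean = mean(x), median = q[2],
           lower = q[1], upper = q[3], level = level,
           rhat = unname(fit$rhat[pn]))
  })
  bind_rows(rows)
}

#' @exportS3Method generics::tidy
tidy.mixing_fit <- function(x, level = 0.95, ...) {
  out <- summarize_posterior(x, level)
  out$term <- out$parameter
  out$kind <- ifelse(startsWith(out$parameter, "p_"), "proportion", "residual_sd")
  select(out, "term", "kind", "mean", "median", "lower", "upper", "level", "rhat")
}

#' @exportS3Method generics::glance
glance.mixing_fit <- function(x, ...) {
  tibble(
    chains = x$config$chains,
    draws = nrow(x$draws),
    n_consumers = x$n_consumers,
    acceptance = mean(x$acceptance),
    max_rhat = suppressWarnings(max(x$rhat, na.rm = TRUE)),
    converged = x$converged
  )
}

#' @export
print.mixing_fit <- function(x, ...) {
  cat(sprintf("<mixing_fit> %d sources, %d consumers, %d chains x %d draws\n",
              length(x$source_names), x$n_consumers, x$config$chains,
              nrow(x$draws) / x$config$chains))
  print(tidy(x))
  invisible(x)
}

#' Plot posterior source contributions
#'
#' Credible-interval plot of the modelled diet proportion per source.
#'
#' @param object A `mixing_fit`.
#' @param level Credibility level for whiskers.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.mixing_fit <- function(object, level = 0.95, ...) {
  td <- tidy(object, level = level)
  td <- td[td$kind == "proportion", ]
  td$source <- sub("^p_", "", td$term)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$source, y = .data$mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lower, ymax = .data$upper)) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "Diet proportion",
                  title = "Posterior source contributions",
                  subtitle = sprintf("%d%% credibility intervals", round(level * 100))) +
    ggplot2::theme_minimal()
}
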