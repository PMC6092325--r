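# Distance matrices, permutational multivariate ANOVA (McArdle-Anderson
# partitioning of the Gower-centered inner-product matrix), and SIMPER
# decomposition of Bray-Curtis dissimilarity.

#' Distance matrix with optional log(x+1) transform
#'
#' Applies the transform elementwise, then computes Euclidean or Bray-Curtis
#' distances (Bray-Curtis d(x,y) = sum|x-y| / sum(x+y)). Pairs of all-zero
#' rows under Bray-Curtis are defined as distance 0 with a warning.
#'
#' @param data Samples-by-variables numeric data frame or matrix.
#' @param metric `"euclidean"` or `"bray"` (Bray-Curtis).
#' @param transform `"none"` or `"log1p"` (natural log of x + 1).
#' @return A `dist` object with `metric` and `transform` attributes.
#' @export
distance_matrix <- function(data, metric = c("bray", "euclidean"),
                            transform = c("none", "log1p")) {
  metric <- match.arg(metric)
  transform <- match.arg(transform)
  x <- as.matrix(data[, vapply(as.data.frame(data), is.numeric, logical(1)),
                      drop = FALSE])
  if (nrow(x) < 2L) abort("Need at least two samples")
  if (metric == "bray" && any(x < 0)) {
    abort("Bray-Curtis requires non-negative data")
  }
  if (transform == "log1p") x <- log1p(x)
  # all-zero rows are handled below; vegdist's own warning would duplicate it
  d <- suppressWarnings(
    vegan::vegdist(x, method = if (metric == "bray") "bray" else "euclidean"))
  if (any(is.nan(d))) {
    warn("All-zero sample pairs under Bray-Curtis: distance set to 0")
    d[is.nan(d)] <- 0
  }
  attr(d, "metric") <- metric
  attr(d, "transform") <- transform
  d
}

# Gower-centered inner product matrix of a distance matrix.
gower_matrix <- function(d) {
  D <- as.matrix(d)
  n <- nrow(D)
  A <- -0.5 * D^2
  C <- diag(n) - matrix(1 / n, n, n)
  C %*% A %*% C
}

# Hat matrix of a model matrix via QR (rank-safe).
hat_matrix <- function(X) {
  q <- qr(X)
  Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
  Q %*% t(Q)
}

# Sequential term structure: main effects in given order, then interactions
# of increasing order.
design_terms <- function(factors) {
  nm <- names(factors)
  terms <- as.list(nm)
  if (length(nm) >= 2) {
    for (ord in 2:length(nm)) {
      combs <- utils::combn(nm, ord, simplify = FALSE)
      terms <- c(terms, lapply(combs, paste, collapse = ":"))
    }
  }
  vapply(terms, identity, character(1))
}

# All permutations of 1..n as a matrix (n! rows); used for exact tests.
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (i in seq_len(nrow(sub))) {
      out[r, ] <- c(k, rest[sub[i, ]])
      r <- r + 1L
    }
  }
  out
}

#' Permutational multivariate ANOVA (PERMANOVA)
#'
#' Partitions a distance matrix over 1-3 crossed fixed factors with all
#' interactions, using sequential (Type I) sums of squares computed as
#' traces of projection matrices against the Gower-centered inner-product
#' matrix. Pseudo-F per term is MS_term / MS_residual; significance comes
#' from unrestricted permutation of sample labels with the observed
#' statistic counted into the null set.
#'
#' @param d A `dist` (e.g. from [distance_matrix()]) or square matrix.
#' @param design Data frame of 1-3 factor columns, rows matching `d`'s
#'   samples; multiway designs must be balanced.
#' @param permutations Number of random permutations (>= 99), or `"exact"`
#'   for full enumeration (n <= 8).
#' @param seed Integer seed for the permutation stream.
#' @return A `permanova_fit`: tidy table of `term`, `df`, `SS`, `MS`,
#'   `pseudo_F`, `p`, plus a residual and total row.
#' @export
permanova <- function(d, design, permutations = 999, seed = 1) {
  design <- as.data.frame(design)
  if (ncol(design) < 1 || ncol(design) > 3) abort("design must have 1-3 factor columns")
  design[] <- lapply(design, function(x) factor(as.character(x)))
  if (any(vapply(design, nlevels, integer(1)) < 2)) {
    abort("Every factor needs at least 2 levels")
  }
  D <- as.matrix(d)
  n <- nrow(D)
  if (nrow(design) != n) abort("design rows must match distance matrix size")
  if (ncol(design) > 1) {
    cells <- table(design)
    if (length(unique(as.vector(cells))) != 1L) {
      abort("Unbalanced multiway design: use a one-way design or balance the layout")
    }
  }
  exact <- identical(permutations, "exact")
  if (!exact && (!is.numeric(permutations) || permutations < 99)) {
    abort("permutations must be >= 99 (or \"exact\")")
  }
  if (exact && n > 8) abort("Exact enumeration supported for n <= 8 only")

  G <- gower_matrix(D)
  ss_total <- sum(diag(G))
  terms <- design_terms(design)

  # sequential projections: P_0 = intercept, P_t adds term t
  ones <- matrix(1 / n, n, n)
  hats <- vector("list", length(terms))
  prev <- ones
  dfs <- numeric(length(terms))
  for (t in seq_along(terms)) {
    fml <- stats::as.formula(paste("~", paste(terms[seq_len(t)], collapse = " + ")))
    X <- stats::model.matrix(fml, design)
    P <- hat_matrix(X)
    hats[[t]] <- P - prev
    dfs[t] <- round(sum(diag(P)) - sum(diag(prev)))
    prev <- P
  }
  H_res <- diag(n) - prev
  df_res <- n - round(sum(diag(prev)))

  term_ss <- function(Gm) vapply(hats, function(H) sum(H * Gm), numeric(1))
  ss_obs <- term_ss(G)
  ss_res <- sum(H_res * G)
  if (ss_total <= 1e-12) {
    warn("Total sum of squares is zero: statistics undefined")
    tab <- tibble(term = c(terms, "Residual", "Total"),
                  df = c(dfs, df_res, n - 1),
                  SS = c(ss_obs, ss_res, ss_total),
                  MS = NA_real_, pseudo_F = NA_real_, p = NA_real_)
    return(new_permanova_fit(tab, n, 0, seed, exact))
  }
  ms_res <- ss_res / df_res
  f_obs <- (ss_obs / dfs) / ms_res

  f_perm <- function(idx) {
    Gp <- G[idx, idx]
    ssp <- term_ss(Gp)
    ssr <- sum(H_res * Gp)
    (ssp / dfs) / (ssr / df_res)
  }

  if (exact) {
    P <- all_permutations(n)
    fs <- vapply(seq_len(nrow(P)), function(i) f_perm(P[i, ]),
                 numeric(length(terms)))
    fs <- matrix(fs, nrow = length(terms))
    pvals <- rowMeans(fs >= f_obs - 1e-12)
    n_used <- nrow(P)
  } else {
    pvals <- withr::with_seed(seed, {
      exceed <- numeric(length(terms))
      for (b in seq_len(permutations)) {
        fb <- f_perm(sample.int(n))
        exceed <- exceed + (fb >= f_obs - 1e-12)
      }
      (exceed + 1) / (permutations + 1)
    })
    n_used <- permutations
  }

  tab <- tibble(
    term = c(terms, "Residual", "Total"),
    df = c(dfs, df_res, n - 1),
    SS = c(ss_obs, ss_res, ss_total),
    MS = c(ss_obs / dfs, ms_res, NA_real_),
    pseudo_F = c(f_obs, NA_real_, NA_real_),
    p = c(pvals, NA_real_, NA_real_)
  )
  new_permanova_fit(tab, n, n_used, seed, exact)
}

new_permanova_fit <- function(tab, n, permutations, seed, exact) {
  out <- list(table = tab, n = n, permutations = permutations,
              seed = seed, exact = exact)
  class(out) <- "permanova_fit"
  out
}

#' @exportS3Method generics::tidy
tidy.permanova_fit <- function(x, ...) x$table

#' @exportS3Method generics::glance
glance.permanova_fit <- function(x, ...) {
  tibble(n = x$n, permutations = x$permutations, exact = x$exact,
         total_SS = x$table$SS[x$table$term == "Total"])
}

#' @export
print.permanova_fit <- function(x, ...) {
  cat(sprintf("<permanova_fit> n = %d, %s permutations\n", x$n,
              if (x$exact) "exact" else format(x$permutations)))
  print(x$table)
  invisible(x)
}

#' Plot PERMANOVA term contributions
#'
#' Bar chart of the sequential sum-of-squares share per model term,
#' annotated with permutation p-values.
#'
#' @param object A `permanova_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.permanova_fit <- function(object, ...) {
  tab <- object$table
  tot <- tab$SS[tab$term == "Total"]
  tab <- tab[!tab$term %in% "Total", ]
  tab$term <- factor(tab$term, levels = rev(tab$term))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$SS / tot, y = .data$term)) +
    ggplot2::geom_col() +
    ggplot2::geom_text(ggplot2::aes(label = ifelse(is.na(.data$p), "",
                                                   sprintf("p = %.3f", .data$p))),
                       hjust = -0.1, size = 3) +
    ggplot2::scale_x_continuous(labels = function(v) sprintf("%.0f%%", v * 100),
                                limits = c(0, 1)) +
    ggplot2::labs(x = "Share of total SS", y = NULL,
                  title = "PERMANOVA partition") +
    ggplot2::theme_minimal()
}

#' SIMPER: similarity percentage decomposition
#'
#' For each pair of groups, decomposes the average Bray-Curtis dissimilarity
#' into per-variable contributions: the contribution of variable v is the
#' average over cross-pairs (i in A, k in B) of |x_iv - x_kv| / sum_w(x_iw +
#' x_kw). Contributions sum exactly to the average dissimilarity.
#'
#' @param data Samples-by-variables non-negative numeric data.
#' @param groups Group label per sample (>= 2 non-empty groups).
#' @param transform `"none"` or `"log1p"`, applied before decomposition.
#' @return Tibble with `group_a`, `group_b`, `variable`, `average`
#'   (contribution in dissimilarity units), `contrib_pct`, `cumulative_pct`
#'   and `overall` (average Bray-Curtis dissimilarity of the pair), sorted
#'   by decreasing contribution within each pair.
#' @export
simper <- function(data, groups, transform = c("none", "log1p")) {
  transform <- match.arg(transform)
  x <- as.matrix(data[, vapply(as.data.frame(data), is.numeric, logical(1)),
                      drop = FALSE])
  if (any(x < 0)) abort("SIMPER requires non-negative data")
  if (transform == "log1p") x <- log1p(x)
  groups <- as.character(groups)
  if (length(groups) != nrow(x)) abort("groups must match rows of data")
  gl <- unique(groups)
  if (length(gl) < 2) abort("Need at least two groups")

  vars <- colnames(x)
  if (is.null(vars)) vars <- paste0("V", seq_len(ncol(x)))
  pairs <- utils::combn(gl, 2, simplify = FALSE)
  rows <- purrr::map(pairs, function(pr) {
    ia <- which(groups == pr[1]); ib <- which(groups == pr[2])
    contrib <- matrix(0, length(ia) * length(ib), ncol(x))
    r <- 1L
    for (i in ia) for (k in ib) {
      denom <- sum(x[i, ] + x[k, ])
      contrib[r, ] <- if (denom > 0) abs(x[i, ] - x[k, ]) / denom else 0
      r <- r + 1L
    }
    avg <- colMeans(contrib)
    overall <- sum(avg)
    ord <- order(avg, decreasing = TRUE)
    pct <- if (overall > 0) avg / overall * 100 else rep(0, length(avg))
    tibble(group_a = pr[1], group_b = pr[2],
           variable = vars[ord], average = avg[ord],
           contrib_pct = pct[ord], cumulative_pct = cumsum(pct[ord]),
           overall = overall)
  })
  bind_rows(rows)
}
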