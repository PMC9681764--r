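#' Principal coordinates analysis of a distance matrix
#'
#' Classical (Torgerson) metric scaling: the squared distance matrix is
#' double-centered, eigendecomposed, and the positive-eigenvalue axes are
#' kept in decreasing order. Variance explained is reported over the positive
#' eigenvalues; negative eigenvalues (present for non-Euclidean
#' dissimilarities such as Bray-Curtis) are retained in the result for
#' inspection.
#'
#' @param d A symmetric distance matrix (or `dist`) with sample names.
#'
#' @return An object of class `halohab_pcoa`: list with `points` (tibble of
#'   sample coordinates), `eigenvalues` (positive axes), `var_explained`,
#'   and `negative_eigenvalues`.
#' @export
pcoa_ordination <- function(d) {
  m <- as.matrix(d)
  n <- nrow(m)
  if (n < 3) abort("PCoA needs at least 3 samples.")
  if (max(abs(m - t(m))) > 1e-12) abort("distance matrix must be symmetric.")
  sc <- suppressWarnings(cmdscale(m, k = n - 1, eig = TRUE))
  eig <- sc$eig
  tol <- max(abs(eig)) * 1e-8
  pos <- which(eig > tol)
  if (length(pos) == 0) {
    pts <- matrix(0, n, 1)
  } else {
    pts <- sc$points[, pos, drop = FALSE]
  }
  colnames(pts) <- paste0("Axis", seq_len(ncol(pts)))
  samples <- rownames(m) %||% paste0("s", seq_len(n))
  structure(
    list(
      points = dplyr::bind_cols(tibble(sample = samples), as_tibble(pts)),
      eigenvalues = eig[pos],
      var_explained = if (length(pos)) eig[pos] / sum(eig[pos]) else numeric(0),
      negative_eigenvalues = eig[eig < -tol]
    ),
    class = "halohab_pcoa"
  )
}

#' @export
print.halohab_pcoa <- function(x, ...) {
  cat("Principal coordinates analysis:",
      nrow(x$points), "samples,", length(x$eigenvalues), "positive axes\n")
  if (length(x$var_explained) > 0) {
    cat("Variance explained (first axes):",
        paste0(round(100 * head(x$var_explained, 3), 1), "%",
               collapse = ", "), "\n")
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy halohab_pcoa
#' @export
tidy.halohab_pcoa <- function(x, ...) x$points

#' @method glance halohab_pcoa
#' @export
glance.halohab_pcoa <- function(x, ...) {
  tibble(
    n_samples = nrow(x$points),
    n_positive_axes = length(x$eigenvalues),
    var_axis1 = x$var_explained[1] %||% NA_real_,
    var_axis2 = if (length(x$var_explained) >= 2) x$var_explained[2]
                else NA_real_,
    n_negative_eigenvalues = length(x$negative_eigenvalues)
  )
}

anosim_r <- function(ranks, same_group, n) {
  (mean(ranks[!same_group]) - mean(ranks[same_group])) / (n * (n - 1) / 4)
}

all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (p in sub) {
    for (i in seq_len(n)) {
      k <- k + 1L
      out[[k]] <- append(p, n, after = i - 1L)
    }
  }
  out
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based test of whether between-group dissimilarities exceed
#' within-group dissimilarities. The upper-triangle dissimilarities are
#' ranked (midranks for ties) and
#' `R = (mean between-group rank - mean within-group rank) / (n(n-1)/4)`,
#' so `R` lies in `[-1, 1]` with 1 meaning complete group separation.
#' Significance comes from random relabelings of the samples with the
#' add-one convention `p = (1 + #permuted R >= observed R) / (1 + n_perm)`;
#' with `exhaustive = TRUE` all `n!` relabelings are enumerated and the
#' p-value is the exact exceedance fraction (observed labeling included).
#'
#' @param d Symmetric dissimilarity matrix (or `dist`).
#' @param groups Group (site) label per sample, aligned with the rows of
#'   `d`; at least 2 groups with at least 2 samples each.
#' @param n_perm Number of random permutations.
#' @param seed Optional integer seed for the permutations.
#' @param exhaustive Enumerate all relabelings (only for n <= 8).
#'
#' @return An object of class `halohab_anosim`: list with `statistic`,
#'   `p_value`, `permutations`, `perm_stats`.
#' @export
anosim_test <- function(d, groups, n_perm = 999, seed = NULL,
                        exhaustive = FALSE) {
  m <- as.matrix(d)
  n <- nrow(m)
  groups <- as.factor(groups)
  if (length(groups) != n) abort("`groups` must label every sample in `d`.")
  if (nlevels(droplevels(groups)) < 2 || any(table(groups) < 2)) {
    abort("degenerate grouping: need >= 2 groups with >= 2 samples each.")
  }
  ut <- upper.tri(m)
  ranks <- rank(m[ut]) # midranks for ties
  pair_i <- row(m)[ut]
  pair_j <- col(m)[ut]
  obs <- anosim_r(ranks, groups[pair_i] == groups[pair_j], n)

  if (exhaustive) {
    if (n > 8) abort("exhaustive enumeration is limited to n <= 8 samples.")
    perms <- all_permutations(n)
    stats <- vapply(perms, function(p) {
      g <- groups[p]
      anosim_r(ranks, g[pair_i] == g[pair_j], n)
    }, numeric(1))
    p_value <- mean(stats >= obs - 1e-12)
    n_perm <- length(perms)
  } else {
    run <- function() {
      vapply(seq_len(n_perm), function(i) {
        g <- groups[sample.int(n)]
        anosim_r(ranks, g[pair_i] == g[pair_j], n)
      }, numeric(1))
    }
    stats <- if (is.null(seed)) run() else withr::with_seed(seed, run())
    p_value <- (1 + sum(stats >= obs - 1e-12)) / (1 + n_perm)
  }

  structure(
    list(statistic = obs, p_value = p_value, permutations = n_perm,
         perm_stats = stats, exhaustive = exhaustive),
    class = "halohab_anosim"
  )
}

#' @export
print.halohab_anosim <- function(x, ...) {
  cat(sprintf("ANOSIM R = %.4f, p = %.4g (%d %s permutations)\n",
              x$statistic, x$p_value, x$permutations,
              if (x$exhaustive) "exhaustive" else "random"))
  invisible(x)
}

#' @method tidy halohab_anosim
#' @export
tidy.halohab_anosim <- function(x, ...) {
  tibble(statistic = x$statistic, p.value = x$p_value,
         permutations = x$permutations)
}

#' @method glance halohab_anosim
#' @export
glance.halohab_anosim <- function(x, ...) tidy(x)

#' Welch's unequal-variance t-test
#'
#' Two-sided Welch t-test with Welch-Satterthwaite degrees of freedom. When
#' both groups have zero variance and equal means the statistic is defined
#' as 0 with p = 1; zero variance with unequal means is an error.
#'
#' @param x,y Numeric vectors, each with at least 2 values.
#'
#' @return One-row tibble: `statistic`, `df`, `p_value`, `mean_x`, `mean_y`,
#'   `estimate` (difference in means).
#' @examples
#' welch_t(c(1, 2, 3), c(2, 4, 6))
#' @export
welch_t <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) {
    abort("each group needs at least 2 values.")
  }
  se2 <- var(x) / length(x) + var(y) / length(y)
  if (se2 == 0) {
    if (isTRUE(all.equal(mean(x), mean(y)))) {
      return(tibble(statistic = 0, df = length(x) + length(y) - 2,
                    p_value = 1, mean_x = mean(x), mean_y = mean(y),
                    estimate = 0))
    }
    abort("degenerate variance: both groups constant with unequal means.")
  }
  ht <- t.test(x, y, var.equal = FALSE)
  tibble(
    statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = ht$p.value,
    mean_x = mean(x), mean_y = mean(y),
    estimate = mean(x) - mean(y)
  )
}
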