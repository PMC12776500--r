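# Group-level statistics. The exchangeable unit is the embryo: per-cell
# scores are first reduced to one empirical distribution (or median) per
# embryo, and genotype groups are compared by the ratio of average
# between-group to average within-group pairwise 1-D Wasserstein distances
# (Gini's mean difference applied to inter-embryo distances), with
# significance from permutation of group labels over embryos.

#' Median score per embryo and location
#'
#' One median per (embryo, location) cell group over defined scores only
#' (`NA` scores are excluded, midpoint convention for even counts). Groups
#' whose scores are all undefined are reported as missing with a warning.
#'
#' @param scores numeric per-cell scores (NA = undefined)
#' @param embryo_ids embryo id per cell
#' @param locations location label (bone element / cell type) per cell
#' @return data.frame `embryo`, `location`, `median`, `n`
#' @export
summarize_median <- function(scores, embryo_ids, locations) {
  stopifnot(length(scores) == length(embryo_ids),
            length(scores) == length(locations))
  key <- interaction(embryo_ids, locations, drop = TRUE, sep = "\r")
  med <- tapply(scores, key, function(v) stats::median(v[!is.na(v)]))
  n <- tapply(scores, key, function(v) sum(!is.na(v)))
  parts <- do.call(rbind, strsplit(names(med), "\r", fixed = TRUE))
  out <- data.frame(embryo = parts[, 1], location = parts[, 2],
                    median = as.numeric(med), n = as.integer(n),
                    stringsAsFactors = FALSE)
  out <- out[order(out$embryo, out$location), , drop = FALSE]
  rownames(out) <- NULL
  if (anyNA(out$median))
    warning(sum(is.na(out$median)),
            " embryo/location group(s) with no defined scores")
  out
}

#' Normalize marker intensities to a reference group mean
#'
#' Divides each value by the mean of the reference values (e.g. SOX9
#' intensity normalized to the mean of wild-type chondro-PZ cells in a
#' reference bone element), so the reference group's mean maps to 1.
#'
#' @param values numeric intensities
#' @param reference_values numeric reference intensities (nonempty, positive
#'   mean)
#' @return `values / mean(reference_values)`
#' @export
normalize_marker <- function(values, reference_values) {
  if (length(reference_values) == 0)
    stop("empty reference", call. = FALSE)
  m <- mean(reference_values)
  if (!is.finite(m) || m <= 0)
    stop("reference mean must be finite and > 0", call. = FALSE)
  values / m
}

#' First-order 1-D Wasserstein distance between empirical distributions
#'
#' Equal-weight empirical measures; for equal sample sizes this is the mean
#' absolute difference of matched sorted values, and in general the integral
#' of |Qa - Qb| over the unit interval, evaluated exactly on the piecewise-
#' constant quantile functions.
#'
#' @param sample_a,sample_b nonempty numeric vectors
#' @return distance, in the samples' units
#' @export
wasserstein_1d <- function(sample_a, sample_b) {
  if (length(sample_a) == 0 || length(sample_b) == 0)
    stop("empty sample", call. = FALSE)
  a <- sort(sample_a); b <- sort(sample_b)
  n <- length(a); m <- length(b)
  if (n == m) return(mean(abs(a - b)))
  q <- sort(unique(c(seq_len(n) / n, seq_len(m) / m)))
  w <- diff(c(0, q))
  u <- q - w / 2  # interval midpoints; Q is constant on each interval
  sum(w * abs(a[ceiling(u * n)] - b[ceiling(u * m)]))
}

ratio_from_D <- function(D, same_group) {
  between <- mean(D[!same_group])
  within <- mean(D[same_group])
  if (within == 0) return(Inf)
  between / within
}

#' Wasserstein-ratio (Gini's mean difference) group statistic
#'
#' All unordered embryo pairs (i, j) get D(i, j) = 1-D Wasserstein distance
#' between the embryos' per-cell score distributions. The statistic is the
#' mean of D over between-group pairs divided by the mean of D over the
#' pooled same-group pairs (Gini's mean difference of each set) - analogous
#' to an F statistic but non-parametric, sensitive to both location and
#' dispersion differences.
#'
#' @param values list of numeric vectors, one per embryo (per-cell scores)
#' @param groups group label per embryo (exactly 2 distinct labels)
#' @return the ratio (dimensionless); the pairwise distance matrix is
#'   attached as attribute `D`
#' @export
gini_ratio_statistic <- function(values, groups) {
  groups <- as.character(groups)
  k <- length(values)
  if (k != length(groups)) stop("values/groups length mismatch", call. = FALSE)
  if (length(unique(groups)) != 2)
    stop("exactly two groups required", call. = FALSE)
  if (min(table(groups)) < 1 || k < 3 || max(table(groups)) < 2)
    stop("degenerate design: need at least one within-group pair", call. = FALSE)
  D <- matrix(0, k, k)
  for (i in seq_len(k - 1)) for (j in (i + 1):k)
    D[i, j] <- D[j, i] <- wasserstein_1d(values[[i]], values[[j]])
  ut <- upper.tri(D)
  same <- outer(groups, groups, `==`)[ut]
  stat <- ratio_from_D(D[ut], same)
  attr(stat, "D") <- D
  stat
}

#' Wasserstein-ratio permutation test over embryos
#'
#' Tests whether two groups of embryo-level score distributions differ, using
#' [gini_ratio_statistic()] as the test statistic and permutation of group
#' labels over embryos (the exchangeable unit) as the reference distribution.
#' When the number of distinct label assignments is at most `B`, all of them
#' are enumerated and the p-value is the exact proportion of assignments with
#' a statistic at least the observed one (the observed assignment included,
#' so p > 0). Otherwise `B` random permutations are drawn with the seeded
#' generator and the add-one convention p = (1 + #exceedances) / (B + 1) is
#' used. Equality with the observed statistic counts as an exceedance.
#'
#' @param values list of numeric vectors, one per embryo
#' @param groups group label per embryo (2 groups)
#' @param B maximum number of permutations (default 999)
#' @param seed integer seed for the random-permutation path (optional)
#' @return a `wass_perm_test` object: `statistic`, `p_value`,
#'   `n_permutations`, `exhaustive`, `perm_stats`, `seed`
#' @export
wasserstein_ratio_test <- function(values, groups, B = 999, seed = NULL) {
  if (B < 1) stop("B must be >= 1", call. = FALSE)
  groups <- as.character(groups)
  obs <- gini_ratio_statistic(values, groups)
  D <- attr(obs, "D")
  obs <- as.numeric(obs)
  k <- length(groups)
  ut <- upper.tri(D)
  Dv <- D[ut]
  lev <- unique(groups)
  n1 <- sum(groups == lev[1])
  n_assign <- choose(k, n1)
  if (n_assign <= B) {
    sel <- utils::combn(k, n1)
    perm_stats <- apply(sel, 2, function(ix) {
      g <- rep(lev[2], k); g[ix] <- lev[1]
      ratio_from_D(Dv, outer(g, g, `==`)[ut])
    })
    p <- sum(perm_stats >= obs) / n_assign
    exhaustive <- TRUE
    n_perm <- n_assign
  } else {
    if (B < 99)
      warning("B = ", B, " permutations give poor p-value resolution")
    if (!is.null(seed)) set.seed(seed)
    perm_stats <- vapply(seq_len(B), function(b) {
      g <- sample(groups)
      ratio_from_D(Dv, outer(g, g, `==`)[ut])
    }, numeric(1))
    p <- (1 + sum(perm_stats >= obs)) / (B + 1)
    exhaustive <- FALSE
    n_perm <- B
  }
  structure(list(statistic = obs, p_value = p, n_permutations = n_perm,
                 exhaustive = exhaustive, perm_stats = perm_stats,
                 seed = seed, groups = table(groups), D = D),
            class = "wass_perm_test")
}

#' @export
print.wass_perm_test <- function(x, ...) {
  cat("Wasserstein-ratio permutation test (embryo-level)\n")
  cat(sprintf("  groups: %s\n",
              paste(sprintf("%s (n=%d)", names(x$groups), x$groups), collapse = " vs ")))
  cat(sprintf("  statistic (between/within Gini mean Wasserstein): %.4f\n",
              x$statistic))
  cat(sprintf("  p-value: %.4g (%s, %d permutations)\n", x$p_value,
              if (x$exhaustive) "exhaustive" else "sampled", x$n_permutations))
  invisible(x)
}

#' Histogram of the permutation distribution with the observed statistic
#' @param x a `wass_perm_test`
#' @param ... passed to [graphics::hist()]
#' @return invisibly, `x`
#' @export
plot.wass_perm_test <- function(x, ...) {
  graphics::hist(x$perm_stats, breaks = 30, col = "grey85", border = "white",
                 main = "Permutation distribution",
                 xlab = "between/within Wasserstein ratio", ...)
  graphics::abline(v = x$statistic, col = "firebrick", lwd = 2)
  invisible(x)
}
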