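#' Randomization test for a difference in hybrid proportions
#'
#' Bespoke permutation test: the statistic is the difference in the
#' proportion of flagged (hybrid) individuals between two groups,
#' `mean(flags1) - mean(flags2)`. Null replicates pool the indicator
#' vectors and reassign group membership by sampling without replacement,
#' preserving group sizes. The p-value uses the add-one convention
#' `p = (1 + b) / (n_reps + 1)` where `b` counts null statistics at least
#' as extreme as the observed one (`|null| >= |observed|` two-sided,
#' `null >= observed` one-sided), so p-values are never exactly 0.
#'
#' @param flags1,flags2 Logical (or 0/1) hybrid indicator vectors, one
#'   entry per individual; both nonempty.
#' @param n_reps Number of randomizations (default `1e5`).
#' @param sidedness `"two_sided"` (default) or `"one_sided_greater"`.
#' @param seed Integer seed for the permutation stream.
#' @return List of class `randomization_result` with elements
#'   `observed_stat, p_value, n_reps, sidedness, seed, n1, n2`.
#' @export
randomize_proportion_test <- function(flags1, flags2, n_reps = 1e5,
                                      sidedness = c("two_sided",
                                                    "one_sided_greater"),
                                      seed = 1L) {
  sidedness <- match.arg(sidedness)
  flags1 <- as.logical(flags1); flags2 <- as.logical(flags2)
  n1 <- length(flags1); n2 <- length(flags2)
  if (n1 == 0L || n2 == 0L) stop("both groups must be nonempty")
  stopifnot(n_reps >= 1)
  obs <- mean(flags1) - mean(flags2)
  n <- n1 + n2
  K <- sum(flags1) + sum(flags2)
  tot_mean <- K / n
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(as.integer(seed))
  # permuting a binary pool == drawing which slots of group 1 hold a 1;
  # k1 hits among the first n1 slots of a random permutation
  eps <- 1e-12
  b <- 0L
  for (r in seq_len(n_reps)) {
    k1 <- sum(sample.int(n, n1) <= K)
    stat <- k1 / n1 - (K - k1) / n2
    hit <- if (sidedness == "two_sided") {
      abs(stat) >= abs(obs) - eps
    } else stat >= obs - eps
    b <- b + hit
  }
  structure(list(observed_stat = obs, p_value = (1 + b) / (n_reps + 1),
                 n_reps = n_reps, sidedness = sidedness,
                 seed = as.integer(seed), n1 = n1, n2 = n2,
                 prop1 = mean(flags1), prop2 = mean(flags2)),
            class = "randomization_result")
}

#' @export
print.randomization_result <- function(x, ...) {
  cat(sprintf(
    "<randomization_result> diff = %.4f (%.3f vs %.3f), p = %.5g [%s, %d reps]\n",
    x$observed_stat, x$prop1, x$prop2, x$p_value, x$sidedness, x$n_reps))
  invisible(x)
}

#' Pairwise hybrid-proportion comparisons across regions
#'
#' Runs [randomize_proportion_test()] for every pair of the given regions
#' on one of the two classification flags, then applies the sequential
#' Bonferroni (Holm) correction across the pairs.
#'
#' @param result An `hindex_result`.
#' @param region Region per row of `result`, or `NULL` to join from
#'   `dataset` metadata.
#' @param dataset Optional [genotype_dataset()] supplying regions.
#' @param method `"f1"` (window rule) or `"ci"` (interval rule).
#' @param regions Regions to compare (default: all with `N >= min_n`).
#' @param min_n Minimum region size when `regions` is `NULL` (default 30).
#' @param n_reps,sidedness,seed Passed to [randomize_proportion_test()];
#'   the seed is advanced per pair.
#' @param alpha Family-wise level for the Holm flags.
#' @return Data frame with one row per pair: proportions, sizes, raw
#'   p-value and Holm significance flag.
#' @export
compare_regions <- function(result, region = NULL, dataset = NULL,
                            method = c("f1", "ci"), regions = NULL,
                            min_n = 30L, n_reps = 1e5,
                            sidedness = "two_sided", seed = 1L,
                            alpha = 0.05) {
  method <- match.arg(method)
  if (is.null(region)) {
    if (is.null(dataset) || is.null(dataset$meta)) {
      stop("supply `region` or a dataset with metadata")
    }
    m <- dataset$meta
    region <- m$region[match(result$locality, m$locality_id)]
  }
  flag <- if (method == "f1") result$is_F1 else result$is_hybrid_ci
  keep <- !is.na(region)
  sp <- split(flag[keep], region[keep])
  if (is.null(regions)) {
    regions <- names(sp)[vapply(sp, length, 0L) >= min_n]
  }
  if (length(regions) < 2L) stop("need at least two regions to compare")
  prs <- utils::combn(regions, 2L)
  rows <- lapply(seq_len(ncol(prs)), function(k) {
    r1 <- prs[1, k]; r2 <- prs[2, k]
    rt <- randomize_proportion_test(sp[[r1]], sp[[r2]], n_reps = n_reps,
                                    sidedness = sidedness,
                                    seed = as.integer(seed) + k)
    data.frame(region1 = r1, region2 = r2,
               prop1 = rt$prop1, prop2 = rt$prop2,
               n1 = rt$n1, n2 = rt$n2, p_value = rt$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$significant <- holm_sequential_bonferroni(out$p_value, alpha = alpha)
  out
}

#' Sequential Bonferroni (Holm) significance flags
#'
#' The step-down sequential Bonferroni procedure: the i-th smallest of m
#' p-values is significant iff it is at most `alpha / (m - i + 1)` and all
#' smaller p-values were significant. Implemented through
#' [stats::p.adjust()] with `method = "holm"`; flags are returned in the
#' input order and are never more permissive than plain Bonferroni.
#'
#' @param p_values Numeric vector in `[0, 1]`. Censored reported values
#'   such as `"<.00001"` can be converted with [parse_reported_p()].
#' @param alpha Family-wise error level (default 0.05).
#' @return Logical vector of significance flags, input order; empty input
#'   gives an empty output.
#' @export
holm_sequential_bonferroni <- function(p_values, alpha = 0.05) {
  if (!length(p_values)) return(logical(0))
  stopifnot(all(p_values >= 0 & p_values <= 1))
  stats::p.adjust(p_values, method = "holm") <= alpha
}

#' Parse reported p-values, including censored "<x" entries
#'
#' Published tables often report very small p-values as upper bounds
#' (e.g. `"<.00001"`). Those are parsed to a small stand-in value
#' (`censored_value`) adequate for Holm ordering, and flagged in the
#' `"censored"` attribute.
#'
#' @param x Character (or numeric) vector.
#' @param censored_value Value standing in for censored entries
#'   (default `1e-6`).
#' @return Numeric vector with a logical `"censored"` attribute.
#' @export
parse_reported_p <- function(x, censored_value = 1e-6) {
  x <- as.character(x)
  cens <- grepl("^\\s*<", x)
  val <- as.numeric(sub("^\\s*<\\s*", "", x))
  val[cens] <- censored_value
  structure(val, censored = cens)
}

#' Evanno delta-K from a per-K replicate log-probability table
#'
#' The rate-of-change statistic used to pick the number of clusters from
#' replicate model log-probabilities:
#' `deltaK(K) = |mean L(K+1) - 2 mean L(K) + mean L(K-1)| / sd L(K)`,
#' defined at interior K of a contiguous grid; the replicate standard
#' deviation uses the sample (n-1) denominator. Cluster inference itself
#' is external; this consumes any replicate log-probability table.
#'
#' @param lnp Data frame with columns `K` and `lnp` (one row per
#'   replicate), or a matrix with one column per K (colnames the K
#'   values) and one row per replicate.
#' @return Data frame `K, mean_lnp, sd_lnp, delta_K` (`NA` at the grid
#'   ends; `Inf` with a warning where the replicate SD is 0).
#' @export
evanno_delta_k <- function(lnp) {
  if (is.matrix(lnp)) {
    Ks <- as.integer(colnames(lnp))
    reps <- lapply(seq_along(Ks), function(j) lnp[, j])
  } else {
    stopifnot(all(c("K", "lnp") %in% names(lnp)))
    Ks <- sort(unique(lnp$K))
    reps <- lapply(Ks, function(k) lnp$lnp[lnp$K == k])
  }
  if (length(Ks) < 3L) stop("need at least 3 consecutive K values")
  if (any(diff(Ks) != 1L)) stop("K grid must be contiguous")
  if (any(vapply(reps, length, 0L) < 2L)) {
    stop("need >= 2 replicates per K")
  }
  mu <- vapply(reps, mean, numeric(1))
  sdv <- vapply(reps, stats::sd, numeric(1))
  dK <- rep(NA_real_, length(Ks))
  interior <- 2:(length(Ks) - 1L)
  num <- abs(mu[interior + 1L] - 2 * mu[interior] + mu[interior - 1L])
  if (any(sdv[interior] == 0)) {
    warning("zero replicate SD at some K; delta-K infinite there",
            call. = FALSE)
  }
  dK[interior] <- num / sdv[interior]
  data.frame(K = Ks, mean_lnp = mu, sd_lnp = sdv, delta_K = dK)
}
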