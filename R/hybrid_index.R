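#' Estimate parental reference allele frequencies
#'
#' Computes per-locus allele frequencies for the two pooled parental
#' reference groups, with add-alpha smoothing over the union allele set so
#' that no allele observed anywhere in the dataset has probability zero in
#' either reference:
#' `p = (count + alpha) / (copies + alpha * K)`,
#' where `K` is the number of alleles in the locus's universe. The default
#' `alpha = 0.5` is a Jeffreys-style pseudocount; `alpha = 0` gives raw
#' proportions. A locus untyped in a reference group is dropped with a
#' warning.
#'
#' @param dataset A [genotype_dataset()].
#' @param references A `reference_pair` from [pool_references()].
#' @param alpha Smoothing pseudocount per allele (default `0.5`).
#' @param allele_universe `"dataset"` (default; union over all individuals)
#'   or `"references"` (union over the two reference groups only).
#' @return An `allele_freq_table`: per locus, a matrix with rows `p_A`,
#'   `p_B` over the allele universe, plus allele-copy counts `n_A`, `n_B`.
#' @export
estimate_frequencies <- function(dataset, references, alpha = 0.5,
                                 allele_universe = c("dataset",
                                                     "references")) {
  allele_universe <- match.arg(allele_universe)
  stopifnot(alpha >= 0)
  ia <- match(references$ref_A, dataset$individuals$id)
  ib <- match(references$ref_B, dataset$individuals$id)
  if (anyNA(ia) || anyNA(ib)) stop("reference ids not in dataset")
  loci <- locus_names(dataset)
  tab <- vector("list", length(loci)); names(tab) <- loci
  drop <- character()
  for (j in seq_along(loci)) {
    copies <- function(idx) {
      v <- c(dataset$calls_a[idx, j], dataset$calls_b[idx, j])
      v[!is.na(v)]
    }
    ca <- copies(ia); cb <- copies(ib)
    if (!length(ca) || !length(cb)) { drop <- c(drop, loci[j]); next }
    universe <- if (allele_universe == "dataset") {
      sort(unique(c(dataset$calls_a[, j], dataset$calls_b[, j])))
    } else sort(unique(c(ca, cb)))
    universe <- universe[!is.na(universe)]
    K <- length(universe)
    cnt <- function(v) {
      tabulate(match(v, universe), nbins = K)
    }
    pa <- (cnt(ca) + alpha) / (length(ca) + alpha * K)
    pb <- (cnt(cb) + alpha) / (length(cb) + alpha * K)
    m <- rbind(p_A = pa, p_B = pb)
    colnames(m) <- as.character(universe)
    tab[[j]] <- list(freq = m, n_A = length(ca), n_B = length(cb))
  }
  if (length(drop)) {
    warning("loci untyped in a reference group dropped: ",
            paste(drop, collapse = ", "), call. = FALSE)
    tab <- tab[!names(tab) %in% drop]
  }
  if (!length(tab)) stop("no usable loci")
  structure(tab, class = "allele_freq_table")
}

#' @export
print.allele_freq_table <- function(x, ...) {
  K <- vapply(x, function(l) ncol(l$freq), 0L)
  cat("<allele_freq_table> ", length(x), " loci; alleles/locus ",
      min(K), "-", max(K), "\n", sep = "")
  invisible(x)
}

#' Build an allele frequency table directly from frequency vectors
#'
#' Mostly used by the synthetic-data generator and in tests, where the
#' generating frequencies are known exactly.
#'
#' @param freq_a,freq_b Lists (one element per locus) of named numeric
#'   vectors of allele frequencies; names are allele sizes. Each vector
#'   must sum to 1.
#' @param n_a,n_b Nominal allele-copy counts (default `Inf`, i.e. known
#'   frequencies).
#' @return An `allele_freq_table`.
#' @export
allele_freq_table <- function(freq_a, freq_b, n_a = Inf, n_b = Inf) {
  stopifnot(length(freq_a) == length(freq_b))
  nm <- names(freq_a)
  if (is.null(nm)) nm <- paste0("L", seq_along(freq_a))
  out <- vector("list", length(freq_a)); names(out) <- nm
  for (j in seq_along(freq_a)) {
    alle <- sort(unique(c(names(freq_a[[j]]), names(freq_b[[j]]))))
    pa <- stats::setNames(rep(0, length(alle)), alle)
    pb <- pa
    pa[names(freq_a[[j]])] <- freq_a[[j]]
    pb[names(freq_b[[j]])] <- freq_b[[j]]
    if (abs(sum(pa) - 1) > 1e-9 || abs(sum(pb) - 1) > 1e-9) {
      stop("frequencies at locus ", nm[j], " do not sum to 1")
    }
    m <- rbind(p_A = as.numeric(pa), p_B = as.numeric(pb))
    colnames(m) <- alle
    out[[j]] <- list(freq = m, n_A = n_a, n_B = n_b)
  }
  structure(out, class = "allele_freq_table")
}

# Per-allele-copy mixture components for one individual: returns list of
# vectors pA, pB over the individual's non-missing allele copies.
.copy_probs <- function(dataset, i, freqs) {
  loci <- intersect(locus_names(dataset), names(freqs))
  pa <- numeric(0); pb <- numeric(0)
  for (lc in loci) {
    f <- freqs[[lc]]$freq
    for (v in c(dataset$calls_a[i, lc], dataset$calls_b[i, lc])) {
      if (is.na(v)) next
      k <- match(as.character(v), colnames(f))
      if (is.na(k)) {
        stop("allele ", v, " at locus ", lc,
             " absent from the frequency table; re-estimate frequencies ",
             "with allele_universe = 'dataset' or alpha > 0")
      }
      pa <- c(pa, f["p_A", k]); pb <- c(pb, f["p_B", k])
    }
  }
  if (!length(pa)) stop("individual ", dataset$individuals$id[i],
                        ": all loci missing")
  if (any(pa == 0 & pb == 0)) {
    stop("observed allele has probability 0 in both references; ",
         "use smoothing (alpha > 0)")
  }
  list(p_A = pa, p_B = pb,
       n_loci = length(intersect(loci,
         locus_names(dataset)[!is.na(dataset$calls_a[i, ])])))
}

#' Log-likelihood of a hybrid index for one individual
#'
#' The codominant mixture likelihood: each non-missing allele copy with
#' reference frequencies `p_A`, `p_B` contributes
#' `log(h * p_A + (1 - h) * p_B)`. Orientation: `h = 1` is pure species A,
#' `h = 0` pure species B.
#'
#' @param dataset A [genotype_dataset()].
#' @param individual Individual id (or row index).
#' @param freqs An `allele_freq_table`.
#' @param h Hybrid index value(s) in `[0, 1]`; vectorized.
#' @return Numeric vector of log-likelihoods, same length as `h`.
#' @export
loglik_h <- function(dataset, individual, freqs, h) {
  stopifnot(all(h >= 0 & h <= 1))
  i <- if (is.character(individual)) {
    match(individual, dataset$individuals$id)
  } else individual
  if (is.na(i)) stop("unknown individual")
  cp <- .copy_probs(dataset, i, freqs)
  vapply(h, function(hh) sum(log(hh * cp$p_A + (1 - hh) * cp$p_B)),
         numeric(1))
}

# core ML + profile-likelihood machinery on copy-probability vectors
.hindex_one <- function(pa, pb, ci_drop = stats::qchisq(0.95, 1) / 2,
                        grid_step = 1e-3, tol = 1e-9) {
  ll <- function(h) sum(log(h * pa + (1 - h) * pb))
  grid <- seq(0, 1, by = grid_step)
  # vectorized scan: copies x grid mixture matrix
  lg <- colSums(log(outer(pa - pb, grid) + pb))
  k <- which.max(lg)
  lo <- grid[max(1L, k - 1L)]; hi <- grid[min(length(grid), k + 1L)]
  if (lo < hi) {
    op <- stats::optimize(ll, c(lo, hi), maximum = TRUE, tol = tol)
    h_hat <- op$maximum; l_max <- op$objective
  } else {
    h_hat <- grid[k]; l_max <- lg[k]
  }
  # boundary beats interior refinement when the likelihood is monotone
  for (b in c(0, 1)) {
    lb <- ll(b)
    if (lb >= l_max) { h_hat <- b; l_max <- lb }
  }
  target <- l_max - ci_drop
  ci_lo <- if (ll(0) >= target) 0 else {
    stats::uniroot(function(h) ll(h) - target, c(0, h_hat),
                   tol = 1e-8)$root
  }
  ci_hi <- if (ll(1) >= target) 1 else {
    stats::uniroot(function(h) ll(h) - target, c(h_hat, 1),
                   tol = 1e-8)$root
  }
  c(h_hat = h_hat, logL_max = l_max, ci_low = ci_lo, ci_high = ci_hi)
}

#' Maximum-likelihood hybrid index with profile-likelihood intervals
#'
#' For each individual, maximizes the mixture log-likelihood over
#' `h in [0, 1]` (grid scan at `grid_step` followed by bounded refinement),
#' and attaches a 95% profile-likelihood confidence interval: the set of
#' `h` whose log-likelihood is within `qchisq(0.95, 1) / 2 = 1.92` of the
#' maximum, with endpoints found by root bisection and clamped to
#' `[0, 1]`. Clamping is what makes the "CI extends to 0 or 1"
#' classification rule meaningful. Missing loci are skipped per
#' individual.
#'
#' Both classification rules are attached: `is_F1` if `h_hat` falls inside
#' `f1_bounds` (inclusive), and `is_hybrid_ci` if the CI excludes both 0
#' and 1 (see [classify_f1()], [classify_ci()]).
#'
#' @param dataset A [genotype_dataset()].
#' @param freqs An `allele_freq_table` ([estimate_frequencies()]).
#' @param individuals Ids to estimate (default: all).
#' @param conf Confidence level for the profile interval (default `0.95`).
#' @param f1_bounds Inclusive bounds of the F1 classification window.
#' @param grid_step Grid resolution of the initial scan.
#' @return A data frame of class `hindex_result` with columns
#'   `individual, locality, h_hat, logL_max, ci_low, ci_high,
#'   n_loci_used, is_F1, is_hybrid_ci`.
#' @export
estimate_hybrid_index <- function(dataset, freqs, individuals = NULL,
                                  conf = 0.95, f1_bounds = c(0.25, 0.75),
                                  grid_step = 1e-3) {
  ids <- if (is.null(individuals)) dataset$individuals$id else individuals
  idx <- match(ids, dataset$individuals$id)
  if (anyNA(idx)) stop("unknown individual ids")
  drop <- stats::qchisq(conf, 1) / 2
  out <- matrix(NA_real_, length(idx), 4)
  nl <- integer(length(idx))
  for (r in seq_along(idx)) {
    cp <- .copy_probs(dataset, idx[r], freqs)
    out[r, ] <- .hindex_one(cp$p_A, cp$p_B, ci_drop = drop,
                            grid_step = grid_step)
    nl[r] <- cp$n_loci
  }
  res <- data.frame(individual = ids,
                    locality = dataset$individuals$locality[idx],
                    h_hat = out[, 1], logL_max = out[, 2],
                    ci_low = out[, 3], ci_high = out[, 4],
                    n_loci_used = nl, stringsAsFactors = FALSE)
  res$is_F1 <- classify_f1(res, bounds = f1_bounds)
  res$is_hybrid_ci <- classify_ci(res)
  class(res) <- c("hindex_result", "data.frame")
  res
}

#' F1 classification by hybrid-index window
#'
#' Flags individuals whose point estimate falls inside the window
#' calibrated from laboratory F1 hybrids (default `[0.25, 0.75]`,
#' inclusive at both ends). The window may also capture some backcross or
#' advanced-generation genotypes.
#'
#' @param result An `hindex_result` (or any data frame with `h_hat`).
#' @param bounds Length-2 numeric, `0 <= low < high <= 1`.
#' @return Logical vector.
#' @export
classify_f1 <- function(result, bounds = c(0.25, 0.75)) {
  stopifnot(length(bounds) == 2, bounds[1] < bounds[2],
            bounds[1] >= 0, bounds[2] <= 1)
  result$h_hat >= bounds[1] & result$h_hat <= bounds[2]
}

#' Hybrid classification by confidence interval
#'
#' Flags individuals as hybrids of undetermined class when the 95%
#' interval excludes both parental indices, i.e. does not extend to 0 or
#' to 1.
#'
#' @param result An `hindex_result` (columns `ci_low`, `ci_high`).
#' @param tol Numerical tolerance for "touching" a boundary.
#' @return Logical vector.
#' @export
classify_ci <- function(result, tol = 1e-9) {
  result$ci_low > tol & result$ci_high < 1 - tol
}

#' Per-region admixture summary
#'
#' For each region, the proportion of F1-classified individuals, the
#' proportion of CI-classified hybrids of undetermined class (which
#' includes F1s), and the derived proportion of advanced-generation
#' hybrids (`prop_undetermined - prop_F1`, clipped at 0 with a warning if
#' the two rules disagree in the unexpected direction).
#'
#' @param result An `hindex_result`.
#' @param region Region assignment per row of `result` (vector), or
#'   `NULL` to use the dataset metadata joined on locality via `dataset`.
#' @param dataset Optional [genotype_dataset()] supplying `region` from
#'   its metadata.
#' @return Data frame with columns `region, N, prop_F1,
#'   prop_undetermined, prop_advanced`.
#' @export
summarize_region <- function(result, region = NULL, dataset = NULL) {
  if (is.null(region)) {
    if (is.null(dataset) || is.null(dataset$meta)) {
      stop("supply `region` or a dataset with metadata")
    }
    m <- dataset$meta
    region <- m$region[match(result$locality, m$locality_id)]
  }
  stopifnot(length(region) == nrow(result))
  keep <- !is.na(region)
  sp <- split(seq_len(nrow(result))[keep], region[keep])
  if (!length(sp)) stop("no individuals with a region assignment")
  out <- do.call(rbind, lapply(names(sp), function(rg) {
    i <- sp[[rg]]
    pf <- mean(result$is_F1[i]); pu <- mean(result$is_hybrid_ci[i])
    adv <- pu - pf
    if (adv < 0) {
      warning("region ", rg, ": more F1-flagged than CI-flagged ",
              "individuals; prop_advanced clipped at 0", call. = FALSE)
      adv <- 0
    }
    data.frame(region = rg, N = length(i), prop_F1 = pf,
               prop_undetermined = pu, prop_advanced = adv,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
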