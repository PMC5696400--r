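#' Construct a labelled symmetric distance matrix
#'
#' @param values Symmetric numeric matrix with zero diagonal.
#' @param labels Locality labels (default from dimnames).
#' @param kind One of `"fst"`, `"rst"`, `"geographic_km"`, `"euclidean"`.
#' @return The matrix with class `hz_dist` and a `kind` attribute.
#' @export
dist_matrix <- function(values, labels = NULL, kind = "euclidean") {
  values <- as.matrix(values)
  if (!is.null(labels)) dimnames(values) <- list(labels, labels)
  if (is.null(rownames(values))) {
    dimnames(values) <- list(paste0("L", seq_len(nrow(values))),
                             paste0("L", seq_len(nrow(values))))
  }
  if (!isSymmetric(unname(values), tol = 1e-8)) {
    stop("distance matrix must be symmetric")
  }
  if (any(abs(diag(values)) > 1e-12)) stop("diagonal must be zero")
  kind <- match.arg(kind, c("fst", "rst", "geographic_km", "euclidean"))
  structure(values, kind = kind, class = c("hz_dist", "matrix", "array"))
}

#' @export
print.hz_dist <- function(x, ...) {
  cat("<hz_dist kind=", attr(x, "kind"), "> ", nrow(x), " localities\n",
      sep = "")
  print(unclass(x)[seq_len(min(6L, nrow(x))), seq_len(min(6L, ncol(x)))])
  invisible(x)
}

.upper <- function(m) m[upper.tri(m)]

# allele copies (sizes) per locus for a set of individual row indices
.pop_copies <- function(dataset, idx, j) {
  v <- c(dataset$calls_a[idx, j], dataset$calls_b[idx, j])
  v[!is.na(v)]
}

#' Heterozygosity and G_is diversity statistics
#'
#' Per locality (restricted to localities with at least `min_n` typed
#' individuals) and per locus: observed heterozygosity, unbiased expected
#' heterozygosity `H_exp = (2n / (2n - 1)) * (1 - sum(p^2))`, and the
#' heterozygosity-based inbreeding statistic `G_is = 1 - H_obs / H_exp`,
#' with a permutation p-value obtained by re-pairing the locality's
#' allele copies into random genotypes (expected frequencies are
#' invariant under this shuffle, so only `H_obs` varies). The multilocus
#' `G_is` uses summed heterozygosities, `1 - sum(H_obs) / sum(H_exp)`.
#' The default alternative is one-sided towards heterozygote deficit
#' (`G_is > 0`), the usual screen for inbreeding and null alleles.
#'
#' @param dataset A [genotype_dataset()].
#' @param min_n Minimum typed individuals per locality (default 20).
#' @param n_perms Genotype permutations for the p-value (default 999).
#' @param alternative `"deficit"` (default), `"excess"`, or
#'   `"two_sided"`.
#' @param seed Integer seed.
#' @return List with data frames `per_locus` (`locality, locus, n,
#'   H_obs, H_exp, G_is, p_value`; `G_is` is `NA` for monomorphic loci)
#'   and `multilocus` (`locality, G_is, p_value`).
#' @export
diversity <- function(dataset, min_n = 20L, n_perms = 999L,
                      alternative = c("deficit", "excess", "two_sided"),
                      seed = 1L) {
  alternative <- match.arg(alternative)
  locs <- sort(unique(dataset$individuals$locality))
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(as.integer(seed))
  per <- list(); multi <- list()
  for (loc in locs) {
    idx <- which(dataset$individuals$locality == loc)
    if (length(idx) < min_n) next
    L <- n_loci(dataset)
    ho <- he <- rep(NA_real_, L)
    # per-locus permutation replicates of H_obs
    perm_ho <- matrix(NA_real_, n_perms, L)
    for (j in seq_len(L)) {
      a1 <- dataset$calls_a[idx, j]; a2 <- dataset$calls_b[idx, j]
      typed <- !is.na(a1)
      n <- sum(typed)
      if (n < 2L) next
      ho[j] <- mean(a1[typed] != a2[typed])
      copies <- c(a1[typed], a2[typed])
      p <- tabulate(match(copies, unique(copies))) / (2 * n)
      he[j] <- (2 * n / (2 * n - 1)) * (1 - sum(p^2))
      for (b in seq_len(n_perms)) {
        sh <- sample(copies)
        perm_ho[b, j] <- mean(sh[seq_len(n)] != sh[n + seq_len(n)])
      }
    }
    gis <- ifelse(he > 0, 1 - ho / he, NA_real_)
    pv <- rep(NA_real_, L)
    for (j in seq_len(L)) {
      if (is.na(gis[j])) next
      gperm <- 1 - perm_ho[, j] / he[j]
      pv[j] <- .perm_p(gis[j], gperm, alternative)
    }
    per[[loc]] <- data.frame(
      locality = loc, locus = locus_names(dataset),
      n = length(idx), H_obs = ho, H_exp = he, G_is = gis,
      p_value = pv, stringsAsFactors = FALSE)
    ok <- !is.na(ho) & !is.na(he) & he > 0
    if (any(ok)) {
      g_multi <- 1 - sum(ho[ok]) / sum(he[ok])
      gperm_multi <- 1 - rowSums(perm_ho[, ok, drop = FALSE]) /
        sum(he[ok])
      multi[[loc]] <- data.frame(
        locality = loc, G_is = g_multi,
        p_value = .perm_p(g_multi, gperm_multi, alternative),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(per)) stop("no locality meets min_n = ", min_n)
  list(per_locus = do.call(rbind, c(per, make.row.names = FALSE)),
       multilocus = do.call(rbind, c(multi, make.row.names = FALSE)))
}

.perm_p <- function(obs, perm, alternative) {
  B <- length(perm)
  eps <- 1e-12
  switch(alternative,
         deficit = (1 + sum(perm >= obs - eps)) / (B + 1),
         excess = (1 + sum(perm <= obs + eps)) / (B + 1),
         two_sided = min(1, 2 * min(
           (1 + sum(perm >= obs - eps)) / (B + 1),
           (1 + sum(perm <= obs + eps)) / (B + 1))))
}

# Weir-Cockerham variance components for one pair of populations at one
# locus; returns c(a, b, c) summed over alleles.
.wc_components <- function(a1_1, a2_1, a1_2, a2_2) {
  t1 <- !is.na(a1_1); t2 <- !is.na(a1_2)
  n1 <- sum(t1); n2 <- sum(t2)
  if (n1 < 2L || n2 < 2L) return(c(0, 0, 0, used = 0))
  alleles <- unique(c(a1_1[t1], a2_1[t1], a1_2[t2], a2_2[t2]))
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  A <- B <- C <- 0
  for (al in alleles) {
    p1 <- (sum(a1_1[t1] == al) + sum(a2_1[t1] == al)) / (2 * n1)
    p2 <- (sum(a1_2[t2] == al) + sum(a2_2[t2] == al)) / (2 * n2)
    h1 <- mean((a1_1[t1] == al) != (a2_1[t1] == al))
    h2 <- mean((a1_2[t2] == al) != (a2_2[t2] == al))
    pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    a <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 -
         (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    A <- A + a; B <- B + b; C <- C + cc
  }
  c(A, B, C, used = 1)
}

#' Pairwise multi-allelic Weir-Cockerham Fst matrix
#'
#' Weir-Cockerham theta for every pair of eligible localities, combining
#' loci (and alleles within loci) as a ratio of summed variance
#' components, `theta = sum(a) / sum(a + b + c)`. Negative estimates are
#' retained. This is the estimator computed by the population-genetics
#' software the field commonly uses, distinct from Wright's island-model
#' parameter.
#'
#' @param dataset A [genotype_dataset()].
#' @param min_n Minimum typed individuals per locality (default 5).
#' @param strict Error if a pair shares no usable locus (default `TRUE`);
#'   otherwise the entry is `NA`.
#' @return An `hz_dist` of kind `"fst"`.
#' @export
pairwise_fst <- function(dataset, min_n = 5L, strict = TRUE) {
  locs <- sort(unique(dataset$individuals$locality))
  sizes <- vapply(locs, function(l)
    sum(dataset$individuals$locality == l), 0L)
  locs <- locs[sizes >= min_n]
  if (length(locs) < 2L) stop("need >= 2 localities with n >= ", min_n)
  m <- matrix(0, length(locs), length(locs),
              dimnames = list(locs, locs))
  idx_of <- lapply(locs, function(l)
    which(dataset$individuals$locality == l))
  for (i in seq_along(locs)[-length(locs)]) {
    for (k in (i + 1L):length(locs)) {
      ii <- idx_of[[i]]; kk <- idx_of[[k]]
      A <- B <- C <- 0; used <- 0
      for (j in seq_len(n_loci(dataset))) {
        comp <- .wc_components(dataset$calls_a[ii, j],
                               dataset$calls_b[ii, j],
                               dataset$calls_a[kk, j],
                               dataset$calls_b[kk, j])
        A <- A + comp[1]; B <- B + comp[2]; C <- C + comp[3]
        used <- used + comp[4]
      }
      if (used == 0 || (A + B + C) == 0) {
        if (strict) stop("localities ", locs[i], " and ", locs[k],
                         " share no usable locus")
        m[i, k] <- m[k, i] <- NA_real_
      } else {
        m[i, k] <- m[k, i] <- A / (A + B + C)
      }
    }
  }
  dist_matrix(m, kind = "fst")
}

#' Pairwise Slatkin Rst matrix from allele sizes
#'
#' For each pair of localities and each locus, computes the average
#' squared allele-size difference between all pairs of allele copies
#' pooled over both localities (`S_bar`) and within localities (`S_w`,
#' pooling within-locality copy pairs), and forms
#' `Rst = sum_l (S_bar - S_w) / sum_l S_bar` as a ratio of sums over
#' loci. Requires integer allele sizes (bin midpoints satisfy this).
#'
#' @param dataset A [genotype_dataset()].
#' @param min_n Minimum typed individuals per locality (default 5).
#' @return An `hz_dist` of kind `"rst"`.
#' @export
pairwise_rst <- function(dataset, min_n = 5L) {
  locs <- sort(unique(dataset$individuals$locality))
  sizes <- vapply(locs, function(l)
    sum(dataset$individuals$locality == l), 0L)
  locs <- locs[sizes >= min_n]
  if (length(locs) < 2L) stop("need >= 2 localities with n >= ", min_n)
  # mean squared pairwise difference via the variance identity:
  # mean_{i<j} (x_i - x_j)^2 = 2 * var(x) (sample variance, n-1)
  msd <- function(x) if (length(x) < 2L) NA_real_ else 2 * stats::var(x)
  m <- matrix(0, length(locs), length(locs),
              dimnames = list(locs, locs))
  idx_of <- lapply(locs, function(l)
    which(dataset$individuals$locality == l))
  for (i in seq_along(locs)[-length(locs)]) {
    for (k in (i + 1L):length(locs)) {
      num <- den <- 0
      for (j in seq_len(n_loci(dataset))) {
        x1 <- .pop_copies(dataset, idx_of[[i]], j)
        x2 <- .pop_copies(dataset, idx_of[[k]], j)
        if (length(x1) < 2L || length(x2) < 2L) next
        s_all <- msd(c(x1, x2))
        # S_w pools within-locality copy pairs
        np1 <- choose(length(x1), 2); np2 <- choose(length(x2), 2)
        s_w <- (msd(x1) * np1 + msd(x2) * np2) / (np1 + np2)
        num <- num + (s_all - s_w)
        den <- den + s_all
      }
      if (den == 0) stop("no size variation for pair ", locs[i], "-",
                         locs[k])
      m[i, k] <- m[k, i] <- num / den
    }
  }
  dist_matrix(m, kind = "rst")
}

#' Principal coordinates analysis of a distance matrix
#'
#' Classical metric scaling: Gower double-centering
#' `B = -1/2 * J %*% D^2 %*% J` followed by an eigendecomposition.
#' Coordinates are returned for axes with positive eigenvalues;
#' percent variance is relative to the sum of the positive eigenvalues
#' (negative eigenvalues, which arise for non-Euclidean inputs such as
#' Fst/Rst matrices, are excluded from the denominator).
#'
#' @param D Symmetric zero-diagonal distance matrix (`hz_dist` or plain).
#' @param n_axes Number of axes to keep (default: all positive).
#' @return List of class `pcoa_result`: `coordinates` (localities x
#'   axes), `eigenvalues` (all), `percent_variance` (per kept axis).
#' @export
pcoa <- function(D, n_axes = NULL) {
  D <- as.matrix(D)
  if (!isSymmetric(unname(D), tol = 1e-8)) {
    stop("PCoA input must be symmetric")
  }
  n <- nrow(D)
  A <- -0.5 * D^2
  B <- A - matrix(rowMeans(A), n, n) -
    matrix(colMeans(A), n, n, byrow = TRUE) + mean(A)
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  pos <- which(e$values > max(1e-9 * abs(e$values[1]), 1e-12))
  if (!length(pos)) {
    return(structure(list(coordinates =
                            matrix(0, n, 0,
                                   dimnames = list(rownames(D), NULL)),
                          eigenvalues = e$values,
                          percent_variance = numeric(0)),
                     class = "pcoa_result"))
  }
  keep <- if (is.null(n_axes)) pos else pos[seq_len(min(n_axes,
                                                        length(pos)))]
  coords <- e$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(e$values[keep]), length(keep))
  dimnames(coords) <- list(rownames(D),
                           paste0("Axis", seq_along(keep)))
  structure(list(coordinates = coords, eigenvalues = e$values,
                 percent_variance = 100 * e$values[keep] /
                   sum(e$values[pos])),
            class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  k <- min(3L, length(x$percent_variance))
  cat("<pcoa_result> ", nrow(x$coordinates), " localities; first ",
      k, " axes explain ",
      paste(sprintf("%.1f%%", x$percent_variance[seq_len(k)]),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Pairwise geographic distance matrix from locality metadata
#'
#' Great-circle (haversine, mean Earth radius 6371.0088 km) distances
#' for GPS longitude/latitude input; planar Euclidean distances when the
#' coordinate system is `"planar"` (synthetic zones; coordinate unit km).
#'
#' @param meta Locality metadata ([read_locality_meta()]); `lat`/`lon`
#'   hold y/x for planar input.
#' @param coord_system `"lonlat"` or `"planar"`.
#' @return An `hz_dist` of kind `"geographic_km"`.
#' @export
geographic_distances <- function(meta, coord_system = "lonlat") {
  coord_system <- match.arg(coord_system, c("lonlat", "planar"))
  if (any(!is.finite(meta$lat)) || any(!is.finite(meta$lon))) {
    stop("missing coordinates")
  }
  if (coord_system == "lonlat") {
    if (any(abs(meta$lat) > 90)) stop("latitude outside [-90, 90]")
    m <- geosphere::distm(cbind(meta$lon, meta$lat),
                          fun = function(p1, p2)
                            geosphere::distHaversine(p1, p2,
                                                     r = 6371008.8))
    m <- m / 1000
  } else {
    m <- as.matrix(stats::dist(cbind(meta$lon, meta$lat)))
  }
  dist_matrix(m, labels = meta$locality_id, kind = "geographic_km")
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the off-diagonal upper triangles; the null
#' distribution is obtained by jointly permuting rows and columns of the
#' second matrix. One-tailed for positive association, add-one p-value
#' convention.
#'
#' @param D1,D2 Distance matrices over the same labels, n >= 4.
#' @param n_perms Number of permutations (default 10000).
#' @param seed Integer seed.
#' @return List of class `mantel_result`: `r`, `r_squared`, `p_value`,
#'   `n_perms`.
#' @export
mantel_test <- function(D1, D2, n_perms = 10000L, seed = 1L) {
  D1 <- as.matrix(D1); D2 <- as.matrix(D2)
  stopifnot(identical(dim(D1), dim(D2)))
  if (!is.null(rownames(D1)) && !is.null(rownames(D2))) {
    if (!identical(rownames(D1), rownames(D2))) {
      D2 <- D2[rownames(D1), rownames(D1)]
    }
  }
  n <- nrow(D1)
  if (n < 4L) stop("Mantel test needs n >= 4")
  u1 <- .upper(D1); u2 <- .upper(D2)
  if (stats::sd(u1) == 0 || stats::sd(u2) == 0) {
    stop("zero variance in a distance triangle; r undefined")
  }
  r <- stats::cor(u1, u2)
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(as.integer(seed))
  b <- 0L
  eps <- 1e-12
  for (k in seq_len(n_perms)) {
    idx <- sample.int(n)
    b <- b + (stats::cor(u1, .upper(D2[idx, idx])) >= r - eps)
  }
  structure(list(r = r, r_squared = r^2,
                 p_value = (1 + b) / (n_perms + 1),
                 n_perms = n_perms, seed = as.integer(seed)),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("<mantel_result> r = %.3f (r2 = %.3f), p = %.4g [%d perms]\n",
              x$r, x$r_squared, x$p_value, x$n_perms))
  invisible(x)
}

#' Remove classified hybrids before within-species analyses
#'
#' Drops every individual flagged by either classification rule (the
#' union of the F1 window rule and the CI rule), the filter applied
#' before isolation-by-distance analyses.
#'
#' @param dataset A [genotype_dataset()].
#' @param result The matching `hindex_result`.
#' @return A filtered `genotype_dataset`.
#' @export
filter_hybrids <- function(dataset, result) {
  bad <- result$individual[result$is_F1 | result$is_hybrid_ci]
  keep <- setdiff(dataset$individuals$id, bad)
  subset_dataset(dataset, individuals = keep)
}

#' Isolation by distance with a sympatry-residual randomization test
#'
#' Fits an ordinary least-squares regression of pairwise genetic distance
#' on pairwise geographic distance, and tests whether residual genetic
#' divergence is elevated for locality pairs involving sympatric
#' localities. The test statistic is
#' `mean(residual | pair involves a sympatric locality) -
#'  mean(residual | both localities allopatric)`.
#' The null distribution randomly permutes the sympatric/allopatric
#' labels across localities (preserving class counts); the regression
#' residuals are fixed, only the pair classification changes. One-tailed
#' add-one p-value for a positive statistic. A Mantel test of the same
#' two matrices is attached as the isolation-by-distance summary.
#'
#' @param gen An `hz_dist` of genetic distances (Fst or Rst).
#' @param geo An `hz_dist` of geographic distances, same labels.
#' @param sympatry Character vector `"sympatric"`/`"allopatric"`, named
#'   by locality or in label order; at least 2 localities per class.
#' @param n_reps Number of label randomizations (default 200, the
#'   conventional choice; note the p-value granularity is then 1/201, so
#'   several thousand is advisable when resolution matters).
#' @param linearize If `TRUE`, regress `fst / (1 - fst)` instead of raw
#'   values.
#' @param n_perms_mantel Permutations for the attached Mantel test.
#' @param seed Integer seed.
#' @return List of class `ibd_result`: `slope`, `intercept`, `mantel_r`,
#'   `r_squared`, `p_mantel`, `sympatry_stat`, `p_randomization`,
#'   `residuals` (pair-level data frame), `n_reps`, `seed`.
#' @export
ibd_residual_randomization <- function(gen, geo, sympatry,
                                       n_reps = 200L, linearize = FALSE,
                                       n_perms_mantel = 10000L,
                                       seed = 1L) {
  gen <- as.matrix(gen); geo <- as.matrix(geo)
  labs <- rownames(gen)
  if (!is.null(labs) && !is.null(rownames(geo))) {
    geo <- geo[labs, labs]
  }
  n <- nrow(gen)
  if (!is.null(names(sympatry))) sympatry <- sympatry[labs]
  stopifnot(length(sympatry) == n,
            all(sympatry %in% c("sympatric", "allopatric")))
  is_sym <- sympatry == "sympatric"
  if (sum(is_sym) < 2L || sum(!is_sym) < 2L) {
    stop("need >= 2 sympatric and >= 2 allopatric localities")
  }
  y <- .upper(gen)
  if (linearize) y <- y / (1 - y)
  x <- .upper(geo)
  fit <- stats::lm(y ~ x)
  res <- stats::residuals(fit)
  # upper-triangle pair endpoints
  pr <- which(upper.tri(gen), arr.ind = TRUE)
  pair_stat <- function(sym_flags) {
    involves <- sym_flags[pr[, 1]] | sym_flags[pr[, 2]]
    if (!any(involves) || all(involves)) return(NA_real_)
    mean(res[involves]) - mean(res[!involves])
  }
  obs <- pair_stat(is_sym)
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(as.integer(seed))
  eps <- 1e-12
  null_stats <- vapply(seq_len(n_reps), function(k)
    pair_stat(sample(is_sym)), numeric(1))
  b <- sum(null_stats >= obs - eps, na.rm = TRUE)
  mant <- mantel_test(gen, geo, n_perms = n_perms_mantel,
                      seed = as.integer(seed) + 1L)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 mantel_r = mant$r, r_squared = mant$r_squared,
                 p_mantel = mant$p_value,
                 sympatry_stat = obs,
                 p_randomization = (1 + b) / (n_reps + 1),
                 residuals = data.frame(
                   loc1 = labs[pr[, 1]], loc2 = labs[pr[, 2]],
                   gen = .upper(gen), geo = x, residual = res,
                   involves_sympatric = is_sym[pr[, 1]] | is_sym[pr[, 2]],
                   stringsAsFactors = FALSE),
                 n_reps = n_reps, seed = as.integer(seed)),
            class = "ibd_result")
}

#' @export
print.ibd_result <- function(x, ...) {
  cat(sprintf(
    "<ibd_result> slope = %.4g, Mantel r2 = %.3f (p = %.4g)\n",
    x$slope, x$r_squared, x$p_mantel))
  cat(sprintf("  sympatry residual stat = %.4g, p = %.4g [%d reps]\n",
              x$sympatry_stat, x$p_randomization, x$n_reps))
  invisible(x)
}
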