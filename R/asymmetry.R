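#' Exact binomial test of maternal-parent asymmetry
#'
#' Two-sided exact binomial test of the null that the two parental species
#' are equally likely to be the maternal parent of an F1 hybrid.
#' With `X ~ Binomial(k_A + k_B, 1/2)`,
#' `p = min(1, 2 * min(P(X <= min(k_A, k_B)), P(X >= max(k_A, k_B))))`.
#' At null proportion 1/2 this tail-doubling rule coincides with the
#' minimum-likelihood summation used by [stats::binom.test()], which is
#' why reported values are exactly reproducible.
#'
#' @param k_A,k_B Non-negative counts of F1 hybrids with a species-A /
#'   species-B mother; `k_A + k_B >= 1`.
#' @return The two-sided p-value.
#' @examples
#' exact_binomial_asymmetry(0, 18)   # 2 * 0.5^18
#' @export
exact_binomial_asymmetry <- function(k_A, k_B) {
  if (k_A < 0 || k_B < 0) stop("counts must be non-negative")
  n <- k_A + k_B
  if (n < 1) stop("need at least one labelled F1")
  lo <- min(k_A, k_B); hi <- max(k_A, k_B)
  min(1, 2 * min(stats::pbinom(lo, n, 0.5),
                 stats::pbinom(hi - 1, n, 0.5, lower.tail = FALSE)))
}

#' Tally maternal parentage of F1 hybrids per region
#'
#' Counts species-A and species-B mothers among F1-classified individuals
#' in each region (and pooled over all regions), and attaches the exact
#' binomial asymmetry p-value. Individuals with unknown maternal labels
#' are excluded (their count is reported in the `n_unknown` column).
#' Regions are computed regardless of size; `reportable` flags those
#' exceeding `min_f1` labelled F1s, the conventional reporting threshold.
#'
#' @param result An `hindex_result` with an `is_F1` column (or any data
#'   frame with `individual`, `locality`, `is_F1`).
#' @param maternal Named character vector of labels `A`/`B`/`unknown`
#'   per individual id (e.g. `dataset$maternal` or
#'   [read_maternal_labels()]).
#' @param region Region per row of `result`, or `NULL` to join from
#'   `dataset` metadata.
#' @param dataset Optional [genotype_dataset()] supplying regions and,
#'   if `maternal` is `NULL`, its maternal labels.
#' @param min_f1 Reporting threshold on `n_F1` (default 15, i.e. regions
#'   with more than 15 labelled F1s are flagged reportable).
#' @return Data frame of class `maternal_tally` with columns
#'   `region, n_F1, k_A, k_B, n_unknown, p_value, reportable`; the last
#'   row (`region = "total"`) pools all regions.
#' @export
tally_maternal <- function(result, maternal = NULL, region = NULL,
                           dataset = NULL, min_f1 = 15L) {
  if (is.null(maternal)) {
    if (is.null(dataset) || is.null(dataset$maternal)) {
      stop("supply maternal labels or a dataset carrying them")
    }
    maternal <- dataset$maternal
  }
  if (is.null(region)) {
    if (is.null(dataset) || is.null(dataset$meta)) {
      stop("supply `region` or a dataset with metadata")
    }
    m <- dataset$meta
    region <- m$region[match(result$locality, m$locality_id)]
  }
  f1 <- which(result$is_F1 & !is.na(region))
  if (!length(f1)) {
    warning("no F1-classified individuals with a region; empty tally",
            call. = FALSE)
  }
  lab <- maternal[result$individual[f1]]
  lab[is.na(lab)] <- "unknown"
  one <- function(rg, i) {
    kA <- sum(lab[i] == "A"); kB <- sum(lab[i] == "B")
    unk <- sum(lab[i] == "unknown")
    data.frame(region = rg, n_F1 = kA + kB, k_A = kA, k_B = kB,
               n_unknown = unk,
               p_value = if (kA + kB >= 1)
                 exact_binomial_asymmetry(kA, kB) else NA_real_,
               reportable = (kA + kB) > min_f1,
               stringsAsFactors = FALSE)
  }
  sp <- split(seq_along(f1), region[f1])
  out <- do.call(rbind, c(
    lapply(names(sp), function(rg) one(rg, sp[[rg]])),
    list(one("total", seq_along(f1)))))
  rownames(out) <- NULL
  class(out) <- c("maternal_tally", "data.frame")
  out
}
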