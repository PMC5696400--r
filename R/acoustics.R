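#' Temperature-correct acoustic call variables
#'
#' Advertisement-call characters of ectotherms vary with body/air
#' temperature. For each locality (population) and call variable, the
#' slope of an ordinary regression of the variable on temperature is
#' estimated and used to standardize every male's value to a common
#' temperature: `corrected = observed - b * (T - target)`. Populations
#' with fewer than `min_n` recordings (or no temperature variation) fall
#' back on the pooled within-species slope; the fallback count is
#' reported in the `"fallback"` attribute.
#'
#' Correcting already-corrected values is a no-op (the re-estimated
#' population slope of corrected values is exactly zero).
#'
#' @param calls Data frame with columns `individual, locality, species,
#'   pulse_rate, pulse_number, temperature`.
#' @param target Common temperature in degrees C (default 14).
#' @param min_n Minimum recordings for a population-specific slope
#'   (default 3).
#' @param variables Call variables to correct.
#' @return `calls` with added columns `<variable>_c` per corrected
#'   variable, slopes in the `"slopes"` attribute.
#' @export
temperature_correct <- function(calls, target = 14, min_n = 3L,
                                variables = c("pulse_rate",
                                              "pulse_number")) {
  stopifnot(all(c("locality", "species", "temperature", variables) %in%
                  names(calls)))
  if (all(is.na(calls$temperature))) stop("no temperatures available")
  slopes <- list(); n_fallback <- 0L
  for (v in variables) {
    calls[[paste0(v, "_c")]] <- NA_real_
    # pooled per-species fallback slope
    pooled <- vapply(unique(calls$species), function(sp) {
      d <- calls[calls$species == sp, ]
      if (nrow(d) < 2L || stats::sd(d$temperature) == 0) return(0)
      unname(stats::coef(stats::lm(d[[v]] ~ d$temperature))[2])
    }, numeric(1))
    names(pooled) <- unique(calls$species)
    for (loc in unique(calls$locality)) {
      for (sp in unique(calls$species[calls$locality == loc])) {
        i <- which(calls$locality == loc & calls$species == sp)
        b <- if (length(i) >= min_n &&
                 stats::sd(calls$temperature[i]) > 0) {
          unname(stats::coef(stats::lm(calls[[v]][i] ~
                                         calls$temperature[i]))[2])
        } else {
          n_fallback <- n_fallback + 1L
          pooled[[sp]]
        }
        calls[[paste0(v, "_c")]][i] <-
          calls[[v]][i] - b * (calls$temperature[i] - target)
        slopes[[paste(v, loc, sp, sep = "|")]] <- b
      }
    }
  }
  attr(calls, "slopes") <- unlist(slopes)
  attr(calls, "fallback") <- n_fallback
  calls
}

# corrected call values can go non-positive when a small population's
# temperature slope is wildly estimated; such records cannot be
# log-transformed and are dropped with a message
.drop_nonpositive <- function(d, col) {
  bad <- !is.finite(d[[col]]) | d[[col]] <= 0
  if (any(bad)) {
    message(sum(bad), " record(s) with non-positive corrected ", col,
            " dropped before log transform")
    d <- d[!bad, , drop = FALSE]
  }
  d
}

.match_calls <- function(calls, hindex) {
  i <- match(calls$individual, hindex$individual)
  matched <- which(!is.na(i))
  if (length(matched) < nrow(calls)) {
    message(nrow(calls) - length(matched),
            " call record(s) without a genotype match dropped")
  }
  cbind(calls[matched, , drop = FALSE],
        h_hat = hindex$h_hat[i[matched]])
}

#' Regress hybrid index on a log-transformed call variable
#'
#' Ordinary least squares of the hybrid index on the natural-log of the
#' temperature-corrected call variable, for individuals with both a call
#' record and a genotype (matched on individual id; unmatched records
#' dropped with a message).
#'
#' @param calls Temperature-corrected call table
#'   ([temperature_correct()]).
#' @param hindex An `hindex_result`.
#' @param variable `"pulse_rate"` or `"pulse_number"`.
#' @param log_transform Natural-log the call variable (default `TRUE`).
#' @return List of class `acoustic_fit`: `variable, coefficients,
#'   r_squared, p_value, aic, bic, n, model`.
#' @export
regress_call_on_hindex <- function(calls, hindex,
                                   variable = c("pulse_rate",
                                                "pulse_number"),
                                   log_transform = TRUE) {
  variable <- match.arg(variable)
  d <- .match_calls(calls, hindex)
  vc <- paste0(variable, "_c")
  if (!vc %in% names(d)) stop("run temperature_correct() first")
  if (log_transform) d <- .drop_nonpositive(d, vc)
  if (nrow(d) < 3L) stop("fewer than 3 matched individuals")
  x <- if (log_transform) log(d[[vc]]) else d[[vc]]
  fit <- stats::lm(d$h_hat ~ x)
  sm <- summary(fit)
  structure(list(variable = variable,
                 coefficients = stats::coef(fit),
                 r_squared = sm$r.squared,
                 p_value = unname(sm$coefficients[2, 4]),
                 aic = stats::AIC(fit), bic = stats::BIC(fit),
                 n = nrow(d), model = fit),
            class = "acoustic_fit")
}

#' @export
print.acoustic_fit <- function(x, ...) {
  cat(sprintf("<acoustic_fit> h ~ log(%s): r2 = %.3f, p = %.3g (n = %d)\n",
              x$variable, x$r_squared, x$p_value, x$n))
  invisible(x)
}

#' Model choice among pulse rate, pulse number, and both
#'
#' Fits the three candidate predictors of hybrid index — log pulse rate,
#' log pulse number, and both jointly — and ranks them by AIC and by
#' BIC. If the two (log) variables are collinear to machine precision
#' the joint model is skipped and flagged.
#'
#' @param calls Temperature-corrected call table.
#' @param hindex An `hindex_result`.
#' @return List of class `stepwise_result`: `fits` (data frame of
#'   `model, r_squared, p_value, aic, bic`), `best_aic`, `best_bic`,
#'   `collinear`.
#' @export
stepwise_select <- function(calls, hindex) {
  d <- .match_calls(calls, hindex)
  d <- .drop_nonpositive(.drop_nonpositive(d, "pulse_rate_c"),
                         "pulse_number_c")
  if (nrow(d) < 4L) stop("too few matched individuals")
  lpr <- log(d$pulse_rate_c); lpn <- log(d$pulse_number_c)
  collinear <- abs(stats::cor(lpr, lpn)) > 1 - 1e-12
  models <- list(PR = stats::lm(d$h_hat ~ lpr),
                 PN = stats::lm(d$h_hat ~ lpn))
  if (!collinear) {
    models$`PR+PN` <- stats::lm(d$h_hat ~ lpr + lpn)
  } else {
    warning("pulse rate and pulse number collinear to machine ",
            "precision; joint model skipped", call. = FALSE)
  }
  fits <- do.call(rbind, lapply(names(models), function(nm) {
    f <- models[[nm]]; sm <- summary(f)
    data.frame(model = nm, r_squared = sm$r.squared,
               p_value = stats::pf(sm$fstatistic[1], sm$fstatistic[2],
                                   sm$fstatistic[3], lower.tail = FALSE),
               aic = stats::AIC(f), bic = stats::BIC(f),
               stringsAsFactors = FALSE)
  }))
  rownames(fits) <- NULL
  structure(list(fits = fits,
                 best_aic = fits$model[which.min(fits$aic)],
                 best_bic = fits$model[which.min(fits$bic)],
                 collinear = collinear, n = nrow(d)),
            class = "stepwise_result")
}

#' @export
print.stepwise_result <- function(x, ...) {
  cat("<stepwise_result> best by AIC:", x$best_aic,
      "| by BIC:", x$best_bic, "\n")
  print(x$fits, digits = 4)
  invisible(x)
}

#' Reproductive character displacement distance for one region
#'
#' The displacement of a species' sympatric call phenotype from its
#' allopatric baseline: the Euclidean distance between the sympatric
#' region's mean and the pooled allopatric mean of the two
#' temperature-corrected call variables,
#' `D = sqrt((PRbar_sym - PRbar_allo)^2 + (PNbar_sym - PNbar_allo)^2)`.
#' The two variables have different units; `standardize = TRUE` divides
#' each by its allopatric standard deviation first.
#'
#' @param sym_calls Corrected call records of the species' males in the
#'   sympatric region.
#' @param allo_calls Corrected call records of the species' allopatric
#'   males (pooled baseline).
#' @param standardize Z-scale by allopatric SDs (default `FALSE`, raw
#'   corrected means).
#' @return List: `d_rcd`, per-variable sympatric and allopatric means.
#' @export
rcd_distance <- function(sym_calls, allo_calls, standardize = FALSE) {
  if (!nrow(sym_calls) || !nrow(allo_calls)) {
    stop("need males on both the sympatric and allopatric side")
  }
  need <- c("pulse_rate_c", "pulse_number_c")
  stopifnot(all(need %in% names(sym_calls)),
            all(need %in% names(allo_calls)))
  ms <- vapply(need, function(v) mean(sym_calls[[v]]), numeric(1))
  ma <- vapply(need, function(v) mean(allo_calls[[v]]), numeric(1))
  sc <- if (standardize) {
    vapply(need, function(v) stats::sd(allo_calls[[v]]), numeric(1))
  } else c(1, 1)
  list(d_rcd = sqrt(sum(((ms - ma) / sc)^2)),
       sym_mean = ms, allo_mean = ma,
       n_sym = nrow(sym_calls), n_allo = nrow(allo_calls))
}

#' Per-region RCD table for one species
#'
#' Computes [rcd_distance()] for each sympatric region of a species
#' against the species' pooled allopatric baseline.
#'
#' @param calls Corrected call table with columns `species, region,
#'   sympatry` (region `NA` or sympatry `"allopatric"` marks baseline
#'   males).
#' @param species Species label to summarize.
#' @param standardize Passed to [rcd_distance()].
#' @return Data frame `region, species, d_rcd, pulse_rate_sym,
#'   pulse_number_sym, pulse_rate_allo, pulse_number_allo, n_sym`.
#' @export
rcd_by_region <- function(calls, species, standardize = FALSE) {
  stopifnot(all(c("species", "region", "sympatry") %in% names(calls)))
  d <- calls[calls$species == species, , drop = FALSE]
  allo <- d[d$sympatry == "allopatric", , drop = FALSE]
  regions <- sort(unique(d$region[d$sympatry == "sympatric" &
                                    !is.na(d$region)]))
  if (!length(regions)) stop("no sympatric regions for species ", species)
  out <- do.call(rbind, lapply(regions, function(rg) {
    sym <- d[d$sympatry == "sympatric" & !is.na(d$region) &
               d$region == rg, , drop = FALSE]
    r <- rcd_distance(sym, allo, standardize = standardize)
    data.frame(region = rg, species = species, d_rcd = r$d_rcd,
               pulse_rate_sym = r$sym_mean[["pulse_rate_c"]],
               pulse_number_sym = r$sym_mean[["pulse_number_c"]],
               pulse_rate_allo = r$allo_mean[["pulse_rate_c"]],
               pulse_number_allo = r$allo_mean[["pulse_number_c"]],
               n_sym = r$n_sym, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Regress regional admixture on RCD magnitude
#'
#' Ordinary least squares of a regional admixture proportion (F1 rule,
#' CI rule, or advanced-generation = CI - F1) on the region's
#' displacement distance, per species. With few sympatric regions per
#' species power is low; the fit is reported regardless.
#'
#' @param rcd_table Output of [rcd_by_region()].
#' @param admixture A region-level admixture table
#'   ([summarize_region()]).
#' @param metric `"F1"`, `"CI"`, or `"CI-F1"`.
#' @return List of class `acoustic_fit`-like: `slope, r_squared,
#'   p_value, n, metric, model`.
#' @export
rcd_vs_admixture <- function(rcd_table, admixture,
                             metric = c("F1", "CI", "CI-F1")) {
  metric <- match.arg(metric)
  i <- match(rcd_table$region, admixture$region)
  if (anyNA(i)) stop("regions missing from the admixture table: ",
                     paste(rcd_table$region[is.na(i)], collapse = ", "))
  y <- switch(metric,
              "F1" = admixture$prop_F1[i],
              "CI" = admixture$prop_undetermined[i],
              "CI-F1" = admixture$prop_advanced[i])
  if (nrow(rcd_table) < 3L) {
    stop("need >= 3 regions for a regression (low power below ~8)")
  }
  fit <- stats::lm(y ~ rcd_table$d_rcd)
  sm <- summary(fit)
  r2 <- if (stats::sd(y) == 0) 0 else sm$r.squared
  pv <- if (stats::sd(y) > 0 && nrow(sm$coefficients) > 1L) {
    unname(sm$coefficients[2, 4])
  } else NA_real_
  list(slope = unname(stats::coef(fit)[2]), r_squared = r2,
       p_value = pv, n = nrow(rcd_table), metric = metric, model = fit)
}
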