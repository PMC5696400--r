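#' Default synthetic contact-zone configuration
#'
#' Study conditions for the synthetic generator: two parental gene pools
#' at 12 microsatellite-style loci with 6-32 alleles per locus,
#' between-species differentiation `f_div`, a transect of allopatric and
#' sympatric localities mirroring a two-species contact zone (allopatric
#' reference totals 188 and 80; five large sympatric regions of
#' N = 386, 45, 87, 99, 119 and five small ones), a per-locality
#' class mixture of pure, F1, F2 and backcross individuals, asymmetric
#' F1 maternal parentage, distance-proportional locality drift producing
#' isolation by distance, and a linear call model with temperature
#' dependence and sympatric signal displacement.
#'
#' @param ... Named overrides of any default element.
#' @return A `sim_config` list.
#' @export
sim_config <- function(...) {
  cfg <- list(
    n_loci = 12L,
    alleles_range = c(6L, 32L),
    f_div = 0.2,
    layout = default_layout(),
    # per sympatric region; proportions sum to 1. F1 and
    # advanced-generation fractions vary across regions the way
    # reported hybridization frequencies do (F1 5-31%, hybrids of any
    # class 11-78%); a single vector may be supplied instead
    class_mix = default_class_mix(),
    maternal_asymmetry = 0.74,   # P(F1 mother is species B)
    drift_scale = 2e-4,          # drift f per km of transect distance
    # noise SDs calibrated against the reported call-vs-index
    # regressions at the 75-male focal benchmark (pulse rate r2 ~ .72,
    # pulse number r2 ~ .77) given the default class mixture
    call_model = list(
      pr_intercept = 25, pr_slope = 30, pr_sd = 4.3, pr_temp_slope = 1.2,
      pn_intercept = 10, pn_slope = 12, pn_sd = 1.1, pn_temp_slope = 0.35,
      temp_mean = 14, temp_sd = 3),
    # additive sympatric signal offsets (reinforcement displacement):
    # species A displaced in the southern regions, B (weakly) in the north
    displacement = data.frame(
      region = c("R1", "R2", "R3", "R4", "R5", "R6",
                 "R7", "R8", "R9", "R10"),
      species = c(rep("A", 6), rep("B", 4)),
      d_pr = c(6, 10, 7, 5, 4, 9, -3, -4, -3, -2),
      d_pn = c(2.5, 4, 3, 2, 1.5, 3.5, -1, -1.5, -1, -0.8),
      stringsAsFactors = FALSE),
    seed = 1L)
  over <- list(...)
  for (nm in names(over)) cfg[[nm]] <- over[[nm]]
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_loci >= 1,
            length(cfg$alleles_range) == 2,
            cfg$alleles_range[1] >= 2,
            cfg$alleles_range[1] <= cfg$alleles_range[2],
            cfg$drift_scale >= 0)
  if (!(cfg$f_div > 0 && cfg$f_div < 1)) {
    stop("f_div must lie strictly inside (0, 1)")
  }
  mix <- cfg$class_mix
  if (is.list(mix)) {
    lapply(mix, .check_mix)
  } else .check_mix(mix)
  sds <- unlist(cfg$call_model[c("pr_sd", "pn_sd", "temp_sd")])
  stopifnot(all(sds >= 0))
  structure(cfg, class = "sim_config")
}

.check_mix <- function(mix) {
  cls <- c("pureA", "pureB", "F1", "F2", "BxA", "BxB")
  stopifnot(all(names(mix) %in% cls), abs(sum(mix) - 1) < 1e-9,
            all(mix >= 0))
  invisible(mix)
}

#' Default per-region hybrid class mixtures
#'
#' One mixture per sympatric region, with F1 and advanced-generation
#' (F2/backcross) fractions spanning the range reported for real
#' contact-zone regions: high admixture in the R2 and R8 analogs, low
#' in R5, R6 and R9, moderate elsewhere. Note that the realized
#' proportion of individuals *flagged* by the F1 window rule runs above
#' the planted F1 fraction because the window also captures
#' advanced-generation genotypes.
#'
#' @return Named list of class-mixture vectors, one per region R1-R10.
#' @export
default_class_mix <- function() {
  mix <- function(f1, adv) {
    pure <- 1 - f1 - adv
    c(pureA = pure / 2, pureB = pure / 2, F1 = f1,
      F2 = adv / 3, BxA = adv / 3, BxB = adv / 3)
  }
  list(R1 = mix(0.10, 0.20), R2 = mix(0.31, 0.47),
       R3 = mix(0.12, 0.20), R4 = mix(0.10, 0.20),
       R5 = mix(0.09, 0.22), R6 = mix(0.05, 0.06),
       R7 = mix(0.15, 0.25), R8 = mix(0.23, 0.44),
       R9 = mix(0.15, 0.21), R10 = mix(0.12, 0.20))
}

#' Default locality layout of the synthetic zone
#'
#' Planar transect (km): ten sympatric regions R1-R10 along the contact
#' line at y = 0, allopatric species-A localities to the north and
#' species-B localities to the south. Column `n` gives sample sizes; for
#' sympatric localities `n` is split across hybrid classes by the
#' configured class mixture.
#'
#' @return Data frame `locality_id, species, region, sympatry, lon, lat,
#'   n, group`.
#' @export
default_layout <- function() {
  sym <- data.frame(
    locality_id = paste0("sym_R", 1:10),
    species = "hybrid-unknown",
    region = paste0("R", 1:10),
    sympatry = "sympatric",
    lon = seq(0, 900, length.out = 10),
    lat = 0,
    n = c(10L, 386L, 24L, 7L, 45L, 87L, 29L, 99L, 119L, 26L),
    group = "contact",
    stringsAsFactors = FALSE)
  alloA <- data.frame(
    locality_id = paste0("alloA_", 1:8),
    species = "A", region = NA_character_, sympatry = "allopatric",
    lon = seq(50, 850, length.out = 8),
    lat = c(180, 120, 220, 160, 250, 140, 200, 170),
    n = c(18L, 83L, 9L, 12L, 16L, 10L, 25L, 15L),
    group = "alloA", stringsAsFactors = FALSE)
  alloB <- data.frame(
    locality_id = paste0("alloB_", 1:6),
    species = "B", region = NA_character_, sympatry = "allopatric",
    lon = seq(80, 820, length.out = 6),
    lat = -c(160, 230, 120, 200, 150, 210),
    n = c(5L, 6L, 6L, 12L, 36L, 15L),
    group = "alloB", stringsAsFactors = FALSE)
  rbind(sym, alloA, alloB)
}

.rdirichlet <- function(shape) {
  g <- stats::rgamma(length(shape), shape = shape, rate = 1)
  s <- sum(g)
  if (s == 0) {            # extreme underflow: fall back on argmax mass
    g[which.max(shape)] <- 1
    s <- 1
  }
  g / s
}

#' Simulate parental reference allele frequencies
#'
#' For each locus, draws a shared ancestral frequency vector from a
#' symmetric Dirichlet(1), then draws each species' frequency vector
#' from a Dirichlet with concentration
#' `(1 - f_div) / f_div * ancestral` (a Balding-Nichols model), so
#' `f_div` controls the expected between-species Fst with one knob.
#' Allele identifiers are integer fragment sizes on a tetranucleotide
#' ladder.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed (default from the config).
#' @return An `allele_freq_table` (`n_A`/`n_B` infinite: generating
#'   truth), with the ancestral vectors in the `"ancestral"` attribute.
#' @export
sim_parental_freqs <- function(config = sim_config(),
                               seed = config$seed) {
  config <- validate_sim_config(config)
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(as.integer(seed))
  conc <- (1 - config$f_div) / config$f_div
  fa <- fb <- anc <- vector("list", config$n_loci)
  for (j in seq_len(config$n_loci)) {
    K <- sample(config$alleles_range[1]:config$alleles_range[2], 1L)
    sizes <- 100L + 20L * j + 4L * (seq_len(K) - 1L)
    if (max(sizes) > 999L) sizes <- 100L + 4L * (seq_len(K) - 1L)
    a <- .rdirichlet(rep(1, K))
    pa <- .rdirichlet(conc * a)
    pb <- .rdirichlet(conc * a)
    names(a) <- names(pa) <- names(pb) <- as.character(sizes)
    anc[[j]] <- a; fa[[j]] <- pa; fb[[j]] <- pb
  }
  names(fa) <- names(fb) <- paste0("L", seq_len(config$n_loci))
  tab <- allele_freq_table(fa, fb)
  attr(tab, "ancestral") <- anc
  tab
}

# Drift locality frequencies along a transect chain: localities ordered
# by position; each step draws Dirichlet(prev * (1 - f) / f) with
# f = min(0.5, drift_scale * step_km), so divergence accumulates with
# distance and produces isolation by distance.
.drift_chain <- function(base, order_pos, drift_scale) {
  n <- length(order_pos)
  out <- vector("list", n)
  prev <- base
  prev_pos <- order_pos[1]
  for (k in seq_len(n)) {
    step <- abs(order_pos[k] - prev_pos)
    f <- min(0.5, drift_scale * step)
    cur <- if (f <= 0) prev else {
      lapply(prev, function(p) {
        q <- .rdirichlet((1 - f) / f * p)
        names(q) <- names(p)
        q
      })
    }
    out[[k]] <- cur
    prev <- cur
    prev_pos <- order_pos[k]
  }
  out
}

#' Simulate one individual's genotype from a hybrid class
#'
#' Gamete-based construction: a pure parent contributes an allele drawn
#' from its species pool at every locus; an F1 gamete is species A or B
#' with probability 1/2 independently per locus. Classes: `pureA`
#' (`h_true = 1`), `pureB` (0), `F1` (0.5; one copy from each pool),
#' `F2` (0.5; both copies from F1 gametes), `BxA` (0.75; one copy from
#' A, the other from an F1 gamete), `BxB` (0.25). `h_true` is the
#' expected species-A ancestry proportion; orientation `h = 1` = pure
#' species A. F1 maternal labels are species B with the configured
#' asymmetry probability; pure individuals carry their own species
#' label; later-generation classes are `"unknown"`.
#'
#' @param class One of `pureA, pureB, F1, F2, BxA, BxB`.
#' @param freq_a,freq_b Per-locus named frequency vectors of the
#'   (locality-level) species A and B gene pools.
#' @param maternal_asymmetry P(F1 mother is species B).
#' @return List: `a1`, `a2` (integer allele sizes per locus), `h_true`,
#'   `maternal`.
#' @export
sim_individual <- function(class, freq_a, freq_b,
                           maternal_asymmetry = 0.74) {
  L <- length(freq_a)
  draw <- function(p) as.integer(names(p))[
    sample.int(length(p), 1L, prob = p)]
  gam_pure <- function(pool) vapply(pool, draw, integer(1))
  gam_f1 <- function() {
    fromA <- stats::runif(L) < 0.5
    out <- integer(L)
    for (j in seq_len(L)) {
      out[j] <- draw(if (fromA[j]) freq_a[[j]] else freq_b[[j]])
    }
    out
  }
  res <- switch(class,
    pureA = list(a1 = gam_pure(freq_a), a2 = gam_pure(freq_a),
                 h_true = 1, maternal = "A"),
    pureB = list(a1 = gam_pure(freq_b), a2 = gam_pure(freq_b),
                 h_true = 0, maternal = "B"),
    F1 = list(a1 = gam_pure(freq_a), a2 = gam_pure(freq_b),
              h_true = 0.5,
              maternal = if (stats::runif(1) < maternal_asymmetry)
                "B" else "A"),
    F2 = list(a1 = gam_f1(), a2 = gam_f1(), h_true = 0.5,
              maternal = "unknown"),
    BxA = list(a1 = gam_pure(freq_a), a2 = gam_f1(), h_true = 0.75,
               maternal = "unknown"),
    BxB = list(a1 = gam_pure(freq_b), a2 = gam_f1(), h_true = 0.25,
               maternal = "unknown"),
    stop("unknown hybrid class: ", class))
  res
}

#' Simulate a full synthetic contact zone
#'
#' Generates the complete data bundle the pipeline consumes: a
#' [genotype_dataset()] with locality metadata and maternal labels, a
#' call-record table, and truth tables (class, `h_true`, maternal
#' parent, per-locality drifted frequencies). Localities are laid out on
#' a planar transect; per-species locality gene pools drift along the
#' transect with variance proportional to distance (producing isolation
#' by distance); sympatric individuals are drawn from the configured
#' class mixture; calls follow
#' `call = intercept + slope * h_true + b_T * (T - 14) + noise`,
#' with the configured additive displacement applied to sympatric males
#' of the displaced species per region.
#'
#' @param config A [sim_config()].
#' @param seed Master seed (default from the config).
#' @return List of class `sim_zone`: `dataset`, `calls`, `truth`,
#'   `freqs` (species-level generating `allele_freq_table`), `config`.
#' @export
sim_zone <- function(config = sim_config(), seed = config$seed) {
  config <- validate_sim_config(config)
  # config$freqs lets callers plant known (e.g. fully diagnostic) pools
  freqs <- if (!is.null(config$freqs)) config$freqs else {
    sim_parental_freqs(config, seed = derive_seed(seed, "freqs"))
  }
  base_a <- lapply(freqs, function(l) {
    stats::setNames(l$freq["p_A", ], colnames(l$freq))
  })
  base_b <- lapply(freqs, function(l) {
    stats::setNames(l$freq["p_B", ], colnames(l$freq))
  })
  lay <- config$layout
  empty <- lay$n <= 0L
  if (any(empty)) {
    warning("localities with zero individuals skipped: ",
            paste(lay$locality_id[empty], collapse = ", "),
            call. = FALSE)
    lay <- lay[!empty, , drop = FALSE]
  }
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(derive_seed(seed, "zone"))
  # transect drift chains per species over all localities (ordered by x)
  ord <- order(lay$lon)
  chain_a <- .drift_chain(base_a, lay$lon[ord], config$drift_scale)
  chain_b <- .drift_chain(base_b, lay$lon[ord], config$drift_scale)
  loc_freq_a <- stats::setNames(chain_a[order(ord)], lay$locality_id)
  loc_freq_b <- stats::setNames(chain_b[order(ord)], lay$locality_id)

  classes <- c("pureA", "pureB", "F1", "F2", "BxA", "BxB")
  rows_a <- list(); rows_b <- list(); truth <- list()
  for (r in seq_len(nrow(lay))) {
    loc <- lay$locality_id[r]
    n <- lay$n[r]
    cls <- if (lay$sympatry[r] == "allopatric") {
      rep(if (lay$species[r] == "A") "pureA" else "pureB", n)
    } else {
      mix <- if (is.list(config$class_mix)) {
        config$class_mix[[lay$region[r]]]
      } else config$class_mix
      mix_full <- stats::setNames(rep(0, length(classes)), classes)
      mix_full[names(mix)] <- mix
      classes[sample.int(length(classes), n, replace = TRUE,
                         prob = mix_full)]
    }
    for (i in seq_len(n)) {
      ind <- sim_individual(cls[i], loc_freq_a[[loc]],
                            loc_freq_b[[loc]],
                            config$maternal_asymmetry)
      rows_a[[length(rows_a) + 1L]] <- ind$a1
      rows_b[[length(rows_b) + 1L]] <- ind$a2
      truth[[length(truth) + 1L]] <- data.frame(
        id = sprintf("%s_i%03d", loc, i), locality = loc,
        region = lay$region[r], sympatry = lay$sympatry[r],
        class = cls[i], h_true = ind$h_true, maternal = ind$maternal,
        stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(rbind, truth)
  calls_a <- do.call(rbind, rows_a); calls_b <- do.call(rbind, rows_b)
  colnames(calls_a) <- colnames(calls_b) <- names(base_a)
  meta <- lay[, c("locality_id", "species", "region", "sympatry",
                  "lon", "lat", "group")]
  dataset <- genotype_dataset(
    calls_a, calls_b,
    data.frame(id = truth$id, locality = truth$locality,
               stringsAsFactors = FALSE),
    meta = meta,
    maternal = stats::setNames(truth$maternal, truth$id),
    coord_system = "planar")

  # acoustic records: one call per individual
  cm <- config$call_model
  n_all <- nrow(truth)
  temp <- stats::rnorm(n_all, cm$temp_mean, cm$temp_sd)
  species_lab <- ifelse(truth$h_true >= 0.5, "A", "B")
  pr <- cm$pr_intercept + cm$pr_slope * truth$h_true +
    cm$pr_temp_slope * (temp - 14) + stats::rnorm(n_all, 0, cm$pr_sd)
  pn <- cm$pn_intercept + cm$pn_slope * truth$h_true +
    cm$pn_temp_slope * (temp - 14) + stats::rnorm(n_all, 0, cm$pn_sd)
  if (!is.null(config$displacement) && nrow(config$displacement)) {
    dd <- config$displacement
    for (k in seq_len(nrow(dd))) {
      hit <- truth$sympatry == "sympatric" &
        !is.na(truth$region) & truth$region == dd$region[k] &
        truth$class == paste0("pure", dd$species[k])
      pr[hit] <- pr[hit] + dd$d_pr[k]
      pn[hit] <- pn[hit] + dd$d_pn[k]
    }
  }
  calls <- data.frame(individual = truth$id, locality = truth$locality,
                      species = species_lab, region = truth$region,
                      sympatry = truth$sympatry,
                      pulse_rate = pmax(pr, 1), pulse_number = pmax(pn, 1),
                      temperature = temp, stringsAsFactors = FALSE)
  structure(list(dataset = dataset, calls = calls, truth = truth,
                 freqs = freqs,
                 loc_freqs = list(A = loc_freq_a, B = loc_freq_b),
                 config = config, seed = as.integer(seed)),
            class = "sim_zone")
}

#' @export
print.sim_zone <- function(x, ...) {
  cat("<sim_zone> ", nrow(x$truth), " individuals, ",
      length(unique(x$truth$locality)), " localities, ",
      n_loci(x$dataset), " loci (seed ", x$seed, ")\n", sep = "")
  print(table(x$truth$class))
  invisible(x)
}

#' Simulate a replicate log-probability table for cluster-number choice
#'
#' Produces a mean log-probability curve that rises steeply up to the
#' planted number of clusters and much more shallowly beyond it (a kink
#' at `planted_K`), with Gaussian replicate noise — the shape the
#' delta-K statistic is designed to detect.
#'
#' @param K_range Contiguous integer K grid (default `1:10`).
#' @param n_reps Replicates per K (>= 2; the SD is undefined below
#'   that).
#' @param planted_K Location of the kink.
#' @param rise Log-probability gain per K below the kink.
#' @param plateau Gain per K above the kink.
#' @param noise_sd Replicate noise SD (0 gives an infinite delta-K at
#'   the planted K).
#' @param seed Integer seed.
#' @return Data frame `K, rep, lnp`.
#' @export
sim_lnp_table <- function(K_range = 1:10, n_reps = 10L, planted_K = 2L,
                          rise = 800, plateau = 15, noise_sd = 8,
                          seed = 1L) {
  stopifnot(all(diff(K_range) == 1L), planted_K %in% K_range)
  if (n_reps < 2L) stop("need n_reps >= 2 (replicate SD undefined)")
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(as.integer(seed))
  mu <- -5000 + rise * pmin(K_range, planted_K) +
    plateau * pmax(0, K_range - planted_K)
  out <- do.call(rbind, lapply(seq_along(K_range), function(j) {
    data.frame(K = K_range[j], rep = seq_len(n_reps),
               lnp = mu[j] + stats::rnorm(n_reps, 0, noise_sd))
  }))
  rownames(out) <- NULL
  out
}
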