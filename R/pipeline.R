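#' Run the full contact-zone analysis pipeline
#'
#' Orchestrates every stage on either a synthetic zone or files on disk:
#' read/simulate genotypes -> pool references -> reference allele
#' frequencies -> hybrid indices and both classifications -> per-region
#' admixture summaries -> pairwise randomization tests with sequential
#' Bonferroni -> maternal tallies with exact binomial asymmetry tests ->
#' Fst and Rst matrices -> PCoA -> Mantel isolation by distance and the
#' sympatry-residual randomization test (hybrids removed first) ->
#' acoustic temperature correction, hybrid-index regressions, model
#' choice, and the RCD-vs-admixture regressions. All stage seeds derive
#' deterministically from one master seed and are recorded in the run
#' log; outputs are written as CSV tables under `out_dir` when given.
#'
#' @param config Named list (or path to a JSON file with the same
#'   fields). Recognised fields, all optional: `sim` (a [sim_config()]
#'   or list of overrides; default simulates the default zone),
#'   `genepop`, `meta`, `maternal`, `calls` (input file paths, used
#'   instead of simulation when `genepop` is set), `f1_bounds`,
#'   `alpha`, `n_reps_randomization`, `n_perms_mantel`, `n_reps_ibd`,
#'   `min_region_n`, `sidedness`, `freq_alpha`, `coord_system`,
#'   `out_dir`.
#' @param seed Master integer seed.
#' @return List of class `hz_pipeline` with every stage result and the
#'   run log.
#' @export
run_pipeline <- function(config = list(), seed = 1L) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  defaults <- list(f1_bounds = c(0.25, 0.75), alpha = 0.05,
                   n_reps_randomization = 1e5, n_perms_mantel = 1e4,
                   n_reps_ibd = 200L, min_region_n = 30L,
                   sidedness = "two_sided", freq_alpha = 0.5,
                   coord_system = "lonlat", out_dir = NULL)
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  log <- list(master_seed = as.integer(seed),
              started = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
              package_version = as.character(
                utils::packageVersion("hzadmix")))
  stage <- function(nm) derive_seed(seed, nm)

  # --- stage: data -------------------------------------------------
  if (!is.null(config$genepop)) {
    meta <- read_locality_meta(config$meta)
    dataset <- read_genepop(config$genepop, meta = meta,
                            coord_system = config$coord_system)
    if (!is.null(config$maternal)) {
      dataset <- attach_metadata(dataset, meta,
                                 maternal =
                                   read_maternal_labels(config$maternal))
    }
    calls <- if (!is.null(config$calls)) {
      utils::read.csv(config$calls, stringsAsFactors = FALSE)
    } else NULL
    zone <- NULL
    log$data <- paste("files:", config$genepop)
  } else {
    sc <- if (inherits(config$sim, "sim_config")) config$sim else {
      do.call(sim_config, as.list(config$sim))
    }
    zone <- sim_zone(sc, seed = stage("sim"))
    dataset <- zone$dataset
    calls <- zone$calls
    log$data <- paste("simulated zone, seed", stage("sim"))
  }

  # --- stage: references and hybrid index --------------------------
  refs <- pool_references(dataset)
  freqs <- estimate_frequencies(dataset, refs, alpha = config$freq_alpha)
  hidx <- estimate_hybrid_index(dataset, freqs,
                                f1_bounds = config$f1_bounds)
  admix <- summarize_region(hidx, dataset = dataset)

  # --- stage: randomization comparisons ----------------------------
  comp_f1 <- compare_regions(hidx, dataset = dataset, method = "f1",
                             min_n = config$min_region_n,
                             n_reps = config$n_reps_randomization,
                             sidedness = config$sidedness,
                             seed = stage("compare_f1"),
                             alpha = config$alpha)
  comp_ci <- compare_regions(hidx, dataset = dataset, method = "ci",
                             min_n = config$min_region_n,
                             n_reps = config$n_reps_randomization,
                             sidedness = config$sidedness,
                             seed = stage("compare_ci"),
                             alpha = config$alpha)

  # --- stage: maternal asymmetry -----------------------------------
  tally <- if (!is.null(dataset$maternal)) {
    tally_maternal(hidx, dataset = dataset)
  } else NULL

  # --- stage: population structure ---------------------------------
  no_hyb <- filter_hybrids(dataset, hidx)
  structure_res <- lapply(c(A = "A", B = "B"), function(sp) {
    locs <- dataset$meta$locality_id
    keep_loc <- dataset$meta$species %in% c(sp, "hybrid-unknown")
    ids <- no_hyb$individuals$id[
      no_hyb$individuals$locality %in% locs[keep_loc]]
    sub <- subset_dataset(no_hyb, individuals = ids)
    # species assignment inside sympatric localities: keep individuals
    # whose estimated index is on this species' side
    hh <- hidx$h_hat[match(sub$individuals$id, hidx$individual)]
    ids2 <- sub$individuals$id[(sp == "A" & hh > 0.5) |
                                 (sp == "B" & hh < 0.5)]
    sub <- subset_dataset(sub, individuals = ids2)
    sizes <- table(sub$individuals$locality)
    if (sum(sizes >= 5L) < 4L) return(NULL)
    fst <- pairwise_fst(sub, min_n = 5L)
    rst <- pairwise_rst(sub, min_n = 5L)
    meta_sub <- dataset$meta[match(rownames(fst),
                                   dataset$meta$locality_id), ]
    geo <- geographic_distances(meta_sub,
                                coord_system = dataset$coord_system)
    sym <- stats::setNames(meta_sub$sympatry, meta_sub$locality_id)
    ibd <- if (sum(sym == "sympatric") >= 2L &&
               sum(sym == "allopatric") >= 2L) {
      ibd_residual_randomization(
        fst, geo, sympatry = sym,
        n_reps = config$n_reps_ibd,
        n_perms_mantel = config$n_perms_mantel,
        seed = stage(paste0("ibd_", sp)))
    } else NULL
    list(fst = fst, rst = rst, geo = geo,
         pcoa = pcoa(rst), ibd = ibd)
  })

  # --- stage: acoustics --------------------------------------------
  acoustics <- NULL
  if (!is.null(calls)) {
    cc <- temperature_correct(calls)
    fits <- list(
      pulse_rate = regress_call_on_hindex(cc, hidx, "pulse_rate"),
      pulse_number = regress_call_on_hindex(cc, hidx, "pulse_number"))
    step <- stepwise_select(cc, hidx)
    rcd <- do.call(rbind, lapply(c("A", "B"), function(sp) {
      tryCatch(rcd_by_region(cc, sp), error = function(e) NULL)
    }))
    rcd_reg <- NULL
    if (!is.null(rcd)) {
      rcd_reg <- lapply(split(rcd, rcd$species), function(tab) {
        if (nrow(tab) < 3L) return(NULL)
        lapply(c("F1", "CI", "CI-F1"), function(m)
          rcd_vs_admixture(tab, admix, metric = m))
      })
    }
    acoustics <- list(corrected = cc, fits = fits, stepwise = step,
                      rcd = rcd, rcd_vs_admixture = rcd_reg)
  }

  out <- structure(list(dataset = dataset, zone = zone, refs = refs,
                        freqs = freqs, hindex = hidx, admixture = admix,
                        comparisons = list(f1 = comp_f1, ci = comp_ci),
                        maternal = tally, structure = structure_res,
                        acoustics = acoustics, config = config,
                        log = log),
                   class = "hz_pipeline")
  if (!is.null(config$out_dir)) write_pipeline_outputs(out)
  out
}

#' Write pipeline result tables to CSV
#'
#' Emits the table analogues of the standard report: per-individual
#' hybrid indices, per-region admixture, the pairwise comparison tables
#' for both classification rules, the maternal tally, PCoA scores and
#' distance matrices per species, and the acoustic fits, plus a
#' plain-text run log with all seeds.
#'
#' @param result An `hz_pipeline` result whose config names `out_dir`.
#' @return The output directory, invisibly.
#' @export
write_pipeline_outputs <- function(result) {
  dir <- result$config$out_dir
  stopifnot(!is.null(dir))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, f) utils::write.csv(x, file.path(dir, f),
                                       row.names = FALSE)
  w(as.data.frame(result$hindex), "hybrid_index.csv")
  w(result$admixture, "admixture_by_region.csv")
  w(result$comparisons$f1, "comparisons_f1.csv")
  w(result$comparisons$ci, "comparisons_ci.csv")
  if (!is.null(result$maternal)) w(result$maternal, "maternal_tally.csv")
  for (sp in names(result$structure)) {
    st <- result$structure[[sp]]
    if (is.null(st)) next
    utils::write.csv(as.data.frame(unclass(st$fst)),
                     file.path(dir, paste0("fst_", sp, ".csv")))
    utils::write.csv(as.data.frame(unclass(st$rst)),
                     file.path(dir, paste0("rst_", sp, ".csv")))
    sc <- data.frame(locality = rownames(st$pcoa$coordinates),
                     st$pcoa$coordinates)
    w(sc, paste0("pcoa_", sp, ".csv"))
    ib <- st$ibd
    if (is.null(ib)) next
    w(data.frame(slope = ib$slope, intercept = ib$intercept,
                 mantel_r = ib$mantel_r, r_squared = ib$r_squared,
                 p_mantel = ib$p_mantel,
                 sympatry_stat = ib$sympatry_stat,
                 p_randomization = ib$p_randomization),
      paste0("ibd_", sp, ".csv"))
  }
  if (!is.null(result$acoustics)) {
    f <- result$acoustics$fits
    w(data.frame(variable = c(f$pulse_rate$variable,
                              f$pulse_number$variable),
                 r_squared = c(f$pulse_rate$r_squared,
                               f$pulse_number$r_squared),
                 p_value = c(f$pulse_rate$p_value,
                             f$pulse_number$p_value)),
      "acoustic_fits.csv")
    w(result$acoustics$stepwise$fits, "acoustic_model_choice.csv")
    if (!is.null(result$acoustics$rcd)) w(result$acoustics$rcd,
                                          "rcd_by_region.csv")
  }
  writeLines(paste(names(result$log),
                   vapply(result$log, paste, collapse = " ", ""),
                   sep = ": "),
             file.path(dir, "run_log.txt"))
  invisible(dir)
}

#' @export
print.hz_pipeline <- function(x, ...) {
  cat("<hz_pipeline> master seed", x$log$master_seed, "\n")
  cat("  individuals:", n_individuals(x$dataset),
      "| loci:", n_loci(x$dataset), "\n")
  cat("  regions summarized:", nrow(x$admixture), "\n")
  invisible(x)
}
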