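#!/usr/bin/env Rscript
# Stage 5: within-species population structure.
#
# With all classified hybrids removed (union of both rules), per
# species: pairwise Weir-Cockerham Fst and Slatkin Rst matrices over
# localities with n >= 5, PCoA of the Rst matrix, a Mantel test of
# isolation by distance (Fst vs transect distance, 10,000
# permutations), and the sympatry-residual randomization test asking
# whether residual divergence is elevated for pairs involving
# reinforced (sympatric) localities.

suppressPackageStartupMessages(library(hzadmix))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 1L

meta <- read_locality_meta("results/zone/meta.csv")
dataset <- read_genepop("results/zone/genotypes.gen", meta = meta,
                        coord_system = "planar")
hidx <- read.csv("results/hybrid_index.csv", stringsAsFactors = FALSE)
no_hyb <- filter_hybrids(dataset, hidx)
cat(sprintf("%d of %d individuals retained after hybrid removal\n",
            n_individuals(no_hyb), n_individuals(dataset)))

for (sp in c("A", "B")) {
  keep_loc <- meta$locality_id[meta$species %in% c(sp, "hybrid-unknown")]
  ids <- no_hyb$individuals$id[no_hyb$individuals$locality %in% keep_loc]
  sub <- subset_dataset(no_hyb, individuals = ids)
  hh <- hidx$h_hat[match(sub$individuals$id, hidx$individual)]
  sub <- subset_dataset(sub, individuals =
                          sub$individuals$id[(sp == "A") == (hh > 0.5)])
  sizes <- table(sub$individuals$locality)
  if (sum(sizes >= 5) < 4) { cat("species", sp, ": too few localities\n"); next }

  fst <- pairwise_fst(sub, min_n = 5)
  rst <- pairwise_rst(sub, min_n = 5)
  write.csv(as.data.frame(unclass(fst)),
            sprintf("results/fst_%s.csv", sp))
  write.csv(as.data.frame(unclass(rst)),
            sprintf("results/rst_%s.csv", sp))

  pc <- pcoa(rst)
  write.csv(data.frame(locality = rownames(pc$coordinates),
                       pc$coordinates),
            sprintf("results/pcoa_%s.csv", sp), row.names = FALSE)
  cat(sprintf("\nspecies %s: first PCoA axes explain %s of Rst variance\n",
              sp, paste(sprintf("%.1f%%",
                                utils::head(pc$percent_variance, 3)),
                        collapse = ", ")))

  msub <- meta[match(rownames(fst), meta$locality_id), ]
  geo <- geographic_distances(msub, coord_system = "planar")
  ibd <- ibd_residual_randomization(
    fst, geo, sympatry = setNames(msub$sympatry, msub$locality_id),
    n_reps = 200, n_perms_mantel = 10000,
    seed = derive_seed(seed, paste0("ibd", sp)))
  print(ibd)
  write.csv(data.frame(species = sp, slope = ibd$slope,
                       intercept = ibd$intercept,
                       mantel_r2 = ibd$r_squared,
                       p_mantel = ibd$p_mantel,
                       sympatry_stat = ibd$sympatry_stat,
                       p_randomization = ibd$p_randomization),
            sprintf("results/ibd_%s.csv", sp), row.names = FALSE)
}
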