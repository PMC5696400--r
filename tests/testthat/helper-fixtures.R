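# Shared fixtures built in code.

# Fully diagnostic two-allele loci: species A fixed for the low allele,
# species B for the high allele. Unsmoothed generating truth.
diagnostic_freqs <- function(L = 12L) {
  fa <- lapply(seq_len(L), function(j) {
    stats::setNames(c(1, 0), c(100 + 4 * j, 200 + 4 * j))
  })
  fb <- lapply(fa, function(p) stats::setNames(rev(unname(p)), names(p)))
  names(fa) <- names(fb) <- paste0("L", seq_len(L))
  allele_freq_table(fa, fb)
}

# Named frequency vectors (per locus) out of an allele_freq_table
freq_vectors <- function(tab, side = c("p_A", "p_B")) {
  side <- match.arg(side)
  lapply(tab, function(l) stats::setNames(l$freq[side, ],
                                          colnames(l$freq)))
}

# A dataset holding explicit genotypes at diagnostic loci.
# k_a: number of species-A allele copies (out of 2L) per individual.
diagnostic_dataset <- function(k_a, L = 12L, locality = "sym") {
  tab <- diagnostic_freqs(L)
  aA <- vapply(tab, function(l) as.integer(colnames(l$freq)[1]), 1L)
  aB <- vapply(tab, function(l) as.integer(colnames(l$freq)[2]), 1L)
  n <- length(k_a)
  ca <- matrix(NA_integer_, n, L); cb <- ca
  for (i in seq_len(n)) {
    copies <- c(rep(TRUE, k_a[i]), rep(FALSE, 2 * L - k_a[i]))
    ca[i, ] <- ifelse(copies[seq_len(L)], aA, aB)
    cb[i, ] <- ifelse(copies[L + seq_len(L)], aA, aB)
  }
  colnames(ca) <- colnames(cb) <- names(tab)
  genotype_dataset(ca, cb,
                   data.frame(id = sprintf("ind%03d", seq_len(n)),
                              locality = locality))
}

# Simulate individuals of one class from an allele_freq_table and
# estimate their hybrid indices against a (possibly different) table.
simulate_and_estimate <- function(class, n, gen_tab, est_tab = gen_tab,
                                  seed = 1L) {
  set.seed(seed)
  fa <- freq_vectors(gen_tab, "p_A"); fb <- freq_vectors(gen_tab, "p_B")
  L <- length(fa)
  ca <- matrix(NA_integer_, n, L); cb <- ca
  colnames(ca) <- colnames(cb) <- names(fa)
  truth <- numeric(n)
  for (i in seq_len(n)) {
    ind <- sim_individual(class, fa, fb)
    ca[i, ] <- ind$a1; cb[i, ] <- ind$a2
    truth[i] <- ind$h_true
  }
  ds <- genotype_dataset(ca, cb,
                         data.frame(id = sprintf("i%04d", seq_len(n)),
                                    locality = "x"))
  list(result = estimate_hybrid_index(ds, est_tab), h_true = truth,
       dataset = ds)
}

# Reference table estimated from finite reference samples drawn from the
# generating truth (the realistic estimation setting).
estimated_reference_table <- function(gen_tab, n_ref = 200L, seed = 1L,
                                      alpha = 0.5) {
  set.seed(seed)
  fa <- freq_vectors(gen_tab, "p_A"); fb <- freq_vectors(gen_tab, "p_B")
  L <- length(fa)
  n2 <- 2L * n_ref
  ca <- matrix(NA_integer_, n2, L); cb <- ca
  colnames(ca) <- colnames(cb) <- names(fa)
  for (i in seq_len(n_ref)) {
    ind <- sim_individual("pureA", fa, fb)
    ca[i, ] <- ind$a1; cb[i, ] <- ind$a2
    ind <- sim_individual("pureB", fa, fb)
    ca[n_ref + i, ] <- ind$a1; cb[n_ref + i, ] <- ind$a2
  }
  meta <- data.frame(locality_id = c("refA", "refB"),
                     species = c("A", "B"), sympatry = "allopatric",
                     lat = c(1, -1), lon = c(0, 0))
  ds <- genotype_dataset(
    ca, cb,
    data.frame(id = sprintf("r%04d", seq_len(n2)),
               locality = rep(c("refA", "refB"), each = n_ref)),
    meta = meta, coord_system = "planar")
  estimate_frequencies(ds, pool_references(ds), alpha = alpha)
}

# Realistic estimation setting: focal individuals of one class plus
# finite reference samples in one dataset (so the smoothing universe is
# the dataset's, as in the real workflow); frequencies estimated from
# the pooled references, indices estimated for the focal individuals.
coverage_experiment <- function(class, n, gen_tab, n_ref = 200L,
                                seed = 1L, alpha = 0.5) {
  set.seed(seed)
  fa <- freq_vectors(gen_tab, "p_A"); fb <- freq_vectors(gen_tab, "p_B")
  L <- length(fa)
  total <- n + 2L * n_ref
  ca <- matrix(NA_integer_, total, L); cb <- ca
  colnames(ca) <- colnames(cb) <- names(fa)
  # a numeric `class` means admixture-model draws: every allele copy
  # independently from h * p_A + (1 - h) * p_B (the process the
  # likelihood models, i.e. the calibration setting); a character class
  # uses the mechanistic pedigree construction
  mix_draw <- function(h) {
    a <- integer(L)
    for (j in seq_len(L)) {
      p <- if (stats::runif(1) < h) fa[[j]] else fb[[j]]
      a[j] <- as.integer(names(p))[sample.int(length(p), 1L, prob = p)]
    }
    a
  }
  cls <- c(rep(list(class), n), rep(list("pureA"), n_ref),
           rep(list("pureB"), n_ref))
  h_true <- numeric(n)
  for (i in seq_len(total)) {
    if (is.numeric(cls[[i]])) {
      ca[i, ] <- mix_draw(cls[[i]]); cb[i, ] <- mix_draw(cls[[i]])
      if (i <= n) h_true[i] <- cls[[i]]
    } else {
      ind <- sim_individual(cls[[i]], fa, fb)
      ca[i, ] <- ind$a1; cb[i, ] <- ind$a2
      if (i <= n) h_true[i] <- ind$h_true
    }
  }
  loc <- c(rep("focal", n), rep("refA", n_ref), rep("refB", n_ref))
  meta <- data.frame(
    locality_id = c("focal", "refA", "refB"),
    species = c("hybrid-unknown", "A", "B"),
    sympatry = c("sympatric", "allopatric", "allopatric"),
    region = c("R1", NA, NA), lat = c(0, 1, -1), lon = 0)
  ds <- genotype_dataset(ca, cb,
                         data.frame(id = sprintf("i%05d", seq_len(total)),
                                    locality = loc),
                         meta = meta, coord_system = "planar")
  refs <- pool_references(ds)
  fr <- estimate_frequencies(ds, refs, alpha = alpha)
  res <- estimate_hybrid_index(ds, fr,
                               individuals = ds$individuals$id[1:n])
  list(result = res, h_true = h_true)
}

# Two-locality dataset from explicit genotype pairs (one locus).
make_two_pop <- function(geno1, geno2, locus = "L1") {
  n1 <- length(geno1); n2 <- length(geno2)
  ca <- matrix(c(vapply(geno1, `[`, 1L, 1),
                 vapply(geno2, `[`, 1L, 1)), ncol = 1,
               dimnames = list(NULL, locus))
  cb <- matrix(c(vapply(geno1, `[`, 1L, 2),
                 vapply(geno2, `[`, 1L, 2)), ncol = 1,
               dimnames = list(NULL, locus))
  genotype_dataset(ca, cb,
                   data.frame(id = sprintf("i%03d", seq_len(n1 + n2)),
                              locality = rep(c("p1", "p2"),
                                             c(n1, n2))))
}

# A small, quick synthetic zone shared across tests.
small_zone <- function(seed = 42L, cap = 30L) {
  lay <- default_layout()
  lay$n <- pmin(lay$n, cap)
  sim_zone(sim_config(layout = lay), seed = seed)
}
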