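test_that("fragment binning uses left-closed right-open bins", {
  loc <- list(locus_def("L1", c(100, 104, 108)))
  ind <- data.frame(id = c("a", "b"), locality = "x")
  ds <- bin_fragments(matrix(c(101.2, 105.0), 2, 1),
                      matrix(c(103.9, 104.0), 2, 1), loc, ind)
  ids <- bin_alleles(loc[[1]])          # midpoints 102, 106
  expect_equal(unname(ds$calls_a[, 1]), c(ids[1], ids[2]))
  # 103.9 -> bin1; a length exactly on edge 104 -> right bin
  expect_equal(unname(ds$calls_b[, 1]), c(ids[1], ids[2]))
})

test_that("out-of-range lengths become missing with a warning", {
  loc <- list(locus_def("L1", c(100, 104, 108)))
  ind <- data.frame(id = c("a", "b"), locality = "x")
  # one warning per copy matrix carrying an out-of-range length
  expect_warning(expect_warning(
    ds <- bin_fragments(matrix(c(99.9, 101), 2, 1),
                        matrix(c(101, 108), 2, 1), loc, ind),
    "outside all bins"), "outside all bins")
  # 99.9 below and 108 on the last edge are outside; missing zeroes the
  # whole call
  expect_true(is.na(ds$calls_a[1, 1]) && is.na(ds$calls_a[2, 1]))
})

test_that("unsorted bin edges are a configuration error", {
  expect_error(locus_def("L1", c(104, 100, 108)), "strictly increasing")
  expect_error(locus_def("L1", 100), "at least 2")
})

test_that("binning matches a brute-force linear scan on random lengths", {
  set.seed(1)
  edges <- sort(sample(100:260, 25))
  loc <- list(locus_def("L1", edges))
  n <- 1000L
  x <- runif(n, 95, 265)
  ind <- data.frame(id = sprintf("i%04d", 1:n), locality = "x")
  suppressWarnings(
    ds <- bin_fragments(matrix(x, n, 1), matrix(x, n, 1), loc, ind))
  ids <- bin_alleles(loc[[1]])
  oracle <- vapply(x, function(v) {
    for (k in seq_len(length(edges) - 1L)) {
      if (v >= edges[k] && v < edges[k + 1L]) return(ids[k])
    }
    NA_integer_
  }, 1L)
  expect_equal(unname(ds$calls_a[, 1]), oracle)
})

test_that("binning is idempotent on bin-midpoint alleles", {
  loc <- list(locus_def("L1", c(100, 104, 108)),
              locus_def("L2", c(200, 210, 220, 230)))
  ids1 <- bin_alleles(loc[[1]]); ids2 <- bin_alleles(loc[[2]])
  ind <- data.frame(id = "a", locality = "x")
  ds <- bin_fragments(matrix(c(ids1[1], ids2[3]), 1, 2),
                      matrix(c(ids1[2], ids2[1]), 1, 2), loc, ind)
  again <- bin_fragments(ds$calls_a, ds$calls_b, loc, ind)
  expect_identical(ds$calls_a, again$calls_a)
  expect_identical(ds$calls_b, again$calls_b)
})

test_that("GENEPOP round-trip is the identity, missing parsed as zeros", {
  z <- small_zone(seed = 5, cap = 12L)
  ds <- z$dataset
  # plant a missing call
  ds$calls_a[3, 2] <- NA; ds$calls_b[3, 2] <- NA
  f <- withr::local_tempfile(fileext = ".gen")
  write_genepop(ds, f)
  back <- read_genepop(f)
  ord1 <- order(ds$individuals$id); ord2 <- order(back$individuals$id)
  expect_identical(unname(ds$calls_a[ord1, ]),
                   unname(back$calls_a[ord2, ]))
  expect_identical(unname(ds$calls_b[ord1, ]),
                   unname(back$calls_b[ord2, ]))
  expect_identical(ds$individuals$locality[ord1],
                   back$individuals$locality[ord2])
  expect_true(any(grepl(" 000000| 0000 |000000$",
                        readLines(f))))  # missing written as zeros
})

test_that("GENEPOP parser handles toy files, widths, and errors", {
  f <- withr::local_tempfile(fileext = ".gen")
  writeLines(c("toy", "locA", "locB", "POP",
               "p1:i1 , 101102 0000",
               "p1:i2 , 101101 0103",
               "POP",
               "p2:i1 , 102102 0203"), f)
  expect_error(read_genepop(f), "mixed allele-code widths")
  # fix: make all loci consistently 2-digit
  writeLines(c("toy", "locA", "locB", "POP",
               "p1:i1 , 0102 0000",
               "p1:i2 , 0101 0103",
               "POP",
               "p2:i1 , 0202 0203"), f)
  ds <- read_genepop(f)
  expect_equal(n_individuals(ds), 3L)
  expect_equal(sort(unique(ds$individuals$locality)), c("p1", "p2"))
  expect_true(is.na(ds$calls_a[1, "locB"]))   # "0000" is missing
  expect_equal(unname(ds$calls_a[2, ]), c(1L, 1L))
  expect_equal(unname(ds$calls_b[3, ]), c(2L, 3L))
})

test_that("alleles above 999 are not encodable", {
  ds <- genotype_dataset(matrix(1000L, 1, 1), matrix(2L, 1, 1),
                         data.frame(id = "a", locality = "x"))
  expect_error(write_genepop(ds, withr::local_tempfile()), "999")
})

test_that("empty dataset writes a header-only GENEPOP file", {
  ds <- genotype_dataset(matrix(integer(), 0, 2,
                                dimnames = list(NULL, c("a", "b"))),
                         matrix(integer(), 0, 2,
                                dimnames = list(NULL, c("a", "b"))),
                         data.frame(id = character(),
                                    locality = character()))
  f <- withr::local_tempfile()
  write_genepop(ds, f)
  expect_equal(length(readLines(f)), 3L)  # title + two locus names
})

test_that("STRUCTURE two-row round-trip preserves calls and missing", {
  z <- small_zone(seed = 6, cap = 10L)
  ds <- z$dataset
  ds$calls_a[1, 1] <- NA; ds$calls_b[1, 1] <- NA
  f <- withr::local_tempfile()
  write_structure2(ds, f)
  back <- read_structure2(f)
  expect_identical(unname(ds$calls_a), unname(back$calls_a))
  expect_identical(unname(ds$calls_b), unname(back$calls_b))
  expect_identical(ds$individuals$locality, back$individuals$locality)
  expect_true(any(grepl("-9", readLines(f))))
})

test_that("reference pooling selects all and only matching individuals", {
  z <- small_zone(seed = 7, cap = 10L)
  refs <- pool_references(z$dataset)
  meta <- z$dataset$meta
  alloA <- meta$locality_id[meta$species == "A" &
                              meta$sympatry == "allopatric"]
  expect_setequal(refs$ref_A,
                  z$dataset$individuals$id[
                    z$dataset$individuals$locality %in% alloA])
  expect_length(intersect(refs$ref_A, refs$ref_B), 0)
  expect_error(
    pool_references(z$dataset,
                    selector_a = list(species = "A",
                                      sympatry = "allopatric",
                                      group = "nope")),
    "species A")
})

test_that("default layout reproduces the reference design sizes", {
  # pooled allopatric sample sizes of the study design: 188 and 80
  lay <- default_layout()
  expect_equal(sum(lay$n[lay$species == "A" &
                           lay$sympatry == "allopatric"]), 188L)
  expect_equal(sum(lay$n[lay$species == "B" &
                           lay$sympatry == "allopatric"]), 80L)
  # with one dummy locus, pooled reference sizes equal the layout sums
  n <- sum(lay$n)
  ind <- data.frame(
    id = sprintf("i%04d", seq_len(n)),
    locality = rep(lay$locality_id, lay$n))
  ds <- genotype_dataset(matrix(1L, n, 1), matrix(1L, n, 1), ind,
                         meta = lay[, c("locality_id", "species",
                                        "region", "sympatry",
                                        "lon", "lat", "group")],
                         coord_system = "planar")
  refs <- pool_references(ds)
  expect_length(refs$ref_A, 188L)
  expect_length(refs$ref_B, 80L)
})

test_that("metadata overrides re-home individuals before validation", {
  z <- small_zone(seed = 8, cap = 8L)
  ds <- z$dataset
  id1 <- ds$individuals$id[1]
  loc2 <- ds$individuals$locality[ds$individuals$locality !=
                                    ds$individuals$locality[1]][1]
  ds2 <- attach_metadata(ds, ds$meta,
                         overrides = data.frame(id = id1,
                                                locality_id = loc2))
  expect_equal(ds2$individuals$locality[ds2$individuals$id == id1], loc2)
})
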