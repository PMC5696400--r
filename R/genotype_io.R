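#' Bin raw fragment lengths into discrete alleles
#'
#' Assigns each raw fragment length to the bin containing it, using
#' left-closed right-open intervals between the locus's breakpoints
#' (a length exactly on an internal edge goes to the bin on its right).
#' Lengths falling outside all bins become missing, with a warning giving
#' the count per locus. Allele identifiers are rounded bin midpoints, so
#' downstream size-based statistics see integer fragment sizes.
#'
#' @param raw_a,raw_b Numeric matrices (individuals x loci) of raw fragment
#'   lengths for the two allele copies; `NA` for no call.
#' @param loci List of [locus_def()] objects, one per column.
#' @param individuals Data frame with columns `id`, `locality`.
#' @param ... Passed to [genotype_dataset()] (`meta`, `maternal`,
#'   `coord_system`).
#' @return A [genotype_dataset()].
#' @export
bin_fragments <- function(raw_a, raw_b, loci, individuals, ...) {
  raw_a <- as.matrix(raw_a); raw_b <- as.matrix(raw_b)
  stopifnot(identical(dim(raw_a), dim(raw_b)),
            length(loci) == ncol(raw_a))
  if (any(c(raw_a, raw_b) <= 0, na.rm = TRUE)) {
    stop("raw fragment lengths must be positive")
  }
  nm <- vapply(loci, function(l) l$name, "")
  out_a <- matrix(NA_integer_, nrow(raw_a), ncol(raw_a),
                  dimnames = list(NULL, nm))
  out_b <- out_a
  for (j in seq_along(loci)) {
    ids <- bin_alleles(loci[[j]])
    out_a[, j] <- .bin_one(raw_a[, j], loci[[j]], ids)
    out_b[, j] <- .bin_one(raw_b[, j], loci[[j]], ids)
  }
  genotype_dataset(out_a, out_b, individuals, ...)
}

.bin_one <- function(x, locus, ids) {
  e <- locus$bin_edges
  # findInterval: e[i] <= x < e[i+1] -> i  (left-closed, right-open)
  k <- findInterval(x, e)
  out_of_range <- !is.na(x) & (k < 1L | k >= length(e))
  if (any(out_of_range)) {
    warning(sum(out_of_range), " length(s) outside all bins at locus ",
            locus$name, " set to missing", call. = FALSE)
  }
  k[out_of_range | is.na(x)] <- NA_integer_
  ids[k]
}

#' Read a GENEPOP genotype file
#'
#' Parses the GENEPOP dialect with 2- or 3-digit allele codes. The first
#' line is a title, then one locus name per line (or a comma-separated
#' list), then populations introduced by lines reading `POP`. Allele code
#' `000`/`00` is missing. Populations become localities; if an individual
#' identifier contains `":"` it is split as `locality:individual`
#' (the convention [write_genepop()] uses), otherwise localities are named
#' `pop1`, `pop2`, ...
#'
#' @param path File path.
#' @param ... Passed to [genotype_dataset()] (e.g. `meta`).
#' @return A [genotype_dataset()].
#' @export
read_genepop <- function(path, ...) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) < 2L) stop("not a GENEPOP file: too short")
  is_pop <- grepl("^\\s*pop\\s*$", lines, ignore.case = TRUE)
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) stop("not a GENEPOP file: no POP line")
  loci <- trimws(unlist(strsplit(lines[2:(first_pop - 1)], ",")))
  loci <- loci[nzchar(loci)]
  pop_breaks <- which(is_pop)
  ids <- character(); locs <- character()
  rows_a <- list(); rows_b <- list()
  pop_idx <- 0L
  for (k in seq_along(pop_breaks)) {
    pop_idx <- pop_idx + 1L
    from <- pop_breaks[k] + 1L
    to <- if (k < length(pop_breaks)) pop_breaks[k + 1L] - 1L else length(lines)
    if (to < from) next
    for (ln in from:to) {
      parts <- strsplit(lines[ln], ",")[[1]]
      if (length(parts) < 2L) {
        stop("GENEPOP parse error at line ", ln, ": no comma separator")
      }
      raw_id <- trimws(parts[1])
      geno <- strsplit(trimws(paste(parts[-1], collapse = " ")), "\\s+")[[1]]
      if (length(geno) != length(loci)) {
        stop("GENEPOP parse error at line ", ln, ": ", length(geno),
             " genotypes for ", length(loci), " loci")
      }
      w <- nchar(geno)
      if (!all(w %in% c(4L, 6L))) {
        stop("GENEPOP parse error at line ", ln,
             ": allele codes must be 2 or 3 digits")
      }
      if (length(unique(w)) > 1L) {
        stop("GENEPOP parse error at line ", ln,
             ": mixed allele-code widths")
      }
      d <- w[1] / 2L
      a1 <- as.integer(substr(geno, 1L, d))
      a2 <- as.integer(substr(geno, d + 1L, 2L * d))
      a1[a1 == 0L] <- NA_integer_; a2[a2 == 0L] <- NA_integer_
      if (grepl(":", raw_id, fixed = TRUE)) {
        sp <- strsplit(raw_id, ":", fixed = TRUE)[[1]]
        locs <- c(locs, sp[1])
        ids <- c(ids, paste(sp[-1], collapse = ":"))
      } else {
        locs <- c(locs, paste0("pop", pop_idx))
        ids <- c(ids, raw_id)
      }
      rows_a[[length(rows_a) + 1L]] <- a1
      rows_b[[length(rows_b) + 1L]] <- a2
    }
  }
  calls_a <- do.call(rbind, rows_a); calls_b <- do.call(rbind, rows_b)
  colnames(calls_a) <- colnames(calls_b) <- loci
  # GENEPOP files may reuse individual names across populations
  if (anyDuplicated(ids)) {
    ids <- make.unique(paste(locs, ids, sep = ":"), sep = "_")
  }
  genotype_dataset(calls_a, calls_b,
                   data.frame(id = ids, locality = locs,
                              stringsAsFactors = FALSE), ...)
}

#' Write a genotype dataset in GENEPOP format
#'
#' Writes 3-digit allele codes (alleles above 999 are not encodable and
#' raise an error), zeros for missing, one POP block per locality in
#' sorted locality order with individuals sorted by id within each block.
#' Individual ids are written as `locality:id` so that
#' [read_genepop()] recovers the locality labels, making write-then-read
#' the identity on the genotype content.
#'
#' @param dataset A [genotype_dataset()].
#' @param path Output file path.
#' @param title Title line (first line of the file).
#' @return `path`, invisibly.
#' @export
write_genepop <- function(dataset, path, title = "hzadmix export") {
  av <- c(dataset$calls_a, dataset$calls_b)
  if (any(av > 999L, na.rm = TRUE)) {
    stop("allele identifiers above 999 cannot be encoded in GENEPOP ",
         "3-digit codes")
  }
  if (any(av < 1L, na.rm = TRUE)) stop("allele identifiers must be >= 1")
  con <- file(path, "w"); on.exit(close(con))
  writeLines(title, con)
  writeLines(locus_names(dataset), con)
  ord_loc <- sort(unique(dataset$individuals$locality))
  enc <- function(m) {
    z <- sprintf("%03d", m)
    z[is.na(m)] <- "000"
    z
  }
  for (loc in ord_loc) {
    writeLines("POP", con)
    rows <- which(dataset$individuals$locality == loc)
    rows <- rows[order(dataset$individuals$id[rows])]
    for (i in rows) {
      g <- paste0(enc(dataset$calls_a[i, ]), enc(dataset$calls_b[i, ]))
      writeLines(paste0(loc, ":", dataset$individuals$id[i], " , ",
                        paste(g, collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Read a STRUCTURE two-row genotype table
#'
#' Tab- or whitespace-separated, one row per allele copy (two consecutive
#' rows per individual), `-9` for missing. Expected columns: individual id,
#' locality, then one column per locus. A header row with locus names is
#' required unless `locus_names` is given.
#'
#' @param path File path.
#' @param locus_names Optional locus names if the file has no header.
#' @param ... Passed to [genotype_dataset()].
#' @return A [genotype_dataset()].
#' @export
read_structure2 <- function(path, locus_names = NULL, ...) {
  tab <- utils::read.table(path, header = is.null(locus_names),
                           stringsAsFactors = FALSE)
  if (!is.null(locus_names)) {
    stopifnot(ncol(tab) == length(locus_names) + 2L)
    names(tab) <- c("id", "locality", locus_names)
  }
  if (nrow(tab) %% 2L != 0L) {
    stop("STRUCTURE two-row file must have an even number of data rows")
  }
  odd <- seq(1L, nrow(tab), by = 2L); even <- odd + 1L
  if (!identical(as.character(tab[[1]][odd]), as.character(tab[[1]][even]))) {
    stop("consecutive row pairs must share the individual id")
  }
  g <- as.matrix(tab[, -(1:2), drop = FALSE])
  storage.mode(g) <- "integer"
  g[g == -9L] <- NA_integer_
  genotype_dataset(g[odd, , drop = FALSE], g[even, , drop = FALSE],
                   data.frame(id = as.character(tab[[1]][odd]),
                              locality = as.character(tab[[2]][odd]),
                              stringsAsFactors = FALSE), ...)
}

#' Write a STRUCTURE two-row genotype table
#' @param dataset A [genotype_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure2 <- function(dataset, path) {
  n <- n_individuals(dataset)
  enc <- function(m) { m[is.na(m)] <- -9L; m }
  rows <- matrix(NA_integer_, 2L * n, n_loci(dataset))
  rows[seq(1L, 2L * n, 2L), ] <- enc(dataset$calls_a)
  rows[seq(2L, 2L * n, 2L), ] <- enc(dataset$calls_b)
  out <- data.frame(id = rep(dataset$individuals$id, each = 2L),
                    locality = rep(dataset$individuals$locality, each = 2L),
                    rows)
  names(out) <- c("id", "locality", locus_names(dataset))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read locality metadata
#'
#' CSV with columns `locality_id, species, region, sympatry, lat, lon,
#' group` (`region`/`group` optional). An optional `individual_override`
#' table (columns `id, locality_id`) re-homes named individuals, e.g.
#' single-individual county samples pooled with a neighbouring county.
#'
#' @param path CSV path.
#' @return Validated metadata data frame.
#' @export
read_locality_meta <- function(path) {
  validate_locality_meta(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Read per-individual maternal-parent labels
#'
#' CSV with columns `id, maternal` (values `A`, `B`, `unknown`); stands in
#' for mitochondrial maternal-parent assignment.
#'
#' @param path CSV path.
#' @return Named character vector.
#' @export
read_maternal_labels <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "maternal") %in% names(tab)))
  stats::setNames(as.character(tab$maternal), as.character(tab$id))
}

#' Attach locality metadata (and optionally maternal labels) to a dataset
#' @param dataset A [genotype_dataset()].
#' @param meta Metadata data frame ([read_locality_meta()]).
#' @param maternal Optional named maternal-label vector.
#' @param overrides Optional data frame `id, locality_id` re-homing
#'   individuals before validation.
#' @return The updated `genotype_dataset`.
#' @export
attach_metadata <- function(dataset, meta, maternal = NULL,
                            overrides = NULL) {
  ind <- dataset$individuals
  if (!is.null(overrides)) {
    idx <- match(overrides$id, ind$id)
    if (anyNA(idx)) stop("override names unknown individuals")
    ind$locality[idx] <- as.character(overrides$locality_id)
  }
  genotype_dataset(dataset$calls_a, dataset$calls_b, ind, meta = meta,
                   maternal = if (is.null(maternal)) dataset$maternal
                              else maternal,
                   coord_system = dataset$coord_system)
}

#' Pool allopatric samples into two species reference groups
#'
#' Selects localities matching each selector (by default all allopatric
#' localities of each species), and pools their individuals into the two
#' parental reference groups used for hybrid-index estimation.
#'
#' @param dataset A [genotype_dataset()] with metadata attached.
#' @param selector_a,selector_b Named lists of metadata filters, e.g.
#'   `list(species = "A", sympatry = "allopatric")`; values may be vectors
#'   (matched with `%in%`). An entry `locality_id = c(...)` selects
#'   explicit localities.
#' @return A `reference_pair`: list with character vectors `ref_A`,
#'   `ref_B` of individual ids.
#' @export
pool_references <- function(dataset,
                            selector_a = list(species = "A",
                                              sympatry = "allopatric"),
                            selector_b = list(species = "B",
                                              sympatry = "allopatric")) {
  if (is.null(dataset$meta)) stop("dataset has no locality metadata")
  pick <- function(sel, side) {
    keep <- rep(TRUE, nrow(dataset$meta))
    for (nm in names(sel)) {
      if (!nm %in% names(dataset$meta)) stop("unknown metadata field: ", nm)
      keep <- keep & dataset$meta[[nm]] %in% sel[[nm]]
    }
    loc <- dataset$meta$locality_id[keep]
    ids <- dataset$individuals$id[dataset$individuals$locality %in% loc]
    if (!length(ids)) {
      stop("reference selector for species ", side,
           " matches no individuals")
    }
    ids
  }
  ref_a <- pick(selector_a, "A"); ref_b <- pick(selector_b, "B")
  if (length(intersect(ref_a, ref_b))) {
    stop("reference groups overlap")
  }
  structure(list(ref_A = ref_a, ref_B = ref_b), class = "reference_pair")
}

#' @export
print.reference_pair <- function(x, ...) {
  cat("<reference_pair> A: n =", length(x$ref_A),
      "| B: n =", length(x$ref_B), "\n")
  invisible(x)
}
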