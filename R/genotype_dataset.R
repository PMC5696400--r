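#' Locus definition
#'
#' Describes one codominant length-polymorphic locus: its name, the ordered
#' fragment-length breakpoints used to bin raw sizes into discrete alleles,
#' and the sentinel used for missing calls in text formats.
#'
#' Intervals between successive breakpoints are left-closed, right-open:
#' a fragment exactly on an internal edge falls in the bin to its right.
#'
#' @param name Locus identifier.
#' @param bin_edges Strictly increasing numeric breakpoints (base pairs);
#'   `length(bin_edges) >= 2`, defining `length(bin_edges) - 1` bins.
#' @param missing_code Sentinel used in text formats (default `0`).
#' @return An object of class `locus_def`.
#' @export
locus_def <- function(name, bin_edges, missing_code = 0L) {
  stopifnot(is.character(name), length(name) == 1L, nchar(name) > 0L)
  bin_edges <- as.numeric(bin_edges)
  if (length(bin_edges) < 2L) {
    stop("locus ", name, ": need at least 2 bin edges (1 bin)")
  }
  if (any(diff(bin_edges) <= 0)) {
    stop("locus ", name, ": bin_edges must be strictly increasing")
  }
  structure(list(name = name, bin_edges = bin_edges,
                 missing_code = missing_code),
            class = "locus_def")
}

#' Allele identifier for each bin of a locus
#'
#' Alleles are represented by the rounded midpoint of their fragment-length
#' bin, so allele identifiers are integer sizes usable directly in
#' size-based statistics such as Rst.
#'
#' @param locus A [locus_def()].
#' @return Integer vector, one representative size per bin.
#' @export
bin_alleles <- function(locus) {
  e <- locus$bin_edges
  as.integer(round((e[-length(e)] + e[-1]) / 2))
}

#' Construct a genotype dataset
#'
#' The backbone container of the package: diploid multi-allelic calls for a
#' set of individuals at a set of loci, plus locality metadata and optional
#' maternal-parent labels. Allele identifiers are integer fragment sizes
#' (bin midpoints); missing calls are `NA`.
#'
#' @param calls_a,calls_b Integer matrices (individuals x loci) holding the
#'   two allele copies of each unordered genotype; `NA` for missing. Row
#'   names are individual ids, column names locus names. A call is treated
#'   as missing if either copy is `NA`.
#' @param individuals Data frame with columns `id` and `locality`.
#' @param meta Optional locality metadata, see [read_locality_meta()].
#'   Must contain one row per locality referenced by `individuals`.
#' @param maternal Optional character vector (named by individual id or in
#'   individual order) with values `"A"`, `"B"` or `"unknown"`.
#' @param coord_system `"lonlat"` (GPS decimal degrees) or `"planar"`
#'   (synthetic x/y, distance unit km).
#' @return An object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(calls_a, calls_b, individuals, meta = NULL,
                             maternal = NULL, coord_system = "lonlat") {
  calls_a <- as.matrix(calls_a); calls_b <- as.matrix(calls_b)
  storage.mode(calls_a) <- "integer"; storage.mode(calls_b) <- "integer"
  stopifnot(identical(dim(calls_a), dim(calls_b)))
  if (is.null(colnames(calls_a))) {
    colnames(calls_a) <- colnames(calls_b) <- paste0("L", seq_len(ncol(calls_a)))
  }
  stopifnot(identical(colnames(calls_a), colnames(calls_b)))
  individuals <- as.data.frame(individuals, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "locality") %in% names(individuals)))
  individuals$id <- as.character(individuals$id)
  individuals$locality <- as.character(individuals$locality)
  if (nrow(individuals) != nrow(calls_a)) {
    stop("individuals table and call matrices disagree on n")
  }
  if (anyDuplicated(individuals$id)) stop("duplicate individual ids")
  rownames(calls_a) <- rownames(calls_b) <- individuals$id
  # missing propagates to both copies so a call is whole or absent
  miss <- is.na(calls_a) | is.na(calls_b)
  calls_a[miss] <- NA_integer_; calls_b[miss] <- NA_integer_
  if (!is.null(meta)) {
    meta <- validate_locality_meta(meta)
    unknown <- setdiff(individuals$locality, meta$locality_id)
    if (length(unknown)) {
      stop("localities missing from metadata: ",
           paste(unknown, collapse = ", "))
    }
  }
  if (!is.null(maternal)) {
    maternal <- stats::setNames(as.character(maternal),
                                names(maternal))
    if (!is.null(names(maternal))) {
      maternal <- maternal[individuals$id]
      maternal[is.na(maternal)] <- "unknown"
    }
    stopifnot(length(maternal) == nrow(individuals))
    bad <- !maternal %in% c("A", "B", "unknown")
    if (any(bad)) stop("maternal labels must be A, B or unknown")
    names(maternal) <- individuals$id
  }
  coord_system <- match.arg(coord_system, c("lonlat", "planar"))
  structure(list(calls_a = calls_a, calls_b = calls_b,
                 individuals = individuals, meta = meta,
                 maternal = maternal, coord_system = coord_system),
            class = "genotype_dataset")
}

validate_locality_meta <- function(meta) {
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  need <- c("locality_id", "species", "sympatry")
  if (!all(need %in% names(meta))) {
    stop("locality metadata needs columns: ", paste(need, collapse = ", "))
  }
  meta$locality_id <- as.character(meta$locality_id)
  if (anyDuplicated(meta$locality_id)) stop("duplicate locality ids")
  if (!all(meta$sympatry %in% c("sympatric", "allopatric"))) {
    stop("sympatry must be 'sympatric' or 'allopatric'")
  }
  if (!all(meta$species %in% c("A", "B", "hybrid-unknown"))) {
    stop("species label must be 'A', 'B' or 'hybrid-unknown'")
  }
  for (col in c("region", "lat", "lon", "group")) {
    if (!col %in% names(meta)) meta[[col]] <- NA
  }
  coord <- c(meta$lat, meta$lon)
  if (any(!is.na(coord) & !is.finite(coord))) stop("non-finite coordinates")
  meta
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("<genotype_dataset> ", nrow(x$calls_a), " individuals x ",
      ncol(x$calls_a), " loci\n", sep = "")
  cat("  localities: ", length(unique(x$individuals$locality)),
      if (!is.null(x$meta)) " (with metadata)" else " (no metadata)",
      "\n", sep = "")
  miss <- mean(is.na(x$calls_a))
  cat("  missing calls: ", sprintf("%.1f%%", 100 * miss), "\n", sep = "")
  if (!is.null(x$maternal)) {
    cat("  maternal labels: ",
        sum(x$maternal != "unknown"), " assigned\n", sep = "")
  }
  invisible(x)
}

#' Number of individuals / loci
#' @param dataset A [genotype_dataset()].
#' @return Integer count.
#' @export
n_individuals <- function(dataset) nrow(dataset$calls_a)

#' @rdname n_individuals
#' @export
n_loci <- function(dataset) ncol(dataset$calls_a)

#' Locus names of a dataset
#' @param dataset A [genotype_dataset()].
#' @return Character vector.
#' @export
locus_names <- function(dataset) colnames(dataset$calls_a)

#' Subset a genotype dataset by individuals or loci
#'
#' @param dataset A [genotype_dataset()].
#' @param individuals Character vector of individual ids or logical/integer
#'   index; `NULL` keeps all.
#' @param loci Character vector of locus names (or index); `NULL` keeps all.
#'   Passing the locus set minus excluded loci implements locus-exclusion
#'   sensitivity analyses (e.g. dropping high-null-frequency loci).
#' @return A `genotype_dataset`.
#' @export
subset_dataset <- function(dataset, individuals = NULL, loci = NULL) {
  ii <- if (is.null(individuals)) seq_len(n_individuals(dataset)) else {
    if (is.character(individuals)) {
      idx <- match(individuals, dataset$individuals$id)
      if (anyNA(idx)) stop("unknown individual ids")
      idx
    } else individuals
  }
  jj <- if (is.null(loci)) seq_len(n_loci(dataset)) else {
    if (is.character(loci)) {
      idx <- match(loci, locus_names(dataset))
      if (anyNA(idx)) stop("unknown loci")
      idx
    } else loci
  }
  genotype_dataset(dataset$calls_a[ii, jj, drop = FALSE],
                   dataset$calls_b[ii, jj, drop = FALSE],
                   dataset$individuals[ii, , drop = FALSE],
                   meta = dataset$meta,
                   maternal = if (!is.null(dataset$maternal))
                     dataset$maternal[ii] else NULL,
                   coord_system = dataset$coord_system)
}

#' Locality of each individual, with metadata lookup helpers
#' @param dataset A [genotype_dataset()].
#' @param field Metadata column to return per individual (default the
#'   locality id itself).
#' @return Vector of length `n_individuals(dataset)`.
#' @export
individual_meta <- function(dataset, field = "locality_id") {
  loc <- dataset$individuals$locality
  if (field == "locality_id") return(loc)
  if (is.null(dataset$meta)) stop("dataset has no locality metadata")
  dataset$meta[[field]][match(loc, dataset$meta$locality_id)]
}
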