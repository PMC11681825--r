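#' Construct a functional-connectivity bundle
#'
#' A bundle holds one static connectivity matrix per (subject, band) pair,
#' with a single region order shared by all matrices (the atlas order). It
#' is the container passed between the connectivity, network-statistic,
#' post-hoc, association and cross-validation stages.
#'
#' @param matrices named list, one element per band; each element a numeric
#'   array `n_regions x n_regions x n_subjects` (symmetric, zero diagonal,
#'   values in \[0, 1\]).
#' @param subjects character vector of subject identifiers, in the order of
#'   the third array dimension.
#' @param manifest optional named list of provenance fields (source, seed,
#'   window specification, ...), stored verbatim.
#' @return an object of class `fc_bundle`.
#' @export
fc_bundle <- function(matrices, subjects, manifest = list()) {
  if (!is.list(matrices) || is.null(names(matrices)) ||
      any(names(matrices) == "")) {
    stop("'matrices' must be a named list with one element per band")
  }
  subjects <- as.character(subjects)
  if (anyDuplicated(subjects)) stop("duplicate subject ids in bundle")
  n_regions <- dim(matrices[[1]])[1]
  for (b in names(matrices)) {
    a <- matrices[[b]]
    if (length(dim(a)) != 3L) stop("band '", b, "': expected a 3-d array")
    if (dim(a)[1] != n_regions || dim(a)[2] != n_regions) {
      stop("band '", b, "': region dimensions differ across bands")
    }
    if (dim(a)[3] != length(subjects)) {
      stop("band '", b, "': subject dimension does not match 'subjects'")
    }
  }
  structure(
    list(matrices = matrices, subjects = subjects,
         bands = names(matrices), n_regions = n_regions,
         manifest = manifest),
    class = "fc_bundle")
}

#' @export
print.fc_bundle <- function(x, ...) {
  cat("<fc_bundle> ", length(x$subjects), " subjects, ",
      x$n_regions, " regions, bands: ",
      paste(x$bands, collapse = ", "), "\n", sep = "")
  invisible(x)
}

# subjects x edges matrix for one band, canonical edge order.
bundle_edge_matrix <- function(bundle, band) {
  a <- bundle$matrices[[band]]
  if (is.null(a)) stop("band '", band, "' not present in bundle")
  ut <- upper.tri(a[, , 1])
  t(apply(a, 3, function(m) m[ut]))
}

#' Write a connectivity bundle to a directory
#'
#' Each matrix is stored as a tab-delimited text file with 17 significant
#' digits (bit-exact decimal round trip for doubles), plus a
#' `manifest.json` listing subjects, bands and per-matrix files.
#'
#' @param bundle an [fc_bundle()].
#' @param dir output directory (created if absent).
#' @return the manifest path, invisibly.
#' @export
write_fc_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "fc_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- list()
  for (b in bundle$bands) {
    for (s in seq_along(bundle$subjects)) {
      fn <- sprintf("fc_%s_%s.tsv", b, bundle$subjects[s])
      m <- bundle$matrices[[b]][, , s]
      utils::write.table(format(m, digits = 17, scientific = TRUE,
                                trim = TRUE),
                         file.path(dir, fn), sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
      files[[paste(b, bundle$subjects[s], sep = "\r")]] <- fn
    }
  }
  manifest <- list(
    subjects = bundle$subjects,
    bands = bundle$bands,
    n_regions = bundle$n_regions,
    files = lapply(bundle$bands, function(b) {
      as.list(stats::setNames(
        vapply(bundle$subjects,
               function(s) files[[paste(b, s, sep = "\r")]], ""),
        bundle$subjects))
    }),
    provenance = bundle$manifest)
  names(manifest$files) <- bundle$bands
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a connectivity bundle written by [write_fc_bundle()]
#'
#' @param dir directory containing `manifest.json` and the matrix files.
#' @return an [fc_bundle()]; matrices reproduce the written values exactly.
#' @export
read_fc_bundle <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  subjects <- unlist(manifest$subjects)
  bands <- unlist(manifest$bands)
  n <- manifest$n_regions
  mats <- lapply(bands, function(b) {
    a <- array(0, c(n, n, length(subjects)))
    for (s in seq_along(subjects)) {
      fn <- file.path(dir, manifest$files[[b]][[subjects[s]]])
      if (!file.exists(fn)) {
        stop("bundle integrity error: missing matrix file ", fn)
      }
      a[, , s] <- as.matrix(utils::read.table(fn, sep = "\t"))
    }
    a
  })
  names(mats) <- bands
  fc_bundle(mats, subjects, manifest = manifest$provenance)
}
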