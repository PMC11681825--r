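#' Load a cortical parcellation atlas
#'
#' Reads the region metadata table used to label connectivity matrices. The
#' packaged default is the 68-region Desikan-Killiany gyral parcellation
#' (34 regions per hemisphere, FreeSurfer `aparc` order, left hemisphere
#' first). Each region carries a lobe assignment used for subnetwork
#' composition summaries; the six-lobe scheme (fronto-insular, sensorimotor,
#' limbic, temporal, parietal, occipital) is a package convention shipped as
#' a versioned data file.
#'
#' @param path path to a tab-delimited file with columns `index` (0-based),
#'   `name`, `hemisphere` (`left`/`right`), `lobe`; defaults to the packaged
#'   Desikan-Killiany table.
#' @return a data.frame of class `connstat_atlas` with one row per region,
#'   sorted by `index`.
#' @examples
#' atlas <- load_atlas()
#' nrow(atlas)                 # 68
#' table(atlas$hemisphere)     # 34 left, 34 right
#' @export
load_atlas <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "dk_atlas.tsv", package = "connstat")
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("index", "name", "hemisphere", "lobe")
  if (!all(req %in% names(df))) {
    stop("atlas file must have columns: ", paste(req, collapse = ", "))
  }
  df <- df[order(df$index), req]
  validate_atlas(df)
  class(df) <- c("connstat_atlas", "data.frame")
  df
}

valid_lobes <- c("fronto-insular", "sensorimotor", "limbic", "temporal",
                 "parietal", "occipital")

validate_atlas <- function(df) {
  if (nrow(df) != 68L) {
    stop("atlas must define exactly 68 regions, got ", nrow(df))
  }
  if (!identical(df$index, 0:67)) {
    stop("atlas indices must be 0..67 with no gaps")
  }
  if (anyDuplicated(df$name)) stop("atlas region names must be unique")
  bad_hemi <- setdiff(unique(df$hemisphere), c("left", "right"))
  if (length(bad_hemi)) stop("unknown hemisphere token: ", bad_hemi[1])
  if (any(table(df$hemisphere) != 34L)) {
    stop("atlas must have 34 regions per hemisphere")
  }
  bad_lobe <- setdiff(unique(df$lobe), valid_lobes)
  if (length(bad_lobe)) stop("unknown lobe token: ", bad_lobe[1])
  invisible(df)
}

#' Read a cohort covariate table
#'
#' Loads the per-subject table carrying group membership, model covariates
#' (age, disease duration, medication dose, most-affected side, BMI, ...)
#' and optional hormone columns, as used by the network statistics and
#' association stages.
#'
#' @param path CSV file with a header; must contain `subject_id` and `group`.
#' @param group_levels optional character vector fixing the order of group
#'   levels (the first level is the reference in design matrices); defaults
#'   to order of first appearance in the file.
#' @return a data.frame of class `connstat_cohort`; `group` is a factor.
#' @export
read_cohort <- function(path, group_levels = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_cohort(df, group_levels = group_levels)
}

#' Coerce a data.frame to a cohort table
#'
#' @param df data.frame with `subject_id` and `group` columns.
#' @inheritParams read_cohort
#' @return a `connstat_cohort` data.frame.
#' @export
as_cohort <- function(df, group_levels = NULL) {
  if (!all(c("subject_id", "group") %in% names(df))) {
    stop("cohort table must contain 'subject_id' and 'group' columns")
  }
  df$subject_id <- as.character(df$subject_id)
  if (anyDuplicated(df$subject_id)) {
    stop("duplicate subject_id in cohort table")
  }
  lv <- group_levels %||% unique(as.character(df$group))
  if (!all(as.character(df$group) %in% lv)) {
    stop("group_levels does not cover all observed groups")
  }
  df$group <- factor(as.character(df$group), levels = lv)
  if (nlevels(droplevels(df$group)) < 2L) {
    stop("cohort must contain at least 2 non-empty groups")
  }
  other <- setdiff(names(df), c("subject_id", "group", "sex"))
  for (cn in other) {
    if (!is.numeric(df[[cn]])) {
      v <- suppressWarnings(as.numeric(df[[cn]]))
      if (anyNA(v) && !all(is.na(df[[cn]]))) {
        stop("non-numeric value in covariate column '", cn, "'")
      }
      df[[cn]] <- v
    }
  }
  class(df) <- c("connstat_cohort", "data.frame")
  df
}
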