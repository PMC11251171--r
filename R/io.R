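#' @name forest-tables
#' @title Forest inventory table schemas
#' @description
#' The pipeline exchanges four delimited text tables with a required header
#' row (comma-delimited by default, tab accepted):
#' \describe{
#'   \item{plots}{\code{plot_id, ecoregion_id, slope, altitude, TS, PS,
#'     area_ha} — one row per 0.09-ha plot with topography and temperature /
#'     precipitation seasonality.}
#'   \item{stems}{\code{plot_id, subplot, species_id, dbh, height} — one row
#'     per measured stem; subplot in 1..9, DBH in cm, height in m.}
#'   \item{soil}{\code{plot_id, layer_index, top_cm, bottom_cm, gravel_frac,
#'     bulk_density, organic_c, thickness} — one row per sampled depth layer
#'     (gravel volume fraction in [0,1], bulk density g/cm^3, organic C
#'     g/kg, thickness cm).}
#'   \item{species}{\code{species_id, strategy, seral_status} plus the eight
#'     leaf traits Cmass, Nmass, Pmass, Kmass, LA, SLA, LMA, LDMC (possibly
#'     missing); strategy one of EcM, AM, dual, other.}
#' }
NULL

REQUIRED_COLS <- list(
  plots = c("plot_id", "ecoregion_id", "slope", "altitude", "TS", "PS"),
  stems = c("plot_id", "subplot", "species_id", "dbh", "height"),
  soil = c("plot_id", "layer_index", "top_cm", "bottom_cm", "gravel_frac",
           "bulk_density", "organic_c", "thickness"),
  species = c("species_id", "strategy", "seral_status")
)

check_columns <- function(df, table) {
  missing <- setdiff(REQUIRED_COLS[[table]], names(df))
  if (length(missing)) {
    stop(sprintf("schema error in '%s' table: missing column(s) %s",
                 table, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

#' Validate a forest-inventory dataset bundle
#'
#' Checks schemas, value ranges (positive DBH/height, subplot 1..9, gravel
#' fraction in [0,1], positive bulk density, non-negative organic C,
#' positive and ordered layer thicknesses), and referential integrity of
#' stem species against the species table.
#'
#' @param bundle list with data.frames \code{plots}, \code{stems},
#'   \code{soil}, \code{species}.
#' @return the bundle, invisibly; stops with a descriptive error on the
#'   first violated rule.
#' @export
validate_bundle <- function(bundle) {
  for (tb in names(REQUIRED_COLS)) {
    if (is.null(bundle[[tb]])) stop(sprintf("schema error: '%s' table absent", tb))
    check_columns(bundle[[tb]], tb)
  }
  st <- bundle$stems
  if (nrow(st)) {
    if (any(!is.finite(st$dbh)) || any(st$dbh <= 0))
      stop("validation error: stem dbh must be strictly positive")
    if (any(!is.finite(st$height)) || any(st$height <= 0))
      stop("validation error: stem height must be strictly positive")
    if (any(!(st$subplot %in% 1:9)))
      stop("validation error: subplot must be in 1..9")
    unknown <- setdiff(unique(st$species_id), bundle$species$species_id)
    if (length(unknown)) {
      stop(sprintf("referential-integrity error: species_id not in species table: %s",
                   paste(utils::head(unknown, 10), collapse = ", ")))
    }
  }
  sp <- bundle$species
  if (!all(sp$strategy %in% c("EcM", "AM", "dual", "other")))
    stop("validation error: strategy must be one of EcM, AM, dual, other")
  tr <- intersect(TRAIT_NAMES, names(sp))
  for (t in tr) {
    v <- sp[[t]]
    if (any(!is.na(v) & v <= 0))
      stop(sprintf("validation error: trait %s has non-positive values", t))
  }
  so <- bundle$soil
  if (nrow(so)) {
    if (any(so$gravel_frac < 0 | so$gravel_frac > 1))
      stop("validation error: gravel_frac outside [0, 1]")
    if (any(so$bulk_density <= 0))
      stop("validation error: bulk_density must be positive")
    if (any(so$organic_c < 0))
      stop("validation error: organic_c must be non-negative")
    if (any(abs(so$thickness - (so$bottom_cm - so$top_cm)) > 1e-8) ||
        any(so$thickness <= 0))
      stop("validation error: thickness must equal bottom_cm - top_cm and be positive")
    # per plot: layers ordered and non-overlapping
    bad <- vapply(split(so, so$plot_id), function(d) {
      d <- d[order(d$top_cm), ]
      any(d$top_cm[-1] < d$bottom_cm[-nrow(d)] - 1e-8)
    }, logical(1))
    if (any(bad))
      stop(sprintf("validation error: overlapping soil layers in plot(s) %s",
                   paste(names(bad)[bad], collapse = ", ")))
  }
  if (!is.null(bundle$plots$area_ha) && any(bundle$plots$area_ha <= 0))
    stop("validation error: area_ha must be positive")
  invisible(bundle)
}

#' Read a forest-inventory dataset bundle from delimited files
#'
#' @param paths named character vector or list with entries \code{plots},
#'   \code{stems}, \code{soil}, \code{species} (file paths), or a single
#'   directory containing \code{plots.csv}, \code{stems.csv},
#'   \code{soil.csv}, \code{species.csv}.
#' @param sep field delimiter ("," default; "\\t" accepted).
#' @return validated bundle (list of data.frames).
#' @export
read_forest_tables <- function(paths, sep = ",") {
  if (length(paths) == 1 && is.character(paths) && dir.exists(paths)) {
    paths <- file.path(paths, paste0(names(REQUIRED_COLS), ".csv"))
    names(paths) <- names(REQUIRED_COLS)
  }
  bundle <- lapply(paths[names(REQUIRED_COLS)], function(p) {
    if (!file.exists(p)) stop(sprintf("file not found: %s", p))
    read.csv(p, sep = sep, stringsAsFactors = FALSE)
  })
  names(bundle) <- names(REQUIRED_COLS)
  validate_bundle(bundle)
  bundle
}

#' Write a forest-inventory dataset bundle to a directory
#'
#' Writes \code{plots.csv}, \code{stems.csv}, \code{soil.csv},
#' \code{species.csv}, and (when present in the bundle) \code{truth.json}
#' with the generator's ground truth.
#'
#' @param bundle dataset bundle (see \code{\link{read_forest_tables}}).
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_forest_tables <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (tb in names(REQUIRED_COLS)) {
    write.csv(bundle[[tb]], file.path(dir, paste0(tb, ".csv")),
              row.names = FALSE)
  }
  if (!is.null(bundle$truth)) {
    jsonlite::write_json(bundle$truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Apply the minimum-DBH stem inclusion filter
#'
#' Retains stems with DBH at or above the threshold (3 cm by default, the
#' standard inventory inclusion rule) and reports the number removed.
#'
#' @param stems stems data.frame.
#' @param min_dbh inclusion threshold in cm.
#' @param quiet suppress the removal message.
#' @return filtered stems.
#' @export
apply_stem_filter <- function(stems, min_dbh = 3, quiet = FALSE) {
  keep <- stems$dbh >= min_dbh
  if (!quiet) {
    message(sprintf("stem filter: removed %d of %d stems below %.4g cm DBH",
                    sum(!keep), length(keep), min_dbh))
  }
  stems[keep, , drop = FALSE]
}

#' Exclude rare mycorrhizal strategies from dominance calculations
#'
#' Returns the stems whose species carry an EcM, AM, or dual strategy;
#' ericoid/non-mycorrhizal ("other") species are excluded from the
#' dominance numerator and denominator. By default they still count toward
#' tree carbon and richness elsewhere in the pipeline.
#'
#' @param stems stems data.frame.
#' @param species species table with \code{strategy}.
#' @param quiet suppress the removal message.
#' @return stems of EcM/AM/dual species; warns if nothing remains.
#' @export
apply_strategy_exclusion <- function(stems, species, quiet = FALSE) {
  strat <- species$strategy[match(stems$species_id, species$species_id)]
  keep <- strat %in% c("EcM", "AM", "dual")
  if (!quiet) {
    message(sprintf("strategy exclusion: removed %d of %d stems of 'other'-strategy species",
                    sum(!keep), length(keep)))
  }
  out <- stems[keep, , drop = FALSE]
  if (nrow(stems) > 0 && nrow(out) == 0) {
    warning("all stems carry excluded strategies; mycorrhizal dominance is undefined")
  }
  out
}
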