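#' Write a dose grid as flat text plus a JSON sidecar
#'
#' Serialises a `dose_grid` to `<prefix>.dat` (one dose value per line,
#' column-major voxel order, with a second column of relative uncertainties
#' when present) and `<prefix>.json` (shape, spacing, origin, history count,
#' seed, scoring mode, source pose). The same simple declared format can
#' carry an externally computed grid — e.g. a treatment-planning-system
#' export converted by the user — into the comparison stage.
#'
#' @param grid a `dose_grid`.
#' @param prefix output path prefix (directories must exist).
#' @return The two file paths, invisibly.
#' @export
write_dose_grid <- function(grid, prefix) {
  stopifnot(inherits(grid, "dose_grid"))
  dat <- paste0(prefix, ".dat")
  side <- paste0(prefix, ".json")
  tab <- data.frame(dose = as.numeric(grid$dose))
  if (!is.null(grid$rel_unc)) tab$rel_unc <- as.numeric(grid$rel_unc)
  utils::write.table(format(tab, digits = 17, scientific = TRUE,
                            trim = TRUE),
                     dat, row.names = FALSE, col.names = TRUE,
                     quote = FALSE)
  meta <- list(shape = dim(grid$dose), spacing_mm = grid$spacing_mm,
               origin_cm = grid$origin_cm,
               source_center_cm = grid$source_center_cm,
               source_axis = grid$source_axis,
               n_histories = grid$n_histories, seed = grid$seed,
               scoring = grid$scoring)
  jsonlite::write_json(meta, side, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(dat, side))
}

#' Read a dose grid written by [write_dose_grid()]
#'
#' @param prefix path prefix of the `.dat`/`.json` pair.
#' @return A `dose_grid`.
#' @export
read_dose_grid <- function(prefix) {
  dat <- paste0(prefix, ".dat")
  side <- paste0(prefix, ".json")
  if (!file.exists(dat) || !file.exists(side))
    stop("expected ", dat, " and ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  tab <- utils::read.table(dat, header = TRUE)
  dm <- as.integer(meta$shape)
  if (nrow(tab) != prod(dm))
    stop("grid file holds ", nrow(tab), " voxels; sidecar declares ",
         prod(dm))
  structure(list(
    dose = array(tab$dose, dm),
    rel_unc = if ("rel_unc" %in% names(tab)) array(tab$rel_unc, dm)
              else array(NA_real_, dm),
    n_histories = meta$n_histories,
    scoring = meta$scoring,
    seed = meta$seed,
    spacing_mm = as.numeric(meta$spacing_mm),
    origin_cm = as.numeric(meta$origin_cm),
    source_center_cm = as.numeric(meta$source_center_cm),
    source_axis = meta$source_axis,
    energy_mev = NULL
  ), class = "dose_grid")
}

#' Export a voxel phantom as an integer raster with a JSON legend
#'
#' Writes `<prefix>.dat` (one 1-based material index per line, column-major
#' order) and `<prefix>.json` (shape, spacing, origin and the index ->
#' material-name legend).
#'
#' @param phantom a [voxel_phantom()].
#' @param prefix output path prefix.
#' @return The two file paths, invisibly.
#' @export
write_phantom <- function(phantom, prefix) {
  stopifnot(inherits(phantom, "voxel_phantom"))
  dat <- paste0(prefix, ".dat")
  side <- paste0(prefix, ".json")
  writeLines(as.character(as.integer(phantom$material_index)), dat)
  meta <- list(shape = dim(phantom$material_index),
               spacing_mm = phantom$spacing_mm,
               origin_cm = phantom$origin_cm,
               materials = phantom$materials)
  jsonlite::write_json(meta, side, auto_unbox = TRUE, digits = NA)
  invisible(c(dat, side))
}
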