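#' Load a photon emission spectrum
#'
#' Reads a discrete photon line spectrum (energies in MeV, intensities in
#' photons per decay). The bundled `"ir192"` spectrum is a compilation of the
#' evaluated Ir-192 decay radiation (gamma lines plus Pt/Os K and L X-rays)
#' spanning 7.82 keV to 1.378 MeV with an intensity-weighted mean energy of
#' about 0.35 MeV. Lines at or below `energy_cut` (default 10 keV, matching
#' the transport cut) are retained but flagged `below_cut`; the transport
#' engine drops them at sampling time while still counting them as histories.
#'
#' @param source `"ir192"` (alias `"ir192-nndc"`) for the bundled spectrum, or
#'   a path to a two-column text table (MeV, photons/decay; whitespace or
#'   comma separated; `#` comments).
#' @param energy_cut source-side cut in MeV used only to flag lines.
#' @return A `photon_spectrum`: data frame with columns `energy`, `intensity`,
#'   `below_cut`, ordered by strictly increasing energy, with attributes
#'   `total_intensity`, `total_intensity_above_cut`, `mean_energy` (intensity
#'   weighted) and `energy_cut`.
#' @examples
#' sp <- load_spectrum()
#' range(sp$energy)
#' attr(sp, "mean_energy")
#' @export
load_spectrum <- function(source = "ir192", energy_cut = 0.010) {
  if (source %in% c("ir192", "ir192-nndc")) {
    path <- system.file("extdata", "ir192_lines.csv", package = "brachymc",
                        mustWork = TRUE)
  } else {
    path <- source
    if (!file.exists(path)) stop("spectrum file not found: ", path)
  }
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  rows <- which(keep)
  txt <- lines[keep]
  sep <- if (any(grepl(",", txt))) "," else ""
  tab <- tryCatch(
    read.table(text = txt, sep = sep, header = FALSE,
               colClasses = "numeric", strip.white = TRUE),
    error = function(e) stop("malformed spectrum table: ", conditionMessage(e))
  )
  if (ncol(tab) != 2L)
    stop("spectrum table must have exactly two columns (MeV, intensity)")
  energy <- tab[[1L]]
  intensity <- tab[[2L]]
  bad <- which(!is.finite(energy) | !is.finite(intensity))
  if (length(bad))
    stop("non-numeric spectrum entry at table row ", bad[1L])
  bad <- which(intensity <= 0)
  if (length(bad))
    stop("non-positive intensity at table row ", bad[1L],
         " (file line ", rows[bad[1L]], ")")
  bad <- which(energy <= 0 | energy > 1.4)
  if (length(bad))
    stop("photon energy outside (0, 1.4] MeV at table row ", bad[1L],
         " (file line ", rows[bad[1L]], ")")
  o <- order(energy)
  energy <- energy[o]
  intensity <- intensity[o]
  if (anyDuplicated(energy))
    stop("duplicate line energy in spectrum: ",
         energy[duplicated(energy)][1L], " MeV")
  spec <- data.frame(energy = energy, intensity = intensity,
                     below_cut = energy < energy_cut)
  structure(spec,
            class = c("photon_spectrum", "data.frame"),
            total_intensity = sum(intensity),
            total_intensity_above_cut = sum(intensity[!spec$below_cut]),
            mean_energy = sum(energy * intensity) / sum(intensity),
            energy_cut = energy_cut)
}

#' @export
print.photon_spectrum <- function(x, ...) {
  cat(sprintf(
    "photon spectrum: %d lines, %.4f-%.4f MeV\n", nrow(x),
    min(x$energy), max(x$energy)))
  cat(sprintf("  total intensity      %.4f photons/decay\n",
              attr(x, "total_intensity")))
  cat(sprintf("  above %.0f keV cut     %.4f photons/decay (%d lines flagged below)\n",
              attr(x, "energy_cut") * 1e3,
              attr(x, "total_intensity_above_cut"), sum(x$below_cut)))
  cat(sprintf("  mean energy          %.4f MeV\n", attr(x, "mean_energy")))
  invisible(x)
}

# coerce a bare energy (MeV) into a one-line spectrum for monoenergetic runs
.as_spectrum <- function(x) {
  if (inherits(x, "photon_spectrum")) return(x)
  if (is.numeric(x) && length(x) == 1L && x > 0 && x <= 1.4) {
    sp <- data.frame(energy = x, intensity = 1, below_cut = FALSE)
    return(structure(sp, class = c("photon_spectrum", "data.frame"),
                     total_intensity = 1, total_intensity_above_cut = 1,
                     mean_energy = x, energy_cut = 0.010))
  }
  stop("expected a photon_spectrum or a single photon energy in (0, 1.4] MeV")
}
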