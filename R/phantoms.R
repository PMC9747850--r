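#' Slab phantom specifications
#'
#' The six interchangeable-slab phantom configurations used for the dose
#' comparison study: two 101 mm backscatter slabs (BS1, BS2) sandwiching
#' three 11 mm slabs (medium 1, source slab, medium 2), all 101 x 101 mm
#' laterally; phantom 6 omits BS2. The source sits at the centre of the
#' source slab with its long axis parallel to the slab plane.
#'
#' @param id phantom id, 1 to 6.
#' @return A `phantom_spec` list with a `slabs` data frame (`name`,
#'   `material`, `thickness_mm`) and `lateral_mm`.
#' @examples
#' phantom_spec(1)$slabs$material
#' @export
phantom_spec <- function(id) {
  mats <- switch(as.character(id),
    "1" = c("water", "peek", "water", "air", "water"),
    "2" = c("water", "cartilage", "water", "bone", "water"),
    "3" = c("water", "titanium", "water", "lung", "water"),
    "4" = c("water", "adipose", "water", "muscle", "water"),
    "5" = c("water", "water", "stainless_steel", "water", "water"),
    "6" = c("water", "water", "pmma", "water"),
    stop("unknown phantom id: ", id))
  names <- c("BS1", "M1", "SS", "M2", "BS2")[seq_along(mats)]
  thick <- c(101, 11, 11, 11, 101)[seq_along(mats)]
  structure(list(id = id,
                 slabs = data.frame(name = names, material = mats,
                                    thickness_mm = thick),
                 lateral_mm = 101),
            class = "phantom_spec")
}

#' Build a voxelized slab phantom
#'
#' Voxelizes one of the six slab configurations at 1 mm resolution, stacking
#' slabs along z (235 voxels for ids 1-5, 134 for id 6; 101 x 101 laterally)
#' with half-open voxel boundaries so every slab maps to a whole voxel
#' count. The encapsulated source is carved into the source-slab voxels by
#' sub-voxel supersampling (majority material over `subsamples`^3 points per
#' candidate voxel), its long axis along x through the slab centre.
#'
#' @param id phantom id, 1 to 6.
#' @param carve_source carve the source hardware into the grid
#'   (default TRUE).
#' @param geometry source geometry used for carving.
#' @param subsamples sub-voxel sampling rate per axis (default 10, i.e.
#'   1000 points per voxel).
#' @return A [voxel_phantom()] with attributes `source_center_cm`,
#'   `source_axis`, `phantom_id` and `spec`.
#' @examples
#' ph <- build_slab_phantom(6, carve_source = FALSE)
#' dim(ph$material_index)   # 101 101 134
#' @export
build_slab_phantom <- function(id, carve_source = TRUE,
                               geometry = gmp_source(), subsamples = 10) {
  spec <- phantom_spec(id)
  nz <- sum(spec$slabs$thickness_mm)
  nx <- ny <- spec$lateral_mm
  slab_of_z <- rep(seq_len(nrow(spec$slabs)), spec$slabs$thickness_mm)
  mats <- unique(c(spec$slabs$material, geometry$core_material,
                   geometry$cavity_material, geometry$capsule_material,
                   geometry$wire_material))
  idx <- array(0L, c(nx, ny, nz))
  for (iz in seq_len(nz))
    idx[, , iz] <- match(spec$slabs$material[slab_of_z[iz]], mats)

  # source centred in the source slab, axis along x
  ss_rows <- which(spec$slabs$name == "SS")
  z0 <- sum(spec$slabs$thickness_mm[seq_len(ss_rows - 1)])
  center <- c(nx / 2, ny / 2, z0 + spec$slabs$thickness_mm[ss_rows] / 2) / 10

  if (carve_source) {
    gp <- .source_geom_params(geometry)
    src_mats <- c(geometry$core_material, geometry$cavity_material,
                  geometry$capsule_material, geometry$wire_material)
    # candidate voxels: bounding box of the hardware (local z along x)
    zlo <- gp[["z_wire_bot"]]
    zhi <- gp[["z_cav"]] + gp[["tip_h"]]
    rout <- gp[["r_out"]]
    xr <- floor((center[1] + zlo) * 10):ceiling((center[1] + zhi) * 10 - 1e-9)
    yr <- floor((center[2] - rout) * 10):ceiling((center[2] + rout) * 10)
    zr <- floor((center[3] - rout) * 10):ceiling((center[3] + rout) * 10)
    xr <- xr[xr >= 0 & xr < nx]
    yr <- yr[yr >= 0 & yr < ny]
    zr <- zr[zr >= 0 & zr < nz]
    off <- (seq_len(subsamples) - 0.5) / subsamples / 10  # cm within voxel
    sub <- expand.grid(dx = off, dy = off, dz = off)
    for (ix in xr) for (iy in yr) for (iz in zr) {
      # local source frame: lz along +x, (lx, ly) in the (y, z) plane
      lz <- ix / 10 + sub$dx - center[1]
      lx <- iy / 10 + sub$dy - center[2]
      ly <- iz / 10 + sub$dz - center[3]
      reg <- .source_region(lx, ly, lz, gp)
      counts <- tabulate(reg + 1L, nbins = 5L)
      # a voxel becomes hardware when the hardware occupies at least half
      # of it, taking the dominant hardware region; sub-voxel hardware
      # slivers below that leave the slab material in place
      if (sum(counts[1:4]) >= length(reg) / 2) {
        win <- which.max(counts[1:4])
        idx[ix + 1L, iy + 1L, iz + 1L] <- match(src_mats[win], mats)
      }
    }
  }
  ph <- voxel_phantom(idx, mats, spacing_mm = c(1, 1, 1),
                      origin_cm = c(0, 0, 0))
  attr(ph, "source_center_cm") <- center
  attr(ph, "source_axis") <- "x"
  attr(ph, "phantom_id") <- id
  attr(ph, "spec") <- spec
  ph
}

# vectorised region classifier in the source local frame (see the C++
# tracker for the authoritative surface definitions)
.source_region <- function(x, y, z, gp) {
  rho2 <- x^2 + y^2
  reg <- rep(4L, length(x))
  slope <- (gp[["r_out"]] - gp[["r_tip"]]) / gp[["tip_h"]]
  z_tip <- gp[["z_cav"]] + gp[["tip_h"]]
  rtip <- pmax(gp[["r_out"]] - slope * (z - gp[["z_cav"]]), 0)
  in_wire <- z >= gp[["z_wire_bot"]] & z < gp[["z_cap_bot"]] &
    rho2 <= gp[["r_out"]]^2
  in_caps <- (z >= gp[["z_cap_bot"]] & z <= gp[["z_cav"]] &
                rho2 <= gp[["r_out"]]^2) |
    (z > gp[["z_cav"]] & z <= z_tip & rho2 <= rtip^2)
  in_cav <- abs(z) <= gp[["z_cav"]] & rho2 <= gp[["r_cav"]]^2
  in_core <- abs(z) <= gp[["z_core"]] & rho2 <= gp[["r_core"]]^2
  reg[in_wire] <- 3L
  reg[in_caps] <- 2L
  reg[in_cav] <- 1L
  reg[in_core] <- 0L
  reg
}
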