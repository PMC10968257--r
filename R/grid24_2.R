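#' The 24-2 test-point grid (blind spot removed)
#'
#' Enumerates the 52 visual-field test locations used throughout the package.
#' The full 24-2 pattern has 54 points; the two locations falling on the optic
#' nerve head (the blind spot, at (15, +/-3) degrees in right-eye orientation)
#' carry no usable sensitivity and are dropped at read time.
#'
#' Coordinates are degrees of visual angle in right-eye orientation:
#' positive x is the temporal field, negative x nasal, positive y superior.
#' Left-eye data must be mirrored (x -> -x) before entering the pipeline so a
#' single spatial convention holds internally. Points are enumerated row-major
#' from the superior row downwards, left to right, matching the order of the
#' `dls_00 .. dls_51` cohort columns.
#'
#' @return A data.frame with 52 rows and columns `index` (0-based), `x`, `y`
#'   (degrees), `ecc` (eccentricity, degrees) and `rim` (logical; TRUE for the
#'   peripheral ring of points susceptible to trial-lens-rim artifacts).
#' @export
#' @examples
#' g <- vf_grid_24_2()
#' nrow(g)  # 52
vf_grid_24_2 <- function() {
  .vf_grid_cache
}

# row-major enumeration of the full 54-point pattern, superior row first
.build_grid <- function() {
  rows <- list(
    c(21, -9, 9), c(15, -15, 15), c(9, -21, 21), c(3, -27, 21),
    c(-3, -27, 21), c(-9, -21, 21), c(-15, -15, 15), c(-21, -9, 9)
  )
  pts <- do.call(rbind, lapply(rows, function(r) {
    x <- seq(r[2], r[3], by = 6)
    cbind(x = x, y = r[1])
  }))
  pts <- as.data.frame(pts)
  blind <- pts$x == 15 & abs(pts$y) == 3
  pts$full_index <- seq_len(nrow(pts)) - 1L
  pts <- pts[!blind, , drop = FALSE]
  pts$index <- seq_len(nrow(pts)) - 1L
  pts$ecc <- sqrt(pts$x^2 + pts$y^2)
  pts$rim <- pts$ecc > 20.5
  rownames(pts) <- NULL
  pts[, c("index", "x", "y", "ecc", "rim", "full_index")]
}

#' Indices of the blind-spot points in a 54-point 24-2 export
#'
#' @return Integer vector (0-based indices into the 54-point row-major
#'   enumeration) of the two optic-nerve-head locations.
#' @export
blind_spot_indices_54 <- function() c(25L, 34L)

#' Structure-function map from 24-2 locations to optic-nerve-head sectors
#'
#' A Garway-Heath-style correspondence between visual-field test points and
#' six angular sectors of the peripapillary circle. Angles are measured from
#' the temporal reference (0 degrees), counter-clockwise for right eyes, so 90
#' degrees is superior, 180 nasal and 270 inferior. Superior field locations
#' map to the inferior disc sectors and vice versa; the central
#' (papillomacular) points map to the temporal sector and the far temporal
#' field to the nasal sector.
#'
#' The assignment is shipped as data (one row per 24-2 location) so users can
#' substitute their own map.
#'
#' @return A data.frame with columns `index` (0-based 24-2 index), `sector`
#'   (factor with levels `T`, `ST`, `SN`, `N`, `IN`, `IT`), `angle_lo`,
#'   `angle_hi` (degrees, the sector's angular interval, half-open).
#' @export
#' @examples
#' m <- onh_sector_map()
#' table(m$sector)
onh_sector_map <- function() {
  .sector_map_cache
}

.sector_bands <- function() {
  data.frame(
    sector   = c("T", "ST", "SN", "N", "IN", "IT"),
    angle_lo = c(315, 45, 90, 135, 180, 225),
    angle_hi = c(45, 90, 135, 180, 225, 315),
    stringsAsFactors = FALSE
  )
}

.build_sector_map <- function() {
  g <- .build_grid()
  sec <- character(nrow(g))
  for (i in seq_len(nrow(g))) {
    x <- g$x[i]; y <- g$y[i]
    if (abs(y) <= 3 && abs(x) <= 9) {
      sec[i] <- "T"                       # papillomacular bundle
    } else if (x >= 15 && abs(y) <= 9) {
      sec[i] <- "N"                       # far temporal field -> nasal disc
    } else if (y > 0) {
      # superior field -> inferior disc; peripheral nasal edge -> inferonasal
      edge <- (y == 3 && x == -27) || (y == 9 && x == -21) ||
        (y == 15 && x == -15) || (y == 21 && x == -9)
      sec[i] <- if (edge) "IN" else "IT"
    } else {
      edge <- (y == -3 && x == -27) || (y == -9 && x == -21) ||
        (y == -15 && x == -15) || (y == -21 && x == -9)
      sec[i] <- if (edge) "SN" else "ST"
    }
  }
  bands <- .sector_bands()
  out <- data.frame(index = g$index, sector = factor(sec, levels = bands$sector))
  out$angle_lo <- bands$angle_lo[match(sec, bands$sector)]
  out$angle_hi <- bands$angle_hi[match(sec, bands$sector)]
  out
}

#' Map an RNFL profile angular position to its sector
#'
#' @param angle Numeric vector of angles in degrees (0 = temporal reference,
#'   counter-clockwise for right eyes).
#' @return Factor of sector labels, same levels as [onh_sector_map()].
#' @export
sector_of_angle <- function(angle) {
  a <- angle %% 360
  bands <- .sector_bands()
  out <- rep(NA_character_, length(a))
  for (i in seq_len(nrow(bands))) {
    lo <- bands$angle_lo[i]; hi <- bands$angle_hi[i]
    hit <- if (lo < hi) a >= lo & a < hi else a >= lo | a < hi
    out[hit] <- bands$sector[i]
  }
  factor(out, levels = bands$sector)
}

#' Sector assignment for each of the 256 RNFL profile samples
#'
#' Sample i of the profile sits at angle 360 * i / 256 degrees (i = 0..255),
#' angle 0 at the temporal reference, counter-clockwise for right eyes.
#'
#' @return Factor of length 256.
#' @export
rnfl_profile_sectors <- function() {
  sector_of_angle(360 * (0:255) / 256)
}

#' Age-corrected normal sensitivity for the 24-2 grid
#'
#' A smooth normative surface used by the synthetic cohort and by the mean
#' deviation computation: sensitivity falls linearly with age and with
#' eccentricity. It is a synthetic stand-in for a device normative database
#' (which is proprietary), chosen so values lie in the clinically familiar
#' 28-33 dB range for adults.
#'
#' @param age Age in years (scalar or vector of length 1).
#' @return Numeric vector of 52 normal differential light sensitivities (dB),
#'   ordered by the grid enumeration of [vf_grid_24_2()].
#' @export
normative_dls <- function(age) {
  stopifnot(length(age) == 1, is.finite(age), age > 0)
  g <- vf_grid_24_2()
  34 - 0.08 * (age - 45) - 0.10 * g$ecc
}

.vf_grid_cache <- .build_grid()
.sector_map_cache <- .build_sector_map()
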