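# Core (phi, psi) -> R codec.
#
# The Ramachandran plot, with both axes on [-lambda/2, lambda/2) and
# lambda = 360 degrees, is rotated clockwise by 45 degrees, shifted so both
# new coordinates are non-negative, and rescaled by the grid resolution
# sigma (reciprocal degrees):
#
#   phi' = round((phi - psi + lambda) * sigma / sqrt(2))
#   psi' = round((phi + psi + lambda) * sigma / sqrt(2))
#
# Raster-indexing the rotated grid row by row gives the integer
# Ramachandran number
#
#   rz = phi' + lambda' * psi',   lambda' = round(sqrt(2) * lambda * sigma)
#
# which runs over [rz_min, rz_max) with rz_min = rz(-180, -180) =
# round(lambda * sigma / sqrt(2)) and rz_max = rz_min + lambda'^2.  The
# normalized number r = (rz - rz_min) / (rz_max - rz_min) lies in [0, 1).
#
# Note on the sqrt(2): a true 45-degree rotation scales coordinates by
# 1/sqrt(2), and only this reading makes rz_max - rz_min = lambda'^2 hold
# (psi' at the (180,180) corner must equal lambda').
#
# All rounded quantities are non-negative, so round-half-away-from-zero
# equals round-half-up, implemented as floor(x + 0.5).  rz reaches ~2.6e15
# at sigma = 1e5; doubles represent integers exactly below 2^53, but
# `%/%`/`%%` on such doubles can slip by one at exact multiples, hence the
# corrected .div_mod() below.

.round_half_up <- function(x) floor(x + 0.5)

# exact floor division + non-negative remainder for integer-valued doubles
.div_mod <- function(x, y) {
  q <- floor(x / y)
  r <- x - q * y
  hi <- r >= y
  q[hi] <- q[hi] + 1; r[hi] <- r[hi] - y
  lo <- r < 0
  q[lo] <- q[lo] - 1; r[lo] <- r[lo] + y
  list(q = q, r = r)
}

#' Wrap angles into the canonical dihedral domain
#'
#' Maps angles in degrees into `[-180, 180)`; in particular `+180` wraps to
#' `-180` (the domain is half-open at the top).
#'
#' @param theta Numeric vector of angles in degrees. `NA` is passed through;
#'   non-finite values (`Inf`, `NaN`) are an error.
#' @return Numeric vector of the same length, each value in `[-180, 180)`
#'   and congruent to the input modulo 360.
#' @examples
#' wrap_angle(c(180, 370, -45))  # -180, 10, -45
#' @export
wrap_angle <- function(theta) {
  if (is.logical(theta) && all(is.na(theta))) theta <- as.numeric(theta)
  if (!is.numeric(theta)) stop("`theta` must be numeric")
  bad <- !is.na(theta) & !is.finite(theta)
  if (any(bad)) stop("`theta` contains non-finite values")
  ((theta + 180) %% 360) - 180
}

#' Construct the codec grid for a resolution sigma
#'
#' Derives the raster parameters (stride `lam_prime`, index range
#' `rz_min`..`rz_max`) from the grid resolution `sigma` alone; they are
#' never set independently.
#'
#' @param sigma Grid resolution in reciprocal degrees (> 0). The default
#'   `1e5` makes the back-mapping error (at most `1/sigma` degrees per
#'   angle) far below the coordinate uncertainty of deposited structures.
#' @return An object of class `rama_grid`: a list with elements `sigma`,
#'   `lam` (360), `lam_prime`, `rz_min`, `rz_max`.
#' @examples
#' g <- make_grid(1)
#' g$lam_prime  # 509
#' @export
make_grid <- function(sigma = 1e5) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0)
    stop("`sigma` must be a single positive number (reciprocal degrees)")
  lam <- 360
  lam_prime <- .round_half_up(sqrt(2) * lam * sigma)
  rz_min <- .round_half_up(lam * sigma / sqrt(2))
  rz_max <- rz_min + lam_prime^2
  if (rz_max >= 2^53)
    stop("`sigma` too large: rz would exceed exact double-precision integers")
  structure(list(sigma = sigma, lam = lam, lam_prime = lam_prime,
                 rz_min = rz_min, rz_max = rz_max),
            class = "rama_grid")
}

#' @export
print.rama_grid <- function(x, ...) {
  cat(sprintf(
    "Ramachandran codec grid: sigma = %g /deg, lam' = %.0f, rz in [%.0f, %.0f)\n",
    x$sigma, x$lam_prime, x$rz_min, x$rz_max))
  invisible(x)
}

.as_grid <- function(grid) {
  if (inherits(grid, "rama_grid")) grid else make_grid(grid)
}

#' Rotate dihedral pairs onto the codec grid
#'
#' The 45-degree clockwise rotation + shift + rescale, returning the
#' integer grid indices `(phi_prime, psi_prime)`.
#'
#' @param phi,psi Numeric vectors of dihedral angles in degrees
#'   (canonicalized into `[-180, 180)` internally).
#' @param grid A `rama_grid`, or a sigma value passed to [make_grid()].
#' @return A data frame with integer-valued columns `phi_prime`,
#'   `psi_prime` (stored as doubles; exact).
#' @export
rotate_to_grid <- function(phi, psi, grid = make_grid()) {
  g <- .as_grid(grid)
  phi <- wrap_angle(phi); psi <- wrap_angle(psi)
  s <- g$sigma / sqrt(2)
  data.frame(phi_prime = .round_half_up((phi - psi + g$lam) * s),
             psi_prime = .round_half_up((phi + psi + g$lam) * s))
}

#' Encode dihedral angles as Ramachandran numbers
#'
#' Forward map `(phi, psi) -> rz -> r`. `rz` is the exact integer raster
#' index; `r = (rz - rz_min)/(rz_max - rz_min)` is the normalized
#' Ramachandran number in `[0, 1)` for canonical inputs.
#'
#' @inheritParams rotate_to_grid
#' @return A data frame with columns `rz` (exact integer-valued double)
#'   and `r`. `NA` angles give `NA` rows. The grid is attached as
#'   attribute `"grid"`.
#' @examples
#' encode_rz(-180, -180)$r   # 0: the lower corner of the domain
#' encode_rz(-63, -43)$r     # ~0.353: the alpha-helical region
#' @seealso [decode_dihedrals()] for the inverse, [rama_number()] for a
#'   vector of `r` only.
#' @export
encode_rz <- function(phi, psi, grid = make_grid()) {
  g <- .as_grid(grid)
  rot <- rotate_to_grid(phi, psi, g)
  rz <- rot$phi_prime + g$lam_prime * rot$psi_prime
  out <- data.frame(rz = rz, r = (rz - g$rz_min) / (g$rz_max - g$rz_min))
  attr(out, "grid") <- g
  out
}

#' Normalized Ramachandran number
#'
#' Convenience wrapper around [encode_rz()] returning only the normalized
#' value `r`.
#'
#' @inheritParams rotate_to_grid
#' @return Numeric vector of `r` values in `[0, 1)` (`NA` where an input
#'   angle is `NA`).
#' @export
rama_number <- function(phi, psi, grid = make_grid()) {
  encode_rz(phi, psi, grid)$r
}

#' Recover approximate dihedral angles from a Ramachandran number
#'
#' Inverse raster map: `phi_prime ~ rz %% lam_prime`,
#' `psi_prime ~ rz %/% lam_prime` (floor division, non-negative
#' remainder), then the rotation is undone:
#' `phi = (psi_prime + phi_prime)/(sqrt(2) sigma) - lambda`,
#' `psi = (psi_prime - phi_prime)/(sqrt(2) sigma)`.
#' Each recovered angle is within `1/sigma` degrees of the original for
#' canonical inputs (away from the extreme raster corner).
#'
#' @param rz Integer-valued numeric vector of Ramachandran indices, or a
#'   data frame with an `rz` column as returned by [encode_rz()].
#' @param grid A `rama_grid`, or a sigma value passed to [make_grid()].
#' @return A data frame with columns `phi`, `psi` (degrees).
#' @export
decode_dihedrals <- function(rz, grid = make_grid()) {
  g <- .as_grid(grid)
  if (is.data.frame(rz)) rz <- rz$rz
  ok <- !is.na(rz)
  if (any(rz[ok] < g$rz_min | rz[ok] > g$rz_max))
    stop(sprintf("rz outside [%.0f, %.0f]", g$rz_min, g$rz_max))
  dm <- .div_mod(rz, g$lam_prime)
  s <- sqrt(2) * g$sigma
  data.frame(phi = (dm$q + dm$r) / s - g$lam,
             psi = (dm$q - dm$r) / s)
}

#' Sense of local backbone twist
#'
#' Residues below the negative-sloping diagonal of the Ramachandran plot
#' (`phi + psi < 0`) have a right-handed ("D") local twist; those above
#' (`phi + psi > 0`) are left-handed ("L"); points exactly on the diagonal
#' are "boundary" (the twist-free line, r = 0.5).
#'
#' @inheritParams rotate_to_grid
#' @return Character vector in `{"D", "L", "boundary"}` (`NA` propagated).
#' @export
twist_sense <- function(phi, psi) {
  s <- wrap_angle(phi) + wrap_angle(psi)
  out <- ifelse(s < 0, "D", ifelse(s > 0, "L", "boundary"))
  out
}
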