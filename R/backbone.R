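# Deterministic internal-coordinate (NeRF-style) backbone construction.
# Only the N, CA, C backbone atoms are built (glycine model): phi/psi/omega
# and the end-to-end / gyration statistics depend on nothing else.

#' Ideal backbone geometry parameters
#'
#' Bond lengths (Angstrom), bond angles (degrees) and the default peptide
#' bond dihedral omega used by [build_chain()]. Defaults are standard
#' ideal-geometry values (Engh-Huber type); the package's results are not
#' sensitive to the exact choice.
#'
#' @param b_n_ca,b_ca_c,b_c_n Bond lengths N-CA, CA-C and C-N in Angstrom.
#' @param a_n_ca_c,a_ca_c_n,a_c_n_ca Backbone bond angles in degrees.
#' @param omega Default peptide-bond dihedral in degrees (180 = trans).
#' @return A list of class `geometry_params`.
#' @export
geometry_params <- function(b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329,
                            a_n_ca_c = 111.2, a_ca_c_n = 116.6,
                            a_c_n_ca = 121.9, omega = 180) {
  p <- list(b_n_ca = b_n_ca, b_ca_c = b_ca_c, b_c_n = b_c_n,
            a_n_ca_c = a_n_ca_c, a_ca_c_n = a_ca_c_n, a_c_n_ca = a_c_n_ca,
            omega = omega)
  lens <- unlist(p[1:3]); angs <- unlist(p[4:6])
  if (any(!is.finite(unlist(p))) || any(lens <= 0) ||
      any(angs <= 0 | angs >= 180))
    stop("invalid geometry: lengths must be > 0, angles in (0, 180)")
  class(p) <- "geometry_params"
  p
}

.vcross <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}
.vunit <- function(u) u / sqrt(rowSums(u * u))

# Place atom D given A, B, C (n x 3 matrices), bond length |C-D|, bond
# angle B-C-D (deg) and torsion A-B-C-D (deg). Vectorized over rows.
.place_atoms <- function(a, b, c, len, ang, tor) {
  bc <- .vunit(c - b)
  n  <- .vunit(.vcross(b - a, bc))
  m  <- .vcross(n, bc)
  angr <- ang * pi / 180
  torr <- tor * pi / 180
  dx <- -len * cos(angr)
  dy <- len * sin(angr) * cos(torr)
  dz <- -len * sin(angr) * sin(torr)  # sign fixes IUPAC torsion handedness
  c + bc * dx + m * dy + n * dz
}

# Build many homologous chains at once. phi, psi, omega: n_chain x n_res
# matrices (phi[,1] and psi[,n] are unused). Returns list of three
# n_chain x n_res x 3 arrays: N, CA, C.
.build_many <- function(phi, psi, omega, params) {
  nc <- nrow(phi); nr <- ncol(phi)
  p <- params
  N  <- array(NA_real_, c(nc, nr, 3))
  CA <- array(NA_real_, c(nc, nr, 3))
  C  <- array(NA_real_, c(nc, nr, 3))
  # canonical first-residue frame: N at origin, CA on +x, C in the xy-plane
  N[, 1, ]  <- matrix(rep(c(0, 0, 0), each = nc), nc)
  CA[, 1, ] <- matrix(rep(c(p$b_n_ca, 0, 0), each = nc), nc)
  th <- (180 - p$a_n_ca_c) * pi / 180
  C[, 1, ] <- matrix(rep(c(p$b_n_ca + p$b_ca_c * cos(th),
                           p$b_ca_c * sin(th), 0), each = nc), nc)
  sl <- function(a, i) matrix(a[, i, ], ncol = 3)
  if (nr > 1) for (i in 2:nr) {
    N[, i, ]  <- .place_atoms(sl(N, i - 1), sl(CA, i - 1), sl(C, i - 1),
                              p$b_c_n, p$a_ca_c_n, psi[, i - 1])
    CA[, i, ] <- .place_atoms(sl(CA, i - 1), sl(C, i - 1), sl(N, i),
                              p$b_n_ca, p$a_c_n_ca, omega[, i])
    C[, i, ]  <- .place_atoms(sl(C, i - 1), sl(N, i), sl(CA, i),
                              p$b_ca_c, p$a_n_ca_c, phi[, i])
  }
  list(N = N, CA = CA, C = C)
}

#' Build a backbone chain from dihedral angles
#'
#' Deterministic forward kinematics: the first residue is placed in a
#' canonical frame (N at the origin, CA on the +x axis, C in the xy
#' plane); every further atom is placed from the ideal bond length, bond
#' angle and the supplied torsion. Identical inputs give bitwise-identical
#' coordinates. `phi[1]` and `psi[n]` are not used by the construction and
#' may be `NA`.
#'
#' @param phi,psi Numeric vectors of dihedral angles in degrees, one per
#'   residue.
#' @param omega Peptide-bond dihedrals: a single value, a length-n vector
#'   (`omega[i]` is the torsion about the bond entering residue i;
#'   `omega[1]` unused), or `NULL` for the default in `params`.
#' @param params A [geometry_params()] object.
#' @return An object of class `backbone_chain`: list with `n_res`, the
#'   `n x 3` coordinate matrices `N`, `CA`, `C`, and the input dihedrals.
#' @examples
#' ch <- build_chain(rep(-63, 10), rep(-43, 10))
#' end_to_end(ch)
#' @export
build_chain <- function(phi, psi, omega = NULL, params = geometry_params()) {
  n <- length(phi)
  if (n < 1L || length(psi) != n) stop("need >= 1 residue; phi/psi same length")
  if (is.null(omega)) omega <- params$omega
  omega <- rep_len(omega, n)
  chk <- c(phi[-1], psi[-n], omega[-1])
  if (any(!is.finite(chk)))
    stop("non-finite interior dihedral: every residue needs finite phi/psi/omega")
  b <- .build_many(rbind(phi), rbind(psi), rbind(omega), params)
  structure(list(n_res = n,
                 N = matrix(b$N[1, , ], ncol = 3),
                 CA = matrix(b$CA[1, , ], ncol = 3),
                 C = matrix(b$C[1, , ], ncol = 3),
                 phi = phi, psi = psi, omega = omega, params = params),
            class = "backbone_chain")
}

#' @export
print.backbone_chain <- function(x, ...) {
  cat(sprintf("backbone chain: %d residues (N/CA/C), end-to-end %.2f A\n",
              x$n_res, if (x$n_res >= 2) end_to_end(x) else NA_real_))
  invisible(x)
}

# interleaved n_res*3 x 3 coordinate matrix, N, CA, C per residue
.chain_coords <- function(chain) {
  m <- matrix(NA_real_, chain$n_res * 3, 3)
  m[seq(1, by = 3, length.out = chain$n_res), ] <- chain$N
  m[seq(2, by = 3, length.out = chain$n_res), ] <- chain$CA
  m[seq(3, by = 3, length.out = chain$n_res), ] <- chain$C
  m
}

#' End-to-end distance of a built chain
#'
#' Euclidean distance between the first and last alpha-carbon (the common
#' polymer-physics endpoint convention).
#'
#' @param chain A `backbone_chain` with at least 2 residues.
#' @return Distance in Angstrom.
#' @export
end_to_end <- function(chain) {
  stopifnot(inherits(chain, "backbone_chain"))
  if (chain$n_res < 2) stop("end-to-end distance needs >= 2 residues")
  sqrt(sum((chain$CA[chain$n_res, ] - chain$CA[1, ])^2))
}

#' Radius of gyration of a built chain
#'
#' Root-mean-square distance of the backbone atoms (N, CA, C) from their
#' centroid.
#'
#' @param chain A `backbone_chain`.
#' @return Distance in Angstrom.
#' @export
radius_of_gyration <- function(chain) {
  stopifnot(inherits(chain, "backbone_chain"))
  x <- .chain_coords(chain)
  ctr <- colMeans(x)
  sqrt(mean(rowSums((x - rep(ctr, each = nrow(x)))^2)))
}

#' End-to-end distance map over the Ramachandran plane
#'
#' For every `(phi, psi)` on a regular grid, builds the n-residue
#' homopolymer with all residues at that state and reports its end-to-end
#' distance — the classic negative-sloping contour map that motivates
#' sweeping the plot along increasing `phi + psi`.
#'
#' @param n_residues Chain length (default 20).
#' @param grid_step Grid spacing in degrees; must divide 360.
#' @param params A [geometry_params()] object.
#' @return Data frame with columns `phi`, `psi`, `re` (Angstrom), dense
#'   over the grid, suitable for contouring.
#' @export
re_map <- function(n_residues = 20, grid_step = 10,
                   params = geometry_params()) {
  if (360 %% grid_step != 0) stop("`grid_step` must divide 360")
  ax <- seq(-180, 180 - grid_step, by = grid_step)
  gr <- expand.grid(phi = ax, psi = ax)
  nc <- nrow(gr)
  phi <- matrix(gr$phi, nc, n_residues)
  psi <- matrix(gr$psi, nc, n_residues)
  om <- matrix(params$omega, nc, n_residues)
  b <- .build_many(phi, psi, om, params)
  d <- b$CA[, n_residues, ] - b$CA[, 1, ]
  data.frame(phi = gr$phi, psi = gr$psi, re = sqrt(rowSums(d * d)))
}

# draw n values of s = phi + psi, uniform over the canonical square
# restricted to s in [lo, hi) (density proportional to 360 - |s|/1)
.sample_sum <- function(n, lo, hi) {
  wmax <- max(360 - abs(lo), 360 - abs(hi))
  out <- numeric(0)
  while (length(out) < n) {
    s <- stats::runif(2 * n, lo, hi)
    u <- stats::runif(2 * n, 0, wmax)
    out <- c(out, s[u < (360 - abs(s))])
  }
  out[seq_len(n)]
}

#' Conditional end-to-end statistics along the Ramachandran number
#'
#' Samples `(phi, psi)` uniformly over the canonical square conditioned on
#' `r` falling in each bin, builds the homopolymer at each sampled state,
#' and reports the mean and standard deviation of the end-to-end distance
#' per bin. The spread quantifies the structural coarse-graining of the
#' collapse, which is largest near the twist-free diagonal (r = 0.5).
#'
#' @param n_residues Chain length (default 5).
#' @param r_bin Bin width on r (default 0.01).
#' @param samples_per_bin Number of accepted samples per bin (>= 2).
#' @param seed Integer seed; results are deterministic given it.
#' @param grid Codec grid (or sigma) used to compute r.
#' @param params A [geometry_params()] object.
#' @return Data frame with columns `r_mid`, `n`, `re_mean`, `re_sd`. Bins
#'   whose conditional region is empty (the extreme corners) get `n = 0`
#'   and `NA` statistics, never fabricated values.
#' @export
re_stats_by_r <- function(n_residues = 5, r_bin = 0.01,
                          samples_per_bin = 50, seed = 1,
                          grid = make_grid(), params = geometry_params()) {
  stopifnot(r_bin > 0, samples_per_bin >= 2)
  g <- .as_grid(grid)
  nb <- ceiling(1 / r_bin)
  res <- data.frame(r_mid = (seq_len(nb) - 0.5) * r_bin, n = 0L,
                    re_mean = NA_real_, re_sd = NA_real_)
  .with_seed(seed, {
    for (k in seq_len(nb)) {
      lo <- 720 * ((k - 1) * r_bin) - 360
      hi <- 720 * min(k * r_bin, 1) - 360
      # clip to the open support of s = phi + psi
      if (hi <= -720 + 360 || lo >= 360) next
      lo2 <- max(lo, -360 + 1e-9); hi2 <- min(hi, 360 - 1e-9)
      if (hi2 <= lo2) next
      s <- .sample_sum(samples_per_bin, lo2, hi2)
      dmax <- 360 - abs(s)
      d <- stats::runif(samples_per_bin, -dmax, dmax)
      phi <- wrap_angle((s + d) / 2); psi <- wrap_angle((s - d) / 2)
      nc <- length(phi)
      b <- .build_many(matrix(phi, nc, n_residues),
                       matrix(psi, nc, n_residues),
                       matrix(params$omega, nc, n_residues), params)
      dd <- b$CA[, n_residues, ] - b$CA[, 1, ]
      re <- sqrt(rowSums(dd * dd))
      res$n[k] <- nc
      res$re_mean[k] <- mean(re)
      res$re_sd[k] <- stats::sd(re)
    }
  })
  res
}

# Kabsch superposition of x onto y (n x 3 each); returns aligned x
.superpose <- function(x, y) {
  cx <- colMeans(x); cy <- colMeans(y)
  x0 <- sweep(x, 2, cx); y0 <- sweep(y, 2, cy)
  s <- svd(crossprod(x0, y0))
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sweep(x0 %*% t(rot), 2, cy, "+")
}

#' Round-trip RMSD of the codec on built backbones
#'
#' Encodes every (phi, psi) of each input chain at resolution `sigma`,
#' decodes back, rebuilds both the original and the recovered chain from
#' the same canonical frame (keeping the original omega values), and
#' reports the pooled RMSD over dihedral angles and over alpha-carbon
#' coordinates. By default no superposition is applied, so the coordinate
#' RMSD measures pure propagated dihedral error (superposition could only
#' shrink it); set `superpose = TRUE` to bracket the other convention.
#'
#' @param chains A list of data frames with columns `phi`, `psi` and
#'   optionally `omega` (degrees), each with >= 2 rows.
#' @param sigma Codec resolution in reciprocal degrees.
#' @param params A [geometry_params()] object.
#' @param superpose Apply Kabsch superposition before the coordinate RMSD?
#' @return List with `angle_rmsd` (degrees), `ca_rmsd` (Angstrom), both
#'   pooled over all residues of all chains, and `n_chains`, `n_residues`.
#' @export
roundtrip_rmsd <- function(chains, sigma = 1e5, params = geometry_params(),
                           superpose = FALSE) {
  if (is.data.frame(chains)) chains <- list(chains)
  g <- make_grid(sigma)
  sq_ang <- 0; n_ang <- 0; sq_ca <- 0; n_ca <- 0; n_res <- 0
  for (ch in chains) {
    if (nrow(ch) < 2) stop("each chain needs >= 2 residues")
    phi <- wrap_angle(ch$phi); psi <- wrap_angle(ch$psi)
    om <- if (!is.null(ch$omega)) ch$omega else params$omega
    dec <- decode_dihedrals(encode_rz(phi, psi, g), g)
    sq_ang <- sq_ang + sum((dec$phi - phi)^2) + sum((dec$psi - psi)^2)
    n_ang <- n_ang + 2 * length(phi)
    c0 <- build_chain(phi, psi, om, params)
    c1 <- build_chain(dec$phi, dec$psi, om, params)
    ca1 <- c1$CA
    if (superpose) ca1 <- .superpose(ca1, c0$CA)
    sq_ca <- sq_ca + sum((ca1 - c0$CA)^2)
    n_ca <- n_ca + nrow(ca1)
    n_res <- n_res + nrow(ch)
  }
  list(angle_rmsd = sqrt(sq_ang / n_ang), ca_rmsd = sqrt(sq_ca / n_ca),
       n_chains = length(chains), n_residues = n_res)
}
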