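# Independent reference implementations used as oracles. These deliberately
# do not share code paths with the package internals they check.

# Brute-force raster index via the explicit rotation-matrix form: each
# term is computed separately (different floating-point association than
# the package's single-expression path).
oracle_rz <- function(phi, psi, sigma) {
  lam <- 360
  s <- sigma / sqrt(2)
  shift <- lam * sigma / sqrt(2)
  pp <- floor(phi * s - psi * s + shift + 0.5)
  sp <- floor(phi * s + psi * s + shift + 0.5)
  lamp <- floor(sqrt(2) * lam * sigma + 0.5)
  pp + lamp * sp
}

# Planar zigzag oracle: with every torsion at 180 degrees the backbone is
# confined to a plane and successive bonds turn by (180 - bond angle)
# with alternating sense. Returns the 3n x 2 in-plane coordinates for a
# trans-extended chain, independently of the package's 3D placement.
oracle_planar_chain <- function(n_res, p = geometry_params()) {
  lens <- rep(c(p$b_n_ca, p$b_ca_c, p$b_c_n), n_res)[seq_len(3 * n_res - 1)]
  angs <- rep(c(p$a_n_ca_c, p$a_ca_c_n, p$a_c_n_ca), n_res)
  xy <- matrix(0, 3 * n_res, 2)
  dir <- 0
  sgn <- +1
  for (k in seq_along(lens)) {
    xy[k + 1, ] <- xy[k, ] + lens[k] * c(cos(dir * pi / 180),
                                         sin(dir * pi / 180))
    dir <- dir + sgn * (180 - angs[k])
    sgn <- -sgn
  }
  xy
}

# all pairwise interatomic distances of a built chain (mirror-isometry
# checks compare these, which are frame-independent)
chain_dist <- function(chain) {
  m <- rbind(chain$N, chain$CA, chain$C)
  as.matrix(stats::dist(m))
}

# random proper rotation matrix (QR-based)
random_rotation <- function(seed) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# minimal classic-DSSP text fixture
write_dssp_fixture <- function(path, codes = c("H", "H", "E", "E", " "),
                               with_break = FALSE, with_malformed = FALSE) {
  lines <- c(
    "==== Secondary Structure Definition by the program DSSP ====",
    "REFERENCE ...",
    "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC     N-H-->O    O-->H-N",
    vapply(seq_along(codes), function(i)
      sprintf("%5d%5d %s %s  %s", i, i, "A", "G", codes[i]), ""))
  if (with_break)
    lines <- append(lines, sprintf("%5d        !              ", length(codes) + 1))
  if (with_malformed) lines <- c(lines, "garbage")
  writeLines(lines, path)
  path
}
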