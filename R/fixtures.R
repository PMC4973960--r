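# Seeded synthetic generators: motif ensembles, mixed chains, two-state
# sigma-strand chains and multi-frame trajectories. Everything the test
# suite consumes is generated here; no downloads. All generators are pure
# functions of (parameters, seed) and leave the session RNG untouched.

#' Canonical motif centers on the Ramachandran plot
#'
#' Conventional textbook centers (degrees), used as generator defaults:
#' alpha (-63, -43), beta (-135, 135), polyproline II (-75, 145),
#' left-handed alpha (63, 43).
#'
#' @return Numeric matrix with rows alpha, beta, ppII, alphaL and columns
#'   phi, psi.
#' @export
motif_centers <- function() {
  m <- rbind(alpha = c(-63, -43), beta = c(-135, 135),
             ppII = c(-75, 145), alphaL = c(63, 43))
  colnames(m) <- c("phi", "psi")
  m
}

.motif_center <- function(motif) {
  if (is.character(motif)) {
    ctr <- motif_centers()
    if (!motif %in% rownames(ctr))
      stop("unknown motif '", motif, "'; use one of: ",
           paste(rownames(ctr), collapse = ", "))
    ctr[motif, ]
  } else {
    stopifnot(is.numeric(motif), length(motif) == 2L)
    c(phi = wrap_angle(motif[1]), psi = wrap_angle(motif[2]))
  }
}

#' Sample dihedral pairs around a motif center
#'
#' Isotropic Gaussian noise around the center, wrapped back into the
#' canonical domain.
#'
#' @param motif Motif name (see [motif_centers()]) or a `c(phi, psi)`
#'   center in degrees.
#' @param n Number of pairs (>= 1).
#' @param sd Angular standard deviation in degrees (default 10; 0 gives
#'   n copies of the center).
#' @param seed Integer seed.
#' @return Data frame with columns `phi`, `psi`.
#' @export
sample_motif <- function(motif = "alpha", n, sd = 10, seed = 1) {
  stopifnot(n >= 1, sd >= 0)
  ctr <- .motif_center(motif)
  .with_seed(seed, data.frame(
    phi = wrap_angle(ctr[["phi"]] + stats::rnorm(n, 0, sd)),
    psi = wrap_angle(ctr[["psi"]] + stats::rnorm(n, 0, sd))))
}

#' Mixed-motif chain
#'
#' Each residue independently draws a motif (uniformly among `motifs`)
#' and then Gaussian dihedrals around that motif's center — a synthetic
#' stand-in for structurally heterogeneous chains.
#'
#' @param n_residues Chain length.
#' @param motifs Character vector of motif names to mix.
#' @param sd Angular standard deviation in degrees.
#' @param seed Integer seed.
#' @param omega Peptide-bond dihedral assigned to every residue.
#' @return Data frame with columns `phi`, `psi`, `omega`, `motif`.
#' @export
make_mixed_chain <- function(n_residues, motifs = c("alpha", "beta",
                                                    "ppII", "alphaL"),
                             sd = 10, seed = 1, omega = 180) {
  stopifnot(n_residues >= 1)
  ctr <- motif_centers()[motifs, , drop = FALSE]
  .with_seed(seed, {
    pick <- sample.int(nrow(ctr), n_residues, replace = TRUE)
    data.frame(phi = wrap_angle(ctr[pick, "phi"] + stats::rnorm(n_residues, 0, sd)),
               psi = wrap_angle(ctr[pick, "psi"] + stats::rnorm(n_residues, 0, sd)),
               omega = omega, motif = rownames(ctr)[pick],
               stringsAsFactors = FALSE)
  })
}

#' Two-state sigma-strand chain
#'
#' Alternates residues between a rotational state `(phi0, psi0)` and its
#' twist-opposed mirror `(-phi0, -psi0)` (odd residues in the first
#' state), plus optional Gaussian noise — the alternating, net-untwisted
#' motif of peptoid nanosheet backbones. The two states map to r0 and
#' 1 - r0, symmetric about the twist-free line r = 0.5. The state pair is
#' a parameter (defaults are illustrative, not literature values).
#'
#' @param n_residues Chain length (>= 3).
#' @param state `c(phi0, psi0)` in degrees for odd residues.
#' @param noise_sd Angular noise standard deviation in degrees.
#' @param seed Integer seed.
#' @param omega Peptide-bond dihedral assigned to every residue.
#' @return Data frame with columns `phi`, `psi`, `omega`, `state` (1/2).
#' @export
make_sigma_chain <- function(n_residues, state = c(-60, 150), noise_sd = 0,
                             seed = 1, omega = 180) {
  stopifnot(n_residues >= 3, length(state) == 2L, noise_sd >= 0)
  sgn <- rep_len(c(1, -1), n_residues)
  .with_seed(seed, data.frame(
    phi = wrap_angle(sgn * state[1] + stats::rnorm(n_residues, 0, noise_sd)),
    psi = wrap_angle(sgn * state[2] + stats::rnorm(n_residues, 0, noise_sd)),
    omega = omega, state = ifelse(sgn > 0, 1L, 2L)))
}

#' Synthetic multi-frame trajectory of one chain
#'
#' Frames up to `switch_frame` are drawn from the `before` generator
#' (default: an extended single-state chain at the beta center, which
#' sits on the twist-free diagonal, r = 0.5); later frames from the
#' `after` generator (default: a sigma-strand chain). Per-frame seeds are
#' derived deterministically from the master seed.
#'
#' @param n_frames Number of frames (>= 1).
#' @param switch_frame Last frame drawn from `before` (0 = none, i.e. a
#'   homogeneous `after` trajectory; `n_frames` = all `before`).
#' @param n_residues Chain length used by the default generators.
#' @param noise_sd Angular noise (degrees) used by the default generators.
#' @param state Sigma-strand state pair for the default `after` generator.
#' @param seed Master integer seed.
#' @param before,after Optional generator overrides: functions taking a
#'   single seed and returning a dihedral data frame (`phi`, `psi`, ...).
#' @return Object of class `rama_trajectory`: a list of per-frame dihedral
#'   data frames, each carrying a `frame` column.
#' @export
make_trajectory <- function(n_frames, switch_frame = 0, n_residues = 15,
                            noise_sd = 5, state = c(-60, 150), seed = 1,
                            before = NULL, after = NULL) {
  stopifnot(n_frames >= 1, switch_frame >= 0, switch_frame <= n_frames)
  if (is.null(before))
    before <- function(s) {
      d <- sample_motif("beta", n_residues, sd = noise_sd, seed = s)
      d$omega <- 180
      d
    }
  if (is.null(after))
    after <- function(s) make_sigma_chain(n_residues, state = state,
                                          noise_sd = noise_sd, seed = s)
  frames <- lapply(seq_len(n_frames), function(f) {
    gen <- if (f <= switch_frame) before else after
    d <- gen(.child_seed(seed, f))
    d$frame <- f
    d
  })
  structure(frames, class = "rama_trajectory")
}

#' Dihedral records for a synthetic trajectory
#'
#' Flattens a trajectory (or any list of per-frame dihedral data frames)
#' into the record format used by [residue_trace()], with frames as
#' models.
#'
#' @param frames A `rama_trajectory` or list of data frames with `phi`,
#'   `psi` columns.
#' @return Data frame with `model`, `chain`, `res_seq`, `i_code`, `phi`,
#'   `psi`, `omega`.
#' @export
trajectory_records <- function(frames) {
  do.call(rbind, lapply(seq_along(frames), function(f) {
    d <- frames[[f]]
    data.frame(model = f, chain = "A", res_seq = seq_len(nrow(d)),
               i_code = " ", res_name = "GLY",
               phi = d$phi, psi = d$psi,
               omega = if (!is.null(d$omega)) d$omega else 180,
               stringsAsFactors = FALSE)
  }))
}

#' Build a trajectory into 3D and write it as a multi-model PDB
#'
#' Runs every frame through [build_chain()] so the whole stack
#' (file -> dihedrals -> R -> analytics) can be exercised end to end.
#'
#' @param frames A `rama_trajectory` or list of dihedral data frames.
#' @param path Output PDB path.
#' @param params A [geometry_params()] object.
#' @return `path`, invisibly.
#' @export
write_trajectory_pdb <- function(frames, path, params = geometry_params()) {
  chains <- lapply(frames, function(d)
    build_chain(d$phi, d$psi,
                if (!is.null(d$omega)) d$omega else params$omega, params))
  write_pdb(chains, path)
}
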