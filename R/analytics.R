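# R-code analytics: histograms over R ("R-codes"), per-residue traces,
# per-class matrices, time-resolved maps, highest-density regions and the
# canonical motif landmarks.

#' R-code: histogram of Ramachandran numbers
#'
#' Bins r values over `[0, 1)` with left-closed bins of equal width. The
#' last bin absorbs r = 1.0 (attainable only at the excluded corner of the
#' dihedral domain). With `normalize = TRUE` heights are rescaled so the
#' largest bin is exactly 1, the convention used to display class codes.
#'
#' @param r Numeric vector of Ramachandran numbers in `[0, 1]`; `NA`s
#'   (undefined residues) are dropped.
#' @param bin_width Bin width; must divide 1 evenly (default 0.01).
#' @param normalize Also compute peak-normalized heights?
#' @return Object of class `rcode`: list with `breaks`, `mids`, `counts`,
#'   `n` (total contributing values) and, if requested, `heights`.
#' @export
rcode <- function(r, bin_width = 0.01, normalize = FALSE) {
  nb <- 1 / bin_width
  if (abs(nb - round(nb)) > 1e-9) stop("`bin_width` must divide 1 evenly")
  nb <- as.integer(round(nb))
  r <- r[!is.na(r)]
  if (length(r) && (any(r < 0) || any(r > 1)))
    stop("r values must lie in [0, 1]")
  idx <- pmin(floor(r / bin_width) + 1L, nb)  # clamp r = 1.0 into last bin
  counts <- tabulate(idx, nbins = nb)
  out <- list(breaks = seq(0, 1, length.out = nb + 1L),
              mids = (seq_len(nb) - 0.5) * bin_width,
              counts = counts, n = length(r))
  if (normalize)
    out$heights <- if (any(counts > 0)) counts / max(counts) else counts * 0
  structure(out, class = "rcode")
}

#' @export
print.rcode <- function(x, ...) {
  pk <- rcode_peak(x)
  cat(sprintf("R-code: %d values in %d bins (width %g); peak at r = %.3f\n",
              x$n, length(x$counts), x$mids[2] - x$mids[1], pk))
  invisible(x)
}

#' Location of an R-code's highest bin
#'
#' @param x An `rcode` object.
#' @return Bin midpoint of the maximal count; ties resolve to the lowest-r
#'   bin (deterministic reporting). `NA` for an empty code.
#' @export
rcode_peak <- function(x) {
  stopifnot(inherits(x, "rcode"))
  if (x$n == 0L) return(NA_real_)
  x$mids[which.max(x$counts)]
}

#' Per-class matrix of normalized R-codes
#'
#' One peak-normalized R-code column per class over a shared binning —
#' the representation that reveals, at a glance, the helix/sheet/loop
#' content of whole protein classes.
#'
#' @param groups Named list of numeric vectors of r values, one per class;
#'   column order follows the input order.
#' @param bin_width Shared bin width (default 0.01).
#' @return Numeric matrix (bins x classes) with bin midpoints as row
#'   names; every nonempty column has maximum exactly 1. Empty classes
#'   give an all-zero column with a warning.
#' @export
class_rcode_matrix <- function(groups, bin_width = 0.01) {
  stopifnot(is.list(groups), length(groups) >= 1L)
  cols <- lapply(names(groups), function(nm) {
    rc <- rcode(groups[[nm]], bin_width, normalize = TRUE)
    if (rc$n == 0L) warning("empty class: ", nm)
    rc$heights
  })
  m <- do.call(cbind, cols)
  colnames(m) <- names(groups)
  rownames(m) <- format(rcode(numeric(0), bin_width)$mids)
  m
}

#' Per-residue, per-frame R trace
#'
#' Computes r for every residue of one chain across one or more models
#' (trajectory frames). Frames must be conformers of the same molecule:
#' the residue identity sequence has to match across models.
#'
#' @param records Dihedral records (from [extract_dihedrals()] or a
#'   fixture generator) for a single chain; multiple models allowed.
#' @param grid A `rama_grid`, or a sigma value passed to [make_grid()].
#' @return Numeric matrix (residues x frames) of r values, `NA` where a
#'   dihedral is undefined; residue ids as row names.
#' @export
residue_trace <- function(records, grid = make_grid()) {
  if (length(unique(records$chain)) > 1L)
    stop("records span several chains; trace one chain at a time")
  models <- unique(records$model)
  ids <- NULL
  cols <- list()
  for (m in models) {
    rec <- records[records$model == m, , drop = FALSE]
    id <- paste0(rec$res_seq, rec$i_code)
    if (is.null(ids)) ids <- id
    else if (!identical(id, ids))
      stop("residue set differs between models; frames must be conformers")
    cols[[length(cols) + 1L]] <- rama_number(rec$phi, rec$psi, grid)
  }
  tr <- do.call(cbind, cols)
  rownames(tr) <- trimws(ids)
  colnames(tr) <- as.character(models)
  tr
}

#' Time series of R-codes over trajectory windows
#'
#' Splits the frames of a residue trace into consecutive non-overlapping,
#' left-aligned windows (trailing partial window kept) and computes one
#' R-code per window over all defined residue-frames in it.
#'
#' @param trace Matrix from [residue_trace()].
#' @param frame_bin Number of frames per window (>= 1).
#' @param bin_width R-code bin width.
#' @param normalize Peak-normalize each window's code?
#' @return List of `rcode` objects, one per window, named by the frame
#'   range they cover.
#' @export
rcode_timeseries <- function(trace, frame_bin = 1L, bin_width = 0.01,
                             normalize = FALSE) {
  stopifnot(frame_bin >= 1)
  nf <- ncol(trace)
  starts <- seq(1L, nf, by = frame_bin)
  out <- lapply(starts, function(s) {
    e <- min(s + frame_bin - 1L, nf)
    rcode(as.vector(trace[, s:e]), bin_width, normalize)
  })
  names(out) <- vapply(starts, function(s)
    sprintf("%d-%d", s, min(s + frame_bin - 1L, nf)), "")
  out
}

#' Alternation score of an R sequence along a chain
#'
#' Fraction of interior residues i whose neighbours step in opposite
#' directions with both step magnitudes above `delta` — 1 for a perfect
#' two-state alternating (sigma-strand-like) chain, 0 for constant or
#' monotone sequences. Triplets containing an undefined r are excluded
#' from the denominator.
#'
#' @param r Numeric vector of r values along one chain.
#' @param delta Minimum step magnitude (default 0.05, about half the
#'   separation of the helix and sheet landmarks).
#' @return Score in `[0, 1]`, or `NA` if fewer than 3 consecutive defined
#'   values exist.
#' @export
alternation_score <- function(r, delta = 0.05) {
  n <- length(r)
  if (n < 3L) return(NA_real_)
  d <- diff(r)
  a <- d[-(n - 1L)]; b <- d[-1L]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) return(NA_real_)
  hit <- ok & (a * b < 0) & (abs(a) > delta) & (abs(b) > delta)
  sum(hit) / sum(ok)
}

#' Highest-density region of a dihedral sample
#'
#' Histograms the sample on a fixed `(phi, psi)` grid and returns the
#' smallest set of highest-count cells containing at least the requested
#' probability mass — the construction behind "the region within which
#' 70% of a secondary structure resides".
#'
#' @param phi,psi Numeric vectors of dihedral angles in degrees.
#' @param mass Target mass fraction in `(0, 1]` (default 0.7).
#' @param cell Grid cell edge in degrees (default 5; must divide 360).
#' @return Data frame of selected cells (`phi_lo`, `phi_hi`, `psi_lo`,
#'   `psi_hi`, `count`), ordered by decreasing count (ties toward lower
#'   cell index); total sample size in attribute `"n"`.
#' @export
density_region <- function(phi, psi, mass = 0.7, cell = 5) {
  stopifnot(mass > 0, mass <= 1, 360 %% cell == 0)
  keep <- !is.na(phi) & !is.na(psi)
  phi <- wrap_angle(phi[keep]); psi <- wrap_angle(psi[keep])
  n <- length(phi)
  if (n < 10L) stop("need at least 10 defined (phi, psi) pairs")
  k <- as.integer(360 / cell)
  ip <- pmin(floor((phi + 180) / cell) + 1L, k)
  is <- pmin(floor((psi + 180) / cell) + 1L, k)
  idx <- (is - 1L) * k + ip
  counts <- tabulate(idx, nbins = k * k)
  ord <- order(-counts, seq_along(counts))
  csum <- cumsum(counts[ord])
  take <- ord[seq_len(which(csum >= mass * n)[1])]
  take <- take[counts[take] > 0]
  ipo <- (take - 1L) %% k + 1L
  iso <- (take - 1L) %/% k + 1L
  out <- data.frame(phi_lo = -180 + (ipo - 1L) * cell,
                    phi_hi = -180 + ipo * cell,
                    psi_lo = -180 + (iso - 1L) * cell,
                    psi_hi = -180 + iso * cell,
                    count = counts[take])
  attr(out, "n") <- n
  out
}

#' Canonical motif landmarks on the R line
#'
#' Default landmark positions: the empirically observed helix (r ~ 0.36),
#' sheet (r ~ 0.52) and loop (r ~ 0.62) peaks, plus the polyproline-II
#' and left-handed-helix positions computed from their textbook (phi,
#' psi) centers. Intervals default to +/- `width` around each landmark;
#' the motif distributions genuinely overlap, so intervals may too.
#'
#' @param width Half-width of each landmark interval (default 0.03).
#' @return Data frame with columns `name`, `r`, `lo`, `hi`, `phi`, `psi`
#'   (centers `NA` where a landmark is defined only on the R line).
#' @export
motif_landmarks <- function(width = 0.03) {
  ctr <- motif_centers()
  rpp <- rama_number(ctr["ppII", "phi"], ctr["ppII", "psi"])
  ral <- rama_number(ctr["alphaL", "phi"], ctr["alphaL", "psi"])
  out <- data.frame(
    name = c("alpha", "beta", "loop", "ppII", "alphaL"),
    r = c(0.36, 0.52, 0.62, rpp, ral),
    phi = c(ctr["alpha", "phi"], ctr["beta", "phi"], NA,
            ctr["ppII", "phi"], ctr["alphaL", "phi"]),
    psi = c(ctr["alpha", "psi"], ctr["beta", "psi"], NA,
            ctr["ppII", "psi"], ctr["alphaL", "psi"]),
    stringsAsFactors = FALSE)
  out$lo <- pmax(out$r - width, 0)
  out$hi <- pmin(out$r + width, 1)
  out[, c("name", "r", "lo", "hi", "phi", "psi")]
}
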