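# PDB (ATOM/MODEL/ENDMDL) and classic-DSSP readers, dihedral extraction,
# and the per-residue R table writer. Only the N/CA/C backbone atoms are
# retained: they carry all of phi, psi and omega. Peptoids are handled
# identically to peptides (same backbone atom quadruples); N-substituents
# are simply never read.

.BREAK_CN <- 2.5  # C(i-1)-N(i) beyond this (Angstrom) is a chain break

#' Write backbone chains as a (multi-model) PDB file
#'
#' Emits standard fixed-column ATOM records (glycine residues, chain A)
#' for one built chain, or MODEL/ENDMDL-wrapped records for a list of
#' chains representing trajectory frames.
#'
#' @param chains A `backbone_chain` or a list of them (one per model).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(chains, path) {
  if (inherits(chains, "backbone_chain")) chains <- list(chains)
  multi <- length(chains) > 1L
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_along(chains)) {
    ch <- chains[[m]]
    stopifnot(inherits(ch, "backbone_chain"))
    if (multi) writeLines(sprintf("MODEL     %4d", m), con)
    serial <- 0L
    for (i in seq_len(ch$n_res)) {
      for (at in c("N", "CA", "C")) {
        serial <- serial + 1L
        xyz <- ch[[at]][i, ]
        writeLines(sprintf(
          "ATOM  %5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, paste0(" ", at), " ", "GLY", "A", i, " ",
          xyz[1], xyz[2], xyz[3], 1.00, 0.00,
          substr(at, 1, 1)), con)
      }
    }
    writeLines("TER", con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

.parse_atom_lines <- function(lines) {
  pad <- function(l) formatC(l, width = 80, flag = "-")
  lines <- pad(lines)
  data.frame(
    name = trimws(substr(lines, 13, 16)),
    altloc = substr(lines, 17, 17),
    res_name = trimws(substr(lines, 18, 20)),
    chain = substr(lines, 22, 22),
    res_seq = as.integer(substr(lines, 23, 26)),
    i_code = substr(lines, 27, 27),
    x = as.numeric(substr(lines, 31, 38)),
    y = as.numeric(substr(lines, 39, 46)),
    z = as.numeric(substr(lines, 47, 54)),
    occ = suppressWarnings(as.numeric(substr(lines, 55, 60))),
    stringsAsFactors = FALSE)
}

# one model's ATOM table -> list of per-chain residue data frames with
# N/CA/C coordinates and a completeness flag
.model_from_atoms <- function(at) {
  at <- at[at$name %in% c("N", "CA", "C"), , drop = FALSE]
  if (nrow(at) == 0L) return(list())
  # altloc: keep highest occupancy; ties resolved toward blank then 'A'
  at$occ[is.na(at$occ)] <- 1
  key <- paste(at$chain, at$res_seq, at$i_code, at$name, sep = "\r")
  ord <- order(match(key, unique(key)), -at$occ, at$altloc)
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(paste(at$chain, at$res_seq, at$i_code, at$name,
                             sep = "\r")), , drop = FALSE]
  out <- list()
  for (cid in unique(at$chain)) {
    ac <- at[at$chain == cid, , drop = FALSE]
    rkey <- paste(ac$res_seq, ac$i_code, sep = "\r")
    ids <- unique(rkey)  # file order, no renumbering
    n <- length(ids)
    df <- data.frame(res_seq = ac$res_seq[match(ids, rkey)],
                     i_code = ac$i_code[match(ids, rkey)],
                     res_name = ac$res_name[match(ids, rkey)],
                     stringsAsFactors = FALSE)
    for (a in c("N", "CA", "C"))
      for (d in c("x", "y", "z"))
        df[[paste0(a, "_", d)]] <- NA_real_
    for (j in seq_len(nrow(ac))) {
      i <- match(rkey[j], ids)
      df[i, paste0(ac$name[j], "_", c("x", "y", "z"))] <-
        unlist(ac[j, c("x", "y", "z")])
    }
    df$complete <- stats::complete.cases(
      df[, grep("_[xyz]$", names(df)), drop = FALSE])
    if (any(!df$complete))
      warning(sprintf("chain %s: %d residue(s) with incomplete backbone",
                      cid, sum(!df$complete)))
    out[[cid]] <- df
  }
  out
}

#' Read backbone atoms from a PDB file
#'
#' Parses ATOM records (fixed columns), keeping only the N, CA and C
#' backbone atoms. MODEL/ENDMDL blocks are preserved in order, so a
#' multi-model file yields one model per trajectory frame. Alternate
#' locations are resolved to the highest-occupancy copy (ties toward
#' altloc 'A'); residues with a missing backbone atom are flagged
#' incomplete with a warning. HETATM records are ignored.
#'
#' @param path Path to a PDB file.
#' @return An object of class `pdb_models`: a list of models, each a named
#'   list of per-chain data frames (`res_seq`, `i_code`, `res_name`, the
#'   nine `N_x` .. `C_z` coordinate columns, `complete`).
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- startsWith(rec, "ATOM")
  if (!any(is_atom) && any(startsWith(rec, "HETATM")))
    warning("file contains only HETATM records; no chains read")
  model_id <- cumsum(startsWith(rec, "MODEL "))
  model_id[model_id == 0L] <- 1L
  models <- list()
  for (m in unique(model_id[is_atom])) {
    at <- .parse_atom_lines(lines[is_atom & model_id == m])
    models[[length(models) + 1L]] <- .model_from_atoms(at)
  }
  if (length(models) == 0L) models <- list(list())
  structure(models, class = "pdb_models")
}

#' @export
print.pdb_models <- function(x, ...) {
  cat(sprintf("PDB: %d model(s); model 1 has %d chain(s), %d residue(s)\n",
              length(x), length(x[[1]]),
              sum(vapply(x[[1]], nrow, 0L))))
  invisible(x)
}

.chain_dihedrals <- function(df) {
  n <- nrow(df)
  take <- function(a) as.matrix(df[, paste0(a, "_", c("x", "y", "z"))])
  N <- take("N"); CA <- take("CA"); C <- take("C")
  phi <- psi <- omega <- rep(NA_real_, n)
  if (n >= 2) {
    dcn <- sqrt(rowSums((N[-1, , drop = FALSE] - C[-n, , drop = FALSE])^2))
    bonded <- df$complete[-n] & df$complete[-1] &
      !is.na(dcn) & dcn <= .BREAK_CN  # bonded[i]: residue i+1 follows i
    idx <- which(bonded)
    if (length(idx)) {
      i <- idx + 1L  # residues with a bonded predecessor
      phi[i] <- .dihedral(C[i - 1L, , drop = FALSE], N[i, , drop = FALSE],
                          CA[i, , drop = FALSE], C[i, , drop = FALSE])
      omega[i] <- .dihedral(CA[i - 1L, , drop = FALSE], C[i - 1L, , drop = FALSE],
                            N[i, , drop = FALSE], CA[i, , drop = FALSE])
      j <- idx    # residues with a bonded successor
      psi[j] <- .dihedral(N[j, , drop = FALSE], CA[j, , drop = FALSE],
                          C[j, , drop = FALSE], N[j + 1L, , drop = FALSE])
    }
  }
  data.frame(res_seq = df$res_seq, i_code = df$i_code,
             res_name = df$res_name,
             phi = wrap_angle(phi), psi = wrap_angle(psi),
             omega = wrap_angle(omega), stringsAsFactors = FALSE)
}

#' Extract backbone dihedral angles
#'
#' phi(i) is the torsion C(i-1)-N(i)-CA(i)-C(i); psi(i) is
#' N(i)-CA(i)-C(i)-N(i+1); omega(i) is CA(i-1)-C(i-1)-N(i)-CA(i). Angles
#' are undefined (`NA`) at segment termini, across chain breaks
#' (consecutive residues are bonded only if the C(i-1)-N(i) distance is
#' <= 2.5 Angstrom) and wherever a backbone atom is missing — never
#' fabricated. All angles are wrapped into `[-180, 180)`.
#'
#' @param x A `pdb_models` object, a single model from one, or a
#'   `backbone_chain` built by [build_chain()].
#' @return A data frame of dihedral records: `model`, `chain`, `res_seq`,
#'   `i_code`, `res_name`, `phi`, `psi`, `omega`.
#' @export
extract_dihedrals <- function(x) {
  if (inherits(x, "backbone_chain")) {
    df <- data.frame(res_seq = seq_len(x$n_res), i_code = " ",
                     res_name = "GLY",
                     N_x = x$N[, 1], N_y = x$N[, 2], N_z = x$N[, 3],
                     CA_x = x$CA[, 1], CA_y = x$CA[, 2], CA_z = x$CA[, 3],
                     C_x = x$C[, 1], C_y = x$C[, 2], C_z = x$C[, 3],
                     complete = TRUE, stringsAsFactors = FALSE)
    x <- structure(list(list(A = df)), class = "pdb_models")
  }
  if (!inherits(x, "pdb_models")) x <- structure(list(x), class = "pdb_models")
  out <- list()
  for (m in seq_along(x)) {
    for (cid in names(x[[m]])) {
      rec <- .chain_dihedrals(x[[m]][[cid]])
      if (nrow(rec)) {
        rec <- cbind(model = m, chain = cid, rec, stringsAsFactors = FALSE)
        out[[length(out) + 1L]] <- rec
      }
    }
  }
  if (!length(out))
    return(data.frame(model = integer(), chain = character(),
                      res_seq = integer(), i_code = character(),
                      res_name = character(), phi = numeric(),
                      psi = numeric(), omega = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

.DSSP_COARSE <- c(H = "helix", G = "helix", I = "helix",
                  E = "sheet", B = "sheet")

#' Read a classic DSSP output file
#'
#' Parses the fixed-column residue block of DSSP's classic text output
#' (the lines following the `#  RESIDUE AA STRUCTURE ...` header). Chain
#' break lines (`!` in the amino-acid column) emit no label. The
#' per-residue code is coarsened as H/G/I -> helix, E/B -> sheet,
#' everything else (T, S, blank, ...) -> loop; the mapping is exposed so
#' callers can override it.
#'
#' @param path Path to a DSSP output file.
#' @param coarse_map Named character vector mapping DSSP codes to coarse
#'   classes; unmapped codes become `"loop"`.
#' @return Data frame with columns `chain`, `res_seq`, `i_code`, `aa`,
#'   `ss` (the raw DSSP code, `" "` if blank) and `class`. Malformed
#'   residue lines are skipped with a single warning giving the count.
#' @export
read_dssp <- function(path, coarse_map = .DSSP_COARSE) {
  if (!file.exists(path)) stop("cannot read DSSP file: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^\\s*#\\s+RESIDUE", lines)
  if (!length(hdr)) stop("not a classic DSSP file (no residue header): ", path)
  body <- lines[seq(hdr[1] + 1L, length(lines))]
  body <- body[nzchar(trimws(body))]
  n_bad <- 0L
  out <- list()
  for (ln in body) {
    if (nchar(ln) < 17) { n_bad <- n_bad + 1L; next }
    aa <- substr(ln, 14, 14)
    if (aa == "!") next  # chain break marker, no residue
    res_seq <- suppressWarnings(as.integer(trimws(substr(ln, 6, 10))))
    if (is.na(res_seq)) { n_bad <- n_bad + 1L; next }
    ss <- substr(ln, 17, 17)
    out[[length(out) + 1L]] <- data.frame(
      chain = substr(ln, 12, 12), res_seq = res_seq,
      i_code = substr(ln, 11, 11), aa = aa, ss = ss,
      stringsAsFactors = FALSE)
  }
  if (n_bad > 0L) warning(sprintf("skipped %d malformed DSSP line(s)", n_bad))
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chain = character(), res_seq = integer(),
               i_code = character(), aa = character(), ss = character(),
               stringsAsFactors = FALSE)
  cls <- unname(coarse_map[res$ss])
  cls[is.na(cls)] <- "loop"
  res$class <- cls
  res
}

#' Compute Ramachandran numbers for dihedral records
#'
#' Adds `rz` and `r` columns to a record table from [extract_dihedrals()];
#' rows with undefined phi or psi get `NA`.
#'
#' @param records Data frame with `phi` and `psi` columns (degrees).
#' @param grid A `rama_grid`, or a sigma value passed to [make_grid()].
#' @return The records with `rz` and `r` appended.
#' @export
rama_records <- function(records, grid = make_grid()) {
  enc <- encode_rz(records$phi, records$psi, grid)
  records$rz <- enc$rz
  records$r <- enc$r
  records
}

#' Write a per-residue R table as TSV
#'
#' One row per residue per model; undefined angles and R values are
#' written as empty fields. Readable back with
#' `read.delim(path, comment.char = "#")`.
#'
#' @param records Data frame from [rama_records()] (must contain `model`,
#'   `chain`, `res_seq`, `phi`, `psi`, `r`).
#' @param path Output path.
#' @param header Optional character vector of `#`-prefixed comment lines
#'   (e.g. the run configuration) written before the column names.
#' @return `path`, invisibly.
#' @export
write_r_table <- function(records, path, header = NULL) {
  need <- c("model", "chain", "res_seq", "phi", "psi", "r")
  if (!all(need %in% names(records)))
    stop("records must contain columns: ", paste(need, collapse = ", "))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(records, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
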