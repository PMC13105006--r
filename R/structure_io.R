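# ---- structure ingestion ---------------------------------------------------

#' Construct a chain_geometry from raw components
#'
#' Internal residue numbering is 1-based and contiguous; all downstream
#' geometry uses internal indices, and the author numbering is kept as a
#' bijective map for reporting.
#'
#' @param xyz N x 3 matrix of Calpha coordinates (Angstrom).
#' @param author_resid original residue identifiers (default 1..N).
#' @param chain_id chain identifier.
#' @param seq one-letter amino-acid codes (default "A").
#' @param heavy optional list (length N) of heavy-atom coordinate matrices
#'   (rownames = atom names) or NULL per residue.
#' @return object of class `chain_geometry`.
#' @export
chain_geometry <- function(xyz, author_resid = seq_len(nrow(xyz)),
                           chain_id = "A", seq = rep("A", nrow(xyz)),
                           heavy = NULL) {
  xyz <- as.matrix(xyz)
  dimnames(xyz) <- NULL
  stopifnot(ncol(xyz) == 3, nrow(xyz) >= 1, !anyNA(xyz))
  n <- nrow(xyz)
  stopifnot(length(author_resid) == n, !anyDuplicated(author_resid))
  if (!is.null(heavy)) stopifnot(length(heavy) == n)
  structure(list(xyz = xyz, resid = seq_len(n), author_resid = author_resid,
                 chain_id = chain_id, seq = seq, heavy = heavy),
            class = "chain_geometry")
}

#' @export
print.chain_geometry <- function(x, ...) {
  cat(sprintf("chain_geometry: chain %s, %d residues (author %s..%s)%s\n",
              x$chain_id, nrow(x$xyz), x$author_resid[1],
              x$author_resid[length(x$author_resid)],
              if (is.null(x$heavy)) ", Calpha only" else ", with heavy atoms"))
  invisible(x)
}

aa321 <- function(resname) {
  out <- bio3d::aa321(resname)
  out[is.na(out)] <- "X"
  out
}

#' Read a protein chain from a PDB or mmCIF file
#'
#' Residues are renumbered to a contiguous internal 1..N index; the original
#' (author) numbering is retained as a bijective map. Alternate locations are
#' collapsed to the highest-occupancy conformer (ties broken by first
#' alphabetical altloc ID). Any residue lacking a Calpha is a hard error that
#' names the residue; numbering gaps are an error unless `allow_gaps = TRUE`.
#'
#' @param path PDB (`.pdb`) or mmCIF (`.cif`) file.
#' @param chain chain identifier; default takes the first chain present.
#' @param allow_gaps tolerate gaps in author residue numbering (gaps are
#'   renumbered over and recorded in attribute `"gaps"`).
#' @return a `chain_geometry` carrying heavy atoms when present.
#' @export
read_structure <- function(path, chain = NULL, allow_gaps = FALSE) {
  stopifnot(file.exists(path))
  pdb <- if (grepl("\\.cif(\\.gz)?$", path))
    bio3d::read.cif(path, rm.alt = FALSE, verbose = FALSE)
  else bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (is.null(chain)) chain <- at$chain[1]
  at <- at[at$chain == chain, , drop = FALSE]
  if (nrow(at) == 0L) stop("chain '", chain, "' not found in ", path)
  at <- at[!grepl("^H|^\\dH", at$elety), , drop = FALSE]   # heavy atoms only
  # altloc collapse: highest occupancy, ties by first alphabetical altloc
  alt <- at$alt; alt[is.na(alt)] <- ""
  if (any(nzchar(alt))) {
    key <- paste(at$resno, at$insert, at$elety)
    keep <- rep(TRUE, nrow(at))
    for (k in unique(key[duplicated(key)])) {
      idx <- which(key == k)
      o <- at$o[idx]; o[is.na(o)] <- 0
      best <- idx[order(-o, alt[idx])][1]
      keep[setdiff(idx, best)] <- FALSE
    }
    at <- at[keep, , drop = FALSE]
  }
  resno <- at$resno
  ures <- unique(resno)
  ca <- at[at$elety == "CA", , drop = FALSE]
  miss <- setdiff(ures, ca$resno)
  if (length(miss))
    stop("residue(s) without Calpha in chain ", chain, ": ",
         paste(miss, collapse = ", "))
  ca <- ca[!duplicated(ca$resno), , drop = FALSE]
  ca <- ca[order(match(ca$resno, ures)), , drop = FALSE]
  gaps <- which(diff(ca$resno) > 1)
  if (length(gaps) && !allow_gaps)
    stop("residue-number gap(s) after author residue(s) ",
         paste(ca$resno[gaps], collapse = ", "),
         "; set allow_gaps = TRUE to renumber over them")
  heavy <- lapply(ca$resno, function(r) {
    h <- at[resno == r, , drop = FALSE]
    m <- as.matrix(h[, c("x", "y", "z")])
    rownames(m) <- h$elety
    m
  })
  geom <- chain_geometry(xyz = as.matrix(ca[, c("x", "y", "z")]),
                         author_resid = ca$resno, chain_id = chain,
                         seq = aa321(ca$resid), heavy = heavy)
  if (length(gaps)) attr(geom, "gaps") <- ca$resno[gaps]
  geom
}

#' Write a chain_geometry as a Calpha-trace PDB file
#'
#' @param geometry a `chain_geometry`.
#' @param path output file.
#' @export
write_structure <- function(geometry, path) {
  n <- nrow(geometry$xyz)
  aa3 <- bio3d::aa123(geometry$seq)
  aa3[is.na(aa3)] <- "ALA"
  bio3d::write.pdb(file = path, xyz = as.vector(t(geometry$xyz)),
                   resno = geometry$author_resid, chain = rep(geometry$chain_id, n),
                   resid = aa3, elety = rep("CA", n))
  invisible(path)
}

# ---- secondary structure / domains ----------------------------------------

#' Read secondary-structure elements from a delimited text file
#'
#' One element per line: `start end type` with type `helix` or `strand`
#' (H/E accepted), indices in internal numbering. Elements must be
#' non-overlapping and within the chain.
#'
#' @param path file path.
#' @param n optional chain length for range validation.
#' @return data.frame with columns `start`, `end`, `type`.
#' @export
read_secondary_elements <- function(path, n = NULL) {
  tb <- utils::read.table(path, header = FALSE, col.names = c("start", "end", "type"),
                          colClasses = c("integer", "integer", "character"))
  secondary_elements(tb, n = n)
}

#' Validate a secondary-structure element table
#' @param elements data.frame with `start`, `end`, `type`.
#' @param n optional chain length.
#' @return the validated data.frame, class `secondary_elements`.
#' @export
secondary_elements <- function(elements, n = NULL) {
  el <- as.data.frame(elements)
  el$type <- c(H = "helix", E = "strand", helix = "helix", strand = "strand",
               G = "helix")[el$type]
  stopifnot(!anyNA(el$type), all(el$start <= el$end), all(el$start >= 1))
  if (!is.null(n)) stopifnot(all(el$end <= n))
  el <- el[order(el$start), , drop = FALSE]
  if (nrow(el) > 1 && any(el$start[-1] <= el$end[-nrow(el)]))
    stop("secondary-structure elements overlap")
  rownames(el) <- NULL
  class(el) <- c("secondary_elements", "data.frame")
  el
}

# ---- trajectories ----------------------------------------------------------

#' Wrap a coordinate array as a trajectory handle
#'
#' @param coords numeric array n_frames x N x 3 of Calpha coordinates.
#' @param start number of leading frames to skip (0-based index of the first
#'   exposed frame; must be smaller than the frame count).
#' @param stride keep every `stride`-th frame.
#' @return object of class `trajectory` with fields `coords`, `n_frames`,
#'   `start`, `stride`.
#' @export
trajectory_handle <- function(coords, start = 0L, stride = 1L) {
  stopifnot(length(dim(coords)) == 3, dim(coords)[3] == 3,
            start >= 0L, stride >= 1L)
  if (start >= dim(coords)[1])
    stop("start frame ", start, " beyond trajectory length ", dim(coords)[1])
  sel <- seq(from = start + 1L, to = dim(coords)[1], by = stride)
  structure(list(coords = coords[sel, , , drop = FALSE],
                 n_frames = length(sel), start = as.integer(start),
                 stride = as.integer(stride)),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d frames x %d residues (start %d, stride %d)\n",
              x$n_frames, dim(x$coords)[2], x$start, x$stride))
  invisible(x)
}

#' Extract one frame of a trajectory as an N x 3 matrix
#' @param traj a `trajectory`.
#' @param frame frame index (1-based within the handle).
#' @export
traj_frame <- function(traj, frame) {
  stopifnot(frame >= 1, frame <= traj$n_frames)
  traj$coords[frame, , ]
}

#' Read a Calpha trajectory from a DCD file with a PDB/PSF topology
#'
#' The Calpha selection from the topology defines the atom subset and must
#' match the reference geometry length frame by frame.
#'
#' @param topology PDB or PSF file defining atom identities.
#' @param coords DCD coordinate file.
#' @param start number of leading frames to skip (0-based first frame).
#' @param stride frame stride.
#' @return a `trajectory`.
#' @export
read_trajectory <- function(topology, coords, start = 0L, stride = 1L) {
  stopifnot(file.exists(topology), file.exists(coords))
  dcd <- bio3d::read.dcd(coords, verbose = FALSE)
  if (grepl("\\.psf$", topology)) {
    lines <- readLines(topology)
    natom_line <- grep("!NATOM", lines, value = TRUE)[1]
    natom <- as.integer(sub("^\\s*(\\d+).*", "\\1", natom_line))
    first <- grep("!NATOM", lines)[1]
    atoms <- lines[(first + 1):(first + natom)]
    elety <- vapply(strsplit(trimws(atoms), "\\s+"), `[`, character(1), 5)
    ca_idx <- which(elety == "CA")
    if (!length(ca_idx)) ca_idx <- seq_len(natom)   # CG bead-per-residue model
  } else {
    pdb <- bio3d::read.pdb(topology, verbose = FALSE)
    natom <- nrow(pdb$atom)
    ca_idx <- which(pdb$atom$elety == "CA")
    if (!length(ca_idx)) ca_idx <- seq_len(natom)
  }
  if (ncol(dcd) != 3 * natom)
    stop("atom-count mismatch: topology has ", natom, " atoms, dcd frames have ",
         ncol(dcd) / 3)
  nf <- nrow(dcd)
  arr <- array(NA_real_, c(nf, length(ca_idx), 3))
  for (d in 1:3) arr[, , d] <- dcd[, 3 * (ca_idx - 1) + d, drop = FALSE]
  trajectory_handle(arr, start = start, stride = stride)
}

#' Write a Calpha trajectory to a DCD file
#'
#' Minimal X-PLOR-dialect DCD writer (one atom per residue, no unit cell),
#' round-trippable with [read_trajectory()].
#'
#' @param traj a `trajectory`.
#' @param path output DCD path.
#' @export
write_trajectory <- function(traj, path) {
  nf <- traj$n_frames
  natom <- dim(traj$coords)[2]
  con <- file(path, "wb")
  on.exit(close(con))
  rec <- function(write_body, nbytes) {
    writeBin(as.integer(nbytes), con, size = 4)
    write_body()
    writeBin(as.integer(nbytes), con, size = 4)
  }
  icntrl <- integer(20)
  icntrl[1] <- nf; icntrl[2] <- 1L; icntrl[3] <- 1L
  rec(function() {
    writeChar("CORD", con, nchars = 4, eos = NULL)
    writeBin(icntrl, con, size = 4)
  }, 84L)
  title <- formatC("generated by lassotop", width = 80, flag = "-")
  rec(function() {
    writeBin(1L, con, size = 4)
    writeChar(title, con, nchars = 80, eos = NULL)
  }, 84L)
  rec(function() writeBin(as.integer(natom), con, size = 4), 4L)
  for (f in seq_len(nf)) {
    for (d in 1:3) {
      rec(function() writeBin(as.numeric(traj$coords[f, , d]), con, size = 4),
          4L * natom)
    }
  }
  invisible(path)
}

# ---- visualisation scripts -------------------------------------------------

#' Write a VMD or PyMOL script highlighting an NCLE
#'
#' Colours follow the community convention: loop red, thread blue, the
#' loop-closing Calpha pair orange space-fill, crossing Calpha white
#' space-fill.
#'
#' @param geometry a `chain_geometry` (used for range validation and thread
#'   extent).
#' @param ncle an `ncle` record.
#' @param flavor `"vmd"` (Tcl) or `"pymol"` (.pml).
#' @param file optional path to write to; the script text is returned
#'   invisibly either way.
#' @export
write_visualization_script <- function(geometry, ncle, flavor = c("vmd", "pymol"),
                                       file = NULL) {
  flavor <- match.arg(flavor)
  n <- nrow(geometry$xyz)
  i <- ncle$loop[1]; j <- ncle$loop[2]
  if (i < 1 || j > n) stop("NCLE loop indices out of range 1..", n)
  cr <- ncle$crossings$residue
  if (length(cr) && (min(cr) < 1 || max(cr) > n)) stop("crossing residue out of range")
  thread <- switch(ncle$tail,
                   N = c(1L, i - 1L), C = c(j + 1L, n),
                   both = NULL)
  thr_sel <- function(fmt) {
    if (is.null(thread)) paste(sprintf(fmt, 1L, i - 1L), sprintf(fmt, j + 1L, n))
    else sprintf(fmt, thread[1], thread[2])
  }
  if (flavor == "vmd") {
    lines <- c(
      "# NCLE visualisation (VMD)",
      sprintf("set loop \"resid %d to %d\"", i, j),
      "mol color ColorID 1",                                # red loop
      "mol selection $loop",
      "mol representation NewCartoon", "mol addrep top",
      sprintf("set thread \"resid %s\"", thr_sel("%d to %d")),
      "mol color ColorID 0",                                # blue thread
      "mol selection $thread",
      "mol representation NewCartoon", "mol addrep top",
      sprintf("set closing \"resid %d %d and name CA\"", i, j),
      "mol color ColorID 3",                                # orange closing pair
      "mol selection $closing",
      "mol representation VDW", "mol addrep top")
    if (length(cr))
      lines <- c(lines,
                 sprintf("set crossing \"resid %s and name CA\"",
                         paste(cr, collapse = " ")),
                 "mol color ColorID 8",                      # white crossings
                 "mol selection $crossing",
                 "mol representation VDW", "mol addrep top")
  } else {
    lines <- c(
      "# NCLE visualisation (PyMOL)",
      sprintf("select loop, resi %d-%d", i, j),
      "color red, loop",
      sprintf("select thread, resi %s", thr_sel("%d-%d")),
      "color blue, thread",
      sprintf("select closing, resi %d+%d and name CA", i, j),
      "color orange, closing", "show spheres, closing")
    if (length(cr))
      lines <- c(lines,
                 sprintf("select crossing, resi %s and name CA",
                         paste(cr, collapse = "+")),
                 "color white, crossing", "show spheres, crossing")
  }
  txt <- paste(lines, collapse = "\n")
  if (!is.null(file)) writeLines(txt, file)
  invisible(txt)
}

#' Write an NCLE table to CSV (internal and author numbering)
#'
#' @param records `ncle_list` from [detect_ncles()].
#' @param geometry the `chain_geometry` the records were computed on.
#' @param file output CSV path.
#' @export
write_ncle_csv <- function(records, geometry, file) {
  df <- as.data.frame(records, geometry = geometry)
  df <- cbind(chain = geometry$chain_id, df)
  utils::write.csv(df, file, row.names = FALSE)
  invisible(df)
}
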