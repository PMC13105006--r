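# ---- solvent accessibility -------------------------------------------------

# van der Waals radii (Angstrom) by element, Bondi-style
vdw_radius <- function(element) {
  tab <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, H = 1.20)
  r <- tab[element]
  r[is.na(r)] <- 1.70
  unname(r)
}

element_of_atom <- function(atom_names) substr(gsub("^[0-9]", "", atom_names), 1, 1)

# deterministic quasi-uniform sphere points (golden-spiral)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Per-residue solvent-accessible surface area (Shrake-Rupley)
#'
#' Each atom is expanded by the probe radius and sampled with a deterministic
#' golden-spiral point set; points falling inside any neighbouring expanded
#' sphere are buried. Per-atom areas are summed per residue.
#'
#' @param xyz n_atoms x 3 coordinate matrix (Angstrom).
#' @param residue integer residue index per atom.
#' @param element element symbol per atom (defaults to carbon radii).
#' @param probe probe radius (default 1.4 Angstrom, water).
#' @param n_points sphere sample points per atom (default 512).
#' @param n_residues total residue count of the chain (rows of the output).
#' @return numeric vector of per-residue SASA in Angstrom^2.
#' @export
residue_sasa <- function(xyz, residue = seq_len(nrow(xyz)),
                         element = rep("C", nrow(xyz)),
                         probe = 1.4, n_points = 512L,
                         n_residues = max(residue)) {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  rad <- vdw_radius(element) + probe
  sp <- sphere_points(n_points)
  d2 <- as.matrix(stats::dist(xyz))^2
  area <- numeric(n)
  for (a in seq_len(n)) {
    nb <- which(d2[a, ] < (rad[a] + rad)^2 & seq_len(n) != a)
    pts <- sweep(sp * rad[a], 2, xyz[a, ], "+")
    acc <- rep(TRUE, n_points)
    for (b in nb) {
      if (!any(acc)) break
      dd <- sweep(pts[acc, , drop = FALSE], 2, xyz[b, ], "-")
      acc[acc] <- rowSums(dd * dd) > rad[b]^2
    }
    area[a] <- 4 * pi * rad[a]^2 * sum(acc) / n_points
  }
  out <- numeric(n_residues)
  agg <- tapply(area, residue, sum)
  out[as.integer(names(agg))] <- agg
  out
}

#' SASA of every residue of a chain_geometry conformation
#'
#' Uses heavy atoms when present, otherwise the Calpha trace (each residue a
#' single pseudo-atom).
#'
#' @param geometry a `chain_geometry`.
#' @param xyz optional replacement Calpha coordinates (frame of a
#'   trajectory); forces Calpha mode.
#' @param ... passed to [residue_sasa()].
#' @export
geometry_sasa <- function(geometry, xyz = NULL, ...) {
  n <- nrow(geometry$xyz)
  if (is.null(xyz) && !is.null(geometry$heavy)) {
    coords <- do.call(rbind, geometry$heavy)
    res <- rep(seq_len(n), vapply(geometry$heavy, nrow, integer(1)))
    el <- element_of_atom(rownames(coords))
    residue_sasa(coords, res, el, n_residues = n, ...)
  } else {
    residue_sasa(if (is.null(xyz)) geometry$xyz else xyz,
                 seq_len(n), rep("C", n), n_residues = n, ...)
  }
}

# ---- solvent-accessible surface distance -----------------------------------

crosslink_atom <- function(geometry, res) {
  if (!is.null(geometry$heavy) && !is.null(geometry$heavy[[res]])) {
    h <- geometry$heavy[[res]]
    for (nm in c("NZ", "CB", "CA")) if (nm %in% rownames(h)) return(h[nm, ])
  }
  geometry$xyz[res, ]
}

#' Solvent-accessible surface distance between two residues
#'
#' Shortest path between the crosslinkable atoms (Lys NZ, else Cbeta, else
#' Calpha) over a 3-D grid of solvent voxels (grid points outside the
#' protein's van der Waals volume), 26-neighbour connectivity with Euclidean
#' edge weights. Buried residues (SASA = 0) and unreachable pairs return
#' `Inf` as the failure sentinel.
#'
#' @param geometry a `chain_geometry` (heavy atoms used when present).
#' @param resA,resB residue indices.
#' @param grid grid spacing in Angstrom (default 2).
#' @param margin box margin beyond the structure extent (default 8 A).
#' @param sasa optional precomputed per-residue SASA for the exposure check.
#' @return distance in Angstrom, or `Inf`.
#' @export
sasd <- function(geometry, resA, resB, grid = 2, margin = 8, sasa = NULL) {
  if (is.null(sasa)) sasa <- geometry_sasa(geometry, n_points = 128L)
  if (sasa[resA] <= 0 || sasa[resB] <= 0) return(Inf)
  atoms <- if (!is.null(geometry$heavy)) do.call(rbind, geometry$heavy) else geometry$xyz
  el <- if (!is.null(geometry$heavy)) element_of_atom(rownames(atoms))
        else rep("C", nrow(atoms))
  rad <- vdw_radius(el)
  lo <- apply(atoms, 2, min) - margin
  hi <- apply(atoms, 2, max) + margin
  nx <- ceiling((hi - lo) / grid) + 1L
  ax <- lapply(1:3, function(d) lo[d] + grid * (seq_len(nx[d]) - 1L))
  # voxel blocked when inside any vdW sphere
  blocked <- array(FALSE, nx)
  for (a in seq_len(nrow(atoms))) {
    rng <- lapply(1:3, function(d) {
      which(abs(ax[[d]] - atoms[a, d]) <= rad[a])
    })
    if (any(vapply(rng, length, integer(1)) == 0)) next
    gx <- as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))
    pt <- cbind(ax[[1]][gx[, 1]], ax[[2]][gx[, 2]], ax[[3]][gx[, 3]])
    inside <- rowSums(sweep(pt, 2, atoms[a, ], "-")^2) <= rad[a]^2
    blocked[gx[inside, , drop = FALSE]] <- TRUE
  }
  open_idx <- which(!blocked)
  if (!length(open_idx)) return(Inf)
  lin <- array(0L, nx)
  lin[open_idx] <- seq_along(open_idx)
  coords <- arrayInd(open_idx, nx)
  # 26-neighbour edges (13 unique offsets)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  offs <- offs[offs[, 1] > 0 | (offs[, 1] == 0 & offs[, 2] > 0) |
               (offs[, 1] == 0 & offs[, 2] == 0 & offs[, 3] > 0), , drop = FALSE]
  ed_from <- integer(0); ed_to <- integer(0); ed_w <- numeric(0)
  for (o in seq_len(nrow(offs))) {
    nb <- sweep(coords, 2, offs[o, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= nx[1] & nb[, 2] >= 1 & nb[, 2] <= nx[2] &
          nb[, 3] >= 1 & nb[, 3] <= nx[3]
    tgt <- integer(sum(ok))
    tgt <- lin[nb[ok, , drop = FALSE]]
    src <- lin[coords[ok, , drop = FALSE]]
    keep <- tgt > 0
    ed_from <- c(ed_from, src[keep]); ed_to <- c(ed_to, tgt[keep])
    ed_w <- c(ed_w, rep(grid * sqrt(sum(offs[o, ]^2)), sum(keep)))
  }
  g <- igraph::graph_from_edgelist(cbind(ed_from, ed_to), directed = FALSE)
  if (igraph::vcount(g) < length(open_idx))
    g <- igraph::add_vertices(g, length(open_idx) - igraph::vcount(g))
  igraph::E(g)$weight <- ed_w
  nearest_open <- function(p) {
    d2 <- rowSums(sweep(cbind(ax[[1]][coords[, 1]], ax[[2]][coords[, 2]],
                              ax[[3]][coords[, 3]]), 2, p, "-")^2)
    which.min(d2)
  }
  va <- nearest_open(crosslink_atom(geometry, resA))
  vb <- nearest_open(crosslink_atom(geometry, resB))
  dd <- igraph::distances(g, v = va, to = vb)[1, 1]
  if (!is.finite(dd)) Inf else dd
}

#' Crosslinking propensity from a surface distance
#'
#' Monotone nonincreasing logistic map of SASD to \[0, 1\]:
#' `XP = 1 / (1 + exp((SASD - d0) / s))`, with defaults calibrated for the
#' DSBU linker (midpoint `d0 = 33` Angstrom, steepness `s = 3`). The
#' unreachable sentinel (`Inf`) maps to 0.
#'
#' @param sasd_value SASD in Angstrom (vectorised), `Inf` allowed.
#' @param d0 logistic midpoint (Angstrom).
#' @param s logistic steepness (Angstrom).
#' @export
xp_score <- function(sasd_value, d0 = 33, s = 3) {
  out <- ifelse(is.finite(sasd_value), 1 / (1 + exp((sasd_value - d0) / s)), 0)
  out[sasd_value < 0 & is.finite(sasd_value)] <- NA_real_
  out
}

# ---- ensemble consistency testing ------------------------------------------

#' LiP-MS cut-site features from a per-frame SASA matrix
#'
#' The per-frame feature of a cut-site is the summed SASA over the site and
#' its +/- `window` residues (window truncated at the chain ends).
#'
#' @param sasa_matrix frames x residues SASA matrix.
#' @param cutsites residue indices of the signals.
#' @param window half-width of the accessibility window (default 5).
#' @return frames x signals feature matrix.
#' @export
lip_features <- function(sasa_matrix, cutsites, window = 5L) {
  n <- ncol(sasa_matrix)
  if (any(cutsites < 1 | cutsites > n)) stop("cut-site residue out of range 1..", n)
  out <- sapply(cutsites, function(cs) {
    win <- max(1L, cs - window):min(n, cs + window)
    rowSums(sasa_matrix[, win, drop = FALSE])
  })
  matrix(out, nrow = nrow(sasa_matrix),
         dimnames = list(NULL, paste0("site", cutsites)))
}

#' Two-tailed permutation test of a mean difference, per signal
#'
#' For each signal (column), the statistic is mean(state) - mean(native);
#' group labels are permuted `n_perm` times and the two-tailed p-value uses
#' the add-one convention `p = (1 + #{|perm| >= |obs|}) / (1 + n_perm)`.
#'
#' @param state_feat,native_feat frames x signals feature matrices.
#' @param n_perm number of permutations (default 10000).
#' @param seed RNG seed.
#' @return list with `observed`, `p` (vectors over signals).
#' @export
permutation_test <- function(state_feat, native_feat, n_perm = 10000L, seed = 1L) {
  state_feat <- as.matrix(state_feat); native_feat <- as.matrix(native_feat)
  stopifnot(ncol(state_feat) == ncol(native_feat))
  n1 <- nrow(state_feat); n2 <- nrow(native_feat)
  stopifnot(n1 >= 5, n2 >= 5)
  pooled <- rbind(state_feat, native_feat)
  obs <- colMeans(state_feat) - colMeans(native_feat)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  tot <- colSums(pooled)
  exceed <- integer(ncol(pooled))
  for (b in seq_len(n_perm)) {
    pick <- sample.int(n1 + n2, n1)
    pm <- colSums(pooled[pick, , drop = FALSE]) / n1 - (tot - colSums(pooled[pick, , drop = FALSE])) / n2
    exceed <- exceed + (abs(pm) >= abs(obs) - 1e-12)
  }
  list(observed = obs, p = (1 + exceed) / (1 + n_perm))
}

#' Test a metastable-state ensemble for consistency with MS signals
#'
#' Per signal the feature is the cut-site +/- 5 summed SASA (LiP) or the
#' crosslink XP (XL) per frame; the state-vs-native mean difference is
#' assessed by a two-tailed label-permutation test and Benjamini-Hochberg
#' FDR across signals. A signal is consistent when its adjusted p-value is
#' below `alpha`; states are ranked by the number of consistent signals.
#'
#' @param state_feat,native_feat frames x signals feature matrices (from
#'   [lip_features()] or per-frame [xp_score()] columns).
#' @param n_perm permutations (default 10000).
#' @param alpha FDR level (default 0.05).
#' @param seed RNG seed.
#' @param state_id identifier carried into the result.
#' @return list with `state_id`, `table` (per-signal observed difference, raw
#'   and BH-adjusted p, consistent flag) and `n_consistent`.
#' @export
ensemble_consistency_test <- function(state_feat, native_feat, n_perm = 10000L,
                                      alpha = 0.05, seed = 1L, state_id = 1L) {
  pt <- permutation_test(state_feat, native_feat, n_perm = n_perm, seed = seed)
  adj <- stats::p.adjust(pt$p, method = "BH")
  tab <- data.frame(signal = colnames(as.matrix(state_feat)) %||%
                      paste0("s", seq_along(pt$p)),
                    delta = pt$observed, p = pt$p, p_adj = adj,
                    consistent = adj < alpha)
  rownames(tab) <- NULL
  list(state_id = state_id, table = tab, n_consistent = sum(tab$consistent))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Select representative structures from a tested metastable state
#'
#' Frames are grouped by their signature: the set of entanglement-change
#' cluster ids present in the frame and the set of signals whose feature
#' value falls outside the native ensemble's 95% band (2.5-97.5 percentiles).
#' Within each group the frame with the highest microstate probability is the
#' representative (ties by earliest frame).
#'
#' @param state_feat frames x signals feature matrix of the state ensemble.
#' @param native_feat frames x signals feature matrix of the native ensemble.
#' @param change_ids list (length = state frames) of entanglement-change
#'   cluster ids per frame (may be empty vectors).
#' @param micro_prob per-frame microstate probability (state frames).
#' @return data.frame: one row per group with `signature`, `n_frames`,
#'   `representative` (frame index into the state ensemble).
#' @export
select_representative_structures <- function(state_feat, native_feat,
                                             change_ids = NULL,
                                             micro_prob = rep(1, nrow(as.matrix(state_feat)))) {
  state_feat <- as.matrix(state_feat); native_feat <- as.matrix(native_feat)
  nf <- nrow(state_feat)
  if (is.null(change_ids)) change_ids <- rep(list(integer(0)), nf)
  lo <- apply(native_feat, 2, stats::quantile, probs = 0.025)
  hi <- apply(native_feat, 2, stats::quantile, probs = 0.975)
  signat <- vapply(seq_len(nf), function(f) {
    out_sig <- which(state_feat[f, ] < lo | state_feat[f, ] > hi)
    paste0("ch{", paste(sort(change_ids[[f]]), collapse = ","),
           "}|sig{", paste(out_sig, collapse = ","), "}")
  }, character(1))
  groups <- split(seq_len(nf), signat)
  out <- do.call(rbind, lapply(names(groups), function(s) {
    idx <- groups[[s]]
    rep_f <- idx[order(-micro_prob[idx], idx)][1]
    data.frame(signature = s, n_frames = length(idx), representative = rep_f)
  }))
  out[order(out$signature), , drop = FALSE]
}
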