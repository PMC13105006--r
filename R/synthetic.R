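# ---- seed-deterministic fixture generators ---------------------------------
# All generators use a local RNG scope: the caller's .Random.seed is restored.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(expr)
}

# resample a waypoint polyline at fixed arc-length spacing
resample_polyline <- function(pts, spacing) {
  seg <- sqrt(rowSums(diff(pts)^2))
  cum <- c(0, cumsum(seg))
  s <- seq(0, cum[length(cum)], by = spacing)
  t(vapply(s, function(si) {
    k <- findInterval(si, cum, rightmost.closed = TRUE)
    k <- min(k, nrow(pts) - 1L)
    w <- (si - cum[k]) / max(cum[k + 1] - cum[k], 1e-12)
    (1 - w) * pts[k, ] + w * pts[k + 1, ]
  }, numeric(3)))
}

#' Synthetic single- or multi-pierce lasso with known linking number
#'
#' Builds a protein-like Calpha curve (3.8 Angstrom spacing): a short leader,
#' a planar ring whose ends form the loop-closing contact, and a terminal
#' thread that pierces the ring plane `n_pierces` times in the same sense.
#' The analytic linking number of the construction is
#' `chirality * n_pierces` (before noise).
#'
#' @param loop_points number of ring residues (>= 12).
#' @param pierce_offset radial position of the pierce as a fraction of the
#'   ring radius (|offset| < 0.8).
#' @param n_pierces 1 or 2 same-sense passes through the ring.
#' @param chirality +1 or -1 (sign of the planted linking number).
#' @param tail `"C"` (thread at the C terminus) or `"N"`.
#' @param noise_sd Gaussian positional noise (Angstrom).
#' @param seed RNG seed (noise only).
#' @return list with `geometry` (a `chain_geometry`) and `truth` (list:
#'   `loop` = closing residue pair, `gln`, `tail`, `crossings` = planted
#'   pierce residues).
#' @export
make_lasso <- function(loop_points = 30L, pierce_offset = 0, n_pierces = 1L,
                       chirality = 1L, tail = c("C", "N"), noise_sd = 0,
                       seed = 1L) {
  tail <- match.arg(tail)
  stopifnot(loop_points >= 12, abs(pierce_offset) < 0.8, n_pierces %in% 1:2,
            chirality %in% c(-1L, 1L))
  b <- 3.8
  L <- as.integer(loop_points)
  R <- b / (2 * sin(pi / L))
  th <- 2 * pi * (seq_len(L) - 1L) / L
  ring <- cbind(R * cos(th), R * sin(th), 0)
  leader <- cbind(R + b * (6:1), 0, 0)
  A <- ring[L, ]
  ahat <- A[1:2] / sqrt(sum(A[1:2]^2))
  Zp <- 2.5 * R
  px <- pierce_offset * R
  wp <- rbind(A,
              c(1.6 * R * ahat, -3),
              c(2.5 * R * ahat, -Zp),
              c(px, -0.3 * R, -Zp),
              c(px, 0, -Zp),
              c(px, 0, Zp))
  if (n_pierces == 2L) {
    px2 <- px - 0.25 * R
    wp <- rbind(wp,
                c(px, 1.8 * R, Zp),
                c(2.6 * R, 1.8 * R, Zp),
                c(2.6 * R, 0, -Zp),
                c(px2, -0.3 * R, -Zp),
                c(px2, 0, -Zp),
                c(px2, 0, Zp))
  }
  wp <- rbind(wp, c(3.2 * R, 0, Zp), c(3.2 * R + 6 * b, 0, Zp))
  # chirality -1: thread passes downward instead of upward
  wp[, 3] <- wp[, 3] * chirality
  thread <- resample_polyline(wp, b)[-1, , drop = FALSE]
  pts <- rbind(leader, ring, thread)
  loop <- c(nrow(leader) + 1L, nrow(leader) + L)
  # planted crossings: thread bonds straddling z = 0 inside the ring
  toff <- nrow(leader) + L
  zz <- thread[, 3]
  rr <- sqrt(thread[, 1]^2 + thread[, 2]^2)
  cross <- which(zz[-length(zz)] * zz[-1] < 0 & rr[-length(zz)] < R)
  crossings <- toff + cross
  if (tail == "N") {     # reverse the chain: thread becomes the N terminus
    n <- nrow(pts)
    pts <- pts[n:1, , drop = FALSE]
    loop <- sort(n + 1L - loop)
    crossings <- sort(n + 1L - crossings)
  }
  pts <- with_seed(seed, pts + matrix(stats::rnorm(length(pts), 0, noise_sd),
                                      ncol = 3))
  list(geometry = chain_geometry(pts),
       truth = list(loop = loop, gln = as.integer(chirality * n_pierces),
                    tail = tail, crossings = crossings))
}

#' Synthetic four-helix bundle with secondary-structure elements
#'
#' An idealised antiparallel four-helix bundle (helix radius 2.3 A, rise
#' 1.5 A/residue, 100 degrees/residue) whose helices are the
#' secondary-structure elements; adjacent helices are in native contact,
#' giving well-defined Q and K references.
#'
#' @param helix_len residues per helix.
#' @param loop_len residues per connecting loop.
#' @param axis_sep helix axis separation (Angstrom).
#' @return list with `geometry` (a `chain_geometry`) and `ss`
#'   (`secondary_elements`).
#' @export
make_helix_bundle <- function(helix_len = 12L, loop_len = 4L, axis_sep = 9) {
  centers <- rbind(c(0, 0), c(axis_sep, 0), c(axis_sep, axis_sep), c(0, axis_sep))
  omega <- 100 * pi / 180
  pts <- NULL
  ss <- data.frame(start = integer(), end = integer(), type = character())
  idx <- 0L
  for (h in 1:4) {
    tpar <- seq_len(helix_len) - 1L
    z <- if (h %% 2 == 1) 1.5 * tpar else 1.5 * (helix_len - 1L - tpar)
    hx <- cbind(centers[h, 1] + 2.3 * cos(omega * tpar),
                centers[h, 2] + 2.3 * sin(omega * tpar), z)
    # tilt each helix axis off the bundle axis (supercoil-like packing) so
    # that inter-element chirality signs are well defined (non-collinear axes)
    ang <- (if (h <= 2) 1 else -1) * 12 * pi / 180
    rot <- if (h %% 2 == 1)
      rbind(c(1, 0, 0), c(0, cos(ang), -sin(ang)), c(0, sin(ang), cos(ang)))
    else
      rbind(c(cos(ang), 0, sin(ang)), c(0, 1, 0), c(-sin(ang), 0, cos(ang)))
    ctr <- colMeans(hx)
    hx <- sweep(sweep(hx, 2, ctr) %*% t(rot), 2, ctr, "+")
    ss <- rbind(ss, data.frame(start = idx + 1L, end = idx + helix_len,
                               type = "helix"))
    pts <- rbind(pts, hx)
    idx <- idx + helix_len
    if (h < 4) {
      a <- pts[nrow(pts), ]; bb <- c(centers[h + 1, 1] + 2.3,
                                     centers[h + 1, 2],
                                     if (h %% 2 == 1) 1.5 * (helix_len - 1L) else 0)
      w <- seq_len(loop_len) / (loop_len + 1)
      lp <- t(sapply(w, function(wi) (1 - wi) * a + wi * bb))
      lp[, 3] <- lp[, 3] + 3           # arc the loop out of the helix layer
      pts <- rbind(pts, lp)
      idx <- idx + loop_len
    }
  }
  list(geometry = chain_geometry(pts), ss = secondary_elements(ss, n = nrow(pts)))
}

#' Interpolated toy trajectory between two conformations
#'
#' Frames move linearly from `start` to `end` with seeded Gaussian noise;
#' ground-truth per-frame mixing weights come from the noiseless
#' interpolant.
#'
#' @param start,end `chain_geometry` objects of equal length.
#' @param n_frames number of frames.
#' @param noise_sd positional noise (Angstrom).
#' @param seed RNG seed.
#' @return list with `traj` (a `trajectory`) and `truth` (data.frame
#'   `frame`, `weight_end`).
#' @export
make_trajectory <- function(start, end, n_frames = 100L, noise_sd = 0.1,
                            seed = 1L) {
  x0 <- start$xyz; x1 <- end$xyz
  stopifnot(nrow(x0) == nrow(x1))
  w <- if (n_frames == 1L) 1 else (seq_len(n_frames) - 1L) / (n_frames - 1L)
  arr <- array(NA_real_, c(n_frames, nrow(x0), 3))
  noise <- with_seed(seed, array(stats::rnorm(n_frames * length(x0), 0, noise_sd),
                                 c(n_frames, nrow(x0), 3)))
  for (f in seq_len(n_frames))
    arr[f, , ] <- (1 - w[f]) * x0 + w[f] * x1 + noise[f, , ]
  list(traj = trajectory_handle(arr),
       truth = data.frame(frame = seq_len(n_frames), weight_end = w))
}

#' Synthetic LiP/XL signal tables with paired structural ensembles
#'
#' Peptide abundances are log-normal in two conditions with planted effects;
#' per-site q-values come from Welch tests with Benjamini-Hochberg
#' correction. The paired Calpha frame ensembles realise the planted
#' accessibility changes geometrically: in the "misfolded" ensemble the
#' residues around each planted cut-site are displaced away from the chain
#' body, raising their SASA.
#'
#' @param n_sites number of cut-sites.
#' @param planted_effects numeric vector (length `n_sites`) of planted
#'   log-abundance shifts (0 = null site).
#' @param n_frames_per_ensemble frames per ensemble.
#' @param n_res chain length of the toy structures.
#' @param n_reps abundance replicates per condition.
#' @param displacement outward displacement (Angstrom) realising a planted
#'   site's accessibility change; the default realises a roughly
#'   3-pooled-SD shift of the windowed SASA feature under the default frame
#'   noise.
#' @param seed RNG seed.
#' @return list with `lip` (data.frame `cutsite`, `effect`, `p`, `q_value`),
#'   `cutsites` (planted site residues), `native` and `misfolded`
#'   (`trajectory` ensembles) and `truth`.
#' @export
make_ms_tables <- function(n_sites = 6L, planted_effects = c(2, rep(0, 5)),
                           n_frames_per_ensemble = 50L, n_res = 60L,
                           n_reps = 6L, displacement = 5, seed = 1L) {
  stopifnot(length(planted_effects) == n_sites, all(is.finite(planted_effects)))
  with_seed(seed, {
    sites <- sort(sample(seq(8L, n_res - 8L), n_sites))
    base <- stats::rnorm(n_sites, mean = 20, sd = 1)
    untreated <- matrix(stats::rnorm(n_sites * n_reps, base, 0.5), n_sites)
    treated <- matrix(stats::rnorm(n_sites * n_reps, base + planted_effects, 0.5),
                      n_sites)
    p <- vapply(seq_len(n_sites), function(s)
      stats::t.test(exp(treated[s, ] / 10), exp(untreated[s, ] / 10))$p.value,
      numeric(1))
    q <- stats::p.adjust(p, "BH")
    # compact base chain: tightly wound coil so window residues start partly
    # buried and the planted displacement genuinely changes their exposure
    t0 <- seq_len(n_res) - 1L
    base_xyz <- cbind(4 * cos(0.9 * t0), 4 * sin(0.9 * t0), 0.45 * t0)
    mis_xyz <- base_xyz
    for (s in which(planted_effects != 0)) {
      win <- max(1L, sites[s] - 5L):min(n_res, sites[s] + 5L)
      dir <- base_xyz[sites[s], ] - colMeans(base_xyz)
      dir <- dir / sqrt(sum(dir^2))
      mis_xyz[win, ] <- sweep(base_xyz[win, , drop = FALSE], 2,
                              displacement * dir, "+")
    }
    mk_ens <- function(xyz, sd_ens) {
      arr <- array(stats::rnorm(n_frames_per_ensemble * length(xyz), 0, sd_ens),
                   c(n_frames_per_ensemble, n_res, 3))
      for (f in seq_len(n_frames_per_ensemble)) arr[f, , ] <- arr[f, , ] + xyz
      trajectory_handle(arr)
    }
    native <- mk_ens(base_xyz, 0.6)
    misfolded <- mk_ens(mis_xyz, 0.6)
    list(lip = data.frame(cutsite = sites, effect = planted_effects, p = p,
                          q_value = q),
         cutsites = sites,
         native = native, misfolded = misfolded,
         truth = list(planted = sites[planted_effects != 0]))
  })
}

#' Synthetic proteome of residue evidence tables with planted effects
#'
#' Each protein gets a planted entangled region (contiguous interval) and
#' Bernoulli responses with `logit p = beta0 + beta_region * region`.
#' `beta_region` may be a single value or a per-protein vector (planted
#' subpopulations).
#'
#' @param n_proteins number of proteins (>= 10).
#' @param length_range residue-count range per protein.
#' @param beta_region planted region log-odds (scalar or per-protein).
#' @param beta0 baseline log-odds (default -2.5).
#' @param seed RNG seed.
#' @return list with `tables` (named list of residue evidence tables) and
#'   `truth` (data.frame `protein`, `beta_region`).
#' @export
make_proteome <- function(n_proteins = 40L, length_range = c(300L, 600L),
                          beta_region = 1, beta0 = -2.5, seed = 1L) {
  stopifnot(n_proteins >= 10)
  beta_region <- rep(beta_region, length.out = n_proteins)
  with_seed(seed, {
    tables <- list()
    for (p in seq_len(n_proteins)) {
      n <- sample(length_range[1]:length_range[2], 1)
      reg_len <- round(0.35 * n)
      reg_start <- sample(seq_len(n - reg_len), 1)
      region <- integer(n)
      region[reg_start:(reg_start + reg_len - 1L)] <- 1L
      eta <- beta0 + beta_region[p] * region
      response <- stats::rbinom(n, 1, 1 / (1 + exp(-eta)))
      tables[[sprintf("prot%03d", p)]] <-
        data.frame(protein_id = sprintf("prot%03d", p),
                   residue_index = seq_len(n), response = response,
                   region = region, amino_acid = sample(c("A", "L", "G", "S"),
                                                        n, replace = TRUE),
                   rel_sasa = stats::runif(n), mask = 1L)
    }
    list(tables = tables,
         truth = data.frame(protein = names(tables), beta_region = beta_region))
  })
}
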