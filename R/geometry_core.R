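# ---- discrete Gauss linking ------------------------------------------------

#' Discrete Gauss linking double sum between two open polylines
#'
#' Each curve is discretised by its vertex list; segment a is represented by
#' its midpoint R_a = (r_a + r_{a+1})/2 and bond vector dR_a = r_{a+1} - r_a.
#' The value returned is
#' \deqn{g = \frac{1}{4\pi} \sum_a \sum_b
#'   \frac{R_a - R_b}{|R_a - R_b|^3} \cdot (dR_a \times dR_b)}
#' which approximates the Gauss linking integral of the two curves.
#'
#' @param xyz1,xyz2 numeric matrices (n x 3) of curve vertices, in Angstrom.
#' @return scalar linking value.
#' @keywords internal
gauss_double_sum <- function(xyz1, xyz2) {
  n1 <- nrow(xyz1) - 1L
  n2 <- nrow(xyz2) - 1L
  if (n1 < 1L || n2 < 1L) return(0)
  m1 <- (xyz1[-1L, , drop = FALSE] + xyz1[-nrow(xyz1), , drop = FALSE]) / 2
  b1 <- xyz1[-1L, , drop = FALSE] - xyz1[-nrow(xyz1), , drop = FALSE]
  m2 <- (xyz2[-1L, , drop = FALSE] + xyz2[-nrow(xyz2), , drop = FALSE]) / 2
  b2 <- xyz2[-1L, , drop = FALSE] - xyz2[-nrow(xyz2), , drop = FALSE]
  if (any(rowSums(b1^2) == 0) || any(rowSums(b2^2) == 0))
    stop("degenerate (zero-length) bond in curve discretisation")
  # pairwise difference tensors, flattened to (n1*n2) x 3
  dx <- outer(m1[, 1], m2[, 1], "-")
  dy <- outer(m1[, 2], m2[, 2], "-")
  dz <- outer(m1[, 3], m2[, 3], "-")
  r3 <- (dx * dx + dy * dy + dz * dz)^1.5
  # cross products c_ab = b1_a x b2_b, componentwise outer products
  cx <- outer(b1[, 2], b2[, 3]) - outer(b1[, 3], b2[, 2])
  cy <- outer(b1[, 3], b2[, 1]) - outer(b1[, 1], b2[, 3])
  cz <- outer(b1[, 1], b2[, 2]) - outer(b1[, 2], b2[, 1])
  sum((dx * cx + dy * cy + dz * cz) / r3) / (4 * pi)
}

#' Partial Gauss linking value g(i,j,m,k)
#'
#' Linking between the backbone loop spanned by residues `i..j` (closed by the
#' virtual segment from residue j back to residue i) and the open tail segment
#' spanned by residues `m..k`, evaluated on the Calpha trace.
#'
#' The value is invariant under rigid rotation and translation and flips sign
#' under mirror reflection.
#'
#' @param xyz numeric N x 3 matrix of Calpha coordinates (Angstrom), rows in
#'   internal residue order.
#' @param loop integer pair `c(i, j)`, i < j, the loop-closing contact.
#' @param tail integer pair `c(m, k)`, m < k, the thread segment; must not
#'   overlap the loop range.
#' @return scalar partial linking value.
#' @examples
#' ring <- t(sapply(seq(0, 2 * pi, length.out = 21)[-21],
#'                  function(a) c(10 * cos(a), 10 * sin(a), 0)))
#' line <- cbind(0, 0, seq(-40, 40, length.out = 30))
#' xyz <- rbind(ring, line)
#' abs(partial_linking(xyz, c(1, 20), c(21, 50)))  # ~1
#' @export
partial_linking <- function(xyz, loop, tail) {
  i <- loop[1]; j <- loop[2]; m <- tail[1]; k <- tail[2]
  stopifnot(i < j, m < k, j - i >= 1, k - m >= 1)
  if (m <= j && k >= i) stop("loop and tail ranges overlap")
  loop_xyz <- xyz[i:j, , drop = FALSE]
  loop_xyz <- rbind(loop_xyz, loop_xyz[1L, ])   # close with virtual j -> i
  tail_xyz <- xyz[m:k, , drop = FALSE]
  gauss_double_sum(loop_xyz, tail_xyz)
}

#' Round a partial linking value to a Gauss linking number
#'
#' Uses the modified rounding rule in which the fractional part is rounded up
#' only when its absolute value reaches 0.6 (rather than the conventional 0.5),
#' consistent with the |g| >= 0.6 presence criterion for an entanglement.
#' A remainder of exactly 0.6 rounds away from zero.
#'
#' @param g numeric vector of linking values.
#' @param threshold fractional rounding threshold (default 0.6).
#' @return integer vector of rounded linking numbers.
#' @examples
#' round_linking(c(0.59, 0.61, -0.61, 1.65, 1.55))  # 0 1 -1 2 1
#' @export
round_linking <- function(g, threshold = 0.6) {
  stopifnot(all(is.finite(g)))
  a <- abs(g)
  as.integer(sign(g) * (floor(a) + as.integer(a - floor(a) >= threshold)))
}

# ---- native contacts -------------------------------------------------------

#' Find native contacts in a single conformation
#'
#' A residue pair (i, j) with j - i >= `min_loop_sep` is a contact when the
#' Calpha-Calpha distance is <= 8 Angstrom (`calpha_8A`) or when the minimum
#' distance over all heavy-atom pairs is <= 4.5 Angstrom (`heavy_4p5A`).
#' Heavy mode falls back to Calpha mode, with a warning, when the geometry
#' carries no heavy atoms and `fallback = TRUE`.
#'
#' @param geometry a `chain_geometry` (see [read_structure()]).
#' @param mode contact definition, `"calpha_8A"` or `"heavy_4p5A"`.
#' @param min_loop_sep minimum sequence separation j - i (default 10, suited
#'   to entanglement loops; use 3 for Q-style contacts).
#' @param fallback silently degrade heavy mode to Calpha mode when no heavy
#'   atoms are present.
#' @return data.frame with columns `i`, `j`, `dist` (the native distance used
#'   by the criterion) and attribute `mode`.
#' @export
find_contacts <- function(geometry, mode = c("calpha_8A", "heavy_4p5A"),
                          min_loop_sep = 10, fallback = TRUE) {
  mode <- match.arg(mode)
  stopifnot(min_loop_sep >= 1)
  xyz <- geometry$xyz
  n <- nrow(xyz)
  cutoff <- if (mode == "calpha_8A") 8 else 4.5
  if (mode == "heavy_4p5A" &&
      (is.null(geometry$heavy) || all(vapply(geometry$heavy, is.null, TRUE)))) {
    if (!fallback) stop("heavy-atom contact mode requested but geometry has no heavy atoms")
    warning("no heavy atoms present; falling back to calpha_8A contacts")
    mode <- "calpha_8A"; cutoff <- 8
  }
  d <- as.matrix(stats::dist(xyz))
  idx <- which(upper.tri(d), arr.ind = TRUE)
  sep_ok <- idx[, 2] - idx[, 1] >= min_loop_sep
  idx <- idx[sep_ok, , drop = FALSE]
  if (mode == "calpha_8A") {
    keep <- d[idx] <= cutoff
    out <- data.frame(i = idx[keep, 1], j = idx[keep, 2], dist = d[idx[keep, , drop = FALSE]])
  } else {
    # prefilter by Calpha distance using the largest heavy-atom offset present
    max_off <- max(vapply(seq_len(n), function(r) {
      h <- geometry$heavy[[r]]
      if (is.null(h) || nrow(h) == 0) return(0)
      sqrt(max(rowSums(sweep(h, 2, xyz[r, ])^2)))
    }, numeric(1)))
    cand <- idx[d[idx] <= cutoff + 2 * max_off, , drop = FALSE]
    hv <- geometry$heavy
    keep <- logical(nrow(cand)); hdist <- numeric(nrow(cand))
    for (r in seq_len(nrow(cand))) {
      a <- hv[[cand[r, 1]]]; b <- hv[[cand[r, 2]]]
      if (is.null(a) || is.null(b)) next
      dd <- sqrt(outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b))
      hdist[r] <- min(dd)
      keep[r] <- hdist[r] <= cutoff
    }
    out <- data.frame(i = cand[keep, 1], j = cand[keep, 2], dist = hdist[keep])
  }
  out <- out[order(out$i, out$j), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "mode") <- mode
  out
}

# ---- NCLE detection --------------------------------------------------------

new_ncle <- function(loop, tail, g_N, g_C, gln_N, gln_C,
                     crossings = data.frame(residue = integer(), chirality = integer(),
                                            tail = character())) {
  structure(list(loop = as.integer(loop), tail = tail,
                 g_N = g_N, g_C = g_C,
                 gln_N = as.integer(gln_N), gln_C = as.integer(gln_C),
                 crossings = crossings),
            class = "ncle")
}

#' @export
print.ncle <- function(x, ...) {
  cr <- if (nrow(x$crossings)) paste(sprintf("%+d*%d", x$crossings$chirality,
                                             x$crossings$residue), collapse = ";") else "-"
  cat(sprintf("NCLE loop (%d,%d) tail %s  g_N=%.3f g_C=%.3f  gln=(%d,%d)  crossings: %s\n",
              x$loop[1], x$loop[2], x$tail, x$g_N, x$g_C, x$gln_N, x$gln_C, cr))
  invisible(x)
}

#' Tail windows admissible for a loop-closing contact
#'
#' The first and last 5 residues of the chain are ignored, as are the 4
#' residues immediately preceding the first loop residue and immediately
#' following the last: the N tail is `[6, i-5]` and the C tail `[j+5, N-5]`.
#' Tails spanning fewer than two residues are empty (NULL).
#' @keywords internal
tail_windows <- function(i, j, n, exclude_end = 5L, exclude_loop = 4L) {
  nt <- c(exclude_end + 1L, i - exclude_loop - 1L)
  ct <- c(j + exclude_loop + 1L, n - exclude_end)
  list(N = if (nt[2] - nt[1] >= 1L) nt else NULL,
       C = if (ct[2] - ct[1] >= 1L) ct else NULL)
}

#' Detect non-covalent lasso entanglements in a single conformation
#'
#' For every loop-closing contact (i, j) the partial linking value of the loop
#' against the admissible N- and C-terminal tails is computed; a record is
#' emitted when at least one tail has |g| >= `g_threshold`. Crossing residues
#' are localised on each entangled tail with [find_crossings()].
#'
#' @param geometry a `chain_geometry`.
#' @param contacts optional precomputed contact table from [find_contacts()];
#'   computed with defaults (`mode`, `min_loop_sep = 10`) when NULL.
#' @param mode contact mode passed to [find_contacts()] when `contacts` is NULL.
#' @param g_threshold entanglement presence threshold on |g| (default 0.6).
#' @param exclude_end residues ignored at each chain terminus (default 5).
#' @param exclude_loop residues ignored on each side of the loop-closing
#'   contact (default 4).
#' @param crossing_method `"surface"` (loop-surface tessellation, default) or
#'   `"sliding"` (15-residue window scan).
#' @param min_cross_sep minimum residue separation between accepted crossings
#'   and from the loop-closing residues (default 10).
#' @param compute_crossings localise crossings (set FALSE for speed when only
#'   linking statuses are needed).
#' @return list of `ncle` records (possibly empty), class `ncle_list`.
#' @export
detect_ncles <- function(geometry, contacts = NULL, mode = "calpha_8A",
                         g_threshold = 0.6, exclude_end = 5L, exclude_loop = 4L,
                         crossing_method = c("surface", "sliding"),
                         min_cross_sep = 10L, compute_crossings = TRUE) {
  crossing_method <- match.arg(crossing_method)
  xyz <- geometry$xyz
  n <- nrow(xyz)
  if (is.null(contacts)) contacts <- find_contacts(geometry, mode = mode)
  out <- list()
  if (n < 12L || nrow(contacts) == 0L) return(structure(out, class = "ncle_list"))
  ord <- order(contacts$i, contacts$j)   # deterministic, order-independent
  contacts <- contacts[ord, , drop = FALSE]
  for (r in seq_len(nrow(contacts))) {
    i <- contacts$i[r]; j <- contacts$j[r]
    tw <- tail_windows(i, j, n, exclude_end, exclude_loop)
    g_N <- if (!is.null(tw$N)) partial_linking(xyz, c(i, j), tw$N) else 0
    g_C <- if (!is.null(tw$C)) partial_linking(xyz, c(i, j), tw$C) else 0
    ent_N <- abs(g_N) >= g_threshold
    ent_C <- abs(g_C) >= g_threshold
    if (!ent_N && !ent_C) next
    tail_lab <- if (ent_N && ent_C) "both" else if (ent_N) "N" else "C"
    cr <- data.frame(residue = integer(), chirality = integer(), tail = character())
    if (compute_crossings) {
      if (ent_N) {
        cN <- find_crossings(xyz, c(i, j), tw$N, method = crossing_method,
                             g_threshold = g_threshold, min_cross_sep = min_cross_sep)
        if (nrow(cN)) cr <- rbind(cr, cbind(cN, tail = "N"))
      }
      if (ent_C) {
        cC <- find_crossings(xyz, c(i, j), tw$C, method = crossing_method,
                             g_threshold = g_threshold, min_cross_sep = min_cross_sep)
        if (nrow(cC)) cr <- rbind(cr, cbind(cC, tail = "C"))
      }
    }
    out[[length(out) + 1L]] <- new_ncle(c(i, j), tail_lab, g_N, g_C,
                                        round_linking(g_N, g_threshold),
                                        round_linking(g_C, g_threshold), cr)
  }
  structure(out, class = "ncle_list")
}

#' Flatten a list of NCLE records to a data.frame
#'
#' @param x `ncle_list` from [detect_ncles()].
#' @param geometry optional `chain_geometry`; when given, author-numbered
#'   mirrors of all residue indices are appended.
#' @param ... unused.
#' @export
as.data.frame.ncle_list <- function(x, geometry = NULL, ...) {
  if (length(x) == 0L)
    return(data.frame(i = integer(), j = integer(), tail = character(),
                      g_N = numeric(), g_C = numeric(),
                      gln_N = integer(), gln_C = integer(), crossings = character()))
  df <- do.call(rbind, lapply(x, function(e) {
    cr <- if (nrow(e$crossings))
      paste0(ifelse(e$crossings$chirality > 0, "+", "-"), e$crossings$residue,
             collapse = ";") else ""
    data.frame(i = e$loop[1], j = e$loop[2], tail = e$tail,
               g_N = e$g_N, g_C = e$g_C, gln_N = e$gln_N, gln_C = e$gln_C,
               crossings = cr)
  }))
  if (!is.null(geometry)) {
    df$author_i <- geometry$author_resid[df$i]
    df$author_j <- geometry$author_resid[df$j]
  }
  rownames(df) <- NULL
  df
}

# ---- crossing localisation -------------------------------------------------

#' Localise crossing residues of an entangled tail
#'
#' `surface` mode fan-triangulates the loop polygon (residues i..j plus the
#' virtual closing segment) about its vertex centroid and intersects every
#' tail bond with every triangle; a piercing bond yields a crossing residue
#' whose chirality is the sign of the bond direction against the oriented
#' triangle normal. `sliding` mode scans |g(loop, w..w+14)| over 15-residue
#' windows along the tail and reports local maxima above `g_threshold`, with
#' chirality from the window's g sign.
#'
#' Crossings closer than `min_cross_sep` residues to an already accepted
#' crossing are merged into it when the chirality agrees and cancelled (both
#' dropped) when it is opposite; crossings within `min_cross_sep` residues of a
#' loop-closing residue are discarded.
#'
#' @inheritParams partial_linking
#' @param method `"surface"` or `"sliding"`.
#' @param window sliding-window width in residues (default 15).
#' @param g_threshold window-presence threshold for sliding mode.
#' @param min_cross_sep merge/exclusion distance in residues (default 10).
#' @return data.frame with columns `residue`, `chirality`.
#' @export
find_crossings <- function(xyz, loop, tail, method = c("surface", "sliding"),
                           window = 15L, g_threshold = 0.6, min_cross_sep = 10L) {
  method <- match.arg(method)
  raw <- if (method == "surface") crossings_surface(xyz, loop, tail)
         else crossings_sliding(xyz, loop, tail, window, g_threshold)
  prune_crossings(raw, loop, min_cross_sep)
}

crossings_sliding <- function(xyz, loop, tail, window = 15L, g_threshold = 0.6) {
  m <- tail[1]; k <- tail[2]
  starts <- m:max(m, k - window + 1L)
  ends <- pmin(starts + window - 1L, k)
  keep <- ends - starts >= 1L
  starts <- starts[keep]; ends <- ends[keep]
  gw <- vapply(seq_along(starts), function(s)
    partial_linking(xyz, loop, c(starts[s], ends[s])), numeric(1))
  ag <- abs(gw)
  res <- integer(); chir <- integer()
  for (s in seq_along(ag)) {
    if (ag[s] < g_threshold) next
    lo <- max(1L, s - 1L); hi <- min(length(ag), s + 1L)
    if (ag[s] >= max(ag[lo:hi])) {             # local maximum (plateau-tolerant)
      if (s > 1L && ag[s] == ag[s - 1L]) next  # keep first of a plateau
      res <- c(res, as.integer(round((starts[s] + ends[s]) / 2)))
      chir <- c(chir, as.integer(sign(gw[s])))
    }
  }
  data.frame(residue = res, chirality = chir)
}

crossings_surface <- function(xyz, loop, tail, jitter = 1e-3, .retry = TRUE) {
  i <- loop[1]; j <- loop[2]
  poly <- xyz[i:j, , drop = FALSE]
  centroid <- colMeans(poly)
  nv <- nrow(poly)
  res <- integer(); chir <- integer()
  for (b in tail[1]:(tail[2] - 1L)) {
    p <- xyz[b, ]; q <- xyz[b + 1L, ]
    sgn_sum <- 0L
    for (t in seq_len(nv)) {         # triangle (centroid, poly[t], poly[t+1]); wraps over closure
      v1 <- poly[t, ]; v2 <- poly[if (t == nv) 1L else t + 1L, ]
      hit <- segment_triangle_hit(p, q, centroid, v1, v2)
      if (is.na(hit)) {
        if (!.retry) stop("degenerate triangle in loop-surface tessellation")
        xyz2 <- xyz
        xyz2[i:j, ] <- sweep(poly, 2, jitter * stats::rnorm(3), "+")
        return(crossings_surface(xyz2, loop, tail, jitter, .retry = FALSE))
      }
      sgn_sum <- sgn_sum + hit
    }
    if (sgn_sum != 0L) {
      res <- c(res, b)
      chir <- c(chir, as.integer(sign(sgn_sum)))
    }
  }
  data.frame(residue = res, chirality = chir)
}

# Moeller-Trumbore segment/triangle intersection; returns +1/-1 for a piercing
# (sign = orientation of the segment against the triangle normal), 0 for a
# miss, NA for a degenerate triangle.
segment_triangle_hit <- function(p, q, a, b, cc, eps = 1e-12) {
  dir <- q - p
  e1 <- b - a; e2 <- cc - a
  h <- c(dir[2] * e2[3] - dir[3] * e2[2],
         dir[3] * e2[1] - dir[1] * e2[3],
         dir[1] * e2[2] - dir[2] * e2[1])
  det <- sum(e1 * h)
  if (sum(e1 * e1) < eps || sum(e2 * e2) < eps) return(NA_integer_)
  if (abs(det) < eps) return(0L)       # parallel or grazing: treat as miss
  s <- p - a
  u <- sum(s * h) / det
  if (u < 0 || u > 1) return(0L)
  qv <- c(s[2] * e1[3] - s[3] * e1[2],
          s[3] * e1[1] - s[1] * e1[3],
          s[1] * e1[2] - s[2] * e1[1])
  v <- sum(dir * qv) / det
  if (v < 0 || u + v > 1) return(0L)
  tt <- sum(e2 * qv) / det
  if (tt < 0 || tt > 1) return(0L)
  # orientation: sign of dir . (e1 x e2)
  nrm <- c(e1[2] * e2[3] - e1[3] * e2[2],
           e1[3] * e2[1] - e1[1] * e2[3],
           e1[1] * e2[2] - e1[2] * e2[1])
  as.integer(sign(sum(dir * nrm)))
}

prune_crossings <- function(cr, loop, min_cross_sep) {
  if (nrow(cr) == 0L) return(cr)
  cr <- cr[order(cr$residue), , drop = FALSE]
  near_loop <- abs(cr$residue - loop[1]) < min_cross_sep |
               abs(cr$residue - loop[2]) < min_cross_sep
  cr <- cr[!near_loop, , drop = FALSE]
  keep_res <- integer(); keep_chir <- integer()
  for (r in seq_len(nrow(cr))) {
    if (length(keep_res) && cr$residue[r] - keep_res[length(keep_res)] < min_cross_sep) {
      if (cr$chirality[r] == keep_chir[length(keep_chir)]) next          # merge
      keep_res <- keep_res[-length(keep_res)]                            # cancel pair
      keep_chir <- keep_chir[-length(keep_chir)]
      next
    }
    keep_res <- c(keep_res, cr$residue[r])
    keep_chir <- c(keep_chir, cr$chirality[r])
  }
  data.frame(residue = keep_res, chirality = keep_chir)
}
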