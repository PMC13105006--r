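# Independent oracles, deliberately written differently from the package
# implementations they cross-check.

# Linear densification of a polyline: `factor` subdivisions per segment.
densify_polyline <- function(pts, factor = 10L) {
  out <- NULL
  for (k in seq_len(nrow(pts) - 1L)) {
    w <- seq(0, 1, length.out = factor + 1L)[-(factor + 1L)]
    out <- rbind(out, outer(1 - w, pts[k, ]) + outer(w, pts[k + 1L, ]))
  }
  rbind(out, pts[nrow(pts), , drop = FALSE])
}

# Dense-discretisation Gauss linking oracle: plain per-segment accumulation
# over a `factor`-times denser linear resampling of both curves.
oracle_linking <- function(xyz, loop, tail, factor = 10L) {
  loop_pts <- xyz[loop[1]:loop[2], , drop = FALSE]
  loop_pts <- rbind(loop_pts, loop_pts[1L, ])
  tail_pts <- xyz[tail[1]:tail[2], , drop = FALSE]
  c1 <- densify_polyline(loop_pts, factor)
  c2 <- densify_polyline(tail_pts, factor)
  mid2 <- (c2[-1, , drop = FALSE] + c2[-nrow(c2), , drop = FALSE]) / 2
  db2 <- c2[-1, , drop = FALSE] - c2[-nrow(c2), , drop = FALSE]
  acc <- 0
  for (a in seq_len(nrow(c1) - 1L)) {
    ra <- (c1[a, ] + c1[a + 1L, ]) / 2
    da <- c1[a + 1L, ] - c1[a, ]
    diff <- sweep(mid2, 2, ra, FUN = function(x, y) y - x)
    cr <- cbind(da[2] * db2[, 3] - da[3] * db2[, 2],
                da[3] * db2[, 1] - da[1] * db2[, 3],
                da[1] * db2[, 2] - da[2] * db2[, 1])
    acc <- acc + sum(rowSums(diff * cr) / rowSums(diff^2)^1.5)
  }
  acc / (4 * pi)
}

# Textbook Benjamini-Hochberg step-up: reject H_(1..k*) where k* is the
# largest k with p_(k) <= k/m * alpha.
bh_reject_oracle <- function(p, alpha = 0.05) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  k <- which(ps <= seq_len(m) / m * alpha)
  rej <- logical(m)
  if (length(k)) rej[ord[seq_len(max(k))]] <- TRUE
  rej
}

# Adjusted Rand index between two label vectors.
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  exp_idx <- si * sj / n2
  (sij - exp_idx) / ((si + sj) / 2 - exp_idx)
}

# Cluster purity of `labels` against ground-truth `truth`.
cluster_purity <- function(labels, truth) {
  sum(vapply(split(truth, labels), function(tt) max(table(tt)), numeric(1))) /
    length(truth)
}
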