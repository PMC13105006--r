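# ---- order parameters Q, G, K ---------------------------------------------

#' Native contacts used by the Q order parameter
#'
#' Calpha pairs within 8 Angstrom in the reference, with both residues inside
#' secondary-structure elements and sequence separation >= 3.
#'
#' @param reference a `chain_geometry` (the native state).
#' @param ss a `secondary_elements` table.
#' @param cutoff native-contact distance cutoff (Angstrom).
#' @param min_sep minimum sequence separation.
#' @return data.frame `i`, `j`, `dist`.
#' @export
native_contacts_q <- function(reference, ss, cutoff = 8, min_sep = 3) {
  in_ss <- rep(FALSE, nrow(reference$xyz))
  for (r in seq_len(nrow(ss))) in_ss[ss$start[r]:ss$end[r]] <- TRUE
  ct <- find_contacts(reference, mode = "calpha_8A", min_loop_sep = min_sep)
  ct <- ct[in_ss[ct$i] & in_ss[ct$j] & ct$dist <= cutoff, , drop = FALSE]
  rownames(ct) <- NULL
  ct
}

#' Fraction of native contacts Q
#'
#' A native contact is formed in the frame when its Calpha distance is within
#' `tol` times the native distance (default 1.2x).
#'
#' @param frame N x 3 coordinate matrix.
#' @param reference a `chain_geometry`.
#' @param ss `secondary_elements`; ignored when `contacts` is supplied.
#' @param contacts optional precomputed table from [native_contacts_q()].
#' @param tol formed-contact tolerance factor.
#' @return scalar Q in \[0, 1\].
#' @export
compute_Q <- function(frame, reference, ss = NULL, contacts = NULL, tol = 1.2) {
  if (is.null(contacts)) contacts <- native_contacts_q(reference, ss)
  if (nrow(contacts) == 0L) stop("no native contacts: Q undefined")
  stopifnot(nrow(frame) == nrow(reference$xyz))
  d <- sqrt(rowSums((frame[contacts$i, , drop = FALSE] -
                     frame[contacts$j, , drop = FALSE])^2))
  mean(d <= tol * contacts$dist)
}

#' Per-contact entanglement status (gln_N, gln_C) of a conformation
#'
#' @param xyz N x 3 Calpha coordinates.
#' @param contacts contact table (`i`, `j`).
#' @param exclude_end,exclude_loop exclusion buffers as in [detect_ncles()].
#' @param g_threshold rounding threshold passed to [round_linking()].
#' @return integer matrix (n_contacts x 2) with columns `gln_N`, `gln_C`.
#' @export
contact_linking_status <- function(xyz, contacts, exclude_end = 5L,
                                   exclude_loop = 4L, g_threshold = 0.6) {
  n <- nrow(xyz)
  st <- matrix(0L, nrow(contacts), 2, dimnames = list(NULL, c("gln_N", "gln_C")))
  for (r in seq_len(nrow(contacts))) {
    i <- contacts$i[r]; j <- contacts$j[r]
    tw <- tail_windows(i, j, n, exclude_end, exclude_loop)
    if (!is.null(tw$N))
      st[r, 1] <- round_linking(partial_linking(xyz, c(i, j), tw$N), g_threshold)
    if (!is.null(tw$C))
      st[r, 2] <- round_linking(partial_linking(xyz, c(i, j), tw$C), g_threshold)
  }
  st
}

#' Fraction of native contacts with changed entanglement status, G
#'
#' For every native contact the rounded linking-number pair (gln_N, gln_C) is
#' computed in the reference and in the frame with identical exclusion
#' buffers. A contact counts as changed only when it is formed in the frame
#' (Calpha distance <= `formed_cutoff`) and its status pair differs from the
#' reference; G is the changed count over the total number of native contacts,
#' so G = 0 both for the reference itself and for a fully extended chain.
#'
#' @param frame N x 3 coordinate matrix.
#' @param reference a `chain_geometry`.
#' @param contacts native contact table (typically [find_contacts()] on the
#'   reference with `min_loop_sep = 10`).
#' @param ref_status optional cached [contact_linking_status()] of the
#'   reference over `contacts`.
#' @param formed_cutoff frame distance below which a contact is formed (8 A).
#' @param ... exclusion-buffer settings forwarded to
#'   [contact_linking_status()].
#' @return list with `G` (scalar), `changed_contacts` (data.frame `i`, `j`,
#'   ref/frame gln columns) and `status` (the frame status matrix).
#' @export
compute_G <- function(frame, reference, contacts, ref_status = NULL,
                      formed_cutoff = 8, ...) {
  if (nrow(contacts) == 0L) stop("no native contacts: G undefined")
  stopifnot(nrow(frame) == nrow(reference$xyz))
  if (is.null(ref_status))
    ref_status <- contact_linking_status(reference$xyz, contacts, ...)
  d <- sqrt(rowSums((frame[contacts$i, , drop = FALSE] -
                     frame[contacts$j, , drop = FALSE])^2))
  formed <- d <= formed_cutoff
  frame_status <- matrix(0L, nrow(contacts), 2,
                         dimnames = list(NULL, c("gln_N", "gln_C")))
  if (any(formed))
    frame_status[formed, ] <- contact_linking_status(
      frame, contacts[formed, , drop = FALSE], ...)
  changed <- formed & (frame_status[, 1] != ref_status[, 1] |
                       frame_status[, 2] != ref_status[, 2])
  cc <- data.frame(i = contacts$i[changed], j = contacts$j[changed],
                   ref_gln_N = ref_status[changed, 1], ref_gln_C = ref_status[changed, 2],
                   frame_gln_N = frame_status[changed, 1],
                   frame_gln_C = frame_status[changed, 2])
  list(G = sum(changed) / nrow(contacts), changed_contacts = cc,
       status = frame_status)
}

#' Secondary-structure element pairs scored by the K order parameter
#'
#' Element pairs sharing at least one inter-element native contact, with the
#' reference chirality sign of each pair: sign\[(a x b) . d\] where a and b are
#' the elements' first-to-last Calpha axis vectors and d joins their
#' midpoints.
#'
#' @param reference a `chain_geometry`.
#' @param ss `secondary_elements`.
#' @return data.frame `e1`, `e2`, `ref_sign`.
#' @export
element_pairs_k <- function(reference, ss) {
  ct <- native_contacts_q(reference, ss, min_sep = 1)
  el_of <- rep(NA_integer_, nrow(reference$xyz))
  for (r in seq_len(nrow(ss))) el_of[ss$start[r]:ss$end[r]] <- r
  ei <- el_of[ct$i]; ej <- el_of[ct$j]
  ok <- !is.na(ei) & !is.na(ej) & ei != ej
  pr <- unique(data.frame(e1 = pmin(ei[ok], ej[ok]), e2 = pmax(ei[ok], ej[ok])))
  if (nrow(pr) == 0L) stop("no secondary-structure element pairs in contact")
  pr$ref_sign <- vapply(seq_len(nrow(pr)), function(r)
    pair_chirality_sign(reference$xyz, ss, pr$e1[r], pr$e2[r]), numeric(1))
  # a zero sign (coplanar or parallel axes) carries no handedness to preserve
  pr <- pr[pr$ref_sign != 0, , drop = FALSE]
  if (nrow(pr) == 0L)
    stop("no element pairs with defined packing chirality")
  pr[order(pr$e1, pr$e2), , drop = FALSE]
}

pair_chirality_sign <- function(xyz, ss, e1, e2) {
  a <- xyz[ss$end[e1], ] - xyz[ss$start[e1], ]
  b <- xyz[ss$end[e2], ] - xyz[ss$start[e2], ]
  m1 <- (xyz[ss$start[e1], ] + xyz[ss$end[e1], ]) / 2
  m2 <- (xyz[ss$start[e2], ] + xyz[ss$end[e2], ]) / 2
  d <- m2 - m1
  cx <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
          a[1] * b[2] - a[2] * b[1])
  sign(sum(cx * d))
}

#' Tertiary-structure chirality order parameter K
#'
#' Fraction of native-contacting secondary-element pairs whose chirality sign
#' in the frame matches the reference sign: 1 when native packing chirality is
#' maintained, 0 for a mirror image.
#'
#' @param frame N x 3 coordinate matrix.
#' @param reference a `chain_geometry`.
#' @param ss `secondary_elements`; ignored when `pairs` supplied.
#' @param pairs optional cached [element_pairs_k()] table.
#' @return scalar K in \[0, 1\].
#' @export
compute_K <- function(frame, reference, ss, pairs = NULL) {
  if (is.null(pairs)) pairs <- element_pairs_k(reference, ss)
  sgn <- vapply(seq_len(nrow(pairs)), function(r)
    pair_chirality_sign(frame, ss, pairs$e1[r], pairs$e2[r]), numeric(1))
  mean(sgn == pairs$ref_sign)
}

#' Compute per-frame Q, G, K for a trajectory
#'
#' @param traj a `trajectory`.
#' @param reference a `chain_geometry`.
#' @param ss `secondary_elements`.
#' @param contacts entanglement-loop contacts for G (default
#'   [find_contacts()] on the reference with `min_loop_sep = 10`).
#' @param compute_g set FALSE to skip the (costlier) G column.
#' @return data.frame with columns `frame`, `Q`, `G`, `K`; the per-frame
#'   changed-contact tables are attached as attribute `"changed"`.
#' @export
compute_frame_ops <- function(traj, reference, ss, contacts = NULL,
                              compute_g = TRUE) {
  if (is.null(contacts)) contacts <- find_contacts(reference, min_loop_sep = 10)
  qct <- native_contacts_q(reference, ss)
  prs <- tryCatch(element_pairs_k(reference, ss), error = function(e) {
    warning("K undefined for this reference (", conditionMessage(e),
            "); reporting NA")
    NULL
  })
  ref_st <- if (compute_g) contact_linking_status(reference$xyz, contacts) else NULL
  nf <- traj$n_frames
  Q <- G <- numeric(nf)
  K <- rep(NA_real_, nf)
  changed <- vector("list", nf)
  for (f in seq_len(nf)) {
    fr <- traj_frame(traj, f)
    Q[f] <- compute_Q(fr, reference, contacts = qct)
    if (!is.null(prs)) K[f] <- compute_K(fr, reference, ss = ss, pairs = prs)
    if (compute_g) {
      gg <- compute_G(fr, reference, contacts, ref_status = ref_st)
      G[f] <- gg$G
      changed[[f]] <- gg$changed_contacts
    }
  }
  out <- data.frame(frame = seq_len(nf), Q = Q, G = G, K = K)
  attr(out, "changed") <- changed
  out
}

#' Flag mirror-image trajectories from mean Q and K
#'
#' A trajectory whose analysis-window averages satisfy mean Q > `q_min` and
#' mean K < `k_max` is flagged as a mirror artifact: it keeps near-native
#' contact patterns while its packing chirality is reversed.
#'
#' @param Q,K per-frame values over the analysis window.
#' @param traj_id identifier carried into the verdict.
#' @param q_min,k_max thresholds (defaults 0.2 and 0.6).
#' @return one-row data.frame `traj_id`, `mean_Q`, `mean_K`, `mirror_flag`.
#' @export
flag_mirror_trajectory <- function(Q, K, traj_id = 1L, q_min = 0.2, k_max = 0.6) {
  stopifnot(length(Q) > 0, length(K) > 0)
  mq <- mean(Q); mk <- mean(K)
  data.frame(traj_id = traj_id, mean_Q = mq, mean_K = mk,
             mirror_flag = mq > q_min && mk < k_max)
}
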