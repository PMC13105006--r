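# ---- entanglement-change typing -------------------------------------------

#' Classify an entanglement change between reference and frame
#'
#' Per-tail codes follow the L/C nomenclature: `L+` gain of |linking number|,
#' `L-` loss, `L#` unchanged magnitude; `C*` when any matched crossing flips
#' chirality (including a pure sign flip of the linking number at constant
#' magnitude), else `C#`. The full code concatenates the per-tail codes of
#' tails with activity, prefixed `N:`/`C:` when both tails are active.
#'
#' @param ref_status,frame_status integer pairs `(gln_N, gln_C)`.
#' @param ref_crossings,frame_crossings optional crossing data.frames
#'   (`residue`, `chirality`, `tail`) used to detect chirality flips on
#'   persistent crossings.
#' @return type code string, or `NA_character_` when nothing changed.
#' @examples
#' classify_change(c(0L, 0L), c(0L, 1L))   # "L+C#"
#' classify_change(c(0L, 1L), c(0L, 0L))   # "L-C#"
#' classify_change(c(0L, 1L), c(0L, -1L))  # "L#C*"
#' @export
classify_change <- function(ref_status, frame_status,
                            ref_crossings = NULL, frame_crossings = NULL) {
  stopifnot(length(ref_status) == 2, length(frame_status) == 2)
  codes <- character(0); labs <- character(0)
  for (t in 1:2) {
    tl <- c("N", "C")[t]
    r <- ref_status[t]; f <- frame_status[t]
    lcode <- if (abs(f) > abs(r)) "L+" else if (abs(f) < abs(r)) "L-" else "L#"
    flip <- (r != 0L && f != 0L && sign(r) != sign(f))
    if (!flip && !is.null(ref_crossings) && !is.null(frame_crossings)) {
      rc <- ref_crossings[ref_crossings$tail == tl, , drop = FALSE]
      fc <- frame_crossings[frame_crossings$tail == tl, , drop = FALSE]
      m <- min(nrow(rc), nrow(fc))
      if (m > 0) {
        rc <- rc[order(rc$residue), , drop = FALSE][seq_len(m), ]
        fc <- fc[order(fc$residue), , drop = FALSE][seq_len(m), ]
        flip <- any(rc$chirality != fc$chirality)
      }
    }
    ccode <- if (flip) "C*" else "C#"
    if (r != f || flip) { codes <- c(codes, paste0(lcode, ccode)); labs <- c(labs, tl) }
  }
  if (length(codes) == 0L) return(NA_character_)
  if (length(codes) == 1L) codes else paste(paste0(labs, ":", codes), collapse = "|")
}

#' Build change records from per-frame changed-contact tables
#'
#' @param frame_ops output of [compute_frame_ops()] (uses its `"changed"`
#'   attribute).
#' @param traj_id trajectory identifier.
#' @return data.frame of change records with columns `traj`, `frame`, `i`,
#'   `j`, reference/frame gln columns and `type`.
#' @export
change_records <- function(frame_ops, traj_id = 1L) {
  changed <- attr(frame_ops, "changed")
  rows <- list()
  for (f in seq_along(changed)) {
    cc <- changed[[f]]
    if (is.null(cc) || nrow(cc) == 0L) next
    cc$type <- vapply(seq_len(nrow(cc)), function(r)
      classify_change(c(cc$ref_gln_N[r], cc$ref_gln_C[r]),
                      c(cc$frame_gln_N[r], cc$frame_gln_C[r])), character(1))
    cc$traj <- traj_id; cc$frame <- f
    rows[[length(rows) + 1L]] <- cc
  }
  if (length(rows) == 0L)
    return(data.frame(i = integer(), j = integer(), ref_gln_N = integer(),
                      ref_gln_C = integer(), frame_gln_N = integer(),
                      frame_gln_C = integer(), type = character(),
                      traj = integer(), frame = integer()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# ---- permutation-stabilised clustering ------------------------------------

loop_jaccard <- function(i1, j1, i2, j2) {
  inter <- max(0L, min(j1, j2) - max(i1, i2) + 1L)
  uni <- (j1 - i1 + 1L) + (j2 - i2 + 1L) - inter
  inter / uni
}

# pairwise mergeability within one type partition
change_pair_ok <- function(rec, a, b, jaccard_min, cross_window) {
  if (loop_jaccard(rec$i[a], rec$j[a], rec$i[b], rec$j[b]) < jaccard_min)
    return(FALSE)
  ca <- rec$cross[[a]]; cb <- rec$cross[[b]]
  if (length(ca) && length(cb)) {
    m <- min(length(ca), length(cb))
    if (any(abs(sort(ca)[seq_len(m)] - sort(cb)[seq_len(m)]) > cross_window))
      return(FALSE)
  }
  # crossing contamination: a crossing of one record inside the other's loop
  if (length(ca) && any(ca >= rec$i[b] & ca <= rec$j[b])) return(FALSE)
  if (length(cb) && any(cb >= rec$i[a] & cb <= rec$j[a])) return(FALSE)
  TRUE
}

greedy_pass <- function(rec, order_idx, jaccard_min, cross_window) {
  assign <- integer(nrow(rec))
  seeds <- integer(0)
  for (r in order_idx) {
    placed <- FALSE
    for (s in seq_along(seeds)) {
      if (change_pair_ok(rec, r, seeds[s], jaccard_min, cross_window)) {
        assign[r] <- s; placed <- TRUE; break
      }
    }
    if (!placed) { seeds <- c(seeds, r); assign[r] <- length(seeds) }
  }
  assign
}

#' Cluster entanglement-change records with permutation consensus
#'
#' Records are first partitioned by type code; within a partition a greedy
#' agglomeration joins records whose loops overlap (Jaccard over residue
#' ranges >= `jaccard_min`) and whose matched crossings lie within
#' `cross_window` residues, with a contamination bar (no merging when one
#' record's crossings fall inside the other's loop). The greedy pass is
#' repeated over `n_permutations` shuffled input orders and the final
#' clusters are the connected components of pairs co-clustered in more than
#' half of the permutations, which removes input-order bias.
#'
#' @param records data.frame from [change_records()]; an optional list column
#'   `cross` gives crossing residues per record (defaults to none).
#' @param n_permutations shuffled greedy passes (default 100).
#' @param seed RNG seed for the shuffles.
#' @param jaccard_min loop-overlap threshold (default 0.5).
#' @param cross_window matched-crossing window in residues (default 20).
#' @param total_frames frame universe for the probability column (defaults to
#'   the number of distinct (traj, frame) pairs seen).
#' @param consensus co-clustering fraction required (default 0.5, exclusive).
#' @return data.frame, one row per cluster: `cluster_id`, `type`,
#'   representative loop/status columns, `n_members`, `probability`; member
#'   row indices attached as attribute `"members"`.
#' @export
cluster_changes <- function(records, n_permutations = 100L, seed = 1L,
                            jaccard_min = 0.5, cross_window = 20L,
                            total_frames = NULL, consensus = 0.5) {
  stopifnot(nrow(records) > 0)
  if (is.null(records$cross)) records$cross <- rep(list(integer(0)), nrow(records))
  if (is.null(total_frames))
    total_frames <- nrow(unique(records[, c("traj", "frame")]))
  clusters <- list()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  for (tp in sort(unique(records$type))) {
    idx <- which(records$type == tp)
    rec <- records[idx, , drop = FALSE]
    k <- nrow(rec)
    co <- matrix(0L, k, k)
    for (p in seq_len(n_permutations)) {
      a <- greedy_pass(rec, sample.int(k), jaccard_min, cross_window)
      co <- co + outer(a, a, "==")
    }
    adj <- co / n_permutations > consensus
    diag(adj) <- FALSE
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    memb <- igraph::components(g)$membership
    for (cid in sort(unique(memb))) {
      mi <- idx[memb == cid]
      # representative: highest-probability microstate when a `micro_prob`
      # column is present, ties (or absent column) by lowest (traj, frame)
      mp <- if (is.null(records$micro_prob)) rep(0, length(mi)) else records$micro_prob[mi]
      ord <- order(-mp, records$traj[mi], records$frame[mi], records$i[mi])
      clusters[[length(clusters) + 1L]] <-
        list(type = tp, members = mi, rep = mi[ord[1]])
    }
  }
  out <- do.call(rbind, lapply(seq_along(clusters), function(k) {
    cl <- clusters[[k]]
    r <- records[cl$rep, , drop = FALSE]
    nfr <- nrow(unique(records[cl$members, c("traj", "frame")]))
    data.frame(cluster_id = k, type = cl$type, i = r$i, j = r$j,
               ref_gln_N = r$ref_gln_N, ref_gln_C = r$ref_gln_C,
               frame_gln_N = r$frame_gln_N, frame_gln_C = r$frame_gln_C,
               n_members = length(cl$members),
               probability = nfr / total_frames)
  }))
  rownames(out) <- NULL
  attr(out, "members") <- lapply(clusters, `[[`, "members")
  out
}
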