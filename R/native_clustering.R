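# ---- degenerate-NCLE clustering -------------------------------------------

# chirality signature of a record on one tail: ordered vector of signs
tail_signature <- function(rec, tail) {
  cr <- rec$crossings[rec$crossings$tail == tail, , drop = FALSE]
  cr <- cr[order(cr$residue), , drop = FALSE]
  list(res = cr$residue, chir = cr$chirality)
}

# two records are "degenerate" when they share tail identity and ordered
# chirality signature and every matched crossing pair is close both in
# sequence and in space
ncle_related <- function(a, b, xyz, seq_window, spatial_cutoff) {
  if (a$tail != b$tail) return(FALSE)
  for (tl in intersect(c("N", "C"), strsplit(sub("both", "NC", a$tail), "")[[1]])) {
    sa <- tail_signature(a, tl); sb <- tail_signature(b, tl)
    if (length(sa$chir) != length(sb$chir)) return(FALSE)
    if (length(sa$chir) == 0L) next
    if (any(sa$chir != sb$chir)) return(FALSE)
    if (any(abs(sa$res - sb$res) > seq_window)) return(FALSE)
    dd <- sqrt(rowSums((xyz[sa$res, , drop = FALSE] - xyz[sb$res, , drop = FALSE])^2))
    if (any(dd > spatial_cutoff)) return(FALSE)
  }
  TRUE
}

#' Cluster degenerate NCLEs into non-redundant representatives
#'
#' Two records join a cluster when they share the same entangled tail and the
#' same ordered crossing-chirality signature, and every matched crossing pair
#' is within `seq_window` residues and within `spatial_cutoff` Angstrom
#' (Calpha). Clusters are the connected components of this relation; the
#' representative is the member with the minimal closing loop (ties broken by
#' the smaller loop start).
#'
#' @param records `ncle_list` from [detect_ncles()] (one chain).
#' @param geometry the `chain_geometry` the records came from.
#' @param seq_window sequence proximity window for matched crossings
#'   (residues, default 20).
#' @param spatial_cutoff spatial proximity cutoff for matched crossings
#'   (Angstrom, default 10).
#' @return list of clusters, each a list with `cluster_id`, `representative`
#'   (an `ncle`), and `members` (`ncle_list`); class `ncle_clusters`.
#' @export
cluster_ncles <- function(records, geometry, seq_window = 20, spatial_cutoff = 10) {
  n <- length(records)
  if (n == 0L) return(structure(list(), class = "ncle_clusters"))
  xyz <- geometry$xyz
  adj <- matrix(FALSE, n, n)
  for (a in seq_len(n)) for (b in seq_len(n)) if (a < b)
    adj[a, b] <- adj[b, a] <- ncle_related(records[[a]], records[[b]],
                                           xyz, seq_window, spatial_cutoff)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  # canonical cluster order: by smallest member loop start
  out <- list()
  for (cid in sort(unique(comp))) {
    idx <- which(comp == cid)
    loops <- t(vapply(records[idx], function(r) r$loop, integer(2)))
    len <- loops[, 2] - loops[, 1] + 1L
    rep_i <- idx[order(len, loops[, 1])][1]
    out[[length(out) + 1L]] <- list(cluster_id = length(out) + 1L,
                                    representative = records[[rep_i]],
                                    members = structure(records[idx],
                                                        class = "ncle_list"))
  }
  ord <- order(vapply(out, function(cl) cl$representative$loop[1], integer(1)),
               vapply(out, function(cl) cl$representative$loop[2], integer(1)))
  out <- out[ord]
  for (k in seq_along(out)) out[[k]]$cluster_id <- k
  structure(out, class = "ncle_clusters")
}

#' @export
print.ncle_clusters <- function(x, ...) {
  cat(sprintf("%d NCLE cluster(s)\n", length(x)))
  for (cl in x) {
    cat(sprintf(" [%d] %d member(s), representative: ", cl$cluster_id,
                length(cl$members)))
    print(cl$representative)
  }
  invisible(x)
}

# ---- quality filters -------------------------------------------------------

#' Remove slipknot-like and low-confidence NCLE records
#'
#' Both modes drop slipknot-like records: a tail whose crossings have a net
#' signed sum of zero re-pierces the loop and backs out, which is not a
#' lasso. In `AF` mode (AlphaFold models) records whose loop-closing or
#' crossing residues have pLDDT below `plddt_min` are additionally dropped,
#' since those residues define the topology.
#'
#' @param records `ncle_list`.
#' @param plddt per-residue pLDDT scores (required in AF mode).
#' @param mode `"EXP"` (experimental structure) or `"AF"`.
#' @param plddt_min confidence threshold (default 70).
#' @return filtered `ncle_list`.
#' @export
filter_high_quality <- function(records, plddt = NULL, mode = c("EXP", "AF"),
                                plddt_min = 70) {
  mode <- match.arg(mode)
  if (mode == "AF" && is.null(plddt)) stop("AF mode requires per-residue pLDDT scores")
  keep <- vapply(records, function(r) {
    for (tl in c("N", "C")) {
      cr <- r$crossings[r$crossings$tail == tl, , drop = FALSE]
      if (nrow(cr) > 0 && sum(cr$chirality) == 0L) return(FALSE)  # slipknot-like
    }
    if (mode == "AF") {
      key_res <- c(r$loop, r$crossings$residue)
      if (any(plddt[key_res] < plddt_min)) return(FALSE)
    }
    TRUE
  }, logical(1))
  structure(records[keep], class = "ncle_list")
}

# ---- representative features -----------------------------------------------

#' Features of a representative entanglement
#'
#' * `loop_length`: j - i + 1 residues.
#' * `n_crossings`: crossings stored on the record.
#' * `crossing_depth`: minimum residue distance from a crossing to its tail's
#'   free end (chain terminus by default; the exclusion boundary when
#'   `depth_to = "exclusion"`).
#' * `loop_contact_count`: contacts with exactly one endpoint inside the loop.
#' * `supercoil_count`: full |g| turns beyond the first on the entangled tail,
#'   `max(floor(max |g|) - 1, 0)`.
#'
#' @param cluster one element of an `ncle_clusters` list (or a bare list with
#'   a `representative` field).
#' @param geometry the `chain_geometry`.
#' @param contacts contact table from [find_contacts()].
#' @param depth_to `"terminus"` (default) or `"exclusion"` (stops 5 residues
#'   short of the chain end, matching the detection buffer).
#' @return one-row data.frame of the five features.
#' @export
compute_features <- function(cluster, geometry, contacts,
                             depth_to = c("terminus", "exclusion")) {
  depth_to <- match.arg(depth_to)
  rec <- cluster$representative
  n <- nrow(geometry$xyz)
  i <- rec$loop[1]; j <- rec$loop[2]
  end_off <- if (depth_to == "exclusion") 5L else 0L
  depth <- NA_integer_
  if (nrow(rec$crossings)) {
    d <- vapply(seq_len(nrow(rec$crossings)), function(r) {
      res <- rec$crossings$residue[r]
      if (rec$crossings$tail[r] == "N") res - (1L + end_off)
      else (n - end_off) - res
    }, numeric(1))
    depth <- as.integer(min(d))
  }
  inside <- contacts$i >= i & contacts$i <= j
  jnside <- contacts$j >= i & contacts$j <= j
  data.frame(
    loop_length = j - i + 1L,
    n_crossings = nrow(rec$crossings),
    crossing_depth = depth,
    loop_contact_count = sum(xor(inside, jnside)),
    supercoil_count = max(floor(max(abs(c(rec$g_N, rec$g_C)))) - 1, 0))
}

#' Summarise NCLE clusters (representatives, members, features) as a table
#'
#' @inheritParams compute_features
#' @param clusters an `ncle_clusters` list.
#' @return data.frame, one row per cluster.
#' @export
cluster_summary <- function(clusters, geometry, contacts) {
  if (length(clusters) == 0L) return(data.frame())
  do.call(rbind, lapply(clusters, function(cl) {
    rep_df <- as.data.frame(structure(list(cl$representative), class = "ncle_list"),
                            geometry = geometry)
    degen <- paste(vapply(cl$members, function(m)
      sprintf("(%d,%d)", m$loop[1], m$loop[2]), character(1)), collapse = ";")
    cbind(cluster_id = cl$cluster_id, rep_df, n_members = length(cl$members),
          degenerate_loops = degen,
          compute_features(cl, geometry, contacts))
  }))
}
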