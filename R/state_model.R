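# ---- Q-G microstates and Markov-state lumping ------------------------------

#' Cluster frames into (Q, G) microstates by k-means
#'
#' k-means runs on standardised (Q, G) with a fixed seed; empty clusters are
#' dropped with contiguous renumbering, and `k` is reduced (with a warning)
#' when fewer frames than clusters are supplied.
#'
#' @param opdata data.frame (or matrix) with columns `Q` and `G`, one row per
#'   analysed frame.
#' @param k number of microstates (default 400).
#' @param seed RNG seed.
#' @param nstart k-means restarts.
#' @return list with `microstate` (per-frame id, 1..k'), `centers` (on the
#'   original Q/G scale), `prob` (microstate probabilities, summing to 1).
#' @export
assign_microstates <- function(opdata, k = 400L, seed = 1L, nstart = 5L) {
  qg <- as.matrix(as.data.frame(opdata)[, c("Q", "G")])
  stopifnot(nrow(qg) >= 1, !anyNA(qg))
  if (k > nrow(qg)) {
    warning("fewer frames than microstates; reducing k to ", nrow(qg))
    k <- nrow(qg)
  }
  mu <- colMeans(qg); sdv <- apply(qg, 2, stats::sd)
  sdv[sdv == 0] <- 1
  z <- sweep(sweep(qg, 2, mu), 2, sdv, "/")
  uz <- unique(z)
  k <- min(k, nrow(uz))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  # multi-start k-means with kmeans++-style seeding (successive centres drawn
  # with probability proportional to squared distance from the nearest chosen
  # centre); best total within-cluster sum of squares wins, deterministic
  # under the seed
  pp_centers <- function() {
    idx <- sample.int(nrow(uz), 1L)
    d2 <- rowSums(sweep(uz, 2, uz[idx, ])^2)
    while (length(idx) < k) {
      pick <- if (sum(d2) > 0) sample.int(nrow(uz), 1L, prob = d2)
              else sample(setdiff(seq_len(nrow(uz)), idx), 1L)
      idx <- c(idx, pick)
      d2 <- pmin(d2, rowSums(sweep(uz, 2, uz[pick, ])^2))
    }
    uz[idx, , drop = FALSE]
  }
  if (k >= nrow(uz)) {
    # one microstate per distinct (Q, G) point; k-means degenerates here
    lab <- match(paste(z[, 1], z[, 2]), paste(uz[, 1], uz[, 2]))
    km <- list(centers = uz)
  } else {
    km <- NULL
    for (s in seq_len(max(1L, nstart))) {
      cand <- suppressWarnings(stats::kmeans(z, centers = pp_centers(),
                                             iter.max = 100))
      if (is.null(km) || cand$tot.withinss < km$tot.withinss) km <- cand
    }
    lab <- km$cluster
  }
  used <- sort(unique(lab))
  relab <- match(lab, used)
  centers <- sweep(sweep(km$centers[used, , drop = FALSE], 2, sdv, "*"), 2, mu, "+")
  list(microstate = relab,
       centers = centers,
       prob = as.vector(table(factor(relab, levels = seq_along(used)))) / length(relab))
}

#' Row-stochastic transition matrix over microstates
#'
#' Transitions are counted within trajectories only, at the given lag; rows
#' are normalised to 1 and zero-count states are isolated into their own
#' connected components. Components are found on the transition graph treated
#' as undirected.
#'
#' @param microstate per-frame microstate ids.
#' @param traj per-frame trajectory ids (transitions never cross a boundary).
#' @param lag lag time in frames (default 1).
#' @return list with `T` (row-stochastic matrix), `counts`, `component`
#'   (per-microstate component id; largest component is 1).
#' @export
build_transition_matrix <- function(microstate, traj = rep(1L, length(microstate)),
                                    lag = 1L) {
  k <- max(microstate)
  counts <- matrix(0, k, k)
  for (tr in unique(traj)) {
    s <- microstate[traj == tr]
    if (length(s) > lag) {
      from <- s[seq_len(length(s) - lag)]
      to <- s[-seq_len(lag)]
      for (idx in seq_along(from))
        counts[from[idx], to[idx]] <- counts[from[idx], to[idx]] + 1
    }
  }
  rs <- rowSums(counts)
  Tm <- counts
  nz <- rs > 0
  Tm[nz, ] <- counts[nz, , drop = FALSE] / rs[nz]
  Tm[!nz, ] <- 0
  adj <- (counts + t(counts)) > 0
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  # renumber components by decreasing size (largest = 1), stable by first state
  sizes <- table(comp)
  ord <- order(-as.vector(sizes), as.integer(names(sizes)))
  comp <- match(comp, as.integer(names(sizes))[ord])
  list(T = Tm, counts = counts, component = comp)
}

#' Lump microstates into metastable states
#'
#' The largest connected component is lumped into at most `n_large_states`
#' groups by spectral clustering of the symmetrised transition matrix (top
#' eigenvectors, then k-means on the spectral embedding with a fixed seed);
#' every smaller component becomes one metastable state of its own. Empty
#' groups are discarded, so the final number of states may be lower than
#' requested.
#'
#' @param tm result of [build_transition_matrix()].
#' @param n_large_states maximum states for the largest component.
#' @param seed RNG seed for the embedded k-means.
#' @return integer vector: metastable id per microstate (1-based, contiguous).
#' @export
lump_metastable <- function(tm, n_large_states, seed = 1L) {
  stopifnot(n_large_states >= 1)
  comp <- tm$component
  k <- length(comp)
  meta <- integer(k)
  big <- which(comp == 1L)
  if (length(big) == 1L || n_large_states == 1L) {
    meta[big] <- 1L
  } else {
    S <- (tm$T[big, big, drop = FALSE] + t(tm$T[big, big, drop = FALSE])) / 2
    # symmetric normalised affinity; its leading eigenvalues near 1 mark the
    # slowly-mixing (metastable) subsets
    deg <- rowSums(S)
    deg[deg == 0] <- 1
    L <- diag(1 / sqrt(deg)) %*% S %*% diag(1 / sqrt(deg))
    ev <- eigen(L, symmetric = TRUE)
    kmax <- min(n_large_states, length(big))
    # spectral-gap choice of the state count: the largest drop among the
    # leading eigenvalues separates metastable modes from fast mixing, so
    # wells are not split just because n_large_states allows more states
    lam <- ev$values[seq_len(min(kmax + 1L, length(big)))]
    gaps <- -diff(lam)
    keff <- if (length(gaps)) which.max(gaps[seq_len(kmax)]) else 1L
    if (keff <= 1L) {
      meta[big] <- 1L
    } else {
      emb <- ev$vectors[, seq_len(keff), drop = FALSE]
      nrm <- sqrt(rowSums(emb^2)); nrm[nrm == 0] <- 1
      emb <- emb / nrm
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed)
      km <- stats::kmeans(emb, centers = min(keff, nrow(unique(emb))),
                          nstart = 10, iter.max = 100)
      meta[big] <- km$cluster
    }
  }
  nxt <- max(meta[big])
  for (cc in setdiff(sort(unique(comp)), 1L)) {
    nxt <- nxt + 1L
    meta[comp == cc] <- nxt
  }
  # drop empty labels, renumber contiguously
  match(meta, sort(unique(meta)))
}

#' Jensen-Shannon divergence between two state distributions
#'
#' `JSD = 0.5 * sum_x [ PA ln(PA / M) + PB ln(PB / M) ]` with
#' `M = (PA + PB) / 2`; zero-probability terms contribute 0. Natural
#' logarithm, so the maximum (disjoint support) is `ln 2`.
#'
#' @param pa,pb probability vectors over a common support (each sums to 1).
#' @return scalar in \[0, ln 2\].
#' @export
jsd <- function(pa, pb) {
  stopifnot(length(pa) == length(pb), all(pa >= 0), all(pb >= 0))
  stopifnot(abs(sum(pa) - 1) < 1e-8, abs(sum(pb) - 1) < 1e-8)
  m <- (pa + pb) / 2
  term <- function(p) ifelse(p > 0, p * log(p / m), 0)
  0.5 * sum(term(pa) + term(pb))
}

#' Folding pathways through metastable states
#'
#' Each trajectory's metastable-state sequence is run-length collapsed to its
#' ordered distinct-state pathway; the directed graph aggregates observed
#' transitions with per-edge probabilities (outgoing probabilities per node
#' sum to 1 over observed transitions), and per-pathway probabilities are
#' reported.
#'
#' @param meta per-frame metastable ids.
#' @param traj per-frame trajectory ids.
#' @param native_state_id optional native-state label carried into the
#'   output.
#' @return list with `pathways` (data.frame `pathway`, `n`, `probability`),
#'   `edges` (data.frame `from`, `to`, `count`, `probability`), `sequences`
#'   (list of per-trajectory collapsed sequences) and `native_state_id`.
#' @export
folding_pathways <- function(meta, traj = rep(1L, length(meta)),
                             native_state_id = NULL) {
  seqs <- lapply(split(meta, traj), function(s) s[c(TRUE, diff(s) != 0)])
  path_str <- vapply(seqs, paste, character(1), collapse = "->")
  tab <- table(path_str)
  pathways <- data.frame(pathway = names(tab), n = as.vector(tab),
                         probability = as.vector(tab) / length(seqs))
  pathways <- pathways[order(-pathways$n, pathways$pathway), , drop = FALSE]
  rownames(pathways) <- NULL
  ed <- do.call(rbind, lapply(seqs, function(s) {
    if (length(s) < 2) return(NULL)
    data.frame(from = s[-length(s)], to = s[-1])
  }))
  if (is.null(ed)) {
    edges <- data.frame(from = integer(), to = integer(), count = integer(),
                        probability = numeric())
  } else {
    agg <- stats::aggregate(list(count = rep(1L, nrow(ed))), ed, sum)
    tot <- stats::ave(agg$count, agg$from, FUN = sum)
    agg$probability <- agg$count / tot
    edges <- agg[order(agg$from, agg$to), , drop = FALSE]
    rownames(edges) <- NULL
  }
  list(pathways = pathways, edges = edges, sequences = seqs,
       native_state_id = native_state_id)
}

#' Sample a representative frame from a metastable state
#'
#' A microstate is drawn with probability proportional to its weight within
#' the metastable state, and the frame nearest that microstate's (Q, G)
#' centre is returned. Fixed seed makes the draw reproducible.
#'
#' @param assignment list from [assign_microstates()].
#' @param meta per-microstate metastable ids from [lump_metastable()].
#' @param metastable_id state to sample.
#' @param opdata the (Q, G) table the microstates were fitted on.
#' @param seed RNG seed.
#' @return frame index (row of `opdata`).
#' @export
select_state_representative <- function(assignment, meta, metastable_id,
                                        opdata, seed = 1L) {
  micro_in <- which(meta == metastable_id)
  if (length(micro_in) == 0L) stop("empty metastable state ", metastable_id)
  w <- assignment$prob[micro_in]
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  ms <- if (length(micro_in) == 1L) micro_in else sample(micro_in, 1L, prob = w)
  frames <- which(assignment$microstate == ms)
  qg <- as.matrix(as.data.frame(opdata)[, c("Q", "G")])
  ctr <- assignment$centers[ms, ]
  d2 <- rowSums(sweep(qg[frames, , drop = FALSE], 2, ctr)^2)
  frames[which.min(d2)]
}

#' Negative-log probability surface over (Q, G)
#'
#' Histogram estimate of -ln P(Q, G); occupied-bin probabilities sum to 1.
#'
#' @param opdata data.frame with `Q`, `G`.
#' @param bins number of bins per axis.
#' @return list with `q_breaks`, `g_breaks`, `P` and `neg_log_P` matrices.
#' @export
neg_log_surface <- function(opdata, bins = 50L) {
  qg <- as.data.frame(opdata)
  qb <- seq(min(qg$Q), max(qg$Q) + 1e-9, length.out = bins + 1)
  gb <- seq(min(qg$G), max(qg$G) + 1e-9, length.out = bins + 1)
  iq <- findInterval(qg$Q, qb, rightmost.closed = TRUE)
  ig <- findInterval(qg$G, gb, rightmost.closed = TRUE)
  P <- matrix(0, bins, bins)
  for (r in seq_along(iq)) P[iq[r], ig[r]] <- P[iq[r], ig[r]] + 1
  P <- P / sum(P)
  list(q_breaks = qb, g_breaks = gb, P = P,
       neg_log_P = ifelse(P > 0, -log(P), Inf))
}
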