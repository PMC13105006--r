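blob_data <- function(n_per = 50, seed = 1) {
  set.seed(seed)
  ctrs <- rbind(c(0.9, 0.02), c(0.5, 0.1), c(0.2, 0.35), c(0.75, 0.3))
  lab <- rep(1:4, each = n_per)
  data.frame(Q = ctrs[lab, 1] + rnorm(4 * n_per, 0, 0.01),
             G = ctrs[lab, 2] + rnorm(4 * n_per, 0, 0.01), truth = lab)
}

test_that("k-means microstates recover separated blobs and are seed-deterministic", {
  bd <- blob_data()
  a1 <- assign_microstates(bd, k = 4, seed = 11)
  expect_equal(adjusted_rand_index(a1$microstate, bd$truth), 1)
  expect_equal(sum(a1$prob), 1)
  a2 <- assign_microstates(bd, k = 4, seed = 11)
  expect_identical(a1$microstate, a2$microstate)
  # k = 1: everything in one microstate
  expect_true(all(assign_microstates(bd, k = 1, seed = 1)$microstate == 1L))
  # more clusters than frames: k reduced with warning
  expect_warning(assign_microstates(bd[1:3, ], k = 10, seed = 1), "reducing")
})

test_that("transition matrices are hand-countable, row-stochastic and component-aware", {
  tm <- build_transition_matrix(c(1L, 2L, 1L, 2L))
  expect_equal(tm$T, rbind(c(0, 1), c(1, 0)))
  # two trajectories never sharing states -> two components
  tm2 <- build_transition_matrix(c(1L, 2L, 1L, 3L, 4L, 3L),
                                 traj = c(1L, 1L, 1L, 2L, 2L, 2L))
  expect_equal(length(unique(tm2$component)), 2L)
  expect_false(tm2$component[1] == tm2$component[3])
  # no transitions counted across the trajectory boundary
  expect_equal(tm2$counts[2, 3], 0)
  # empirical recovery of a known 3-state chain
  P <- rbind(c(0.8, 0.15, 0.05), c(0.1, 0.8, 0.1), c(0.05, 0.15, 0.8))
  set.seed(5)
  s <- integer(1e4); s[1] <- 1L
  for (t in 2:1e4) s[t] <- sample.int(3, 1, prob = P[s[t - 1], ])
  tm3 <- build_transition_matrix(s)
  expect_lt(max(abs(tm3$T - P)), 0.05)
  expect_true(all(abs(rowSums(tm3$T) - 1) < 1e-12))
})

test_that("metastable lumping recovers planted block structure", {
  # two-block chain: rare inter-block hops
  P <- matrix(0.001, 6, 6)
  P[1:3, 1:3] <- 0.32; P[4:6, 4:6] <- 0.32
  P <- P / rowSums(P)
  set.seed(7)
  s <- integer(2e4); s[1] <- 1L
  for (t in 2:2e4) s[t] <- sample.int(6, 1, prob = P[s[t - 1], ])
  tm <- build_transition_matrix(s)
  meta <- lump_metastable(tm, n_large_states = 2, seed = 1)
  expect_equal(cluster_purity(meta, rep(1:2, each = 3)), 1)
  expect_length(unique(meta), 2L)
  # n_large_states = 1: single state for the largest component
  expect_true(all(lump_metastable(tm, 1, seed = 1) == 1L))
  # 3 wells, room for 5 states: wells never split
  P3 <- matrix(0.0005, 9, 9)
  for (b in 0:2) P3[b * 3 + 1:3, b * 3 + 1:3] <- 0.33
  P3 <- P3 / rowSums(P3)
  set.seed(8)
  s3 <- integer(3e4); s3[1] <- 1L
  for (t in 2:3e4) s3[t] <- sample.int(9, 1, prob = P3[s3[t - 1], ])
  tm3 <- build_transition_matrix(s3)
  meta3 <- lump_metastable(tm3, n_large_states = 5, seed = 1)
  expect_lte(length(unique(meta3)), 5L)
  expect_equal(cluster_purity(rep(1:3, each = 3), meta3), 1)  # wells unbroken
})

test_that("Jensen-Shannon divergence matches closed forms", {
  p <- c(0.3, 0.2, 0.5)
  expect_identical(jsd(p, p), 0)
  expect_equal(jsd(c(1, 0), c(0, 1)), log(2), tolerance = 1e-15)
  # direct arithmetic oracle for an asymmetric case
  pa <- c(0.5, 0.5); pb <- c(0.9, 0.1)
  m <- (pa + pb) / 2
  direct <- 0.5 * (sum(pa * log(pa / m)) + sum(pb * log(pb / m)))
  expect_equal(jsd(pa, pb), direct, tolerance = 1e-15)
  expect_equal(jsd(pb, pa), jsd(pa, pb))
  expect_error(jsd(c(0.5, 0.6), c(0.5, 0.5)))
  expect_error(jsd(c(-0.1, 1.1), c(0.5, 0.5)))
})

test_that("pathways run-length collapse and aggregate into a stochastic edge graph", {
  fp <- folding_pathways(c(2L, 2L, 1L, 1L, 0L) + 1L)
  expect_equal(fp$pathways$pathway, "3->2->1")
  fp2 <- folding_pathways(c(3L, 3L, 2L, 1L, 3L, 1L, 1L, 3L, 2L, 2L, 1L),
                          traj = c(1, 1, 1, 1, 2, 2, 2, 3, 3, 3, 3),
                          native_state_id = 1L)
  # every trajectory ends in the native state
  expect_true(all(vapply(fp2$sequences, function(s) s[length(s)] == 1L,
                         logical(1))))
  # outgoing probabilities sum to 1 per source node
  for (f in unique(fp2$edges$from))
    expect_equal(sum(fp2$edges$probability[fp2$edges$from == f]), 1)
  expect_equal(sum(fp2$pathways$probability), 1)
})

test_that("state representatives are sampled by microstate weight, reproducibly", {
  bd <- blob_data()
  a <- assign_microstates(bd, k = 4, seed = 2)
  meta <- rep(1L, 4)
  r1 <- select_state_representative(a, meta, 1L, bd, seed = 9)
  expect_identical(r1, select_state_representative(a, meta, 1L, bd, seed = 9))
  # single-microstate state is deterministic: the frame nearest the centre
  meta2 <- c(1L, 2L, 2L, 2L)
  rr <- select_state_representative(a, meta2, 1L, bd, seed = 1)
  ms <- which(meta2 == 1L)
  frames <- which(a$microstate == ms)
  d2 <- rowSums(sweep(as.matrix(bd[frames, c("Q", "G")]), 2, a$centers[ms, ])^2)
  expect_equal(rr, frames[which.min(d2)])
  expect_error(select_state_representative(a, meta2, 99L, bd, seed = 1), "empty")
  # weighted draw: 0.99 / 0.01 microstates chosen in proportion
  a2 <- list(microstate = c(rep(1L, 99), rep(2L, 1)),
             centers = rbind(c(0, 0), c(1, 1)), prob = c(0.99, 0.01))
  op <- data.frame(Q = c(rep(0, 99), 1), G = c(rep(0, 99), 1))
  picks <- vapply(1:10000, function(s)
    select_state_representative(a2, c(1L, 1L), 1L, op, seed = s) <= 99,
    logical(1))
  expect_gt(mean(picks), 0.98)
  expect_lt(mean(picks), 1)
})

test_that("the -ln P surface renormalises to probability 1", {
  bd <- blob_data()
  sf <- neg_log_surface(bd, bins = 20)
  expect_equal(sum(sf$P), 1)
  expect_equal(sum(exp(-sf$neg_log_P[is.finite(sf$neg_log_P)])), 1)
})
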