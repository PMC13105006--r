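test_that("order parameters satisfy their reference identities", {
  hb <- make_helix_bundle()
  ref <- hb$geometry$xyz
  ct <- find_contacts(hb$geometry, min_loop_sep = 10)
  expect_equal(compute_Q(ref, hb$geometry, hb$ss), 1)
  expect_equal(compute_G(ref, hb$geometry, ct)$G, 0)
  expect_equal(compute_K(ref, hb$geometry, hb$ss), 1)
  mir <- ref; mir[, 1] <- -mir[, 1]
  expect_equal(compute_K(mir, hb$geometry, hb$ss), 0)
  # fully extended frame: no contacts formed
  ext <- cbind(3.8 * seq_len(nrow(ref)), 0, 0)
  expect_equal(compute_Q(ext, hb$geometry, hb$ss), 0)
  expect_equal(compute_G(ext, hb$geometry, ct)$G, 0)
})

test_that("Q counts formed contacts against the 1.2x native-distance rule", {
  # engineered contact set: 10 contacts, half broken in the frame
  ref <- chain_geometry(cbind(0, 100 * (1:40), 0))
  contacts <- data.frame(i = 1:10, j = 21:30, dist = 4)
  frame <- ref$xyz
  for (k in 1:10) {
    frame[k, ] <- c(0, 100 * k, 0)
    frame[20 + k, ] <- c(if (k <= 5) 4 else 8.5, 100 * k, 0)
  }
  expect_equal(compute_Q(frame, ref, contacts = contacts), 0.5)
  # brute-force recount on a random frame
  set.seed(9)
  rf <- ref$xyz + matrix(rnorm(120, 0, 30), ncol = 3)
  brute <- mean(sqrt(rowSums((rf[contacts$i, ] - rf[contacts$j, ])^2)) <=
                  1.2 * contacts$dist)
  expect_equal(compute_Q(rf, ref, contacts = contacts), brute)
  expect_error(compute_Q(frame, ref, contacts = contacts[0, ]), "native contacts")
})

test_that("G detects a lost thread through the loop-family contacts only", {
  fx <- lasso_with_loss(seed = 1)
  ct <- find_contacts(fx$native, min_loop_sep = 10)
  res <- compute_G(fx$pulled$xyz, fx$native, ct)
  # independent expectation: per-contact status change from the dense oracle,
  # counted only for contacts still formed in the pulled frame
  n <- nrow(fx$native$xyz)
  expected_changed <- 0
  for (r in seq_len(nrow(ct))) {
    tw <- lassotop:::tail_windows(ct$i[r], ct$j[r], n)
    st <- function(xyz) c(
      if (is.null(tw$N)) 0L else round_linking(oracle_linking(xyz, c(ct$i[r], ct$j[r]), tw$N)),
      if (is.null(tw$C)) 0L else round_linking(oracle_linking(xyz, c(ct$i[r], ct$j[r]), tw$C)))
    d <- sqrt(sum((fx$pulled$xyz[ct$i[r], ] - fx$pulled$xyz[ct$j[r], ])^2))
    if (d <= 8 && any(st(fx$native$xyz) != st(fx$pulled$xyz)))
      expected_changed <- expected_changed + 1
  }
  expect_gt(res$G, 0)
  expect_equal(res$G, expected_changed / nrow(ct))
  expect_equal(nrow(res$changed_contacts), expected_changed)
})

test_that("K scores chirality per contacting element pair", {
  fx <- four_element_fixture()
  pairs <- element_pairs_k(fx$geometry, fx$ss)
  expect_equal(nrow(pairs), 4L)
  expect_equal(paste(pairs$e1, pairs$e2), c("1 2", "2 3", "2 4", "3 4"))
  # reversing element 1 flips exactly its one pair: K = 3/4
  frame <- fx$geometry$xyz
  frame[1:2, ] <- frame[2:1, ]
  expect_equal(compute_K(frame, fx$geometry, fx$ss), 0.75)
  # brute-force sign recount
  sgn <- function(xyz, e1, e2) {
    s <- fx$ss
    a <- xyz[s$end[e1], ] - xyz[s$start[e1], ]
    b <- xyz[s$end[e2], ] - xyz[s$start[e2], ]
    d <- (xyz[s$start[e2], ] + xyz[s$end[e2], ]) / 2 -
         (xyz[s$start[e1], ] + xyz[s$end[e1], ]) / 2
    sign(sum(c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
               a[1] * b[2] - a[2] * b[1]) * d))
  }
  match_ct <- sum(vapply(seq_len(4), function(r)
    sgn(frame, pairs$e1[r], pairs$e2[r]) == sgn(fx$geometry$xyz, pairs$e1[r],
                                                pairs$e2[r]), logical(1)))
  expect_equal(compute_K(frame, fx$geometry, fx$ss), match_ct / 4)
})

test_that("mirror flagging follows the Q/K threshold quadrants", {
  expect_true(flag_mirror_trajectory(Q = 0.8, K = 0.3)$mirror_flag)
  expect_false(flag_mirror_trajectory(Q = 0.1, K = 0.3)$mirror_flag)
  expect_false(flag_mirror_trajectory(Q = 0.8, K = 0.9)$mirror_flag)
  expect_false(flag_mirror_trajectory(Q = 0.1, K = 0.9)$mirror_flag)
  v <- flag_mirror_trajectory(Q = c(0.7, 0.9), K = c(0.5, 0.6), traj_id = 7)
  expect_equal(v$mean_Q, 0.8)
  expect_equal(v$mean_K, 0.55)
  expect_true(v$mirror_flag)
})

test_that("trajectory toward a mirror image is flagged; toward itself is not", {
  hb <- make_helix_bundle()
  mir <- hb$geometry$xyz; mir[, 1] <- -mir[, 1]
  tr <- make_trajectory(hb$geometry, chain_geometry(mir), n_frames = 20,
                        noise_sd = 0.05, seed = 2)
  ops <- compute_frame_ops(tr$traj, hb$geometry, hb$ss, compute_g = FALSE)
  late <- ops[ops$frame > 15, ]
  expect_lt(mean(late$K), 0.6)
  vd <- flag_mirror_trajectory(late$Q, late$K)
  expect_true(vd$mirror_flag)
  # constant trajectory: Q and K stay at their native values
  tc <- make_trajectory(hb$geometry, hb$geometry, n_frames = 10,
                        noise_sd = 0.02, seed = 3)
  ops0 <- compute_frame_ops(tc$traj, hb$geometry, hb$ss, compute_g = FALSE)
  expect_true(all(ops0$Q > 0.9))
  expect_true(all(ops0$K == 1))
})

test_that("G rises when a native lasso unthreads along a trajectory", {
  fx <- lasso_with_loss(seed = 2)
  tr <- make_trajectory(fx$native, fx$pulled, n_frames = 12, noise_sd = 0,
                        seed = 1)
  ct <- find_contacts(fx$native, min_loop_sep = 10)
  ref_st <- contact_linking_status(fx$native$xyz, ct)
  G <- vapply(seq_len(12), function(f)
    compute_G(traj_frame(tr$traj, f), fx$native, ct, ref_status = ref_st)$G,
    numeric(1))
  expect_equal(G[1], 0)
  expect_gt(G[12], 0)
  expect_true(all(diff(G) >= -1e-12 | G[-1] > 0))   # monotone rise to the loss
})
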