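test_that("Shrake-Rupley SASA agrees with an independent implementation", {
  # isolated glycine backbone; reference value computed with biotite
  # (struc.sasa, probe 1.4 A, 2000 points, Bondi single-element radii)
  xyz <- rbind(c(0, 0, 0), c(1.458, 0, 0), c(2.009, 1.42, 0), c(1.251, 2.39, 0))
  s <- residue_sasa(xyz, residue = rep(1L, 4), element = c("N", "C", "C", "O"),
                    n_points = 960L)
  expect_lt(abs(s - 183.62) / 183.62, 0.05)
})

test_that("a residue enclosed in a shell is buried; the shell is exposed", {
  sp <- 3.2 * lassotop:::sphere_points(80)
  xyz <- rbind(c(0, 0, 0), sp)
  s <- residue_sasa(xyz, residue = c(1L, rep(2L, 80)), n_points = 256L)
  expect_lt(s[1], 1)
  expect_gt(s[2], 100)
})

test_that("probe size changes cleft accessibility more than convex accessibility", {
  # residue 1 at the bottom of a narrow cleft between two walls; residue 2 on
  # a convex exterior far away
  wall <- as.matrix(expand.grid(x = c(-2.5, 2.5), y = seq(-4, 4, 2),
                                z = seq(0, 6, 2)))
  xyz <- rbind(c(0, 0, 0), wall, c(40, 0, 0))
  res <- c(1L, rep(3L, nrow(wall)), 2L)
  rel <- function(probe) {
    s <- residue_sasa(xyz, residue = res, probe = probe, n_points = 256L,
                      n_residues = 3)
    s[1] / s[2]
  }
  expect_lt(rel(2.8), rel(1.4))   # doubling the probe shuts the cleft first
})

test_that("surface distance respects the straight-line lower bound and slab arcs", {
  # two exposed pseudo-residues on a convex pair
  geo <- chain_geometry(rbind(c(0, 0, 0), c(0, 30, 0), c(10, 15, 0)))
  d <- sasd(geo, 1, 2, grid = 2)
  expect_gte(d, 30)
  # slab fixture: residues on opposite faces, path must round the rim
  gs <- seq(-10, 10, 2.5)
  slab <- as.matrix(expand.grid(x = gs, y = gs, z = 0))
  pts <- rbind(c(0, 0, 5), slab, c(0, 0, -5))
  geo2 <- chain_geometry(pts)
  d2 <- sasd(geo2, 1, nrow(pts), grid = 1.25)
  arc <- 2 * sqrt(11.7^2 + 5^2)   # out to just past the rim and back
  expect_gte(d2, 10)              # straight-line distance
  expect_lt(abs(d2 - arc) / arc, 0.15)
})

test_that("buried endpoints give the unreachable sentinel and XP 0", {
  sp <- 3.2 * lassotop:::sphere_points(80)
  geo <- chain_geometry(rbind(c(0, 0, 0), sp))
  expect_identical(sasd(geo, 1, 5), Inf)
  expect_equal(xp_score(Inf), 0)
})

test_that("crosslink propensity is a monotone logistic in SASD", {
  expect_equal(xp_score(33), 0.5)
  expect_gt(xp_score(0), 0.99)
  grid <- xp_score(seq(0, 120, 5))
  expect_true(all(diff(grid) <= 0))
  expect_equal(xp_score(c(30, 36), d0 = 33, s = 3),
               1 / (1 + exp(c(-1, 1))))
})

test_that("cut-site features sum SASA over truncated +/-5 windows", {
  sm <- matrix(1, nrow = 3, ncol = 20)
  f <- lip_features(sm, cutsites = c(3L, 10L), window = 5L)
  expect_equal(dim(f), c(3L, 2L))
  expect_equal(f[1, ], c(site3 = 8, site10 = 11))   # window truncated at N-term
  expect_error(lip_features(sm, cutsites = 25L), "range")
})

test_that("identical ensembles yield null-looking adjusted p-values", {
  set.seed(4)
  feat <- matrix(rnorm(100 * 4), 100)
  res <- ensemble_consistency_test(feat[1:50, ], feat[51:100, ], n_perm = 499,
                                   seed = 1)
  expect_true(all(res$table$p_adj > 0.05))
  expect_equal(res$n_consistent, 0L)
})

test_that("a planted accessibility shift is detected with the BH gate", {
  ms <- make_ms_tables(n_sites = 4, planted_effects = c(2, 0, 0, 0),
                       n_frames_per_ensemble = 30, seed = 6)
  sas_n <- t(sapply(seq_len(ms$native$n_frames), function(f)
    geometry_sasa(chain_geometry(traj_frame(ms$native, f)), n_points = 128L)))
  sas_m <- t(sapply(seq_len(ms$misfolded$n_frames), function(f)
    geometry_sasa(chain_geometry(traj_frame(ms$misfolded, f)), n_points = 128L)))
  fn <- lip_features(sas_n, ms$cutsites)
  fm <- lip_features(sas_m, ms$cutsites)
  res <- ensemble_consistency_test(fm, fn, n_perm = 999, seed = 2)
  # the planted site must pass the BH gate; displacing its window also
  # re-exposes spatial neighbours, so other sites may legitimately shift too
  expect_true(res$table$consistent[1])
  expect_gte(res$n_consistent, 1L)
})

test_that("BH adjustment matches the textbook step-up rule", {
  p <- c(0.01, 0.02, 0.04, 0.5)
  adj <- stats::p.adjust(p, "BH")
  expect_equal(adj < 0.05, bh_reject_oracle(p, 0.05))
  # step-up stops at k* = 2: p_(3) = 0.04 > 3/4 * 0.05
  expect_equal(sum(adj < 0.05), 2L)
  set.seed(10)
  for (rep in 1:50) {
    pv <- runif(sample(3:12, 1))^sample(1:3, 1)
    expect_equal(stats::p.adjust(pv, "BH") < 0.05, bh_reject_oracle(pv, 0.05))
  }
})

test_that("representative-structure grouping separates planted signatures", {
  set.seed(12)
  native <- matrix(rnorm(200), 50, 4)
  state <- matrix(0, 50, 4)                   # baseline inside every native CI
  state[1:20, 1] <- 10                        # signature A: signal 1 out of CI
  state[21:50, 3] <- -10                      # signature B: signal 3 out of CI
  ch <- c(rep(list(1L), 20), rep(list(2L), 30))
  grp <- select_representative_structures(state, native, change_ids = ch,
                                          micro_prob = seq(0.5, 1, length.out = 50))
  expect_equal(nrow(grp), 2L)
  expect_equal(sum(grp$n_frames), 50L)
  # highest microstate probability wins within each group
  expect_true(20 %in% grp$representative && 50 %in% grp$representative)
  # identical frames: a single (possibly empty) signature group
  flat_s <- matrix(0, 10, 2); flat_n <- matrix(rnorm(40), 20, 2)
  g1 <- select_representative_structures(flat_s, flat_n)
  expect_equal(nrow(g1), 1L)
})
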