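test_that("contact detection matches an exhaustive distance scan and thresholds", {
  # explicit two-point threshold checks
  mk <- function(d) chain_geometry(rbind(c(0, 0, 0), cbind(2 * (1:10), 5, 0),
                                         c(d, 0, 0)))
  ct <- find_contacts(mk(7.9), min_loop_sep = 5)
  expect_true(any(ct$i == 1 & ct$j == 12))
  ct <- find_contacts(mk(8.1), min_loop_sep = 5)
  expect_false(any(ct$i == 1 & ct$j == 12))
  # brute-force oracle on a random coil
  set.seed(42)
  steps <- matrix(rnorm(19 * 3), ncol = 3)
  steps <- steps / sqrt(rowSums(steps^2)) * 3.8
  coil <- chain_geometry(apply(rbind(0, steps), 2, cumsum))
  ct <- find_contacts(coil, min_loop_sep = 4)
  brute <- NULL
  for (i in 1:19) for (j in (i + 1):20)
    if (j - i >= 4 && sqrt(sum((coil$xyz[i, ] - coil$xyz[j, ])^2)) <= 8)
      brute <- rbind(brute, c(i, j))
  expect_equal(cbind(ct$i, ct$j), brute, ignore_attr = TRUE)
})

test_that("heavy-atom contact mode uses the minimum heavy-atom distance", {
  xyz <- rbind(c(0, 0, 0), cbind(3 * (1:10), 20, 0), c(30, 0, 0))
  heavy <- c(list(rbind(CA = c(0, 0, 0), CB = c(2, 0, 0))),
             lapply(1:10, function(k) rbind(CA = c(3 * k, 20, 0))),
             list(rbind(CA = c(30, 0, 0), CB = c(6, 0, 0))))
  geo <- chain_geometry(xyz, heavy = heavy)
  ct <- find_contacts(geo, mode = "heavy_4p5A", min_loop_sep = 5)
  # CB-CB distance 4 A although CA-CA distance is 30 A
  expect_true(any(ct$i == 1 & ct$j == 12))
  # and Calpha fallback warns when heavy atoms are absent
  geo_ca <- chain_geometry(xyz)
  expect_warning(find_contacts(geo_ca, mode = "heavy_4p5A", min_loop_sep = 5),
                 "falling back")
  expect_error(find_contacts(geo_ca, mode = "heavy_4p5A", min_loop_sep = 5,
                             fallback = FALSE), "heavy")
})

test_that("partial linking reproduces ring-through-line topology and its symmetries", {
  th <- 2 * pi * (0:59) / 60
  ring <- cbind(10 * cos(th), 10 * sin(th), 0)
  line <- cbind(0.5, 0, seq(-60, 60, length.out = 40))
  xyz <- rbind(ring, line)
  g <- partial_linking(xyz, c(1, 60), c(61, 100))
  expect_gt(abs(g), 0.95); expect_lt(abs(g), 1.05)
  expect_lt(abs(g - oracle_linking(xyz, c(1, 60), c(61, 100))), 0.02)
  # coplanar curves do not link
  flat <- rbind(ring, cbind(seq(25, 60, length.out = 20), 5, 0))
  expect_lt(abs(partial_linking(flat, c(1, 60), c(61, 80))), 0.05)
  # mirror antisymmetry is exact
  mir <- xyz; mir[, 1] <- -mir[, 1]
  expect_equal(partial_linking(mir, c(1, 60), c(61, 100)), -g, tolerance = 1e-12)
  # rigid-transform invariance
  set.seed(7)
  for (rep in 1:5) {
    q <- qr.Q(qr(matrix(rnorm(9), 3)))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    moved <- xyz %*% q + matrix(rnorm(3), nrow(xyz), 3, byrow = TRUE)
    expect_lt(abs(partial_linking(moved, c(1, 60), c(61, 100)) - g), 1e-9)
  }
  expect_error(partial_linking(xyz, c(1, 60), c(50, 80)), "overlap")
})

test_that("linking numbers round at the 0.6 remainder threshold", {
  expect_identical(round_linking(0.59), 0L)
  expect_identical(round_linking(0.61), 1L)
  expect_identical(round_linking(-0.61), -1L)
  expect_identical(round_linking(1.65), 2L)
  expect_identical(round_linking(1.55), 1L)
  expect_identical(round_linking(0.6), 1L)      # ties round away from zero
  expect_identical(round_linking(-0.6), -1L)
  expect_identical(round_linking(c(0.2, -2.7, 2.59)), c(0L, -3L, 2L))
})

test_that("lasso detection recovers the planted loop family and nothing on an extended chain", {
  lz <- make_lasso(seed = 3)
  recs <- detect_ncles(lz$geometry)
  expect_gt(length(recs), 0)
  df <- as.data.frame(recs)
  expect_true(all(df$gln_C == lz$truth$gln))
  expect_true(all(df$tail == "C"))
  # every detected loop is a near-duplicate of the planted closure
  expect_true(all(abs(df$i - lz$truth$loop[1]) <= 4))
  expect_true(all(abs(df$j - lz$truth$loop[2]) <= 4))
  # extended chain: no contacts, no loops
  ext <- chain_geometry(cbind(3.8 * (1:50), 0, 0))
  expect_length(detect_ncles(ext), 0)
})

test_that("detection is deterministic and independent of contact ordering", {
  lz <- make_lasso(seed = 5, noise_sd = 0.2)
  ct <- find_contacts(lz$geometry)
  base <- as.data.frame(detect_ncles(lz$geometry, contacts = ct))
  for (rep in 1:5) {
    sh <- ct[sample(nrow(ct)), , drop = FALSE]
    expect_equal(as.data.frame(detect_ncles(lz$geometry, contacts = sh)), base)
  }
})

test_that("crossing localisation finds planted pierces with correct chirality", {
  for (ch in c(1L, -1L)) {
    lz <- make_lasso(chirality = ch, seed = 11)
    tw <- lassotop:::tail_windows(lz$truth$loop[1], lz$truth$loop[2],
                                  nrow(lz$geometry$xyz))
    cr <- find_crossings(lz$geometry$xyz, lz$truth$loop, tw$C, method = "surface")
    expect_equal(nrow(cr), 1L)
    expect_lte(abs(cr$residue - lz$truth$crossings), 1L)
    expect_equal(cr$chirality, ch)
    # sliding window agrees on the pierce neighbourhood
    sl <- find_crossings(lz$geometry$xyz, lz$truth$loop, tw$C, method = "sliding")
    expect_equal(nrow(sl), 1L)
    expect_lte(abs(sl$residue - lz$truth$crossings), 8L)
    expect_equal(sl$chirality, ch)
  }
})

test_that("double pierce yields two same-chirality crossings whose signed sum is the gln", {
  lz <- make_lasso(n_pierces = 2L, seed = 13)
  tw <- lassotop:::tail_windows(lz$truth$loop[1], lz$truth$loop[2],
                                nrow(lz$geometry$xyz))
  cr <- find_crossings(lz$geometry$xyz, lz$truth$loop, tw$C, method = "surface")
  expect_equal(nrow(cr), 2L)
  expect_equal(sum(cr$chirality), 2L)
  g <- partial_linking(lz$geometry$xyz, lz$truth$loop, tw$C)
  expect_equal(sum(cr$chirality), round_linking(g))
  expect_true(all(abs(sort(cr$residue) - sort(lz$truth$crossings)) <= 1))
})
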