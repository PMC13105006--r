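# Fixtures shared across test files; everything is generated in code.

# Hand-written 5-residue Calpha PDB, optionally with an altloc pair on
# residue 3 and/or a numbering gap after residue 3.
toy_pdb_text <- function(altloc = FALSE, gap = FALSE) {
  at <- function(serial, resno, x, alt = " ", occ = "1.00")
    sprintf("ATOM  %5d  CA %sALA A%4d    %8.3f%8.3f%8.3f  %s  0.00           C",
            serial, alt, resno, x, 0, 0, occ)
  lines <- c(at(1, 1, 0.0), at(2, 2, 3.8))
  if (altloc) {
    lines <- c(lines,
               at(3, 3, 7.6, alt = "A", occ = "0.40"),
               at(4, 3, 7.9, alt = "B", occ = "0.60"))
  } else {
    lines <- c(lines, at(3, 3, 7.6))
  }
  r4 <- if (gap) 5L else 4L
  lines <- c(lines, at(5, r4, 11.4), at(6, r4 + 1L, 15.2), "END")
  lines
}

write_toy_pdb <- function(path, ...) {
  writeLines(toy_pdb_text(...), path)
  path
}

# A lasso geometry plus an "unthreaded" variant: the thread section is
# translated far along +z so it no longer pierces the loop, while the loop
# and leader are untouched.
lasso_with_loss <- function(seed = 1L) {
  lz <- make_lasso(seed = seed)
  geo <- lz$geometry
  pulled <- geo$xyz
  thread_idx <- (lz$truth$loop[2] + 1L):nrow(pulled)
  pulled[thread_idx, 3] <- pulled[thread_idx, 3] + 400
  list(native = geo, pulled = chain_geometry(pulled), truth = lz$truth)
}

# Four 2-residue "strand" elements with contact pairs (1,2), (2,3), (3,4),
# (2,4); reversing element 1 in a frame flips exactly one pair's chirality.
four_element_fixture <- function() {
  seg <- function(p, d) rbind(p, p + d)
  xyz <- rbind(
    seg(c(-8, -4, 0), c(3, 2, -1)),    # e1  (contacts e2 only)
    seg(c(0, 0, 0),   c(1, 4, 0)),     # e2  (contacts e1, e3, e4)
    seg(c(5, 5, 2),   c(-1, 4, 2)),    # e3  (contacts e2, e4)
    seg(c(6, 0, 3),   c(3, 2, -2)))    # e4  (contacts e2, e3)
  ss <- secondary_elements(data.frame(start = c(1, 3, 5, 7),
                                      end = c(2, 4, 6, 8),
                                      type = "strand"))
  list(geometry = chain_geometry(xyz), ss = ss)
}

# Build an ncle record by hand (bypasses detection) for clustering tests.
mk_record <- function(i, j, cross_res, cross_chir, tail = "C",
                      g = 0.9 * max(abs(cross_chir))) {
  gs <- sum(cross_chir)
  cr <- data.frame(residue = as.integer(cross_res),
                   chirality = as.integer(cross_chir),
                   tail = rep(tail, length(cross_res)))
  rec <- list(loop = c(as.integer(i), as.integer(j)), tail = tail,
              g_N = if (tail == "N") gs * 0.95 else 0,
              g_C = if (tail == "C") gs * 0.95 else 0,
              gln_N = if (tail == "N") as.integer(gs) else 0L,
              gln_C = if (tail == "C") as.integer(gs) else 0L,
              crossings = cr)
  class(rec) <- "ncle"
  rec
}

as_ncle_list <- function(...) structure(list(...), class = "ncle_list")
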