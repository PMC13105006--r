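# ---- observability filters -------------------------------------------------

#' Coverage filter and sum-of-peptide-abundance (SPA) per protein
#'
#' Proteins are retained when the fraction of canonical-sequence residues
#' detected in the untreated condition reaches `coverage_min` (default 0.5).
#' SPA, a proxy for natural protein abundance, is the sum over detected
#' peptides of the median untreated abundance across replicates.
#'
#' @param peptides data.frame with columns `protein`, `start`, `end`
#'   (residue positions) and one or more `abundance*` replicate columns.
#' @param lengths named vector of canonical protein lengths.
#' @param coverage_min minimum detected-residue coverage (default 0.5).
#' @return data.frame per protein: `protein`, `coverage`, `spa`, `kept`.
#' @export
apply_observability_filters <- function(peptides, lengths, coverage_min = 0.5) {
  ab_cols <- grep("^abundance", names(peptides), value = TRUE)
  stopifnot(length(ab_cols) >= 1)
  out <- do.call(rbind, lapply(names(lengths), function(pr) {
    pp <- peptides[peptides$protein == pr, , drop = FALSE]
    if (nrow(pp) == 0L)
      return(data.frame(protein = pr, coverage = 0, spa = 0, kept = FALSE))
    covered <- logical(lengths[[pr]])
    for (r in seq_len(nrow(pp))) covered[pp$start[r]:pp$end[r]] <- TRUE
    med <- apply(as.matrix(pp[, ab_cols, drop = FALSE]), 1, stats::median)
    cov <- mean(covered)
    data.frame(protein = pr, coverage = cov, spa = sum(med),
               kept = cov >= coverage_min)
  }))
  rownames(out) <- NULL
  out
}

# ---- residue evidence tables -----------------------------------------------

#' Build the per-residue evidence table for one protein
#'
#' `region = 1` for residues inside any representative NCLE loop or within
#' +/- `cross_window` residues of any crossing residue; `response = 1` at
#' significant cut-site residues. Confounder columns are carried through.
#'
#' @param n protein length (residues).
#' @param clusters `ncle_clusters` of representative native entanglements
#'   (may be empty).
#' @param signal_residues residues with a significant conformational-change
#'   signal.
#' @param protein_id identifier column value.
#' @param amino_acid optional per-residue one-letter codes.
#' @param rel_sasa optional per-residue relative solvent accessibility.
#' @param mask optional 0/1 observability per residue (1 = observed).
#' @param cross_window half-width of the entangled region around a crossing
#'   (default 5 residues).
#' @return data.frame with columns `protein_id`, `residue_index`, `response`,
#'   `region`, `amino_acid`, `rel_sasa`, `mask`.
#' @export
build_residue_table <- function(n, clusters, signal_residues,
                                protein_id = "prot", amino_acid = NULL,
                                rel_sasa = NULL, mask = NULL, cross_window = 5L) {
  if (any(signal_residues < 1 | signal_residues > n))
    stop("signal residue beyond protein length ", n)
  region <- integer(n)
  for (cl in clusters) {
    rec <- cl$representative
    region[rec$loop[1]:rec$loop[2]] <- 1L
    for (cr in rec$crossings$residue)
      region[max(1L, cr - cross_window):min(n, cr + cross_window)] <- 1L
  }
  response <- integer(n)
  response[signal_residues] <- 1L
  data.frame(protein_id = protein_id, residue_index = seq_len(n),
             response = response, region = region,
             amino_acid = if (is.null(amino_acid)) rep("A", n) else amino_acid,
             rel_sasa = if (is.null(rel_sasa)) rep(NA_real_, n) else rel_sasa,
             mask = if (is.null(mask)) rep(1L, n) else as.integer(mask))
}

# ---- logistic regression ---------------------------------------------------

#' Logistic regression of misfolding signals on structural region
#'
#' Maximum-likelihood logistic fit (IRLS via `stats::glm`) of the response
#' (significant conformational change at a residue) on the supplied formula
#' terms; masked residues are excluded. Coefficients are reported with Wald
#' p-values and odds ratios. Complete separation on the `region` term is
#' flagged with an infinite-OR sentinel rather than an error.
#'
#' @param table residue evidence table (rbind of [build_residue_table()]
#'   outputs for one or many proteins).
#' @param formula model formula, e.g. `response ~ amino_acid + region`.
#' @return object of class `misfold_regression`: data.frame of coefficients
#'   (`term`, `estimate`, `se`, `p`, `odds_ratio`) with attributes
#'   `n` (rows fitted), `separation` (logical), `formula`.
#' @export
fit_misfolding_regression <- function(table, formula = response ~ region) {
  tab <- table[is.na(table$mask) | table$mask == 1L, , drop = FALSE]
  if (length(unique(tab$response)) < 2)
    stop("response has fewer than 2 distinct values after masking")
  sep <- FALSE
  if ("region" %in% all.vars(formula)) {
    ct <- table(tab$region, tab$response)
    if (nrow(ct) == 2 && any(ct == 0)) sep <- TRUE
  }
  fit <- suppressWarnings(stats::glm(formula, data = tab, family = stats::binomial()))
  sm <- summary(fit)$coefficients
  out <- data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
                    p = sm[, 4], odds_ratio = exp(sm[, 1]))
  if (sep) {
    r <- grep("^region", out$term)
    out$odds_ratio[r] <- ifelse(out$estimate[r] > 0, Inf, 0)
  }
  rownames(out) <- NULL
  structure(out, n = nrow(tab), separation = sep, formula = formula,
            class = c("misfold_regression", "data.frame"))
}

#' Benjamini-Hochberg correction across region-term p-values of several fits
#'
#' @param fits list of `misfold_regression` objects (one per condition set).
#' @param alpha FDR level.
#' @return data.frame `condition`, `p`, `p_adj`, `significant`.
#' @export
adjust_region_pvalues <- function(fits, alpha = 0.05) {
  p <- vapply(fits, function(f) f$p[grep("^region", f$term)][1], numeric(1))
  adj <- stats::p.adjust(p, method = "BH")
  data.frame(condition = names(fits) %||% seq_along(fits), p = p, p_adj = adj,
             significant = adj < alpha)
}

# ---- Monte Carlo candidate selection ---------------------------------------

# region log-odds of one group of proteins: pooled residue rows with
# per-protein intercepts, so between-protein base-rate differences do not
# contaminate the within-protein region effect
group_beta <- function(tables, members) {
  rows <- do.call(rbind, tables[members])
  rows <- rows[rows$mask == 1L, , drop = FALSE]
  y <- rows$response
  if (length(unique(y)) < 2 || length(unique(rows$region)) < 2) return(NA_real_)
  pid <- factor(rows$protein_id)
  x <- if (nlevels(pid) > 1)
    cbind(stats::model.matrix(~ pid), region = rows$region)
  else cbind(1, region = rows$region)
  fit <- suppressWarnings(stats::glm.fit(x, y, family = stats::binomial()))
  fit$coefficients[["region"]]
}

#' Rank-weighted Monte Carlo energy of a set of group coefficients
#'
#' Groups are ordered by their region coefficient ascending. The default
#' `"or"` objective scores the top-ranked group's odds ratio,
#' `E = -n * exp(beta_(n))`: its minima concentrate the proteins with the
#' strongest positive misfolding bias in the single top-ranked group, which
#' is exactly what the candidate selection uses, while swaps among the lower
#' ranks stay energy-neutral and keep the chain exploring. The `"beta"`
#' objective, `E = -sum_g g * beta_(g)`, weights every rank linearly and
#' treats both tails symmetrically; its minima spread strong proteins across
#' the upper ranks and pool strongly negative proteins in the bottom rank,
#' so it ranks all groups but does not concentrate candidates.
#'
#' @param betas per-group region log-odds coefficients.
#' @param objective `"or"` (default) or `"beta"`.
#' @return scalar energy.
#' @export
mc_energy <- function(betas, objective = c("or", "beta")) {
  objective <- match.arg(objective)
  s <- sort(betas)
  if (objective == "or") -length(s) * exp(s[length(s)])
  else -sum(seq_along(s) * s)
}

#' Metropolis Monte Carlo selection of misfolding-prone protein subsets
#'
#' Proteins start in a random balanced assignment to `n_groups` groups. Each
#' step proposes swapping one protein between two groups, refits the region
#' log-odds of the affected groups, recomputes the rank-weighted energy
#' `E = -sum_g g * beta_(g)` (betas sorted ascending) and accepts with the
#' Metropolis probability `min(1, exp(-dE / T))` under a geometric
#' temperature schedule `T(t) = T0 * gamma^t`. After the trace, groups are
#' rank-ordered by their mean odds ratio over the last `rank_window` steps;
#' with `n_runs > 1` independent runs, consensus candidates are proteins in
#' the top group in more than `consensus` of runs.
#'
#' @param tables named list of residue evidence tables, one per protein.
#' @param n_groups number of groups (default 4; at least 3).
#' @param n_steps Monte Carlo steps (default 200000; scale down for small
#'   problems).
#' @param T0 initial temperature.
#' @param gamma geometric decay per step (1 = constant temperature).
#' @param seed RNG seed.
#' @param n_runs independent runs for the consensus (default 1).
#' @param rank_window trailing steps averaged for the ranking (default 100).
#' @param consensus top-group membership fraction for a consensus candidate.
#' @return list with `assignment` (final groups, last run), `trace`
#'   (data.frame `step`, `E`, `T`, `accepted`, per-group beta columns),
#'   `ranking` (groups by trailing mean OR, best first), `top_proteins`
#'   (last run) and `candidates` (consensus across runs).
#' @export
monte_carlo_select <- function(tables, n_groups = 4L, n_steps = 2000L,
                               T0 = 1, gamma = 1, seed = 1L, n_runs = 1L,
                               rank_window = 100L, consensus = 0.7,
                               objective = c("or", "beta")) {
  objective <- match.arg(objective)
  stopifnot(n_groups >= 3, length(tables) >= 2 * n_groups)
  np <- length(tables)
  prot_names <- names(tables) %||% paste0("p", seq_len(np))
  run_once <- function(run_seed) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(run_seed)
    assign <- sample(rep(seq_len(n_groups), length.out = np))
    betas <- vapply(seq_len(n_groups), function(g)
      group_beta(tables, which(assign == g)), numeric(1))
    if (anyNA(betas)) stop("unfittable initial group (degenerate response or region)")
    E <- mc_energy(betas, objective)
    Tt <- T0
    trace <- matrix(NA_real_, n_steps, 4 + n_groups)
    acc_n <- 0L
    for (st in seq_len(n_steps)) {
      gpair <- sample.int(n_groups, 2)
      pa <- sample(which(assign == gpair[1]), 1)
      pb <- sample(which(assign == gpair[2]), 1)
      prop <- assign
      prop[pa] <- gpair[2]; prop[pb] <- gpair[1]
      nb <- betas
      nb[gpair[1]] <- group_beta(tables, which(prop == gpair[1]))
      nb[gpair[2]] <- group_beta(tables, which(prop == gpair[2]))
      if (anyNA(nb)) {
        trace[st, ] <- c(st, E, Tt, 0, betas)
        Tt <- Tt * gamma
        next
      }
      newE <- mc_energy(nb, objective)
      dE <- newE - E
      if (dE <= 0 || (is.finite(Tt) && Tt > 0 && stats::runif(1) < exp(-dE / Tt)) ||
          is.infinite(Tt)) {
        assign <- prop; betas <- nb; E <- newE; acc_n <- acc_n + 1L
        trace[st, ] <- c(st, E, Tt, 1, betas)
      } else {
        trace[st, ] <- c(st, E, Tt, 0, betas)
      }
      Tt <- Tt * gamma
    }
    trace <- as.data.frame(trace)
    names(trace) <- c("step", "E", "T", "accepted", paste0("beta_g", seq_len(n_groups)))
    win <- trace[max(1, n_steps - rank_window + 1):n_steps, , drop = FALSE]
    mean_or <- exp(colMeans(win[, paste0("beta_g", seq_len(n_groups)), drop = FALSE]))
    ranking <- order(-mean_or)
    list(assignment = assign, trace = trace, mean_or = mean_or,
         ranking = ranking, acceptance = acc_n / n_steps,
         top_proteins = prot_names[assign == ranking[1]])
  }
  runs <- lapply(seq_len(n_runs), function(r) run_once(seed + r - 1L))
  last <- runs[[n_runs]]
  top_count <- table(unlist(lapply(runs, `[[`, "top_proteins")))
  candidates <- names(top_count)[as.vector(top_count) / n_runs > consensus]
  list(assignment = last$assignment, trace = last$trace,
       ranking = last$ranking, mean_or = last$mean_or,
       acceptance = last$acceptance, top_proteins = last$top_proteins,
       candidates = candidates, runs = runs)
}

#' Recompute the Monte Carlo energy from a stored assignment
#'
#' Bookkeeping identity check: the energy is exactly recomputable from any
#' assignment.
#'
#' @param tables list of residue evidence tables.
#' @param assignment group id per protein.
#' @param objective energy form, as in [mc_energy()].
#' @export
mc_energy_from_assignment <- function(tables, assignment,
                                      objective = c("or", "beta")) {
  betas <- vapply(sort(unique(assignment)), function(g)
    group_beta(tables, which(assignment == g)), numeric(1))
  mc_energy(betas, objective)
}
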