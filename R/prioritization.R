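# Minimum-set conservation prioritization over grid cells: select planning
# units of minimum total cost such that every species' standardized-abundance
# target is held, with shortfalls penalized by species penalty factors.
# Solved by simulated annealing (compiled inner loop) with greedy shortfall
# repair and redundancy pruning; a brute-force enumerator serves as an exact
# oracle on tiny problems.

#' Build a minimum-set planning problem
#'
#' Scenario 1 minimizes area (unit cost 1 per cell); scenario 2 adds the
#' general human-use score (`cost = 1 + human_use`). Features are the species
#' standardized-abundance layers; each target is a proportion of the
#' feature's total amount; species penalty factors default to
#' `spf_base * max(total) / total_f` so scarcer features carry
#' proportionally larger shortfall penalties.
#'
#' @param cells data.frame with `cell_id` and, for scenario 2, `human_use`.
#' @param amounts species x cells matrix (or data.frame) of non-negative
#'   standardized abundances; rownames are species.
#' @param scenario 1 (area cost) or 2 (human-use cost).
#' @param target proportion in (0, 1] of each feature total (typical levels
#'   0.10, 0.30, 0.50).
#' @param spf optional per-feature penalty factors (> 0).
#' @param spf_base multiplier for the default SPF rule.
#' @return object of class `planning_problem`.
#' @export
build_problem <- function(cells, amounts, scenario = 1, target = 0.10,
                          spf = NULL, spf_base = 10) {
  amounts <- as.matrix(amounts)
  stopifnot(scenario %in% c(1, 2), ncol(amounts) == nrow(cells),
            all(amounts >= 0))
  if (!(target > 0 && target <= 1)) stop("target must be in (0, 1]")
  cost <- if (scenario == 1) rep(1, nrow(cells)) else {
    if (is.null(cells$human_use))
      stop("scenario 2 requires a human_use column")
    1 + cells$human_use
  }
  totals <- rowSums(amounts)
  if (is.null(spf))
    spf <- spf_base * max(totals, 1e-12) / pmax(totals, 1e-12)
  stopifnot(all(spf > 0), all(cost > 0))
  structure(list(cell_id = cells$cell_id, cost = cost, amounts = amounts,
                 target_prop = target, targets = target * totals, spf = spf,
                 scenario = scenario, n_units = nrow(cells),
                 species = rownames(amounts)),
            class = "planning_problem")
}

#' Minimum-set objective of a selection
#'
#' `sum(cost[selected]) + sum_f spf_f * max(0, target_f - held_f)`.
#'
#' @param problem a [build_problem()] result.
#' @param selection logical vector over units, or integer indices.
#' @return scalar objective value.
#' @export
objective <- function(problem, selection) {
  sel <- as_selection(problem, selection)
  held <- as.numeric(problem$amounts %*% sel)
  sum(problem$cost[sel > 0]) +
    sum(problem$spf * pmax(0, problem$targets - held))
}

as_selection <- function(problem, selection) {
  if (is.logical(selection)) {
    stopifnot(length(selection) == problem$n_units)
    return(as.numeric(selection))
  }
  stopifnot(all(selection >= 1 & selection <= problem$n_units))
  sel <- numeric(problem$n_units)
  sel[selection] <- 1
  sel
}

# greedy shortfall repair: while some addition reduces penalty by more than
# its cost, add the best one; then prune units whose removal does not worsen
# the objective (most expensive first)
greedy_repair_prune <- function(problem, sel) {
  A <- problem$amounts; cost <- problem$cost
  held <- as.numeric(A %*% sel)
  repeat {
    short <- pmax(0, problem$targets - held)
    if (all(short <= 1e-12)) break
    red <- colSums(problem$spf * pmin(A, short))  # penalty averted by adding
    red[sel > 0] <- -Inf
    score <- red - cost
    j <- which.max(score)
    if (!is.finite(score[j]) || score[j] <= 0) break
    sel[j] <- 1
    held <- held + A[, j]
  }
  repeat {
    active <- which(sel > 0)
    if (length(active) == 0L) break
    improved <- FALSE
    for (j in active[order(-cost[active])]) {
      held_new <- held - A[, j]
      dpen <- sum(problem$spf * (pmax(0, problem$targets - held_new) -
                                   pmax(0, problem$targets - held)))
      if (dpen <= cost[j] + 1e-12) {
        sel[j] <- 0; held <- held_new; improved <- TRUE
      }
    }
    if (!improved) break
  }
  sel
}

#' Solve a planning problem by simulated annealing
#'
#' Single-cell add/remove moves with Boltzmann acceptance and geometric
#' cooling (initial temperature calibrated so roughly 80% of uphill moves are
#' accepted), followed by greedy shortfall repair and redundancy pruning.
#' The returned solution is never worse than the greedy-only solution.
#' Infeasible targets yield the irreducible shortfall, reported.
#'
#' @param problem a [build_problem()] result.
#' @param seed integer seed (runs are deterministic given it).
#' @param n_moves annealing iterations (default `10000 * max(1, n/100)`).
#' @param cooling geometric cooling factor per move.
#' @return object of class `prioritization_solution`: `selected` (unit
#'   indices), `objective`, `held`, `shortfall`, `seed`.
#' @export
anneal <- function(problem, seed = 1L, n_moves = NULL, cooling = 0.995) {
  set.seed(seed)
  n <- problem$n_units
  if (is.null(n_moves)) n_moves <- as.integer(10000 * max(1, n / 100))
  # calibration: typical uphill delta from random toggles of a random config
  sel0 <- as.numeric(stats::runif(n) < 0.3)
  ups <- c()
  held0 <- as.numeric(problem$amounts %*% sel0)
  obj0 <- objective(problem, sel0 > 0)
  for (k in seq_len(min(200, 4 * n))) {
    u <- sample.int(n, 1)
    s2 <- sel0; s2[u] <- 1 - s2[u]
    d <- objective(problem, s2 > 0) - obj0
    if (d > 0) ups <- c(ups, d)
  }
  t0 <- if (length(ups) > 0) stats::median(ups) / -log(0.8) else 1
  res <- .anneal_core(problem$amounts, problem$cost, problem$targets,
                      problem$spf, sel0 > 0, as.integer(n_moves), t0, cooling)
  sel_sa <- greedy_repair_prune(problem, as.numeric(res$selection))
  sel_greedy <- greedy_repair_prune(problem, numeric(n))
  obj_sa <- objective(problem, sel_sa > 0)
  obj_greedy <- objective(problem, sel_greedy > 0)
  sel <- if (obj_sa <= obj_greedy) sel_sa else sel_greedy
  held <- as.numeric(problem$amounts %*% sel)
  structure(list(selected = which(sel > 0),
                 objective = min(obj_sa, obj_greedy), held = held,
                 shortfall = pmax(0, problem$targets - held), seed = seed),
            class = "prioritization_solution")
}

#' @export
print.prioritization_solution <- function(x, ...) {
  cat(sprintf("solution: %d units, objective %.3f, total shortfall %.4g\n",
              length(x$selected), x$objective, sum(x$shortfall)))
  invisible(x)
}

#' Ensemble of independent annealing runs
#'
#' Runs the annealer `R` times under derived seeds; reports per-cell
#' selection frequency, the best (minimum-objective) solution, and the
#' upper-half frequency classes used for mapping.
#'
#' @param problem a [build_problem()] result.
#' @param R number of runs (default 100).
#' @param seed base seed; run `r` uses `seed + r`.
#' @param ... passed to [anneal()].
#' @return object of class `run_ensemble`: `frequency` (in [0, 1] per cell),
#'   `best` (a `prioritization_solution`), `runs` (list), `upper_half`
#'   (logical: cells in the upper 50% of positive selection frequencies).
#' @export
run_ensemble <- function(problem, R = 100, seed = 1L, ...) {
  stopifnot(R >= 1)
  runs <- lapply(seq_len(R), function(r) anneal(problem, seed + r, ...))
  freq <- numeric(problem$n_units)
  for (s in runs) freq[s$selected] <- freq[s$selected] + 1
  freq <- freq / R
  best <- runs[[which.min(vapply(runs, `[[`, 0, "objective"))]]
  pos <- freq[freq > 0]
  thr <- if (length(pos) > 0) stats::median(pos) else Inf
  structure(list(frequency = freq, best = best, runs = runs,
                 upper_half = freq >= thr & freq > 0, R = R, seed = seed),
            class = "run_ensemble")
}

#' Exact minimum-set optimum by exhaustive enumeration
#'
#' Enumerates all 2^n subsets (n <= 20) and returns the minimum-objective
#' selection; ties are broken by smaller cardinality, then lexicographically.
#' Used as the oracle for validating the annealer.
#'
#' @param problem a [build_problem()] result with at most 20 units.
#' @return a `prioritization_solution`.
#' @export
brute_force <- function(problem) {
  n <- problem$n_units
  if (n > 20L) stop("brute force refused for more than 20 units")
  if (n == 0L) {
    return(structure(list(selected = integer(),
                          objective = sum(problem$spf * problem$targets),
                          held = numeric(nrow(problem$amounts)),
                          shortfall = problem$targets, seed = NA),
                     class = "prioritization_solution"))
  }
  n_sub <- 2^n
  # bits matrix n x n_sub
  bits <- vapply(seq_len(n), function(b) {
    rep(rep(c(0, 1), each = 2^(b - 1)), length.out = n_sub)
  }, numeric(n_sub))
  bits <- t(bits)
  held <- problem$amounts %*% bits
  pen <- colSums(matrix(problem$spf * pmax(0, problem$targets - held),
                        nrow = nrow(problem$amounts)))
  costs <- as.numeric(problem$cost %*% bits)
  obj <- costs + pen
  card <- colSums(bits)
  ord <- order(obj, card, seq_len(n_sub))
  j <- ord[1]
  sel <- bits[, j] > 0
  structure(list(selected = which(sel), objective = obj[j],
                 held = as.numeric(problem$amounts %*% as.numeric(sel)),
                 shortfall = pmax(0, problem$targets -
                                    as.numeric(problem$amounts %*% as.numeric(sel))),
                 seed = NA),
            class = "prioritization_solution")
}

#' Write a planning problem as Marxan-dialect CSV tables
#'
#' `pu.csv` (id, cost), `spec.csv` (id, name, target, spf), `puvspr.csv`
#' (species, pu, amount).
#'
#' @param problem a [build_problem()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_marxan_tables <- function(problem, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(data.frame(id = problem$cell_id, cost = problem$cost),
                   file.path(dir, "pu.csv"), row.names = FALSE)
  utils::write.csv(data.frame(id = seq_along(problem$targets),
                              name = problem$species %||% seq_along(problem$targets),
                              target = problem$targets, spf = problem$spf),
                   file.path(dir, "spec.csv"), row.names = FALSE)
  idx <- which(problem$amounts > 0, arr.ind = TRUE)
  utils::write.csv(data.frame(species = idx[, 1],
                              pu = problem$cell_id[idx[, 2]],
                              amount = problem$amounts[idx]),
                   file.path(dir, "puvspr.csv"), row.names = FALSE)
  invisible(dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
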