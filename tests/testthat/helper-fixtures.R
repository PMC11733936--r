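# Shared fixture builders; everything is generated in code under a fixed
# seed so tests carry no data files.

# Screening records with a planted signal: actives score better (lower)
# than decoys by `separation` standard deviations.
make_screen_records <- function(n_active, n_decoy, separation = 2,
                                seed = 1) {
  set.seed(seed)
  data.frame(
    compound_id = sprintf("cmp%04d", seq_len(n_active + n_decoy)),
    label = c(rep("ACTIVE", n_active), rep("DECOY", n_decoy)),
    docking_score = c(rnorm(n_active, mean = -separation), rnorm(n_decoy)),
    stringsAsFactors = FALSE
  )
}

# Independent ROC AUC oracle: explicit loop over all active-decoy pairs
# with half credit for ties (larger oriented score = better).
brute_force_auc <- function(scores_oriented, active) {
  a <- scores_oriented[active]
  d <- scores_oriented[!active]
  total <- 0
  for (x in a) {
    for (y in d) {
      total <- total + (x > y) + 0.5 * (x == y)
    }
  }
  total / (length(a) * length(d))
}

# Benchmark records across targets with controllable per-target offsets.
make_bench_records <- function(n_per_target = 6, targets = c("T1", "T2"),
                               noise = 0.3, seed = 2) {
  set.seed(seed)
  do.call(rbind, lapply(seq_along(targets), function(i) {
    obs <- rnorm(n_per_target, mean = -3, sd = 1.2)
    data.frame(target_id = targets[i],
               ligand_id = sprintf("%s_L%d", targets[i],
                                   seq_len(n_per_target)),
               observed = obs,
               predicted = 2 * obs + 5 * i + rnorm(n_per_target, sd = noise),
               binding_mode_class = "allosteric",
               stringsAsFactors = FALSE)
  }))
}

# RMSD between two flat xyz vectors over the given atom indices.
xyz_rmsd <- function(a, b, atom_idx) {
  cols <- as.vector(t(outer(3 * (atom_idx - 1), 1:3, "+")))
  d <- matrix(a[cols] - b[cols], ncol = 3, byrow = TRUE)
  sqrt(mean(rowSums(d^2)))
}

# One-ligand event table shorthand (times NA = censored).
events_of <- function(times, t_max) {
  unbinding_events(seq_along(times), times, t_max)
}
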