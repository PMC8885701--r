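# Shared fixtures, built in code at test time.

# tiny hand-written cohort: 2 groups, 2 features
tiny_cohort <- function() {
  as_cohort(data.frame(
    id = paste0("p", 1:6),
    group = c("a", "a", "a", "b", "b", "b"),
    outcome = c(1, 0, 1, 0, 0, 1),
    x1 = c(0.5, -1.2, 0.3, 2.0, -0.7, 0.1),
    x2 = c(1.0, 0.4, -0.3, 0.8, -1.5, 0.2)
  ))
}

# moderately sized synthetic cohort with two groups of unequal size and
# unequal incidence, shared feature-outcome structure
demo_scenario <- function(seed = 42L) {
  scenario_spec(
    group_fractions = c(0.7, 0.3),
    target_incidences = c(0.10, 0.25),
    group_coefficients = list(c(1, -0.5, 0.25), c(1, -0.5, 0.25)),
    seed = seed
  )
}

# brute-force strict pairwise AUC complement (independent oracle for g_auc)
brute_g_auc <- function(scores, outcomes) {
  pos <- scores[outcomes == 1]
  neg <- scores[outcomes == 0]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  conc <- 0
  for (p in pos) for (n in neg) conc <- conc + (p > n)
  1 - conc / (length(pos) * length(neg))
}

# brute-force tie-aware AUC (independent oracle for auc)
brute_auc <- function(scores, outcomes) {
  pos <- scores[outcomes == 1]
  neg <- scores[outcomes == 0]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  s <- 0
  for (p in pos) for (n in neg) s <- s + (p > n) + 0.5 * (p == n)
  s / (length(pos) * length(neg))
}

# tiny end-to-end experiment configuration (smoke scale)
smoke_config <- function(seed = 1L) {
  experiment_config(
    scenario = demo_scenario(17),
    n = 800,
    approaches = c("balanced_erm", "dro_unadjusted"),
    model_specs = list(model_spec("logistic", learning_rate = 0.05)),
    eta_grid = 1, samplers = "balanced",
    stop_criteria = "population_loss",
    selection_criterion = "worst_group_loss",
    train_config = train_config(max_epochs = 3, batches_per_epoch = 6,
                                batch_size = 128, patience = 3),
    metrics = c("auc", "loss"), B = 50, seed = seed
  )
}

# quick two-part split of a cohort for direct train/dev use
simple_split <- function(cohort, dev_frac = 0.2, seed = 1L) {
  n <- nrow(cohort)
  idx <- withr::with_seed(seed, sample.int(n))
  ndev <- round(dev_frac * n)
  list(train = groupdro:::cohort_slice(cohort, idx[-seq_len(ndev)]),
       dev = groupdro:::cohort_slice(cohort, idx[seq_len(ndev)]))
}
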