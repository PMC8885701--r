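#' Define a synthetic subpopulation-cohort scenario
#'
#' A scenario describes K disjoint demographic subpopulations with unequal
#' sizes, per-group Gaussian feature distributions, per-group logistic
#' outcome models, target marginal outcome incidences and optional label
#' noise. It stands in for restricted inpatient / intensive-care cohorts:
#' group fractions of a few percent to a majority, and incidences in the low
#' single digits to ~0.25, match the structure of real inpatient admission
#' tables.
#'
#' @param group_fractions Simplex vector of length K (all entries > 0).
#' @param target_incidences Per-group target marginal incidences, each
#'   strictly inside (0, 1).
#' @param group_coefficients List of K numeric vectors of length `m`: the
#'   true per-group log-odds feature weights.
#' @param group_names Character vector of length K; defaults `g1..gK`.
#' @param group_means List of K numeric mean vectors for the Gaussian feature
#'   draws; default all zero.
#' @param group_cov List of K covariance matrices; default identity (keeps
#'   the group-wise Bayes-optimal predictor logistic in x).
#' @param label_noise Per-group probability in `[0, 0.5)` that an outcome is
#'   flipped after the Bernoulli draw; default 0.
#' @param seed Integer master seed for the scenario.
#' @return A `scenario_spec` list.
#' @export
scenario_spec <- function(group_fractions, target_incidences,
                          group_coefficients, group_names = NULL,
                          group_means = NULL, group_cov = NULL,
                          label_noise = NULL, seed = 1L) {
  K <- length(group_fractions)
  stopifnot(K >= 1, abs(sum(group_fractions) - 1) < 1e-8,
            all(group_fractions > 0),
            length(target_incidences) == K,
            is.list(group_coefficients), length(group_coefficients) == K)
  if (any(target_incidences <= 0 | target_incidences >= 1)) {
    abort("spec error: target incidences must lie strictly in (0, 1)",
          class = "groupdro_spec_error")
  }
  m <- length(group_coefficients[[1]])
  stopifnot(all(vapply(group_coefficients, length, integer(1)) == m))
  if (is.null(group_names)) group_names <- paste0("g", seq_len(K))
  ord <- order(group_names)
  if (is.null(group_means)) group_means <- rep(list(rep(0, m)), K)
  if (is.null(group_cov)) group_cov <- rep(list(diag(m)), K)
  if (is.null(label_noise)) label_noise <- rep(0, K)
  if (length(label_noise) == 1) label_noise <- rep(label_noise, K)
  if (any(label_noise < 0 | label_noise >= 0.5)) {
    abort("spec error: label_noise must be in [0, 0.5)",
          class = "groupdro_spec_error")
  }
  # store in vocabulary (sorted-name) order so downstream indexing matches
  structure(list(
    K = K, m = m,
    group_names = group_names[ord],
    group_fractions = group_fractions[ord],
    target_incidences = target_incidences[ord],
    group_coefficients = group_coefficients[ord],
    group_means = group_means[ord],
    group_cov = group_cov[ord],
    label_noise = label_noise[ord],
    seed = as.integer(seed)
  ), class = "scenario_spec")
}

# Gaussian draw for one group: n x m matrix
draw_features <- function(n, mu, Sigma) {
  m <- length(mu)
  # row-major fill: the first rows of a group's draw do not depend on how
  # many rows follow, so group substreams share prefixes across cohort sizes
  Z <- matrix(rnorm(n * m), n, m, byrow = TRUE)
  R <- chol(Sigma)
  sweep(Z %*% R, 2, mu, "+")
}

# Solve the per-group intercept so that the marginal incidence (after label
# noise) matches the target, by 1-D root finding on a Monte-Carlo estimate of
# E[sigmoid(b0 + x.beta)] under the group's feature distribution.
solve_intercept <- function(target, rho, beta, mu, Sigma, seed,
                            n_mc = 1e5) {
  q0 <- (target - rho) / (1 - 2 * rho)
  if (q0 <= 0 || q0 >= 1) {
    abort("spec error: target incidence infeasible under label noise",
          class = "groupdro_spec_error")
  }
  eta <- withr::with_seed(seed, drop(draw_features(n_mc, mu, Sigma) %*% beta))
  f <- function(b0) mean(plogis(b0 + eta)) - q0
  uniroot(f, c(-50, 50), tol = 1e-10)$root
}

#' Per-group intercepts implied by a scenario
#'
#' @param spec A [scenario_spec()].
#' @param n_mc Number of Monte-Carlo draws for the marginal-incidence
#'   integral; default `1e5`.
#' @return Numeric vector of length K, in vocabulary order.
#' @export
scenario_intercepts <- function(spec, n_mc = 1e5) {
  vapply(seq_len(spec$K), function(k) {
    solve_intercept(spec$target_incidences[k], spec$label_noise[k],
                    spec$group_coefficients[[k]], spec$group_means[[k]],
                    spec$group_cov[[k]],
                    seed = derive_seed(spec$seed, "intercept", spec$group_names[k]),
                    n_mc = n_mc)
  }, numeric(1))
}

#' Generate a synthetic cohort from a scenario
#'
#' Group sizes are multinomial in the declared fractions; features are drawn
#' from each group's Gaussian; outcomes are Bernoulli in a group-specific
#' logistic model whose intercept is pre-solved so the marginal per-group
#' incidence matches the target; outcomes are then flipped with the group's
#' label-noise probability. Each group consumes an independent substream of
#' the scenario seed, so adding a group never perturbs another group's draws.
#'
#' @param spec A [scenario_spec()].
#' @param n Total number of individuals (`n >= K`).
#' @param seed Optional integer overriding `spec$seed` for this draw.
#' @return A `cohort` tibble with feature columns `x1..xm`.
#' @examples
#' sp <- scenario_spec(c(0.5, 0.5), c(0.02, 0.20),
#'                     list(c(1, -1), c(0.5, 0.5)))
#' co <- generate_cohort(sp, 500)
#' group_summary(co)
#' @export
generate_cohort <- function(spec, n, seed = NULL) {
  stopifnot(inherits(spec, "scenario_spec"), n >= spec$K)
  seed <- seed %||% spec$seed
  b0 <- scenario_intercepts(spec)
  sizes <- withr::with_seed(
    derive_seed(seed, "sizes"),
    drop(rmultinom(1, n, spec$group_fractions))
  )
  parts <- lapply(seq_len(spec$K), function(k) {
    nk <- sizes[k]
    if (nk == 0) return(NULL)
    withr::with_seed(derive_seed(seed, "group", spec$group_names[k]), {
      X <- draw_features(nk, spec$group_means[[k]], spec$group_cov[[k]])
      p <- plogis(b0[k] + drop(X %*% spec$group_coefficients[[k]]))
      y <- rbinom(nk, 1, p)
      if (spec$label_noise[k] > 0) {
        flip <- rbinom(nk, 1, spec$label_noise[k]) == 1
        y[flip] <- 1L - y[flip]
      }
      colnames(X) <- paste0("x", seq_len(spec$m))
      dplyr::bind_cols(
        tibble::tibble(group = spec$group_names[k], outcome = as.integer(y)),
        tibble::as_tibble(X)
      )
    })
  })
  # rows stay in group blocks, each block in generation order: samplers and
  # split assignment randomize downstream, and block order keeps each
  # group's draw independent of the others
  tbl <- dplyr::bind_rows(parts)
  tbl$id <- sprintf("id%07d", seq_len(nrow(tbl)))
  as_cohort(tbl, group_levels = spec$group_names,
            require_nonempty_groups = FALSE)
}

#' Two-group scenario where subpopulation-optimal predictors conflict
#'
#' Builds the regime that motivates worst-case training: two groups share an
#' identical standard-Gaussian feature distribution and ~0.5 incidence, but
#' their true log-odds coefficient vectors are exact negatives. A single
#' low-capacity linear model cannot serve both; the pooled-ERM optimum tracks
#' the majority group and performs worse than chance on the minority, while a
#' worst-case-seeking learner retreats towards the uninformative predictor
#' that equalizes group losses.
#'
#' @param minority_fraction Minority group fraction, in (0, 0.5).
#' @param m Feature dimension; default 2.
#' @param effect_size Euclidean norm of the true coefficient vector;
#'   default 1.5 (a strong but realistic signal, group Bayes AUC ~ 0.86).
#' @param seed Scenario seed.
#' @return A [scenario_spec()] with groups `"majority"` and `"minority"`.
#' @export
conflict_scenario <- function(minority_fraction, m = 2L, effect_size = 1.5,
                              seed = 1L) {
  stopifnot(minority_fraction > 0, minority_fraction < 0.5)
  w <- rep(effect_size / sqrt(m), m)
  scenario_spec(
    group_fractions = c(1 - minority_fraction, minority_fraction),
    target_incidences = c(0.5, 0.5),
    group_coefficients = list(w, -w),
    group_names = c("majority", "minority"),
    seed = seed
  )
}

#' Serialize / deserialize a scenario as YAML
#'
#' @param spec A [scenario_spec()].
#' @param path File path.
#' @return `write_scenario()` returns `path` invisibly; `read_scenario()`
#'   returns a `scenario_spec`.
#' @export
write_scenario <- function(spec, path) {
  x <- unclass(spec)
  x$group_cov <- lapply(x$group_cov, function(S) apply(S, 1, as.numeric,
                                                       simplify = FALSE))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  x <- yaml::read_yaml(path)
  scenario_spec(
    group_fractions = as.numeric(x$group_fractions),
    target_incidences = as.numeric(x$target_incidences),
    group_coefficients = lapply(x$group_coefficients, as.numeric),
    group_names = as.character(x$group_names),
    group_means = lapply(x$group_means, as.numeric),
    group_cov = lapply(x$group_cov, function(rows) {
      do.call(rbind, lapply(rows, as.numeric))
    }),
    label_noise = as.numeric(x$label_noise),
    seed = x$seed
  )
}
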