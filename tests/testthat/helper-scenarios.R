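# Lazily computed, shared scenario runs for the evaluation test-suite.
# Several checks (type-I error, thresholds, power ordering) read different
# aspects of the same simulation families, so each family is run once.
# Problem sizes follow the evaluation design (10,000 variants, 100 causal);
# replicate counts are the package's evaluation choices.

.scenario_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .scenario_cache, inherits = FALSE))
    assign(name, force(expr), envir = .scenario_cache)
  get(name, envir = .scenario_cache, inherits = FALSE)
}

lt_ratio_runs <- function() cached("lt_ratio",
  run_scenario("lt_ratio", values = c(1, 5, 20, 50, 100), replicates = 20,
               seed = 4100, n_individuals = 3000))

# the n = 3000 arm of the sample-size family is the same design as the
# LT-ratio family's L = 5 arm, so those replicates are shared
sample_size_runs <- function() cached("sample_size", {
  part <- run_scenario("sample_size", values = c(1000, 2000, 10000),
                       replicates = c(9, 9, 4), seed = 4200, L = 5)
  lt <- lt_ratio_runs()
  arm3000 <- lt$replicates[lt$replicates$value == 5, ]
  arm3000$value <- 3000
  reps <- rbind(part$replicates[names(arm3000)], arm3000)
  agg3000 <- lt$aggregate[lt$aggregate$value == 5, ]
  agg3000$value <- 3000
  agg <- rbind(part$aggregate[names(agg3000)], agg3000)
  agg <- agg[order(agg$value), ]
  list(scenario = "sample_size", replicates = reps, aggregate = agg,
       n_failed = part$n_failed + lt$n_failed)
})

missingness_runs <- function() cached("missingness",
  run_scenario("missingness", values = c(0.15, 0.5), replicates = 6,
               seed = 4300, n_individuals = 3000, L = 5))

# pooled mean and Monte-Carlo standard error of a per-replicate column,
# weighting scenario values equally
family_mean_se <- function(res, col) {
  agg <- res$aggregate
  m <- mean(agg[[paste0(col, "_mean")]])
  se <- sqrt(sum(agg[[paste0(col, "_se")]]^2)) / nrow(agg)
  c(mean = m, se = se)
}
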