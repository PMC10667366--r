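# Scenario runner and metrics: Bonferroni thresholds, power and type-I error
# per effect type, multi- vs single-trait standard-error comparison, and the
# replicate loops for the LT-ratio, sample-size and missingness designs.

#' Bonferroni-corrected significance threshold
#'
#' `0.05` divided by the number of variants that passed the filters and were
#' scanned.
#'
#' @param n_tested count of tested variants (>= 1).
#' @export
bonferroni_threshold <- function(n_tested) {
  if (length(n_tested) != 1L || !is.finite(n_tested) || n_tested < 1)
    stop("need at least one tested variant")
  0.05 / n_tested
}

#' Power and type-I error of a scan against simulation truth
#'
#' Power is the fraction of causal (tested) variants with `p` below the
#' threshold, averaged over traits; type-I error is the analogous fraction
#' over non-causal tested variants — separately for the CS and LT effect
#' types.
#'
#' @param scan a `snp_scan`.
#' @param causal logical vector of causal flags per variant.
#' @param threshold significance threshold in `(0, 1]`.
#' @return list with `power_cs/power_lt/type1_cs/type1_lt` (trait-averaged),
#'   `per_trait` (2K x 2 matrix of per-trait rates), `n_tested`, `threshold`.
#' @export
compute_power_type1 <- function(scan, causal, threshold) {
  stopifnot(inherits(scan, "snp_scan"))
  if (!is.finite(threshold) || threshold <= 0 || threshold > 1)
    stop("threshold must lie in (0, 1]")
  K <- length(scan$traits)
  csr <- seq(1L, 2L * K, 2L); ltr <- seq(2L, 2L * K, 2L)
  tz <- scan$tested
  hit <- scan$p < threshold
  rate <- function(rows, cols) {
    if (!any(cols)) return(NA_real_)
    mean(hit[rows, cols & tz, drop = FALSE])
  }
  per_trait <- list(
    power = matrix(vapply(seq_len(K), function(k)
      c(rate(csr[k], causal), rate(ltr[k], causal)), numeric(2)), 2L, K,
      dimnames = list(c("CS", "LT"), scan$traits)),
    type1 = matrix(vapply(seq_len(K), function(k)
      c(rate(csr[k], !causal), rate(ltr[k], !causal)), numeric(2)), 2L, K,
      dimnames = list(c("CS", "LT"), scan$traits)))
  list(power_cs = rate(csr, causal), power_lt = rate(ltr, causal),
       type1_cs = rate(csr, !causal), type1_lt = rate(ltr, !causal),
       per_trait = per_trait, n_tested = sum(tz), threshold = threshold)
}

#' Paired standard-error comparison of two scans
#'
#' Matches variants by (variant_id, trait, effect) across a joint and a
#' single-trait scan and summarizes with the through-origin regression slope
#' of joint on single standard errors.
#'
#' @param joint,single tidy scan data.frames (see
#'   [as.data.frame.snp_scan()]), already restricted to comparable rows.
#' @return list with `pairs` (merged data.frame), `slope` (overall) and
#'   `slope_by_effect`.
#' @export
compare_se <- function(joint, single) {
  jk <- paste(joint$variant_id, joint$trait, joint$effect)
  sk <- paste(single$variant_id, single$trait, single$effect)
  if (!setequal(jk, sk)) {
    d <- c(setdiff(jk, sk), setdiff(sk, jk))
    stop("variant sets differ; e.g. ", paste(utils::head(d, 5L), collapse = "; "))
  }
  m <- merge(joint[, c("variant_id", "trait", "effect", "se")],
             single[, c("variant_id", "trait", "effect", "se")],
             by = c("variant_id", "trait", "effect"),
             suffixes = c("_joint", "_single"))
  m <- m[is.finite(m$se_joint) & is.finite(m$se_single), , drop = FALSE]
  sl <- function(x, y) sum(x * y) / sum(x * x)
  slope_eff <- vapply(split(m, m$effect), function(d)
    sl(d$se_single, d$se_joint), numeric(1))
  list(pairs = m, slope = sl(m$se_single, m$se_joint),
       slope_by_effect = slope_eff)
}

#' Run a simulation scenario family
#'
#' Loops simulate -> variance components -> association scan -> metrics over
#' replicates, for one of the three scenario families: `"lt_ratio"` (values
#' are LT attenuation scalars L at fixed n), `"sample_size"` (values are
#' sample sizes at fixed L) or `"missingness"` (values are fractions of
#' individuals partially measured for one of the traits; also runs the
#' single-trait comparator for that trait). Per-replicate seeds are
#' `seed + replicate counter`, recorded in the output.
#'
#' @param scenario scenario family.
#' @param values scenario values (L, n, or missingness fractions).
#' @param replicates replicates per value (recycled to `length(values)`).
#' @param seed master seed.
#' @param n_individuals sample size (ignored for `"sample_size"`).
#' @param L LT attenuation (ignored for `"lt_ratio"`).
#' @param n_variants,n_causal simulation sizes.
#' @param vc_mode `"truth"` (implied generating components) or `"estimate"`
#'   (pairwise AI-REML per replicate).
#' @param mac_min,mac_rule filter settings (see [apply_mac_filter()]).
#' @param missing_mode for the missingness family (see
#'   [inject_missingness()]).
#' @return list of class `scenario_result`: `replicates` (one row per
#'   replicate) and `aggregate` (means and Monte-Carlo standard errors per
#'   value).
#' @export
run_scenario <- function(scenario = c("lt_ratio", "sample_size", "missingness"),
                         values, replicates = 10L, seed = 1L,
                         n_individuals = 3000L, L = 5,
                         n_variants = 10000L, n_causal = 100L,
                         vc_mode = c("truth", "estimate"),
                         mac_min = 3, mac_rule = "geno_time_cells",
                         missing_mode = "individuals") {
  scenario <- match.arg(scenario)
  vc_mode <- match.arg(vc_mode)
  replicates <- rep_len(as.integer(replicates), length(values))
  rows <- list(); counter <- 0L
  for (vi in seq_along(values)) {
    v <- values[vi]
    for (r in seq_len(replicates[vi])) {
      counter <- counter + 1L
      seed_rep <- seed + counter
      row <- tryCatch(
        scenario_replicate(scenario, v, seed_rep, n_individuals, L,
                           n_variants, n_causal, vc_mode, mac_min, mac_rule,
                           missing_mode),
        error = function(e) {
          warning(sprintf("replicate %d (value %s) failed: %s",
                          counter, format(v), conditionMessage(e)))
          NULL
        })
      if (is.null(row)) {
        row <- data.frame(value = v, failed = TRUE)
      } else {
        row$failed <- FALSE
      }
      row$replicate <- counter; row$seed <- seed_rep
      rows[[counter]] <- row
    }
  }
  reps <- data.table::rbindlist(rows, fill = TRUE)
  reps <- as.data.frame(reps)
  num <- setdiff(names(reps)[vapply(reps, is.numeric, logical(1))],
                 c("value", "replicate", "seed"))
  ok <- !reps$failed
  agg <- do.call(rbind, lapply(split(reps[ok, , drop = FALSE], reps$value[ok]),
    function(d) {
      out <- data.frame(value = d$value[1L], n_replicates = nrow(d))
      for (cn in num) {
        out[[paste0(cn, "_mean")]] <- mean(d[[cn]], na.rm = TRUE)
        out[[paste0(cn, "_se")]] <- stats::sd(d[[cn]], na.rm = TRUE) /
          sqrt(sum(is.finite(d[[cn]])))
      }
      out
    }))
  rownames(agg) <- NULL
  structure(list(scenario = scenario, replicates = reps, aggregate = agg,
                 n_failed = sum(reps$failed)),
            class = "scenario_result")
}

scenario_replicate <- function(scenario, value, seed_rep, n_individuals, L,
                               n_variants, n_causal, vc_mode, mac_min,
                               mac_rule, missing_mode) {
  n <- if (scenario == "sample_size") as.integer(value) else n_individuals
  Lv <- if (scenario == "lt_ratio") value else L
  mf <- if (scenario == "missingness") value else 0
  K <- 3L
  target <- paste0("trait", K)
  cfg <- sim_config(n_individuals = n, n_variants = n_variants,
                    n_causal = n_causal, L = Lv,
                    missing_fraction = mf, missing_mode = missing_mode,
                    missing_trait = target, seed = seed_rep)
  sim <- simulate_dataset(cfg)
  vc <- if (vc_mode == "truth") sim$truth$vc
        else estimate_variance_components(sim$phenotypes)
  des <- build_design(sim$phenotypes)
  ns <- build_null_system(des, vc)
  scan <- scan_genotypes(ns, sim$genotypes, mac_min = mac_min,
                         mac_rule = mac_rule)
  thr <- bonferroni_threshold(sum(scan$tested))
  met <- compute_power_type1(scan, sim$truth$causal, thr)
  out <- data.frame(value = value, threshold = thr, n_tested = met$n_tested,
                    power_cs = met$power_cs, power_lt = met$power_lt,
                    type1_cs = met$type1_cs, type1_lt = met$type1_lt)
  if (scenario == "missingness") {
    out$power_cs_target <- met$per_trait$power["CS", target]
    out$power_lt_target <- met$per_trait$power["LT", target]
    out$type1_cs_target <- met$per_trait$type1["CS", target]
    out$type1_lt_target <- met$per_trait$type1["LT", target]
    single <- single_trait_scan(sim$phenotypes, sim$genotypes, vc, target,
                                mac_min = mac_min, mac_rule = mac_rule)
    thr_s <- bonferroni_threshold(sum(single$tested))
    met_s <- compute_power_type1(single, sim$truth$causal, thr_s)
    out$power_cs_single <- met_s$power_cs
    out$power_lt_single <- met_s$power_lt
    jd <- as.data.frame(scan); sd_ <- as.data.frame(single)
    jd <- jd[jd$trait == target & jd$filter_status == "tested", , drop = FALSE]
    sd_ <- sd_[sd_$filter_status == "tested", , drop = FALSE]
    common <- intersect(jd$variant_id, sd_$variant_id)
    cmp <- compare_se(jd[jd$variant_id %in% common, , drop = FALSE],
                      sd_[sd_$variant_id %in% common, , drop = FALSE])
    out$se_slope <- cmp$slope
    out$se_slope_cs <- cmp$slope_by_effect[["CS"]]
    out$se_slope_lt <- cmp$slope_by_effect[["LT"]]
  }
  out
}
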