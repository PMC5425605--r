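#' End-to-end dynamic functional connectivity pipeline
#'
#' Orchestrates the full analysis over a (synthetic or supplied) cohort:
#' motion preprocessing and censoring, group-level consensus partition,
#' per-subject sliding-window series (bi-nodal FC, module-pair FC,
#' modularity Q), within-subject cross-level correlations, group-level
#' regressions and t-tests, and the within-subject SVR over network-network
#' interactions. All stage defaults follow the reference analysis: 22-TR
#' windows stepped by 5 TRs, gamma 1.7, 300 consensus runs, 25 restarts per
#' window, FD threshold 0.5, SVR cost 1.
#'
#' @param cohort a `synthetic_cohort` from [generate_cohort()], or a
#'   [cohort_config()] (then the cohort is generated first).
#' @param spec a [window_spec()].
#' @param gamma resolution for group and per-window community detection.
#' @param consensus_runs Louvain runs per consensus round.
#' @param window_runs Louvain restarts per window.
#' @param fd_threshold,run_fraction censoring parameters.
#' @param svr_cost,svr_epsilon SVR parameters.
#' @param filter apply the bandpass step (default `TRUE`).
#' @param do_sweep also run the resolution sweep (slow; default `FALSE`).
#' @param sweep_runs Louvain runs per swept gamma.
#' @param do_svr run the SVR stage (default `TRUE`).
#' @param do_loocv compute LOOCV performance per subject (slowest stage;
#'   default `TRUE`).
#' @param seed global seed; per-subject and per-window seeds are derived
#'   from it deterministically.
#' @param out_dir optional directory: stage tables are written as TSV plus a
#'   JSON manifest.
#' @return list with elements `cohort`, `prep` (masks, mean FD, usable
#'   flags), `group_partition`, `sweep` (or `NULL`), `subject_series`,
#'   `cross_level` (per-subject table), `stats` (group tests and
#'   regressions), `svr` (per-subject weights/performance and group weight
#'   table), and `manifest`.
#' @export
run_pipeline <- function(cohort, spec = window_spec(), gamma = 1.7,
                         consensus_runs = 300, window_runs = 25,
                         fd_threshold = 0.5, run_fraction = 0.5,
                         svr_cost = 1, svr_epsilon = 0.1,
                         filter = TRUE, do_sweep = FALSE, sweep_runs = 100,
                         do_svr = TRUE, do_loocv = TRUE,
                         seed = 1, out_dir = NULL) {
  if (inherits(cohort, "cohort_config")) cohort <- generate_cohort(cohort)
  stopifnot(inherits(cohort, "synthetic_cohort"))
  n_sub <- length(cohort$subjects)

  ## ---- stage 1: preprocessing and censoring -------------------------------
  prep <- lapply(seq_len(n_sub), function(s) {
    prep_subject(cohort$subjects[[s]], cohort$motion[[s]],
                 fd_threshold = fd_threshold, run_fraction = run_fraction,
                 filter = filter)
  })
  usable <- vapply(prep, function(p) p$mask$usable, logical(1))
  covariates <- cohort$covariates
  covariates$mean_fd <- vapply(prep, function(p) p$mean_fd, numeric(1))
  covariates$usable <- usable
  kept <- which(usable)
  if (length(kept) == 0) stop("pipeline: no usable subjects", call. = FALSE)

  ## ---- stage 2: group partition ------------------------------------------
  gm <- group_matrix(lapply(prep[kept], `[[`, "ts"),
                     lapply(prep[kept], `[[`, "mask"))
  sweep <- NULL
  if (do_sweep) {
    sweep <- gamma_sweep(gm, n_runs = sweep_runs,
                         seed = derive_seed(seed, 10))
  }
  gpart <- consensus_partition(gm, gamma = gamma, n_runs = consensus_runs,
                               seed = derive_seed(seed, 11))
  roles <- cohort$subjects[[1]]$roles
  limbic_mod <- gpart$labels[roles$amygdala]
  dmn_mod <- gpart$labels[roles$mpfc]
  if (limbic_mod == dmn_mod) {
    warning("amygdala and mPFC fall in the same consensus module; ",
            "cross-level series will be degenerate")
  }

  ## ---- stage 3: per-subject window series ---------------------------------
  subject_series <- vector("list", n_sub)
  for (s in kept) {
    ts <- prep[[s]]$ts
    mask <- prep[[s]]$mask
    wins <- window_connectivity(ts, mask, spec)
    qser <- window_modularity(wins, gamma = gamma, n_runs = window_runs,
                              seed = derive_seed(seed, 20, s))
    mp <- module_pair_fc(ts, gpart, mask, spec)
    binodal <- node_pair_fc(ts, roles$amygdala, roles$mpfc, mask, spec)
    caudate <- node_pair_fc(ts, roles$caudate, roles$mpfc, mask, spec)
    subject_series[[s]] <- list(q = qser, module_pairs = mp,
                                binodal = binodal, caudate_mpfc = caudate)
  }

  ## ---- stage 4: cross-level summaries -------------------------------------
  netpair <- function(mp) pair_series(mp, limbic_mod, dmn_mod)
  cross <- do.call(rbind, lapply(kept, function(s) {
    ser <- subject_series[[s]]
    out <- cross_level_summary(ser$binodal, netpair(ser$module_pairs), ser$q)
    out$z_caudate_network <- cross_level_correlate(ser$caudate_mpfc,
                                                  netpair(ser$module_pairs))
    out$z_caudate_q <- cross_level_correlate(ser$caudate_mpfc, ser$q)
    cbind(data.frame(subject = covariates$subject[s]), out)
  }))
  cross <- merge(covariates[covariates$usable, ], cross, by = "subject",
                 sort = FALSE)

  ## ---- stage 5: group statistics ------------------------------------------
  stats <- list(
    t_binodal_network = one_sample_t(cross$z_binodal_network),
    t_binodal_q = one_sample_t(cross$z_binodal_q),
    t_network_q = one_sample_t(cross$z_network_q)
  )
  X_ctq <- build_design(cross, "ctq")
  X_grp <- build_design(cross, "group")
  stats$ctq_on_median_binodal <- ols_fit(cross$median_binodal, X_ctq,
                                         "median_binodal_fc")
  stats$ctq_on_median_q <- ols_fit(cross$median_q, X_ctq, "median_q")
  stats$group_on_z_binodal_network <- ols_fit(cross$z_binodal_network, X_grp,
                                              "z_binodal_network")
  stats$group_on_z_binodal_q <- ols_fit(cross$z_binodal_q, X_grp,
                                        "z_binodal_q")
  stats$group_on_z_network_q <- ols_fit(cross$z_network_q, X_grp,
                                        "z_network_q")

  ## ---- stage 6: SVR over network-network interactions ---------------------
  svr <- NULL
  if (do_svr) {
    weights <- NULL
    perf <- rep(NA_real_, length(kept))
    for (i in seq_along(kept)) {
      s <- kept[i]
      ser <- subject_series[[s]]
      ok <- ser$module_pairs$valid & ser$binodal$valid
      fit <- fit_linear_svr(ser$module_pairs$z, ser$binodal$value,
                            cost = svr_cost, epsilon = svr_epsilon,
                            valid = ok)
      if (is.null(weights)) {
        weights <- matrix(NA_real_, length(kept), length(fit$weights),
                          dimnames = list(covariates$subject[kept],
                                          names(fit$weights)))
      }
      weights[i, ] <- fit$weights
      if (do_loocv) {
        perf[i] <- loocv_performance(ser$module_pairs$z, ser$binodal$value,
                                     cost = svr_cost, epsilon = svr_epsilon,
                                     valid = ok)
      }
    }
    svr <- list(weights = weights, performance = perf,
                group_tests = group_weight_tests(weights),
                limbic_dmn_pair = paste0(min(limbic_mod, dmn_mod), "-",
                                         max(limbic_mod, dmn_mod)))
  }

  manifest <- list(
    n_subjects = n_sub,
    n_subjects_retained = length(kept),
    n_nodes = ncol(cohort$subjects[[1]]$mat),
    n_timepoints = nrow(cohort$subjects[[1]]$mat),
    n_windows = nrow(make_windows(nrow(cohort$subjects[[1]]$mat), spec)),
    n_modules = gpart$n_modules,
    n_module_pairs = gpart$n_modules * (gpart$n_modules - 1) / 2,
    gamma = gamma, window_length_trs = spec$length_trs,
    window_step_trs = spec$step_trs, fd_threshold = fd_threshold,
    consensus_runs = consensus_runs, window_runs = window_runs,
    svr_cost = svr_cost, svr_epsilon = svr_epsilon, seed = seed
  )

  result <- list(cohort = cohort,
                 prep = list(masks = lapply(prep, `[[`, "mask"),
                             mean_fd = covariates$mean_fd, usable = usable),
                 covariates = covariates,
                 group_matrix = gm, group_partition = gpart,
                 limbic_module = limbic_mod, dmn_module = dmn_mod,
                 sweep = sweep, subject_series = subject_series,
                 cross_level = cross, stats = stats, svr = svr,
                 manifest = manifest)
  if (!is.null(out_dir)) write_pipeline(result, out_dir)
  invisible(result)
}

write_pipeline <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    write.table(df, file.path(out_dir, name), sep = "\t",
                row.names = FALSE, quote = FALSE)
  }
  wt(result$covariates, "covariates.tsv")
  wt(data.frame(node = seq_along(result$group_partition$labels),
                module = result$group_partition$labels),
     "group_partition.tsv")
  if (!is.null(result$sweep)) wt(result$sweep, "gamma_sweep.tsv")
  wt(result$cross_level, "cross_level.tsv")
  for (nm in names(result$stats)) {
    st <- result$stats[[nm]]
    if (is.data.frame(st)) wt(st, paste0(nm, ".tsv"))
  }
  if (!is.null(result$svr)) {
    wt(cbind(subject = rownames(result$svr$weights),
             performance = result$svr$performance,
             as.data.frame(result$svr$weights)), "svr_subjects.tsv")
    wt(result$svr$group_tests, "svr_group_tests.tsv")
  }
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
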