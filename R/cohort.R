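#' Configuration for a synthetic resting-state cohort
#'
#' Defines the study conditions for [generate_cohort()]: cohort composition,
#' node/module layout, scan length, and the planted effects. Defaults emulate
#' a 56-subject adolescent cohort (30 control, 26 assaulted) scanned for
#' 450 s at TR = 2 s (225 time points) and parcellated into 215 nodes
#' grouped in 10 large-scale networks, with a designated amygdala node in the
#' limbic network, an mPFC node in the default-mode network, and two caudate
#' nodes in the limbic network.
#'
#' The generative model is a stand-in: no public data accompany the study
#' design being emulated, so all distributional choices here are synthetic
#' and documented in the methods vignette. Each network has a latent Gaussian
#' time course; a node's signal is its network signal plus independent noise.
#' The limbic and default-mode networks share a latent factor whose coupling
#' follows a bounded AR(1) state, so windowed between-network connectivity
#' genuinely fluctuates within subject; all remaining networks share a static
#' global factor. The amygdala and mPFC nodes receive an extra shared
#' component that ties their pairwise correlation to the latent limbic-DMN
#' coupling (slope `binodal_gain`) and to the subject's emotional-abuse score
#' (slope `trauma_effect_fc` per SD of log abuse); higher abuse also lowers
#' the static between-network coupling (slope `trauma_effect_mod`), which
#' raises modularity. Caudate nodes carry network signal only, so bi-nodal
#' specificity is testable.
#'
#' @param n_control,n_assaulted group sizes.
#' @param n_nodes,n_modules parcellation size and number of networks
#'   (modules). Module 1 is the default-mode network, module 2 the limbic
#'   network.
#' @param n_timepoints,tr_seconds scan length in TRs and TR duration (s).
#' @param coupling_base mean limbic-DMN coupling and static between-network
#'   coupling, on the correlation scale.
#' @param coupling_volatility stationary SD of the AR(1) latent coupling
#'   state (correlation scale); 0 freezes the coupling at `coupling_base`.
#' @param binodal_gain slope tying the amygdala-mPFC correlation to
#'   fluctuations of the latent limbic-DMN coupling around its mean.
#' @param trauma_effect_fc signed shift of mean amygdala-mPFC correlation per
#'   SD of z-scored log emotional-abuse score (negative: more abuse, weaker
#'   bi-nodal coupling).
#' @param trauma_effect_mod signed shift of between-network coupling per SD
#'   of abuse (positive values lower the coupling and hence raise modularity
#'   Q with abuse).
#' @param trauma_effect_tracking variance fraction of independent signal
#'   admixed into the amygdala/mPFC nodes of assaulted subjects, partially
#'   decoupling the pair from its networks (emulates the weaker cross-level
#'   correspondence reported for assaulted girls).
#' @param noise_sd node-level observation noise SD (network signals have
#'   unit variance).
#' @param motion_spike_prob per-TR probability of a head-motion spike.
#' @param window_length_trs,window_step_trs sliding-window grid implied by
#'   the config; determines the length of the stored latent coupling series.
#' @param seed integer seed; the whole cohort is a deterministic function of
#'   the config.
#' @return A `cohort_config` list, validated.
#' @export
cohort_config <- function(n_control = 30, n_assaulted = 26,
                          n_nodes = 215, n_modules = 10,
                          n_timepoints = 225, tr_seconds = 2,
                          coupling_base = 0.35, coupling_volatility = 0.25,
                          binodal_gain = 0.5,
                          trauma_effect_fc = -0.2, trauma_effect_mod = 0.1,
                          trauma_effect_tracking = 0.25,
                          noise_sd = 0.8, motion_spike_prob = 0.02,
                          window_length_trs = 22, window_step_trs = 5,
                          seed = 1) {
  cfg <- list(n_control = n_control, n_assaulted = n_assaulted,
              n_nodes = n_nodes, n_modules = n_modules,
              n_timepoints = n_timepoints, tr_seconds = tr_seconds,
              coupling_base = coupling_base,
              coupling_volatility = coupling_volatility,
              binodal_gain = binodal_gain,
              trauma_effect_fc = trauma_effect_fc,
              trauma_effect_mod = trauma_effect_mod,
              trauma_effect_tracking = trauma_effect_tracking,
              noise_sd = noise_sd, motion_spike_prob = motion_spike_prob,
              window_length_trs = window_length_trs,
              window_step_trs = window_step_trs,
              seed = seed)
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  chk_count <- function(field, min = 1) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < min ||
        v != round(v)) {
      stop("invalid cohort config: `", field, "` must be an integer >= ",
           min, call. = FALSE)
    }
  }
  chk_num <- function(field, lo = -Inf, hi = Inf) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < lo || v > hi) {
      stop("invalid cohort config: `", field, "` must be in [", lo, ", ",
           hi, "]", call. = FALSE)
    }
  }
  for (f in c("n_control", "n_assaulted", "n_nodes", "n_timepoints",
              "window_length_trs", "window_step_trs")) chk_count(f)
  chk_count("n_modules", min = 2)
  chk_num("tr_seconds", lo = 1e-6)
  chk_num("coupling_base", -0.9, 0.9)
  chk_num("coupling_volatility", 0, 1)
  chk_num("binodal_gain", 0, 5)
  chk_num("trauma_effect_fc", -1, 1)
  chk_num("trauma_effect_mod", -1, 1)
  chk_num("trauma_effect_tracking", 0, 1)
  chk_num("noise_sd", 0, Inf)
  chk_num("motion_spike_prob", 0, 1)
  chk_count("seed", min = 0)
  if (cfg$n_timepoints < cfg$window_length_trs) {
    stop("invalid cohort config: `n_timepoints` must be >= `window_length_trs`",
         call. = FALSE)
  }
  if (cfg$n_nodes < 3 * cfg$n_modules) {
    stop("invalid cohort config: `n_nodes` must allow >= 3 nodes per module ",
         "(need amygdala plus two caudate nodes in the limbic module)",
         call. = FALSE)
  }
  invisible(cfg)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

ar1_series <- function(n, phi, stationary_sd) {
  if (stationary_sd <= 0) return(rep(0, n))
  x <- numeric(n)
  x[1] <- rnorm(1, 0, stationary_sd)
  innov_sd <- stationary_sd * sqrt(1 - phi^2)
  eps <- rnorm(n - 1, 0, innov_sd)
  for (t in seq_len(n - 1)) x[t + 1] <- phi * x[t] + eps[t]
  x
}

#' Generate a six-parameter rigid-body motion trace
#'
#' Baseline smooth drift (a small-step random walk in each of three
#' translations and three rotations) plus step-change spikes: at each
#' non-initial TR, with probability `spike_prob`, every parameter jumps by
#' 0.1-0.25 units (random sign) and stays, so the framewise displacement at
#' that TR exceeds 0.5 while subsequent TRs return to drift-level FD.
#'
#' @param n_timepoints number of TRs.
#' @param spike_prob per-TR spike probability in `[0, 1]`.
#' @param seed integer seed.
#' @return numeric matrix with `n_timepoints` rows and 6 columns.
#' @export
generate_motion_trace <- function(n_timepoints, spike_prob = 0.02, seed = 1) {
  stopifnot(n_timepoints >= 2)
  if (!is.numeric(spike_prob) || spike_prob < 0 || spike_prob > 1) {
    stop("`spike_prob` must be a probability in [0, 1]", call. = FALSE)
  }
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  steps <- matrix(rnorm(n_timepoints * 6, 0, 0.008), n_timepoints, 6)
  steps[1, ] <- rnorm(6, 0, 0.05)   # arbitrary start position
  spikes <- c(FALSE, runif(n_timepoints - 1) < spike_prob)
  if (any(spikes)) {
    n_sp <- sum(spikes)
    jump <- matrix(runif(n_sp * 6, 0.1, 0.25) * sample(c(-1, 1), n_sp * 6,
                                                       replace = TRUE),
                   n_sp, 6)
    steps[spikes, ] <- steps[spikes, , drop = FALSE] + jump
  }
  trace <- apply(steps, 2, cumsum)
  colnames(trace) <- c("trans_x", "trans_y", "trans_z",
                       "rot_1", "rot_2", "rot_3")
  attr(trace, "spike") <- spikes
  trace
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

#' A subject's node-level time series
#'
#' Lightweight container for a time-by-node signal matrix with its TR and the
#' designated node roles (amygdala, mPFC, caudate).
#'
#' @param mat numeric matrix, one row per time point, one column per node.
#' @param tr_seconds repetition time in seconds.
#' @param roles named list of node indices: `amygdala`, `mpfc`, `caudate`.
#' @param subject_id identifier.
#' @param nuisance optional named list of nuisance series (`csf`, `wm`).
#' @return an object of class `roi_ts`.
#' @export
roi_ts <- function(mat, tr_seconds, roles = list(), subject_id = NA_character_,
                   nuisance = NULL) {
  stopifnot(is.matrix(mat), is.numeric(mat))
  structure(list(mat = mat, tr_seconds = tr_seconds, roles = roles,
                 subject_id = subject_id, nuisance = nuisance),
            class = "roi_ts")
}

#' @export
print.roi_ts <- function(x, ...) {
  cat(sprintf("<roi_ts %s: %d TRs x %d nodes, TR = %gs>\n",
              x$subject_id, nrow(x$mat), ncol(x$mat), x$tr_seconds))
  invisible(x)
}

#' Generate a synthetic cohort with planted ground truth
#'
#' Draws covariates, motion traces, and node-level time series for every
#' subject under the generative model described in [cohort_config()], and
#' returns the planted ground truth (module labels, latent per-window
#' limbic-DMN coupling, per-subject true effects) so downstream stages can be
#' validated against it.
#'
#' @param config a [cohort_config()].
#' @return a list of class `synthetic_cohort` with elements
#'   `subjects` (list of [roi_ts()]), `motion` (list of motion matrices),
#'   `covariates` (data.frame: subject, group, age, verbal_iq, five CTQ
#'   subscales), and `truth` (list: `module_labels`, `module_names`,
#'   `latent_coupling` subject-by-window matrix, `subject_effects`
#'   data.frame).
#' @export
generate_cohort <- function(config = cohort_config()) {
  validate_cohort_config(config)
  cfg <- config
  old <- get_rng_state()
  on.exit(restore_rng_state(old))

  n <- cfg$n_control + cfg$n_assaulted
  K <- cfg$n_modules
  T_ <- cfg$n_timepoints

  # module layout: module 1 = DMN (mPFC), module 2 = limbic (amygdala,
  # bilateral caudate); contiguous blocks, with the DMN and limbic networks
  # twice the size of the remaining networks (large-scale parcellations
  # assign the default-mode system the largest share of nodes)
  wts <- c(2, 2, rep(1, K - 2))
  sizes <- floor(cfg$n_nodes * wts / sum(wts))
  rem <- cfg$n_nodes - sum(sizes)
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  module_labels <- rep(seq_len(K), times = sizes)
  module_names <- c("default_mode", "limbic",
                    if (K > 2) sprintf("network%02d", 3:K))
  dmn_nodes <- which(module_labels == 1)
  limbic_nodes <- which(module_labels == 2)
  roles <- list(amygdala = limbic_nodes[1], mpfc = dmn_nodes[1],
                caudate = limbic_nodes[2:3])

  set.seed(derive_seed(cfg$seed, 1))
  covariates <- draw_covariates(cfg)
  abuse_z <- as.numeric(scale(log(covariates$ctq_emotional_abuse)))
  if (!all(is.finite(abuse_z))) abuse_z <- rep(0, n)   # degenerate: no spread

  win <- make_windows(T_, window_spec(cfg$window_length_trs,
                                      cfg$window_step_trs))
  n_win <- nrow(win)

  subjects <- vector("list", n)
  motion <- vector("list", n)
  latent_coupling <- matrix(NA_real_, n, n_win)
  eff <- data.frame(subject = covariates$subject,
                    group = covariates$group,
                    abuse_score = covariates$ctq_emotional_abuse,
                    abuse_z = abuse_z,
                    true_binodal_mean = NA_real_,
                    between_coupling = NA_real_,
                    tracking_gain = NA_real_)

  for (s in seq_len(n)) {
    set.seed(derive_seed(cfg$seed, 2, s))
    assaulted <- covariates$group[s] == "assaulted"

    # latent limbic-DMN coupling path (bounded AR(1), slow drift); the
    # limbic and DMN modules also carry a partial loading on the global
    # factor (b_h) so they stay embedded in the whole-brain graph
    b_h <- 0.4 * cfg$coupling_base
    x <- ar1_series(T_, phi = 0.94, stationary_sd = cfg$coupling_volatility)
    lambda <- clamp(cfg$coupling_base + x, b_h + 0.02, 0.90)

    # bi-nodal target correlation tracks the latent coupling with slope
    # (1 + binodal_gain) plus the abuse-severity shift of its mean
    rho <- clamp(lambda + cfg$binodal_gain * (lambda - cfg$coupling_base) +
                   cfg$trauma_effect_fc * abuse_z[s], -0.5, 0.95)
    e <- rho - lambda
    e_imp <- ifelse(e >= 0, e / (1 - rho), e / (1 + rho))
    a <- sqrt(abs(e_imp))
    sgn <- sign(e_imp)

    b_s <- clamp(cfg$coupling_base - cfg$trauma_effect_mod * abuse_z[s],
                 0.05, 0.85)

    h <- rnorm(T_)                       # global static between-network factor
    g <- rnorm(T_)                       # limbic-DMN shared factor
    q <- rnorm(T_)                       # amygdala-mPFC private shared factor
    u <- matrix(rnorm(T_ * K), T_, K)    # network-unique signals

    s_mod <- matrix(NA_real_, T_, K)
    for (m in seq_len(K)) {
      if (m %in% c(1, 2)) {
        s_mod[, m] <- sqrt(1 - lambda) * u[, m] + sqrt(b_h) * h +
          sqrt(lambda - b_h) * g
      } else {
        s_mod[, m] <- sqrt(1 - b_s) * u[, m] + sqrt(b_s) * h
      }
    }

    X <- s_mod[, module_labels] + cfg$noise_sd *
      matrix(rnorm(T_ * cfg$n_nodes), T_, cfg$n_nodes)
    # in assaulted subjects the amygdala/mPFC pair is partially decoupled
    # from its networks (independent admixture d), weakening both the
    # bi-nodal coupling and its correspondence with network-level FC
    d <- cfg$trauma_effect_tracking * as.numeric(assaulted)
    norm_bn <- sqrt(1 + abs(e_imp))
    amy_core <- (s_mod[, 2] + a * q) / norm_bn
    mpfc_core <- (s_mod[, 1] + sgn * a * q) / norm_bn
    amy_core <- sqrt(1 - d) * amy_core + sqrt(d) * rnorm(T_)
    mpfc_core <- sqrt(1 - d) * mpfc_core + sqrt(d) * rnorm(T_)
    X[, roles$amygdala] <- amy_core + cfg$noise_sd * rnorm(T_)
    X[, roles$mpfc] <- mpfc_core + cfg$noise_sd * rnorm(T_)
    colnames(X) <- sprintf("n%03d", seq_len(cfg$n_nodes))

    tr <- generate_motion_trace(T_, cfg$motion_spike_prob,
                                seed = derive_seed(cfg$seed, 3, s))
    fd <- framewise_displacement(tr)
    spike_trs <- fd > 0.5
    if (any(spike_trs)) {
      # global artifact at high-motion TRs, scaled with the noise floor
      X[spike_trs, ] <- X[spike_trs, , drop = FALSE] +
        2 * cfg$noise_sd * rnorm(sum(spike_trs))
    }

    nuis <- list(csf = ar1_series(T_, 0.3, 1), wm = ar1_series(T_, 0.3, 1))

    subjects[[s]] <- roi_ts(X, cfg$tr_seconds, roles = roles,
                            subject_id = covariates$subject[s],
                            nuisance = nuis)
    motion[[s]] <- tr
    latent_coupling[s, ] <- vapply(seq_len(n_win), function(w) {
      mean(lambda[win$start[w]:win$end[w]])
    }, numeric(1))
    eff$true_binodal_mean[s] <- (1 - d) * mean(rho)
    eff$between_coupling[s] <- b_s
    eff$tracking_gain[s] <- 1 - d
  }

  structure(list(subjects = subjects, motion = motion,
                 covariates = covariates,
                 truth = list(module_labels = module_labels,
                              module_names = module_names,
                              roles = roles,
                              latent_coupling = latent_coupling,
                              subject_effects = eff),
                 config = cfg),
            class = "synthetic_cohort")
}

# Covariates loosely follow the demographic table of the emulated study:
# controls near the CTQ floor (minimum subscale score 5), assaulted group
# shifted upward, age ~ 11-17, verbal IQ slightly lower in the assaulted
# group. Purely synthetic stand-ins.
draw_covariates <- function(cfg) {
  n_c <- cfg$n_control
  n_a <- cfg$n_assaulted
  n <- n_c + n_a
  group <- rep(c("control", "assaulted"), c(n_c, n_a))
  draw_ctq <- function(n, shape, scale) {
    clamp(5 + round(rgamma(n, shape = shape, scale = scale)), 5, 25)
  }
  data.frame(
    subject = sprintf("sub%03d", seq_len(n)),
    group = group,
    age = round(clamp(c(rnorm(n_c, 14.7, 1.9), rnorm(n_a, 15.2, 1.5)),
                      11, 17), 1),
    verbal_iq = round(c(rnorm(n_c, 107.5, 19.1), rnorm(n_a, 99.4, 13.7))),
    ctq_emotional_abuse = c(draw_ctq(n_c, 1.3, 1.3), draw_ctq(n_a, 2.5, 3.2)),
    ctq_emotional_neglect = c(draw_ctq(n_c, 1.5, 1.5), draw_ctq(n_a, 2.2, 2.8)),
    ctq_physical_abuse = c(draw_ctq(n_c, 0.8, 1.0), draw_ctq(n_a, 2.0, 2.5)),
    ctq_physical_neglect = c(draw_ctq(n_c, 1.2, 1.2), draw_ctq(n_a, 1.8, 2.2)),
    ctq_sexual_abuse = c(draw_ctq(n_c, 0.4, 1.0), draw_ctq(n_a, 1.5, 3.0)),
    stringsAsFactors = FALSE
  )
}

#' Write a synthetic cohort to plain-text files
#'
#' Per-subject signal matrices as whitespace-delimited numeric text with a
#' one-line node-id header, motion traces as six-column text, covariates as
#' TSV, ground truth as JSON.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in seq_along(cohort$subjects)) {
    id <- cohort$covariates$subject[s]
    write.table(cohort$subjects[[s]]$mat,
                file.path(dir, paste0(id, "_ts.txt")),
                row.names = FALSE, quote = FALSE)
    write.table(cohort$motion[[s]],
                file.path(dir, paste0(id, "_motion.txt")),
                row.names = FALSE, quote = FALSE)
  }
  write.table(cohort$covariates, file.path(dir, "covariates.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(cohort$truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
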