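#' Replicate noise model for synthetic observations
#'
#' Synthetic replicate observations are drawn as true value plus
#' Gaussian noise with standard deviation `max(cv * true, floor)`,
#' optionally truncated at zero. The published profiles show
#' quintuplicate means with small error bars; a 2% coefficient of
#' variation with small absolute floors emulates that regime.
#'
#' @param cv Coefficient of variation of the replicate noise (default
#'   0.02).
#' @param floor_conc Absolute noise floor for concentrations, mM
#'   (default 0.1).
#' @param floor_enzyme Absolute noise floor for relative enzyme
#'   activity, % (default 0.5).
#' @param replicates Number of replicates per time point (default 5,
#'   the study's quintuplicates).
#' @param truncate_at_zero Truncate negative replicate draws at zero
#'   (default `TRUE`).
#' @param zero_byproducts Report acetaldehyde and acetoin observations
#'   as 0 regardless of the simulation, emulating levels below the
#'   detection limit as in the study (default `TRUE`; applies to noisy
#'   datasets only).
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(cv = 0.02, floor_conc = 0.1, floor_enzyme = 0.5,
                        replicates = 5, truncate_at_zero = TRUE,
                        zero_byproducts = TRUE) {
  check_nonneg(cv, "cv"); check_nonneg(floor_conc, "floor_conc")
  check_nonneg(floor_enzyme, "floor_enzyme")
  if (replicates < 1) abort("`replicates` must be >= 1",
                            class = "packinetics_invalid_argument")
  structure(list(cv = cv, floor_conc = floor_conc,
                 floor_enzyme = floor_enzyme,
                 replicates = as.integer(replicates),
                 truncate_at_zero = isTRUE(truncate_at_zero),
                 zero_byproducts = isTRUE(zero_byproducts)),
            class = "noise_model")
}

#' Study design for synthetic dataset generation
#'
#' Encodes the structure of the batch biotransformation study: the
#' initial benzaldehyde/pyruvate condition pairs (nominal molar ratio
#' pyruvate:benzaldehyde = 1.2), the phosphate buffer levels, the range
#' of initial relative enzyme activity, and the sampling scheme (eight
#' time points, 0-210 min every 30 min).
#'
#' @param pairs Character vector of condition pairs; the defaults
#'   `"30/36"`, `"50/60"`, `"100/120"` use the study's measured initial
#'   states (see [pac_study_conditions()]). Custom pairs of the form
#'   `"B0/A0"` (mM) are simulated from their nominal concentrations with
#'   an initial enzyme activity drawn uniformly from `E0_range`.
#' @param Ph_b Phosphate buffer concentration used for the generated
#'   kinetic profiles, mM (default 250, the modelled buffer level).
#' @param buffer_levels The study's full set of buffer levels, mM
#'   (metadata; default 20, 250, 500, 1000).
#' @param E0_range Range of initial relative enzyme activity, %
#'   (default 89-114).
#' @param t_end,sampling_interval Sampling scheme in minutes.
#' @param seed Master seed for reproducible noise generation.
#' @return An object of class `study_design`.
#' @export
study_design <- function(pairs = c("30/36", "50/60", "100/120"),
                         Ph_b = 250,
                         buffer_levels = c(20, 250, 500, 1000),
                         E0_range = c(89, 114),
                         t_end = 210, sampling_interval = 30,
                         seed = 1L) {
  stopifnot(length(pairs) >= 1, length(E0_range) == 2)
  structure(list(pairs = pairs, Ph_b = Ph_b,
                 buffer_levels = buffer_levels,
                 E0_range = E0_range, t_end = t_end,
                 sampling_interval = sampling_interval,
                 seed = as.integer(seed)),
            class = "study_design")
}

design_conditions <- function(design, pair, E0 = NULL) {
  if (pair %in% c("30/36", "50/60", "100/120") && is.null(E0)) {
    cond <- pac_study_conditions(pair, Ph_b = design$Ph_b)
    cond$t_end <- design$t_end
    cond$sampling_interval <- design$sampling_interval
    return(cond)
  }
  ba <- as.numeric(strsplit(pair, "/", fixed = TRUE)[[1]])
  if (length(ba) != 2 || any(!is.finite(ba))) {
    abort(paste0("cannot parse condition pair: ", pair),
          class = "packinetics_invalid_argument")
  }
  E0 <- E0 %||% mean(design$E0_range)
  reaction_conditions(
    Ph_b = design$Ph_b,
    initial = c(P = 0.01, A = ba[2], B = ba[1], Q = 0, R = 0, E = E0),
    t_end = design$t_end, sampling_interval = design$sampling_interval,
    label = pair)
}

#' Generate a noiseless synthetic profile
#'
#' Simulates the model under the given conditions and reports the
#' sampled states as an error-free experimental profile (standard
#' errors 0, one replicate). Used as ground truth in parameter-recovery
#' experiments.
#'
#' @param params A [kinetic_parameters()] object.
#' @param conditions A [reaction_conditions()] object.
#' @param step Integration step in minutes (default 0.6).
#' @return A [pac_profile()].
#' @export
#' @examples
#' generate_noiseless_profile(pac_parameters_optimized(),
#'                            pac_study_conditions("50/60"))
generate_noiseless_profile <- function(params, conditions, step = 0.6) {
  traj <- simulate_pac(params, conditions, step = step)
  samp <- sampled_states(traj)
  df <- samp[, profile_column_order(se = FALSE)]
  pac_profile(df, conditions, replicates = 1L)
}

#' Generate a noisy synthetic dataset with the study's structure
#'
#' For each condition pair of the design, simulates the model, draws
#' replicate observations under the noise model, and stores replicate
#' means and standard errors. The dataset is a pure function of
#' `(params, design, noise, seed)`: per-profile child seeds are derived
#' from the master seed by fixed offsets.
#'
#' @param params A [kinetic_parameters()] object (ground truth).
#' @param design A [study_design()].
#' @param noise A [noise_model()].
#' @param seed Integer master seed (defaults to the design's seed).
#' @param step Integration step in minutes (default 0.6).
#' @return A named list of [pac_profile()] objects, one per condition
#'   pair.
#' @export
generate_noisy_dataset <- function(params, design = study_design(),
                                   noise = noise_model(),
                                   seed = design$seed, step = 0.6) {
  stopifnot(inherits(design, "study_design"), inherits(noise, "noise_model"))
  params <- as_kinetic_parameters(params)
  out <- vector("list", length(design$pairs))
  names(out) <- design$pairs
  for (i in seq_along(design$pairs)) {
    pair <- design$pairs[i]
    child_seed <- (as.integer(seed) + 1000L * i) %% .Machine$integer.max
    E0 <- NULL
    if (!pair %in% c("30/36", "50/60", "100/120")) {
      # custom pairs draw their initial enzyme activity from the design range
      old <- .Random.seed_get()
      set.seed(child_seed)
      E0 <- stats::runif(1, design$E0_range[1], design$E0_range[2])
      .Random.seed_restore(old)
    }
    cond <- design_conditions(design, pair, E0 = E0)
    truth <- profile_matrix(generate_noiseless_profile(params, cond, step))
    out[[i]] <- noisy_profile_from_truth(truth, cond, noise, child_seed)
  }
  out
}

noisy_profile_from_truth <- function(truth, conditions, noise, seed) {
  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n_t <- nrow(truth)
  floors <- c(P = noise$floor_conc, A = noise$floor_conc,
              B = noise$floor_conc, Q = noise$floor_conc,
              R = noise$floor_conc, E = noise$floor_enzyme)
  means <- truth
  ses <- truth * 0
  for (j in seq_len(ncol(truth))) {
    sdj <- pmax(noise$cv * truth[, j], floors[j])
    reps <- matrix(rnorm(n_t * noise$replicates,
                         mean = truth[, j], sd = sdj),
                   nrow = n_t)
    if (noise$truncate_at_zero) reps[reps < 0] <- 0
    means[, j] <- rowMeans(reps)
    ses[, j] <- apply(reps, 1, sd) / sqrt(noise$replicates)
    if (noise$replicates == 1) ses[, j] <- 0
  }
  if (noise$zero_byproducts) {
    means[, c("Q", "R")] <- 0
    ses[, c("Q", "R")] <- 0
  }
  cols <- species_columns()
  df <- tibble(time_min = seq(0, conditions$t_end,
                              by = conditions$sampling_interval))
  for (s in names(cols)) df[[cols[[s]]]] <- means[, s]
  for (s in names(cols)) df[[paste0(cols[[s]], "_se")]] <- ses[, s]
  pac_profile(df, conditions, replicates = noise$replicates)
}

# save/restore the global RNG state so generators are pure functions of
# their seed and leave the session's RNG untouched
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
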