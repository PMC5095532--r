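#' Configuration for the synthetic TMT time-course experiment
#'
#' Describes a 6-plex TMT design over three macrophage activation states:
#' unstimulated control `M(-)`, interferon-gamma stimulated `M(IFNg)` and
#' interleukin-4 stimulated `M(IL-4)`, each measured at the same time points.
#' Candidate regulators are planted with a log10 abundance rise in `M(IFNg)`
#' that reaches `candidate_effect` by 24 h and is sustained, and a mirror-image
#' fall in `M(IL-4)`. Background proteins (and every protein in the control)
#' only drift around zero.
#'
#' @param n_candidate_proteins number of planted candidate regulators.
#' @param n_background_proteins number of unresponsive background proteins.
#' @param psms_per_protein PSMs generated per protein and condition; either a
#'   single count or a `c(min, max)` range sampled per protein.
#' @param timepoints sampling times in hours; must start at 0 (the TMT
#'   reference channel).
#' @param candidate_effect planted effect size, log10 fold change reached by
#'   24 h in `M(IFNg)` (and `-candidate_effect` in `M(IL-4)`). Must be > 0.
#' @param control_drift_sd s.d. (log10 units) of the per-protein, per-time
#'   baseline drift present in every condition's null component.
#' @param psm_noise_sd s.d. (log10 units) of the multiplicative measurement
#'   noise added independently to each PSM reporter ratio.
#' @param rng_seed integer seed; identical seeds give identical outputs.
#'
#' @return An object of class `tmt_sim_config`.
#' @seealso [simulate_tmt_experiment()]
#' @export
tmt_sim_config <- function(n_candidate_proteins = 10L,
                           n_background_proteins = 100L,
                           psms_per_protein = 3L,
                           timepoints = c(0, 8, 12, 24, 48, 72),
                           candidate_effect = 0.3,
                           control_drift_sd = 0.03,
                           psm_noise_sd = 0.05,
                           rng_seed = 1L) {
  stop_if_not_count(n_candidate_proteins, "n_candidate_proteins")
  stop_if_not_count(n_background_proteins, "n_background_proteins")
  if (length(psms_per_protein) == 1L) psms_per_protein <- rep(psms_per_protein, 2L)
  stop_if_not_count(psms_per_protein[1], "psms_per_protein[min]")
  stop_if_not_count(psms_per_protein[2], "psms_per_protein[max]",
                    min = psms_per_protein[1])
  if (timepoints[1] != 0) stop("`timepoints` must start at 0", call. = FALSE)
  if (candidate_effect <= 0) stop("`candidate_effect` must be > 0", call. = FALSE)
  if (control_drift_sd < 0 || psm_noise_sd < 0) {
    stop("noise standard deviations must be >= 0", call. = FALSE)
  }
  structure(list(n_candidate_proteins = as.integer(n_candidate_proteins),
                 n_background_proteins = as.integer(n_background_proteins),
                 psms_per_protein = as.integer(psms_per_protein),
                 timepoints = as.numeric(timepoints),
                 candidate_effect = candidate_effect,
                 control_drift_sd = control_drift_sd,
                 psm_noise_sd = psm_noise_sd,
                 rng_seed = as.integer(rng_seed)),
            class = "tmt_sim_config")
}

# Time course of the planted effect: linear rise to full effect at 24 h,
# then sustained through the final time point.
effect_ramp <- function(timepoints) pmin(timepoints / 24, 1)

#' Simulate PSM-level TMT reporter tables with planted candidate regulators
#'
#' Generates one peptide-spectrum-match (PSM) table per condition. Each PSM
#' carries six reporter intensities ordered by time point; the time-zero
#' channel is the reference. True protein profiles are composed of the
#' planted effect (candidates only, stimulated conditions only), a
#' per-protein baseline drift shared by all PSMs of that protein, and
#' independent per-PSM reporter noise, all on the log10 ratio scale.
#'
#' @param cfg a [tmt_sim_config()].
#' @return A list with elements
#'   \describe{
#'     \item{psms}{named list of three data frames (`M(-)`, `M(IFNg)`,
#'       `M(IL-4)`) with columns `psm_id`, `protein`, `peptide`, `unique`
#'       (unique-to-protein-group flag), `condition`, and one intensity
#'       column per time point (`t0`, `t8`, ...).}
#'     \item{truth}{ground truth: `stage = "tmt"`, `labels` mapping each
#'       protein to `"candidate"` or `"background"`, and the true log10
#'       profile arrays.}
#'   }
#' @export
simulate_tmt_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "tmt_sim_config"))
  with_seed(cfg$rng_seed, {
    tp <- cfg$timepoints
    nt <- length(tp)
    proteins <- c(sprintf("CAND%03d", seq_len(cfg$n_candidate_proteins)),
                  sprintf("BG%04d", seq_len(cfg$n_background_proteins)))
    labels <- setNames(rep(c("candidate", "background"),
                           c(cfg$n_candidate_proteins, cfg$n_background_proteins)),
                       proteins)
    ramp <- effect_ramp(tp)
    np <- length(proteins)

    true_profiles <- list()
    psm_tables <- list()
    for (cond in MAC_CONDITIONS) {
      # planted effect component (zero at t = 0 by construction of the ramp)
      eff <- switch(cond,
                    "M(-)" = 0,
                    "M(IFNg)" = cfg$candidate_effect,
                    "M(IL-4)" = -cfg$candidate_effect)
      planted <- outer(as.numeric(labels == "candidate") * eff, ramp)
      drift <- matrix(rnorm(np * nt, 0, cfg$control_drift_sd), np, nt)
      drift[, tp == 0] <- 0
      truth_mat <- planted + drift
      dimnames(truth_mat) <- list(proteins, as.character(tp))
      true_profiles[[cond]] <- truth_mat

      psm_range <- cfg$psms_per_protein
      n_psms <- if (psm_range[1] == psm_range[2]) rep(psm_range[1], np) else
        sample(seq(psm_range[1], psm_range[2]), np, replace = TRUE)
      rows <- rep(seq_len(np), n_psms)
      total <- length(rows)
      base <- 10^runif(total, 5, 7)  # reference-channel intensity
      noise <- matrix(rnorm(total * nt, 0, cfg$psm_noise_sd), total, nt)
      noise[, tp == 0] <- 0
      log_ratio <- truth_mat[rows, , drop = FALSE] + noise
      intens <- base * 10^log_ratio
      colnames(intens) <- paste0("t", tp)
      pep_idx <- unlist(lapply(n_psms, seq_len))
      df <- data.frame(psm_id = sprintf("%s_psm%05d", cond, seq_len(total)),
                       protein = proteins[rows],
                       peptide = sprintf("%s_pep%02d", proteins[rows], pep_idx),
                       unique = TRUE,
                       condition = cond,
                       stringsAsFactors = FALSE)
      psm_tables[[cond]] <- cbind(df, as.data.frame(intens))
    }
    list(psms = psm_tables,
         truth = list(stage = "tmt", labels = labels,
                      profiles = true_profiles, config = cfg))
  })
}
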