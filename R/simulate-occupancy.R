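#' Simulate modified/unmodified precursor pairs with known site occupancy
#'
#' Generates precursor pairs for mono-ADP-ribosylated peptides and their
#' unmodified counterparts. The modified neutral mass exceeds the unmodified
#' one by the ADP-ribose mass (541.06 Da); extracted-ion-chromatogram areas
#' split a common total according to the planted occupancy, optionally
#' perturbed by multiplicative noise.
#'
#' @param n_pairs number of peptide pairs.
#' @param occupancies planted occupancies in `[0, 1]`, recycled to `n_pairs`.
#' @param rng_seed integer seed.
#' @param total_auc_range range of the total (modified + unmodified) AUC.
#' @param rel_noise_sd relative s.d. of multiplicative noise applied to each
#'   AUC; 0 gives exactly the planted split.
#' @param delta_mass mass difference between modified and unmodified neutral
#'   forms (Da).
#' @return A list with `pairs` (data frame: `pair_id`, `charge`,
#'   `unmod_neutral_mass`, `mod_neutral_mass`, `mod_mz`, `unmod_mz`,
#'   `rt_start`, `rt_end`, `auc_mod`, `auc_unmod`) and `truth` (planted
#'   occupancy per pair).
#' @export
simulate_occupancy_data <- function(n_pairs = 10L,
                                    occupancies = 0.5,
                                    rng_seed = 1L,
                                    total_auc_range = c(1e6, 1e7),
                                    rel_noise_sd = 0,
                                    delta_mass = 541.06) {
  stop_if_not_count(n_pairs, "n_pairs")
  if (any(occupancies < 0) || any(occupancies > 1)) {
    stop("`occupancies` must lie in [0, 1]", call. = FALSE)
  }
  occ <- rep_len(occupancies, n_pairs)
  with_seed(rng_seed, {
    proton <- 1.007276
    charge <- sample(2:3, n_pairs, replace = TRUE)
    unmod_mass <- runif(n_pairs, 800, 2500)
    mod_mass <- unmod_mass + delta_mass
    rt_start <- runif(n_pairs, 5, 100)
    total <- runif(n_pairs, total_auc_range[1], total_auc_range[2])
    noise <- function(n) pmax(1 + rnorm(n, 0, rel_noise_sd), 0)
    pairs <- data.frame(
      pair_id = sprintf("pair%03d", seq_len(n_pairs)),
      charge = charge,
      unmod_neutral_mass = unmod_mass,
      mod_neutral_mass = mod_mass,
      mod_mz = (mod_mass + charge * proton) / charge,
      unmod_mz = (unmod_mass + charge * proton) / charge,
      rt_start = rt_start,
      rt_end = rt_start + 2,
      auc_mod = occ * total * noise(n_pairs),
      auc_unmod = (1 - occ) * total * noise(n_pairs),
      stringsAsFactors = FALSE)
    list(pairs = pairs,
         truth = list(stage = "occupancy",
                      labels = setNames(occ, pairs$pair_id)))
  })
}
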