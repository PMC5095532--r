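## ADP-ribosylated peptide screening and site-occupancy quantification.
## All mass deltas are applied on the neutral scale and converted by charge.

ADP_RIBOSE_MASS <- 541.06

#' Screen an MS/MS spectrum for the ADP-ribose marker ion
#'
#' Reports whether any fragment peak lies within a ppm tolerance of the
#' marker m/z (default 348.1, the adenosine-monophosphate-derived "m6"
#' fragment diagnostic of ADP-ribosylated peptides).
#'
#' @param spectrum either a peak data frame with columns `mz`, `intensity`,
#'   or a list with a `peaks` element of that form.
#' @param marker_mz marker ion m/z (default 348.1).
#' @param tol_ppm matching tolerance in parts per million (default 20).
#' @return List with `hit` (logical) and `peak` (the closest matching peak
#'   row, or `NULL`).
#' @export
screen_marker_ion <- function(spectrum, marker_mz = 348.1, tol_ppm = 20) {
  peaks <- if (is.data.frame(spectrum)) spectrum else spectrum$peaks
  if (is.null(peaks) || nrow(peaks) == 0L) return(list(hit = FALSE, peak = NULL))
  ppm <- abs(peaks$mz - marker_mz) / marker_mz * 1e6
  within <- ppm <= tol_ppm
  if (!any(within)) return(list(hit = FALSE, peak = NULL))
  best <- which(within)[which.min(ppm[within])]
  list(hit = TRUE, peak = peaks[best, , drop = FALSE])
}

#' m/z of the unmodified counterpart of a modified precursor
#'
#' Subtracts the modification mass from the precursor on the neutral scale:
#' `unmodified m/z = modified m/z - delta_mass / charge`.
#'
#' @param modified_mz observed precursor m/z of the modified peptide.
#' @param charge precursor charge (>= 1).
#' @param delta_mass neutral mass of the modification (default the
#'   ADP-ribose mass, 541.06 Da).
#' @return Unmodified precursor m/z.
#' @export
unmodified_mz <- function(modified_mz, charge, delta_mass = ADP_RIBOSE_MASS) {
  if (any(charge < 1) || any(charge != round(charge))) {
    stop("`charge` must be a positive integer", call. = FALSE)
  }
  out <- modified_mz - delta_mass / charge
  if (any(out <= 0)) stop("resulting m/z is not positive", call. = FALSE)
  out
}

#' Build a targeted-acquisition inclusion list from precursor pairs
#'
#' Emits one row per form (modified and unmodified) of each pair with its
#' retention-time window. Rows with identical m/z and charge are merged into
#' a single entry spanning the widest window; the table is sorted by window
#' start, then m/z.
#'
#' @param pairs data frame with columns `mod_mz`, `unmod_mz`, `charge`,
#'   `rt_start`, `rt_end` (as produced by [simulate_occupancy_data()]).
#' @return Data frame with columns `mz`, `charge`, `rt_start`, `rt_end`.
#' @export
build_inclusion_list <- function(pairs) {
  if (any(pairs$rt_start >= pairs$rt_end)) {
    stop("retention-time windows must satisfy start < end", call. = FALSE)
  }
  long <- rbind(
    data.frame(mz = pairs$mod_mz, charge = pairs$charge,
               rt_start = pairs$rt_start, rt_end = pairs$rt_end),
    data.frame(mz = pairs$unmod_mz, charge = pairs$charge,
               rt_start = pairs$rt_start, rt_end = pairs$rt_end))
  key <- paste(format(long$mz, digits = 10), long$charge)
  if (anyDuplicated(key)) {
    message(sprintf("%d duplicate entr(ies) merged with widest window",
                    sum(duplicated(key))))
    long <- do.call(rbind, lapply(split(long, key), function(g) {
      data.frame(mz = g$mz[1], charge = g$charge[1],
                 rt_start = min(g$rt_start), rt_end = max(g$rt_end))
    }))
  }
  out <- long[order(long$rt_start, long$mz), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mono-ADP-ribosylation site occupancy from chromatogram areas
#'
#' The occupancy of a site is the modified fraction of the extracted-ion
#' chromatogram areas: `AUC_mod / (AUC_mod + AUC_unmod)`.
#'
#' @param auc_mod,auc_unmod nonnegative areas under the curve for the
#'   modified and unmodified forms (vectorized).
#' @return An object of class `occupancy_result`: data frame with columns
#'   `auc_mod`, `auc_unmod`, `occupancy` (in `[0, 1]`; `NA` with a warning
#'   when both areas are zero).
#' @export
occupancy <- function(auc_mod, auc_unmod) {
  if (any(auc_mod < 0) || any(auc_unmod < 0)) {
    stop("areas must be nonnegative", call. = FALSE)
  }
  total <- auc_mod + auc_unmod
  ratio <- ifelse(total > 0, auc_mod / total, NA_real_)
  if (anyNA(ratio)) warning("occupancy undefined where both areas are zero")
  structure(data.frame(auc_mod = auc_mod, auc_unmod = auc_unmod,
                       occupancy = ratio),
            class = c("occupancy_result", "data.frame"))
}
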