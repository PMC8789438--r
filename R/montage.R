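#' Default 16-channel 10-20 montage
#'
#' Electrode labels for the 16-channel recording layout assumed throughout the
#' package, ordered frontal to occipital.  P300 responses are expected over
#' the posterior (parieto-occipital) subset.
#'
#' @return Character vector of 16 channel labels.
#' @export
#' @examples
#' default_montage()
default_montage <- function() {
  c("Fp1", "Fp2", "F3", "Fz", "F4", "C3", "Cz", "C4",
    "P3", "Pz", "P4", "PO3", "POz", "PO4", "O1", "O2")
}

#' Posterior (parieto-occipital) channel labels
#'
#' The parietal / parieto-occipital / occipital subset of the montage used to
#' score P3 strength: P300 amplitude concentrates over these electrodes.
#'
#' @return Character vector of channel labels.
#' @export
posterior_channels <- function() {
  c("P3", "Pz", "P4", "PO3", "POz", "PO4", "O1", "O2")
}

# Canonical P3 scalp pattern on the default montage, max-normalized.
# Posterior-dominant with a soft fall-off toward central and frontal sites.
p3_scalp_pattern <- function(channels = default_montage()) {
  base <- c(Fp1 = 0.05, Fp2 = 0.05, F3 = 0.10, Fz = 0.12, F4 = 0.10,
            C3 = 0.25, Cz = 0.35, C4 = 0.25,
            P3 = 0.60, Pz = 0.85, P4 = 0.60,
            PO3 = 0.90, POz = 1.00, PO4 = 0.90,
            O1 = 0.70, O2 = 0.70)
  if (!all(channels %in% names(base))) {
    stop("unknown channel label(s): ",
         paste(setdiff(channels, names(base)), collapse = ", "))
  }
  unname(base[channels])
}
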