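#' The 32-channel recording montage
#'
#' Channel labels of the 32-electrode cap (extended international 10-20
#' system) in recording order, as used by the synthetic generator and
#' expected by [rereference_mastoids()] and [aggregate_by_region()].
#'
#' @return Character vector of 32 channel labels.
#' @export
eeg_montage <- function() {
  c("Fp1", "Fz", "F3", "F7", "FT9", "FC5", "FC1", "C3", "T7", "TP9",
    "CP5", "CP1", "Pz", "P3", "P7", "O1", "Oz", "O2", "P4", "P8",
    "TP10", "CP6", "CP2", "Cz", "C4", "T8", "FT10", "FC6", "FC2",
    "F4", "F8", "Fp2")
}

#' Electrode-to-region grouping
#'
#' Maps every montage channel to one of five scalp regions used when
#' aggregating channel-pair connectivity. The central group is
#' \{C3, Cz, C4\}: C4 substitutes for the sometimes-quoted C5, which is not
#' part of this montage (the substitution is recorded in the `"note"`
#' attribute of the returned vector). Note that after mean-mastoid
#' re-referencing TP9 and TP10 are algebraically degenerate
#' (each equals plus/minus half their original difference); they are kept in
#' the temporal group for fidelity with the standard grouping and the
#' degeneracy is flagged by [rereference_mastoids()].
#'
#' @return Named character vector: names are channel labels, values are
#'   regions in `c("frontal", "central", "temporal", "parietal", "occipital")`.
#' @export
region_map <- function() {
  regions <- c(
    Fp1 = "frontal", Fp2 = "frontal", F7 = "frontal", F3 = "frontal",
    Fz = "frontal", F4 = "frontal", F8 = "frontal", FC5 = "frontal",
    FC1 = "frontal", FC2 = "frontal", FC6 = "frontal",
    C3 = "central", Cz = "central", C4 = "central",
    FT9 = "temporal", T7 = "temporal", TP9 = "temporal",
    FT10 = "temporal", T8 = "temporal", TP10 = "temporal",
    CP5 = "parietal", CP1 = "parietal", CP6 = "parietal", CP2 = "parietal",
    P7 = "parietal", P3 = "parietal", Pz = "parietal", P4 = "parietal",
    P8 = "parietal",
    O1 = "occipital", Oz = "occipital", O2 = "occipital"
  )
  regions <- regions[eeg_montage()]
  attr(regions, "note") <- "central group uses C4 in place of C5 (C5 absent from montage)"
  regions
}

#' Canonical frequency bands
#'
#' The five analysis bands: delta 1-3 Hz, theta 4-7 Hz, alpha 8-12 Hz,
#' beta 13-30 Hz, gamma 31-50 Hz.
#'
#' @return A data frame with columns `name`, `lo`, `hi` (Hz).
#' @export
band_specs <- function() {
  data.frame(
    name = c("delta", "theta", "alpha", "beta", "gamma"),
    lo = c(1, 4, 8, 13, 31),
    hi = c(3, 7, 12, 30, 50),
    stringsAsFactors = FALSE
  )
}

band_spec <- function(name) {
  bs <- band_specs()
  row <- bs[bs$name == name, ]
  if (nrow(row) != 1L) stop("unknown band: ", name)
  row
}
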