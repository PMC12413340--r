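#' Default 30-channel montage
#'
#' A fixed 30-label subset of the extended 10-10 system, matching a typical
#' 32-electrode MR-compatible cap with the two non-EEG channels removed.
#' The 2-D positions are schematic top-view head coordinates (head radius 1,
#' nose up, right ear at positive x); they are used only by the synthetic
#' generator's distance-decaying volume-conduction mixing, not for plotting
#' or source modelling.
#'
#' @return Data frame with columns `name`, `x`, `y`; 30 rows in the channel
#'   order used by all package defaults.
#' @export
default_montage <- function() {
  m <- matrix(c(
    -0.31,  0.95,   0.31,  0.95,                                    # Fp1 Fp2
    -0.81,  0.59,  -0.40,  0.52,  0.00,  0.50,  0.40,  0.52,  0.81,  0.59,  # F7 F3 Fz F4 F8
    -0.62,  0.28,  -0.22,  0.26,  0.22,  0.26,  0.62,  0.28,        # FC5 FC1 FC2 FC6
    -1.00,  0.00,  -0.50,  0.00,  0.00,  0.00,  0.50,  0.00,  1.00,  0.00,  # T7 C3 Cz C4 T8
    -0.62, -0.28,  -0.22, -0.26,  0.22, -0.26,  0.62, -0.28,        # CP5 CP1 CP2 CP6
    -1.03, -0.36,   1.03, -0.36,                                    # TP9 TP10
    -0.81, -0.59,  -0.40, -0.52,  0.00, -0.50,  0.40, -0.52,  0.81, -0.59,  # P7 P3 Pz P4 P8
    -0.31, -0.95,   0.00, -1.00,  0.31, -0.95                       # O1 Oz O2
  ), ncol = 2, byrow = TRUE)
  data.frame(
    name = c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
             "FC5", "FC1", "FC2", "FC6",
             "T7", "C3", "Cz", "C4", "T8",
             "CP5", "CP1", "CP2", "CP6", "TP9", "TP10",
             "P7", "P3", "Pz", "P4", "P8", "O1", "Oz", "O2"),
    x = m[, 1], y = m[, 2],
    stringsAsFactors = FALSE
  )
}
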