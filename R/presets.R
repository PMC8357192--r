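#' Tissue presets for the phantom generator
#'
#' Returns the ground-truth optical parameters for one of three treatment
#' conditions of bovine articular cartilage explants: untreated
#' (`"control"`) and two intensities of chondroitinase ABC digestion
#' (`"low"`, `"high"`) which strip glycosaminoglycan (GAG) from a
#' superficial layer.
#'
#' Channel-1 lifetime ramps from 5.7 ns at the surface to 6.1 ns beyond
#' 0.5 mm depth in every condition. Healthy channel-2/3 lifetimes are
#' 6.34 / 5.22 ns; inside the depleted layer they drop by 0.44 / 0.75 ns.
#' The depleted layer is 0.3 mm thick for `"low"` and 0.7 mm for `"high"`.
#'
#' Intensity-ratio triples: GAG loss changes the three channel ratios by
#' -37%, -31% and +23% respectively. Because ratios are closed (sum to 1),
#' those three relative changes pin the control triple to a one-parameter
#' family satisfying `0.63 r1 + 0.69 r2 + 1.23 r3 = 1`; the default fixes
#' channel 1 at `r1 = 0.323` (above the 0.25 segmentation threshold, with
#' the depleted value 0.203 below it), giving control
#' `(0.323, 0.0670, 0.6100)` and depleted `(0.203, 0.0463, 0.7503)`.
#'
#' @param name `"control"`, `"low"` or `"high"`.
#' @param surfaceFn Function mapping lateral position (mm) to cartilage
#'   surface depth (mm from image top). Default: flat surface at 1 mm
#'   (row 5 at 0.2 mm pitch).
#' @param r1Healthy Channel-1 control intensity ratio used to fix the
#'   closure family (see Details).
#' @return A [TissuePreset-class] object.
#' @examples
#' tissuePreset("high")
#' @export
tissuePreset <- function(name = c("control", "low", "high"),
                         surfaceFn = function(x) rep(1.0, length(x)),
                         r1Healthy = 0.323) {
  name <- match.arg(name)
  rel <- c(-0.37, -0.31, 0.23)          # relative ratio changes under GAG loss
  r1 <- r1Healthy
  # closure: sum(r) = 1 and sum(r * (1 + rel)) = 1
  r2 <- (-rel[3] - (rel[1] - rel[3]) * r1) / (rel[2] - rel[3])
  r3 <- 1 - r1 - r2
  healthy <- c(r1, r2, r3)
  depleted <- healthy * (1 + rel)
  depleted[3] <- 1 - depleted[1] - depleted[2]  # exact closure
  thick <- switch(name, control = 0, low = 0.3, high = 0.7)
  new("TissuePreset",
      name = name,
      ltCh1Surface = 5.7, ltCh1Deep = 6.1, ltRampDepth = 0.5,
      ltCh2 = 6.34, ltCh3 = 5.22,
      ltCh2Depleted = 6.34 - 0.44, ltCh3Depleted = 5.22 - 0.75,
      ratiosHealthy = healthy, ratiosDepleted = depleted,
      depletedThickness = thick, surfaceFn = surfaceFn)
}
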