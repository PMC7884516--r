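#' Run configuration
#'
#' All tunable constants of the measurement pipeline in one place.  The
#' defaults are the protocol values: a 25 mm distal femoral band for
#' condyle detection, 1 mm condylar tip bands, a 10 mm metaphyseal slab
#' on the proximal side of the distal joint plane, the second principal
#' component as the distal axis, six shaft sections at 40-140 mm in 20 mm
#' steps below the plateau, and 1.0 mm axial slice offsets for the 2D
#' methods (one CT slice).
#'
#' @param condyle_band_mm height of the distal femoral band used for
#'   condyle detection.
#' @param tip_band_mm height of the condylar tip band.
#' @param slab_thickness_mm distal metaphyseal slab thickness.
#' @param slab_side `"proximal"` (default) or `"distal"`: which side of
#'   the distal joint plane the slab is taken from.
#' @param dta_component principal component index (1 or 2) defining the
#'   distal tibia axis.
#' @param shaft_offsets_mm section offsets (mm, distal of the plateau
#'   plane centre) for the anatomical axis.
#' @param n_samples surface sample budget for stochastic stages.
#' @param slice_offset_mm axial slice offset for the 2D methods.
#' @param seed default integer seed threaded to all stochastic stages.
#' @return A named list of class `run_config`.
#' @export
run_config <- function(condyle_band_mm = 25, tip_band_mm = 1,
                       slab_thickness_mm = 10, slab_side = c("proximal", "distal"),
                       dta_component = 2, shaft_offsets_mm = seq(40, 140, by = 20),
                       n_samples = 8000, slice_offset_mm = 1.0, seed = 1) {
  slab_side <- match.arg(slab_side)
  cfg <- list(condyle_band_mm = condyle_band_mm, tip_band_mm = tip_band_mm,
              slab_thickness_mm = slab_thickness_mm, slab_side = slab_side,
              dta_component = dta_component, shaft_offsets_mm = shaft_offsets_mm,
              n_samples = n_samples, slice_offset_mm = slice_offset_mm,
              seed = seed)
  num <- cfg[c("condyle_band_mm", "tip_band_mm", "slab_thickness_mm",
               "n_samples", "slice_offset_mm", "shaft_offsets_mm")]
  if (any(!unlist(lapply(num, is.numeric))) || any(unlist(num) <= 0)) {
    stop("run_config: all geometric constants must be positive numbers", call. = FALSE)
  }
  if (!dta_component %in% c(1, 2)) {
    stop("run_config: dta_component must be 1 or 2", call. = FALSE)
  }
  structure(cfg, class = c("run_config", "list"))
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-18s %s\n", nm, paste(format(x[[nm]]), collapse = " ")))
  }
  invisible(x)
}
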