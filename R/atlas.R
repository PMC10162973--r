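#' Desikan-Killiany cortical parcellation labels
#'
#' The 68 cortical regions of interest (ROIs) of the Desikan-Killiany atlas:
#' 34 regions per hemisphere, suffixed `_lh` (left) and `_rh` (right). All
#' ROI-level containers in the package index rows by this vector, in this
#' order (left hemisphere first, regions alphabetical within hemisphere).
#'
#' @return Character vector of length 68.
#' @export
#' @examples
#' length(dk_rois())
#' grep("_rh$", dk_rois(), value = TRUE)[1:3]
dk_rois <- function() {
  regions <- c(
    "bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
    "entorhinal", "frontalpole", "fusiform", "inferiorparietal",
    "inferiortemporal", "insula", "isthmuscingulate", "lateraloccipital",
    "lateralorbitofrontal", "lingual", "medialorbitofrontal", "middletemporal",
    "paracentral", "parahippocampal", "parsopercularis", "parsorbitalis",
    "parstriangularis", "pericalcarine", "postcentral", "posteriorcingulate",
    "precentral", "precuneus", "rostralanteriorcingulate",
    "rostralmiddlefrontal", "superiorfrontal", "superiorparietal",
    "superiortemporal", "supramarginal", "temporalpole", "transversetemporal"
  )
  c(paste0(regions, "_lh"), paste0(regions, "_rh"))
}

# Resolve ROI labels to row indices, with validation.
roi_index <- function(rois) {
  all_rois <- dk_rois()
  idx <- match(rois, all_rois)
  if (anyNA(idx))
    stop("unknown ROI id(s): ", paste(rois[is.na(idx)], collapse = ", "),
         call. = FALSE)
  idx
}
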