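#' AAL90 region labels
#'
#' The 90 cerebral regions of the Automated Anatomical Labelling atlas in
#' standard order (odd indices left hemisphere, even indices right).
#'
#' @return character vector of length 90.
#' @export
aal90_labels <- function() {
  base <- c(
    "Precentral", "Frontal_Sup", "Frontal_Sup_Orb", "Frontal_Mid",
    "Frontal_Mid_Orb", "Frontal_Inf_Oper", "Frontal_Inf_Tri",
    "Frontal_Inf_Orb", "Rolandic_Oper", "Supp_Motor_Area", "Olfactory",
    "Frontal_Sup_Medial", "Frontal_Med_Orb", "Rectus", "Insula",
    "Cingulum_Ant", "Cingulum_Mid", "Cingulum_Post", "Hippocampus",
    "ParaHippocampal", "Amygdala", "Calcarine", "Cuneus", "Lingual",
    "Occipital_Sup", "Occipital_Mid", "Occipital_Inf", "Fusiform",
    "Postcentral", "Parietal_Sup", "Parietal_Inf", "SupraMarginal",
    "Angular", "Precuneus", "Paracentral_Lobule", "Caudate", "Putamen",
    "Pallidum", "Thalamus", "Heschl", "Temporal_Sup", "Temporal_Pole_Sup",
    "Temporal_Mid", "Temporal_Pole_Mid", "Temporal_Inf"
  )
  as.vector(rbind(paste0(base, "_L"), paste0(base, "_R")))
}

#' Default five-module partition of the AAL90 atlas
#'
#' Assigns each AAL region to one of five large-scale networks: sensorimotor
#' (SMN), default mode (DMN), fronto-parietal (FPN), visual (VN) and
#' subcortical (SN). Published five-module groupings of AAL90 differ in
#' detail and the exact assignment used by any given study is rarely
#' printed; this mapping follows standard anatomical membership (precentral,
#' postcentral, supplementary motor, rolandic, paracentral and superior
#' temporal/Heschl regions to SMN; medial prefrontal, orbital, cingulate,
#' medial temporal, angular and precuneus regions to DMN; lateral prefrontal
#' and lateral parietal regions to FPN; occipital and fusiform regions to
#' VN; basal ganglia, thalamus, insula, amygdala and olfactory regions to
#' SN) and is intended as a replaceable default: supply your own
#' region-to-module table wherever a `partition` argument is accepted.
#'
#' @return named character vector: names are AAL region labels, values are
#'   module labels in `c("SMN", "DMN", "FPN", "VN", "SN")`.
#' @export
aal90_partition <- function() {
  mod_of <- c(
    Precentral = "SMN", Frontal_Sup = "FPN", Frontal_Sup_Orb = "DMN",
    Frontal_Mid = "FPN", Frontal_Mid_Orb = "DMN", Frontal_Inf_Oper = "FPN",
    Frontal_Inf_Tri = "FPN", Frontal_Inf_Orb = "DMN", Rolandic_Oper = "SMN",
    Supp_Motor_Area = "SMN", Olfactory = "SN", Frontal_Sup_Medial = "DMN",
    Frontal_Med_Orb = "DMN", Rectus = "DMN", Insula = "SN",
    Cingulum_Ant = "DMN", Cingulum_Mid = "DMN", Cingulum_Post = "DMN",
    Hippocampus = "DMN", ParaHippocampal = "DMN", Amygdala = "SN",
    Calcarine = "VN", Cuneus = "VN", Lingual = "VN", Occipital_Sup = "VN",
    Occipital_Mid = "VN", Occipital_Inf = "VN", Fusiform = "VN",
    Postcentral = "SMN", Parietal_Sup = "FPN", Parietal_Inf = "FPN",
    SupraMarginal = "FPN", Angular = "DMN", Precuneus = "DMN",
    Paracentral_Lobule = "SMN", Caudate = "SN", Putamen = "SN",
    Pallidum = "SN", Thalamus = "SN", Heschl = "SMN", Temporal_Sup = "SMN",
    Temporal_Pole_Sup = "DMN", Temporal_Mid = "DMN",
    Temporal_Pole_Mid = "DMN", Temporal_Inf = "DMN"
  )
  labs <- aal90_labels()
  stem <- sub("_[LR]$", "", labs)
  stats::setNames(unname(mod_of[stem]), labs)
}

#' Module labels recognized by the default partition
#' @return character vector of the five module names.
#' @export
module_levels <- function() c("SMN", "DMN", "FPN", "VN", "SN")

#' Synthetic display coordinates for a parcellation
#'
#' Deterministic points on a brain-sized ellipsoid, usable as placeholder
#' node coordinates in BrainNet Viewer `.node` files when real MNI
#' centroids are not supplied. Purely synthetic; not anatomical locations.
#'
#' @param p number of regions.
#' @return p x 3 numeric matrix of x, y, z coordinates (mm scale).
#' @export
synthetic_coordinates <- function(p) {
  i <- seq_len(p)
  phi <- acos(1 - 2 * (i - 0.5) / p)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(
    x = 70 * sin(phi) * cos(theta),
    y = 85 * sin(phi) * sin(theta),
    z = 60 * cos(phi)
  )
}
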