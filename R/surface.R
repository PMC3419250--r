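#' Mean distance between ligand anchors in a supported membrane
#'
#' Biotinylated anchor lipids at molar fraction `chi` occupy on average
#' one anchor per `area_per_lipid / chi` of membrane, giving a mean
#' inter-anchor spacing `<d> = sqrt(area_per_lipid / chi)`. With the
#' standard fluid-phase area per lipid of 60 A^2, chi = 0.02 gives
#' ~5.5 nm and chi = 0.005 gives ~11 nm.
#'
#' @param chi anchor (biotin-lipid) molar fraction, in (0, 1].
#' @param area_per_lipid area per lipid in A^2 (default 60).
#' @return mean anchor distance in nm.
#' @examples
#' anchor_distance(0.02)   # ~5.48 nm
#' anchor_distance(0.005)  # ~10.95 nm
#' @export
anchor_distance <- function(chi, area_per_lipid = 60) {
  if (any(chi <= 0) || any(chi > 1))
    stop("'chi' must lie in (0, 1]")
  stop_if_not_scalar_num(area_per_lipid, "area_per_lipid", positive = TRUE)
  sqrt(area_per_lipid / chi) / 10   # Angstrom -> nm
}

#' Anchor molar fraction for a target spacing
#'
#' Inverse of [anchor_distance()]: `chi = area_per_lipid / d^2` with d in
#' Angstrom. Round-trips through [anchor_distance()] to machine
#' precision.
#'
#' @param target_d_nm desired mean anchor distance (nm); must be at least
#'   one anchor per lipid, i.e. `sqrt(area_per_lipid)/10` nm.
#' @param area_per_lipid area per lipid in A^2 (default 60).
#' @return molar fraction chi in (0, 1].
#' @export
chi_for_distance <- function(target_d_nm, area_per_lipid = 60) {
  stop_if_not_scalar_num(area_per_lipid, "area_per_lipid", positive = TRUE)
  d_min <- sqrt(area_per_lipid) / 10
  if (any(target_d_nm < d_min))
    stop(sprintf("target spacing below one anchor per lipid (min %.3f nm)",
                 d_min))
  area_per_lipid / (10 * target_d_nm)^2
}

#' Design table of anchor fractions and spacings
#'
#' @param chi vector of molar fractions.
#' @param area_per_lipid area per lipid (A^2, default 60).
#' @return data.frame: chi, mean_distance_nm.
#' @export
surface_design_table <- function(chi, area_per_lipid = 60) {
  data.frame(chi = chi,
             mean_distance_nm = anchor_distance(chi, area_per_lipid))
}
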