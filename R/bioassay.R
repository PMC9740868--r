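#' Protein content from a Bradford-type standard curve
#'
#' Inverts the absorbance standard curve Y = slope * X + intercept to the
#' protein content X (mg/g of solution) and normalizes by the powder mass:
#' content = X / mass. The default curve is the bovine-serum-albumin
#' calibration of the packaged study, Y = 0.0058 X - 0.0047.
#'
#' @param absorbance Measured absorbance Y; must be >= the curve intercept.
#' @param mass_g Powder mass m in grams (> 0).
#' @param slope,intercept Standard-curve parameters.
#' @return Protein content in mg per g of powder.
#' @export
#' @examples
#' protein_from_absorbance(0.0058 * 10 - 0.0047, mass_g = 1)
protein_from_absorbance <- function(absorbance, mass_g,
                                    slope = 0.0058, intercept = -0.0047) {
  if (any(mass_g <= 0)) stop("sample mass must be positive")
  if (any(absorbance < intercept))
    stop("absorbance below the curve intercept gives a negative content")
  ((absorbance - intercept) / slope) / mass_g
}

#' Protein extraction yield
#'
#' yield = purity * extract mass / (powder mass * powder protein fraction)
#' * 100: the fraction of the powder's protein recovered in the extract.
#'
#' @param purity Protein purity of the extract (fraction, e.g. 0.5423).
#' @param mass_extract_g Mass of the freeze-dried extract (g).
#' @param mass_powder_g Mass of starting powder (g).
#' @param protein_frac Protein fraction of the powder (e.g. 0.1331).
#' @return Yield as a percentage.
#' @export
yield_percent <- function(purity, mass_extract_g, mass_powder_g, protein_frac) {
  if (any(c(purity, mass_powder_g, protein_frac) <= 0) || any(mass_extract_g < 0))
    stop("purity, masses and protein fraction must be positive")
  purity * mass_extract_g / (mass_powder_g * protein_frac) * 100
}

#' Radical-scavenging rate (DPPH or ABTS)
#'
#' (1 - (A1 - A2) / A0) * 100, where A1 is the control (radical + sample
#' solvent), A2 the sample background, and A0 the blank (radical only). The
#' same form serves both the DPPH and ABTS colorimetric assays.
#'
#' @param a0 Blank absorbance (> 0).
#' @param a1 Control absorbance.
#' @param a2 Sample-background absorbance.
#' @return Scavenging rate as a percentage.
#' @export
#' @examples
#' scavenging_rate(a0 = 0.5, a1 = 0.30, a2 = 0.234)
scavenging_rate <- function(a0, a1, a2) {
  if (any(a0 == 0)) stop("blank absorbance A0 must be nonzero")
  if (any(c(a0, a1, a2) < 0)) stop("absorbances must be nonnegative")
  (1 - (a1 - a2) / a0) * 100
}

#' Cytostatic (growth-inhibition) rate from a CCK-8 assay
#'
#' (1 - (OD1 - OD0) / (OD2 - OD0)) * 100, with OD1 the treated wells, OD2 the
#' untreated control and OD0 the cell-free blank.
#'
#' @param od0 Blank optical density.
#' @param od1 Treated-well optical density.
#' @param od2 Untreated-control optical density (must differ from `od0`).
#' @return Inhibition rate as a percentage.
#' @export
cytostatic_rate <- function(od0, od1, od2) {
  if (any(od2 == od0)) stop("control and blank OD coincide: rate undefined")
  if (any(c(od0, od1, od2) < 0)) stop("optical densities must be nonnegative")
  (1 - (od1 - od0) / (od2 - od0)) * 100
}

#' Migration (wound-closure) rate from a scratch assay
#'
#' (H1 - H2) / H1 * 100, with H1 the scratch area at time zero and H2 the
#' area at the later time point (same units).
#'
#' @param h1 Initial scratch area (> 0).
#' @param h2 Later scratch area (>= 0).
#' @return Closure percentage.
#' @export
migration_rate <- function(h1, h2) {
  if (any(h1 <= 0)) stop("initial scratch area H1 must be positive")
  if (any(h2 < 0)) stop("scratch areas must be nonnegative")
  (h1 - h2) / h1 * 100
}

#' Essential amino acids (Thr, Val, Met, Ile, Leu, Phe, Lys)
#' @keywords internal
essential_residues <- function() c("Thr", "Val", "Met", "Ile", "Leu", "Phe", "Lys")

# Hydrophobic set fixed as {Ala, Val, Leu, Ile, Pro, Phe, Met}: the common
# aliphatic+aromatic convention excluding Gly, Trp and Cys.
hydrophobic_residues <- function() c("Ala", "Val", "Leu", "Ile", "Pro", "Phe", "Met")

#' Amino-acid profile of the packaged extraction study
#'
#' Contents in percent by mass (g/100 g) of 16 residues; Cys and Trp are
#' absent because hydrolysis destroys them, and the total is the sum over the
#' listed residues only.
#'
#' @return A named numeric vector of contents (percent by mass).
#' @export
#' @examples
#' aa_summary(sep_amino_acids())
sep_amino_acids <- function() {
  path <- system.file("extdata", "sep_amino_acids.csv", package = "protexopt",
                      mustWork = TRUE)
  df <- utils::read.csv(path)
  stats::setNames(df$content_pct, df$residue)
}

#' Summarize an amino-acid profile
#'
#' Essential fraction = sum of Thr, Val, Met, Ile, Leu, Phe, Lys over the
#' total; hydrophobic fraction = sum of Ala, Val, Leu, Ile, Pro, Phe, Met over
#' the total. Residues from either set that are missing from the profile are
#' listed in a warning and treated as zero. Both fractions are invariant
#' under uniform scaling of the profile.
#'
#' @param profile A named numeric vector of residue contents (percent by
#'   mass), or a data frame with columns `residue` and `content_pct`.
#' @return A list with `essential_pct`, `hydrophobic_pct` and `total`.
#' @export
aa_summary <- function(profile) {
  if (is.data.frame(profile))
    profile <- stats::setNames(profile$content_pct, profile$residue)
  profile <- profile[!is.na(profile)]
  if (any(profile < 0)) stop("amino-acid contents must be nonnegative")
  total <- sum(profile)
  if (total <= 0) stop("profile total must be positive")
  missing <- setdiff(union(essential_residues(), hydrophobic_residues()),
                     names(profile))
  if (length(missing))
    warning("residues missing from profile (treated as 0): ",
            paste(missing, collapse = ", "))
  pick <- function(set) sum(profile[intersect(set, names(profile))])
  list(essential_pct = pick(essential_residues()) / total * 100,
       hydrophobic_pct = pick(hydrophobic_residues()) / total * 100,
       total = total)
}
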