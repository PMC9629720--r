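#' Default outer-membrane protein species table
#'
#' Per-species membrane-plane footprint radii and masses for the seven OMPs
#' of the default island: the OmpF trimer scaffold, four TonB-dependent
#' transporters (TBDTs: BtuB, FhuE, FhuA, FepA) and the two biogenesis
#' machines carried as single complexes (BamA with its BamBCDE lipoproteins,
#' LptD with LptE). Radii are footprint estimates in nm chosen so that the
#' closed-form annular shell counts give 18 LPS around an OmpF trimer and 13
#' around a TBDT barrel; they are tunable. `mass_kda` is the mass of the
#' mature species including lipoprotein partners for complexes; `barrel_kda`
#' is the beta-barrel-only mass used as the "OMP" numerator of the protein
#' mass fraction.
#'
#' @return data.frame with columns `name`, `category` (one of
#'   `"trimeric-porin"`, `"monomeric-barrel"`, `"barrel-complex"`),
#'   `effective_radius` (nm), `mass_kda`, `barrel_kda`.
#' @export
default_omp_species <- function() {
  df <- data.frame(
    name = c("OmpF-trimer", "BtuB", "FhuE", "FhuA", "FepA",
             "BamA-complex", "LptD-complex"),
    category = c("trimeric-porin", rep("monomeric-barrel", 4),
                 "barrel-complex", "barrel-complex"),
    effective_radius = c(3.5, 2.25, 2.25, 2.25, 2.25, 3.0, 2.4),
    mass_kda = c(111.3, 66.3, 75.0, 78.9, 79.8, 205.0, 105.8),
    barrel_kda = c(111.3, 66.3, 75.0, 78.9, 79.8, 88.4, 87.0),
    stringsAsFactors = FALSE
  )
  validate_omp_species(df)
  df
}

validate_omp_species <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("name", "category", "effective_radius", "mass_kda", "barrel_kda")
  if (!all(need %in% names(df)))
    stop("OMP species table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$name))
    stop("validation error: OMP species names must be unique")
  if (any(df$effective_radius <= 0))
    stop("validation error: effective_radius must be > 0")
  if (any(df$mass_kda <= 0) || any(df$barrel_kda <= 0))
    stop("validation error: masses must be > 0")
  bad <- setdiff(df$category,
                 c("trimeric-porin", "monomeric-barrel", "barrel-complex"))
  if (length(bad)) stop("validation error: unknown OMP category: ", bad[1])
  invisible(df)
}

#' Default lipid species table
#'
#' The asymmetric outer-membrane lipid complement: rough LPS (RaLPS, lacking
#' O-antigen) in the outer leaflet and POPE/POPG/cardiolipin in the inner
#' leaflet. `footprint_diameter` is the membrane-plane cross-section in nm;
#' the 1.43 nm RaLPS value (footprint area about 1.6 nm^2) drives the annular
#' shell counts. Masses in kDa.
#'
#' @return data.frame with columns `name`, `leaflet`, `footprint_diameter`
#'   (nm), `mass_kda`.
#' @export
default_lipid_species <- function() {
  data.frame(
    name = c("RaLPS", "POPE", "POPG", "CL"),
    leaflet = c("outer", "inner", "inner", "inner"),
    footprint_diameter = c(1.43, 0.91, 0.91, 1.29),
    mass_kda = c(3.9, 0.718, 0.749, 1.43),
    stringsAsFactors = FALSE
  )
}

#' Default mass table for island mass accounting
#'
#' Combines the OMP and lipid species masses with the counter-ion
#' convention: three Ca2+ ions (0.040 kDa each) per RaLPS molecule,
#' neutralising the LPS charges, counted in the total mass but not in the
#' protein mass.
#'
#' @return list with elements `omp` (the OMP species table), `lipid` (the
#'   lipid species table), `ca_mass_kda`, `ca_per_lps`.
#' @export
default_mass_table <- function() {
  list(
    omp = default_omp_species(),
    lipid = default_lipid_species(),
    ca_mass_kda = 0.040,
    ca_per_lps = 3L
  )
}

#' LPS footprint diameter used throughout the package (nm)
#' @keywords internal
lps_diameter <- function(lipids = default_lipid_species()) {
  lipids$footprint_diameter[lipids$name == "RaLPS"]
}
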