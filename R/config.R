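#' Geometry configuration for island construction
#'
#' @param patch_size Square membrane patch side length in nm. Default 150.
#' @param lattice_spacing Scaffold centroid-to-centroid spacing `a` in nm.
#'   Must lie in the 8.0--9.0 nm band (80--90 Angstrom) observed for
#'   porin-porin centroid distances. Default 8.5.
#' @param jitter_sd Standard deviation (nm) of seeded Gaussian displacement
#'   applied to scaffold sites; 0 (default) gives a perfect lattice.
#' @param n_hexagons Number of hexagon rings (kagome-patch layout). Default 18.
#' @param layout `"reference"` (the packaged 102-site/18-hexagon layout) or
#'   `"kagome-patch"` (a generated kagome patch with `n_hexagons` rings).
#' @param seed Integer seed for the jitter displacement.
#' @return object of class `geometry_config`.
#' @export
geometry_config <- function(patch_size = 150, lattice_spacing = 8.5,
                            jitter_sd = 0, n_hexagons = 18L,
                            layout = c("reference", "kagome-patch"),
                            seed = 1L) {
  layout <- match.arg(layout)
  g <- structure(list(patch_size = as.numeric(patch_size),
                      lattice_spacing = as.numeric(lattice_spacing),
                      jitter_sd = as.numeric(jitter_sd),
                      n_hexagons = as.integer(n_hexagons),
                      layout = layout, seed = as.integer(seed)),
                 class = "geometry_config")
  validate_geometry_config(g)
  g
}

validate_geometry_config <- function(g) {
  if (!is.finite(g$patch_size) || g$patch_size <= 0)
    stop("validation error: patch_size must be > 0")
  if (g$lattice_spacing < 8.0 || g$lattice_spacing > 9.0)
    stop("validation error: lattice_spacing must lie in [8.0, 9.0] nm")
  if (g$jitter_sd < 0) stop("validation error: jitter_sd must be >= 0")
  if (g$n_hexagons < 1) stop("validation error: n_hexagons must be >= 1")
  invisible(g)
}

#' Island composition specification
#'
#' Compositional constraints of the island: total OMP count, the OmpF
#' fraction that defines the scaffold, the guest species list, and the
#' lipid complement of the asymmetric bilayer.
#'
#' @param total_omps Total number of OMP instances. Default 218.
#' @param ompf_fraction Fraction of OMPs that are OmpF trimers; the scaffold
#'   site count must equal `round(ompf_fraction * total_omps)`. Default 0.47.
#' @param guest_species Character vector of guest species names, in
#'   round-robin assignment order. Defaults to the six non-porin species.
#' @param lps_total Number of outer-leaflet RaLPS molecules. Default 8093.
#' @param pl_total Number of inner-leaflet phospholipids. Default 25099.
#' @param pl_fractions Named fractions of POPE/POPG/CL; must sum to 1.
#' @param omp_species OMP species table (see [default_omp_species()]).
#' @param lipid_species Lipid species table (see [default_lipid_species()]).
#' @return object of class `composition_spec`.
#' @export
composition_spec <- function(total_omps = 218L, ompf_fraction = 0.47,
                             guest_species = c("BtuB", "FhuE", "FhuA", "FepA",
                                               "BamA-complex", "LptD-complex"),
                             lps_total = 8093L, pl_total = 25099L,
                             pl_fractions = c(POPE = 0.90, POPG = 0.05, CL = 0.05),
                             omp_species = default_omp_species(),
                             lipid_species = default_lipid_species()) {
  cs <- structure(list(total_omps = as.integer(total_omps),
                       ompf_fraction = as.numeric(ompf_fraction),
                       guest_species = as.character(guest_species),
                       lps_total = as.integer(lps_total),
                       pl_total = as.integer(pl_total),
                       pl_fractions = pl_fractions,
                       omp_species = omp_species,
                       lipid_species = lipid_species),
                  class = "composition_spec")
  validate_composition_spec(cs)
  cs
}

validate_composition_spec <- function(cs) {
  if (cs$total_omps < 1) stop("validation error: total_omps must be >= 1")
  if (!(cs$ompf_fraction > 0 && cs$ompf_fraction < 1))
    stop("validation error: ompf_fraction must lie strictly between 0 and 1")
  if (abs(sum(cs$pl_fractions) - 1) > 1e-8)
    stop("validation error: pl_fractions must sum to 1")
  if (any(cs$pl_fractions < 0))
    stop("validation error: pl_fractions must be non-negative")
  if (cs$lps_total < 0 || cs$pl_total < 0)
    stop("validation error: lipid totals must be non-negative")
  validate_omp_species(cs$omp_species)
  unknown <- setdiff(cs$guest_species, cs$omp_species$name)
  if (length(unknown))
    stop("validation error: guest species not in species table: ",
         paste(unknown, collapse = ", "))
  pl_names <- names(cs$pl_fractions)
  if (is.null(pl_names) || !all(pl_names %in% cs$lipid_species$name))
    stop("validation error: pl_fractions must be named with lipid species")
  invisible(cs)
}

#' Read a geometry + composition configuration from a YAML file
#'
#' The file may contain `geometry`, `composition` and `masses` sections; all
#' keys are optional and missing keys are filled with package defaults. An
#' empty file therefore yields the default island (218 OMPs, 47% OmpF,
#' 8093 LPS / 25099 PLs).
#'
#' @param path Path to a YAML configuration file.
#' @return list with elements `geometry` ([geometry_config()]),
#'   `composition` ([composition_spec()]) and `masses`
#'   ([default_mass_table()], with any overridden species masses applied).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration error: file not found: ", path)
  raw <- tryCatch(yaml::read_yaml(path),
                  error = function(e)
                    stop("configuration error: cannot parse ", path, ": ",
                         conditionMessage(e)))
  if (is.null(raw)) raw <- list()
  if (!is.list(raw))
    stop("configuration error: top level must be a mapping")
  known_sections <- c("geometry", "composition", "masses")
  bad <- setdiff(names(raw), known_sections)
  if (length(bad))
    stop("configuration error: unknown section '", bad[1], "'")

  take <- function(section, allowed) {
    sec <- raw[[section]]
    if (is.null(sec)) return(list())
    if (!is.list(sec))
      stop("configuration error: section '", section, "' must be a mapping")
    bad <- setdiff(names(sec), allowed)
    if (length(bad))
      stop("configuration error: unknown key '", bad[1], "' in [", section, "]")
    sec
  }

  gsec <- take("geometry", c("patch_size", "lattice_spacing", "jitter_sd",
                             "n_hexagons", "layout", "seed"))
  geometry <- do.call(geometry_config, gsec)

  csec <- take("composition", c("total_omps", "ompf_fraction", "guest_species",
                                "lps_total", "pl_total", "pl_fractions"))
  if (!is.null(csec$pl_fractions)) csec$pl_fractions <- unlist(csec$pl_fractions)
  composition <- do.call(composition_spec, csec)

  masses <- default_mass_table()
  msec <- take("masses", c(masses$omp$name, masses$lipid$name, "Ca"))
  for (nm in names(msec)) {
    v <- as.numeric(msec[[nm]])
    if (!is.finite(v) || v <= 0)
      stop("validation error: mass for '", nm, "' must be > 0")
    if (nm == "Ca") masses$ca_mass_kda <- v
    else if (nm %in% masses$omp$name) masses$omp$mass_kda[masses$omp$name == nm] <- v
    else masses$lipid$mass_kda[masses$lipid$name == nm] <- v
  }
  list(geometry = geometry, composition = composition, masses = masses)
}

#' Write a configuration back to YAML
#'
#' Round-trips losslessly through [load_config()].
#'
#' @param geometry A [geometry_config()].
#' @param composition A [composition_spec()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(geometry, composition, path) {
  out <- list(
    geometry = list(patch_size = geometry$patch_size,
                    lattice_spacing = geometry$lattice_spacing,
                    jitter_sd = geometry$jitter_sd,
                    n_hexagons = geometry$n_hexagons,
                    layout = geometry$layout,
                    seed = geometry$seed),
    composition = list(total_omps = composition$total_omps,
                       ompf_fraction = composition$ompf_fraction,
                       guest_species = composition$guest_species,
                       lps_total = composition$lps_total,
                       pl_total = composition$pl_total,
                       pl_fractions = as.list(composition$pl_fractions))
  )
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @export
print.geometry_config <- function(x, ...) {
  cat("Island geometry: ", x$patch_size, " x ", x$patch_size, " nm patch, ",
      "spacing ", x$lattice_spacing, " nm (", x$lattice_spacing * 10,
      " A), layout '", x$layout, "', jitter sd ", x$jitter_sd,
      " nm, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' @export
print.composition_spec <- function(x, ...) {
  n_scaffold <- round(x$ompf_fraction * x$total_omps)
  cat("Island composition: ", x$total_omps, " OMPs (", n_scaffold,
      " OmpF trimers, ", x$total_omps - n_scaffold, " guests over ",
      length(x$guest_species), " species); ", x$lps_total, " LPS + ",
      x$pl_total, " PL (", paste(sprintf("%s %.0f%%", names(x$pl_fractions),
                                         100 * x$pl_fractions),
                                 collapse = ", "), ")\n", sep = "")
  invisible(x)
}
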