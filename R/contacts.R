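# First-shell membership, OMP-LPS-OMP bridge counting and whole-cell
# extrapolation, plus near-neighbour distance statistics.

#' Recompute first-shell lipid membership from coordinates
#'
#' A lipid belongs to an OMP's first shell iff its centre lies within
#' `r_OMP + shell_margin` of the OMP centroid. The default margin is one LPS
#' footprint diameter (one lipid ring). Membership is recomputed from
#' coordinates, independent of the `shell_of` tags stored at construction.
#'
#' @param model A lipidised `island_model`.
#' @param shell_margin Margin in nm added to each OMP footprint radius;
#'   default the RaLPS footprint diameter.
#' @return object of class `contact_map`: a long data.frame
#'   (`lipid_id`, `omp_id`) plus lipid species/leaflet lookup.
#' @export
first_shell_assignment <- function(model, shell_margin = NULL) {
  if (is.null(model$lipids)) stop("domain error: model has no lipids")
  if (is.null(shell_margin))
    shell_margin <- lps_diameter(model$composition$lipid_species)
  sp <- model$composition$omp_species
  radius <- sp$effective_radius[match(model$omps$species, sp$name)]
  lx <- model$lipids$x; ly <- model$lipids$y
  hits <- vector("list", nrow(model$omps))
  for (j in seq_len(nrow(model$omps))) {
    cut2 <- (radius[j] + shell_margin)^2
    sel <- which((lx - model$omps$x[j])^2 + (ly - model$omps$y[j])^2 <= cut2)
    if (length(sel))
      hits[[j]] <- data.frame(lipid_id = model$lipids$id[sel],
                              omp_id = model$omps$id[j],
                              stringsAsFactors = FALSE)
  }
  membership <- do.call(rbind, c(hits, list(
    data.frame(lipid_id = character(0), omp_id = character(0)))))
  structure(list(membership = membership,
                 lipid_species = stats::setNames(model$lipids$species,
                                                 model$lipids$id),
                 lipid_leaflet = stats::setNames(model$lipids$leaflet,
                                                 model$lipids$id),
                 shell_margin = shell_margin),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat("Contact map:", nrow(x$membership), "lipid-OMP first-shell memberships",
      sprintf("(margin %.3f nm)\n", x$shell_margin))
  invisible(x)
}

#' Count OMP-LPS-OMP bridges
#'
#' An outer-leaflet LPS whose centre lies in the first shells of two or more
#' distinct OMPs bridges those OMPs. Each bridged pair a lipid joins counts
#' once, so a lipid in three shells contributes three contacts.
#'
#' @param cm A `contact_map` from [first_shell_assignment()].
#' @param species_filter Lipid species allowed to bridge; default `"RaLPS"`.
#' @return Integer bridge (contact pair) count, with attribute
#'   `bridging_lipids` (number of distinct bridging lipids).
#' @export
count_bridges <- function(cm, species_filter = "RaLPS") {
  mm <- cm$membership
  keep <- cm$lipid_species[mm$lipid_id] %in% species_filter &
    cm$lipid_leaflet[mm$lipid_id] == "outer"
  mm <- mm[keep, , drop = FALSE]
  if (!nrow(mm)) {
    out <- 0L; attr(out, "bridging_lipids") <- 0L; return(out)
  }
  m <- table(mm$lipid_id)
  out <- as.integer(sum(choose(as.numeric(m), 2)))
  attr(out, "bridging_lipids") <- sum(m >= 2)
  out
}

#' Extrapolate a patch bridge count to the whole cell
#'
#' Scales a per-patch count by the fraction of outer-membrane surface area
#' the patch represents.
#'
#' @param bridge_count Bridges counted in the patch.
#' @param soi_area_fraction Fraction of the cell's OM area covered by the
#'   patch, in (0, 1]. The published figure for a 150 nm x 150 nm patch of a
#'   ~6 um^2 cell is 0.06% (0.0006); the geometric value is
#'   `patch_area / cell_area`.
#' @return Extrapolated whole-cell count.
#' @export
extrapolate_cell <- function(bridge_count, soi_area_fraction = 0.0006) {
  if (!is.finite(soi_area_fraction) || soi_area_fraction <= 0 ||
      soi_area_fraction > 1)
    stop("domain error: soi_area_fraction must lie in (0, 1]")
  as.numeric(bridge_count) / soi_area_fraction
}

#' Near-neighbour distance distribution of a point pattern
#'
#' For each point, the distances to its `k` nearest neighbours, histogrammed
#' over the given bin edges.
#'
#' @param points n x 2 matrix of coordinates.
#' @param k Number of nearest neighbours per point.
#' @param bins Numeric vector of bin edges (nm); distances beyond the last
#'   edge fall into the last bin. Default `seq(0, 30, by = 1)`.
#' @return object of class `distance_distribution`: `bin_edges`, `counts`,
#'   `n_points` and the raw `distances`.
#' @export
neighbor_distance_distribution <- function(points, k = 1,
                                           bins = seq(0, 30, by = 1)) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < k + 1)
    stop("domain error: need at least k + 1 = ", k + 1, " points")
  D <- as.matrix(stats::dist(points))
  diag(D) <- Inf
  dd <- apply(D, 1, function(row) sort(row, partial = k)[seq_len(k)])
  dd <- as.numeric(dd)
  if (length(bins) < 2) stop("domain error: need at least 2 bin edges")
  clipped <- pmin(pmax(dd, bins[1]), bins[length(bins)])
  counts <- graphics::hist(clipped, breaks = bins, plot = FALSE)$counts
  structure(list(bin_edges = bins, counts = counts, n_points = n,
                 distances = dd),
            class = "distance_distribution")
}

#' Kolmogorov-Smirnov distance between two binned distributions
#'
#' Maximum absolute difference between the normalised cumulative histograms;
#' 0 for identical distributions, 1 for disjoint supports.
#'
#' @param d1,d2 `distance_distribution` objects on identical bin edges.
#' @return KS statistic in \[0, 1\].
#' @export
compare_distributions <- function(d1, d2) {
  if (length(d1$bin_edges) != length(d2$bin_edges) ||
      any(abs(d1$bin_edges - d2$bin_edges) > 1e-9))
    stop("domain error: distributions must share bin edges")
  if (sum(d1$counts) == 0 || sum(d2$counts) == 0)
    stop("domain error: empty distribution")
  c1 <- cumsum(d1$counts) / sum(d1$counts)
  c2 <- cumsum(d2$counts) / sum(d2$counts)
  max(abs(c1 - c2))
}

#' Export a distance distribution as CSV
#'
#' @param d A `distance_distribution`.
#' @param path Output path; columns `bin_left`, `bin_right`, `count`.
#' @return `path`, invisibly.
#' @export
export_distribution_csv <- function(d, path) {
  nb <- length(d$bin_edges) - 1
  utils::write.csv(data.frame(bin_left = d$bin_edges[seq_len(nb)],
                              bin_right = d$bin_edges[-1],
                              count = d$counts),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
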