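# Scaffold lattice construction.
#
# The scaffold is kagome-type: OmpF trimer centroids sit on the edge
# midpoints of a triangular lattice, so corner-sharing triangles enclose
# hexagonal rings whose centres can host guest OMPs. The packaged reference
# layout fixes 102 scaffold sites forming 18 complete hexagons; every
# nearest-neighbour centroid distance equals the lattice spacing.

# Frozen reference layout: 44 triangular-lattice vertices (axial coordinates,
# edge length = 2 * lattice_spacing) and the 102 vertex pairs whose edge
# midpoints are the scaffold sites. `hexctr` lists the 18 vertices whose six
# incident edges are all present (complete hexagon rings).
.reference_layout_raw <- function() {
  verts <- matrix(c(
    -3L,0L,-3L,1L,-3L,2L,-3L,3L,-2L,-1L,-2L,0L,-2L,1L,-2L,2L,-2L,3L,-1L,-2L,
    -1L,-1L,-1L,0L,-1L,1L,-1L,2L,-1L,3L,0L,-3L,0L,-2L,0L,-1L,0L,0L,0L,1L,
    0L,2L,0L,3L,1L,-3L,1L,-2L,1L,-1L,1L,0L,1L,1L,1L,2L,2L,-3L,2L,-2L,
    2L,-1L,2L,0L,2L,1L,3L,-3L,3L,-2L,3L,-1L,-2L,4L,2L,-4L,-4L,2L,-2L,-2L,
    2L,2L,4L,-2L,3L,1L,4L,-1L), ncol = 2, byrow = TRUE)
  edges <- matrix(c(
    1L,6L,1L,5L,2L,7L,2L,3L,2L,6L,2L,39L,3L,8L,3L,39L,3L,4L,3L,7L,4L,9L,
    4L,8L,5L,11L,5L,6L,5L,40L,5L,10L,6L,12L,6L,7L,6L,11L,7L,13L,7L,8L,
    7L,12L,8L,14L,8L,9L,8L,13L,9L,15L,9L,37L,9L,14L,10L,17L,10L,40L,10L,11L,
    10L,16L,11L,18L,11L,12L,11L,17L,12L,19L,12L,13L,12L,18L,13L,20L,13L,14L,
    13L,19L,14L,21L,14L,15L,14L,20L,15L,22L,15L,21L,15L,37L,16L,23L,16L,17L,
    17L,24L,17L,18L,17L,23L,18L,25L,18L,19L,18L,24L,19L,26L,19L,20L,19L,25L,
    20L,27L,20L,21L,20L,26L,21L,28L,21L,22L,21L,27L,22L,28L,23L,29L,23L,24L,
    23L,38L,24L,30L,24L,25L,24L,29L,25L,31L,25L,26L,25L,30L,26L,32L,26L,27L,
    26L,31L,27L,33L,27L,28L,27L,32L,28L,41L,28L,33L,29L,34L,29L,30L,29L,38L,
    30L,35L,30L,31L,30L,34L,31L,36L,31L,32L,31L,35L,32L,33L,32L,36L,33L,43L,
    33L,41L,34L,35L,35L,42L,35L,36L,36L,44L,36L,42L,41L,43L,42L,44L),
    ncol = 2, byrow = TRUE)
  hexctr <- c(6L, 7L, 8L, 11L, 12L, 13L, 14L, 17L, 18L, 19L, 20L, 21L,
              24L, 25L, 26L, 27L, 30L, 31L)
  list(verts = verts, edges = edges, hexctr = hexctr)
}

.ax2xy <- function(qr, edge_len) {
  cbind(edge_len * (qr[, 1] + qr[, 2] / 2),
        edge_len * (sqrt(3) / 2) * qr[, 2])
}

# faces (triples of mutually adjacent vertices) of a vertex/edge graph
.faces_of <- function(n_vert, edges) {
  adj <- matrix(FALSE, n_vert, n_vert)
  adj[edges] <- TRUE
  adj <- adj | t(adj)
  out <- list()
  for (i in seq_len(n_vert - 2)) {
    ni <- which(adj[i, ] & seq_len(n_vert) > i)
    if (length(ni) < 2) next
    for (a in seq_along(ni)[-length(ni)]) for (b in (a + 1):length(ni)) {
      j <- ni[a]; k <- ni[b]
      if (adj[j, k]) out[[length(out) + 1L]] <- c(i, j, k)
    }
  }
  if (!length(out)) return(matrix(integer(0), ncol = 3))
  do.call(rbind, out)
}

#' Build the porin scaffold lattice
#'
#' Generates the OmpF-trimer scaffold: either the packaged reference layout
#' (102 sites, 18 hexagons), scaled to the configured lattice spacing and
#' centred in the patch, or a generated kagome patch with `n_hexagons`
#' hexagon rings. Optional seeded Gaussian jitter models the "imperfect"
#' arrays seen on live cells.
#'
#' @param geometry A [geometry_config()].
#' @return object of class `island_layout`: scaffold site coordinates (nm),
#'   hexagon rings and triangle triples as site-index sets, hexagon centre
#'   coordinates, and candidate guest slots (hexagon centres first, then
#'   interstitial positions at least 8 nm from every scaffold site).
#' @export
build_scaffold <- function(geometry = geometry_config()) {
  validate_geometry_config(geometry)
  a <- geometry$lattice_spacing
  edge_len <- 2 * a

  if (geometry$layout == "reference") {
    raw <- .reference_layout_raw()
    vxy <- .ax2xy(raw$verts, edge_len)
    sites <- (vxy[raw$edges[, 1], ] + vxy[raw$edges[, 2], ]) / 2
    centers <- vxy[raw$hexctr, , drop = FALSE]
    hexagons <- lapply(raw$hexctr, function(v)
      which(raw$edges[, 1] == v | raw$edges[, 2] == v))
    faces <- .faces_of(nrow(raw$verts), raw$edges)
    ekey <- paste(raw$edges[, 1], raw$edges[, 2])
    eidx <- function(i, j) match(paste(pmin(i, j), pmax(i, j)), ekey)
    triangles <- cbind(eidx(faces[, 1], faces[, 2]),
                       eidx(faces[, 1], faces[, 3]),
                       eidx(faces[, 2], faces[, 3]))
    triangles <- triangles[stats::complete.cases(triangles), , drop = FALSE]
  } else {
    # kagome-patch: spiral of hexagon-centre vertices on a triangular
    # lattice; sites are the midpoints of each centre's six incident edges
    n <- geometry$n_hexagons
    ctr_ax <- .hex_spiral(n)
    vxy <- .ax2xy(ctr_ax, edge_len)
    dirs <- cbind(cos(pi / 3 * (0:5)), sin(pi / 3 * (0:5)))
    all_mid <- do.call(rbind, lapply(seq_len(n), function(i)
      sweep(a * dirs, 2, vxy[i, ], "+")))
    key <- paste(round(all_mid[, 1], 6), round(all_mid[, 2], 6))
    keep <- !duplicated(key)
    sites <- all_mid[keep, , drop = FALSE]
    site_id <- match(key, key[keep])
    hexagons <- lapply(seq_len(n), function(i) site_id[(i - 1) * 6 + 1:6])
    centers <- vxy
    # faces around chosen centres whose three edge midpoints are all present
    ctr_key <- paste(ctr_ax[, 1], ctr_ax[, 2])
    nbr <- rbind(c(1, 0), c(0, 1), c(-1, 1), c(-1, 0), c(0, -1), c(1, -1))
    tri <- list()
    mid_key <- function(p1, p2) {
      m <- (p1 + p2) / 2
      paste(round(m[1], 6), round(m[2], 6))
    }
    site_key <- paste(round(sites[, 1], 6), round(sites[, 2], 6))
    for (i in seq_len(n)) for (k in 1:6) {
      v1 <- ctr_ax[i, ]; v2 <- v1 + nbr[k, ]; v3 <- v1 + nbr[if (k == 6) 1 else k + 1, ]
      p1 <- .ax2xy(rbind(v1), edge_len)[1, ]
      p2 <- .ax2xy(rbind(v2), edge_len)[1, ]
      p3 <- .ax2xy(rbind(v3), edge_len)[1, ]
      s3 <- match(c(mid_key(p1, p2), mid_key(p1, p3), mid_key(p2, p3)), site_key)
      if (!anyNA(s3)) tri[[length(tri) + 1L]] <- sort(s3)
    }
    triangles <- unique(do.call(rbind, c(tri, list(matrix(integer(0), ncol = 3)))))
  }

  # centre in the patch, leaving room for the OmpF footprint + one LPS ring
  margin <- 3.5 + lps_diameter()
  shift <- geometry$patch_size / 2 -
    c(mean(range(sites[, 1])), mean(range(sites[, 2])))
  sites <- sweep(sites, 2, shift, "+")
  centers <- sweep(centers, 2, shift, "+")
  if (any(sites < margin) || any(sites > geometry$patch_size - margin))
    stop("construction error: patch too small for ", geometry$n_hexagons,
         " hexagons at spacing ", a, " nm (need ",
         ceiling(diff(range(sites)) + 2 * margin), " nm)")

  if (geometry$jitter_sd > 0) {
    os <- .with_seed(derive_seed(geometry$seed, "jitter"), {
      sites + matrix(stats::rnorm(length(sites), 0, geometry$jitter_sd),
                     ncol = 2)
    })
    sites <- pmin(pmax(os, margin), geometry$patch_size - margin)
  }

  layout <- structure(list(
    scaffold_sites = sites,
    hexagons = hexagons,
    triangles = triangles,
    hexagon_centers = centers,
    guest_slots = NULL,
    spacing = a,
    patch_size = geometry$patch_size,
    geometry = geometry
  ), class = "island_layout")
  layout$guest_slots <- .guest_slots(layout)
  layout
}

# axial coordinates of n triangular-lattice vertices in spiral order
.hex_spiral <- function(n) {
  out <- matrix(c(0L, 0L), ncol = 2)
  ring <- 1L
  dirs <- rbind(c(-1, 1), c(-1, 0), c(0, -1), c(1, -1), c(1, 0), c(0, 1))
  while (nrow(out) < n) {
    p <- c(ring, 0L)
    for (d in seq_len(6)) for (s in seq_len(ring)) {
      out <- rbind(out, p)
      p <- p + dirs[d, ]
    }
    ring <- ring + 1L
  }
  out[seq_len(n), , drop = FALSE]
}

# candidate guest positions: hexagon centres first (centre-to-vertex distance
# equals the lattice spacing, automatically in bounds), then a hexagonal grid
# of interstitial positions >= 8 nm from every scaffold site and centre
.guest_slots <- function(layout, min_sep = 8.0, grid_spacing = 8.2) {
  margin <- 3.0 + lps_diameter()  # largest guest footprint + one LPS ring
  ps <- layout$patch_size
  gx <- seq(margin, ps - margin, by = grid_spacing)
  gy <- seq(margin, ps - margin, by = grid_spacing * sqrt(3) / 2)
  cand <- do.call(rbind, lapply(seq_along(gy), function(i) {
    xs <- gx + (i %% 2) * grid_spacing / 2
    cbind(xs[xs <= ps - margin], gy[i])
  }))
  obstacles <- rbind(layout$scaffold_sites, layout$hexagon_centers)
  ok <- vapply(seq_len(nrow(cand)), function(i) {
    d2 <- (obstacles[, 1] - cand[i, 1])^2 + (obstacles[, 2] - cand[i, 2])^2
    all(d2 >= min_sep^2)
  }, logical(1))
  slots <- rbind(layout$hexagon_centers, cand[ok, , drop = FALSE])
  attr(slots, "type") <- c(rep("hexagon-center", nrow(layout$hexagon_centers)),
                           rep("interstitial", sum(ok)))
  slots
}

#' Place guest OMPs on the scaffold
#'
#' Distributes `total_omps - n_scaffold` guest OMPs over the guest species in
#' round-robin order (so per-species counts differ by at most one), occupying
#' hexagon centres first and then a seeded selection of interstitial slots.
#' All centroid pairs keep at least 8 nm separation.
#'
#' @param layout An `island_layout` from [build_scaffold()].
#' @param composition A [composition_spec()].
#' @param seed Integer seed for interstitial slot selection.
#' @return object of class `island_model` with OMP placements (no lipids).
#' @export
place_guests <- function(layout, composition = composition_spec(), seed = 1L) {
  validate_composition_spec(composition)
  n_scaffold <- nrow(layout$scaffold_sites)
  expect_scaffold <- round(composition$ompf_fraction * composition$total_omps)
  if (expect_scaffold != n_scaffold)
    stop("composition error: round(ompf_fraction * total_omps) = ",
         expect_scaffold, " but the scaffold has ", n_scaffold, " sites")
  n_guest <- composition$total_omps - n_scaffold

  slots <- layout$guest_slots
  type <- attr(slots, "type")
  # honour the minimum spacing against (possibly jittered) scaffold sites
  ok <- vapply(seq_len(nrow(slots)), function(i) {
    d2 <- (layout$scaffold_sites[, 1] - slots[i, 1])^2 +
      (layout$scaffold_sites[, 2] - slots[i, 2])^2
    all(d2 >= 8.0^2 - 1e-9)
  }, logical(1))
  slots <- slots[ok, , drop = FALSE]; type <- type[ok]

  ctr <- which(type == "hexagon-center")
  inter <- which(type == "interstitial")
  inter <- .with_seed(derive_seed(seed, "guest-slots"), sample(inter))
  order_all <- c(ctr, inter)
  if (n_guest > length(order_all))
    stop("capacity error: ", n_guest, " guests requested but only ",
         length(order_all), " slots available (shortfall ",
         n_guest - length(order_all), ")")
  chosen <- slots[order_all[seq_len(n_guest)], , drop = FALSE]

  k <- length(composition$guest_species)
  guest_sp <- if (n_guest > 0 && k > 0)
    composition$guest_species[((seq_len(n_guest) - 1) %% k) + 1]
  else character(0)
  if (n_guest > 0 && k == 0)
    stop("capacity error: guests requested but guest_species is empty")

  omps <- data.frame(
    id = sprintf("omp%03d", seq_len(n_scaffold + n_guest)),
    species = c(rep("OmpF-trimer", n_scaffold), guest_sp),
    x = c(layout$scaffold_sites[, 1], chosen[, 1]),
    y = c(layout$scaffold_sites[, 2], chosen[, 2]),
    role = c(rep("scaffold", n_scaffold), rep("guest", n_guest)),
    stringsAsFactors = FALSE
  )
  model <- structure(list(geometry = layout$geometry,
                          composition = composition,
                          layout = layout, omps = omps, lipids = NULL),
                     class = "island_model")
  .validate_island_model(model)
  model
}

.validate_island_model <- function(model) {
  ps <- model$geometry$patch_size
  if (any(model$omps$x < 0 | model$omps$x > ps |
          model$omps$y < 0 | model$omps$y > ps))
    stop("validation error: OMP coordinates outside patch")
  if (!is.null(model$lipids)) {
    if (any(model$lipids$x < 0 | model$lipids$x > ps |
            model$lipids$y < 0 | model$lipids$y > ps))
      stop("validation error: lipid coordinates outside patch")
    if (anyDuplicated(model$lipids$id))
      stop("validation error: lipid ids not unique")
  }
  invisible(model)
}

#' Check lattice geometry against the porin-array constraints
#'
#' Computes per-site nearest-neighbour centroid distances over the scaffold
#' and internal angles over all triangle triples, and reports values outside
#' the configured bounds (defaults: 8--9 nm distances, 57--63 degree angles).
#'
#' @param model An `island_model` or `island_layout`.
#' @param nn_bounds Length-2 numeric, allowed nearest-neighbour range in nm.
#' @param angle_bounds Length-2 numeric, allowed internal angle range in
#'   degrees.
#' @return object of class `constraint_report` with fields
#'   `min_nn_distance`, `max_nn_distance` (nm), `min_angle`, `max_angle`
#'   (degrees) and a `violations` data.frame.
#' @export
validate_geometry <- function(model, nn_bounds = c(8, 9),
                              angle_bounds = c(57, 63)) {
  layout <- if (inherits(model, "island_layout")) model else model$layout
  sites <- layout$scaffold_sites
  if (nrow(sites) < 2) stop("domain error: need at least 2 scaffold sites")
  D <- as.matrix(stats::dist(sites))
  diag(D) <- Inf
  nn <- apply(D, 1, min)

  tri <- layout$triangles
  angles <- numeric(0)
  tri_idx <- integer(0)
  if (!is.null(tri) && nrow(tri) > 0) {
    for (t in seq_len(nrow(tri))) {
      p <- sites[tri[t, ], , drop = FALSE]
      for (v in 1:3) {
        e1 <- p[setdiff(1:3, v)[1], ] - p[v, ]
        e2 <- p[setdiff(1:3, v)[2], ] - p[v, ]
        cosang <- sum(e1 * e2) / sqrt(sum(e1^2) * sum(e2^2))
        angles <- c(angles, acos(pmin(pmax(cosang, -1), 1)) * 180 / pi)
        tri_idx <- c(tri_idx, t)
      }
    }
  }

  viol <- data.frame(kind = character(0), index = integer(0),
                     value = numeric(0))
  bad_nn <- which(nn < nn_bounds[1] - 1e-9 | nn > nn_bounds[2] + 1e-9)
  if (length(bad_nn))
    viol <- rbind(viol, data.frame(kind = "nn_distance", index = bad_nn,
                                   value = nn[bad_nn]))
  bad_a <- which(angles < angle_bounds[1] - 1e-9 |
                 angles > angle_bounds[2] + 1e-9)
  if (length(bad_a))
    viol <- rbind(viol, data.frame(kind = "angle", index = tri_idx[bad_a],
                                   value = angles[bad_a]))

  structure(list(min_nn_distance = min(nn), max_nn_distance = max(nn),
                 min_angle = if (length(angles)) min(angles) else NA_real_,
                 max_angle = if (length(angles)) max(angles) else NA_real_,
                 nn_distances = nn, angles = angles,
                 nn_bounds = nn_bounds, angle_bounds = angle_bounds,
                 violations = viol),
            class = "constraint_report")
}

#' @export
print.constraint_report <- function(x, ...) {
  cat("Lattice constraint report\n")
  cat(sprintf("  nearest-neighbour distance: %.3f - %.3f nm (%.1f - %.1f A)\n",
              x$min_nn_distance, x$max_nn_distance,
              10 * x$min_nn_distance, 10 * x$max_nn_distance))
  if (!is.na(x$min_angle))
    cat(sprintf("  triangle internal angles:   %.2f - %.2f deg\n",
                x$min_angle, x$max_angle))
  cat("  violations:", nrow(x$violations), "\n")
  invisible(x)
}

#' @export
print.island_layout <- function(x, ...) {
  cat("Island layout: ", nrow(x$scaffold_sites), " scaffold sites, ",
      length(x$hexagons), " hexagons, ", nrow(x$triangles), " triangles, ",
      "spacing ", x$spacing, " nm\n", sep = "")
  invisible(x)
}

#' @export
print.island_model <- function(x, ...) {
  cat("OMP island model: ", nrow(x$omps), " OMPs (",
      sum(x$omps$role == "scaffold"), " scaffold + ",
      sum(x$omps$role == "guest"), " guests)", sep = "")
  if (!is.null(x$lipids)) {
    cat("; ", sum(x$lipids$species == "RaLPS"), " LPS + ",
        sum(x$lipids$species != "RaLPS"), " PL", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Export an island model to CSV
#'
#' Writes one row per placed molecule: `id, species, leaflet, x_nm, y_nm,
#' shell_of` (semicolon-joined owner OMP ids for shell lipids). OMPs carry
#' leaflet `"membrane"` and empty `shell_of`.
#'
#' @param model An `island_model`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_model_csv <- function(model, path) {
  omp <- data.frame(id = model$omps$id, species = model$omps$species,
                    leaflet = "membrane", x_nm = model$omps$x,
                    y_nm = model$omps$y, shell_of = "",
                    stringsAsFactors = FALSE)
  out <- omp
  if (!is.null(model$lipids)) {
    lip <- data.frame(id = model$lipids$id, species = model$lipids$species,
                      leaflet = model$lipids$leaflet, x_nm = model$lipids$x,
                      y_nm = model$lipids$y, shell_of = model$lipids$shell_of,
                      stringsAsFactors = FALSE)
    out <- rbind(out, lip)
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export an island model as a bead PDB for visualisation
#'
#' One CA-named bead per OMP centroid and one per lipid, in nm-to-Angstrom
#' scaled coordinates, chain A for proteins and chain L for lipids.
#'
#' @param model An `island_model`.
#' @param path Output PDB path.
#' @return `path`, invisibly.
#' @export
export_model_pdb <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- function(serial, resn, chain, resi, x, y, z)
    sprintf("ATOM  %5d  CA  %-3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
            serial, substr(resn, 1, 3), chain, resi, x, y, z)
  serial <- 1L
  for (i in seq_len(nrow(model$omps))) {
    writeLines(fmt(serial, toupper(gsub("[^A-Za-z]", "", model$omps$species[i])),
                   "A", i %% 10000, 10 * model$omps$x[i], 10 * model$omps$y[i],
                   0), con)
    serial <- serial + 1L
  }
  if (!is.null(model$lipids)) {
    for (i in seq_len(nrow(model$lipids))) {
      z <- if (model$lipids$leaflet[i] == "outer") 20 else -20
      writeLines(fmt(serial, model$lipids$species[i], "L", i %% 10000,
                     10 * model$lipids$x[i], 10 * model$lipids$y[i], z), con)
      serial <- serial + 1L
    }
  }
  writeLines("END", con)
  invisible(path)
}
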