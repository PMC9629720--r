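# Shared fixtures, built in code.

# assemble an island_model directly from placement tables (bypasses the
# builders, for targeted geometry)
manual_model <- function(omps, lipids = NULL, patch_size = 150,
                         composition = composition_spec()) {
  geometry <- geometry_config(patch_size = patch_size)
  structure(list(geometry = geometry, composition = composition,
                 layout = NULL, omps = omps, lipids = lipids),
            class = "island_model")
}

omp_df <- function(species, x, y, role = "scaffold") {
  data.frame(id = sprintf("omp%03d", seq_along(x)),
             species = as.character(species), x = x, y = y,
             role = rep(role, length.out = length(x)),
             stringsAsFactors = FALSE)
}

lipid_df <- function(species, x, y, leaflet = "outer") {
  data.frame(id = sprintf("lip%05d", seq_along(x)), species = species,
             leaflet = leaflet, x = x, y = y, shell_of = "",
             stringsAsFactors = FALSE)
}

# two OmpF trimers one lattice spacing apart, lipids on a listed grid
two_trimer_model <- function(grid_n = 40) {
  omps <- omp_df(c("OmpF-trimer", "OmpF-trimer"), c(70, 78.5), c(75, 75))
  g <- expand.grid(x = seq(62, 86, length.out = ceiling(sqrt(grid_n))),
                   y = seq(67, 83, length.out = ceiling(sqrt(grid_n))))
  g <- g[seq_len(grid_n), ]
  manual_model(omps, lipid_df(rep("RaLPS", grid_n), g$x, g$y))
}

# n1 x n2 triangular lattice, spacing a; box-commensurate when wrapped
triangular_points <- function(n1 = 10, n2 = 10, a = 8.5) {
  pts <- do.call(rbind, lapply(seq_len(n2) - 1, function(r)
    cbind(a * (seq_len(n1) - 1) + (r %% 2) * a / 2, a * sqrt(3) / 2 * r)))
  pts
}

# small lipidised kagome island for dynamics tests
small_island <- function(seed = 1, lps = 1200, pl = 1500) {
  g <- geometry_config(patch_size = 80, layout = "kagome-patch",
                       n_hexagons = 7)
  lay <- build_scaffold(g)
  comp <- composition_spec(total_omps = round(nrow(lay$scaffold_sites) / 0.47),
                           lps_total = lps, pl_total = pl)
  populate_lipids(place_guests(lay, comp, seed = seed), seed = seed)
}

# brute-force first-shell membership: plain double loop over all pairs
brute_membership <- function(model, shell_margin = 1.43) {
  sp <- model$composition$omp_species
  out <- list()
  for (i in seq_len(nrow(model$lipids))) {
    for (j in seq_len(nrow(model$omps))) {
      r <- sp$effective_radius[sp$name == model$omps$species[j]]
      d <- sqrt((model$lipids$x[i] - model$omps$x[j])^2 +
                  (model$lipids$y[i] - model$omps$y[j])^2)
      if (d <= r + shell_margin)
        out[[length(out) + 1]] <- data.frame(
          lipid_id = model$lipids$id[i], omp_id = model$omps$id[j],
          stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(out, list(data.frame(lipid_id = character(0),
                                        omp_id = character(0)))))
}

# brute-force bridge count from a membership table
brute_bridges <- function(membership, model) {
  lps <- model$lipids$id[model$lipids$species == "RaLPS" &
                           model$lipids$leaflet == "outer"]
  mm <- membership[membership$lipid_id %in% lps, ]
  sum(vapply(split(mm$omp_id, mm$lipid_id),
             function(o) choose(length(unique(o)), 2), numeric(1)))
}

# independent dual-cutoff oracle: explicit per-frame state carried forward
oracle_intervals <- function(d, on = 0.475, off = 0.8) {
  state <- logical(length(d))
  s <- FALSE
  for (t in seq_along(d)) {
    if (d[t] < on) s <- TRUE else if (d[t] > off) s <- FALSE
    state[t] <- s
  }
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  m <- cbind(start = starts[r$values] - 1L, end = ends[r$values])
  # an open final contact runs to the end of the series, as [start, n)
  m
}

# minimal trajectory object for statistics tests
manual_traj <- function(pos, species, is_omp, radius, box = 150,
                        timestep = 1) {
  structure(list(pos = pos, ids = paste0("p", seq_along(species)),
                 species = species, is_omp = is_omp, radius = radius,
                 tethered = rep(FALSE, length(species)), box = box,
                 timestep = timestep, mode = "asymmetric", seed = 1L),
            class = "membrane_trajectory")
}

# brute-force topographic prominence oracle for unique-valued images:
# for each local maximum, descend a threshold until the connected region
# (8-connectivity) that contains it touches a strictly higher pixel; the
# prominence is peak minus that saddle level (or peak minus the image
# minimum for the global maximum).
oracle_prominence <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  is_max <- matrix(TRUE, nr, nc)
  for (dy in -1:1) for (dx in -1:1) {
    if (dx == 0 && dy == 0) next
    ys <- pmin(pmax(seq_len(nr) + dy, 1), nr)
    xs <- pmin(pmax(seq_len(nc) + dx, 1), nc)
    nbr <- img[ys, xs]
    same <- outer(ys == seq_len(nr), xs == seq_len(nc), "&")
    is_max <- is_max & (img >= nbr | same)
  }
  maxima <- which(is_max, arr.ind = TRUE)
  levels <- sort(unique(as.numeric(img)))  # ascending
  # flood fill of {img >= L} from a seed; returns TRUE if the component
  # contains a pixel strictly higher than v
  touches_higher <- function(seed, L, v) {
    lab <- matrix(FALSE, nr, nc)
    frontier <- matrix(seed, ncol = 2)
    lab[seed[1], seed[2]] <- TRUE
    while (nrow(frontier)) {
      nxt <- NULL
      for (dy in -1:1) for (dx in -1:1) {
        if (dx == 0 && dy == 0) next
        y <- frontier[, 1] + dy; x <- frontier[, 2] + dx
        okk <- y >= 1 & y <= nr & x >= 1 & x <= nc
        y <- y[okk]; x <- x[okk]
        idx <- cbind(y, x)
        keep <- !lab[idx] & img[idx] >= L
        if (any(keep)) {
          idx <- idx[keep, , drop = FALSE]
          if (any(img[idx] > v)) return(TRUE)
          lab[idx] <- TRUE
          nxt <- rbind(nxt, idx)
        }
      }
      frontier <- if (is.null(nxt)) matrix(numeric(0), ncol = 2) else nxt
    }
    FALSE
  }
  out <- list()
  for (m in seq_len(nrow(maxima))) {
    seed <- maxima[m, ]
    v <- img[seed[1], seed[2]]
    cand <- levels[levels <= v]
    if (!touches_higher(seed, cand[1], v)) {
      prom <- v - min(img)  # global maximum
    } else {
      lo <- 1; hi <- length(cand)  # connected at lo, search highest L
      while (lo < hi) {
        mid <- ceiling((lo + hi) / 2)
        if (touches_higher(seed, cand[mid], v)) lo <- mid else hi <- mid - 1
      }
      prom <- v - cand[lo]
    }
    out[[m]] <- data.frame(x = seed[2], y = seed[1], value = v,
                           prominence = prom)
  }
  do.call(rbind, out)
}
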