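# Lipid population: annular LPS shells around each OMP, bulk outer-leaflet
# LPS, and the inner phospholipid leaflet, at exact target counts.

#' Closed-form annular shell count
#'
#' Number of LPS footprints that pack the first annular ring around a
#' membrane-protein footprint of the given radius:
#' `floor(2 * pi * (radius + diameter/2) / diameter)`, i.e. the number of
#' lipid discs whose centres fit on the circle touching the footprint.
#'
#' @param radius Protein footprint radius in nm (>= 0). Vectorised.
#' @param lps_diameter Lipid footprint diameter in nm (> 0).
#' @return Integer count(s).
#' @examples
#' annular_shell_count(3.5, 1.43)   # OmpF trimer: 18
#' annular_shell_count(2.25, 1.43)  # TBDT barrel: 13
#' @export
annular_shell_count <- function(radius, lps_diameter = 1.43) {
  if (any(lps_diameter <= 0)) stop("domain error: lps_diameter must be > 0")
  if (any(radius < 0)) stop("domain error: radius must be >= 0")
  as.integer(floor(2 * pi * (radius + lps_diameter / 2) / lps_diameter))
}

# greedy merge of points closer than `tol`; returns indices of kept points.
# Cell-hash neighbourhood search keeps this near-linear.
.dedup_points <- function(pts, tol) {
  n <- nrow(pts)
  if (n < 2) return(seq_len(n))
  cell <- floor(pts / tol)
  keykeep <- new.env(hash = TRUE, parent = emptyenv())
  keep <- logical(n)
  for (i in seq_len(n)) {
    cx <- cell[i, 1]; cy <- cell[i, 2]
    clash <- FALSE
    for (dx in -1:1) {
      for (dy in -1:1) {
        k <- paste(cx + dx, cy + dy)
        js <- keykeep[[k]]
        if (!is.null(js)) {
          d2 <- (pts[js, 1] - pts[i, 1])^2 + (pts[js, 2] - pts[i, 2])^2
          if (any(d2 < tol^2)) { clash <- TRUE; break }
        }
      }
      if (clash) break
    }
    if (!clash) {
      keep[i] <- TRUE
      k <- paste(cx, cy)
      keykeep[[k]] <- c(keykeep[[k]], i)
    }
  }
  which(keep)
}

# largest-remainder apportionment of n over fractions
.largest_remainder <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

# adaptive hexagonal fill: return at least n positions inside the patch with
# the given margin, none closer than `clearance(p)` to an obstacle
.adaptive_fill <- function(n, patch, margin, spacing0, min_spacing,
                           omps, block_radius) {
  if (n == 0) return(matrix(numeric(0), ncol = 2))
  s <- spacing0
  for (it in 1:60) {
    cand <- .hex_grid(margin, patch - margin, s)
    ok <- rep(TRUE, nrow(cand))
    for (j in seq_len(nrow(omps))) {
      ok <- ok & ((cand[, 1] - omps$x[j])^2 + (cand[, 2] - omps$y[j])^2 >=
                    block_radius[j]^2)
    }
    if (sum(ok) >= n) return(list(pos = cand[ok, , drop = FALSE], spacing = s))
    s <- s * 0.97
    if (s < min_spacing)
      stop("capacity error: cannot fit ", n,
           " lipids in the free leaflet area without overlap")
  }
  stop("capacity error: leaflet fill did not converge")
}

#' Populate an island model with lipids
#'
#' Places the asymmetric bilayer: each OMP receives its annular first shell
#' of RaLPS at equal angles on the circle of radius `r + d/2` (seeded ring
#' phase per OMP); ring positions of neighbouring OMPs closer than half a
#' lipid footprint are merged into a single shared lipid tagged with all
#' owners. Remaining LPS fill the outer-leaflet free area on a seeded
#' hexagonal grid, and the inner leaflet is filled with POPE/POPG/cardiolipin
#' at the configured fractions using largest-remainder rounding. Totals match
#' the composition exactly.
#'
#' @param model An `island_model` with OMP placements.
#' @param composition A [composition_spec()]; defaults to the model's own.
#' @param seed Integer seed for ring phases, grid jitter and species
#'   assignment.
#' @return The lipidised `island_model`.
#' @export
populate_lipids <- function(model, composition = model$composition, seed = 1L) {
  validate_composition_spec(composition)
  omps <- model$omps
  sp <- composition$omp_species
  radius <- sp$effective_radius[match(omps$species, sp$name)]
  if (anyNA(radius)) stop("lookup error: OMP species missing from table")
  d <- lps_diameter(composition$lipid_species)
  ps <- model$geometry$patch_size

  # --- annular shells -------------------------------------------------
  ring_n <- annular_shell_count(radius, d)
  phases <- .with_seed(derive_seed(seed, "ring-phase"),
                       stats::runif(nrow(omps), 0, 2 * pi))
  ring_pos <- do.call(rbind, lapply(seq_len(nrow(omps)), function(i) {
    ang <- phases[i] + 2 * pi * (seq_len(ring_n[i]) - 1) / ring_n[i]
    rr <- radius[i] + d / 2
    cbind(omps$x[i] + rr * cos(ang), omps$y[i] + rr * sin(ang))
  }))
  ring_pos[, 1] <- pmin(pmax(ring_pos[, 1], d / 2), ps - d / 2)
  ring_pos[, 2] <- pmin(pmax(ring_pos[, 2], d / 2), ps - d / 2)
  keep <- .dedup_points(ring_pos, d / 2)
  shell <- ring_pos[keep, , drop = FALSE]
  n_shell <- nrow(shell)
  if (n_shell > composition$lps_total)
    stop("capacity error: shell demand ", n_shell, " exceeds lps_total ",
         composition$lps_total)

  # owners recorded by the same rule used for first-shell membership
  owners <- rep("", n_shell)
  for (j in seq_len(nrow(omps))) {
    hit <- (shell[, 1] - omps$x[j])^2 + (shell[, 2] - omps$y[j])^2 <=
      (radius[j] + d)^2 + 1e-12
    owners[hit] <- ifelse(owners[hit] == "", omps$id[j],
                          paste(owners[hit], omps$id[j], sep = ";"))
  }

  # --- bulk outer-leaflet LPS ------------------------------------------
  n_bulk <- composition$lps_total - n_shell
  # footprint + ring band blocked: radial clearance r + 1.5 d covers both
  free_area <- ps^2 - sum(pi * (radius + 1.5 * d)^2)
  bulk <- matrix(numeric(0), ncol = 2)
  if (n_bulk > 0) {
    s0 <- sqrt(2 * max(free_area, 1) / (sqrt(3) * n_bulk))
    fill <- .adaptive_fill(n_bulk, ps, d / 2, s0, d, omps, radius + 1.5 * d)
    jit_sd <- max(0, min(0.1, (fill$spacing - d) / 6))
    bulk <- .with_seed(derive_seed(seed, "bulk-lps"), {
      pos <- fill$pos[sample(nrow(fill$pos), n_bulk), , drop = FALSE]
      pos + matrix(stats::rnorm(2 * n_bulk, 0, jit_sd), ncol = 2)
    })
    bulk[, 1] <- pmin(pmax(bulk[, 1], d / 2), ps - d / 2)
    bulk[, 2] <- pmin(pmax(bulk[, 2], d / 2), ps - d / 2)
  }

  # --- inner leaflet phospholipids --------------------------------------
  pl_names <- names(composition$pl_fractions)
  pl_counts <- .largest_remainder(composition$pl_total,
                                  composition$pl_fractions)
  lsp <- composition$lipid_species
  d_pl <- max(lsp$footprint_diameter[lsp$name %in% pl_names])
  inner <- matrix(numeric(0), ncol = 2)
  pl_species <- character(0)
  if (composition$pl_total > 0) {
    free_in <- ps^2 - sum(pi * (radius + d_pl / 2)^2)
    s0 <- sqrt(2 * max(free_in, 1) / (sqrt(3) * composition$pl_total))
    fill <- .adaptive_fill(composition$pl_total, ps, d_pl / 2, s0,
                           0.4, omps, radius + d_pl / 2)
    inner <- .with_seed(derive_seed(seed, "inner-pl"), {
      fill$pos[sample(nrow(fill$pos), composition$pl_total), , drop = FALSE]
    })
    pl_species <- .with_seed(derive_seed(seed, "pl-species"),
                             sample(rep(pl_names, pl_counts)))
  }

  n_lps <- n_shell + n_bulk
  lipids <- data.frame(
    id = c(sprintf("lps%05d", seq_len(n_lps)),
           sprintf("pl%05d", seq_len(nrow(inner)))),
    species = c(rep("RaLPS", n_lps), pl_species),
    leaflet = c(rep("outer", n_lps), rep("inner", nrow(inner))),
    x = c(shell[, 1], bulk[, 1], inner[, 1]),
    y = c(shell[, 2], bulk[, 2], inner[, 2]),
    shell_of = c(owners, rep("", n_bulk + nrow(inner))),
    stringsAsFactors = FALSE
  )
  model$lipids <- lipids
  model$composition <- composition
  attr(model$lipids, "n_shell") <- n_shell
  .validate_island_model(model)
  stopifnot(sum(lipids$species == "RaLPS") == composition$lps_total,
            sum(lipids$species != "RaLPS") == composition$pl_total)
  model
}

#' Mass budget of a lipidised island
#'
#' Sums component masses: beta-barrel protein mass (lipoprotein partners of
#' the BAM and LptDE complexes counted separately), lipid mass, and the
#' neutralising Ca2+ ions (3 per LPS). The OMP fraction is the barrel-only
#' protein mass over the total, in percent.
#'
#' @param model A lipidised `island_model` (OMP-only models give a
#'   lipid-free budget).
#' @param mass_table A mass table, see [default_mass_table()].
#' @return object of class `mass_report` with masses in MDa.
#' @export
mass_summary <- function(model, mass_table = default_mass_table()) {
  omp_tab <- mass_table$omp
  m_omp <- match(model$omps$species, omp_tab$name)
  if (anyNA(m_omp))
    stop("lookup error: unknown OMP species: ",
         paste(unique(model$omps$species[is.na(m_omp)]), collapse = ", "))
  barrel_kda <- sum(omp_tab$barrel_kda[m_omp])
  complex_kda <- sum(omp_tab$mass_kda[m_omp])
  lipo_kda <- complex_kda - barrel_kda

  lipid_kda <- 0
  ion_kda <- 0
  if (!is.null(model$lipids) && nrow(model$lipids) > 0) {
    lip_tab <- mass_table$lipid
    m_lip <- match(model$lipids$species, lip_tab$name)
    if (anyNA(m_lip))
      stop("lookup error: unknown lipid species: ",
           paste(unique(model$lipids$species[is.na(m_lip)]), collapse = ", "))
    lipid_kda <- sum(lip_tab$mass_kda[m_lip])
    n_lps <- sum(model$lipids$species == "RaLPS")
    ion_kda <- n_lps * mass_table$ca_per_lps * mass_table$ca_mass_kda
  }

  total_kda <- barrel_kda + lipo_kda + lipid_kda + ion_kda
  structure(list(
    total_mass = total_kda / 1000,
    protein_mass = barrel_kda / 1000,
    lipoprotein_mass = lipo_kda / 1000,
    lipid_mass = lipid_kda / 1000,
    ion_mass = ion_kda / 1000,
    omp_fraction = if (total_kda > 0) 100 * barrel_kda / total_kda else 0
  ), class = "mass_report")
}

#' @export
print.mass_report <- function(x, ...) {
  cat(sprintf(paste0("Island mass budget: total %.1f MDa ",
                     "(barrel OMPs %.1f, lipoproteins %.1f, lipids %.1f, ",
                     "ions %.2f); OMP fraction %.1f%%\n"),
              x$total_mass, x$protein_mass, x$lipoprotein_mass,
              x$lipid_mass, x$ion_mass, x$omp_fraction))
  invisible(x)
}
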