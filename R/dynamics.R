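# Simplified 2D membrane dynamics and dual-cutoff residence statistics.
#
# The dynamics are a statistical stand-in for coarse-grained MD: overdamped
# Brownian motion with per-species diffusion coefficients, annular-shell LPS
# tethered to their OMP ring in the asymmetric membrane, and everything
# mobile in the symmetric phospholipid membrane. The residence-time
# machinery (dual-cutoff contact intervals, occupancy) is the faithful part.

#' Dynamics configuration
#'
#' @param timestep Frame spacing in ns. Default 1.
#' @param n_frames Number of frames. Default 1000.
#' @param diffusion Named diffusion coefficients in nm^2/ns. `"OMP"` is used
#'   for protein centroids when mobile. Defaults: free LPS 0.005, PLs 0.05
#'   (approx. 5 um^2/s, a fluid-phase lipid), OMP 0.01.
#' @param omp_mobile Should OMP centroids diffuse in asymmetric mode?
#'   Default `FALSE` (OMPs and their LPS are near-arrested in the asymmetric
#'   membrane; the symmetric mode always frees them).
#' @param lps_unbind_rate Per-frame probability that a tethered shell LPS
#'   unbinds and diffuses freely. Default 0.
#' @param pl_membrane_mode `"asymmetric"` (LPS outer leaflet, shell LPS
#'   tethered) or `"symmetric"` (all lipids PL-like, OMPs free).
#' @param tether_sd Standard deviation (nm) of the positional fluctuation of
#'   tethered shell LPS about their ring anchor; `NULL` (default) uses the
#'   per-frame Brownian step of the species, `sqrt(2 D dt)`, so a frozen
#'   species (D = 0) shows exactly zero displacement.
#' @param seed Integer seed.
#' @return object of class `dynamics_config`.
#' @export
dynamics_config <- function(timestep = 1, n_frames = 1000,
                            diffusion = c(RaLPS = 0.005, POPE = 0.05,
                                          POPG = 0.05, CL = 0.05, OMP = 0.01),
                            omp_mobile = FALSE, lps_unbind_rate = 0,
                            pl_membrane_mode = c("asymmetric", "symmetric"),
                            tether_sd = NULL, seed = 1L) {
  pl_membrane_mode <- match.arg(pl_membrane_mode)
  if (any(diffusion < 0)) stop("validation error: diffusion must be >= 0")
  if (lps_unbind_rate < 0 || lps_unbind_rate > 1)
    stop("validation error: lps_unbind_rate must lie in [0, 1]")
  if (timestep <= 0 || n_frames < 1)
    stop("validation error: timestep must be > 0 and n_frames >= 1")
  structure(list(timestep = timestep, n_frames = as.integer(n_frames),
                 diffusion = diffusion, omp_mobile = omp_mobile,
                 lps_unbind_rate = lps_unbind_rate,
                 pl_membrane_mode = pl_membrane_mode,
                 tether_sd = tether_sd, seed = as.integer(seed)),
            class = "dynamics_config")
}

#' Simulate membrane dynamics on a lipidised island
#'
#' Overdamped Brownian updates with per-species diffusion coefficients.
#' In asymmetric mode, shell LPS stay tethered to their OMP ring position
#' (non-accumulating Gaussian fluctuation) unless a seeded unbind event
#' fires, after which they diffuse freely; OMP centroids are frozen unless
#' `omp_mobile`. In symmetric mode all lipids diffuse like phospholipids and
#' OMP centroids diffuse with the `"OMP"` coefficient. Lipids are reflected
#' off OMP footprints (excluded volume), so a diffusing phospholipid samples
#' the annular contact zone but never the protein interior. Positions are
#' stored unwrapped; distance computations use the minimum-image convention.
#'
#' @param model A lipidised `island_model`.
#' @param cfg A [dynamics_config()].
#' @param max_lipids Optional seeded subsample size for the lipids, to keep
#'   trajectories of the full island desk-sized.
#' @return object of class `membrane_trajectory`.
#' @export
simulate_membrane <- function(model, cfg = dynamics_config(),
                              max_lipids = NULL) {
  if (is.null(model$lipids)) stop("domain error: model has no lipids")
  lips <- model$lipids
  if (!is.null(max_lipids) && nrow(lips) > max_lipids) {
    idx <- .with_seed(derive_seed(cfg$seed, "traj-subsample"),
                      sort(sample(nrow(lips), max_lipids)))
    lips <- lips[idx, , drop = FALSE]
  }
  omps <- model$omps
  sp <- model$composition$omp_species
  omp_r <- sp$effective_radius[match(omps$species, sp$name)]
  lsp <- model$composition$lipid_species
  lip_r <- lsp$footprint_diameter[match(lips$species, lsp$name)] / 2

  n_omp <- nrow(omps)
  n_lip <- nrow(lips)
  n <- n_omp + n_lip
  Tn <- cfg$n_frames
  box <- model$geometry$patch_size
  dt <- cfg$timestep
  sym <- cfg$pl_membrane_mode == "symmetric"

  # per-particle diffusion coefficient
  d_of <- function(species) {
    v <- cfg$diffusion[species]
    if (anyNA(v)) stop("validation error: no diffusion coefficient for ",
                       paste(unique(species[is.na(v)]), collapse = ", "))
    as.numeric(v)
  }
  lip_species_eff <- if (sym) rep("POPE", n_lip) else lips$species
  D_lip <- d_of(lip_species_eff)
  D_omp <- if (sym || cfg$omp_mobile) rep(d_of("OMP"), n_omp) else rep(0, n_omp)
  D <- c(D_omp, D_lip)
  step_sd <- sqrt(2 * D * dt)
  if (any(6 * step_sd > box / 2))
    stop("stability error: per-frame displacement can exceed half the box; ",
         "reduce timestep or diffusion")

  tethered <- if (sym) rep(FALSE, n_lip) else lips$shell_of != ""
  teth_idx <- n_omp + which(tethered)

  teth_sd <- if (is.null(cfg$tether_sd)) step_sd else rep(cfg$tether_sd, n)
  lip_rows <- n_omp + seq_len(n_lip)
  contact_r <- outer(rep(1, n_lip), omp_r) + lip_r  # n_lip x n_omp

  pos0 <- rbind(cbind(omps$x, omps$y), cbind(lips$x, lips$y))
  pos <- array(0, dim = c(Tn, n, 2))
  .with_seed(derive_seed(cfg$seed, "dynamics"), {
    cur <- pos0
    anchors <- pos0
    teth_now <- c(rep(FALSE, n_omp), tethered)
    pos[1, , ] <- cur
    for (t in seq_len(Tn)[-1]) {
      if (cfg$lps_unbind_rate > 0 && any(teth_now)) {
        fire <- which(teth_now)[stats::runif(sum(teth_now)) <
                                  cfg$lps_unbind_rate]
        teth_now[fire] <- FALSE
      }
      stepv <- matrix(stats::rnorm(2 * n), ncol = 2) * step_sd
      cur <- cur + stepv
      if (any(teth_now)) {
        ti <- which(teth_now)
        cur[ti, ] <- anchors[ti, ] +
          matrix(stats::rnorm(2 * length(ti)), ncol = 2) * teth_sd[ti]
      }
      # excluded volume: push lipids radially out of OMP footprints
      for (j in seq_len(n_omp)) {
        dx <- cur[lip_rows, 1] - cur[j, 1]
        dy <- cur[lip_rows, 2] - cur[j, 2]
        dd <- sqrt(dx^2 + dy^2)
        rmin <- contact_r[, j]
        inside <- which(dd < rmin)
        if (length(inside)) {
          scl <- rmin[inside] / pmax(dd[inside], 1e-9)
          cur[lip_rows[inside], 1] <- cur[j, 1] + dx[inside] * scl
          cur[lip_rows[inside], 2] <- cur[j, 2] + dy[inside] * scl
        }
      }
      pos[t, , ] <- cur
    }
  })

  structure(list(pos = pos,
                 ids = c(omps$id, lips$id),
                 species = c(omps$species, lips$species),
                 is_omp = c(rep(TRUE, n_omp), rep(FALSE, n_lip)),
                 radius = c(omp_r, lip_r),
                 tethered = c(rep(FALSE, n_omp), tethered),
                 box = box, timestep = dt,
                 mode = cfg$pl_membrane_mode, seed = cfg$seed),
            class = "membrane_trajectory")
}

#' @export
print.membrane_trajectory <- function(x, ...) {
  cat("Membrane trajectory:", dim(x$pos)[1], "frames x", dim(x$pos)[2],
      "particles (", sum(x$is_omp), "OMPs ),", x$mode, "mode,",
      x$timestep, "ns/frame\n")
  invisible(x)
}

#' Extract dual-cutoff contact intervals from a distance series
#'
#' A contact opens at the first frame with distance `< on` and closes at the
#' first subsequent frame with distance `> off`; frames in `(on, off]`
#' prolong an open contact but never open one. This double threshold
#' suppresses boundary flicker in residence-time estimates.
#'
#' @param d Numeric vector of distances (nm), one per frame.
#' @param on Opening cutoff (nm), default 0.475.
#' @param off Closing cutoff (nm), default 0.8. Must exceed `on`.
#' @return Integer matrix with columns `start`, `end`: half-open frame
#'   intervals `[start, end)`, 0-based.
#' @examples
#' dual_cutoff_intervals(c(0.9, 0.4, 0.6, 0.7, 0.9))  # single interval [1, 4)
#' @export
dual_cutoff_intervals <- function(d, on = 0.475, off = 0.8) {
  if (on >= off) stop("configuration error: on-cutoff must be < off-cutoff")
  open <- d < on
  shut <- d > off
  out <- list()
  state <- FALSE
  start <- NA_integer_
  for (t in seq_along(d)) {
    if (!state && open[t]) { state <- TRUE; start <- t - 1L }
    else if (state && shut[t]) {
      out[[length(out) + 1L]] <- c(start, t - 1L)
      state <- FALSE
    }
  }
  if (state) out[[length(out) + 1L]] <- c(start, length(d))
  m <- if (length(out)) do.call(rbind, out) else
    matrix(integer(0), ncol = 2)
  colnames(m) <- c("start", "end")
  m
}

# minimum-image lipid-to-OMP surface distance series for one pair
.pair_distance <- function(traj, li, oi) {
  dx <- traj$pos[, li, 1] - traj$pos[, oi, 1]
  dy <- traj$pos[, li, 2] - traj$pos[, oi, 2]
  b <- traj$box
  dx <- dx - b * round(dx / b)
  dy <- dy - b * round(dy / b)
  sqrt(dx^2 + dy^2) - traj$radius[oi] - traj$radius[li]
}

#' Dual-cutoff lipid-protein contact intervals of a trajectory
#'
#' Applies [dual_cutoff_intervals()] to the surface-to-surface distance
#' series of every lipid-OMP pair (centroid separation minus the OMP
#' footprint radius and the lipid footprint radius, minimum-image).
#'
#' @param traj A `membrane_trajectory`.
#' @param on,off Cutoffs in nm (default 0.475 / 0.8).
#' @return object of class `contact_intervals`: data.frame `lipid`, `omp`,
#'   `start`, `end` (half-open, 0-based frames).
#' @export
dual_cutoff_contacts <- function(traj, on = 0.475, off = 0.8) {
  if (on >= off) stop("configuration error: on-cutoff must be < off-cutoff")
  li_all <- which(!traj$is_omp)
  oi_all <- which(traj$is_omp)
  rows <- list()
  for (li in li_all) for (oi in oi_all) {
    iv <- dual_cutoff_intervals(.pair_distance(traj, li, oi), on, off)
    if (nrow(iv))
      rows[[length(rows) + 1L]] <- data.frame(
        lipid = traj$ids[li], omp = traj$ids[oi],
        start = iv[, 1], end = iv[, 2], stringsAsFactors = FALSE)
  }
  iv <- do.call(rbind, c(rows, list(data.frame(
    lipid = character(0), omp = character(0),
    start = integer(0), end = integer(0)))))
  structure(list(intervals = iv, n_frames = dim(traj$pos)[1],
                 timestep = traj$timestep, on = on, off = off),
            class = "contact_intervals")
}

#' @export
print.contact_intervals <- function(x, ...) {
  cat("Contact intervals:", nrow(x$intervals), "intervals over", x$n_frames,
      sprintf("frames (cutoffs %.3f / %.3f nm)\n", x$on, x$off))
  invisible(x)
}

#' Occupancy and residence statistics per lipid species
#'
#' Occupancy of a lipid is the fraction of frames it spends inside any
#' contact interval with any OMP; species occupancy is the mean over lipids,
#' in percent. Mean residence time is the mean contact interval length times
#' the timestep.
#'
#' @param ci A `contact_intervals`.
#' @param traj The `membrane_trajectory` the intervals came from.
#' @param by_tether Split species rows into tethered (annular shell) and
#'   free lipids? Bulk LPS far from the lattice dilutes the species mean;
#'   the shell population is the one whose occupancy approaches 100%.
#' @return data.frame with one row per lipid species (and tether class when
#'   `by_tether`): `species`, `occupancy` (%), `mean_residence_ns`,
#'   `n_lipids`.
#' @export
occupancy_stats <- function(ci, traj, by_tether = FALSE) {
  if (nrow(ci$intervals) &&
      max(ci$intervals$end) > dim(traj$pos)[1])
    stop("domain error: intervals exceed trajectory length")
  Tn <- dim(traj$pos)[1]
  lip_ids <- traj$ids[!traj$is_omp]
  lip_sp <- traj$species[!traj$is_omp]
  if (by_tether) {
    teth <- traj$tethered[!traj$is_omp]
    lip_sp <- paste0(lip_sp, ifelse(teth, " (tethered)", " (free)"))
  }
  occ <- stats::setNames(numeric(length(lip_ids)), lip_ids)
  if (nrow(ci$intervals)) {
    by_lip <- split(ci$intervals, ci$intervals$lipid)
    for (nm in names(by_lip)) {
      iv <- by_lip[[nm]]
      frames <- logical(Tn)
      for (r in seq_len(nrow(iv)))
        frames[(iv$start[r] + 1):iv$end[r]] <- TRUE
      occ[nm] <- sum(frames) / Tn
    }
  }
  res <- if (nrow(ci$intervals)) {
    sp_of <- stats::setNames(lip_sp, lip_ids)[ci$intervals$lipid]
    tapply((ci$intervals$end - ci$intervals$start) * ci$timestep, sp_of, mean)
  } else NULL
  out <- data.frame(species = sort(unique(lip_sp)), stringsAsFactors = FALSE)
  out$occupancy <- vapply(out$species, function(s)
    100 * mean(occ[lip_sp == s]), numeric(1))
  out$mean_residence_ns <- vapply(out$species, function(s)
    if (!is.null(res) && s %in% names(res)) as.numeric(res[[s]]) else 0,
    numeric(1))
  out$n_lipids <- vapply(out$species, function(s) sum(lip_sp == s), integer(1))
  rownames(out) <- NULL
  out
}

#' Hexatic order and mean squared displacement of a trajectory
#'
#' The global bond-orientational order parameter psi6 of the OMP point
#' pattern per frame (see [psi6_order()]; six nearest neighbours per OMP),
#' and per-species MSD curves versus lag. psi6 is 1 for a perfect
#' triangular lattice and near zero for disordered patterns.
#'
#' @param traj A `membrane_trajectory` with at least 7 OMPs.
#' @return list with `psi6` (numeric, one value in \[0,1\] per frame) and
#'   `msd` (matrix lag x species, nm^2).
#' @export
lattice_order <- function(traj) {
  oi <- which(traj$is_omp)
  if (length(oi) < 7) stop("domain error: need at least 7 OMPs for psi6")
  Tn <- dim(traj$pos)[1]
  psi6 <- vapply(seq_len(Tn), function(t)
    psi6_order(traj$pos[t, oi, , drop = TRUE], box = traj$box), numeric(1))
  species <- unique(traj$species)
  lags <- seq_len(Tn) - 1
  msd <- sapply(species, function(s) {
    idx <- which(traj$species == s)
    dx <- traj$pos[, idx, 1, drop = FALSE] -
      rep(traj$pos[1, idx, 1], each = Tn)
    dy <- traj$pos[, idx, 2, drop = FALSE] -
      rep(traj$pos[1, idx, 2], each = Tn)
    rowMeans(dx^2 + dy^2)
  })
  rownames(msd) <- lags
  list(psi6 = psi6, msd = msd)
}

#' Bond-orientational (hexatic) order of a 2D point pattern
#'
#' The global hexatic order parameter: `|mean_i psi6_i|`, where `psi6_i` is
#' the complex bond-orientational factor `mean_j exp(6 i theta_ij)` over
#' point i's `k` nearest neighbours. A perfect triangular lattice scores 1;
#' uniform random points score near zero because the per-point phases
#' decorrelate.
#'
#' @param points n x 2 coordinate matrix (n >= 7).
#' @param k Neighbours per point (default 6).
#' @param box Optional periodic box (length 1 or 2); with a box, neighbours
#'   and bond angles use the minimum-image convention, so a box-commensurate
#'   perfect triangular lattice scores exactly 1.
#' @return Order value in \[0, 1\].
#' @export
psi6_order <- function(points, k = 6, box = NULL) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < k + 1) stop("domain error: need at least k + 1 points")
  if (!is.null(box)) box <- rep(box, length.out = 2)
  vals <- vapply(seq_len(n), function(i) {
    dx <- points[, 1] - points[i, 1]
    dy <- points[, 2] - points[i, 2]
    if (!is.null(box)) {
      dx <- dx - box[1] * round(dx / box[1])
      dy <- dy - box[2] * round(dy / box[2])
    }
    dd <- dx^2 + dy^2
    dd[i] <- Inf
    nb <- order(dd)[seq_len(k)]
    mean(exp(6i * atan2(dy[nb], dx[nb])))
  }, complex(1))
  Mod(mean(vals))
}

#' Export a trajectory as long-format CSV
#'
#' Columns `frame` (0-based), `id`, `species`, `x`, `y`.
#' @param traj A `membrane_trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_trajectory_csv <- function(traj, path) {
  Tn <- dim(traj$pos)[1]; n <- dim(traj$pos)[2]
  df <- data.frame(frame = rep(seq_len(Tn) - 1L, each = n),
                   id = rep(traj$ids, Tn),
                   species = rep(traj$species, Tn),
                   x = as.numeric(t(traj$pos[, , 1])),
                   y = as.numeric(t(traj$pos[, , 2])))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a trajectory as XYZ
#'
#' One block per frame with z = 0; species as the atom label.
#' @param traj A `membrane_trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_trajectory_xyz <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  Tn <- dim(traj$pos)[1]; n <- dim(traj$pos)[2]
  lab <- gsub("[^A-Za-z0-9]", "", traj$species)
  for (t in seq_len(Tn)) {
    writeLines(c(as.character(n), paste("frame", t - 1)), con)
    writeLines(sprintf("%s %.4f %.4f 0.0", lab,
                       traj$pos[t, , 1], traj$pos[t, , 2]), con)
  }
  invisible(path)
}
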