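test_that("reference scaffold has 102 sites forming 18 hexagons", {
  lay <- build_scaffold(geometry_config())
  expect_equal(nrow(lay$scaffold_sites), 102)
  expect_equal(length(lay$hexagons), 18)
  expect_true(all(lengths(lay$hexagons) == 6))
  # hexagon rings are six distinct sites
  for (h in lay$hexagons) expect_equal(length(unique(h)), 6)
  # triangles present ("small triangular arrangements")
  expect_gt(nrow(lay$triangles), 0)
})

test_that("ideal lattice: every nearest-neighbour distance equals the spacing
           and every triangle angle is 60 degrees", {
  lay <- build_scaffold(geometry_config(lattice_spacing = 8.5, jitter_sd = 0))
  rep <- validate_geometry(lay)
  expect_equal(rep$min_nn_distance, 8.5, tolerance = 1e-9)
  expect_equal(rep$max_nn_distance, 8.5, tolerance = 1e-9)
  expect_equal(rep$min_angle, 60, tolerance = 1e-9)
  expect_equal(rep$max_angle, 60, tolerance = 1e-9)
  expect_equal(nrow(rep$violations), 0)
})

test_that("minimal kagome patch is a single six-site hexagon ring", {
  lay <- build_scaffold(geometry_config(layout = "kagome-patch",
                                        n_hexagons = 1L))
  expect_equal(nrow(lay$scaffold_sites), 6)
  expect_equal(length(lay$hexagons), 1)
  expect_equal(nrow(lay$triangles), 0)
  # ring sites all at distance a from the centre and a from ring neighbours
  ctr <- lay$hexagon_centers[1, ]
  dd <- sqrt((lay$scaffold_sites[, 1] - ctr[1])^2 +
               (lay$scaffold_sites[, 2] - ctr[2])^2)
  expect_equal(dd, rep(8.5, 6), tolerance = 1e-9)
})

test_that("scaling the lattice spacing scales distances, not angles", {
  r1 <- validate_geometry(build_scaffold(geometry_config(lattice_spacing = 8)))
  r2 <- validate_geometry(build_scaffold(geometry_config(lattice_spacing = 8.96)))
  expect_equal(r2$min_nn_distance / r1$min_nn_distance, 8.96 / 8,
               tolerance = 1e-9)
  expect_equal(r2$max_nn_distance / r1$max_nn_distance, 8.96 / 8,
               tolerance = 1e-9)
  expect_equal(r1$min_angle, r2$min_angle, tolerance = 1e-9)
})

test_that("default composition places 218 OMPs with 116 guests split 19/20", {
  lay <- build_scaffold(geometry_config())
  m <- place_guests(lay, composition_spec(), seed = 1)
  expect_equal(nrow(m$omps), 218)
  expect_equal(sum(m$omps$role == "guest"), 116)
  counts <- table(m$omps$species[m$omps$role == "guest"])
  expect_true(all(counts %in% c(19, 20)))
  expect_equal(sum(counts), 116)
})

test_that("scaffold mismatch and capacity problems raise informative errors", {
  lay <- build_scaffold(geometry_config())
  expect_error(place_guests(lay, composition_spec(total_omps = 100L)),
               "scaffold")
  expect_error(place_guests(lay, composition_spec(total_omps = 900L,
                                                  ompf_fraction = 102 / 900)),
               "capacity error")
  expect_error(build_scaffold(geometry_config(patch_size = 50)),
               "patch too small")
})

test_that("empty guest list yields a scaffold-only model", {
  lay <- build_scaffold(geometry_config(layout = "kagome-patch",
                                        n_hexagons = 3L, patch_size = 60))
  n <- nrow(lay$scaffold_sites)
  comp <- composition_spec(total_omps = n + 1L,
                           ompf_fraction = n / (n + 1L),
                           guest_species = "BtuB")
  m <- place_guests(lay, comp, seed = 1)
  expect_equal(sum(m$omps$role == "guest"), 1)
})

test_that("guest placement keeps 8 nm centroid spacing across seeds", {
  for (seed in 1:4) {
    g <- geometry_config(jitter_sd = 0.25, seed = seed)
    m <- place_guests(build_scaffold(g), composition_spec(), seed = seed)
    # jitter may perturb scaffold-scaffold spacing (validate_geometry reports
    # that); guests must never sit closer than 8 nm to anything
    D <- as.matrix(dist(cbind(m$omps$x, m$omps$y)))
    diag(D) <- Inf
    guest <- m$omps$role == "guest"
    expect_gte(min(D[guest, ]), 8.0 - 1e-9)
  }
})

test_that("violations are reported for displaced sites", {
  lay <- build_scaffold(geometry_config())
  # drag two neighbouring sites to 7 nm apart
  D <- as.matrix(dist(lay$scaffold_sites))
  diag(D) <- Inf
  ij <- which(D == min(D), arr.ind = TRUE)[1, ]
  v <- lay$scaffold_sites[ij[2], ] - lay$scaffold_sites[ij[1], ]
  lay$scaffold_sites[ij[2], ] <- lay$scaffold_sites[ij[1], ] + v * 7 / 8.5
  rep <- validate_geometry(lay)
  expect_gt(nrow(rep$violations), 0)
  expect_true(any(rep$violations$kind == "nn_distance" &
                    abs(rep$violations$value - 7) < 1e-6))
})

test_that("same configuration and seed give identical models and exports", {
  g <- geometry_config(jitter_sd = 0.1, seed = 7L)
  m1 <- place_guests(build_scaffold(g), composition_spec(), seed = 7)
  m2 <- place_guests(build_scaffold(g), composition_spec(), seed = 7)
  expect_identical(m1$omps, m2$omps)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  export_model_csv(m1, f1); export_model_csv(m2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("model exports are well-formed", {
  m <- small_island()
  f <- withr::local_tempfile(fileext = ".csv")
  export_model_csv(m, f)
  df <- read.csv(f)
  expect_equal(nrow(df), nrow(m$omps) + nrow(m$lipids))
  expect_named(df, c("id", "species", "leaflet", "x_nm", "y_nm", "shell_of"))
  p <- withr::local_tempfile(fileext = ".pdb")
  export_model_pdb(m, p)
  lines <- readLines(p)
  expect_equal(sum(startsWith(lines, "ATOM")),
               nrow(m$omps) + nrow(m$lipids))
})
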