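rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3)
}

test_that("superposition recovers exact rigid transforms", {
  s <- make_structure(synthetic_spec(8, "ideal_helix"))
  X <- coords(s)
  sp0 <- superpose(X, X)
  expect_equal(sp0$rmsd, 0, tolerance = 1e-10)
  expect_equal(sp0$rotation, diag(3), tolerance = 1e-8)

  Xr <- X %*% rot_z(90)
  sp <- superpose(Xr, X)
  expect_equal(sp$rmsd, 0, tolerance = 1e-9)
  expect_equal(Xr %*% sp$rotation, X, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(det(sp$rotation), 1, tolerance = 1e-10)
})

test_that("superposition RMSD matches a direct rotation-space minimisation", {
  set.seed(5)
  A <- matrix(stats::rnorm(30, sd = 3), 10, 3)
  B <- matrix(stats::rnorm(30, sd = 3), 10, 3)
  kabsch <- superpose(A, B)$rmsd
  oracle <- oracle_min_rmsd(A, B)
  expect_lt(abs(kabsch - oracle), 1e-3)
  expect_lte(kabsch, oracle + 1e-9)  # Kabsch is the true minimum
})

test_that("superposition RMSD is invariant under rigid motion of the mobile set", {
  set.seed(11)
  A <- matrix(stats::rnorm(36), 12, 3)
  B <- matrix(stats::rnorm(36), 12, 3)
  base <- superpose(A, B)$rmsd
  for (k in 1:5) {
    R <- rot_z(runif(1, 0, 360)) %*%
      superpose(matrix(rnorm(9), 3), matrix(rnorm(9), 3))$rotation
    moved <- sweep(A %*% R, 2, runif(3, -20, 20), "+")
    expect_equal(superpose(moved, B)$rmsd, base, tolerance = 1e-6)
  }
})

test_that("degenerate fit selections are rejected", {
  line <- cbind(1:5, 0, 0)
  expect_error(superpose(line, line), "collinear")
  expect_error(superpose(matrix(0, 2, 3), matrix(0, 2, 3)), "3 fit atoms")
})

test_that("rmsd_series is zero for static or rigidly shifted frames", {
  spec <- synthetic_spec(6, n_frames = 4, sigma = 0)
  s <- make_structure(spec)
  ens <- make_ensemble(spec, s)
  expect_equal(rmsd_series(ens), rep(0, 4), tolerance = 1e-9)
  ens$xyz[3, ] <- ens$xyz[3, ] + rep(c(1, 1, 1), ncol(ens$xyz) / 3)
  expect_equal(rmsd_series(ens), rep(0, 4), tolerance = 1e-9)
})

test_that("rmsd_series matches a direct post-fit evaluation for one moved atom", {
  spec <- synthetic_spec(6, n_frames = 3, sigma = 0)
  s <- make_structure(spec)
  ens <- make_ensemble(spec, s)
  sel <- backbone_indices(s)
  delta <- 0.8
  ens$xyz[2, 3 * (sel[1] - 1) + 1] <- ens$xyz[2, 3 * (sel[1] - 1) + 1] + delta
  # oracle: fit the perturbed frame by explicit minimisation, then measure
  ref <- coords(s)
  mob <- matrix(ens$xyz[2, ], ncol = 3, byrow = TRUE)
  expect_equal(rmsd_series(ens, selection = sel)[2],
               oracle_min_rmsd(mob[sel, ], ref[sel, ]), tolerance = 1e-4)
  expect_lt(rmsd_series(ens, selection = sel)[2], delta)
})

test_that("rmsf reproduces hand-computable fluctuation patterns", {
  spec <- synthetic_spec(8, "extended_chain", n_frames = 2, sigma = 0)
  s <- make_structure(spec)
  ens <- make_ensemble(spec, s)
  expect_error(rmsf(make_ensemble(synthetic_spec(8, "extended_chain",
                                                 n_frames = 1, sigma = 0), s)),
               "2 frames")
  static <- make_ensemble(synthetic_spec(8, "extended_chain", n_frames = 5,
                                         sigma = 0), s)
  expect_equal(rmsf(static), rep(0, 8), tolerance = 1e-9)
})

test_that("rmsf of an isotropic Gaussian ensemble approaches sigma * sqrt(3)", {
  sigma <- 0.4
  spec <- synthetic_spec(60, "ideal_helix", n_frames = 1000, sigma = sigma,
                         seed = 21)
  s <- make_structure(spec)
  ens <- make_ensemble(spec, s)
  r <- rmsf(ens)
  expect_equal(mean(r), sigma * sqrt(3), tolerance = 0.05)
})

test_that("single-atom SASA matches the closed-form sphere area", {
  s <- hand_structure(list(data.frame(name = "CA", element = "C",
                                      x = 0, y = 0, z = 0)))
  out <- sasa(s, probe_radius = 1.4, n_points = 960)
  exact <- 4 * pi * (1.7 + 1.4)^2 / 100     # nm^2
  expect_equal(out$total, exact, tolerance = 0.02)
  expect_equal(sum(out$per_residue), out$total, tolerance = 1e-12)
})

test_that("well-separated atoms contribute independent areas", {
  s <- hand_structure(list(
    data.frame(name = "CA", element = "C", x = 0, y = 0, z = 0),
    data.frame(name = "CA", element = "C", x = 100, y = 0, z = 0)))
  one <- sasa(hand_structure(list(data.frame(name = "CA", element = "C",
                                             x = 0, y = 0, z = 0))))$total
  expect_equal(sasa(s)$total, 2 * one, tolerance = 1e-10)
})

test_that("two overlapping spheres match the analytic spherical-cap area", {
  for (d in c(2.0, 3.5, 5.0)) {
    s <- hand_structure(list(
      data.frame(name = "CA", element = "C", x = 0, y = 0, z = 0),
      data.frame(name = "CA", element = "C", x = d, y = 0, z = 0)))
    exact <- two_sphere_area(1.7, 1.4, d) / 100
    expect_equal(sasa(s)$total, exact, tolerance = 0.02)
  }
})

test_that("SASA decreases monotonically as two atoms approach", {
  areas <- vapply(c(7, 5, 4, 3, 2), function(d)
    sasa(hand_structure(list(
      data.frame(name = "CA", element = "C", x = 0, y = 0, z = 0),
      data.frame(name = "CA", element = "C", x = d, y = 0, z = 0))))$total,
    numeric(1))
  expect_true(all(diff(areas) < 1e-9))
})

test_that("unknown elements are reported by name", {
  s <- hand_structure(list(data.frame(name = "FE", element = "FE",
                                      x = 0, y = 0, z = 0)))
  expect_error(sasa(s), "FE")
})

test_that("hydrogen-bond detection applies both distance and angle cutoffs", {
  base <- make_structure(synthetic_spec(8, "extended_chain"))
  planted_detected <- function(d, ang) {
    s <- plant_hbond(base, 2, 6, d, ang)
    hb <- find_hbonds(s)
    any(hb$donor_res == 2 & hb$acceptor_res == 6 &
          s$atoms$name[hb$donor] == "OD1")
  }
  expect_true(planted_detected(2.9, 10))
  expect_false(planted_detected(3.6, 0))
  expect_false(planted_detected(2.9, 45))
  # boundary: the criterion is inclusive at d = 3.5 and 30 degrees
  expect_true(planted_detected(3.5, 30))
})

test_that("hydrogen-bond detection is independent of atom ordering", {
  s <- plant_hbond(make_structure(synthetic_spec(8, "extended_chain")),
                   2, 6, 2.9, 10)
  hb1 <- find_hbonds(s)
  atoms <- s$atoms[, setdiff(names(s$atoms), "resindex")]
  set.seed(4)
  shuffled <- atoms[sample(nrow(atoms)), ]
  shuffled$eleno <- seq_len(nrow(shuffled))
  s2 <- allomap:::new_structure3d(shuffled)
  hb2 <- find_hbonds(s2)
  key <- function(h) paste(h$donor_res, h$acceptor_res,
                           round(h$distance, 6), round(h$angle, 4))
  expect_setequal(key(hb1), key(hb2))
})

test_that("the donor-side and hydrogen-side angle conventions agree on planted bonds", {
  s <- plant_hbond(make_structure(synthetic_spec(8, "extended_chain")),
                   2, 6, 2.9, 10)
  hda <- find_hbonds(s, angle_def = "HDA")
  dha <- find_hbonds(s, angle_def = "DHA")
  pick <- function(h) h[h$donor_res == 2 & h$acceptor_res == 6 &
                          s$atoms$name[h$donor] == "OD1", ]
  expect_equal(nrow(pick(hda)), 1L)
  expect_equal(nrow(pick(dha)), 1L)
  expect_equal(pick(hda)$distance, pick(dha)$distance)
})
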