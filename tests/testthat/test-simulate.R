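# Langevin engine: coil construction, minimization, canonical sampling,
# scheduling arithmetic, determinism, trajectory I/O.

test_that("initial coils have exact bond lengths, hard-core clearance and seed determinism", {
  p <- params_fixture()
  x <- build_initial_coil("GG", p, seed = 1)
  expect_equal(sqrt(sum((x[2, ] - x[1, ])^2)), p$bond$r0)

  seq <- random_seq(25, 3)
  x <- build_initial_coil(seq, p, seed = 3)
  bonds <- sqrt(rowSums((x[-1, ] - x[-25, ])^2))
  expect_equal(bonds, rep(p$bond$r0, 24))
  d <- as.matrix(dist(x))
  nb <- d[abs(row(d) - col(d)) >= 2]
  expect_true(all(nb >= 0.8 * min(p$beads$sigma)))

  expect_identical(build_initial_coil(seq, p, seed = 3), x)
  expect_false(identical(build_initial_coil(seq, p, seed = 4), x))
})

test_that("minimization relaxes a stretched dimer to the bond minimum and never raises energy", {
  p <- params_fixture()
  x0 <- rbind(c(0, 0, 0), c(p$bond$r0 + 2, 0, 0))
  xm <- minimize(x0, "GG", p)
  expect_lt(abs(sqrt(sum((xm[2, ] - xm[1, ])^2)) - p$bond$r0), 1e-4)

  # already-minimal dimer: force tolerance triggers immediately
  x1 <- rbind(c(0, 0, 0), c(p$bond$r0, 0, 0))
  out <- minimize(x1, "GG", p)
  expect_equal(attr(out, "iterations"), 0L)

  seq <- random_seq(15, 9)
  coil <- build_initial_coil(seq, p, seed = 9)
  e_in <- total_energy_forces(coil, seq, p)$energy
  e_out <- total_energy_forces(minimize(coil, seq, p, max_iters = 50), seq, p)$energy
  expect_lte(e_out, e_in)
})

test_that("frame count follows production / save_interval", {
  p <- params_fixture()
  cfg <- sim_config("desk", production_ns = 10, save_interval_ns = 2,
                    equilibration_ns = 1, seed = 5)
  x <- minimize(build_initial_coil("GSGSG", p, seed = 5), "GSGSG", p)
  tr <- run_langevin(x, "GSGSG", p, cfg)
  expect_equal(dim(tr$coords)[1], 5)  # 10 ns / 2 ns
  expect_equal(tr$frame_ns, 2)
})

test_that("trajectories are bitwise deterministic per seed", {
  p <- params_fixture()
  cfg <- sim_config("desk", production_ns = 4, save_interval_ns = 1,
                    equilibration_ns = 1, seed = 21)
  x <- minimize(build_initial_coil("MKVAY", p, seed = 2), "MKVAY", p)
  t1 <- run_langevin(x, "MKVAY", p, cfg)
  t2 <- run_langevin(x, "MKVAY", p, cfg)
  expect_identical(t1$coords, t2$coords)
  cfg2 <- cfg; cfg2$seed <- 22L
  t3 <- run_langevin(x, "MKVAY", p, cfg2)
  expect_false(identical(t1$coords, t3$coords))
})

test_that("harmonic dimer samples the 1-D canonical bond distribution", {
  p <- params_fixture()
  cfg <- sim_config("desk", production_ns = 150, save_interval_ns = 0.05,
                    equilibration_ns = 2, seed = 11)
  x <- build_initial_coil("GG", p, seed = 1)
  tr <- run_langevin(x, "GG", p, cfg)
  b <- sqrt(rowSums((tr$coords[, 2, ] - tr$coords[, 1, ])^2))

  # canonical closed form: p(r) ~ r^2 exp(-k (r - r0)^2 / kBT)
  kBT <- 0.0019872041 * 300
  rr <- seq(2, 6, by = 1e-4)
  w <- rr^2 * exp(-p$bond$k * (rr - p$bond$r0)^2 / kBT)
  m_th <- sum(rr * w) / sum(w)
  v_th <- sum(rr^2 * w) / sum(w) - m_th^2
  se <- sd(b) / sqrt(length(b) / 4)  # conservative effective sample size
  expect_lt(abs(mean(b) - m_th), 3 * se)
  expect_lt(abs(var(b) - v_th) / v_th, 0.15)
})

test_that("free-bead diffusion follows the Langevin closed form", {
  p <- params_fixture()
  cfg <- sim_config("desk", production_ns = 100, save_interval_ns = 0.05,
                    equilibration_ns = 0.2, seed = 13)
  tr <- run_langevin(matrix(0, 1, 3), "G", p, cfg)
  pos <- tr$coords[, 1, ]
  # D = kBT / (m gamma) in A^2/fs
  kBT <- 0.0019872041 * 300 * 4.184e-4
  D <- kBT / (p$beads["G", "mass"] * 1e-5)
  lag <- 20  # frames = 1 ns, ~100 quasi-independent segments
  disp <- pos[(lag + 1):nrow(pos), ] - pos[1:(nrow(pos) - lag), ]
  msd <- mean(rowSums(disp^2))
  # full Langevin closed form: MSD(t) = 6 D (t - (1 - exp(-gamma t))/gamma)
  t_fs <- lag * 0.05 * 1e6; gamma <- 1e-5
  msd_th <- 6 * D * (t_fs - (1 - exp(-gamma * t_fs)) / gamma)
  expect_equal(msd, msd_th, tolerance = 0.25)
})

test_that("kinetic temperature of a 30-bead chain matches the thermostat target", {
  p <- params_fixture()
  seq <- design_by_composition(c(G = 0.4, S = 0.4, A = 0.2), 30, seed = 2)
  cfg <- sim_config("desk", production_ns = 30, save_interval_ns = 0.1,
                    equilibration_ns = 2, seed = 17)
  x <- minimize(build_initial_coil(seq, p, seed = 2), seq, p)
  tr <- run_langevin(x, seq, p, cfg)
  tk <- kinetic_temperature(tr)
  se <- sd(tk) / sqrt(length(tk))
  expect_lt(abs(mean(tk) - 300), 3 * se + 3)  # 3 s.e. plus O(dt^2) bias allowance
})

test_that("NVE limit conserves energy at the production timestep", {
  p <- params_fixture()
  x <- rbind(c(0, 0, 0), c(p$bond$r0 + 0.3, 0, 0))
  v0 <- matrix(0, 2, 3)
  ff <- idrsim:::ff_tables("GG", p, box = 500, hard_floor = 0)
  res <- idrsim:::cpp_run_nve(x, v0, rep(p$beads["G", "mass"], 2), ff,
                              dt = 20, nsteps = 2e5, save_every = 50)
  # secular drift = linear slope of total energy vs time; the bounded
  # symplectic oscillation of velocity-Verlet averages out of the fit
  t_ns <- seq_along(res$etot) * 50 * 20 * 1e-6
  slope <- stats::lm.fit(cbind(1, t_ns), res$etot)$coefficients[2]
  expect_lt(abs(slope), 1e-3)  # kcal/mol per ns
})

test_that("paper preset assigns production time by chain length", {
  p <- params_fixture()
  cfg <- sim_config("paper")
  expect_null(cfg$production_ns)   # set per chain by the protocol
  expect_equal(cfg$save_interval_ns, 2)
  expect_equal(cfg$equilibration_ns, 10)
  expect_equal(cfg$timestep_fs, 20)
  expect_equal(cfg$box_edge, 500)

  # production length rule: 6 us under 250 residues, 10 us above; the
  # unassigned boundary length 250 warns and takes the shorter schedule
  expect_equal(paper_production_ns(100), 6000)
  expect_equal(paper_production_ns(300), 10000)
  expect_warning(b <- paper_production_ns(250), "250")
  expect_equal(b, 6000)
})

test_that("replicates use distinct derived seeds", {
  p <- params_fixture()
  cfg <- sim_config("desk", production_ns = 3, save_interval_ns = 1,
                    equilibration_ns = 0.5)
  trs <- simulate_protocol("GSGSGSGS", p, preset = "desk", seed = 30,
                           replicates = 3, config = cfg)
  expect_length(trs, 3)
  seeds <- vapply(trs, function(t) t$config$seed, integer(1))
  expect_equal(length(unique(seeds)), 3)
  expect_false(identical(trs[[1]]$coords, trs[[2]]$coords))
})

test_that("trajectory write/read round-trips coordinates, spacing and provenance", {
  p <- params_fixture()
  cfg <- sim_config("desk", production_ns = 4, save_interval_ns = 1,
                    equilibration_ns = 0.5, seed = 2)
  x <- minimize(build_initial_coil("MKVAYE", p, seed = 2), "MKVAYE", p)
  tr <- run_langevin(x, "MKVAYE", p, cfg)
  dir <- withr::local_tempdir()
  prefix <- file.path(dir, "traj")
  write_trajectory(tr, prefix)
  tr2 <- read_trajectory(prefix)
  expect_equal(tr2$coords, tr$coords, tolerance = 1e-5)
  expect_equal(tr2$seq, tr$seq)
  expect_equal(tr2$frame_ns, tr$frame_ns)
  expect_equal(tr2$config$seed, tr$config$seed)

  # mismatched topology: sequence in sidecar no longer matches frames
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  meta$seq <- paste0(meta$seq, "G")
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE)
  expect_error(read_trajectory(prefix), "mismatch")
})
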