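test_that("unwrapping restores continuous coordinates across the boundary", {
  # one particle crossing the boundary: wrapped 9.9 -> 0.1 becomes 9.9 -> 10.1
  st <- wall_structure(data.frame(
    elety = "OW", element = "O", mass = 18.02, component = "water",
    group = "none", resid = 1, site_head = FALSE))
  xyz <- array(0, dim = c(1, 3, 2))
  xyz[1, , 1] <- c(9.9, 5, 5); xyz[1, , 2] <- c(0.1, 5, 5)
  tr <- wall_trajectory(st, xyz, c(10, 10, 10), dt = 1)
  un <- unwrap_trajectory(tr)
  expect_equal(un$xyz[1, , 2], c(10.1, 5, 5))

  # a stationary particle is unchanged
  xyz2 <- array(rep(c(3, 4, 5), 2), dim = c(1, 3, 2))
  tr2 <- wall_trajectory(st, xyz2, c(10, 10, 10), dt = 1)
  expect_equal(unwrap_trajectory(tr2)$xyz, xyz2)
})

test_that("unwrap inverts wrapping on Brownian trajectories", {
  g <- gen_brownian(brownian_spec(1.5, n_particles = 60, n_frames = 120,
                                  dt = 0.1, box = c(20, 20, 20), seed = 19))
  un <- unwrap_trajectory(g$trajectory)
  # unwrapped coordinates agree with the generator's pre-wrap record up to a
  # constant per-particle offset (the initial wrap)
  diff0 <- un$xyz[, , 1] - g$truth$unwrapped[, , 1]
  for (f in c(2, 60, 120))
    expect_equal(un$xyz[, , f] - g$truth$unwrapped[, , f], diff0,
                 tolerance = 1e-9)
})

test_that("unwrapped Brownian increments match the planted variance", {
  d_true <- 2.0; dt <- 0.1
  g <- gen_brownian(brownian_spec(d_true, n_particles = 300, n_frames = 150,
                                  dt = dt, seed = 23))
  un <- unwrap_trajectory(g$trajectory)
  inc <- un$xyz[, , -1] - un$xyz[, , -150]
  v <- var(as.vector(inc))
  se <- (2 * d_true * dt) * sqrt(2 / length(inc))
  expect_lt(abs(v - 2 * d_true * dt), 3 * se)
})

test_that("reference drift removal is exact for rigid translations", {
  g <- gen_brownian(brownian_spec(1.0, n_particles = 20, n_frames = 40,
                                  dt = 0.1, seed = 3))
  un <- unwrap_trajectory(g$trajectory)
  # translate every frame by a different offset: MSDs relative to any group
  # must vanish after alignment to the full system
  drifted <- un
  for (f in seq_len(n_frames(un)))
    drifted$xyz[, , f] <- sweep(un$xyz[, , f], 2, c(0.3, -0.1, 0.2) * f, "+")
  aligned <- remove_reference_drift(drifted, seq_len(20))
  still <- remove_reference_drift(un, seq_len(20))
  # alignment anchors to frame 1, so a constant offset may remain; all
  # displacements (hence every MSD) must coincide exactly
  off <- aligned$xyz[, , 1] - still$xyz[, , 1]
  for (f in c(1, 10, 40))
    expect_equal(aligned$xyz[, , f] - still$xyz[, , f], off,
                 tolerance = 1e-9)

  # a reference at rest changes nothing
  st <- wall_structure(data.frame(
    elety = rep("OW", 3), element = "O", mass = 18.02, component = "water",
    group = "none", resid = 1:3, site_head = FALSE))
  xyz <- array(runif(3 * 3 * 5), dim = c(3, 3, 5))
  xyz[1, , ] <- 2  # atom 1 at rest
  tr <- wall_trajectory(st, xyz, c(10, 10, 10), dt = 1, wrapped = FALSE)
  expect_equal(remove_reference_drift(tr, 1)$xyz, xyz)
  expect_error(remove_reference_drift(tr, integer()), "empty")
})

test_that("drift removal recovers the diffusion coefficient of tracers", {
  d_true <- 0.62
  g <- gen_brownian(brownian_spec(d_true, n_particles = 300, n_frames = 800,
                                  dt = 0.1, seed = 31))
  un <- unwrap_trajectory(g$trajectory)
  np <- 300
  # append a 10-atom rigid reference that drifts linearly
  ref_struct <- data.frame(
    elety = "C1", element = "C", mass = 12.011, component = "cellulose",
    group = "none", resid = np + (1:10), site_head = FALSE)
  atoms <- rbind(un$structure$atoms, ref_struct)
  nf <- n_frames(un)
  xyz <- array(0, dim = c(np + 10, 3, nf))
  drift_rate <- c(0.05, -0.02, 0.01)  # A per frame
  ref0 <- matrix(seq_len(10) * 2, 10, 3)
  for (f in seq_len(nf)) {
    shift <- drift_rate * (f - 1)
    xyz[1:np, , f] <- sweep(un$xyz[, , f], 2, shift, "+")
    xyz[np + (1:10), , f] <- sweep(ref0, 2, shift, "+")
  }
  tr <- wall_trajectory(wall_structure(atoms), xyz, un$box, dt = 0.1,
                        wrapped = FALSE)
  aligned <- remove_reference_drift(tr, np + (1:10))
  est <- diffusion_linear(msd_time_averaged(aligned, 1:np))
  expect_lt(abs(est$d_a2ns - d_true) / d_true, 0.05)
})

test_that("fixed-origin MSD matches closed forms", {
  st <- wall_structure(data.frame(
    elety = "OW", element = "O", mass = 18.02, component = "water",
    group = "none", resid = 1, site_head = FALSE))
  # stationary: all zeros
  xyz <- array(rep(c(1, 2, 3), 10), dim = c(1, 3, 10))
  tr <- wall_trajectory(st, xyz, c(50, 50, 50), dt = 1, wrapped = FALSE)
  m <- msd_fixed_origin(tr, 1, t_ref = 0)
  expect_true(all(m$msd == 0))

  # ballistic motion at 1 A/ns: MSD(t) = t^2
  xyz2 <- array(0, dim = c(1, 3, 10))
  xyz2[1, 1, ] <- 0:9
  tr2 <- wall_trajectory(st, xyz2, c(100, 100, 100), dt = 1, wrapped = FALSE)
  m2 <- msd_fixed_origin(tr2, 1, t_ref = 0)
  expect_equal(m2$msd, m2$lag^2)

  expect_error(msd_fixed_origin(tr2, integer()), "empty")
  expect_error(msd_fixed_origin(tr2, 1, t_ref = 100), "beyond")
})

test_that("the linear estimator reads the slope exactly on synthetic MSD", {
  msd <- data.frame(time = 0:50, lag = 0:50, msd = 36 * (0:50))
  class(msd) <- c("wall_msd", "data.frame")
  est <- diffusion_linear(msd)
  expect_equal(est$d_a2ns, 6)
  expect_equal(est$d_cm2s, 6e-7)
  expect_equal(est$r_squared, 1)

  flat <- data.frame(time = 0:50, lag = 0:50, msd = rep(0, 51))
  class(flat) <- c("wall_msd", "data.frame")
  expect_equal(diffusion_linear(flat)$d_a2ns, 0)
})

test_that("the sliding-window estimator is zero for frozen groups and equals the single-interval form at full window", {
  g <- gen_brownian(brownian_spec(0, n_particles = 10, n_frames = 50,
                                  dt = 0.1, seed = 5))
  un <- unwrap_trajectory(g$trajectory)
  expect_equal(diffusion_sliding(un, 1:10, window = 2)$d_a2ns, 0)

  g2 <- gen_brownian(brownian_spec(3.0, n_particles = 40, n_frames = 60,
                                   dt = 0.1, seed = 6))
  un2 <- unwrap_trajectory(g2$trajectory)
  span <- (n_frames(un2) - 1) * un2$dt
  sli <- diffusion_sliding(un2, 1:40, window = span)
  d <- un2$xyz[, , 60] - un2$xyz[, , 1]
  expect_equal(sli$d_a2ns, mean(rowSums(d * d)) / (6 * span),
               tolerance = 1e-12)
})

test_that("the sliding-window estimator recovers a planted coefficient", {
  d_true <- 6.1
  g <- gen_brownian(brownian_spec(d_true, n_particles = 300, n_frames = 500,
                                  dt = 0.1, seed = 7))
  un <- unwrap_trajectory(g$trajectory)
  sli <- diffusion_sliding(un, 1:300, window = 5)
  expect_lt(abs(sli$d_a2ns - d_true) / d_true, 0.10)
  expect_true(is.finite(sli$se_a2ns) && sli$se_a2ns > 0)
})

test_that("estimates are invariant to whole-system drift after alignment", {
  g <- gen_brownian(brownian_spec(2.0, n_particles = 50, n_frames = 100,
                                  dt = 0.1, seed = 9))
  un <- unwrap_trajectory(g$trajectory)
  base <- remove_reference_drift(un, 1:50)
  shifted <- un
  for (f in seq_len(n_frames(un)))
    shifted$xyz[, , f] <- sweep(un$xyz[, , f], 2, c(1, 2, -1) * f, "+")
  shifted <- remove_reference_drift(shifted, 1:50)
  m1 <- msd_fixed_origin(base, 1:50)
  m2 <- msd_fixed_origin(shifted, 1:50)
  expect_equal(m1$msd, m2$msd, tolerance = 1e-9)
  s1 <- diffusion_sliding(base, 1:50, window = 2)
  s2 <- diffusion_sliding(shifted, 1:50, window = 2)
  expect_equal(s1$d_a2ns, s2$d_a2ns, tolerance = 1e-9)
})

test_that("block errors follow the block-mean formula", {
  expect_equal(block_error(c(5, 5, 5, 5), n_blocks = 2), 0)
  expect_equal(block_error(c(1, 3)), 1)  # sd sqrt(2) over sqrt(2) blocks
  expect_error(block_error(5, n_blocks = 1), "2 blocks")
  # Monte-Carlo: 19 blocks of unit-variance draws give se near 1/sqrt(19)
  withr::with_seed(41, {
    ses <- replicate(200, block_error(rnorm(19), n_blocks = 19))
    expect_lt(abs(mean(ses) - 1 / sqrt(19)), 3 * sd(ses) / sqrt(200))
    expect_true(all(ses < 3 / sqrt(19)))
  })
})
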