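test_that("the switching weight has the documented shape", {
  expect_equal(switching_weight(5), 0.5)          # midpoint
  expect_equal(switching_weight(4), 1 / (1 + exp(-5)))  # 0.9933071
  d <- seq(0, 12, by = 0.1)
  expect_true(all(diff(switching_weight(d)) < 0))  # strictly decreasing
  expect_true(all(switching_weight(d) > 0 & switching_weight(d) < 1))
})

test_that("contact scores evaluate single pairs exactly", {
  box <- c(50, 50, 50)
  co <- rbind(c(10, 10, 10), c(15, 10, 10), c(14, 10, 10))
  expect_equal(contact_score(co, box, 1, 2), 0.5)
  expect_equal(contact_score(co, box, 1, 3), 1 / (1 + exp(-5)),
               tolerance = 1e-12)
  expect_error(contact_score(co, box, integer(), 1), "nonempty")
})

test_that("contact scores match the untruncated brute force within 1e-9", {
  withr::with_seed(12, {
    n <- 200
    box <- c(30, 30, 30)
    co <- cbind(runif(n, 0, 30), runif(n, 0, 30), runif(n, 0, 30))
    ia <- 1:80; ib <- 81:200
    got <- contact_score(co, box, ia, ib)
    want <- oracle_contact(co, box, ia, ib)
    expect_lt(abs(got - want), 1e-9)
  })
})

test_that("contact scores are invariant under rigid translation and rewrapping", {
  withr::with_seed(14, {
    box <- c(25, 25, 25)
    co <- cbind(runif(60, 0, 25), runif(60, 0, 25), runif(60, 0, 25))
    base <- contact_score(co, box, 1:30, 31:60)
    shift <- c(11.3, -7.2, 40.9)
    co2 <- sweep(co, 2, shift, "+") %% matrix(box, 60, 3, byrow = TRUE)
    expect_equal(contact_score(co2, box, 1:30, 31:60), base,
                 tolerance = 1e-9)
  })
})

test_that("contact time series report one score per frame and honour equilibration", {
  # ion held 3 A from a carboxyl oxygen: constant weight 1/(1+e^-10)
  st <- wall_structure(rbind(
    data.frame(elety = "CX", element = "C", mass = 12.011,
               component = "hemicellulose", group = "carboxyl", resid = 1,
               site_head = TRUE),
    data.frame(elety = "SOD", element = "NA.", mass = 22.99,
               component = "ion", group = "none", resid = 2,
               site_head = FALSE)))
  nf <- 8
  xyz <- array(0, dim = c(2, 3, nf))
  xyz[1, , ] <- 20; xyz[2, , ] <- c(23, 20, 20)
  tr <- wall_trajectory(st, xyz, c(60, 60, 60), dt = 1)
  ts <- group_contact_timeseries(tr, list(ion_carboxyl = list(a = 2, b = 1)))
  expect_equal(nrow(ts), nf)
  expect_equal(unique(ts$score), 1 / (1 + exp(-10)), tolerance = 1e-12)
  expect_error(group_contact_timeseries(tr, list(p = list(a = 2, b = 1)),
                                        frames = integer()), "empty")
})

test_that("interaction probabilities normalise scores by abundance", {
  p <- interaction_probability(c(acetyl = 100, carboxyl = 30),
                               c(acetyl = 50, carboxyl = 10))
  # per-site scores 2 and 3 -> ratio 2/3
  expect_equal(p[["acetyl"]] / p[["carboxyl"]], 2 / 3)
  expect_equal(sum(p), 1)
  p2 <- interaction_probability(c(a = 4, b = 8), c(a = 1, b = 2))
  expect_equal(p2[["a"]] / p2[["b"]], 1)
  expect_error(interaction_probability(c(a = 1), c(a = 0)), "abundance")
})

test_that("free-energy differences follow -RT log ratios", {
  expect_identical(delta_g(0.2, 0.2), 0)
  # -RT ln 0.5 at 300 K with R = 1.987204e-3
  expect_equal(delta_g(0.1, 0.2, 300), 0.4132275, tolerance = 1e-6)
  expect_error(delta_g(0, 0.5), "not estimable")
  expect_error(delta_g(0.5, 0), "not estimable")
})

test_that("free-energy error propagation matches the quadrature formula", {
  expect_equal(delta_g_error(0.5, 0, 0.5, 0), 0)
  # relative errors 0.1 and 0.1: RT * sqrt(0.02) = 0.0843099
  expect_equal(delta_g_error(1, 0.1, 1, 0.1, 300),
               wall_constants(300)$RT * sqrt(0.02), tolerance = 1e-12)
  one <- delta_g_error(0.4, 0.02, 0.2, 0.01)
  two <- delta_g_error(0.4, 0.04, 0.2, 0.02)
  expect_equal(two, 2 * one)
  expect_error(delta_g_error(0, 0.1, 1, 0.1), "probabilities")
})

test_that("the RDF of an ideal gas is flat at unity", {
  # bin populations are kept high (dense uniform gas, 0.5 A bins) so the
  # 0.02 band sits several standard errors out
  withr::with_seed(3, {
    box <- c(20, 20, 20)
    nf <- 12
    n_c <- 400; n_t <- 4000
    st <- wall_structure(data.frame(
      elety = "OW", element = "O", mass = 18.02, component = "water",
      group = "none", resid = seq_len(n_c + n_t), site_head = FALSE))
    xyz <- array(runif((n_c + n_t) * 3 * nf, 0, 20),
                 dim = c(n_c + n_t, 3, nf))
    tr <- wall_trajectory(st, xyz, box, dt = 1)
    prof <- rdf(tr, seq_len(n_c), n_c + seq_len(n_t), r_max = 10,
                bin_width = 0.5)
    keep <- prof$r > 1
    expect_true(all(abs(prof$g[keep] - 1) < 0.02))
  })
})

test_that("ideal-gas RDF noise shrinks with sample size", {
  mad_of <- function(n_t, nf, seed) {
    withr::with_seed(seed, {
      box <- c(30, 30, 30)
      st <- wall_structure(data.frame(
        elety = "OW", element = "O", mass = 18.02, component = "water",
        group = "none", resid = seq_len(20 + n_t), site_head = FALSE))
      xyz <- array(runif((20 + n_t) * 3 * nf, 0, 30),
                   dim = c(20 + n_t, 3, nf))
      tr <- wall_trajectory(st, xyz, box, dt = 1)
      prof <- rdf(tr, 1:20, 20 + seq_len(n_t), r_max = 10, bin_width = 0.25)
      mean(abs(prof$g[prof$r > 1] - 1))
    })
  }
  expect_lt(mad_of(100, 40, 8), mad_of(100, 10, 8))
})

test_that("a clamped pair occupies a single RDF bin with coordination one", {
  st <- wall_structure(data.frame(
    elety = c("OW", "OW"), element = "O", mass = 18.02, component = "water",
    group = "none", resid = 1:2, site_head = FALSE))
  xyz <- array(0, dim = c(2, 3, 5))
  xyz[1, , ] <- 10; xyz[2, , ] <- c(13, 10, 10)
  tr <- wall_trajectory(st, xyz, c(40, 40, 40), dt = 1)
  prof <- rdf(tr, 1, 2, r_max = 10, bin_width = 0.2)
  occupied <- which(prof$mean_counts > 0)
  expect_length(occupied, 1)
  expect_equal(prof$r[occupied], 3.1)  # bin centred at 3.0-3.2
  integ <- integrate_rdf_to_first_minimum(prof, r_min = 5)
  expect_equal(integ$coordination, 1)
})

test_that("RDF integration to r_max reproduces a direct neighbour count", {
  withr::with_seed(9, {
    box <- c(24, 24, 24)
    n <- 120; nf <- 10
    st <- wall_structure(data.frame(
      elety = "OW", element = "O", mass = 18.02, component = "water",
      group = "none", resid = seq_len(n), site_head = FALSE))
    xyz <- array(runif(n * 3 * nf, 0, 24), dim = c(n, 3, nf))
    tr <- wall_trajectory(st, xyz, box, dt = 1)
    centers <- 1:30; targets <- 31:120
    prof <- rdf(tr, centers, targets, r_max = 10, bin_width = 0.25)
    # direct mean count of targets within r_max per center per frame
    direct <- 0
    for (f in seq_len(nf)) {
      for (ci in centers) {
        d <- vapply(targets, function(tj)
          oracle_min_dist(xyz[ci, , f], xyz[tj, , f], box), numeric(1))
        direct <- direct + sum(d < 10)
      }
    }
    direct <- direct / (nf * length(centers))
    expect_equal(sum(prof$mean_counts), direct, tolerance = 1e-9)
  })
})

test_that("first-minimum detection integrates a constructed profile only to 3.5 A", {
  r <- seq(0.1, 9.9, by = 0.2)
  g <- exp(-((r - 2.5) / 0.6)^2) * 3 + exp(-((r - 5.5) / 1.2)^2) * 1.2
  prof <- structure(list(r = r, g = g, mean_counts = rep(1, length(r)),
                         bin_width = 0.2, r_max = 10, n_frames = 1,
                         n_centers = 1, n_targets = 1), class = "wall_rdf")
  integ <- integrate_rdf_to_first_minimum(prof)
  expect_equal(integ$r_min, 3.9, tolerance = 0.45)
  expect_equal(integ$coordination, sum(r <= integ$r_min))
  # a monotone profile has no minimum: error unless a radius is supplied
  mono <- prof; mono$g <- rev(sort(g))
  expect_error(integrate_rdf_to_first_minimum(mono), "no first minimum")
  expect_equal(integrate_rdf_to_first_minimum(mono, r_min = 3)$r_min, 3)
})

test_that("dwell runs are censored at both trajectory ends", {
  tr <- binary_dwell_trajectory(c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE))
  dw <- dwell_times(tr, ions = 2, sites = 1, cutoff = 6)
  expect_equal(sort(dw$duration_ns), c(0.4, 0.6))
  # the first run touches the start, the second the end: both censored
  expect_true(all(dw$censored))

  tr2 <- binary_dwell_trajectory(c(FALSE, TRUE, TRUE, FALSE))
  dw2 <- dwell_times(tr2, ions = 2, sites = 1, cutoff = 6)
  expect_equal(dw2$duration_ns, 0.4)
  expect_false(dw2$censored)

  tr3 <- binary_dwell_trajectory(rep(FALSE, 5))
  expect_equal(nrow(dwell_times(tr3, ions = 2, sites = 1, cutoff = 6)), 0)
})

test_that("the run-length coder agrees with a brute-force scan on random series", {
  withr::with_seed(27, {
    for (rep in 1:10) {
      series <- runif(60) < 0.4
      tr <- binary_dwell_trajectory(series)
      dw <- dwell_times(tr, ions = 2, sites = 1, cutoff = 6)
      want <- oracle_runs(series, 0.2)
      expect_equal(dw$duration_ns, want$duration_ns)
      expect_equal(dw$censored, want$censored)
    }
  })
})

test_that("dwell estimation recovers the generator's mean bound time", {
  g <- gen_binding(binding_spec(n_sites = 16, n_ions = 40, mean_bound = 10,
                                mean_unbound = 2, n_frames = 2000, dt = 0.2,
                                seed = 2))
  dw <- dwell_times(g$trajectory, g$truth$ion_index, g$truth$site_index,
                    cutoff = 6)
  est <- mean(dw$duration_ns[!dw$censored])
  truth <- g$truth$bound_runs
  expect_equal(est, mean(truth$duration_ns[!truth$censored]),
               tolerance = 1e-12)
})

test_that("the time-weighted CDF weights events by their duration", {
  cdf <- time_weighted_cdf(c(1, 1, 8))
  expect_equal(max(cdf$cdf[cdf$duration <= 1]), 0.2)
  expect_equal(max(cdf$cdf), 1.0)
  # equal durations: time weighting reduces to the ordinary empirical CDF
  cdf2 <- time_weighted_cdf(rep(2.5, 4))
  expect_equal(cdf2$cdf, (1:4) / 4)
  expect_error(time_weighted_cdf(numeric()), "empty")
  # brute-force comparison on random durations
  withr::with_seed(5, {
    d <- runif(50, 0.2, 20)
    got <- time_weighted_cdf(d)
    s <- sort(d)
    expect_equal(got$duration, s)
    expect_equal(got$cdf, cumsum(s) / sum(s), tolerance = 1e-12)
  })
})

test_that("free-energy tables recover planted offsets by both routes", {
  bz <- boltzmann_fixture(1.18, 2.26, seed = 1)
  tab <- binding_free_energy_table(bz$trajectory,
                                   atom_select(bz$trajectory,
                                               component = "ion"))
  ref <- tab[tab$group == "carboxyl", ]
  expect_true(all(ref$delta_g == 0))
  expect_true(all(ref$sigma == 0))
  for (g in c("acetyl", "hydroxyl")) {
    planted <- bz$truth$delta_g[[g]]
    for (m in c("atom_pair", "rdf")) {
      row <- tab[tab$group == g & tab$method == m, ]
      expect_lt(abs(row$delta_g - planted), 2 * row$sigma)
    }
    ap <- tab[tab$group == g & tab$method == "atom_pair", ]
    rd <- tab[tab$group == g & tab$method == "rdf", ]
    expect_lt(abs(ap$delta_g - rd$delta_g),
              2 * sqrt(ap$sigma^2 + rd$sigma^2) + 1e-12)
  }
})

test_that("contact score ratios track the planted occupancy ratio", {
  bz <- boltzmann_fixture(1.18, 2.26, seed = 10, n_frames = 150)
  tr <- bz$trajectory
  ions <- atom_select(tr, component = "ion")
  ts <- group_contact_timeseries(tr, list(
    acetyl = list(a = ions, b = atom_select(tr, group = "acetyl")),
    carboxyl = list(a = ions, b = atom_select(tr, group = "carboxyl"))))
  m <- tapply(ts$score, ts$pair, mean)
  per_site_ratio <- (m[["acetyl"]] / 240) / (m[["carboxyl"]] / 60)
  expect_equal(per_site_ratio, exp(-1.18 / wall_constants(300)$RT),
               tolerance = 0.1)
})
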