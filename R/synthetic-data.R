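## Seeded generators producing trajectories with machine-readable ground
## truth. These are statistical stand-ins for microsecond MD data: no force
## field, no excluded volume, no electrostatics. Each emulates exactly the
## statistical structure one downstream estimator assumes.

random_unit_vectors <- function(n) {
  v <- matrix(stats::rnorm(3 * n), ncol = 3)
  v / sqrt(rowSums(v^2))
}

# n points on a cubic grid with given spacing, centred in a cube; returns the
# positions and the enclosing box.
grid_positions <- function(n, spacing) {
  k <- ceiling(n^(1 / 3))
  idx <- seq_len(n) - 1L
  pos <- cbind(idx %% k, (idx %/% k) %% k, idx %/% (k * k)) * spacing +
    spacing / 2
  list(pos = pos, box = rep(k * spacing, 3))
}

tracer_structure <- function(n, component = "water", element = "O",
                             mass = 18.02) {
  wall_structure(data.frame(
    elety = paste0(element, "W"), element = element, mass = mass,
    component = component, group = "none", resid = seq_len(n),
    site_head = FALSE))
}

#' Specification for a free-diffusion (Brownian) trajectory
#'
#' Independent Gaussian random walks with per-step per-dimension displacement
#' variance 2 * D * dt, wrapped into a periodic box. Used to validate the MSD
#' and sliding-window diffusion estimators against a known coefficient.
#'
#' @param d_true true diffusion coefficient, Angstrom^2/ns.
#' @param n_particles number of independent tracers.
#' @param n_frames number of frames.
#' @param dt frame interval, ns.
#' @param box length-3 box vector, Angstrom.
#' @param seed RNG seed.
#' @return a `brownian_spec` list.
#' @export
brownian_spec <- function(d_true, n_particles = 500, n_frames = 1000,
                          dt = 0.1, box = c(50, 50, 50), seed = 1) {
  stopifnot(is.finite(d_true), d_true >= 0, n_particles >= 1, n_frames >= 2,
            dt > 0, all(is.finite(box)), all(box > 0))
  structure(list(d_true = d_true, n_particles = n_particles,
                 n_frames = n_frames, dt = dt, box = box, seed = seed),
            class = "brownian_spec")
}

#' Generate a Brownian tracer trajectory with known diffusion coefficient
#'
#' @param spec a [brownian_spec()].
#' @return list with elements `trajectory` (wrapped coordinates) and `truth`
#'   (`d_true` in Angstrom^2/ns and the unwrapped coordinate array).
#' @export
gen_brownian <- function(spec) {
  stopifnot(inherits(spec, "brownian_spec"))
  withr::with_seed(spec$seed, {
    np <- spec$n_particles; nf <- spec$n_frames
    sd_step <- sqrt(2 * spec$d_true * spec$dt)
    xyz <- array(0, dim = c(np, 3, nf))
    xyz[, , 1] <- cbind(stats::runif(np, 0, spec$box[1]),
                        stats::runif(np, 0, spec$box[2]),
                        stats::runif(np, 0, spec$box[3]))
    if (nf > 1 && sd_step > 0) {
      steps <- array(stats::rnorm(np * 3 * (nf - 1), sd = sd_step),
                     dim = c(np, 3, nf - 1))
      for (f in 2:nf) xyz[, , f] <- xyz[, , f - 1] + steps[, , f - 1]
    } else if (nf > 1) {
      for (f in 2:nf) xyz[, , f] <- xyz[, , 1]
    }
    unwrapped <- xyz
    for (f in seq_len(nf)) {
      b <- matrix(spec$box, np, 3, byrow = TRUE)
      xyz[, , f] <- xyz[, , f] - b * floor(xyz[, , f] / b)
    }
    traj <- wall_trajectory(tracer_structure(np), xyz, spec$box,
                            dt = spec$dt, equilibration = 0)
    list(trajectory = traj,
         truth = list(d_true = spec$d_true, unwrapped = unwrapped))
  })
}

#' Specification for a two-state ion-binding trajectory
#'
#' Ions alternate between a bound state (within `contact_radius` of a home
#' site) and an unbound state (far from every site) following a two-state
#' Markov chain with geometric run lengths, so the mean dwell in each state is
#' known. Dwell means are in ns and converted to per-frame leave probabilities
#' by the frame interval.
#'
#' @param n_sites number of binding sites (placed on a grid).
#' @param n_ions number of ions; each is assigned a home site.
#' @param mean_bound,mean_unbound mean dwell times, ns (`mean_unbound = 0`
#'   keeps ions permanently bound).
#' @param contact_radius maximum bound-state ion-site distance, Angstrom.
#' @param n_frames,dt frame count and interval (ns).
#' @param spacing site grid spacing, Angstrom.
#' @param seed RNG seed.
#' @return a `binding_spec` list.
#' @export
binding_spec <- function(n_sites = 25, n_ions = 50, mean_bound = 10,
                         mean_unbound = 2, contact_radius = 2.5,
                         n_frames = 2000, dt = 0.2, spacing = 20, seed = 1) {
  stopifnot(mean_bound > 0, mean_unbound >= 0, contact_radius > 0,
            n_frames >= 2, dt > 0)
  far <- spacing * sqrt(3) / 2
  if (far <= max(6, contact_radius))
    stop("site spacing too small: the unbound position (", round(far, 1),
         " A from the nearest site) cannot be placed outside the contact shell")
  structure(list(n_sites = n_sites, n_ions = n_ions, mean_bound = mean_bound,
                 mean_unbound = mean_unbound, contact_radius = contact_radius,
                 n_frames = n_frames, dt = dt, spacing = spacing, seed = seed),
            class = "binding_spec")
}

#' Generate an ion-binding trajectory with known dwell-time law
#'
#' @param spec a [binding_spec()].
#' @return list with `trajectory` (sites labelled as carboxyl heads on
#'   hemicellulose, plus ions) and `truth` (`bound_runs`: data.frame of true
#'   bound-run durations in ns per ion with censoring flags; `mean_bound`,
#'   `site_index`, `ion_index`).
#' @export
gen_binding <- function(spec) {
  stopifnot(inherits(spec, "binding_spec"))
  withr::with_seed(spec$seed, {
    g <- grid_positions(spec$n_sites, spec$spacing)
    nf <- spec$n_frames
    ns <- spec$n_sites; ni <- spec$n_ions
    home <- rep_len(seq_len(ns), ni)
    q_b <- min(1, spec$dt / spec$mean_bound)
    q_u <- if (spec$mean_unbound > 0) min(1, spec$dt / spec$mean_unbound) else 1
    always_bound <- spec$mean_unbound == 0
    state <- matrix(TRUE, ni, nf)  # TRUE = bound
    runs <- vector("list", ni)
    for (i in seq_len(ni)) {
      if (always_bound) {
        runs[[i]] <- data.frame(ion = i, duration_ns = nf * spec$dt,
                                censored = TRUE)
        next
      }
      s <- logical(0)
      bound <- stats::runif(1) < spec$mean_bound /
        (spec$mean_bound + spec$mean_unbound)
      while (length(s) < nf) {
        len <- stats::rgeom(1, if (bound) q_b else q_u) + 1L
        s <- c(s, rep(bound, len))
        bound <- !bound
      }
      state[i, ] <- s[seq_len(nf)]
      r <- rle(state[i, ])
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      keep <- r$values
      runs[[i]] <- data.frame(
        ion = i,
        duration_ns = r$lengths[keep] * spec$dt,
        censored = (starts[keep] == 1L) | (ends[keep] == nf))
    }
    nat <- ns + ni
    site_struct <- data.frame(
      elety = "CX", element = "C", mass = 12.011,
      component = "hemicellulose", group = "carboxyl",
      resid = seq_len(ns), site_head = TRUE)
    ion_struct <- data.frame(
      elety = "SOD", element = "NA.", mass = 22.990,
      component = "ion", group = "none",
      resid = ns + seq_len(ni), site_head = FALSE)
    struct <- wall_structure(rbind(site_struct, ion_struct))
    xyz <- array(0, dim = c(nat, 3, nf))
    far_off <- rep(spec$spacing / 2, 3)
    for (f in seq_len(nf)) {
      xyz[seq_len(ns), , f] <- g$pos
      b <- state[, f]
      pos <- g$pos[home, , drop = FALSE] +
        matrix(far_off, ni, 3, byrow = TRUE)
      nb <- sum(b)
      if (nb > 0)
        pos[b, ] <- g$pos[home[b], , drop = FALSE] +
          random_unit_vectors(nb) * stats::runif(nb, 0.5, spec$contact_radius)
      xyz[ns + seq_len(ni), , f] <- pos
    }
    traj <- wall_trajectory(struct, xyz, g$box, dt = spec$dt,
                            equilibration = 0)
    list(trajectory = traj,
         truth = list(bound_runs = do.call(rbind, runs),
                      mean_bound = spec$mean_bound,
                      state = state,
                      site_index = seq_len(ns),
                      ion_index = ns + seq_len(ni)))
  })
}

#' Specification for Boltzmann-weighted site occupancy
#'
#' Each frame, every ion independently occupies a site of type s with
#' probability proportional to count_s * exp(-E_s / RT), then sits within 3
#' Angstrom of that site so contact and RDF analyses register the occupancy.
#' Occupancy is resampled independently per frame (no kinetics): this fixture
#' validates the thermodynamic estimators, while [gen_binding()] validates the
#' kinetic ones.
#'
#' @param site_types data.frame with columns `group` (functional-group label),
#'   `count`, and `energy` (kcal/mol, offsets relative to the reference
#'   group).
#' @param n_ions,n_frames ions and frames.
#' @param temperature Kelvin.
#' @param dt frame interval, ns.
#' @param spacing site grid spacing, Angstrom (large enough that an ion's
#'   contact weight with any non-occupied site is negligible).
#' @param seed RNG seed.
#' @return a `boltzmann_site_spec` list.
#' @export
boltzmann_site_spec <- function(site_types, n_ions = 120, n_frames = 400,
                                temperature = 300, dt = 0.2, spacing = 20,
                                seed = 1) {
  stopifnot(is.data.frame(site_types),
            all(c("group", "count", "energy") %in% names(site_types)),
            all(is.finite(site_types$energy)), all(site_types$count >= 1),
            n_ions >= 1, n_frames >= 1)
  if (sum(site_types$count) == 0) stop("zero total sites")
  structure(list(site_types = site_types, n_ions = n_ions,
                 n_frames = n_frames, temperature = temperature, dt = dt,
                 spacing = spacing, seed = seed),
            class = "boltzmann_site_spec")
}

#' Generate ion configurations with Boltzmann-weighted site occupancy
#'
#' @param spec a [boltzmann_site_spec()].
#' @return list with `trajectory` and `truth` (`delta_g`: named vector of
#'   planted free-energy offsets, `occupancy`: n_ions x n_frames matrix of
#'   occupied group labels, `ion_index`, per-group site indices).
#' @export
gen_boltzmann_sites <- function(spec) {
  stopifnot(inherits(spec, "boltzmann_site_spec"))
  withr::with_seed(spec$seed, {
    st <- spec$site_types
    rt <- wall_constants(spec$temperature)$RT
    ns <- sum(st$count); ni <- spec$n_ions; nf <- spec$n_frames
    g <- grid_positions(ns, spec$spacing)
    type_of_site <- rep(seq_len(nrow(st)), st$count)
    w <- st$count * exp(-st$energy / rt)
    site_struct <- data.frame(
      elety = "STE", element = "O", mass = 15.999,
      component = "hemicellulose", group = st$group[type_of_site],
      resid = seq_len(ns), site_head = TRUE)
    ion_struct <- data.frame(
      elety = "SOD", element = "NA.", mass = 22.990,
      component = "ion", group = "none",
      resid = ns + seq_len(ni), site_head = FALSE)
    struct <- wall_structure(rbind(site_struct, ion_struct))
    xyz <- array(0, dim = c(ns + ni, 3, nf))
    occ <- matrix(NA_character_, ni, nf)
    sites_by_type <- split(seq_len(ns), type_of_site)
    for (f in seq_len(nf)) {
      xyz[seq_len(ns), , f] <- g$pos
      ty <- sample.int(nrow(st), ni, replace = TRUE, prob = w)
      occ[, f] <- st$group[ty]
      site <- vapply(ty, function(t) {
        s <- sites_by_type[[t]]
        s[sample.int(length(s), 1)]
      }, integer(1))
      xyz[ns + seq_len(ni), , f] <- g$pos[site, , drop = FALSE] +
        random_unit_vectors(ni) * stats::runif(ni, 2, 3)
    }
    traj <- wall_trajectory(struct, xyz, g$box, dt = spec$dt,
                            equilibration = 0)
    sites <- lapply(split(seq_len(ns), st$group[type_of_site]), identity)
    list(trajectory = traj,
         truth = list(delta_g = stats::setNames(st$energy, st$group),
                      occupancy = occ,
                      ion_index = ns + seq_len(ni),
                      site_index = sites))
  })
}

#' Specification for a toy cell-wall configuration
#'
#' Polymer bead chains carrying hydroxyl and carboxyl sites, waters split by
#' construction into a bound shell (< 5 Angstrom from polymer) and a distant
#' bulk cloud, and optional ions. Every hydroxyl's distance to its nearest
#' water is known exactly, which exercises exposure selection, contact, RDF
#' and water-pocket code against constructed truth.
#'
#' @param n_chains,chain_length polymer chains (alternating lignin and
#'   hemicellulose) and beads per chain.
#' @param hydroxyl_every place a hydroxyl (O + H) on every k-th bead.
#' @param n_carboxyl number of carboxyl sites (C + 2 O) placed on beads.
#' @param n_bound_water waters placed 2.8-4.2 Angstrom from a polymer bead.
#' @param n_bulk_water waters placed in a cloud at least 12 Angstrom from
#'   every polymer atom.
#' @param n_ions ions placed in the bulk region.
#' @param exposure_distances optional numeric vector; for each value an
#'   isolated hydroxyl-water pair at exactly that separation is added, far
#'   from everything else.
#' @param seed RNG seed.
#' @return a `toy_cellwall_spec` list.
#' @export
toy_cellwall_spec <- function(n_chains = 4, chain_length = 20,
                              hydroxyl_every = 2, n_carboxyl = 4,
                              n_bound_water = 10, n_bulk_water = 10,
                              n_ions = 0, exposure_distances = NULL,
                              seed = 1) {
  stopifnot(n_chains >= 1, chain_length >= 2, hydroxyl_every >= 1,
            n_carboxyl >= 0, n_bound_water >= 0, n_bulk_water >= 0)
  structure(list(n_chains = n_chains, chain_length = chain_length,
                 hydroxyl_every = hydroxyl_every, n_carboxyl = n_carboxyl,
                 n_bound_water = n_bound_water, n_bulk_water = n_bulk_water,
                 n_ions = n_ions, exposure_distances = exposure_distances,
                 seed = seed),
            class = "toy_cellwall_spec")
}

#' Generate a toy cell-wall configuration with constructed ground truth
#'
#' @param spec a [toy_cellwall_spec()].
#' @return list with `trajectory` (single frame), `structure`, and `truth`
#'   (`hydroxyl_heads`, `nearest_water` distance per hydroxyl head,
#'   `water_resids`, `water_is_bulk`, `bulk_fraction_pct`).
#' @export
gen_toy_cellwall <- function(spec) {
  stopifnot(inherits(spec, "toy_cellwall_spec"))
  withr::with_seed(spec$seed, {
    rows <- list(); pos <- list(); resid <- 0L
    add <- function(elety, element, mass, component, group, head, xyz) {
      rows[[length(rows) + 1]] <<- data.frame(
        elety = elety, element = element, mass = mass, component = component,
        group = group, resid = resid, site_head = head)
      pos[[length(pos) + 1]] <<- xyz
    }
    bead_xyz <- list()
    # polymer slab
    for (ch in seq_len(spec$n_chains)) {
      comp <- if (ch %% 2) "lignin" else "hemicellulose"
      y <- 5 + 4 * (ch - 1)
      for (b in seq_len(spec$chain_length)) {
        resid <- resid + 1L
        p <- c(5 + 1.5 * (b - 1), y, 8)
        add("C1", "C", 12.011, comp, "none", FALSE, p)
        bead_xyz[[length(bead_xyz) + 1]] <- p
        if (b %% spec$hydroxyl_every == 0) {
          o <- p + c(0, 0, 1.4)
          add("OH1", "O", 15.999, comp, "hydroxyl", TRUE, o)
          add("HO1", "H", 1.008, comp, "hydroxyl", FALSE, o + c(0, 0, 0.96))
        }
      }
    }
    # carboxyls on the first hemicellulose chain
    n_cx <- spec$n_carboxyl
    if (n_cx > 0) {
      for (k in seq_len(n_cx)) {
        resid <- resid + 1L
        p <- c(5 + 3 * (k - 1), 5 + 4 * 1 - 2, 9.5)
        add("CX", "C", 12.011, "hemicellulose", "carboxyl", TRUE, p)
        add("OX1", "O", 15.999, "hemicellulose", "carboxyl", FALSE,
            p + c(0.6, 0, 1.0))
        add("OX2", "O", 15.999, "hemicellulose", "carboxyl", FALSE,
            p + c(-0.6, 0, 1.0))
      }
    }
    poly_xyz <- do.call(rbind, pos)
    y_max <- 5 + 4 * spec$n_chains
    add_water <- function(o) {
      resid <<- resid + 1L
      add("OW", "O", 15.999, "water", "none", FALSE, o)
      add("HW1", "H", 1.008, "water", "none", FALSE, o + c(0.76, 0.59, 0))
      add("HW2", "H", 1.008, "water", "none", FALSE, o + c(-0.76, 0.59, 0))
    }
    is_bulk <- logical(0)
    if (spec$n_bound_water > 0) {
      beads <- do.call(rbind, bead_xyz)
      pick <- sample.int(nrow(beads), spec$n_bound_water, replace = TRUE)
      for (k in seq_len(spec$n_bound_water)) {
        o <- beads[pick[k], ] + random_unit_vectors(1)[1, ] *
          stats::runif(1, 2.8, 4.2)
        add_water(o)
        is_bulk <- c(is_bulk, FALSE)
      }
    }
    x_max <- 5 + 1.5 * spec$chain_length + 5
    if (spec$n_bulk_water > 0) {
      for (k in seq_len(spec$n_bulk_water)) {
        o <- c(stats::runif(1, 5, x_max), stats::runif(1, 5, y_max),
               stats::runif(1, 30, 38))
        add_water(o)
        is_bulk <- c(is_bulk, TRUE)
      }
    }
    if (spec$n_ions > 0) {
      for (k in seq_len(spec$n_ions)) {
        resid <- resid + 1L
        add("SOD", "NA.", 22.990, "ion", "none", FALSE,
            c(stats::runif(1, 5, x_max), stats::runif(1, 5, y_max),
              stats::runif(1, 30, 38)))
      }
    }
    # isolated exposure pairs in their own y-band, 30 A apart
    if (!is.null(spec$exposure_distances)) {
      for (k in seq_along(spec$exposure_distances)) {
        d <- spec$exposure_distances[k]
        base <- c(10 + 30 * (k - 1), y_max + 40, 10)
        resid <- resid + 1L
        add("C1", "C", 12.011, "lignin", "none", FALSE, base)
        o <- base + c(0, 0, 1.4)
        add("OH1", "O", 15.999, "lignin", "hydroxyl", TRUE, o)
        add("HO1", "H", 1.008, "lignin", "hydroxyl", FALSE, o + c(0, 0, 0.96))
        add_water(o + c(d, 0, 0))
        is_bulk <- c(is_bulk, NA)  # not part of the bulk/bound construction
      }
    }
    atoms <- do.call(rbind, rows)
    xyz <- do.call(rbind, pos)
    box <- c(max(xyz[, 1]) + 40, max(xyz[, 2]) + 40, max(xyz[, 3]) + 40)
    struct <- wall_structure(atoms)
    traj <- wall_trajectory(struct, array(xyz, dim = c(nrow(xyz), 3, 1)),
                            box, dt = 1, equilibration = 0)
    heads <- atom_select(struct, group = "hydroxyl", site_head = TRUE)
    wat_o <- atom_select(struct, component = "water", element = "O")
    nearest <- if (length(wat_o))
      apply(min_image_distances(xyz[heads, , drop = FALSE],
                                xyz[wat_o, , drop = FALSE], box), 1, min)
    else rep(Inf, length(heads))
    wat_resid <- atoms$resid[wat_o]
    real <- !is.na(is_bulk)
    list(trajectory = traj, structure = struct,
         truth = list(
           hydroxyl_heads = heads,
           nearest_water = stats::setNames(nearest, heads),
           water_resids = wat_resid,
           water_is_bulk = is_bulk,
           bulk_fraction_pct = if (any(real))
             100 * mean(is_bulk[real]) else NA_real_))
  })
}
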