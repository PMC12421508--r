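# Independent brute-force oracles and small fixture builders shared across
# test files. The oracles deliberately use 27-image enumeration, not the
# package's arithmetic wrap, so they check the implementation from a
# different route.

# minimum-image displacement by explicit enumeration of all 27 periodic
# images of b
oracle_min_image <- function(a, b, box) {
  best <- NULL; best_n <- Inf
  for (kx in -1:1) for (ky in -1:1) for (kz in -1:1) {
    d <- (b + c(kx, ky, kz) * box) - a
    n <- sum(d * d)
    if (n < best_n) { best <- d; best_n <- n }
  }
  best
}

oracle_min_dist <- function(a, b, box) {
  sqrt(sum(oracle_min_image(a, b, box)^2))
}

# O(N^2) neighbour search over 27 images
oracle_pairs <- function(coords, box, ia, ib, cutoff) {
  out <- list()
  for (i in ia) for (j in ib) {
    if (i == j) next
    d <- oracle_min_dist(coords[i, ], coords[j, ], box)
    if (d <= cutoff) out[[length(out) + 1]] <- c(i, j, d)
  }
  if (!length(out))
    return(data.frame(i = integer(), j = integer(), distance = numeric()))
  m <- do.call(rbind, out)
  data.frame(i = m[, 1], j = m[, 2], distance = m[, 3])
}

# untruncated switching-function contact score
oracle_contact <- function(coords, box, ia, ib, d0 = 5, k = 5) {
  s <- 0
  for (i in ia) for (j in ib) {
    if (i == j) next
    d <- oracle_min_dist(coords[i, ], coords[j, ], box)
    s <- s + 1 / (1 + exp(k * (d - d0)))
  }
  s
}

oracle_bulk <- function(coords, box, water_o, polymer, threshold) {
  vapply(water_o, function(w) {
    all(vapply(polymer, function(p)
      oracle_min_dist(coords[w, ], coords[p, ], box), numeric(1)) > threshold)
  }, logical(1))
}

# canonicalise a pair list for set comparison (unordered pairs)
pair_key <- function(df) {
  sort(paste(pmin(df$i, df$j), pmax(df$i, df$j)))
}

# single-frame trajectory from a raw coordinate matrix and a uniform
# structure (all atoms one component)
coords_trajectory <- function(coords, box, component = "water",
                              element = "O") {
  st <- wall_structure(data.frame(
    elety = paste0(element, "W"), element = element, mass = 18.02,
    component = component, group = "none", resid = seq_len(nrow(coords)),
    site_head = FALSE))
  wall_trajectory(st, array(coords, dim = c(nrow(coords), 3, 1)), box,
                  dt = 1)
}

# trajectory of one ion and one carboxyl site following a prescribed
# bound/unbound binary series (bound = 3 A, unbound = 20 A), box 50
binary_dwell_trajectory <- function(series, dt = 0.2) {
  st <- wall_structure(rbind(
    data.frame(elety = "CX", element = "C", mass = 12.011,
               component = "hemicellulose", group = "carboxyl", resid = 1,
               site_head = TRUE),
    data.frame(elety = "SOD", element = "NA.", mass = 22.99,
               component = "ion", group = "none", resid = 2,
               site_head = FALSE)))
  nf <- length(series)
  xyz <- array(0, dim = c(2, 3, nf))
  xyz[1, , ] <- 10
  for (f in seq_len(nf)) xyz[2, , f] <- c(10 + if (series[f]) 3 else 20, 10, 10)
  wall_trajectory(st, xyz, c(50, 50, 50), dt = dt)
}

# brute-force dwell scan over a binary series: consecutive TRUE runs with
# end-censoring flags
oracle_runs <- function(series, dt) {
  out <- data.frame(duration_ns = numeric(), censored = logical())
  i <- 1; n <- length(series)
  while (i <= n) {
    if (series[i]) {
      j <- i
      while (j < n && series[j + 1]) j <- j + 1
      out <- rbind(out, data.frame(duration_ns = (j - i + 1) * dt,
                                   censored = (i == 1) | (j == n)))
      i <- j + 1
    } else i <- i + 1
  }
  out
}

# standard Boltzmann-occupancy fixture used by the free-energy tests
boltzmann_fixture <- function(e_acetyl, e_hydroxyl, seed = 1,
                              n_frames = 400) {
  st <- data.frame(group = c("carboxyl", "acetyl", "hydroxyl"),
                   count = c(60, 240, 120),
                   energy = c(0, e_acetyl, e_hydroxyl))
  gen_boltzmann_sites(boltzmann_site_spec(st, n_ions = 120,
                                          n_frames = n_frames, seed = seed))
}
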