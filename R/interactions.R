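## Contact statistics, radial distribution functions, relative binding free
## energies with block-averaged uncertainties, and ion dwell-time
## distributions.

#' Logistic switching weight for atom-pair contacts
#'
#' weight(d) = 1 / (1 + exp(k * (d - d0))) with midpoint d0 = 5 Angstrom and
#' steepness k = 5 / Angstrom: a smooth cutoff that weights close contacts
#' more heavily than distant ones. Strictly decreasing in distance; 0.5 at
#' the midpoint.
#'
#' @param d distance(s), Angstrom.
#' @param d0 switching midpoint, Angstrom.
#' @param k steepness, 1/Angstrom.
#' @return weights in (0, 1).
#' @export
switching_weight <- function(d, d0 = 5, k = 5) {
  1 / (1 + exp(k * (d - d0)))
}

#' Weighted contact score between two atom groups in one frame
#'
#' Sum of the logistic switching weight over all inter-group atom pairs at
#' minimum-image distance. Pairs beyond `truncation` (default 12 Angstrom,
#' where the weight is below 1e-15) are skipped, so the score does not depend
#' on any neighbour-search radius. Atoms shared by both groups are excluded
#' as self-pairs. Callers pass heavy atoms only, matching the contact
#' convention of the analysis.
#'
#' @param coords n_atoms x 3 matrix for the frame.
#' @param box length-3 box vector.
#' @param ia,ib atom index vectors of the two groups.
#' @param d0,k switching parameters, see [switching_weight()].
#' @param truncation hard truncation radius, Angstrom.
#' @return numeric score (<= number of pairs).
#' @export
contact_score <- function(coords, box, ia, ib, d0 = 5, k = 5,
                          truncation = 12) {
  if (length(ia) == 0 || length(ib) == 0) stop("contact groups must be nonempty")
  D <- min_image_distances(coords[ia, , drop = FALSE],
                           coords[ib, , drop = FALSE], box)
  if (any(ia %in% ib)) {
    self <- outer(ia, ib, "==")
    D[self] <- Inf
  }
  sum(switching_weight(D[D <= truncation], d0, k))
}

#' Per-frame contact score series for group pairs
#'
#' Evaluates the switching-function contact score for each named pair of
#' atom groups over the post-equilibration frames. Supports polymer-polymer
#' pairings as well as ion-functional-group pairings.
#'
#' @param traj a wrapped [wall_trajectory()].
#' @param pairs named list; each element is a list with atom index vectors
#'   `a` and `b`.
#' @param frames frame indices to analyse (default post-equilibration).
#' @param d0,k,truncation see [contact_score()].
#' @return data.frame with columns `frame`, `time`, `pair`, `score`.
#' @export
group_contact_timeseries <- function(traj, pairs,
                                     frames = production_frames(traj),
                                     d0 = 5, k = 5, truncation = 12) {
  if (length(frames) == 0) stop("empty frame range")
  if (is.null(names(pairs)) || any(!nzchar(names(pairs))))
    stop("pairs must be a named list")
  tt <- frame_times(traj)
  out <- lapply(names(pairs), function(nm) {
    p <- pairs[[nm]]
    sc <- vapply(frames, function(f)
      contact_score(frame_coords(traj, f), traj$box[f, ], p$a, p$b,
                    d0, k, truncation), numeric(1))
    data.frame(frame = frames, time = tt[frames], pair = nm, score = sc)
  })
  do.call(rbind, out)
}

#' Per-site interaction probabilities from contact means
#'
#' Normalises mean contact scores by functional-group abundance (number of
#' group instances, not atoms) and rescales so the probabilities sum to one
#' across groups. Ratios between groups -- the only quantity entering the
#' free-energy estimate -- are independent of the rescaling.
#'
#' @param scores named numeric vector of mean contact scores per group.
#' @param abundances named numeric vector of group abundances (>= 1).
#' @return named probability vector.
#' @export
interaction_probability <- function(scores, abundances) {
  abundances <- abundances[names(scores)]
  if (any(is.na(abundances)) || any(abundances < 1))
    stop("every group needs an abundance >= 1")
  per_site <- scores / abundances
  per_site / sum(per_site)
}

#' Relative binding free energy from an interaction-probability ratio
#'
#' Delta-G = -RT ln(P_s / P_c) against the carboxyl reference (the most
#' strongly ion-binding group). Identical probabilities give exactly zero.
#'
#' @param p_s interaction probability of the group of interest.
#' @param p_c reference (carboxyl) interaction probability.
#' @param temperature Kelvin.
#' @return kcal/mol.
#' @export
delta_g <- function(p_s, p_c, temperature = 300) {
  if (any(p_s <= 0) || any(p_c <= 0))
    stop("free energy not estimable: zero interaction probability")
  rt <- wall_constants(temperature)$RT
  ifelse(p_s == p_c, 0, -rt * log(p_s / p_c))
}

#' Standard error of a relative binding free energy
#'
#' Propagates the block standard errors of the two interaction
#' probabilities: sigma = RT * sqrt((sigma_s/P_s)^2 + (sigma_c/P_c)^2).
#'
#' @param p_s,sigma_s probability and standard error for the group.
#' @param p_c,sigma_c probability and standard error for the reference.
#' @param temperature Kelvin.
#' @return kcal/mol.
#' @export
delta_g_error <- function(p_s, sigma_s, p_c, sigma_c, temperature = 300) {
  if (any(p_s <= 0) || any(p_c <= 0)) stop("non-positive probabilities")
  rt <- wall_constants(temperature)$RT
  rt * sqrt((sigma_s / p_s)^2 + (sigma_c / p_c)^2)
}

#' Radial distribution function between two atom groups
#'
#' Standard number-density-normalised g(r): per-bin pair counts divided by
#' (shell volume x target number density x centre count x frames), with
#' minimum-image distances. The raw mean pair count per centre per bin is
#' retained so the profile can be integrated into a coordination number.
#'
#' @param traj a [wall_trajectory()].
#' @param centers,targets atom index vectors.
#' @param r_max histogram range, Angstrom (must not exceed half the shortest
#'   box length).
#' @param bin_width bin width, Angstrom.
#' @param frames frames to analyse (default post-equilibration).
#' @return object of class `wall_rdf`: list with `r` (bin centres), `g`,
#'   `mean_counts` (mean pairs per centre per bin), `n_frames`, group sizes.
#' @export
rdf <- function(traj, centers, targets, r_max = 10, bin_width = 0.1,
                frames = production_frames(traj)) {
  if (length(centers) == 0 || length(targets) == 0) stop("empty groups")
  if (length(frames) == 0) stop("empty frame range")
  if (r_max > min(traj$box[frames, ]) / 2)
    stop("r_max exceeds half the minimum box length")
  breaks <- seq(0, r_max, by = bin_width)
  nb <- length(breaks) - 1
  counts <- numeric(nb)
  g_acc <- numeric(nb)
  shell <- 4 / 3 * pi * (breaks[-1]^3 - breaks[-length(breaks)]^3)
  for (f in frames) {
    co <- frame_coords(traj, f)
    D <- min_image_distances(co[centers, , drop = FALSE],
                             co[targets, , drop = FALSE], traj$box[f, ])
    if (any(centers %in% targets)) D[outer(centers, targets, "==")] <- Inf
    h <- tabulate(findInterval(D[D < r_max], breaks,
                               rightmost.closed = FALSE), nbins = nb)
    counts <- counts + h
    vol <- prod(traj$box[f, ])
    rho <- length(targets) / vol
    g_acc <- g_acc + h / (length(centers) * shell * rho)
  }
  structure(list(r = (breaks[-1] + breaks[-length(breaks)]) / 2,
                 g = g_acc / length(frames),
                 mean_counts = counts / (length(frames) * length(centers)),
                 bin_width = bin_width, r_max = r_max,
                 n_frames = length(frames),
                 n_centers = length(centers), n_targets = length(targets)),
            class = "wall_rdf")
}

#' @export
print.wall_rdf <- function(x, ...) {
  cat("wall_rdf:", length(x$r), "bins to", x$r_max, "A,",
      x$n_centers, "centers x", x$n_targets, "targets over",
      x$n_frames, "frames\n")
  invisible(x)
}

# First strict local minimum of the smoothed profile after the global first
# peak. Returns NULL when the profile is monotone / has no interior minimum.
detect_first_minimum <- function(profile, smooth_bins = 5) {
  g <- as.numeric(stats::filter(profile$g, rep(1 / smooth_bins, smooth_bins),
                                sides = 2))
  g[is.na(g)] <- profile$g[is.na(g)]
  peak <- which.max(g)
  if (peak >= length(g) - 1) return(NULL)
  for (i in (peak + 1):(length(g) - 1)) {
    if (g[i] < g[i - 1] && g[i] <= g[i + 1]) return(profile$r[i])
  }
  NULL
}

#' Integrate an RDF up to its first minimum
#'
#' Coordination number: the mean number of target atoms per centre within
#' the first solvation shell, i.e. the sum of raw mean pair counts over all
#' bins up to the first minimum of the (smoothed) profile. Detection uses the
#' first strict local minimum after the global peak; profiles without one
#' (monotone or flat) raise an error unless a radius is supplied, since
#' multi-peaked acetyl profiles need a well-defined shell boundary.
#'
#' @param profile a [rdf()] result.
#' @param r_min optional fixed integration radius, Angstrom (overrides
#'   detection).
#' @return list with `coordination` and `r_min`.
#' @export
integrate_rdf_to_first_minimum <- function(profile, r_min = NULL) {
  if (is.null(r_min)) r_min <- detect_first_minimum(profile)
  if (is.null(r_min))
    stop("no first minimum detected in the RDF; supply r_min explicitly")
  list(coordination = sum(profile$mean_counts[profile$r <= r_min]),
       r_min = r_min)
}

#' Ion-site dwell-time distribution
#'
#' For every ion-site pair, finds maximal runs of consecutive frames with
#' minimum-image distance at or below the cutoff (6 Angstrom in the source
#' protocol); a run's duration is its frame count times the frame interval.
#' Runs touching either end of the analysed window are flagged censored --
#' their true length is unknown (trivalent ions routinely stay bound beyond
#' the whole trajectory) -- and should be excluded from mean statistics.
#'
#' @param traj a [wall_trajectory()].
#' @param ions,sites atom index vectors.
#' @param cutoff contact cutoff, Angstrom (must be below half the minimum
#'   box length).
#' @param frames frames to analyse (default post-equilibration).
#' @return object of class `wall_dwell`: data.frame with columns `ion`,
#'   `site`, `duration_ns`, `censored`; attribute `dt`.
#' @export
dwell_times <- function(traj, ions, sites, cutoff = 6,
                        frames = production_frames(traj)) {
  stopifnot(length(ions) > 0, length(sites) > 0, length(frames) >= 1)
  if (cutoff >= min(traj$box[frames, ]) / 2)
    stop("cutoff must be below half the minimum box length")
  ni <- length(ions); ns <- length(sites); nf <- length(frames)
  bound <- array(FALSE, dim = c(ni, ns, nf))
  for (k in seq_len(nf)) {
    f <- frames[k]
    co <- frame_coords(traj, f)
    D <- min_image_distances(co[ions, , drop = FALSE],
                             co[sites, , drop = FALSE], traj$box[f, ])
    bound[, , k] <- D <= cutoff
  }
  res <- vector("list", ni * ns)
  idx <- 0
  for (i in seq_len(ni)) {
    for (s in seq_len(ns)) {
      b <- bound[i, s, ]
      if (!any(b)) next
      r <- rle(b)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      keep <- r$values
      idx <- idx + 1
      res[[idx]] <- data.frame(
        ion = ions[i], site = sites[s],
        duration_ns = r$lengths[keep] * traj$dt,
        censored = (starts[keep] == 1L) | (ends[keep] == nf))
    }
  }
  out <- if (idx > 0) do.call(rbind, res[seq_len(idx)])
  else data.frame(ion = integer(), site = integer(),
                  duration_ns = numeric(), censored = logical())
  attr(out, "dt") <- traj$dt
  class(out) <- c("wall_dwell", "data.frame")
  out
}

#' Time-weighted cumulative distribution of dwell durations
#'
#' Weights each binding event by its duration as a fraction of the total
#' bound time, answering "how long has a randomly chosen bound moment been
#' bound for": long-lived interactions dominate the picture even when short
#' events outnumber them.
#'
#' @param durations numeric vector of dwell durations (ns), nonempty.
#' @return data.frame with sorted `duration`, per-event `weight`, and `cdf`
#'   (fraction of total bound time in events of that duration or shorter).
#' @export
#' @examples
#' time_weighted_cdf(c(1, 1, 8))  # cdf reaches 0.2 at 1 ns, 1.0 at 8 ns
time_weighted_cdf <- function(durations) {
  if (length(durations) == 0) stop("empty durations")
  d <- sort(durations)
  w <- d / sum(d)
  data.frame(duration = d, weight = w, cdf = cumsum(w))
}

#' Relative binding free-energy table via contacts and RDF integration
#'
#' Computes, for each functional group present, the relative binding free
#' energy of an ion species against the carboxyl reference by both routes:
#' per-site mean contact scores (atom-pair route) and integrated RDF
#' coordination numbers up to the first minimum (RDF route). Uncertainties
#' are standard errors over `n_blocks` equal post-equilibration trajectory
#' blocks, propagated through the log-ratio.
#'
#' @param traj a [wall_trajectory()].
#' @param ions ion atom indices.
#' @param groups character vector of functional-group labels to analyse.
#' @param reference reference group label (carboxyl).
#' @param n_blocks number of trajectory blocks for uncertainties.
#' @param temperature Kelvin.
#' @param r_max,bin_width RDF histogram parameters.
#' @param frames frames to analyse (default post-equilibration).
#' @param r_min optional named vector of fixed shell radii per group.
#' @return data.frame with one row per group x method
#'   (`atom_pair`, `rdf`): `delta_g`, `sigma` (kcal/mol), `p` (per-site
#'   probability), `abundance`. Reference rows are exactly 0 +/- 0.
#' @export
binding_free_energy_table <- function(traj, ions, groups = c("carboxyl",
                                                             "acetyl",
                                                             "hydroxyl"),
                                      reference = "carboxyl", n_blocks = 20,
                                      temperature = 300, r_max = 10,
                                      bin_width = 0.2,
                                      frames = production_frames(traj),
                                      r_min = NULL) {
  stopifnot(reference %in% groups, length(frames) >= n_blocks)
  heavy <- which(traj$structure$atoms$element != "H")
  idx <- lapply(groups, function(g)
    intersect(atom_select(traj, group = g), heavy))
  names(idx) <- groups
  empty <- vapply(idx, length, integer(1)) == 0
  if (any(empty))
    stop("no atoms for group(s): ", paste(groups[empty], collapse = ", "))
  abund <- vapply(groups, function(g) group_abundance(traj, g), integer(1))
  nb_bins <- round(r_max / bin_width)
  breaks <- seq(0, r_max, by = bin_width)
  block_id <- floor((seq_along(frames) - 1) * n_blocks / length(frames)) + 1
  ng <- length(groups)
  score <- matrix(0, ng, length(frames), dimnames = list(groups, NULL))
  hist_block <- array(0, dim = c(ng, nb_bins, n_blocks))
  hist_all <- matrix(0, ng, nb_bins)
  g_acc <- matrix(0, ng, nb_bins)
  shell <- 4 / 3 * pi * (breaks[-1]^3 - breaks[-length(breaks)]^3)
  for (k in seq_along(frames)) {
    f <- frames[k]
    co <- frame_coords(traj, f)
    box <- traj$box[f, ]
    vol <- prod(box)
    for (gi in seq_len(ng)) {
      D <- min_image_distances(co[ions, , drop = FALSE],
                               co[idx[[gi]], , drop = FALSE], box)
      score[gi, k] <- sum(switching_weight(D[D <= 12]))
      h <- tabulate(findInterval(D[D < r_max], breaks), nbins = nb_bins)
      hist_block[gi, , block_id[k]] <- hist_block[gi, , block_id[k]] + h
      hist_all[gi, ] <- hist_all[gi, ] + h
      g_acc[gi, ] <- g_acc[gi, ] +
        h / (length(ions) * shell * (length(idx[[gi]]) / vol))
    }
  }
  frames_per_block <- tabulate(block_id, n_blocks)
  r_ctr <- (breaks[-1] + breaks[-length(breaks)]) / 2
  rows <- list()
  # atom-pair route: per-site per-frame scores
  per_site <- sweep(score, 1, abund, "/")
  p_mean <- rowMeans(per_site)
  p_se <- apply(per_site, 1, block_error, n_blocks = n_blocks)
  # rdf route: per-block coordination per site
  coord_block <- matrix(NA_real_, ng, n_blocks, dimnames = list(groups, NULL))
  r_used <- stats::setNames(numeric(ng), groups)
  for (gi in seq_len(ng)) {
    prof <- structure(list(r = r_ctr, g = g_acc[gi, ] / length(frames),
                           mean_counts = hist_all[gi, ] /
                             (length(frames) * length(ions)),
                           bin_width = bin_width, r_max = r_max,
                           n_frames = length(frames),
                           n_centers = length(ions),
                           n_targets = length(idx[[gi]])),
                      class = "wall_rdf")
    rm_g <- if (!is.null(r_min) && groups[gi] %in% names(r_min))
      r_min[[groups[gi]]] else detect_first_minimum(prof)
    if (is.null(rm_g))
      stop("no first RDF minimum for group '", groups[gi],
           "'; supply r_min")
    r_used[gi] <- rm_g
    in_shell <- r_ctr <= rm_g
    coord_block[gi, ] <- vapply(seq_len(n_blocks), function(b)
      sum(hist_block[gi, in_shell, b]), numeric(1)) /
      (frames_per_block * length(ions) * abund[gi])
  }
  c_mean <- rowMeans(coord_block)
  c_se <- apply(coord_block, 1, function(x) stats::sd(x) / sqrt(length(x)))
  ref <- which(groups == reference)
  for (gi in seq_len(ng)) {
    is_ref <- gi == ref
    rows[[length(rows) + 1]] <- data.frame(
      group = groups[gi], method = "atom_pair",
      delta_g = if (is_ref) 0 else
        delta_g(p_mean[gi], p_mean[ref], temperature),
      sigma = if (is_ref) 0 else
        delta_g_error(p_mean[gi], p_se[gi], p_mean[ref], p_se[ref],
                      temperature),
      p = p_mean[gi], abundance = abund[gi])
    rows[[length(rows) + 1]] <- data.frame(
      group = groups[gi], method = "rdf",
      delta_g = if (is_ref) 0 else
        delta_g(c_mean[gi], c_mean[ref], temperature),
      sigma = if (is_ref) 0 else
        delta_g_error(c_mean[gi], c_se[gi], c_mean[ref], c_se[ref],
                      temperature),
      p = c_mean[gi], abundance = abund[gi])
  }
  out <- do.call(rbind, rows)
  attr(out, "r_min") <- r_used
  attr(out, "n_blocks") <- n_blocks
  out
}
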