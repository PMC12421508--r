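## Acetylation bookkeeping: exposure-based hydroxyl selection, weight-percent
## gain, constant-volume water removal, and the inverse atom-count
## arithmetic. Acetylation replaces the hydroxyl hydrogen with -C(=O)CH3:
## +6 atoms (carbonyl C, carbonyl O, methyl C, 3 methyl H), -1 atom (the
## hydroxyl H), net +5 atoms and +42.037 g/mol per site; the hydroxyl oxygen
## becomes the ester oxygen of the new acetyl group.

ACETYL_ATOM_DELTA <- 5L            # net atoms added per acetylated site
ACETYL_MASS_DELTA <- 42.037        # g/mol: +43.045 (C2H3O) - 1.008 (H)
WATER_ATOMS <- 3L                  # O + 2 H per removed water

#' Weight-percent gain from dry masses
#'
#' WPG = 100 * (m_post - m_pre) / m_pre, the standard measure of acetylation
#' degree from the dry mass before and after modification. Water-removal
#' policy cannot affect it: only dry mass enters.
#'
#' @param m_pre,m_post dry mass before/after acetylation (g/mol or any common
#'   unit).
#' @return percent gain (negative for mass loss).
#' @export
#' @examples
#' compute_wpg(100, 118)  # 18, full acetylation of the cell-wall model
compute_wpg <- function(m_pre, m_post) {
  if (any(m_pre <= 0)) stop("m_pre must be > 0")
  100 * (m_post - m_pre) / m_pre
}

#' Number of waters to remove for a constant-volume system
#'
#' Converts the volume change of the expanded system into the equivalent
#' number of water molecules at liquid density:
#' round(rho * N_A * dV / MW_H2O), with dV converted from Angstrom^3 to cm^3.
#'
#' @param delta_v volume change in Angstrom^3 (>= 0).
#' @param constants a [wall_constants()] list (density configurable there).
#' @return integer count of waters.
#' @export
waters_to_remove <- function(delta_v, constants = wall_constants()) {
  if (any(delta_v < 0)) stop("delta_v must be >= 0")
  v_cm3 <- delta_v * 1e-24
  as.integer(round(constants$rho_water * constants$n_avogadro * v_cm3 /
                     constants$mw_water))
}

#' Recover the acetylation-site count from system sizes
#'
#' Inverse bookkeeping: acetylation adds 5 atoms per site and removing a
#' water subtracts 3, so post = pre + 5 * sites - 3 * waters_removed and
#' sites = (post - pre + 3 * waters_removed) / 5. A non-integer result
#' signals mutually inconsistent inputs and is an error.
#'
#' @param pre_atoms,post_atoms total atom counts before/after.
#' @param waters_removed waters removed (0 for an expanded system).
#' @return integer site count.
#' @export
#' @examples
#' sites_from_atom_counts(190803, 186780, 8171)  # 4098
sites_from_atom_counts <- function(pre_atoms, post_atoms, waters_removed) {
  stopifnot(pre_atoms >= 0, post_atoms >= 0, waters_removed >= 0)
  num <- post_atoms - pre_atoms + WATER_ATOMS * waters_removed
  if (num %% ACETYL_ATOM_DELTA != 0)
    stop("inconsistent atom counts: (post - pre + 3*waters) = ", num,
         " is not divisible by ", ACETYL_ATOM_DELTA)
  as.integer(num / ACETYL_ATOM_DELTA)
}

#' Counterions needed to neutralise a polymer charge
#'
#' @param total_charge net polymer charge in elementary charges (e.g. -150
#'   from the anionic hemicellulose carboxylates).
#' @param valence cation valence (1 for Na+, 3 for Fe3+).
#' @return integer ion count.
#' @export
#' @examples
#' neutralizing_counterions(-150, 3)  # 50 Fe3+
neutralizing_counterions <- function(total_charge, valence) {
  stopifnot(valence >= 1)
  as.integer(ceiling(abs(total_charge) / valence))
}

#' Moisture content (water weight percent)
#'
#' 100 * water mass / total mass. Ions are excluded from the total by
#' default (set `include_ions = TRUE` to count them).
#'
#' @param struct a [wall_structure()].
#' @param include_ions logical.
#' @return percent by weight.
#' @export
moisture_content <- function(struct, include_ions = FALSE) {
  a <- struct$atoms
  keep <- if (include_ions) rep(TRUE, nrow(a)) else a$component != "ion"
  tot <- sum(a$mass[keep])
  if (tot <= 0) stop("zero total mass")
  100 * sum(a$mass[a$component == "water"]) / tot
}

dry_mass <- function(struct) {
  a <- struct$atoms
  sum(a$mass[!(a$component %in% c("water", "ion"))])
}

#' Find water-exposed hydroxyl sites
#'
#' Selects hydroxyl sites on hemicellulose and lignin whose oxygen lies
#' within `cutoff` (minimum image) of the nearest water oxygen. The O-O
#' distance convention is used because it does not depend on hydrogen
#' placement. `cutoff = Inf` returns every hydroxyl site.
#'
#' @param traj a [wall_trajectory()].
#' @param cutoff exposure cutoff in Angstrom (3, 6, 12, or Inf in the source
#'   study), > 0.
#' @param frame frame index to evaluate (default 1).
#' @return sorted integer vector of hydroxyl head-atom indices.
#' @export
find_exposed_hydroxyls <- function(traj, cutoff, frame = 1) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  heads <- atom_select(traj, group = "hydroxyl", site_head = TRUE,
                       component = c("hemicellulose", "lignin"))
  if (is.infinite(cutoff)) return(sort(heads))
  wat_o <- atom_select(traj, component = "water", element = "O")
  if (length(wat_o) == 0)
    stop("no water oxygens present; a finite exposure cutoff needs water")
  if (length(heads) == 0) return(integer())
  co <- frame_coords(traj, frame)
  d <- min_image_distances(co[heads, , drop = FALSE],
                           co[wat_o, , drop = FALSE], traj$box[frame, ])
  sort(heads[apply(d, 1, min) <= cutoff])
}

#' Build an acetylation plan
#'
#' Records the selected hydroxyl sites, the per-site atom and mass deltas,
#' the resulting dry masses and weight-percent gain, and -- in constant
#' (fixed-volume) mode -- how many waters to remove and by what policy.
#'
#' @param traj a [wall_trajectory()] (coordinates are needed for exposure
#'   selection and displacement-based water removal).
#' @param cutoff exposure cutoff in Angstrom, or `Inf` for full acetylation.
#' @param mode `"expanded"` (water kept, box grows) or `"constant"` (fixed
#'   volume, acetyl groups displace water).
#' @param delta_v volume change of the expanded system in Angstrom^3; in
#'   constant mode the water-removal count is derived from it via
#'   [waters_to_remove()]. Alternatively give `n_water_removed` directly.
#' @param n_water_removed explicit water-removal count (overrides `delta_v`).
#' @param policy water-removal policy: `"displace"` removes the waters
#'   nearest the new acetyl sites, `"random"` removes a seeded random bulk
#'   sample.
#' @param seed seed for the random policy.
#' @param constants a [wall_constants()] list.
#' @param frame frame used for exposure selection.
#' @return an `acetylation_plan` list.
#' @export
acetylation_plan <- function(traj, cutoff = Inf,
                             mode = c("expanded", "constant"),
                             delta_v = NULL, n_water_removed = NULL,
                             policy = c("displace", "random"), seed = 1,
                             constants = wall_constants(), frame = 1) {
  mode <- match.arg(mode); policy <- match.arg(policy)
  sites <- find_exposed_hydroxyls(traj, cutoff, frame)
  struct <- traj$structure
  m_pre <- dry_mass(struct)
  m_post <- m_pre + length(sites) * ACETYL_MASS_DELTA
  nw <- 0L
  if (mode == "constant") {
    nw <- if (!is.null(n_water_removed)) as.integer(n_water_removed)
    else if (!is.null(delta_v)) waters_to_remove(delta_v, constants)
    else stop("constant mode needs delta_v or n_water_removed")
    n_avail <- length(unique(struct$atoms$resid[struct$atoms$component ==
                                                  "water"]))
    if (nw < 0) stop("n_water_removed must be >= 0")
    if (nw > n_avail)
      stop("cannot remove ", nw, " waters; only ", n_avail, " available")
  }
  structure(list(sites = sites, cutoff = cutoff, mode = mode,
                 policy = policy, seed = seed,
                 atom_delta = ACETYL_ATOM_DELTA,
                 mass_delta = ACETYL_MASS_DELTA,
                 m_pre = m_pre, m_post = m_post,
                 wpg = compute_wpg(m_pre, m_post),
                 n_water_removed = nw, frame = frame),
            class = "acetylation_plan")
}

#' @export
print.acetylation_plan <- function(x, ...) {
  cat("acetylation_plan:", length(x$sites), "sites (cutoff",
      if (is.infinite(x$cutoff)) "Inf" else paste0(x$cutoff, " A"),
      "), mode", x$mode, "\n")
  cat(sprintf("  dry mass %.1f -> %.1f g/mol, WPG %.2f%%\n",
              x$m_pre, x$m_post, x$wpg))
  if (x$mode == "constant")
    cat("  waters removed:", x$n_water_removed, "(policy", x$policy, ")\n")
  invisible(x)
}

#' Apply an acetylation plan to a structure
#'
#' Replaces each selected hydroxyl with an acetyl group at the bookkeeping
#' level: the hydroxyl hydrogen is removed, six acetyl atoms are added with
#' pseudo-coordinates near the site, and the hydroxyl oxygen is relabelled as
#' the acetyl ester oxygen. In constant mode the configured number of water
#' molecules is removed according to the plan's policy. Coordinates are
#' bookkeeping placements, not minimised geometry: downstream analyses need
#' labels, counts and masses, not strain-free structures.
#'
#' @param traj a [wall_trajectory()] (frame 1 is modified).
#' @param plan an [acetylation_plan()].
#' @return list with `trajectory` (modified single-frame trajectory) and
#'   `report` (atom counts and masses pre/post, WPG, moisture pre/post,
#'   waters removed).
#' @export
apply_plan <- function(traj, plan) {
  stopifnot(inherits(plan, "acetylation_plan"))
  struct <- traj$structure
  a <- struct$atoms
  co <- traj$xyz[, , plan$frame]
  box <- traj$box[plan$frame, ]
  if (length(plan$sites) &&
      !all(a$group[plan$sites] == "hydroxyl" & a$site_head[plan$sites]))
    stop("plan contains indices that are not hydroxyl site heads")
  pre_atoms <- nrow(a)
  pre_moist <- moisture_content(struct)
  drop <- integer(); new_rows <- list(); new_xyz <- list()
  for (s in plan$sites) {
    # the hydroxyl H shares the site's resid and group
    h <- which(a$resid == a$resid[s] & a$group == "hydroxyl" &
                 a$element == "H")
    if (length(h) < 1)
      stop("hydroxyl site ", s, " has no hydrogen to replace")
    drop <- c(drop, h[1])
    a$group[a$resid == a$resid[s] & a$group == "hydroxyl"] <- "acetyl"
    a$site_head[s] <- FALSE  # ester O; the carbonyl C becomes the head
    base <- co[s, ]
    add <- data.frame(
      elety = c("CA", "OA", "CME", "HM1", "HM2", "HM3"),
      element = c("C", "O", "C", "H", "H", "H"),
      mass = c(12.011, 15.999, 12.011, 1.008, 1.008, 1.008),
      component = a$component[s], group = "acetyl",
      resid = a$resid[s],
      site_head = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE))
    off <- rbind(c(0, 0, 1.4), c(0.9, 0, 2.2), c(-1.2, 0, 2.2),
                 c(-1.2, 0.9, 2.8), c(-1.9, -0.5, 2.0), c(-0.9, -0.6, 2.9))
    new_rows[[length(new_rows) + 1]] <- add
    new_xyz[[length(new_xyz) + 1]] <-
      sweep(off, 2, base, "+")
  }
  if (plan$mode == "constant" && plan$n_water_removed > 0) {
    wat_o <- which(a$component == "water" & a$element == "O")
    w_res <- a$resid[wat_o]
    rem_res <- if (plan$policy == "random") {
      withr::with_seed(plan$seed, sample(w_res, plan$n_water_removed))
    } else {
      ref <- if (length(plan$sites)) co[plan$sites, , drop = FALSE]
      else co[which(a$component != "water" & a$component != "ion"), ,
              drop = FALSE]
      d <- apply(min_image_distances(co[wat_o, , drop = FALSE], ref, box),
                 1, min)
      w_res[order(d)[seq_len(plan$n_water_removed)]]
    }
    drop <- c(drop, which(a$component == "water" & a$resid %in% rem_res))
  }
  keep <- setdiff(seq_len(nrow(a)), drop)
  a2 <- rbind(a[keep, ], do.call(rbind, new_rows))
  xyz2 <- rbind(co[keep, , drop = FALSE], do.call(rbind, new_xyz))
  out <- wall_structure(a2, charge = struct$charge)
  traj2 <- wall_trajectory(out, array(xyz2, dim = c(nrow(xyz2), 3, 1)),
                           box, dt = traj$dt, equilibration = 0)
  report <- list(
    n_sites = length(plan$sites),
    pre_atoms = pre_atoms, post_atoms = nrow(a2),
    m_pre = plan$m_pre, m_post = dry_mass(out),
    wpg = compute_wpg(plan$m_pre, dry_mass(out)),
    moisture_pre = pre_moist, moisture_post = moisture_content(out),
    n_water_removed = if (plan$mode == "constant") plan$n_water_removed
    else 0L)
  list(trajectory = traj2, report = report)
}
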