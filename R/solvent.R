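## Bulk-water-pocket quantification: the fraction of water molecules whose
## oxygen is at least a threshold distance (5 Angstrom) from every cell-wall
## biopolymer atom, tracked over time.

#' Bulk-water fraction of a single frame
#'
#' A water molecule counts as bulk iff the minimum-image distance from its
#' oxygen to every polymer atom exceeds the threshold -- such waters sit in
#' pockets, not hydrogen-bonded to the biopolymers. The water oxygen is the
#' reference point (hydrogen placement is irrelevant at a 5 Angstrom scale);
#' the polymer side includes all biopolymer atoms, hydrogens included, read
#' literally, with `heavy_only` to restrict to heavy atoms. Ions are not
#' polymer atoms.
#'
#' @param coords n_atoms x 3 coordinate matrix.
#' @param box length-3 box vector.
#' @param water_o water oxygen atom indices (nonempty).
#' @param polymer polymer atom indices (nonempty).
#' @param threshold exclusion distance, Angstrom.
#' @return list with `fraction_pct` (percent of waters that are bulk) and
#'   `is_bulk` (logical per water oxygen).
#' @export
bulk_water_fraction <- function(coords, box, water_o, polymer,
                                threshold = 5) {
  if (length(water_o) == 0) stop("empty water group")
  if (length(polymer) == 0) stop("empty polymer group")
  d <- min_image_distances(coords[water_o, , drop = FALSE],
                           coords[polymer, , drop = FALSE], box)
  is_bulk <- apply(d, 1, min) > threshold
  list(fraction_pct = 100 * mean(is_bulk), is_bulk = is_bulk)
}

#' Bulk-water fraction time series
#'
#' Per-frame bulk-water percentage over a whole trajectory; frames inside
#' the equilibration window are kept in the series but flagged, so plots can
#' grey them out while summary statistics exclude them.
#'
#' @param traj a [wall_trajectory()] with water/polymer annotations.
#' @param threshold exclusion distance, Angstrom.
#' @param heavy_only restrict the polymer side to heavy atoms.
#' @return object of class `wall_bulkwater`: data.frame with `frame`,
#'   `time`, `bulk_pct`, `equilibration` (logical); attribute `threshold`.
#' @export
bulk_fraction_series <- function(traj, threshold = 5, heavy_only = FALSE) {
  water_o <- atom_select(traj, component = "water", element = "O")
  polymer <- atom_select(traj, component = c("cellulose", "hemicellulose",
                                             "lignin"))
  if (heavy_only)
    polymer <- intersect(polymer,
                         which(traj$structure$atoms$element != "H"))
  if (length(water_o) == 0)
    stop("trajectory contains no water oxygens")
  tt <- frame_times(traj)
  pct <- vapply(seq_len(n_frames(traj)), function(f)
    bulk_water_fraction(frame_coords(traj, f), traj$box[f, ], water_o, polymer,
                        threshold)$fraction_pct, numeric(1))
  out <- data.frame(frame = seq_len(n_frames(traj)), time = tt,
                    bulk_pct = pct,
                    equilibration = tt < traj$equilibration)
  attr(out, "threshold") <- threshold
  class(out) <- c("wall_bulkwater", "data.frame")
  out
}
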