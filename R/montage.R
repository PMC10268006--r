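#' Standard 32-channel extended 10-20 montage
#'
#' Approximate 2D scalp coordinates (head seen from above, nose up;
#' x: left negative to right positive, y: posterior negative to anterior
#' positive, unit head radius) for the 32 active electrodes of a standard
#' extended 10-20 cap, including the mastoid reference pair TP9/TP10. The
#' coordinates drive the spatial correlation of simulated background noise,
#' the topographies of simulated components, and the hemisphere bookkeeping
#' of the ablation analysis.
#'
#' @return A data.frame with columns `name`, `x`, `y`, `z` (z kept at 0; the
#'   layout is a 2D projection).
#' @export
#' @examples
#' head(standard_montage_32())
standard_montage_32 <- function() {
  m <- matrix(c(
    -0.31,  0.95,   0.31,  0.95,                                  # Fp1 Fp2
    -0.81,  0.59,  -0.45,  0.55,  0.00,  0.50,  0.45,  0.55,  0.81, 0.59,
    -0.69,  0.28,  -0.25,  0.27,  0.25,  0.27,  0.69,  0.28,      # FC row
    -1.00,  0.00,  -0.50,  0.00,  0.00,  0.00,  0.50,  0.00,  1.00, 0.00,
    -1.03, -0.36,                                                 # TP9
    -0.69, -0.28,  -0.25, -0.27,  0.25, -0.27,  0.69, -0.28,      # CP row
     1.03, -0.36,                                                 # TP10
    -0.81, -0.59,  -0.45, -0.55,  0.00, -0.50,  0.45, -0.55,  0.81, -0.59,
    -0.63, -0.88,  -0.31, -0.95,  0.00, -1.00,  0.31, -0.95,  0.63, -0.88
  ), ncol = 2, byrow = TRUE)
  data.frame(
    name = c("Fp1", "Fp2",
             "F7", "F3", "Fz", "F4", "F8",
             "FC5", "FC1", "FC2", "FC6",
             "T7", "C3", "Cz", "C4", "T8",
             "TP9", "CP5", "CP1", "CP2", "CP6", "TP10",
             "P7", "P3", "Pz", "P4", "P8",
             "PO9", "O1", "Oz", "O2", "PO10"),
    x = m[, 1], y = m[, 2], z = 0,
    stringsAsFactors = FALSE
  )
}

#' Named electrode subsets for the ablation analysis
#'
#' The eight scalp regions whose removal is used to rank electrode groups by
#' their contribution to single-trial classification: four rostro-caudal
#' bands, the two hemispheres (odd-/even-numbered electrodes), and the left
#' and right halves of the parietal band.
#'
#' @param montage Montage data.frame (default [standard_montage_32()]); every
#'   listed electrode must exist in it.
#' @return Named list of character vectors of electrode names.
#' @export
electrode_subsets <- function(montage = standard_montage_32()) {
  subsets <- list(
    frontal        = c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8"),
    central        = c("FC5", "FC1", "FC2", "FC6", "T7", "C3", "Cz", "C4", "T8"),
    parietal       = c("CP5", "CP1", "CP2", "CP6", "P7", "P3", "Pz", "P4", "P8"),
    occipital      = c("PO9", "O1", "Oz", "O2", "PO10"),
    left_hemisphere  = c("Fp1", "F7", "F3", "FC5", "FC1", "T7", "C3",
                         "TP9", "CP5", "CP1", "P7", "P3", "PO9", "O1"),
    right_hemisphere = c("Fp2", "F8", "F4", "FC6", "FC2", "T8", "C4",
                         "TP10", "CP6", "CP2", "P8", "P4", "PO10", "O2"),
    parietal_left  = c("CP5", "CP1", "P7", "P3"),
    parietal_right = c("CP2", "CP6", "P4", "P8")
  )
  missing <- setdiff(unique(unlist(subsets)), montage$name)
  if (length(missing) > 0) {
    stop("electrode subsets reference channels absent from the montage: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  stopifnot(length(intersect(subsets$left_hemisphere,
                             subsets$right_hemisphere)) == 0)
  subsets
}

#' Write / read a montage file
#'
#' Plain TSV with columns `name`, `x`, `y`, `z`, `subsets` (comma-joined
#' region tags), so the subset definitions used by [ablate_and_rank()] are
#' fully configurable from a file.
#'
#' @param montage Montage data.frame.
#' @param subsets Named list of electrode-name vectors (default
#'   [electrode_subsets()]).
#' @param path File path.
#' @return `write_montage_tsv()` returns `path` invisibly;
#'   `read_montage_tsv()` returns a list with elements `montage` and
#'   `subsets`.
#' @export
write_montage_tsv <- function(montage, path, subsets = electrode_subsets(montage)) {
  tags <- vapply(montage$name, function(ch) {
    paste(names(subsets)[vapply(subsets, function(s) ch %in% s, logical(1))],
          collapse = ",")
  }, character(1))
  out <- cbind(montage[, c("name", "x", "y", "z")], subsets = tags)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_montage_tsv
#' @export
read_montage_tsv <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  stopifnot(all(c("name", "x", "y", "subsets") %in% names(tab)))
  tags <- strsplit(tab$subsets, ",", fixed = TRUE)
  all_tags <- setdiff(unique(unlist(tags)), "")
  subsets <- lapply(all_tags, function(tg) {
    tab$name[vapply(tags, function(v) tg %in% v, logical(1))]
  })
  names(subsets) <- all_tags
  list(montage = tab[, c("name", "x", "y", "z")], subsets = subsets)
}

# Euclidean channel distance matrix from montage coordinates
montage_distances <- function(montage) {
  as.matrix(stats::dist(cbind(montage$x, montage$y)))
}

# smooth topography centred on (x0, y0), unit peak, gaussian falloff
topography_at <- function(montage, x0, y0, width = 0.55) {
  exp(-((montage$x - x0)^2 + (montage$y - y0)^2) / (2 * width^2))
}

#' Default destabilization topography
#'
#' Channel weights of the simulated pre-reversal signature: bilateral
#' parietal, peaked at Pz, symmetric across the midline, zero outside the
#' parietal band. Returned as a named vector over the montage channels.
#'
#' @param montage Montage data.frame.
#' @return Named numeric vector of unitless weights in `[0, 1]`.
#' @export
parietal_topography <- function(montage = standard_montage_32()) {
  w <- stats::setNames(numeric(nrow(montage)), montage$name)
  w[c("Pz")] <- 1.0
  w[c("P3", "P4")] <- 0.9
  w[c("CP1", "CP2")] <- 0.8
  w[c("CP5", "CP6")] <- 0.5
  w[c("P7", "P8")] <- 0.5
  w
}
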