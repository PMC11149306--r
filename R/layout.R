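#' Idealized 64-channel BioSemi scalp layout
#'
#' Positions the 64 BioSemi electrode labels on an idealized 10-20 grid: the
#' anterior-posterior coordinate counts 10%-of-arc steps from the vertex
#' (Fp row = -4 ... O row = +4, Iz = +5) and the lateral coordinate counts
#' steps from the midline (z = 0, numbered sites 1/2 ... 9/10 = levels 1-5,
#' odd numbers left/negative).  Distances on this grid preserve the
#' neighbourhood structure of the montage, which is all the pipeline needs
#' (nearest-neighbour interpolation and grouping retained electrodes into
#' contiguous scalp clusters); it is not a measured head digitisation.
#'
#' @return A tibble with `label`, `x` (lateral, left negative), `y`
#'   (anterior positive).
#' @export
#' @examples
#' lay <- biosemi64_layout()
#' subset(lay, label %in% c("Oz", "PO8", "P10"))
biosemi64_layout <- function() {
  labels <- c(
    "Fp1", "AF7", "AF3", "F1", "F3", "F5", "F7", "FT7", "FC5", "FC3", "FC1",
    "C1", "C3", "C5", "T7", "TP7", "CP5", "CP3", "CP1", "P1", "P3", "P5",
    "P7", "P9", "PO7", "PO3", "O1", "Iz", "Oz", "POz", "Pz", "CPz",
    "Fpz", "Fp2", "AF8", "AF4", "AFz", "Fz", "F2", "F4", "F6", "F8", "FT8",
    "FC6", "FC4", "FC2", "FCz", "Cz", "C2", "C4", "C6", "T8", "TP8", "CP6",
    "CP4", "CP2", "P2", "P4", "P6", "P8", "P10", "PO8", "PO4", "O2"
  )
  pos <- t(vapply(labels, electrode_grid_position, numeric(2)))
  tibble::tibble(label = labels, x = pos[, 1], y = pos[, 2])
}

# Parse a 10-20 label into (lateral steps, anterior-posterior steps).
electrode_grid_position <- function(label) {
  m <- regmatches(label, regexec("^([A-Za-z]+?)(z|[0-9]+)$", label))[[1]]
  if (length(m) == 0) stop("unrecognised electrode label: ", label)
  row <- m[2]
  suffix <- m[3]
  # rows front (negative y steps) to back; T/FT/TP share the C/FC/CP arcs
  row_step <- c(
    Fp = -4, AF = -3, F = -2, FT = -1, FC = -1, C = 0, T = 0,
    TP = 1, CP = 1, P = 2, PO = 3, O = 4, I = 5
  )
  if (!row %in% names(row_step)) stop("unrecognised electrode row: ", row)
  y <- unname(row_step[[row]])
  if (suffix == "z") {
    x <- 0
  } else {
    num <- as.integer(suffix)
    level <- ceiling(num / 2)
    # temporal labels T7/T8, FT7/..., TP7/... carry the 7/8 suffix of the
    # outermost standard arc (lateral level 4)
    x <- level * if (num %% 2 == 1) -1 else 1
  }
  c(x, -y)  # y positive = anterior
}

# Pairwise Euclidean distances between electrode positions.
layout_distances <- function(layout) {
  xy <- as.matrix(layout[, c("x", "y")])
  d <- as.matrix(stats::dist(xy))
  dimnames(d) <- list(layout$label, layout$label)
  d
}

#' Standard analysis regions of interest
#'
#' The medial-occipital ROI used for the general visual (base-rate) response
#' and the left/right occipito-temporal ROIs used for the oddball response.
#'
#' @return A named list of character vectors of electrode labels.
#' @export
default_rois <- function() {
  list(
    MO = c("Oz", "Iz", "O1", "O2"),
    LOT = c("P9", "PO7"),
    ROT = c("P10", "P8", "PO8")
  )
}
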