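#' Default 40-channel fronto-parietal montage
#'
#' Channel labels of the default recording montage: 40 active electrodes of
#' the international 10-20 system (extended), covering frontal, central and
#' parietal cortex. The label \code{"AF5"} is retained as used by some
#' acquisition setups; \code{"AF7"} is accepted as an alias wherever labels
#' are matched.
#'
#' @return Character vector of 40 channel labels.
#' @export
default_montage <- function() {
  c("FP1", "FP2", "AF3", "AF4", "AF5",
    "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
    "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6",
    "C5", "C3", "C1", "Cz", "C2", "C4", "C6",
    "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6",
    "P3", "P1", "Pz", "P2", "P4")
}

#' Channels excluded before analysis
#'
#' Frontal channels most affected by ocular activity, removed from the
#' montage before artifact statistics and decoding (40 - 7 = 33 retained).
#'
#' @return Character vector of 7 channel labels.
#' @export
default_excluded_channels <- function() {
  c("FP1", "FP2", "AF3", "AF4", "AF5", "F5", "F6")
}

# Alias table for label dialect drift (AF5/AF7 denote the same electrode here).
.label_aliases <- c(AF7 = "AF5", AF8 = "AF6")

canonical_labels <- function(labels) {
  hit <- labels %in% names(.label_aliases)
  labels[hit] <- .label_aliases[labels[hit]]
  labels
}

#' Schematic 2-D scalp coordinates for 10-20 labels
#'
#' Maps 10-20 channel labels onto the unit head circle (nose towards +y,
#' left ear towards -x). Coordinates are schematic: rows (FP, AF, F, FC, C,
#' CP, P, PO, O) are placed at fixed anterior-posterior heights and numbered
#' positions spread laterally, compressed near the head rim.
#'
#' @param labels Character vector of 10-20 channel labels.
#' @return A data.frame with columns \code{label}, \code{x}, \code{y}.
#' @export
montage_coordinates <- function(labels) {
  labels <- as.character(labels)
  canon <- canonical_labels(labels)
  row_y <- c(FP = 0.90, AF = 0.72, F = 0.54, FC = 0.28, C = 0.00,
             CP = -0.28, P = -0.54, PO = -0.72, O = -0.90, T = 0.00)
  m <- regmatches(canon, regexec("^([A-Za-z]+?)(z|[0-9]+)$", canon))
  xs <- ys <- numeric(length(canon))
  for (i in seq_along(canon)) {
    if (length(m[[i]]) != 3L)
      stop("cannot place channel label '", labels[i], "' on the montage")
    row <- toupper(m[[i]][2]); pos <- m[[i]][3]
    if (row == "T") row <- "C"  # T7/T8 lie on the central row
    if (!row %in% names(row_y))
      stop("unknown 10-20 row in channel label '", labels[i], "'")
    y <- row_y[[row]]
    if (pos %in% c("z", "Z")) {
      x <- 0
    } else {
      n <- as.integer(pos)
      mag <- 0.2 * ceiling(n / 2)
      x <- ifelse(n %% 2 == 1L, -mag, mag)
    }
    xs[i] <- x * sqrt(max(0, 1 - y^2))
    ys[i] <- y
  }
  data.frame(label = labels, x = xs, y = ys, stringsAsFactors = FALSE)
}

#' Frontal channel subset of a montage
#'
#' Channels whose schematic y coordinate is at least \code{y_min}; used for
#' the frontal-concentration criterion when flagging ocular independent
#' components.
#'
#' @param labels Channel labels.
#' @param y_min Anterior cut-off on the unit head circle.
#' @return Character vector (subset of \code{labels}).
#' @export
frontal_channels <- function(labels, y_min = 0.5) {
  co <- montage_coordinates(labels)
  co$label[co$y >= y_min]
}
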