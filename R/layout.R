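# Unit-sphere 3-D electrode positions for the 19-channel 10-20 montage
# (classic T3/T4/T5/T6 naming). x = right, y = front, z = up.
.montage_1020 <- local({
  tab <- matrix(c(
    -0.329991,  0.940726, -0.078359,   # Fp1
     0.330899,  0.940402, -0.078426,   # Fp2
    -0.847627,  0.512395, -0.137767,   # F7
    -0.595220,  0.629189,  0.499834,   # F3
     0.003526,  0.660786,  0.750566,   # Fz
     0.606623,  0.635512,  0.477633,   # F4
     0.846108,  0.514567, -0.139004,   # F8
    -0.976571, -0.185874, -0.108447,   # T3
    -0.706876, -0.125802,  0.696060,   # C3
     0.003983, -0.091066,  0.995837,   # Cz
     0.720988, -0.117092,  0.682983,   # C4
     0.978884, -0.172815, -0.109187,   # T4
    -0.701950, -0.711819, -0.024101,   # T5
    -0.480960, -0.714878,  0.507570,   # P3
     0.002804, -0.700597,  0.713552,   # Pz
     0.498504, -0.703519,  0.506513,   # P4
     0.706832, -0.706954, -0.024575,   # T6
    -0.252329, -0.964666,  0.075827,   # O1
     0.256398, -0.963610,  0.075607    # O2
  ), ncol = 3, byrow = TRUE)
  rownames(tab) <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "T3", "C3",
                     "Cz", "C4", "T4", "T5", "P3", "Pz", "P4", "T6", "O1", "O2")
  colnames(tab) <- c("x", "y", "z")
  tab
})

#' Montage labels of the packaged 19-channel 10-20 fixture
#' @return Character vector of the 19 standard labels in montage order.
#' @export
montage_1020_labels <- function() rownames(.montage_1020)

#' Electrode coordinates for a set of 10-20 labels
#'
#' Looks up unit-sphere 3-D positions for channels of the standard 10-20
#' placement scheme (19-channel montage, classic temporal naming T3/T4/T5/T6).
#' Coordinates are unitless and normalized to the unit sphere, so inter-channel
#' Euclidean distances lie in \[0, 2\].
#'
#' @param labels Character vector of montage names; defaults to the full
#'   packaged 19-channel table.
#' @return An `electrode_layout`: list with `coords` (n x 3 matrix in label
#'   order, rows unit-normalized) and `labels`.
#' @export
#' @examples
#' lay <- standard_1020_layout(c("Cz", "O1"))
#' lay$coords
standard_1020_layout <- function(labels = montage_1020_labels()) {
  labels <- as.character(labels)
  unknown <- setdiff(labels, rownames(.montage_1020))
  if (length(unknown)) {
    stop(sprintf("unknown electrode label(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  coords <- .montage_1020[labels, , drop = FALSE]
  coords <- coords / sqrt(rowSums(coords^2))
  structure(list(coords = coords, labels = labels), class = "electrode_layout")
}
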