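#' Channel layout constructor
#'
#' A channel layout describes the montage of an epoched recording: channel
#' names, unit-sphere 3-D positions, a scalp region tag and a hemisphere tag
#' per channel. Region tags drive the regional channel groupings; hemisphere
#' tags drive the asymmetry contrasts.
#'
#' @param channel character vector of unique channel names.
#' @param x,y,z numeric electrode positions; they are projected onto the unit
#'   sphere (x = right, y = anterior, z = superior).
#' @param region one of `"frontal"`, `"central"`, `"parietal"`, `"occipital"`,
#'   `"lateral"` per channel.
#' @param hemisphere one of `"left"`, `"right"`, `"midline"` per channel.
#' @return a `channel_layout` data frame with one row per channel.
#' @export
channel_layout <- function(channel, x, y, z, region, hemisphere) {
  channel <- as.character(channel)
  if (anyDuplicated(channel)) stop("duplicate channel names")
  n <- length(channel)
  stopifnot(length(x) == n, length(y) == n, length(z) == n,
            length(region) == n, length(hemisphere) == n)
  region <- match.arg(as.character(region),
                      c("frontal", "central", "parietal", "occipital", "lateral"),
                      several.ok = TRUE)
  hemisphere <- match.arg(as.character(hemisphere),
                          c("left", "right", "midline"), several.ok = TRUE)
  nrm <- sqrt(x^2 + y^2 + z^2)
  if (any(nrm == 0) || any(!is.finite(nrm))) stop("positions must be finite and non-zero")
  out <- data.frame(channel = channel, x = x / nrm, y = y / nrm, z = z / nrm,
                    region = region, hemisphere = hemisphere,
                    stringsAsFactors = FALSE)
  pos <- as.matrix(out[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(pos))
  diag(d) <- Inf
  if (any(d < 1e-8)) stop("duplicate channel positions")
  class(out) <- c("channel_layout", "data.frame")
  out
}

## spherical placement: inclination from vertex (deg), azimuth from the
## anterior axis, positive toward the right ear (deg)
.sph <- function(incl, az) {
  ir <- incl * pi / 180; ar <- az * pi / 180
  c(x = sin(ir) * sin(ar), y = sin(ir) * cos(ar), z = cos(ir))
}

#' Default 32-channel extended 10-20 layout
#'
#' An idealised 32-channel montage on the unit sphere with region and
#' hemisphere tags chosen so that all 13 regional groupings, 5 asymmetry
#' contrasts and 7 ISPC pair sets are non-empty.
#'
#' @return a [channel_layout()].
#' @export
default_layout <- function() {
  spec <- list(
    # name,           incl, az,    region,      hemisphere
    list("Fp1",  90, -18, "frontal",  "left"),
    list("Fp2",  90,  18, "frontal",  "right"),
    list("F3",   60, -39, "frontal",  "left"),
    list("Fz",   46,   0, "frontal",  "midline"),
    list("F4",   60,  39, "frontal",  "right"),
    list("FC1",  32, -45, "frontal",  "left"),
    list("FC2",  32,  45, "frontal",  "right"),
    list("F7",   90, -54, "lateral",  "left"),
    list("F8",   90,  54, "lateral",  "right"),
    list("FC5",  71, -69, "lateral",  "left"),
    list("FC6",  71,  69, "lateral",  "right"),
    list("T7",   90, -90, "lateral",  "left"),
    list("T8",   90,  90, "lateral",  "right"),
    list("C3",   46, -90, "central",  "left"),
    list("Cz",    0,   0, "central",  "midline"),
    list("C4",   46,  90, "central",  "right"),
    list("CP1",  32, -135, "central", "left"),
    list("CP2",  32,  135, "central", "right"),
    list("CP5",  71, -111, "lateral", "left"),
    list("CP6",  71,  111, "lateral", "right"),
    list("TP9", 100, -108, "lateral", "left"),
    list("TP10", 100, 108, "lateral", "right"),
    list("P3",   60, -141, "parietal", "left"),
    list("Pz",   46,  180, "parietal", "midline"),
    list("P4",   60,  141, "parietal", "right"),
    list("P7",   90, -126, "lateral",  "left"),
    list("P8",   90,  126, "lateral",  "right"),
    list("O1",   90, -162, "occipital", "left"),
    list("Oz",   90,  180, "occipital", "midline"),
    list("O2",   90,  162, "occipital", "right"),
    list("PO9", 100, -144, "occipital", "left"),
    list("PO10", 100, 144, "occipital", "right"))
  pos <- t(vapply(spec, function(s) .sph(s[[2]], s[[3]]), numeric(3)))
  channel_layout(channel = vapply(spec, `[[`, "", 1),
                 x = pos[, 1], y = pos[, 2], z = pos[, 3],
                 region = vapply(spec, `[[`, "", 4),
                 hemisphere = vapply(spec, `[[`, "", 5))
}

#' Homologous left/right channel pairs of a layout
#'
#' Pairs each left-hemisphere channel with the right-hemisphere channel
#' nearest to its mirror image across the sagittal plane.
#'
#' @param layout a [channel_layout()].
#' @return two-column character matrix (left, right).
#' @export
homologous_pairs <- function(layout) {
  left <- layout[layout$hemisphere == "left", , drop = FALSE]
  right <- layout[layout$hemisphere == "right", , drop = FALSE]
  if (nrow(left) == 0L || nrow(right) == 0L)
    return(matrix(character(0), ncol = 2))
  rp <- as.matrix(right[, c("x", "y", "z")])
  out <- t(vapply(seq_len(nrow(left)), function(i) {
    mir <- c(-left$x[i], left$y[i], left$z[i])
    d <- colSums((t(rp) - mir)^2)
    c(left$channel[i], right$channel[which.min(d)])
  }, character(2)))
  colnames(out) <- c("left", "right")
  out
}
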