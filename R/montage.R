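# Idealized spherical 10-10 montage for the 30-channel scalp set (a 32
# electrode cap minus the two mastoids). Coordinates are constructed
# geometrically on the unit sphere: ring and midline electrodes at their
# exact 10-20 angles, intermediate 10-10 electrodes as spherical (slerp)
# midpoints of their neighbours. This is an idealized synthetic layout, not
# a digitized head shape.

sph_xyz <- function(colat_deg, azim_deg) {
  # +x right, +y front (nasion), +z vertex; azimuth from front midline,
  # positive towards the right ear
  c_ <- deg2rad(colat_deg)
  a <- deg2rad(azim_deg)
  c(sin(c_) * sin(a), sin(c_) * cos(a), cos(c_))
}

slerp_mid <- function(p, q) {
  m <- (p + q) / 2
  m / sqrt(sum(m^2))
}

#' Default 30-channel scalp montage
#'
#' Idealized unit-sphere positions for the 10-10 labels Fp1, Fpz, Fp2, F7,
#' F3, Fz, F4, F8, FC5, FC1, FC2, FC6, T7, C3, Cz, C4, T8, CP5, CP1, CP2,
#' CP6, P7, P3, Pz, P4, P8, POz, O1, Oz, O2.
#'
#' @param blacklist Labels of edge electrodes excluded from inference
#'   (attached as an attribute); defaults to the outer ring.
#' @return A data.frame with columns label, x, y, z and attribute
#'   "blacklist".
#' @export
default_montage <- function(blacklist = c("Fp1", "Fpz", "Fp2", "F7", "F8",
                                          "T7", "T8", "P7", "P8",
                                          "O1", "Oz", "O2")) {
  pos <- list(
    # outer ring, colatitude 72
    Fpz = sph_xyz(72, 0),    Fp1 = sph_xyz(72, -18), Fp2 = sph_xyz(72, 18),
    F7  = sph_xyz(72, -54),  F8  = sph_xyz(72, 54),
    T7  = sph_xyz(72, -90),  T8  = sph_xyz(72, 90),
    P7  = sph_xyz(72, -126), P8  = sph_xyz(72, 126),
    O1  = sph_xyz(72, -162), O2  = sph_xyz(72, 162), Oz = sph_xyz(72, 180),
    # midline and central coronal line
    Fz = sph_xyz(36, 0), Cz = sph_xyz(0, 0), Pz = sph_xyz(36, 180),
    C3 = sph_xyz(36, -90), C4 = sph_xyz(36, 90)
  )
  pos$F3 <- slerp_mid(pos$Fz, pos$F7);  pos$F4 <- slerp_mid(pos$Fz, pos$F8)
  pos$P3 <- slerp_mid(pos$Pz, pos$P7);  pos$P4 <- slerp_mid(pos$Pz, pos$P8)
  fcz <- slerp_mid(pos$Fz, pos$Cz); cpz <- slerp_mid(pos$Cz, pos$Pz)
  fc3 <- slerp_mid(pos$F3, pos$C3); fc4 <- slerp_mid(pos$F4, pos$C4)
  cp3 <- slerp_mid(pos$C3, pos$P3); cp4 <- slerp_mid(pos$C4, pos$P4)
  ft7 <- slerp_mid(pos$F7, pos$T7); ft8 <- slerp_mid(pos$F8, pos$T8)
  tp7 <- slerp_mid(pos$T7, pos$P7); tp8 <- slerp_mid(pos$T8, pos$P8)
  pos$FC1 <- slerp_mid(fcz, fc3); pos$FC2 <- slerp_mid(fcz, fc4)
  pos$FC5 <- slerp_mid(fc3, ft7); pos$FC6 <- slerp_mid(fc4, ft8)
  pos$CP1 <- slerp_mid(cpz, cp3); pos$CP2 <- slerp_mid(cpz, cp4)
  pos$CP5 <- slerp_mid(cp3, tp7); pos$CP6 <- slerp_mid(cp4, tp8)
  pos$POz <- slerp_mid(pos$Pz, pos$Oz)

  order30 <- c("Fp1", "Fpz", "Fp2", "F7", "F3", "Fz", "F4", "F8",
               "FC5", "FC1", "FC2", "FC6", "T7", "C3", "Cz", "C4", "T8",
               "CP5", "CP1", "CP2", "CP6", "P7", "P3", "Pz", "P4", "P8",
               "POz", "O1", "Oz", "O2")
  m <- do.call(rbind, pos[order30])
  out <- data.frame(label = order30, x = m[, 1], y = m[, 2], z = m[, 3],
                    row.names = NULL)
  stopifnot(!anyDuplicated(out$label))
  attr(out, "blacklist") <- intersect(blacklist, order30)
  out
}

#' Write a montage to JSON
#' @param montage A montage data.frame from [default_montage()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_montage_json <- function(montage, path) {
  jsonlite::write_json(
    list(channels = montage, blacklist = attr(montage, "blacklist")),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows"
  )
  invisible(path)
}

#' Read a montage from JSON
#' @param path JSON path written by [write_montage_json()].
#' @return A montage data.frame with the "blacklist" attribute.
#' @export
read_montage_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- as.data.frame(raw$channels)
  attr(out, "blacklist") <- raw$blacklist
  out
}
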