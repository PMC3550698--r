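#' 17-segment left-ventricular mask for a polar-map geometry
#'
#' Partitions a ring x sector polar map into the standard 17-segment LV model:
#' 6 basal segments (60 degrees each) on the outer third of rings, 6 mid
#' segments on the middle third, 4 apical segments (90 degrees each) on the
#' inner third, and the apical cap (segment 17) on the innermost rings.
#'
#' Segment numbering follows the standard polar display: 1 basal anterior,
#' 2 basal anteroseptal, 3 basal inferoseptal, 4 basal inferior,
#' 5 basal inferolateral, 6 basal anterolateral; 7-12 the same order at
#' mid-cavity; 13 apical anterior, 14 apical septal, 15 apical inferior,
#' 16 apical lateral; 17 apex.
#'
#' Ring allocation: the apex core is the innermost `ceiling(n_rings / 9)`
#' rings; the remaining rings split into thirds by floor division with the
#' remainder given to the basal zone, so the partition is exact for any
#' supported `n_rings`. Angular assignment is by bin-centre angle with
#' half-open arcs, so every bin belongs to exactly one segment even when a
#' segment boundary falls inside a bin.
#'
#' @param n_rings number of rings (>= 4).
#' @param n_sectors number of sectors; must be divisible by 6 and by 4.
#' @return Integer matrix `(n_rings, n_sectors)` of segment ids 1-17, with
#'   class `segment_mask`.
#' @export
build_segment_mask <- function(n_rings = 36L, n_sectors = 60L) {
  n_rings <- as.integer(n_rings); n_sectors <- as.integer(n_sectors)
  if (n_rings < 4L) stop("`n_rings` must be at least 4")
  if (n_sectors %% 6L != 0L || n_sectors %% 4L != 0L)
    stop("`n_sectors` must be divisible by 6 and by 4")
  n_apex <- ceiling(n_rings / 9)
  n_rem <- n_rings - n_apex
  n_third <- n_rem %/% 3L
  if (n_third < 1L) stop("`n_rings` too small for three zones plus apex core")
  n_basal <- n_rem - 2L * n_third
  # ring 1 is innermost (apex); zones from the centre outward
  zone <- rep.int(c(0L, 1L, 2L, 3L), c(n_apex, n_third, n_third, n_basal))
  # bin-centre angle counterclockwise from anterior, degrees
  alpha <- (seq_len(n_sectors) - 1) * 360 / n_sectors
  seg6 <- floor(((alpha + 30) %% 360) / 60) # 0 anterior .. 5 anterolateral
  seg4 <- floor(((alpha + 45) %% 360) / 90) # 0 anterior .. 3 lateral
  m <- matrix(17L, n_rings, n_sectors)
  for (j in seq_len(n_sectors)) {
    m[zone == 1L, j] <- 13L + seg4[j]
    m[zone == 2L, j] <- 7L + seg6[j]
    m[zone == 3L, j] <- 1L + seg6[j]
  }
  structure(m, class = c("segment_mask", "matrix", "array"))
}

#' Mean percent uptake per segment
#'
#' @param polar a normalized `polar_map`.
#' @param mask a `segment_mask` of matching dimensions.
#' @return Numeric vector of 17 segment means (percent uptake).
#' @export
segment_mean_uptake <- function(polar, mask) {
  stopifnot(inherits(polar, "polar_map"), inherits(mask, "segment_mask"))
  if (!all(dim(polar$uptake) == dim(mask)))
    stop("polar map and segment mask dimensions differ")
  means <- vapply(1:17, function(s) mean(polar$uptake[mask == s]), numeric(1))
  names(means) <- paste0("seg", 1:17)
  means
}
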