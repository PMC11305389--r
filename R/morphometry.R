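#' Spine classification thresholds
#'
#' Threshold set used to assign each dendritic spine to one of the four
#' canonical morphological classes (thin, stubby, mushroom, filopodia).
#' Defaults are the established Neurolucida parameters: head-to-neck ratio
#' 1.1, length-to-head ratio 2.5, mushroom head size 0.35 um, filopodium
#' length 3.0 um.
#'
#' @param head_neck_ratio head/neck diameter ratio separating mushroom-like
#'   from thin-like necked spines.
#' @param length_head_ratio length/head ratio marking elongated spines.
#' @param mushroom_head minimum head diameter (um) for the mushroom class.
#' @param filopodium_length minimum total length (um) for filopodia.
#' @return A list of class \code{"classifier_thresholds"}.
#' @export
classifier_thresholds <- function(head_neck_ratio = 1.1,
                                  length_head_ratio = 2.5,
                                  mushroom_head = 0.35,
                                  filopodium_length = 3.0) {
  t <- list(head_neck_ratio = head_neck_ratio,
            length_head_ratio = length_head_ratio,
            mushroom_head = mushroom_head,
            filopodium_length = filopodium_length)
  if (any(!vapply(t, function(x) is.numeric(x) && length(x) == 1 && x > 0,
                  logical(1))))
    stop("all classifier thresholds must be single positive numbers")
  class(t) <- "classifier_thresholds"
  t
}

#' Names of the four spine morphology classes
#' @return Character vector: thin, stubby, mushroom, filopodia.
#' @export
spine_classes <- function() c("thin", "stubby", "mushroom", "filopodia")

#' Curvilinear spine length
#'
#' Backbone length from the insertion point to the most distal point,
#' computed as the sum of Euclidean distances between consecutive backbone
#' points.
#'
#' @param backbone numeric matrix (n x 3) of backbone coordinates in um,
#'   ordered insertion point first.
#' @return Length in um; always at least the straight insertion-to-tip
#'   distance.
#' @export
spine_length <- function(backbone) {
  backbone <- as.matrix(backbone)
  if (nrow(backbone) < 2)
    stop("spine backbone needs at least 2 points")
  d <- diff(backbone)
  sum(sqrt(rowSums(d * d)))
}

#' Head and neck diameter from a backbone diameter profile
#'
#' The head diameter is the breadth of the spine head at its widest
#' cross-sectional point; operationally, the profile is split at its global
#' minimum strictly between insertion and tip: the neck diameter is that
#' minimum (the insertion point itself is excluded) and the head diameter is
#' the maximum over the distal portion from the minimum to the tip.
#' Profiles too short to have an interior point are flagged degenerate and
#' fall back to the global max/min.
#'
#' @param diameter_profile numeric vector of per-point diameters (um),
#'   ordered insertion point first.
#' @return List with \code{head}, \code{neck} (um) and logical
#'   \code{degenerate}.
#' @export
head_and_neck <- function(diameter_profile) {
  d <- as.numeric(diameter_profile)
  k <- length(d)
  if (k < 2 || any(!is.finite(d)) || any(d <= 0))
    stop("diameter profile must have >= 2 finite positive values")
  if (k < 3)
    return(list(head = max(d), neck = min(d), degenerate = TRUE))
  interior <- 2:(k - 1)
  m <- interior[which.min(d[interior])]
  list(head = max(d[m:k]), neck = d[m], degenerate = FALSE)
}

#' Spine volume from voxel count
#'
#' Volume is the number of voxels making up the reconstructed spine object
#' multiplied by the volume of a single voxel.
#'
#' @param voxel_count integer voxel count (>= 1); vectorized.
#' @param voxel_dims numeric 3-vector of voxel edge lengths (um).
#' @return Volume in um^3.
#' @export
spine_volume <- function(voxel_count, voxel_dims) {
  if (length(voxel_dims) != 3 || any(voxel_dims <= 0))
    stop("voxel_dims must be 3 positive edge lengths (um)")
  if (any(voxel_count < 1)) stop("voxel_count must be >= 1")
  voxel_count * prod(voxel_dims)
}

#' Classify spines from measured morphology
#'
#' Rule order: (1) head-to-neck ratio > 1.1 and head diameter > 0.35 um is
#' mushroom; (2) head-to-neck ratio < 1.1 and either length-to-head ratio
#' > 2.5 or head diameter < 0.35 um is filopodia when total length > 3.0 um,
#' thin otherwise; (3) everything else is stubby.  Stubby is the residual
#' class: boundary cases the quoted rules leave unmatched (ratio exactly at
#' the threshold, or ratio above it with a small head) land there and are
#' flagged by \code{\link{classify_residual_flag}}.
#'
#' @param head_diameter,neck_diameter,length numeric vectors (um), recycled
#'   to common length.
#' @param thresholds a \code{\link{classifier_thresholds}} object.
#' @return Character vector of class labels.
#' @export
classify_spine <- function(head_diameter, neck_diameter, length,
                           thresholds = classifier_thresholds()) {
  n <- max(length(head_diameter), length(neck_diameter), length(length))
  head_diameter <- rep_len(head_diameter, n)
  neck_diameter <- rep_len(neck_diameter, n)
  length <- rep_len(length, n)
  if (any(!is.finite(head_diameter)) || any(!is.finite(neck_diameter)) ||
      any(!is.finite(length)))
    stop("non-finite spine measurements")
  if (any(head_diameter <= 0) || any(neck_diameter <= 0) || any(length <= 0))
    stop("spine measurements must be positive")
  hnr <- head_diameter / neck_diameter
  lhr <- length / head_diameter
  out <- rep("stubby", n)
  mush <- hnr > thresholds$head_neck_ratio &
    head_diameter > thresholds$mushroom_head
  guard <- !mush & hnr < thresholds$head_neck_ratio &
    (lhr > thresholds$length_head_ratio |
       head_diameter < thresholds$mushroom_head)
  out[mush] <- "mushroom"
  out[guard & length > thresholds$filopodium_length] <- "filopodia"
  out[guard & length <= thresholds$filopodium_length] <- "thin"
  out
}

#' Flag spines routed to stubby by the residual rule
#'
#' TRUE where the spine matched neither the mushroom rule nor the
#' thin/filopodia guard yet has head-to-neck ratio at or above the mushroom
#' cut — the corner the classification rules leave undefined.
#'
#' @inheritParams classify_spine
#' @return Logical vector.
#' @export
classify_residual_flag <- function(head_diameter, neck_diameter, length,
                                   thresholds = classifier_thresholds()) {
  hnr <- head_diameter / neck_diameter
  mush <- hnr > thresholds$head_neck_ratio &
    head_diameter > thresholds$mushroom_head
  !mush & hnr >= thresholds$head_neck_ratio
}

#' Spine density per 10 um of dendrite
#'
#' @param spine_count spine count on the segment; vectorized.
#' @param segment_length segment length in um (> 0).
#' @return Spines per 10 um of dendrite length.
#' @export
segment_density <- function(spine_count, segment_length) {
  if (any(segment_length <= 0)) stop("segment_length must be positive")
  10 * spine_count / segment_length
}

#' Measure and classify one spine geometry
#'
#' @param geometry a spine geometry: list with \code{backbone} (n x 3 matrix,
#'   um), \code{diameter_profile} (um per backbone point),
#'   \code{voxel_count}, \code{voxel_dims}.
#' @param thresholds a \code{\link{classifier_thresholds}} object.
#' @return List with length_um, head_diameter_um, neck_diameter_um,
#'   volume_um3, head_neck_ratio, length_head_ratio, spine_class,
#'   residual_flag, degenerate_profile.
#' @export
measure_spine <- function(geometry, thresholds = classifier_thresholds()) {
  len <- spine_length(geometry$backbone)
  hn <- head_and_neck(geometry$diameter_profile)
  vol <- spine_volume(geometry$voxel_count, geometry$voxel_dims)
  cls <- classify_spine(hn$head, hn$neck, len, thresholds)
  list(length_um = len,
       head_diameter_um = hn$head,
       neck_diameter_um = hn$neck,
       volume_um3 = vol,
       head_neck_ratio = hn$head / hn$neck,
       length_head_ratio = len / hn$head,
       spine_class = cls,
       residual_flag = classify_residual_flag(hn$head, hn$neck, len,
                                              thresholds),
       degenerate_profile = hn$degenerate)
}

#' Measure and classify all spines in a long-format geometry table
#'
#' @param geometry a data.frame/data.table in the geometry CSV schema: one
#'   row per backbone point with columns case_id, region, neuron_id,
#'   segment_id, spine_id, point_index, x_um, y_um, z_um, diameter_um,
#'   voxel_count, voxel_x_um, voxel_y_um, voxel_z_um.
#' @param thresholds a \code{\link{classifier_thresholds}} object.
#' @return data.table, one row per spine, with the measured columns of
#'   \code{\link{measure_spine}}.
#' @export
measure_spines <- function(geometry, thresholds = classifier_thresholds()) {
  g <- data.table::as.data.table(geometry)
  need <- c("case_id", "region", "neuron_id", "segment_id", "spine_id",
            "point_index", "x_um", "y_um", "z_um", "diameter_um",
            "voxel_count", "voxel_x_um", "voxel_y_um", "voxel_z_um")
  miss <- setdiff(need, names(g))
  if (length(miss))
    stop("geometry table lacks required um-unit columns: ",
         paste(miss, collapse = ", "))
  point_index <- NULL  # NSE note for R CMD check
  data.table::setorderv(g, c("case_id", "region", "neuron_id", "segment_id",
                             "spine_id", "point_index"))
  g[, {
    bb <- cbind(x_um, y_um, z_um)
    hn <- head_and_neck(diameter_um)
    len <- spine_length(bb)
    list(length_um = len,
         head_diameter_um = hn$head,
         neck_diameter_um = hn$neck,
         volume_um3 = spine_volume(voxel_count[1],
                                   c(voxel_x_um[1], voxel_y_um[1],
                                     voxel_z_um[1])),
         voxel_count = voxel_count[1],
         spine_class = classify_spine(hn$head, hn$neck, len, thresholds),
         residual_flag = classify_residual_flag(hn$head, hn$neck, len,
                                                thresholds),
         degenerate_profile = hn$degenerate)
  }, by = c("case_id", "region", "neuron_id", "segment_id", "spine_id")]
}
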