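#' Landmark pair defining the protraction distance
#'
#' Two bony landmarks, in mm coordinates of the stated frame, from which the
#' shoulder protraction distance is measured: the anterior tubercle of the
#' C5 vertebra and the infraglenoid tubercle of the scapula.
#'
#' @param c5_anterior_tubercle Numeric length-3 mm coordinate.
#' @param infraglenoid_tubercle Numeric length-3 mm coordinate.
#' @param frame Axis-convention tag; the anterior-posterior direction is
#'   axis 2 of this frame. Default `"LPS"`.
#'
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(c5_anterior_tubercle, infraglenoid_tubercle,
                         frame = "LPS") {
  for (p in list(c5_anterior_tubercle, infraglenoid_tubercle)) {
    if (length(p) != 3L || any(!is.finite(p))) {
      stop("landmarks must be finite length-3 mm coordinates", call. = FALSE)
    }
  }
  if (is.null(frame) || !nzchar(frame)) {
    stop("`frame` tag must be present", call. = FALSE)
  }
  structure(
    list(c5_anterior_tubercle = as.numeric(c5_anterior_tubercle),
         infraglenoid_tubercle = as.numeric(infraglenoid_tubercle),
         frame = frame),
    class = "landmark_set"
  )
}

#' One atlas: gold-standard mask, landmarks and derived protraction
#'
#' @param id Unique atlas identifier (character scalar).
#' @param gold_mask A [label_volume()] holding the gold-standard
#'   segmentation.
#' @param landmarks A [landmark_set()].
#'
#' @return An object of class `atlas_record` with the protraction distance
#'   derived from the landmarks (`protraction_mm`).
#' @export
atlas_record <- function(id, gold_mask, landmarks) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is_label_volume(gold_mask), inherits(landmarks, "landmark_set"))
  structure(
    list(id = id, gold_mask = gold_mask, landmarks = landmarks,
         protraction_mm = protraction_distance(landmarks)),
    class = "atlas_record"
  )
}

#' Protraction distance from a landmark pair
#'
#' The protraction distance is the horizontal distance, in the sagittal
#' plane, between a vertical line through the anterior tubercle of C5 and a
#' vertical line through the infraglenoid tubercle: the absolute difference
#' of the two landmarks' anterior-posterior coordinates. It quantifies how
#' far the shoulder girdle sits forward, the morphometric criterion used to
#' pick patient-similar atlases.
#'
#' @param landmarks A [landmark_set()].
#' @return Non-negative distance in mm. Symmetric in the two landmarks.
#' @export
#' @examples
#' lm <- landmark_set(c(10, 50, 100), c(80, 30, 40))
#' protraction_distance(lm) # 20
protraction_distance <- function(landmarks) {
  if (!inherits(landmarks, "landmark_set")) {
    stop("`landmarks` must be a landmark_set", call. = FALSE)
  }
  abs(landmarks$infraglenoid_tubercle[2] - landmarks$c5_anterior_tubercle[2])
}

#' Rank atlases by protraction similarity to a patient
#'
#' Sorts candidate atlases by the absolute difference between their
#' protraction distance and the patient's, most similar first. Ties are
#' broken by atlas id (lexicographic) so runs are reproducible.
#'
#' @param patient_protraction Patient protraction distance in mm.
#' @param atlases Non-empty list of [atlas_record()] objects (the patient
#'   itself must not be in the list).
#'
#' @return The same atlases, reordered.
#' @export
rank_atlases <- function(patient_protraction, atlases) {
  if (length(atlases) == 0L) {
    stop("`atlases` must be a non-empty list", call. = FALSE)
  }
  stopifnot(is.numeric(patient_protraction), length(patient_protraction) == 1L)
  dist <- vapply(atlases, function(a) abs(a$protraction_mm - patient_protraction),
                 numeric(1))
  ids <- vapply(atlases, function(a) a$id, character(1))
  atlases[order(dist, ids, method = "radix")]
}

#' Take the first k atlases of a ranked list
#'
#' @param ranked Ranked list, as returned by [rank_atlases()].
#' @param k Number of atlases to keep, `1 <= k <= length(ranked)`.
#' @return The first `k` elements, order preserved.
#' @export
select_top_k <- function(ranked, k) {
  if (!is.numeric(k) || length(k) != 1L || k != as.integer(k) ||
      k < 1L || k > length(ranked)) {
    stop(sprintf("`k` (%s) must be an integer in [1, %d]",
                 format(k), length(ranked)), call. = FALSE)
  }
  ranked[seq_len(k)]
}
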