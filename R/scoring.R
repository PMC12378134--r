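#' Visual segmental defect score from percent counts
#'
#' The segmental 0-4 visual scale used for MIBG uptake: 0 (normal),
#' 1 (slight), 2 (moderate), 3 (severely decreased), 4 (absent), assigned
#' from percent counts per segment with bands >= 70%, 60-69%, 50-59%,
#' 40-49% and < 40% of reference.
#'
#' @param uptake Percent uptake value(s), non-negative.
#' @return Integer score(s) in 0..4.
#' @examples
#' visual_score_segment(c(72, 45, 35))
#' @export
visual_score_segment <- function(uptake) {
  uptake <- as.numeric(uptake)
  if (any(!is.finite(uptake)) || any(uptake < 0))
    stop("percent uptake must be finite and non-negative", call. = FALSE)
  ifelse(uptake >= 70, 0L,
  ifelse(uptake >= 60, 1L,
  ifelse(uptake >= 50, 2L,
  ifelse(uptake >= 40, 3L, 4L))))
}

#' Automated segmental defect score against a normal database
#'
#' Scores a segment by how many SDs its uptake falls below the normal mean:
#' `z = (mean_s - uptake_s) / sd_s`, with score equal to the number of
#' threshold multipliers (default 2, 3, 4, 5) that `z` meets or exceeds,
#' capped at 4. Uptake at or above the normal mean always scores 0; the
#' mapping is monotone non-increasing in uptake. Segments whose database SD
#' falls below `sd_floor` are scored with the floor to avoid division
#' blow-up (a warning is emitted once per call).
#'
#' @param uptake Percent uptake, one value per segment (length 17 for a
#'   whole profile, or any length with matching `segments`).
#' @param ndb A [build_ndb()] database.
#' @param thresholds Increasing SD multipliers mapping to scores 1..4.
#' @param sd_floor Minimum SD (percent) used in the denominator.
#' @param segments Segment indices corresponding to `uptake` (default
#'   `seq_along(uptake)`).
#' @return Integer score(s) in 0..4.
#' @export
auto_score_segment <- function(uptake, ndb, thresholds = c(2, 3, 4, 5),
                               sd_floor = 0.5,
                               segments = seq_along(uptake)) {
  stopifnot(inherits(ndb, "normal_database"))
  uptake <- as.numeric(uptake)
  if (any(!is.finite(uptake)) || any(uptake < 0))
    stop("percent uptake must be finite and non-negative", call. = FALSE)
  if (length(thresholds) != 4L || any(diff(thresholds) <= 0))
    stop("thresholds must be 4 increasing SD multipliers", call. = FALSE)
  if (any(segments < 1L | segments > 17L))
    stop("segment indices must lie in 1..17", call. = FALSE)
  sd_s <- ndb$sd[segments]
  if (any(sd_s <= 0) && sd_floor <= 0)
    stop("scoring undefined: database SD is zero and no sd_floor set",
         call. = FALSE)
  if (any(sd_s < sd_floor))
    warning(sum(sd_s < sd_floor),
            " segment(s) with database SD below the floor of ", sd_floor,
            "%; floor applied", call. = FALSE)
  z <- (ndb$mean[segments] - uptake) / pmax(sd_s, sd_floor)
  vapply(z, function(zz) sum(zz >= thresholds), integer(1))
}

#' Summed defect score over the 17 segments
#'
#' The sum of the segmental 0-4 scores, range 0-68: the summed early score
#' (SES) for early-phase profiles and summed late score (SLS) for
#' late-phase profiles.
#'
#' @param scores Integer vector of 17 segmental scores in 0..4.
#' @return Integer in 0..68.
#' @export
summed_score <- function(scores) {
  scores <- as.integer(scores)
  if (length(scores) != 17L || anyNA(scores))
    stop("incomplete score: 17 valid segment scores are required",
         call. = FALSE)
  if (any(scores < 0L | scores > 4L))
    stop("segment scores must lie in 0..4", call. = FALSE)
  sum(scores)
}

#' Score every subject of a cohort
#'
#' Applies either the visual percent-count banding rule or NDB-relative
#' automated scoring to each row of a cohort and appends the summed score.
#'
#' @param cohort Cohort data frame (see [build_ndb()]).
#' @param method `"ndb_auto"` or `"visual_rule"`.
#' @param ndb Normal database, required for `"ndb_auto"`. Its phase must
#'   match the cohort rows being scored.
#' @param ndb_id Label recorded in the output (default: the database's
#'   population label, or `NA` for visual scoring).
#' @inheritParams auto_score_segment
#' @return Data frame with `subject_id`, `population`, `sex`, `phase`
#'   (plus `label` if present), the 17 segmental scores, `summed`,
#'   `method` and `ndb_id`.
#' @export
score_cohort <- function(cohort, method = c("ndb_auto", "visual_rule"),
                         ndb = NULL, thresholds = c(2, 3, 4, 5),
                         sd_floor = 0.5, ndb_id = NULL) {
  method <- match.arg(method)
  m <- profile_matrix(cohort)
  if (method == "ndb_auto") {
    if (!inherits(ndb, "normal_database"))
      stop("ndb_auto scoring needs a normal_database", call. = FALSE)
    if (!all(cohort$phase == ndb$phase))
      stop("stratum error: cohort phase differs from the database phase",
           call. = FALSE)
    if (is.null(ndb_id)) ndb_id <- ndb$population
    scores <- t(apply(m, 1, auto_score_segment, ndb = ndb,
                      thresholds = thresholds, sd_floor = sd_floor))
  } else {
    if (is.null(ndb_id)) ndb_id <- NA_character_
    scores <- matrix(visual_score_segment(m), nrow(m), 17L)
  }
  colnames(scores) <- seg_cols()
  meta_cols <- intersect(c("subject_id", "population", "sex", "phase",
                           "label"), names(cohort))
  out <- cbind(cohort[, meta_cols, drop = FALSE], as.data.frame(scores))
  out$summed <- apply(scores, 1, summed_score)
  out$method <- method
  out$ndb_id <- ndb_id
  rownames(out) <- NULL
  out
}
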