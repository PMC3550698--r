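#' Threshold table mapping relative uptake to 0-4 scores
#'
#' Four strictly decreasing percent-uptake boundaries. A segment whose
#' relative uptake lies above all boundaries scores 0 (normal); below all
#' four it scores 4 (absent uptake). Equality with a boundary takes the
#' milder score (inclusive downward). The defaults (70, 50, 30, 10) are the
#' conventional 5-point bands; they are fully configurable.
#'
#' @param boundaries 4 strictly decreasing values in (0, 100).
#' @return A `threshold_table`.
#' @export
threshold_table <- function(boundaries = c(70, 50, 30, 10)) {
  boundaries <- as.numeric(boundaries)
  if (length(boundaries) != 4L || any(diff(boundaries) >= 0) ||
      any(boundaries <= 0) || any(boundaries >= 100))
    stop("`boundaries` must be 4 strictly decreasing values in (0, 100)")
  structure(list(boundaries = boundaries), class = "threshold_table")
}

#' Normal database of per-segment reference uptake
#'
#' Per-segment mean and SD of percent uptake for each tracer, against which a
#' patient's segment uptake is expressed. The shipped default is uniform
#' (mean 100 for every segment and tracer), which reduces scoring to raw
#' percent-uptake bands; [build_normal_db()] constructs one from a phantom
#' population.
#'
#' @param table data frame with columns `tracer`, `segment`, `mean`, `sd`.
#' @return A `normal_db`.
#' @export
normal_db <- function(table) {
  need <- c("tracer", "segment", "mean", "sd")
  if (!all(need %in% names(table))) stop("normal database needs columns: ",
                                         paste(need, collapse = ", "))
  if (any(table$mean <= 0) || any(table$mean > 100))
    stop("normal means must lie in (0, 100]")
  if (any(table$sd <= 0)) stop("normal SDs must be positive")
  if (any(!table$segment %in% 1:17)) stop("segment ids must be 1..17")
  structure(list(table = as.data.frame(table)), class = "normal_db")
}

#' Uniform normal database (mean 100 everywhere)
#'
#' @param sd common SD assigned to every segment (must be positive).
#' @param tracers tracer labels to cover.
#' @return A `normal_db`.
#' @export
uniform_normal_db <- function(sd = 5,
                              tracers = c("TL_STRESS", "TL_REST", "BMIPP")) {
  normal_db(data.frame(
    tracer = rep(tracers, each = 17),
    segment = rep(1:17, length(tracers)),
    mean = 100, sd = sd))
}

normal_mean_for <- function(normaldb, tracer, segment_id) {
  if (!segment_id %in% 1:17) stop("unknown segment id: ", segment_id)
  tab <- normaldb$table
  row <- tab[tab$tracer == tracer & tab$segment == segment_id, ]
  if (nrow(row) != 1L)
    stop("normal database has no entry for ", tracer, " segment ", segment_id)
  row$mean
}

#' Score one segment from its mean percent uptake
#'
#' Relative uptake = segment mean / normal-database mean x 100, capped at
#' 100. The score is the number of threshold boundaries strictly above the
#' relative uptake, so uptake equal to a boundary takes the milder score.
#'
#' @param mean_pct segment mean uptake in `[0, 100]` percent.
#' @param tracer tracer label.
#' @param thresholds a [threshold_table()].
#' @param normaldb a [normal_db()].
#' @param segment_id segment number 1-17.
#' @return Integer score in 0-4.
#' @export
score_segment <- function(mean_pct, tracer, thresholds = threshold_table(),
                          normaldb = uniform_normal_db(), segment_id) {
  if (is.na(mean_pct) || mean_pct < 0 || mean_pct > 100)
    stop("`mean_pct` must lie in [0, 100]")
  ref <- normal_mean_for(normaldb, tracer, segment_id)
  rel <- min(mean_pct / ref * 100, 100)
  sum(thresholds$boundaries > rel)
}

#' Score all 17 segments of a polar map
#'
#' Runs [segment_mean_uptake()] then [score_segment()] per segment.
#'
#' @param polar normalized `polar_map`.
#' @param mask `segment_mask`.
#' @inheritParams score_segment
#' @return A `segment_scores` object: list with `scores` (17 integers 0-4),
#'   `segment_mean_uptake` (17 values) and `tracer`.
#' @export
score_segments <- function(polar, mask, tracer,
                           thresholds = threshold_table(),
                           normaldb = uniform_normal_db()) {
  means <- segment_mean_uptake(polar, mask)
  scores <- vapply(1:17, function(s)
    score_segment(means[s], tracer, thresholds, normaldb, s), numeric(1))
  segment_scores(as.integer(scores), tracer, means)
}

#' Construct a `segment_scores` object
#'
#' @param scores 17 integers in 0-4.
#' @param tracer tracer label.
#' @param segment_mean_uptake optional 17 mean uptake values.
#' @return A `segment_scores`.
#' @export
segment_scores <- function(scores, tracer, segment_mean_uptake = NULL) {
  scores <- as.integer(scores)
  if (length(scores) != 17L) stop("need 17 segment scores")
  if (any(is.na(scores)) || any(scores < 0L) || any(scores > 4L))
    stop("segment scores must lie in {0, 1, 2, 3, 4}")
  structure(list(scores = scores, tracer = tracer,
                 segment_mean_uptake = segment_mean_uptake),
            class = "segment_scores")
}

#' @export
print.segment_scores <- function(x, ...) {
  cat(sprintf("<segment_scores> %s: sum %d | %s\n", x$tracer,
              sum(x$scores), paste(x$scores, collapse = " ")))
  invisible(x)
}

#' Summed score over the 17 segments
#'
#' @param scores a `segment_scores` or an integer vector of 17 scores.
#' @return Integer sum in `[0, 68]` (SSS, SRS or SBS depending on tracer).
#' @export
summed_score <- function(scores) {
  v <- if (inherits(scores, "segment_scores")) scores$scores else as.integer(scores)
  if (length(v) != 17L || any(is.na(v)) || any(v < 0L) || any(v > 4L))
    stop("segment scores must be 17 integers in 0-4")
  sum(v)
}

#' Summed difference score (SDS) from stress and rest thallium scores
#'
#' Per-segment clamped difference: `sum(max(stress_i - rest_i, 0))`. A rest
#' score exceeding the stress score in a segment contributes 0, so SDS is
#' always non-negative and equals SSS - SRS when no segment reverses.
#'
#' @param stress `segment_scores` with tracer `TL_STRESS`.
#' @param rest `segment_scores` with tracer `TL_REST`.
#' @return Integer SDS in `[0, 68]`.
#' @export
summed_difference <- function(stress, rest) {
  stopifnot(inherits(stress, "segment_scores"), inherits(rest, "segment_scores"))
  if (stress$tracer != "TL_STRESS" || rest$tracer != "TL_REST")
    stop("SDS requires stress and rest thallium score sets (tracer mismatch)")
  sum(pmax(stress$scores - rest$scores, 0L))
}

#' Classify a summed score as abnormal
#'
#' Abnormal is defined as summed score >= `cutoff` (default 4); scores <= 3
#' are normal at the default cutoff.
#'
#' @param summed non-negative summed score.
#' @param cutoff abnormality cutoff (default 4).
#' @return Logical: `TRUE` if abnormal.
#' @export
classify_abnormal <- function(summed, cutoff = 4L) {
  if (any(is.na(summed)) || any(summed < 0)) stop("summed score must be non-negative")
  if (cutoff < 1) stop("`cutoff` must be at least 1")
  summed >= cutoff
}
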