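# CSV serialization of the tabular artifacts. Floats are written with
# 6 decimals; absent fields (untracked frames) are written empty.

fmt6 <- function(x) {
  ifelse(is.na(x), "", formatC(x, format = "f", digits = 6))
}

# Atomic write: assemble in a sibling temp file, then rename.
write_lines_atomic <- function(lines, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  writeLines(lines, tmp)
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(path)
}

csv_line <- function(...) paste(c(...), collapse = ",")

#' Write interest points as CSV
#'
#' Header `x,y,scale,response,sign`, one row per point, floats with 6
#' decimals.
#'
#' @param pts Tibble from [detect_interest_points()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_keypoints_csv <- function(pts, path) {
  lines <- c("x,y,scale,response,sign",
             vapply(seq_len(nrow(pts)), function(i) csv_line(
               fmt6(pts$x[i]), fmt6(pts$y[i]), fmt6(pts$scale[i]),
               fmt6(pts$response[i]), format(pts$sign[i])), character(1)))
  write_lines_atomic(lines, path)
}

#' Write descriptors as CSV
#'
#' Header `x,y,scale,sign,v0..v63`.
#'
#' @param desc Tibble from [describe_points()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_descriptors_csv <- function(desc, path) {
  vcols <- paste0("v", 0:63)
  header <- csv_line("x", "y", "scale", "sign", vcols)
  lines <- c(header, vapply(seq_len(nrow(desc)), function(i) csv_line(
    fmt6(desc$x[i]), fmt6(desc$y[i]), fmt6(desc$scale[i]),
    format(desc$sign[i]),
    fmt6(as.numeric(desc[i, vcols]))), character(1)))
  write_lines_atomic(lines, path)
}

#' Write matches as CSV
#'
#' Header `query_index,train_index,distance,is_inlier` (indices
#' 1-based; `is_inlier` empty when no homography was estimated).
#'
#' @param matches Tibble from [match_descriptors()].
#' @param path Output path.
#' @param h Optional `homography` providing the inlier mask.
#' @return `path`, invisibly.
#' @export
write_matches_csv <- function(matches, path, h = NULL) {
  inl <- if (!is.null(h)) as.integer(h$inlier_mask) else
    rep(NA_integer_, nrow(matches))
  lines <- c("query_index,train_index,distance,is_inlier",
             vapply(seq_len(nrow(matches)), function(i) csv_line(
               matches$query_index[i], matches$train_index[i],
               fmt6(matches$distance[i]),
               if (is.na(inl[i])) "" else inl[i]), character(1)))
  write_lines_atomic(lines, path)
}

#' Write a homography as 9 comma-separated row-major values
#'
#' @param h A `homography` object or 3x3 matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_homography_csv <- function(h, path) {
  m <- as_homography_matrix(h)
  write_lines_atomic(csv_line(fmt6(as.numeric(t(m)))), path)
}

#' Write per-frame tracking results as CSV
#'
#' Header `frame,n_keypoints,n_good,present,h00..h22,c0x..c3y`; fields
#' of absent frames are empty.
#'
#' @param run A `track_run` from [run_tracking_sequence()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_track_csv <- function(run, path) {
  r <- run$results
  hn <- paste0("h", c(t(outer(0:2, 0:2, paste0))))
  cn <- paste0("c", rep(0:3, each = 2), c("x", "y"))
  header <- csv_line("frame", "n_keypoints", "n_good", "present", hn, cn)
  lines <- c(header, vapply(seq_len(nrow(r)), function(i) csv_line(
    r$frame[i], r$n_keypoints[i], r$n_good[i],
    as.integer(r$present[i]),
    fmt6(as.numeric(r[i, hn])), fmt6(as.numeric(r[i, cn]))), character(1)))
  write_lines_atomic(lines, path)
}

#' Write an evaluation curve as CSV
#'
#' Header `level,n,mean_good,ci_lower,ci_upper`.
#'
#' @param curve An `eval_curve` from [run_sweep()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curve_csv <- function(curve, path) {
  lines <- c("level,n,mean_good,ci_lower,ci_upper",
             vapply(seq_len(nrow(curve)), function(i) csv_line(
               curve$level[i], curve$n[i], fmt6(curve$mean_good[i]),
               fmt6(curve$ci_lower[i]), fmt6(curve$ci_upper[i])),
               character(1)))
  write_lines_atomic(lines, path)
}

#' Write match-count summaries as CSV
#'
#' Header
#' `condition,n,median,q1,q3,lo_whisker,hi_whisker,n_outliers`.
#'
#' @param summary Tibble from [summarize_matches()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_csv <- function(summary, path) {
  lines <- c("condition,n,median,q1,q3,lo_whisker,hi_whisker,n_outliers",
             vapply(seq_len(nrow(summary)), function(i) csv_line(
               summary$condition[i], summary$n[i], fmt6(summary$median[i]),
               fmt6(summary$q1[i]), fmt6(summary$q3[i]),
               fmt6(summary$lo_whisker[i]), fmt6(summary$hi_whisker[i]),
               summary$n_outliers[i]), character(1)))
  write_lines_atomic(lines, path)
}
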