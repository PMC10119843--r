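#' Trajectory-weighted fate activity profile
#'
#' For one fate, combines per-cell regulon activity with that fate's
#' trajectory scores into a TFs x time-points profile: at each time point
#' the entry is the trajectory-score-weighted mean activity,
#' `sum_c(score_c * activity_c) / sum_c(score_c)` over cells at that time.
#' (The weighted mean rather than the bare weighted sum keeps columns
#' comparable across time points with different cell counts; set
#' `normalize = FALSE` for the raw weighted sum.)
#'
#' @param activity cells x TFs matrix from [auc_activity()].
#' @param scores a [trajectory_scores()] data.frame for one fate.
#' @param time_labels optional time ordering (default: order of appearance
#'   in `scores`).
#' @param normalize divide by total score per time point (default TRUE).
#' @return An object of class `fate_activity_profile`: `fate`, `profile`
#'   (TFs x time matrix; columns with zero total score are NA and listed in
#'   `missing_times`).
#' @export
weighted_activity <- function(activity, scores, time_labels = NULL,
                              normalize = TRUE) {
  stopifnot(is.matrix(activity))
  if (!all(scores$barcode %in% rownames(activity))) {
    stop("activity and scores must be indexed by the same cells")
  }
  times <- if (is.null(time_labels)) unique(scores$time_point) else time_labels
  prof <- matrix(NA_real_, ncol(activity), length(times),
                 dimnames = list(colnames(activity), times))
  missing_times <- character(0)
  for (t in times) {
    sc <- scores[scores$time_point == t, ]
    tot <- sum(sc$score)
    if (nrow(sc) == 0L || tot <= 0) {
      missing_times <- c(missing_times, t)
      next
    }
    a <- activity[sc$barcode, , drop = FALSE]
    w <- sc$score
    prof[, t] <- as.vector(crossprod(a, w)) / if (normalize) tot else 1
  }
  if (length(missing_times)) {
    pd_log("weighted_activity", fate = attr(scores, "fate"),
           missing_time_points = paste(missing_times, collapse = ","))
  }
  structure(list(fate = attr(scores, "fate") %||% "fate",
                 profile = prof, missing_times = missing_times),
            class = "fate_activity_profile")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.fate_activity_profile <- function(x, ...) {
  cat(sprintf("fate_activity_profile '%s': %d TFs x %d time points\n",
              x$fate, nrow(x$profile), ncol(x$profile)))
  invisible(x)
}

#' Rank fate-specific TFs
#'
#' Orders TFs by a specificity statistic: for each TF, the maximum over
#' time points of the difference between its activity in one fate's profile
#' and the best competing fate at that time; the TF is labelled with the
#' fate achieving the maximum. Ties in the ranking are broken
#' alphabetically by TF name.
#'
#' @param profiles list of [weighted_activity()] profiles (>= 2 fates,
#'   same TFs and time points).
#' @return Data.frame (tf, fate, statistic, peak_time) sorted by decreasing
#'   statistic.
#' @export
rank_fate_tfs <- function(profiles) {
  stopifnot(length(profiles) >= 2L)
  fates <- vapply(profiles, `[[`, character(1), "fate")
  mats <- lapply(profiles, `[[`, "profile")
  tfs <- rownames(mats[[1]])
  times <- colnames(mats[[1]])
  for (m in mats) stopifnot(identical(rownames(m), tfs),
                            identical(colnames(m), times))
  rows <- lapply(tfs, function(tf) {
    per_fate <- vapply(seq_along(fates), function(fi) {
      own <- mats[[fi]][tf, ]
      other <- do.call(pmax, c(lapply(mats[-fi], function(m) m[tf, ]),
                               list(na.rm = TRUE)))
      d <- own - other
      if (all(is.na(d))) return(c(-Inf, NA_integer_))
      k <- which.max(d)
      c(d[k], k)
    }, numeric(2))
    top <- max(per_fate[1, ])
    # ties across fates broken alphabetically; a zero contrast has no fate
    best <- which(per_fate[1, ] == top)[order(fates[per_fate[1, ] == top])][1]
    data.frame(tf = tf,
               fate = if (top == 0) "none" else fates[best],
               statistic = top,
               peak_time = times[per_fate[2, best]], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$statistic, out$tf), ]
  rownames(out) <- NULL
  out
}
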