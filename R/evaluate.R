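#' Match localizations to ground truth
#'
#' Within each frame, repeatedly pairs the globally closest unmatched
#' (truth, found) pair whose distance is at most \code{tolerance_nm}; each
#' record is used at most once. Matched pairs are true positives, unmatched
#' found records false positives, unmatched truth records false negatives.
#'
#' @param truth data.frame with columns \code{frame}, \code{x_nm},
#'   \code{y_nm} (the reference set).
#' @param found data.frame with the same columns (the reconstructed set).
#' @param tolerance_nm Matching radius, nm. Always report it alongside
#'   metrics: scores at different tolerances are not comparable.
#' @param per_frame Match within frames (default TRUE); FALSE pools all
#'   records, for position-only comparisons.
#' @return A \code{loc_matching}: list with \code{pairs} (data.frame:
#'   truth_index, found_index, dist_nm), \code{tp}, \code{fp}, \code{fn},
#'   \code{tolerance_nm}.
#' @export
match_localizations <- function(truth, found, tolerance_nm,
                                per_frame = TRUE) {
  stopifnot(all(c("x_nm", "y_nm") %in% names(truth)),
            all(c("x_nm", "y_nm") %in% names(found)),
            tolerance_nm > 0)
  if (per_frame && nrow(truth) && nrow(found) &&
      !any(truth$frame %in% found$frame) && length(found$frame))
    warning("truth and found share no frame indices; check frame ranges")
  groups <- if (per_frame) {
    keys <- union(unique(truth$frame), unique(found$frame))
    lapply(keys, function(k) list(t = which(truth$frame == k),
                                  f = which(found$frame == k)))
  } else {
    list(list(t = seq_len(nrow(truth)), f = seq_len(nrow(found))))
  }
  pairs <- list()
  for (g in groups) {
    ti <- g$t; fi <- g$f
    if (!length(ti) || !length(fi)) next
    d <- sqrt(outer(truth$x_nm[ti], found$x_nm[fi], "-")^2 +
              outer(truth$y_nm[ti], found$y_nm[fi], "-")^2)
    repeat {
      best <- which.min(d)
      if (!length(best) || d[best] > tolerance_nm || !is.finite(d[best])) break
      rc <- arrayInd(best, dim(d))
      pairs[[length(pairs) + 1L]] <-
        data.frame(truth_index = ti[rc[1L]], found_index = fi[rc[2L]],
                   dist_nm = d[best])
      d[rc[1L], ] <- Inf
      d[, rc[2L]] <- Inf
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(truth_index = integer(0), found_index = integer(0),
               dist_nm = numeric(0))
  structure(list(pairs = pairs, tp = nrow(pairs),
                 fp = nrow(found) - nrow(pairs),
                 fn = nrow(truth) - nrow(pairs),
                 tolerance_nm = tolerance_nm),
            class = "loc_matching")
}

#' Jaccard, precision, recall and RMSD from a matching
#'
#' \code{jaccard = TP/(TP+FP+FN)}, \code{precision = TP/(TP+FP)},
#' \code{recall = TP/(TP+FN)} (0/0 taken as 0), and \code{rmsd_nm} the root
#' mean square distance over matched pairs (NaN when nothing matched). The
#' Jaccard index never exceeds either precision or recall and is the single
#' best summary of identification accuracy.
#'
#' @param matching A \code{loc_matching}.
#' @return An \code{evaluation_result} list: tp, fp, fn, jaccard, precision,
#'   recall, rmsd_nm, tolerance_nm.
#' @export
compute_metrics <- function(matching) {
  stopifnot(inherits(matching, "loc_matching"))
  tp <- matching$tp; fp <- matching$fp; fn <- matching$fn
  safe_div <- function(num, den) if (den == 0) 0 else num / den
  rmsd <- if (tp > 0) sqrt(mean(matching$pairs$dist_nm^2)) else {
    message("no matched pairs; RMSD undefined")
    NaN
  }
  structure(list(tp = tp, fp = fp, fn = fn,
                 jaccard = safe_div(tp, tp + fp + fn),
                 precision = safe_div(tp, tp + fp),
                 recall = safe_div(tp, tp + fn),
                 rmsd_nm = rmsd,
                 tolerance_nm = matching$tolerance_nm),
            class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf("evaluation at %.0f nm tolerance:\n", x$tolerance_nm))
  cat(sprintf("  TP %d  FP %d  FN %d\n", x$tp, x$fp, x$fn))
  cat(sprintf("  Jaccard %.3f  precision %.3f  recall %.3f  RMSD %.1f nm\n",
              x$jaccard, x$precision, x$recall, x$rmsd_nm))
  invisible(x)
}

#' Score a localization table against ground truth
#'
#' Convenience wrapper: match then compute metrics.
#'
#' @inheritParams match_localizations
#' @return An \code{evaluation_result}.
#' @export
evaluate_localizations <- function(truth, found, tolerance_nm,
                                   per_frame = TRUE) {
  compute_metrics(match_localizations(truth, found, tolerance_nm, per_frame))
}
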