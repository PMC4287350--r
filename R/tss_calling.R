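## TSS calling: the theta enrichment statistic, control-based threshold
## calibration, RNA-seq step filter, peak merging and the calling decision.

#' Normalize a count track to a common scale
#'
#' Each count is multiplied by \code{scale / total_nonrrna}. With
#' \code{scale} set to the mean non-rRNA total over the libraries being
#' compared, normalized values stay on a raw-count-like scale, which is the
#' scale on which the read floors (25, 30, 2, 10, 20) are defined.
#'
#' @param x a \code{\link{position_counts}} object.
#' @param scale target scale (reads); e.g. the mean library total.
#' @return a \code{position_counts} object with rescaled counts.
#' @export
normalize_counts <- function(x, scale) {
  total <- attr(x, "total_nonrrna")
  if (is.null(total) || total <= 0) stop("library total must be > 0")
  out <- x
  out$count <- x$count * scale / total
  out
}

#' The TAP-enrichment statistic theta
#'
#' theta = ln((plus + c) / (minus + c)) where plus/minus are the normalized
#' +TAP and -TAP read counts at a position and c is a pseudocount guarding
#' against zero counts. Antisymmetric under swapping arguments.
#'
#' @param plus_tap,minus_tap normalized read counts (vectors allowed).
#' @param pseudocount c >= 0; must be > 0 if either count may be zero.
#' @return theta in natural-log units.
#' @export
compute_theta <- function(plus_tap, minus_tap, pseudocount = 1) {
  if (any(plus_tap < 0) || any(minus_tap < 0)) stop("counts must be >= 0")
  if (pseudocount == 0 && any(plus_tap == 0 & minus_tap == 0))
    stop("theta undefined: both counts zero with pseudocount 0")
  log((plus_tap + pseudocount) / (minus_tap + pseudocount))
}

#' Match known control sites to observed 5'-end peaks
#'
#' Each known site is matched to the nearest observed peak on the same strand
#' within \code{max_distance} bp (ties broken toward the higher-count peak,
#' then leftmost); peaks below \code{min_reads} are ignored and unmatched
#' sites are dropped and counted.
#'
#' @param known data.frame with columns \code{pos}, \code{strand}.
#' @param peaks data.frame with columns \code{pos}, \code{strand},
#'   \code{count} (the library used for the floor) and \code{theta}.
#' @param max_distance maximum matching distance in bp (default 5).
#' @param min_reads minimum normalized read floor for a usable peak
#'   (default 30, the control floor).
#' @return list with \code{theta} (matched theta values), \code{matched}
#'   (data.frame of matches) and \code{n_unmatched}.
#' @export
match_controls <- function(known, peaks, max_distance = 5, min_reads = 30) {
  peaks <- peaks[peaks$count >= min_reads, , drop = FALSE]
  idx <- integer(0)
  for (i in seq_len(nrow(known))) {
    sel <- which(peaks$strand == known$strand[i] &
                 abs(peaks$pos - known$pos[i]) <= max_distance)
    if (length(sel) == 0) { idx <- c(idx, NA_integer_); next }
    d <- abs(peaks$pos[sel] - known$pos[i])
    sel <- sel[d == min(d)]
    if (length(sel) > 1) {
      sel <- sel[peaks$count[sel] == max(peaks$count[sel])]
      sel <- sel[which.min(peaks$pos[sel])]
    }
    idx <- c(idx, sel)
  }
  ok <- !is.na(idx)
  matched_peaks <- peaks[idx[ok], c("pos", "count", "theta"), drop = FALSE]
  names(matched_peaks) <- c("peak_pos", "peak_count", "peak_theta")
  list(theta = peaks$theta[idx[ok]],
       matched = cbind(known[ok, , drop = FALSE], matched_peaks),
       n_unmatched = sum(!ok))
}

#' Calibrate the theta threshold on control samples
#'
#' Computes sample means/sds of the positive- and negative-control theta
#' samples, a Welch two-sample t-test between them, and the threshold
#' \code{mean_neg + z(1 - alpha) * sd_neg}. The default alpha is the upper
#' 2-standard-deviation normal tail (0.02275). An explicit
#' \code{override} (the published operating point 0.26) may be supplied and
#' is then used as the operating threshold while the calibrated value is
#' retained for reporting.
#'
#' @param pos_thetas,neg_thetas numeric vectors (n >= 2 each).
#' @param alpha upper-tail probability for the threshold.
#' @param override optional fixed threshold recorded as the operating point.
#' @return an object of class \code{tss_calibration}.
#' @export
calibrate_threshold <- function(pos_thetas, neg_thetas,
                                alpha = stats::pnorm(-2), override = NULL) {
  stopifnot(length(pos_thetas) >= 2, length(neg_thetas) >= 2)
  mean_pos <- mean(pos_thetas); sd_pos <- stats::sd(pos_thetas)
  mean_neg <- mean(neg_thetas); sd_neg <- stats::sd(neg_thetas)
  wt <- stats::t.test(pos_thetas, neg_thetas, var.equal = FALSE)
  if (sd_neg == 0) {
    warning("degenerate negative-control sd of 0; threshold = mean_neg")
    calibrated <- mean_neg
  } else {
    calibrated <- mean_neg + stats::qnorm(1 - alpha) * sd_neg
  }
  structure(list(mean_pos = mean_pos, sd_pos = sd_pos,
                 mean_neg = mean_neg, sd_neg = sd_neg,
                 n_pos = length(pos_thetas), n_neg = length(neg_thetas),
                 welch_t = unname(wt$statistic),
                 welch_df = unname(wt$parameter),
                 welch_p = wt$p.value,
                 alpha = alpha,
                 calibrated = calibrated,
                 override = override,
                 threshold = if (is.null(override)) calibrated else override),
            class = "tss_calibration")
}

#' @export
print.tss_calibration <- function(x, ...) {
  cat("Theta threshold calibration\n")
  cat(sprintf("  positive controls: n = %d, mean = %.3f, sd = %.3f\n",
              x$n_pos, x$mean_pos, x$sd_pos))
  cat(sprintf("  negative controls: n = %d, mean = %.3f, sd = %.3f\n",
              x$n_neg, x$mean_neg, x$sd_neg))
  cat(sprintf("  Welch t = %.2f, df = %.1f, p = %.3g\n",
              x$welch_t, x$welch_df, x$welch_p))
  cat(sprintf("  calibrated threshold (alpha = %.4f): %.3f\n",
              x$alpha, x$calibrated))
  if (!is.null(x$override))
    cat(sprintf("  operating threshold (override): %.3f\n", x$override))
  invisible(x)
}

#' RNA-seq coverage step filter
#'
#' A genuine TSS adds transcript coverage immediately downstream. The filter
#' passes iff the mean RNA-seq coverage over the \code{window} bases
#' downstream in the direction of transcription (including the TSS base)
#' exceeds \code{(1 + min_increase)} times the mean over the \code{window}
#' bases immediately upstream. An upstream mean of 0 with any downstream
#' coverage passes. Windows are clipped at genome ends.
#'
#' @param coverage list with numeric vectors \code{plus} and \code{minus} of
#'   per-position RNA-seq coverage (full genome length each).
#' @param pos,strand TSS position(s) and strand(s).
#' @param window window size in bp (default 38).
#' @param min_increase required fractional increase (default 0.35).
#' @return logical vector of pass flags.
#' @export
rna_seq_step_filter <- function(coverage, pos, strand, window = 38,
                                min_increase = 0.35) {
  stopifnot(window >= 1)
  L <- length(coverage$plus)
  strand <- rep_len(strand, length(pos))
  vapply(seq_along(pos), function(i) {
    cov <- if (strand[i] == "+") coverage$plus else coverage$minus
    p <- pos[i]
    if (strand[i] == "+") {
      down <- cov[p:min(L, p + window - 1)]
      up <- if (p > 1) cov[max(1, p - window):(p - 1)] else numeric(0)
    } else {
      down <- cov[max(1, p - window + 1):p]
      up <- if (p < L) cov[(p + 1):min(L, p + window)] else numeric(0)
    }
    mu_up <- if (length(up)) mean(up) else 0
    mu_down <- if (length(down)) mean(down) else 0
    if (mu_up == 0) mu_down > 0 else mu_down > (1 + min_increase) * mu_up
  }, logical(1))
}

#' Merge nearby 5'-end peaks
#'
#' Positions on one strand that lie within \code{max_gap} bp of each other
#' (transitively chained) are merged: counts are summed and the merged peak
#' is placed at the member position with the highest +TAP count (ties go to
#' the leftmost position). Total reads are conserved.
#'
#' @param candidates data.frame with columns \code{pos}, \code{plus} and
#'   optionally further count columns to sum (e.g. \code{minus},
#'   \code{t0}...); one strand only, need not be sorted.
#' @param max_gap maximum gap in bp for chaining (default 5).
#' @return merged data.frame with the same count columns.
#' @export
merge_peaks <- function(candidates, max_gap = 5) {
  if (nrow(candidates) == 0) return(candidates)
  o <- order(candidates$pos)
  candidates <- candidates[o, , drop = FALSE]
  gap_break <- c(0, cumsum(diff(candidates$pos) > max_gap))
  count_cols <- setdiff(names(candidates), "pos")
  out <- do.call(rbind, lapply(split(seq_len(nrow(candidates)), gap_break),
    function(ii) {
      block <- candidates[ii, , drop = FALSE]
      best <- which(block$plus == max(block$plus))[1]   # leftmost tie-break
      row <- block[best, , drop = FALSE]
      for (cc in count_cols) row[[cc]] <- sum(block[[cc]])
      row$pos <- block$pos[best]
      row
    }))
  rownames(out) <- NULL
  out
}

#' Call TSSs from +TAP/-TAP tracks
#'
#' The full position-level calling procedure: normalize both libraries to
#' their mean non-rRNA total, merge nearby 5'-end peaks per strand, compute
#' theta at every merged peak, and call a TSS iff the normalized +TAP count
#' is at least \code{min_plus_tap}, theta strictly exceeds the calibration's
#' operating threshold, and the RNA-seq step filter passes.
#'
#' @param plus_tap,minus_tap \code{\link{position_counts}} for the +TAP and
#'   -TAP libraries (raw counts).
#' @param coverage RNA-seq coverage list (\code{plus}/\code{minus} vectors),
#'   or NULL to skip the step filter.
#' @param calibration a \code{\link{calibrate_threshold}} result, or a bare
#'   numeric threshold.
#' @param min_plus_tap minimum normalized +TAP reads (default 25).
#' @param pseudocount pseudocount for theta (default 1).
#' @param max_gap peak-merging distance (default 5).
#' @param window,min_increase step-filter parameters.
#' @return data.frame of candidates (\code{pos}, \code{strand},
#'   \code{raw_plus}, \code{raw_minus}, \code{plus}, \code{minus} normalized,
#'   \code{theta}, \code{step_pass}, \code{called}).
#' @export
call_tss <- function(plus_tap, minus_tap, coverage, calibration,
                     min_plus_tap = 25, pseudocount = 1, max_gap = 5,
                     window = 38, min_increase = 0.35) {
  threshold <- if (inherits(calibration, "tss_calibration"))
    calibration$threshold else as.numeric(calibration)
  scale <- mean(c(attr(plus_tap, "total_nonrrna"),
                  attr(minus_tap, "total_nonrrna")))
  np <- normalize_counts(plus_tap, scale)
  nm <- normalize_counts(minus_tap, scale)
  res <- lapply(c("+", "-"), function(s) {
    p <- np[np$strand == s, , drop = FALSE]
    m <- nm[nm$strand == s, , drop = FALSE]
    pos <- sort(unique(c(p$pos, m$pos)))
    if (length(pos) == 0) return(NULL)
    cand <- data.frame(pos = pos,
                       plus = counts_at(np, pos, s),
                       minus = counts_at(nm, pos, s),
                       raw_plus = counts_at(plus_tap, pos, s),
                       raw_minus = counts_at(minus_tap, pos, s))
    cand <- cand[cand$plus > 0, , drop = FALSE]   # 5'-end peaks are +TAP-led
    if (nrow(cand) == 0) return(NULL)
    cand <- merge_peaks(cand, max_gap = max_gap)
    cand$strand <- s
    cand
  })
  cand <- do.call(rbind, res)
  if (is.null(cand) || nrow(cand) == 0)
    return(data.frame(pos = integer(), strand = character(),
                      raw_plus = numeric(), raw_minus = numeric(),
                      plus = numeric(), minus = numeric(), theta = numeric(),
                      step_pass = logical(), called = logical()))
  cand$theta <- compute_theta(cand$plus, cand$minus, pseudocount)
  cand$step_pass <- if (is.null(coverage)) TRUE else
    rna_seq_step_filter(coverage, cand$pos, cand$strand,
                        window = window, min_increase = min_increase)
  cand$called <- cand$plus >= min_plus_tap & cand$theta > threshold &
    cand$step_pass
  cand <- cand[, c("pos", "strand", "raw_plus", "raw_minus", "plus", "minus",
                   "theta", "step_pass", "called")]
  rownames(cand) <- NULL
  cand
}
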