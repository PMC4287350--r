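## Fourier-based classification of cell-cycle-regulated TSSs and temporal
## clustering of 8-point profiles (t = 0, 20, ..., 140 min).

#' Discrete-Fourier magnitudes of an 8-point profile
#'
#' coeff_k = |sum_t x_t exp(-2 pi i k t / 8)| for k = 0..7; coeff0 is the
#' profile sum and coefficients 5..7 mirror 3..1 (conjugate symmetry for a
#' real signal).
#'
#' @param levels numeric vector of exactly 8 finite values (read counts in
#'   the pipeline, but any real signal is transformable).
#' @return named numeric vector coeff0..coeff7.
#' @export
fourier_coefficients <- function(levels) {
  if (length(levels) != 8) stop("profile must have exactly 8 time points")
  if (any(!is.finite(levels)))
    stop("levels must be finite")
  co <- Mod(stats::fft(levels))
  names(co) <- paste0("coeff", 0:7)
  co
}

#' First-harmonic dominance ratio
#'
#' coeff1 / (coeff1 + coeff2 + coeff3 + coeff4); defined as 0 when the
#' denominator is 0 (a constant profile).
#'
#' @param coeff coefficients from \code{\link{fourier_coefficients}} or a
#'   raw 8-point profile.
#' @return ratio in [0, 1].
#' @export
harmonic_ratio <- function(coeff) {
  if (is.null(names(coeff)) || !all(paste0("coeff", 0:7) %in% names(coeff)))
    coeff <- fourier_coefficients(coeff)
  den <- sum(coeff[paste0("coeff", 1:4)])
  if (den == 0) 0 else unname(coeff["coeff1"] / den)
}

#' Classify a profile as cell-cycle regulated
#'
#' A TSS is regulated iff all three criteria hold on its 8-point profile of
#' normalized reads:
#' (1) coeff1/(coeff1+coeff2+coeff3+coeff4) >= ratio_min;
#' (2) ln(a) - ln(b) >= log_fold_min, where a and b are the profile maximum
#' and minimum; (3) a >= a_min. A minimum of exactly 0 passes criterion 2
#' provided a >= a_min (a zero trough implies unbounded fold change).
#'
#' @param levels 8-point profile of normalized reads.
#' @param ratio_min first-harmonic ratio floor (default 0.35).
#' @param log_fold_min natural-log fold-change floor (default 1.1).
#' @param a_min minimum peak level on the normalized-count scale
#'   (default 20).
#' @param detail if TRUE return a list with the pieces instead of a flag.
#' @return logical flag (or a list when \code{detail = TRUE}).
#' @export
is_regulated <- function(levels, ratio_min = 0.35, log_fold_min = 1.1,
                         a_min = 20, detail = FALSE) {
  co <- fourier_coefficients(levels)
  ratio <- harmonic_ratio(co)
  a <- max(levels); b <- min(levels)
  c1 <- ratio >= ratio_min
  c2 <- if (b <= 0) a >= a_min else (log(a) - log(b)) >= log_fold_min
  c3 <- a >= a_min
  flag <- c1 && c2 && c3
  if (!detail) return(flag)
  list(regulated = flag, ratio = ratio, a = a, b = b,
       log_fold = if (b > 0) log(a) - log(b) else Inf,
       criteria = c(ratio = c1, fold = c2, level = c3), coeff = co)
}

#' Display normalization of a profile
#'
#' log2-transform (with pseudocount), center to mean 0, then divide by the
#' maximum absolute value so all values lie in [-1, 1] with at least one
#' endpoint attained. A constant profile maps to all zeros.
#'
#' @param levels 8-point profile (>= 0).
#' @param pseudocount added before the log2 (default 1).
#' @return numeric vector in [-1, 1].
#' @export
normalize_profile <- function(levels, pseudocount = 1) {
  y <- log2(levels + pseudocount)
  y <- y - mean(y)
  m <- max(abs(y))
  if (m == 0) rep(0, length(y)) else y / m
}

#' Peak time of a profile
#'
#' 20 * (argmax - 1) minutes on the 0..140 grid; ties go to the earliest
#' time point.
#'
#' @param levels 8-point profile.
#' @return peak time in minutes.
#' @export
peak_time <- function(levels) {
  20 * (which.max(levels) - 1)
}

#' k-means clustering of display-normalized profiles
#'
#' Clusters are renumbered so the cluster index increases with the
#' cluster-mean peak time ("ordered by maximum time of activation").
#' Deterministic given \code{seed}; if there are fewer profiles (or fewer
#' distinct profiles) than \code{k}, k is reduced with a warning.
#'
#' @param profiles numeric matrix, one row per TSS, 8 columns (already
#'   display-normalized; see \code{\link{normalize_profile}}).
#' @param k number of clusters (default 15).
#' @param seed RNG seed (default 0).
#' @param nstart k-means restarts (default 100).
#' @return integer vector of cluster labels (1..k, time-ordered).
#' @export
kmeans_profiles <- function(profiles, k = 15, seed = 0, nstart = 100) {
  profiles <- as.matrix(profiles)
  n_distinct <- nrow(unique(profiles))
  if (n_distinct < k) {
    warning("fewer distinct profiles than k; reducing k to ", n_distinct)
    k <- n_distinct
  }
  if (k == 1) return(rep(1L, nrow(profiles)))
  if (k >= nrow(profiles))   # one cluster per (distinct) profile
    return(relabel_by_peak_time(as.integer(factor(
      apply(profiles, 1, paste, collapse = ","))), profiles))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  km <- if (n_distinct == k)
    stats::kmeans(profiles, centers = unique(profiles), iter.max = 100)
  else
    stats::kmeans(profiles, centers = k, nstart = nstart, iter.max = 100)
  relabel_by_peak_time(km$cluster, profiles)
}

#' Hierarchical grouping of profiles
#'
#' Agglomerative clustering (average linkage, Euclidean distance on the
#' display-normalized profiles) cut at \code{n_groups} groups, renumbered by
#' group-mean peak time.
#'
#' @param profiles numeric matrix, one row per TSS.
#' @param n_groups number of groups.
#' @return integer vector of group labels.
#' @export
hierarchical_groups <- function(profiles, n_groups) {
  profiles <- as.matrix(profiles)
  hc <- stats::hclust(stats::dist(profiles), method = "average")
  relabel_by_peak_time(stats::cutree(hc, k = n_groups), profiles)
}

## Renumber cluster labels so index increases with cluster-mean argmax time.
relabel_by_peak_time <- function(labels, profiles) {
  pt <- vapply(seq_len(nrow(profiles)), function(i)
    peak_time(profiles[i, ]), numeric(1))
  mean_pt <- tapply(pt, labels, mean)
  new_order <- names(sort(mean_pt))
  as.integer(match(as.character(labels), new_order))
}

## Save/restore .Random.seed so seeded clustering does not perturb the
## caller's RNG stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
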