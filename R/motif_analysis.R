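## Promoter motif scanning: gapped IUPAC consensus matching, PWM scoring
## with exact p-values (dynamic programming over the score distribution),
## CtrA binding-mode classification, regulator co-occurrence, and ChIP fold
## enrichment.

BASES <- c("A", "C", "G", "T")

#' Define a motif model
#'
#' Either a gapped IUPAC consensus written as segments joined by
#' \code{-N<k>-} spacers (e.g. \code{"TTAA-N7-TTAA"}) or a position weight
#' matrix (4 x width, rows A/C/G/T, columns summing to 1).
#'
#' @param name motif name.
#' @param consensus gapped IUPAC consensus string, or NULL.
#' @param pwm probability matrix (4 x width), or NULL.
#' @param window c(min_offset, max_offset) search window of the motif's 5'
#'   base relative to the TSS (negative = upstream).
#' @param background background base probabilities (A,C,G,T), used for PWM
#'   scoring; defaults to uniform.
#' @return an object of class \code{motif_model}.
#' @export
motif_model <- function(name, consensus = NULL, pwm = NULL,
                        window = c(-100, -1),
                        background = c(A = .25, C = .25, G = .25, T = .25)) {
  stopifnot(xor(is.null(consensus), is.null(pwm)))
  if (window[1] >= window[2] || window[2] > 0)
    stop("window must satisfy min < max <= 0")
  if (!is.null(consensus)) {
    pattern <- expand_consensus(consensus)
    width <- nchar(pattern)
    kind <- "consensus"
  } else {
    pwm <- as.matrix(pwm)
    if (nrow(pwm) != 4) stop("pwm must have 4 rows (A, C, G, T)")
    rownames(pwm) <- BASES
    if (any(abs(colSums(pwm) - 1) > 1e-9))
      stop("pwm columns must sum to 1")
    pattern <- NULL
    width <- ncol(pwm)
    kind <- "pwm"
  }
  background <- background / sum(background)
  names(background) <- BASES
  structure(list(name = name, kind = kind, consensus = consensus,
                 pattern = pattern, pwm = pwm, width = width,
                 window = window, background = background),
            class = "motif_model")
}

#' @export
print.motif_model <- function(x, ...) {
  cat(sprintf("<motif_model> %s (%s, width %d, window %d..%d)\n", x$name,
              if (x$kind == "consensus") x$consensus else "PWM",
              x$width, x$window[1], x$window[2]))
  invisible(x)
}

## "TTAA-N7-TTAA" -> "TTAANNNNNNNTTAA"; validates IUPAC letters.
expand_consensus <- function(consensus) {
  parts <- strsplit(consensus, "-", fixed = TRUE)[[1]]
  expanded <- vapply(parts, function(p) {
    if (grepl("^N[0-9]+$", p))
      strrep("N", as.integer(sub("^N", "", p)))
    else p
  }, character(1))
  out <- toupper(paste(expanded, collapse = ""))
  iupac <- strsplit("ACGTRYSWKMBDHVN", "")[[1]]
  bad <- setdiff(strsplit(out, "")[[1]], iupac)
  if (length(bad) > 0)
    stop("non-IUPAC characters in consensus: ", paste(bad, collapse = ", "))
  out
}

#' Extract the promoter sequence upstream of a TSS
#'
#' Returns the sequence 5'->3' on the TSS strand covering offsets
#' \code{-length..-1} (clipped at genome ends), i.e. ending at the base just
#' upstream of the TSS.
#'
#' @param genome genome sequence (character string).
#' @param pos,strand TSS position and strand.
#' @param length promoter length in bp (default 100).
#' @return character string (possibly shorter than \code{length} at ends).
#' @export
promoter_seq <- function(genome, pos, strand, length = 100) {
  L <- nchar(genome)
  if (strand == "+") {
    if (pos <= 1) return("")
    substr(genome, max(1, pos - length), pos - 1)
  } else {
    if (pos >= L) return("")
    s <- substr(genome, pos + 1, min(L, pos + length))
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }
}

#' Scan a promoter with a consensus motif
#'
#' Every offset where all non-N consensus positions match under IUPAC
#' semantics is reported; overlapping hits are allowed. The promoter is the
#' strand-aware upstream sequence ending at offset -1 (see
#' \code{\link{promoter_seq}}); hits outside the motif's search window are
#' dropped.
#'
#' @param promoter promoter sequence (5'->3' on the TSS strand).
#' @param motif a consensus \code{\link{motif_model}}.
#' @return data.frame with \code{offset} (5' base relative to the TSS) and
#'   \code{seq} (matched sequence).
#' @export
scan_consensus <- function(promoter, motif) {
  stopifnot(inherits(motif, "motif_model"), motif$kind == "consensus")
  empty <- data.frame(offset = integer(), seq = character())
  W <- nchar(promoter)
  if (W < motif$width) return(empty)
  m <- Biostrings::matchPattern(motif$pattern,
                                Biostrings::DNAString(promoter),
                                fixed = "subject")
  if (length(m) == 0) return(empty)
  offset <- Biostrings::start(m) - W - 1L
  keep <- offset >= motif$window[1] &
    (offset + motif$width - 1L) <= motif$window[2]
  data.frame(offset = offset[keep],
             seq = as.character(m)[keep], stringsAsFactors = FALSE)
}

#' Build a position weight matrix from aligned sites
#'
#' Column base frequencies with an additive pseudocount, normalized to sum
#' to 1.
#'
#' @param sites character vector of equal-length aligned sites (n >= 2).
#' @param pseudocount added to each cell count (default 0.5).
#' @param name,window passed to \code{\link{motif_model}}.
#' @param background background base probabilities.
#' @return a PWM \code{\link{motif_model}}.
#' @export
build_pwm <- function(sites, pseudocount = 0.5, name = "pwm",
                      window = c(-100, -1),
                      background = c(A = .25, C = .25, G = .25, T = .25)) {
  stopifnot(length(sites) >= 2, length(unique(nchar(sites))) == 1)
  mat <- do.call(cbind, lapply(seq_len(nchar(sites[1])), function(j) {
    col <- substr(sites, j, j)
    counts <- table(factor(col, levels = BASES)) + pseudocount
    as.numeric(counts / sum(counts))
  }))
  rownames(mat) <- BASES
  motif_model(name, pwm = mat, window = window, background = background)
}

## Per-column log-odds scores (bits): 4 x width matrix.
pwm_logodds <- function(motif) {
  log2(motif$pwm / motif$background[BASES])
}

#' Score a word against a PWM
#'
#' Sum of per-position log-odds (bits) against the motif's background.
#'
#' @param motif a PWM \code{\link{motif_model}}.
#' @param word character string of the motif's width.
#' @return log-odds score in bits.
#' @export
pwm_score <- function(motif, word) {
  lo <- pwm_logodds(motif)
  idx <- match(strsplit(toupper(word), "")[[1]], BASES)
  if (anyNA(idx)) stop("word contains non-ACGT characters")
  if (length(idx) != motif$width) stop("word length != motif width")
  ## accumulate column by column in double precision, the same order as
  ## the p-value DP, so equal scores compare bit-for-bit
  s <- 0
  for (j in seq_along(idx)) s <- s + lo[idx[j], j]
  unname(s)
}

#' Exact distribution of PWM scores under the background
#'
#' Dynamic programming over the per-column score distribution. For widths up
#' to \code{max_exact_width} the DP merges exactly equal partial sums, so
#' the resulting distribution equals exhaustive enumeration over all 4^w
#' words; wider matrices fall back to a fixed grid of \code{grid} bits.
#'
#' @param motif a PWM \code{\link{motif_model}}.
#' @param max_exact_width width limit for exact-merge DP (default 10).
#' @param grid bin width in bits for the wide-matrix fallback
#'   (default 1e-4).
#' @return data.frame with \code{score} (ascending) and \code{prob}.
#' @export
pwm_score_distribution <- function(motif, max_exact_width = 10,
                                   grid = 1e-4) {
  lo <- pwm_logodds(motif)
  bg <- motif$background[BASES]
  exact <- motif$width <= max_exact_width
  if (!exact) lo <- round(lo / grid) * grid
  score <- 0; prob <- 1
  for (j in seq_len(ncol(lo))) {
    score <- rep(score, each = 4) + rep(lo[, j], times = length(score))
    prob <- rep(prob, each = 4) * rep(bg, times = length(prob))
    ## merge exactly-equal partial sums; column scores are added left to
    ## right, the same order a word score is summed, so equal-scoring words
    ## collapse bit-for-bit and the result equals exhaustive enumeration
    key <- sprintf("%.17g", score)
    agg <- rowsum(prob, key)
    score <- as.numeric(rownames(agg))
    prob <- as.numeric(agg)
  }
  o <- order(score)
  data.frame(score = score[o], prob = prob[o])
}

#' Exact PWM p-value
#'
#' P(score of a random background word >= observed), computed from
#' \code{\link{pwm_score_distribution}}. Monotone non-increasing in the
#' observed score.
#'
#' @param motif a PWM \code{\link{motif_model}}.
#' @param score observed score(s), bits.
#' @param dist optional precomputed score distribution.
#' @return p-value(s) in (0, 1].
#' @export
pwm_pvalue <- function(motif, score, dist = NULL) {
  if (is.null(dist)) dist <- pwm_score_distribution(motif)
  tail_p <- rev(cumsum(rev(dist$prob)))
  vapply(score, function(s) {
    i <- which(dist$score >= s - 1e-9)[1]
    if (is.na(i)) 0 else tail_p[i]
  }, numeric(1))
}

#' Scan a promoter with a PWM
#'
#' Scores every in-window offset on the promoter strand and reports those
#' with p-value below \code{alpha}.
#'
#' @param promoter promoter sequence (5'->3' on the TSS strand, ending at
#'   offset -1).
#' @param motif a PWM \code{\link{motif_model}}.
#' @param alpha p-value threshold (default 0.001).
#' @param dist optional precomputed score distribution (reuse across
#'   promoters for speed).
#' @return data.frame with \code{offset}, \code{seq}, \code{score},
#'   \code{p_value}.
#' @export
scan_pwm <- function(promoter, motif, alpha = 0.001, dist = NULL) {
  stopifnot(inherits(motif, "motif_model"), motif$kind == "pwm")
  empty <- data.frame(offset = integer(), seq = character(),
                      score = numeric(), p_value = numeric())
  W <- nchar(promoter)
  w <- motif$width
  if (W < w) return(empty)
  if (is.null(dist)) dist <- pwm_score_distribution(motif)
  lo <- pwm_logodds(motif)
  idx <- match(strsplit(toupper(promoter), "")[[1]], BASES)
  starts <- seq_len(W - w + 1)
  offset <- starts - W - 1L
  keep <- offset >= motif$window[1] & (offset + w - 1L) <= motif$window[2]
  starts <- starts[keep]; offset <- offset[keep]
  if (length(starts) == 0) return(empty)
  score <- vapply(starts, function(s) {
    ii <- idx[s:(s + w - 1)]
    if (anyNA(ii)) return(-Inf)   # ambiguous bases never hit
    acc <- 0
    for (j in seq_len(w)) acc <- acc + lo[ii[j], j]
    acc
  }, numeric(1))
  p <- pwm_pvalue(motif, score, dist = dist)
  ## alpha >= 1 reports every scored offset (p is capped at 1)
  hit <- is.finite(score) & (p < alpha | alpha >= 1)
  if (!any(hit)) return(empty)
  data.frame(offset = offset[hit],
             seq = substring(promoter, starts[hit], starts[hit] + w - 1),
             score = score[hit], p_value = p[hit], stringsAsFactors = FALSE)
}

#' Classify CtrA binding mode from motif hits
#'
#' Full-motif hits are "full". Half-motif hits whose 5' offset falls in the
#' repressor band (over the -10 element, default [-20, -5]) are
#' "half_repressor"; in the activator band (near the -35 element, default
#' [-45, -25]) "half_activator"; otherwise "unclassified".
#'
#' @param motif_name character vector: \code{"full"} or \code{"half"} per
#'   hit (any name containing "full" counts as full).
#' @param offset numeric vector of 5'-base offsets.
#' @param repressor_band,activator_band inclusive offset bands.
#' @return character vector of modes.
#' @export
classify_ctra_mode <- function(motif_name, offset,
                               repressor_band = c(-20, -5),
                               activator_band = c(-45, -25)) {
  full <- grepl("full", motif_name, ignore.case = TRUE)
  mode <- rep("unclassified", length(offset))
  mode[full] <- "full"
  in_band <- function(x, b) x >= b[1] & x <= b[2]
  mode[!full & in_band(offset, repressor_band)] <- "half_repressor"
  mode[!full & in_band(offset, activator_band)] <- "half_activator"
  mode
}

#' Histogram of motif offsets
#'
#' @param offsets numeric vector of 5'-base offsets relative to the TSS.
#' @param bin bin width in bp (default 1).
#' @return data.frame with \code{offset} (bin left edge) and \code{count}.
#' @export
positions_histogram <- function(offsets, bin = 1) {
  if (length(offsets) == 0)
    return(data.frame(offset = integer(), count = integer()))
  b <- floor(offsets / bin) * bin
  tab <- table(b)
  data.frame(offset = as.integer(names(tab)), count = as.integer(tab))
}

#' Regulator co-occurrence across promoters
#'
#' @param hit_sets list (one element per TSS) of character vectors naming
#'   the regulators with at least one hit in that promoter.
#' @return list with \code{matrix} (symmetric pair counts; the diagonal
#'   counts promoters where that regulator is the sole hit),
#'   \code{n_regulators} (per-TSS regulator count) and
#'   \code{combination_counts} (promoters with 1, 2, 3, >= 4 regulators).
#' @export
cooccurrence <- function(hit_sets) {
  regs <- sort(unique(unlist(hit_sets)))
  m <- matrix(0L, length(regs), length(regs), dimnames = list(regs, regs))
  nreg <- vapply(hit_sets, function(s) length(unique(s)), integer(1))
  for (s in hit_sets) {
    s <- unique(s)
    if (length(s) == 1) m[s, s] <- m[s, s] + 1L
    else if (length(s) > 1)
      for (pair in utils::combn(sort(s), 2, simplify = FALSE)) {
        m[pair[1], pair[2]] <- m[pair[1], pair[2]] + 1L
        m[pair[2], pair[1]] <- m[pair[2], pair[1]] + 1L
      }
  }
  combo <- c(`1` = sum(nreg == 1), `2` = sum(nreg == 2),
             `3` = sum(nreg == 3), `>=4` = sum(nreg >= 4))
  list(matrix = m, n_regulators = nreg, combination_counts = combo)
}

#' ChIP fold enrichment upstream of a TSS
#'
#' Mean ChIP coverage in the strand-aware window upstream of the TSS divided
#' by the genome-wide mean coverage; flagged when the fold reaches
#' \code{min_fold}.
#'
#' @param track numeric vector of per-position ChIP coverage (strandless,
#'   full genome length).
#' @param pos,strand TSS position(s) and strand(s).
#' @param window upstream window in bp (default 50).
#' @param min_fold enrichment flag threshold (default 3).
#' @return data.frame with \code{fold} and \code{enriched}.
#' @export
chip_enrichment <- function(track, pos, strand, window = 50, min_fold = 3) {
  gmean <- mean(track)
  if (gmean <= 0) stop("genome-wide mean coverage must be > 0")
  L <- length(track)
  strand <- rep_len(strand, length(pos))
  fold <- vapply(seq_along(pos), function(i) {
    p <- pos[i]
    win <- if (strand[i] == "+") {
      if (p <= 1) return(0) else max(1, p - window):(p - 1)
    } else {
      if (p >= L) return(0) else (p + 1):min(L, p + window)
    }
    mean(track[win]) / gmean
  }, numeric(1))
  data.frame(fold = fold, enriched = fold >= min_fold)
}

#' Default motif set for the cell-cycle master regulators
#'
#' The printed consensus models and search windows: CtrA full
#' (TTAA-N7-TTAA) and half (TTAA), SciP full (GCGNC-N5-GNCGC) and half
#' (GCGNC) at -100..-1, the CcrM methylation site GANTC at -50..-1, and a
#' DnaA PWM built from the printed DnaA box variants (CTCCACA, ATCCACA,
#' GTCCACA; a synthetic stand-in for a full curated site alignment) at
#' -100..-1.
#'
#' @param background background base probabilities for the PWM (GC-aware;
#'   default uniform).
#' @return named list of \code{\link{motif_model}} objects.
#' @export
default_motifs <- function(background = c(A = .25, C = .25, G = .25,
                                          T = .25)) {
  list(
    CtrA_full = motif_model("CtrA_full", consensus = "TTAA-N7-TTAA",
                            window = c(-100, -1)),
    CtrA_half = motif_model("CtrA_half", consensus = "TTAA",
                            window = c(-100, -1)),
    SciP_full = motif_model("SciP_full", consensus = "GCGNC-N5-GNCGC",
                            window = c(-100, -1)),
    SciP_half = motif_model("SciP_half", consensus = "GCGNC",
                            window = c(-100, -1)),
    CcrM = motif_model("CcrM", consensus = "GANTC", window = c(-50, -1)),
    DnaA = build_pwm(c("CTCCACA", "ATCCACA", "GTCCACA"), name = "DnaA",
                     window = c(-100, -1), background = background)
  )
}
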