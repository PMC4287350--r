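## Synthetic-data generator: a miniature genome with annotation, planted
## TSSs/processing sites/motifs, and simulated +TAP/-TAP, time-course,
## RNA-seq and ChIP tracks with a known truth table.

#' Generator configuration
#'
#' Defaults encode the emulated study conditions: a GC-rich ~0.67 genome,
#' theta at true TSSs ~ Normal(1.71, 1.26) and at processing sites ~
#' Normal(-0.52, 0.35) (natural-log units), an 8 x 20-min time course over
#' a 160-min cycle, and a -TAP site rate (lambda) of 200 reads so the
#' Poisson bias on recovered theta stays well under 1%.
#'
#' @param genome_length genome length in bp (default 200000).
#' @param gc_fraction GC content in (0, 1) (default 0.67).
#' @param n_cds number of CDSs (default 150).
#' @param n_operons number of operons (default 12).
#' @param n_true_tss number of true TSSs (default 200).
#' @param n_processing_sites number of 5' processing sites (default 50).
#' @param frac_regulated fraction of true TSSs that are cell-cycle
#'   regulated (default 0.3).
#' @param theta_pos_mean,theta_pos_sd theta distribution at true TSSs
#'   (defaults 1.71, 1.26).
#' @param theta_neg_mean,theta_neg_sd theta distribution at processing
#'   sites (defaults -0.52, 0.35).
#' @param baseline_minus_tap_mean expected -TAP reads (lambda) at a site
#'   (default 200).
#' @param amplitude_range peak-to-trough fold range for regulated profiles
#'   (default c(4, 16)).
#' @param library_depth target total reads per library, or NA for the
#'   natural depth implied by the rates (default NA).
#' @param tss_level_range range of mean time-course levels per TSS,
#'   log-uniform (default c(30, 300)).
#' @param period cell-cycle period in minutes (default 160; the 8 samples
#'   cover 0-140 so the first DFT harmonic is dominant for a single-peak
#'   profile).
#' @param background_rate uniform per-position Poisson background of
#'   spurious 5' ends (default 0.02 reads).
#' @param motif_frac fraction of true TSSs given a planted regulator motif
#'   (default 0.5).
#' @param chip_frac fraction of true TSSs with a planted ChIP enrichment
#'   bump (default 0.2).
#' @param chip_baseline,chip_fold flat ChIP baseline and the planted fold
#'   (defaults 10, 5).
#' @param rnaseq_baseline,rnaseq_step_factor RNA-seq baseline coverage and
#'   the per-TSS downstream increment in baseline units (defaults 5, 4; the
#'   resulting step is well above the 35% filter).
#' @param transcript_length how far downstream the RNA-seq step extends
#'   (default 400 bp).
#' @param min_site_separation minimum spacing between planted sites on one
#'   strand (default 12 bp, beyond the 5-bp merge reach).
#' @param seed integer RNG seed (default 1).
#' @return a validated list of class \code{generator_config}.
#' @export
generator_config <- function(genome_length = 200000, gc_fraction = 0.67,
                             n_cds = 150, n_operons = 12, n_true_tss = 200,
                             n_processing_sites = 50, frac_regulated = 0.3,
                             theta_pos_mean = 1.71, theta_pos_sd = 1.26,
                             theta_neg_mean = -0.52, theta_neg_sd = 0.35,
                             baseline_minus_tap_mean = 200,
                             amplitude_range = c(4, 16),
                             library_depth = NA_real_,
                             tss_level_range = c(30, 300), period = 160,
                             background_rate = 0.02, motif_frac = 0.5,
                             chip_frac = 0.2, chip_baseline = 10,
                             chip_fold = 5, rnaseq_baseline = 5,
                             rnaseq_step_factor = 4,
                             transcript_length = 400,
                             min_site_separation = 12, seed = 1) {
  cfg <- as.list(environment())
  counts <- c(cfg$n_cds, cfg$n_operons, cfg$n_true_tss,
              cfg$n_processing_sites)
  if (any(counts < 0)) stop("counts must be >= 0")
  if (cfg$theta_pos_sd <= 0 || cfg$theta_neg_sd <= 0)
    stop("theta sds must be > 0")
  if (cfg$gc_fraction <= 0 || cfg$gc_fraction >= 1)
    stop("gc_fraction must be in (0, 1)")
  if (cfg$genome_length < 1000) stop("genome_length must be >= 1000")
  if (cfg$frac_regulated < 0 || cfg$frac_regulated > 1)
    stop("frac_regulated must be in [0, 1]")
  structure(cfg, class = "generator_config")
}

## Category mix of the emulated dataset (fractions of 2726 TSSs).
CATEGORY_MIX <- c(P = 1443, I = 344, A = 503, IP = 197, AP = 84, N = 155) /
  2726

## Motif plan: what gets planted where (5'-base offsets within each motif's
## search window).
MOTIF_PLAN <- data.frame(
  motif = c("CtrA_full", "CtrA_half", "SciP_full", "SciP_half", "CcrM",
            "DnaA"),
  consensus = c("TTAA-N7-TTAA", "TTAA", "GCGNC-N5-GNCGC", "GCGNC", "GANTC",
                "CTCCACA"),
  offset = c(-39, -14, -80, -74, -28, -52),
  stringsAsFactors = FALSE)

#' Generate a random genome and annotation
#'
#' I.i.d. bases at the configured GC fraction; non-overlapping CDSs on both
#' strands, some grouped into operons (same-strand runs with short gaps);
#' a few tRNA/rRNA/ncRNA features in intergenic gaps. Deterministic given
#' the config seed.
#'
#' @param config a \code{\link{generator_config}}.
#' @return list with \code{genome} (character string) and \code{annotation}
#'   (a \code{\link{genome_annotation}}).
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  L <- config$genome_length
  p <- c(A = (1 - config$gc_fraction) / 2, C = config$gc_fraction / 2,
         G = config$gc_fraction / 2, T = (1 - config$gc_fraction) / 2)
  genome <- paste(sample(names(p), L, replace = TRUE, prob = p),
                  collapse = "")
  cds <- data.frame(id = character(), start = integer(), end = integer(),
                    strand = character(), stringsAsFactors = FALSE)
  operons <- list()
  cursor <- 600
  i <- 0; op_i <- 0
  ops_left <- config$n_operons
  while (i < config$n_cds) {
    in_operon <- ops_left > 0 && (config$n_cds - i) >
      2 * ops_left && stats::runif(1) < 0.25
    block <- if (in_operon) sample(2:4, 1) else 1
    block <- min(block, config$n_cds - i)
    strand <- sample(c("+", "-"), 1)
    members <- character(0)
    for (b in seq_len(block)) {
      len <- sample(600:1500, 1)
      if (cursor + len > L - 600) break
      i <- i + 1
      id <- sprintf("cds%03d", i)
      cds <- rbind(cds, data.frame(id = id, start = cursor,
                                   end = cursor + len - 1, strand = strand,
                                   stringsAsFactors = FALSE))
      members <- c(members, id)
      cursor <- cursor + len +
        (if (b < block) sample(20:50, 1) else sample(120:400, 1))
    }
    if (in_operon && length(members) >= 2) {
      op_i <- op_i + 1
      operons[[sprintf("operon%02d", op_i)]] <- members
      ops_left <- ops_left - 1
    }
    if (cursor > L - 2200) break
  }
  if (i < config$n_cds)
    stop("genome too short to place ", config$n_cds, " CDSs")
  ## a few typed RNA features in remaining space near the end
  rnas <- data.frame(id = character(), type = character(),
                     start = integer(), end = integer(),
                     strand = character(), stringsAsFactors = FALSE)
  rna_types <- c("rRNA", "rRNA", "tRNA", "tRNA", "ncRNA", "ncRNA")
  rcur <- cursor + 200
  for (k in seq_along(rna_types)) {
    len <- sample(80:120, 1)
    if (rcur + len > L) break
    rnas <- rbind(rnas, data.frame(
      id = sprintf("%s%02d", tolower(rna_types[k]), k),
      type = rna_types[k], start = rcur, end = rcur + len - 1,
      strand = sample(c("+", "-"), 1), stringsAsFactors = FALSE))
    rcur <- rcur + len + 150
  }
  ann <- genome_annotation(cds, operons, rnas, L, ori = 1L,
                           ter = as.integer(floor(L / 2)))
  list(genome = genome, annotation = ann)
}

## Logical position masks used for category-aware placement.
category_masks <- function(annotation, upstream_window = 300,
                           tail_fraction = 0.30) {
  L <- annotation$genome_length
  cds <- annotation$cds
  mask <- function() logical(L)
  inside <- list(`+` = mask(), `-` = mask())
  tail30 <- list(`+` = mask(), `-` = mask())
  windowP <- list(`+` = mask(), `-` = mask())
  for (j in seq_len(nrow(cds))) {
    s <- cds$strand[j]
    inside[[s]][cds$start[j]:cds$end[j]] <- TRUE
    len <- cds$end[j] - cds$start[j] + 1
    tl <- floor(tail_fraction * len)
    if (tl >= 1) {
      rng <- if (s == "+") (cds$end[j] - tl + 1):cds$end[j]
             else cds$start[j]:(cds$start[j] + tl - 1)
      tail30[[s]][rng] <- TRUE
    }
    win <- if (s == "+") max(1, cds$start[j] - upstream_window):cds$start[j]
           else cds$end[j]:min(L, cds$end[j] + upstream_window)
    windowP[[s]][win] <- TRUE
  }
  inside_any <- inside[["+"]] | inside[["-"]]
  masks <- list()
  for (s in c("+", "-")) {
    o <- setdiff(c("+", "-"), s)
    masks[[s]] <- list(
      P = windowP[[s]] & !inside_any,
      IP = windowP[[s]] & tail30[[s]],
      AP = windowP[[s]] & inside[[o]] & !inside[[s]],
      I = inside[[s]] & !windowP[[s]] & !tail30[[s]],
      A = inside[[o]] & !inside[[s]] & !windowP[[s]],
      N = !inside_any & !windowP[[s]])
  }
  masks
}

## Greedy spaced sampling from candidate positions.
pick_spaced <- function(candidates, n, taken, min_sep) {
  picked <- integer(0)
  if (n == 0 || length(candidates) == 0) return(picked)
  for (p in sample(candidates)) {
    if (length(picked) == n) break
    if (length(taken) == 0 || min(abs(taken - p)) >= min_sep) {
      picked <- c(picked, p)
      taken <- c(taken, p)
    }
  }
  picked
}

#' Plant ground-truth sites and motifs
#'
#' Places true TSSs realizing every genomic-context category (P, IP, AP, I,
#' A, N) in proportions mirroring the emulated dataset, including at least
#' one gene with two primary TSSs and at least one operon-internal TSS;
#' places processing sites inside CDSs; writes exact motif realizations
#' into the genome at recorded offsets (overwriting bases, so coordinates
#' stay stable); assigns phases and amplitudes to regulated TSSs and marks
#' a subset as ChIP-enriched.
#'
#' @param genome genome string from \code{\link{generate_genome}}.
#' @param annotation matching annotation.
#' @param config the \code{\link{generator_config}}.
#' @return list with \code{genome} (edited) and \code{truth} (class
#'   \code{tss_truth}: data.frames \code{true_tss}, \code{processing_sites},
#'   \code{chip_enriched}).
#' @export
plant_truth <- function(genome, annotation, config) {
  set.seed(config$seed + 1L)
  L <- annotation$genome_length
  masks <- category_masks(annotation)
  n <- config$n_true_tss
  quota <- floor(CATEGORY_MIX * n)
  rem <- n - sum(quota)
  if (rem > 0) {
    bump <- names(sort(CATEGORY_MIX * n - quota, decreasing = TRUE))[
      seq_len(rem)]
    quota[bump] <- quota[bump] + 1
  }
  if (n >= length(quota)) quota[quota == 0] <- pmax(
    quota[quota == 0], 1)  # every category realized
  taken <- list(`+` = integer(0), `-` = integer(0))
  rows <- list()
  add_tss <- function(pos, strand, category) {
    rows[[length(rows) + 1]] <<- data.frame(
      pos = pos, strand = strand, category = category,
      stringsAsFactors = FALSE)
    taken[[strand]] <<- c(taken[[strand]], pos)
  }
  ## guaranteed features first: a 2-promoter gene and an operon-internal TSS
  if (quota["P"] >= 2 && nrow(annotation$cds) > 0) {
    cds <- annotation$cds
    for (j in sample(nrow(cds))) {
      s <- cds$strand[j]
      st <- if (s == "+") cds$start[j] else cds$end[j]
      p1 <- if (s == "+") st - 120 else st + 120
      p2 <- if (s == "+") st - 22 else st + 22
      ok <- p1 >= 1 && p1 <= L && p2 >= 1 && p2 <= L &&
        masks[[s]]$P[p1] && masks[[s]]$P[p2]
      if (ok) {
        add_tss(p1, s, "P"); add_tss(p2, s, "P")
        quota["P"] <- quota["P"] - 2
        break
      }
    }
  }
  if (length(annotation$operons) > 0 && quota["P"] >= 1) {
    for (op in annotation$operons) {
      cds <- annotation$cds
      mi <- match(op, cds$id)
      s <- cds$strand[mi[1]]
      op_ord <- op[order(cds$start[mi], decreasing = (s == "-"))]
      second <- cds[match(op_ord[2], cds$id), ]
      st <- if (s == "+") second$start else second$end
      cand <- if (s == "+") (st - 45):(st - 5) else (st + 5):(st + 45)
      cand <- cand[cand >= 1 & cand <= L]
      cand <- cand[masks[[s]]$P[cand]]
      pk <- pick_spaced(cand, 1, taken[[s]], config$min_site_separation)
      if (length(pk) == 1) {
        add_tss(pk, s, "P")
        quota["P"] <- quota["P"] - 1
        break
      }
    }
  }
  for (cat in names(quota)) {
    need <- quota[[cat]]
    if (need <= 0) next
    strands <- sample(c("+", "-"))
    target <- c(ceiling(need / 2), floor(need / 2))
    for (k in 1:2) {      # balanced across strands, then top up
      s <- strands[k]
      pk <- pick_spaced(which(masks[[s]][[cat]]), target[k], taken[[s]],
                        config$min_site_separation)
      for (p in pk) add_tss(p, s, cat)
      need <- need - length(pk)
    }
    for (s in strands) {
      if (need <= 0) break
      pk <- pick_spaced(which(masks[[s]][[cat]]), need, taken[[s]],
                        config$min_site_separation)
      for (p in pk) add_tss(p, s, cat)
      need <- need - length(pk)
    }
    if (need > 0)
      stop("insufficient genomic space to place ", need,
           " more TSSs of category ", cat)
  }
  tss <- do.call(rbind, rows)
  tss <- tss[seq_len(min(nrow(tss), n)), , drop = FALSE]
  tss$id <- sprintf("tss%04d", seq_len(nrow(tss)))
  ## regulation, phase, amplitude
  tss$regulated <- stats::runif(nrow(tss)) < config$frac_regulated
  tss$phase <- ifelse(tss$regulated,
                      sample(seq(0, 140, by = 20), nrow(tss),
                             replace = TRUE), NA)
  amp <- exp(stats::runif(nrow(tss), log(config$amplitude_range[1]),
                          log(config$amplitude_range[2])))
  tss$amplitude <- ifelse(tss$regulated, amp, NA)
  ## processing sites: inside CDSs, same strand as host
  proc_cand <- list(`+` = which(masks[["+"]]$I | masks[["+"]]$IP),
                    `-` = which(masks[["-"]]$I | masks[["-"]]$IP))
  prows <- list()
  for (s in c("+", "-")) {
    want <- if (s == "+") ceiling(config$n_processing_sites / 2)
            else floor(config$n_processing_sites / 2)
    pk <- pick_spaced(proc_cand[[s]], want, taken[[s]],
                      config$min_site_separation)
    taken[[s]] <- c(taken[[s]], pk)
    if (length(pk) < want)
      stop("insufficient space for processing sites")
    if (length(pk) > 0)
      prows[[s]] <- data.frame(pos = pk, strand = s,
                               stringsAsFactors = FALSE)
  }
  proc <- do.call(rbind, prows)
  if (is.null(proc)) proc <- data.frame(pos = integer(),
                                        strand = character())
  if (nrow(proc) > 0) proc$id <- sprintf("proc%03d", seq_len(nrow(proc)))
  rownames(proc) <- NULL
  ## plant motifs into the genome
  tss$motifs <- ""
  genome_vec <- strsplit(genome, "")[[1]]
  n_motif <- round(config$motif_frac * nrow(tss))
  if (n_motif > 0 && nrow(tss) > 0) {
    chosen <- sample(nrow(tss), n_motif)
    plan_idx <- rep(seq_len(nrow(MOTIF_PLAN)), length.out = n_motif)
    planted_base <- logical(L)   # never overwrite an earlier planting
    for (k in seq_len(n_motif)) {
      i <- chosen[k]
      pl <- MOTIF_PLAN[plan_idx[k], ]
      real <- realize_consensus(expand_consensus(pl$consensus))
      w <- nchar(real)
      if (tss$strand[i] == "+") {
        a <- tss$pos[i] + pl$offset
        b <- a + w - 1
        if (a < 1 || b >= tss$pos[i] || any(planted_base[a:b])) next
        genome_vec[a:b] <- strsplit(real, "")[[1]]
      } else {
        b <- tss$pos[i] - pl$offset
        a <- b - w + 1
        if (b > L || a <= tss$pos[i] || any(planted_base[a:b])) next
        rc <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(real)))
        genome_vec[a:b] <- strsplit(rc, "")[[1]]
      }
      planted_base[a:b] <- TRUE
      tss$motifs[i] <- paste0(tss$motifs[i],
                              if (nzchar(tss$motifs[i])) ";" else "",
                              pl$motif, "@", pl$offset)
    }
  }
  ## ChIP-enriched subset
  n_chip <- round(config$chip_frac * nrow(tss))
  chip <- if (n_chip > 0)
    data.frame(id = sample(tss$id, n_chip), fold = config$chip_fold,
               stringsAsFactors = FALSE)
  else data.frame(id = character(), fold = numeric())
  truth <- structure(list(true_tss = tss[, c("id", "pos", "strand",
                                             "category", "regulated",
                                             "phase", "amplitude",
                                             "motifs")],
                          processing_sites = proc[, c("id", "pos",
                                                      "strand")],
                          chip_enriched = chip),
                     class = "tss_truth")
  list(genome = paste(genome_vec, collapse = ""), truth = truth)
}

#' @export
print.tss_truth <- function(x, ...) {
  cat(sprintf("<tss_truth> %d true TSSs (%d regulated), %d processing sites, %d ChIP-enriched\n",
              nrow(x$true_tss), sum(x$true_tss$regulated),
              nrow(x$processing_sites), nrow(x$chip_enriched)))
  invisible(x)
}

## One concrete realization of an IUPAC consensus.
realize_consensus <- function(pattern) {
  iupac <- list(A = "A", C = "C", G = "G", T = "T", R = c("A", "G"),
                Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
                K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
                D = c("A", "G", "T"), H = c("A", "C", "T"),
                V = c("A", "C", "G"), N = c("A", "C", "G", "T"))
  paste(vapply(strsplit(pattern, "")[[1]], function(ch) {
    opts <- iupac[[ch]]
    if (length(opts) == 1) opts else sample(opts, 1)
  }, character(1)), collapse = "")
}

#' Simulate one theta observation per site through the Poisson count layer
#'
#' For n sites draws theta ~ Normal(mean, sd), realizes -TAP ~
#' Poisson(lambda) and +TAP ~ Poisson(lambda e^theta), and returns the
#' recovered theta = ln(plus/minus) (counts clamped at 1 read; with lambda
#' >= 100 this and the Jensen bias are both well below 1%).
#'
#' @param n number of sites.
#' @param mean,sd planted theta distribution (natural-log units).
#' @param lambda expected -TAP reads per site.
#' @return list with \code{theta_planted} and \code{theta_observed}.
#' @export
simulate_theta_counts <- function(n, mean, sd, lambda = 200) {
  theta <- stats::rnorm(n, mean, sd)
  minus <- pmax(1, stats::rpois(n, lambda))
  plus <- pmax(1, stats::rpois(n, lambda * exp(theta)))
  list(theta_planted = theta, theta_observed = log(plus / minus))
}

## Sparse Poisson background: positions and counts on both strands.
sample_background <- function(L, rate) {
  n_reads <- stats::rpois(1, 2 * L * rate)
  if (n_reads == 0)
    return(data.frame(pos = integer(), strand = character(),
                      count = numeric()))
  pos <- sample.int(L, n_reads, replace = TRUE)
  strand <- sample(c("+", "-"), n_reads, replace = TRUE)
  agg <- rowsum(rep(1, n_reads), paste(pos, strand))
  key <- strsplit(rownames(agg), " ")
  data.frame(pos = as.integer(vapply(key, `[`, "", 1)),
             strand = vapply(key, `[`, "", 2),
             count = as.numeric(agg), stringsAsFactors = FALSE)
}

## Assemble a position_counts from site expectations (Poisson-realized)
## plus sparse background.
realize_library <- function(site_pos, site_strand, site_mean, L, rate,
                            library_id, scale = 1) {
  counts <- stats::rpois(length(site_pos), site_mean * scale)
  bg <- sample_background(L, rate * scale)
  df <- rbind(data.frame(pos = site_pos, strand = site_strand,
                         count = counts, stringsAsFactors = FALSE), bg)
  agg <- rowsum(df$count, paste(df$pos, df$strand))
  key <- strsplit(rownames(agg), " ")
  pos <- as.integer(vapply(key, `[`, "", 1))
  strand <- vapply(key, `[`, "", 2)
  keep <- as.numeric(agg) > 0
  position_counts(pos[keep], strand[keep], as.numeric(agg)[keep],
                  library_id = library_id, genome_length = L)
}

#' Simulate all sequencing libraries and auxiliary tracks
#'
#' For each true TSS draws theta from the positive distribution and for
#' each processing site from the negative one; expected -TAP reads are
#' lambda and +TAP reads lambda e^theta, both realized with Poisson noise
#' over a uniform background. Because a real -TAP library is dominated by
#' processed 5'-monophosphate ends, the -TAP background is raised so the
#' two libraries have equal expected totals (total-count normalization is
#' then composition-neutral and the planted theta survives the pipeline).
#' Time-point t levels for a regulated TSS follow
#' m exp(A cos(2 pi (t - phase) / period)) with A = ln(amplitude)/2,
#' sampled at t = 0, 20, ..., 140 with Poisson noise; constitutive TSSs are
#' flat at m. RNA-seq coverage steps up downstream of every true TSS and
#' the ChIP track carries fold bumps in the 50 bp upstream of
#' ChIP-enriched TSSs.
#'
#' @param genome genome string (with planted motifs).
#' @param truth a \code{tss_truth} from \code{\link{plant_truth}}.
#' @param config the \code{\link{generator_config}}.
#' @return list with \code{plus_tap}, \code{minus_tap}
#'   (\code{\link{position_counts}}), \code{timepoints} (list of 8),
#'   \code{rnaseq} (list of \code{plus}/\code{minus} coverage vectors),
#'   \code{chip} (coverage vector), and \code{site_truth} (per-site planted
#'   theta and mean level).
#' @export
simulate_libraries <- function(genome, truth, config) {
  set.seed(config$seed + 2L)
  L <- config$genome_length
  lam <- config$baseline_minus_tap_mean
  tss <- truth$true_tss
  proc <- truth$processing_sites
  n_t <- nrow(tss); n_p <- nrow(proc)
  theta <- c(stats::rnorm(n_t, config$theta_pos_mean, config$theta_pos_sd),
             stats::rnorm(n_p, config$theta_neg_mean, config$theta_neg_sd))
  site_pos <- c(tss$pos, proc$pos)
  site_strand <- c(tss$strand, proc$strand)
  mean_minus <- rep(lam, n_t + n_p)
  mean_plus <- lam * exp(theta)
  ## equalize expected library totals via extra processed-end background
  bg <- config$background_rate
  e_plus <- 2 * L * bg + sum(mean_plus)
  e_minus <- 2 * L * bg + sum(mean_minus)
  bg_plus <- bg + max(0, (e_minus - e_plus)) / (2 * L)
  bg_minus <- bg + max(0, (e_plus - e_minus)) / (2 * L)
  e_total <- max(e_plus, e_minus)
  scale <- if (is.finite(config$library_depth))
    config$library_depth / e_total else 1
  plus_tap <- realize_library(site_pos, site_strand, mean_plus, L, bg_plus,
                              "plus_tap", scale)
  minus_tap <- realize_library(site_pos, site_strand, mean_minus, L,
                               bg_minus, "minus_tap", scale)
  ## time course
  m <- exp(stats::runif(n_t, log(config$tss_level_range[1]),
                        log(config$tss_level_range[2])))
  A <- ifelse(tss$regulated, log(tss$amplitude) / 2, 0)
  phase <- ifelse(tss$regulated, tss$phase, 0)
  times <- seq(0, 140, by = 20)
  timepoints <- lapply(times, function(t) {
    lev_t <- m * exp(A * cos(2 * pi * (t - phase) / config$period))
    site_mean_t <- c(lev_t, rep(lam, n_p))
    tp_total <- 2 * L * bg + sum(site_mean_t)
    tp_scale <- if (is.finite(config$library_depth))
      config$library_depth / tp_total else 1
    realize_library(site_pos, site_strand, site_mean_t, L, bg,
                    sprintf("t%d", t), tp_scale)
  })
  names(timepoints) <- sprintf("t%d", times)
  ## RNA-seq coverage with a step downstream of every true TSS
  rnaseq <- list(plus = rep(config$rnaseq_baseline, L),
                 minus = rep(config$rnaseq_baseline, L))
  inc <- config$rnaseq_step_factor * config$rnaseq_baseline
  for (i in seq_len(n_t)) {
    p <- tss$pos[i]
    rng <- if (tss$strand[i] == "+") p:min(L, p + config$transcript_length)
           else max(1, p - config$transcript_length):p
    s <- if (tss$strand[i] == "+") "plus" else "minus"
    rnaseq[[s]][rng] <- rnaseq[[s]][rng] + inc
  }
  ## ChIP track
  chip <- rep(config$chip_baseline, L)
  for (id in truth$chip_enriched$id) {
    i <- match(id, tss$id)
    p <- tss$pos[i]
    rng <- if (tss$strand[i] == "+") max(1, p - 50):(p - 1)
           else (p + 1):min(L, p + 50)
    chip[rng] <- config$chip_baseline * config$chip_fold
  }
  site_truth <- data.frame(
    id = c(tss$id, proc$id),
    pos = site_pos, strand = site_strand,
    kind = rep(c("tss", "processing"), c(n_t, n_p)),
    theta = theta,
    level = c(m, rep(NA, n_p)), stringsAsFactors = FALSE)
  list(plus_tap = plus_tap, minus_tap = minus_tap,
       timepoints = timepoints, rnaseq = rnaseq, chip = chip,
       site_truth = site_truth)
}

#' Generate a complete synthetic dataset in memory
#'
#' Runs \code{\link{generate_genome}}, \code{\link{plant_truth}} and
#' \code{\link{simulate_libraries}} in sequence.
#'
#' @param config a \code{\link{generator_config}} (default config if
#'   missing).
#' @return list with \code{genome}, \code{annotation}, \code{truth} and all
#'   simulated tracks (see \code{\link{simulate_libraries}}).
#' @export
simulate_tss_dataset <- function(config = generator_config()) {
  g <- generate_genome(config)
  pt <- plant_truth(g$genome, g$annotation, config)
  sim <- simulate_libraries(pt$genome, pt$truth, config)
  c(list(genome = pt$genome, annotation = g$annotation,
         truth = pt$truth, config = config), sim)
}

#' Write a synthetic dataset to disk
#'
#' FASTA + GFF3 + one bedGraph pair per library (suffixes
#' \code{.plus.bedGraph} / \code{.minus.bedGraph}) + RNA-seq pair + ChIP
#' bedGraph + truth TSV (header: id pos strand category regulated phase
#' amplitude motifs). Round-trips losslessly through the package readers.
#'
#' @param dataset result of \code{\link{simulate_tss_dataset}}.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_fixture <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(...) file.path(dir, paste0(...))
  write_fasta(dataset$genome, path("genome.fasta"))
  write_gff3(dataset$annotation, path("annotation.gff3"))
  wpair <- function(x, stem)
    write_bedgraph_pair(x, path(stem, ".plus.bedGraph"),
                        path(stem, ".minus.bedGraph"))
  wpair(dataset$plus_tap, "plus_tap")
  wpair(dataset$minus_tap, "minus_tap")
  for (nm in names(dataset$timepoints))
    wpair(dataset$timepoints[[nm]], nm)
  write_bedgraph_vector(dataset$rnaseq$plus, path("rnaseq.plus.bedGraph"))
  write_bedgraph_vector(dataset$rnaseq$minus, path("rnaseq.minus.bedGraph"))
  write_bedgraph_vector(dataset$chip, path("chip.bedGraph"))
  truth_rows <- dataset$truth$true_tss
  proc <- dataset$truth$processing_sites
  if (nrow(proc) > 0) {
    proc_rows <- data.frame(id = proc$id, pos = proc$pos,
                            strand = proc$strand, category = "processing",
                            regulated = NA, phase = NA, amplitude = NA,
                            motifs = "", stringsAsFactors = FALSE)
    truth_rows <- rbind(truth_rows, proc_rows)
  }
  write.table(truth_rows, path("truth.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(dir)
}

#' Read a synthetic dataset back from disk
#'
#' Inverse of \code{\link{write_fixture}}.
#'
#' @param dir fixture directory.
#' @return list shaped like \code{\link{simulate_tss_dataset}} output
#'   (without the config).
#' @export
read_fixture <- function(dir) {
  path <- function(...) file.path(dir, paste0(...))
  genome <- read_fasta(path("genome.fasta"))
  L <- nchar(genome)
  annotation <- read_gff3(path("annotation.gff3"), genome_length = L)
  rpair <- function(stem) read_bedgraph_pair(
    path(stem, ".plus.bedGraph"), path(stem, ".minus.bedGraph"), L,
    library_id = stem)
  times <- sprintf("t%d", seq(0, 140, by = 20))
  timepoints <- lapply(times, rpair)
  names(timepoints) <- times
  tt <- read.delim(path("truth.tsv"), stringsAsFactors = FALSE)
  is_proc <- tt$category == "processing"
  truth <- structure(list(
    true_tss = tt[!is_proc, , drop = FALSE],
    processing_sites = tt[is_proc, c("id", "pos", "strand"), drop = FALSE],
    chip_enriched = data.frame(id = character(), fold = numeric())),
    class = "tss_truth")
  rownames(truth$true_tss) <- rownames(truth$processing_sites) <- NULL
  list(genome = genome, annotation = annotation, truth = truth,
       plus_tap = rpair("plus_tap"), minus_tap = rpair("minus_tap"),
       timepoints = timepoints,
       rnaseq = list(plus = read_bedgraph_vector(path("rnaseq.plus.bedGraph"), L),
                     minus = read_bedgraph_vector(path("rnaseq.minus.bedGraph"), L)),
       chip = read_bedgraph_vector(path("chip.bedGraph"), L))
}
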