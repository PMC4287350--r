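## End-to-end orchestration: call -> annotate -> classify -> motifs ->
## report, on an in-memory dataset or an on-disk fixture directory.

#' Run the full TSS analysis pipeline
#'
#' Stages, in order: TSS calling from the +TAP/-TAP pair with the RNA-seq
#' step filter (\code{\link{call_tss}}); extraction of 8-point time-course
#' levels (normalized to the mean time-point library total, summed over the
#' 5-bp merge reach around each call); genomic-context categorization and
#' the per-CDS contribution filters; Fourier classification of regulated
#' TSSs and k-means profile clustering; promoter motif scanning and ChIP
#' enrichment; context analyses (multi-promoter genes, operon-internal
#' TSSs, antisense pairing, direction bias, density profile) and a summary.
#'
#' @param dataset a list as returned by \code{\link{simulate_tss_dataset}}
#'   or \code{\link{read_fixture}}, or a fixture directory path.
#' @param threshold theta operating threshold (default 0.26, the published
#'   operating point) or a \code{\link{calibrate_threshold}} result.
#' @param min_plus_tap minimum normalized +TAP reads (default 25).
#' @param k number of k-means clusters for regulated profiles (default 15).
#' @param motifs named list of \code{\link{motif_model}}s; default
#'   \code{\link{default_motifs}} with a GC-aware PWM background estimated
#'   from the genome.
#' @param alpha PWM scan p-value threshold (default 0.001).
#' @param chip_min_fold ChIP enrichment flag threshold (default 3).
#' @param seed seed for the clustering stage (default 0).
#' @param out_dir optional output directory for TSV/BED reports.
#' @param ... further parameters passed to \code{\link{call_tss}}.
#' @return an object of class \code{tss_pipeline}.
#' @export
run_pipeline <- function(dataset, threshold = 0.26, min_plus_tap = 25,
                         k = 15, motifs = NULL, alpha = 0.001,
                         chip_min_fold = 3, seed = 0, out_dir = NULL, ...) {
  if (is.character(dataset)) dataset <- read_fixture(dataset)
  for (need in c("genome", "annotation", "plus_tap", "minus_tap",
                 "timepoints"))
    if (is.null(dataset[[need]]))
      stop("pipeline input is missing the '", need, "' component")
  L <- nchar(dataset$genome)
  ann <- dataset$annotation

  ## --- call ---
  calls <- call_tss(dataset$plus_tap, dataset$minus_tap, dataset$rnaseq,
                    threshold, min_plus_tap = min_plus_tap, ...)
  tss <- calls[calls$called, , drop = FALSE]
  if (nrow(tss) == 0) stop("no TSSs called; check inputs and threshold")
  tss$id <- sprintf("TSS%04d", seq_len(nrow(tss)))

  ## --- time-course levels (mean-total normalization, 5-bp reach) ---
  tp <- dataset$timepoints
  tp_scale <- mean(vapply(tp, attr, numeric(1), "total_nonrrna"))
  tp_norm <- lapply(tp, normalize_counts, scale = tp_scale)
  reach <- -5:5
  for (nm in names(tp_norm)) {
    tss[[nm]] <- vapply(seq_len(nrow(tss)), function(i)
      sum(counts_at(tp_norm[[nm]], tss$pos[i] + reach, tss$strand[i])),
      numeric(1))
  }
  level_cols <- names(tp_norm)

  ## --- annotate + contribution filters ---
  tss <- categorize_tss(tss, ann)
  tss <- contribution_filter(tss)

  ## --- cell-cycle classification ---
  levels_mat <- as.matrix(tss[, level_cols])
  reg_detail <- lapply(seq_len(nrow(tss)), function(i)
    is_regulated(levels_mat[i, ], detail = TRUE))
  tss$regulated <- vapply(reg_detail, `[[`, logical(1), "regulated")
  tss$peak_time <- apply(levels_mat, 1, peak_time)
  tss$cluster <- NA_integer_
  reg_idx <- which(tss$regulated)
  display <- t(apply(levels_mat, 1, normalize_profile))
  if (length(reg_idx) >= 2) {
    kk <- min(k, length(reg_idx))
    tss$cluster[reg_idx] <- kmeans_profiles(display[reg_idx, , drop = FALSE],
                                            k = kk, seed = seed)
  }

  ## --- motifs ---
  if (is.null(motifs)) {
    base_freq <- Biostrings::letterFrequency(
      Biostrings::DNAString(dataset$genome), c("A", "C", "G", "T"))
    motifs <- default_motifs(background = base_freq / sum(base_freq))
  }
  pwm_dists <- lapply(motifs, function(m)
    if (m$kind == "pwm") pwm_score_distribution(m) else NULL)
  hit_rows <- list()
  for (i in seq_len(nrow(tss))) {
    prom <- promoter_seq(dataset$genome, tss$pos[i], tss$strand[i], 100)
    for (nm in names(motifs)) {
      m <- motifs[[nm]]
      h <- if (m$kind == "consensus") scan_consensus(prom, m)
           else scan_pwm(prom, m, alpha = alpha, dist = pwm_dists[[nm]])
      if (nrow(h) > 0) {
        h$tss_id <- tss$id[i]
        h$motif <- nm
        hit_rows[[length(hit_rows) + 1]] <- h
      }
    }
  }
  motif_hits <- if (length(hit_rows) > 0) {
    mh <- do.call(rbind, lapply(hit_rows, function(h) {
      for (cc in c("score", "p_value")) if (is.null(h[[cc]])) h[[cc]] <- NA
      h[, c("tss_id", "motif", "offset", "seq", "score", "p_value")]
    }))
    rownames(mh) <- NULL
    mh
  } else data.frame(tss_id = character(), motif = character(),
                    offset = integer(), seq = character(),
                    score = numeric(), p_value = numeric())

  ## --- ChIP enrichment (GcrA-style) ---
  chip <- if (!is.null(dataset$chip)) {
    ce <- chip_enrichment(dataset$chip, tss$pos, tss$strand,
                          min_fold = chip_min_fold)
    cbind(data.frame(tss_id = tss$id), ce)
  } else NULL

  ## --- regulator sets per regulated TSS (motif families + ChIP) ---
  reg_ids <- tss$id[tss$regulated]
  regulator_of <- function(id) {
    regs <- sub("_(full|half)$", "",
                motif_hits$motif[motif_hits$tss_id == id])
    if (!is.null(chip) && chip$enriched[match(id, chip$tss_id)])
      regs <- c(regs, "GcrA")
    unique(regs)
  }
  hit_sets <- lapply(reg_ids, regulator_of)
  names(hit_sets) <- reg_ids
  cooc <- cooccurrence(hit_sets)

  ## --- context analyses ---
  multi_promoter <- find_multi_promoter_genes(tss)
  operon_internal <- find_operon_internal_tss(tss, ann)
  antisense <- pair_antisense(tss, ann)
  direction <- if (!is.na(ann$ori) && !is.na(ann$ter))
    direction_bias(tss, ann$ori, ann$ter, L) else NULL
  density <- density_profile(tss, L)

  summary_counts <- c(
    n_tss = nrow(tss),
    table(factor(tss$category, levels = c("P", "IP", "AP", "I", "A", "N"))),
    n_regulated = sum(tss$regulated),
    n_regulated_with_motif =
      sum(vapply(hit_sets, length, integer(1)) > 0),
    n_multi_promoter_genes = length(multi_promoter),
    n_operon_internal = nrow(operon_internal),
    n_antisense_pairs = sum(!is.na(antisense$relationship)),
    n_codirectional = if (!is.null(direction)) direction$n_codirectional
      else NA,
    n_opposing = if (!is.null(direction)) direction$n_opposing else NA)

  out <- structure(list(
    calls = calls, tss = tss, threshold = threshold,
    level_cols = level_cols, motif_hits = motif_hits, chip = chip,
    cooccurrence = cooc, multi_promoter = multi_promoter,
    operon_internal = operon_internal, antisense = antisense,
    direction = direction, density = density, summary = summary_counts,
    seed = seed), class = "tss_pipeline")

  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

## TSV/BED reports for a pipeline run.
write_pipeline_outputs <- function(x, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tss <- x$tss
  names(tss)[match(x$level_cols, names(tss))] <-
    paste0("t", seq(0, 140, by = 20))
  write_tss_table(tss, file.path(out_dir, "tss_table.tsv"))
  write_tss_bed(tss, file.path(out_dir, "tss.bed"))
  write.table(x$motif_hits, file.path(out_dir, "motif_hits.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(x$antisense, file.path(out_dir, "antisense_pairs.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(x$operon_internal, file.path(out_dir, "operon_internal.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(x$cooccurrence$matrix,
              file.path(out_dir, "cooccurrence_matrix.tsv"),
              sep = "\t", quote = FALSE, col.names = NA)
  summ <- data.frame(metric = names(x$summary),
                     value = as.numeric(x$summary))
  write.table(summ, file.path(out_dir, "summary.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}

#' @export
print.tss_pipeline <- function(x, ...) {
  cat("TSS analysis pipeline result\n")
  cat(sprintf("  called TSSs: %d (threshold theta > %.2f)\n",
              nrow(x$tss),
              if (inherits(x$threshold, "tss_calibration"))
                x$threshold$threshold else x$threshold))
  cats <- table(factor(x$tss$category,
                       levels = c("P", "IP", "AP", "I", "A", "N")))
  cat("  categories:", paste(sprintf("%s=%d", names(cats), cats),
                             collapse = " "), "\n")
  cat(sprintf("  cell-cycle regulated: %d\n", sum(x$tss$regulated)))
  cat(sprintf("  motif hits: %d across %d TSSs\n", nrow(x$motif_hits),
              length(unique(x$motif_hits$tss_id))))
  invisible(x)
}

#' @export
summary.tss_pipeline <- function(object, ...) {
  object$summary
}

#' Simulate a dataset and run the pipeline on it
#'
#' One-call demonstration target: generates the default synthetic fixture
#' and runs the full pipeline, returning both.
#'
#' @param config a \code{\link{generator_config}}.
#' @param ... passed to \code{\link{run_pipeline}}.
#' @return list with \code{dataset} and \code{result}.
#' @export
run_demo <- function(config = generator_config(), ...) {
  dataset <- simulate_tss_dataset(config)
  result <- run_pipeline(dataset, ...)
  list(dataset = dataset, result = result)
}
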