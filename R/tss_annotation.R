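## Genomic-context categories for called TSSs, per-CDS contribution
## filters, and the context analyses (multi-promoter genes, operon-internal
## TSSs, antisense pairing, replication-direction bias, density profile).

cds_start_pos <- function(cds) ifelse(cds$strand == "+", cds$start, cds$end)

## Distance from a TSS to a same-strand CDS start, measured upstream in the
## CDS's direction of transcription. 0 = first base of the start codon.
upstream_distance <- function(pos, cds_start, strand) {
  n <- max(length(pos), length(cds_start))
  ifelse(rep_len(strand == "+", n), cds_start - pos, pos - cds_start)
}

#' Categorize TSSs by genomic context
#'
#' Rules (applied per TSS): a TSS within \code{upstream_window} bp upstream
#' of a same-strand CDS start (or on the start codon's first base) is
#' promoter-like. If additionally intergenic it is P; if inside the
#' upstream same-strand CDS's final \code{tail_fraction} it is IP; if
#' inside an opposite-strand CDS it is AP. Otherwise a TSS inside a
#' same-strand CDS is I, inside an opposite-strand CDS is A, and anything
#' else is N. When a TSS is within the window of two CDS starts it is
#' assigned to the nearer one. N TSSs within 1 kb upstream of a CDS start
#' get \code{needs_review = TRUE} (possible long-5'UTR primary promoters).
#'
#' @param tss data.frame with \code{pos} and \code{strand}.
#' @param annotation a \code{\link{genome_annotation}}.
#' @param upstream_window bp upstream of a CDS start that counts as its
#'   promoter region (default 300).
#' @param tail_fraction fraction of the upstream CDS 3' tail within which a
#'   promoter-like internal TSS is IP rather than I (default 0.30).
#' @return the input with added columns \code{category} (one of P, IP, AP,
#'   I, A, N), \code{assigned_cds} (CDS id served, or NA) and
#'   \code{needs_review}.
#' @export
categorize_tss <- function(tss, annotation, upstream_window = 300,
                           tail_fraction = 0.30) {
  cds <- annotation$cds
  starts <- cds_start_pos(cds)
  n <- nrow(tss)
  category <- character(n)
  assigned <- rep(NA_character_, n)
  needs_review <- rep(FALSE, n)
  for (i in seq_len(n)) {
    p <- tss$pos[i]; s <- tss$strand[i]
    inside <- which(cds$start <= p & p <= cds$end)
    inside_same <- inside[cds$strand[inside] == s]
    ## a leaderless TSS on the start codon's first base is upstream-like,
    ## not internal to its own CDS
    inside_same <- inside_same[starts[inside_same] != p]
    inside_opp <- inside[cds$strand[inside] != s]
    same <- which(cds$strand == s)
    d <- upstream_distance(p, starts[same], s)
    served <- same[d >= 0 & d <= upstream_window]
    served <- setdiff(served, inside_same)
    if (length(served) > 0) {
      dd <- upstream_distance(p, starts[served], s)
      target <- served[which.min(dd)]
      assigned[i] <- cds$id[target]
      if (length(inside_opp) > 0) {
        category[i] <- "AP"
      } else if (length(inside_same) > 0) {
        host <- inside_same[1]
        len <- cds$end[host] - cds$start[host] + 1
        dist3 <- if (cds$strand[host] == "+") cds$end[host] - p
                 else p - cds$start[host]
        category[i] <- if (dist3 < tail_fraction * len) "IP" else "I"
        if (category[i] == "I") assigned[i] <- cds$id[host]
      } else {
        category[i] <- "P"
      }
    } else if (length(inside_same) > 0) {
      category[i] <- "I"
      assigned[i] <- cds$id[inside_same[1]]
    } else if (length(inside_opp) > 0) {
      category[i] <- "A"
      assigned[i] <- cds$id[inside_opp[1]]
    } else {
      category[i] <- "N"
      if (length(same) > 0) {
        d1k <- upstream_distance(p, starts[same], s)
        needs_review[i] <- any(d1k >= 0 & d1k <= 1000)
      }
    }
  }
  tss$category <- category
  tss$assigned_cds <- assigned
  tss$needs_review <- needs_review
  tss
}

#' Per-CDS contribution and read-floor filters
#'
#' For each (assigned CDS, TSS strand) group the candidate reads are summed;
#' promoter-like TSSs (P, IP, AP) are kept iff their share of that total
#' exceeds \code{upstream_share}, purely internal/antisense TSSs (I, A) iff
#' their share exceeds \code{internal_share}. Independently, the maximum of
#' the 8 time-point levels must reach \code{min_level_primary} (P/IP/AP) or
#' \code{min_level_other} (I/A/N).
#'
#' @param records categorized TSS data.frame with \code{plus} (normalized
#'   +TAP reads), \code{category}, \code{assigned_cds}, \code{strand}, and
#'   time-point columns \code{t0..t140} (if absent the level floors are
#'   skipped).
#' @param upstream_share,internal_share contribution floors (defaults 0.10
#'   and 0.25, strict >).
#' @param min_level_primary,min_level_other time-point floors (defaults 2
#'   and 10).
#' @return the kept records, with a \code{share} column.
#' @export
contribution_filter <- function(records, upstream_share = 0.10,
                                internal_share = 0.25,
                                min_level_primary = 2,
                                min_level_other = 10) {
  if (nrow(records) == 0) { records$share <- numeric(0); return(records) }
  key <- paste(records$assigned_cds, records$strand)
  totals <- tapply(records$plus, key, sum)
  records$share <- records$plus / as.numeric(totals[key])
  records$share[is.na(records$assigned_cds)] <- 1
  promoter_like <- records$category %in% c("P", "IP", "AP")
  floor_share <- ifelse(promoter_like, upstream_share, internal_share)
  keep_share <- records$share > floor_share | records$category == "N"
  level_cols <- intersect(paste0("t", seq(0, 140, by = 20)), names(records))
  if (length(level_cols) > 0) {
    max_level <- do.call(pmax, records[level_cols])
    floor_level <- ifelse(promoter_like, min_level_primary, min_level_other)
    keep_level <- max_level >= floor_level
  } else keep_level <- TRUE
  out <- records[keep_share & keep_level, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' CDSs served by multiple primary promoters
#'
#' @param records categorized (and filtered) TSS data.frame.
#' @return list of data.frames, one per CDS with >= 2 primary-like TSSs
#'   (P/IP/AP toward that CDS), each ordered by distance to the CDS start;
#'   names are CDS ids.
#' @export
find_multi_promoter_genes <- function(records) {
  prim <- records[records$category %in% c("P", "IP", "AP") &
                  !is.na(records$assigned_cds), , drop = FALSE]
  if (nrow(prim) == 0) return(list())
  out <- split(prim, prim$assigned_cds)
  out <- out[vapply(out, nrow, integer(1)) >= 2]
  lapply(out, function(df) {
    if ("distance" %in% names(df)) df[order(df$distance), , drop = FALSE]
    else df[order(df$pos), , drop = FALSE]
  })
}

#' TSSs internal to operons
#'
#' A TSS is operon-internal when it lies strictly downstream of the operon's
#' first CDS start (in the operon's direction) and serves a non-first
#' member.
#'
#' @param records categorized TSS data.frame.
#' @param annotation a \code{\link{genome_annotation}} with operons.
#' @return data.frame with one row per internal TSS: \code{operon},
#'   \code{pos}, \code{strand}, \code{assigned_cds}, \code{regulated} (if
#'   present) and \code{downstream_members} (comma-joined member ids from
#'   the served CDS on).
#' @export
find_operon_internal_tss <- function(records, annotation) {
  cds <- annotation$cds
  rows <- list()
  for (op in names(annotation$operons)) {
    members <- annotation$operons[[op]]
    mi <- match(members, cds$id)
    strand <- cds$strand[mi[1]]
    ## order members in transcription direction
    members <- members[order(cds$start[mi],
                             decreasing = (strand == "-"))]
    first_start <- cds_start_pos(cds[match(members[1], cds$id), ])
    cand <- records[records$strand == strand &
                    records$assigned_cds %in% members[-1] &
                    !is.na(records$assigned_cds), , drop = FALSE]
    if (nrow(cand) == 0) next
    after_first <- if (strand == "+") cand$pos > first_start
                   else cand$pos < first_start
    cand <- cand[after_first, , drop = FALSE]
    if (nrow(cand) == 0) next
    served_idx <- match(cand$assigned_cds, members)
    rows[[op]] <- data.frame(
      operon = op, pos = cand$pos, strand = cand$strand,
      assigned_cds = cand$assigned_cds,
      regulated = if ("regulated" %in% names(cand)) cand$regulated else NA,
      downstream_members = vapply(served_idx, function(k)
        paste(members[k:length(members)], collapse = ","), character(1)),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(operon = character(), pos = integer(),
                      strand = character(), assigned_cds = character(),
                      regulated = logical(),
                      downstream_members = character())
  rownames(out) <- NULL
  out
}

#' Pair antisense TSSs with the primary TSS of their host CDS
#'
#' Antisense TSSs (A or AP) are paired with the primary-like TSS of the CDS
#' they lie within; peak times are compared and the pair is labelled
#' \code{anticorrelated} when the peak times differ by at least
#' \code{anti_min} minutes, \code{correlated} when by at most
#' \code{corr_max}, and \code{intermediate} otherwise. Antisense TSSs in a
#' CDS with no primary TSS are reported unpaired.
#'
#' @param records TSS data.frame with \code{category}, \code{pos},
#'   \code{strand}, \code{assigned_cds} and time-point columns
#'   \code{t0..t140}.
#' @param annotation a \code{\link{genome_annotation}}.
#' @param corr_max,anti_min peak-time-difference cutoffs in minutes
#'   (defaults 20 and 40).
#' @return data.frame with one row per antisense TSS: host CDS, both peak
#'   times, \code{delta_peak} and \code{relationship} (NA when unpaired).
#' @export
pair_antisense <- function(records, annotation, corr_max = 20,
                           anti_min = 40) {
  level_cols <- intersect(paste0("t", seq(0, 140, by = 20)), names(records))
  peak_of <- function(row) peak_time(as.numeric(row[1, level_cols]))
  cds <- annotation$cds
  anti <- records[records$category %in% c("A", "AP"), , drop = FALSE]
  prim <- records[records$category %in% c("P", "IP", "AP"), , drop = FALSE]
  rows <- lapply(seq_len(nrow(anti)), function(i) {
    p <- anti$pos[i]
    host <- which(cds$start <= p & p <= cds$end &
                  cds$strand != anti$strand[i])
    host_id <- if (length(host) > 0) cds$id[host[1]] else NA_character_
    mate <- prim[!is.na(prim$assigned_cds) & prim$assigned_cds %in% host_id,
                 , drop = FALSE]
    a_pk <- peak_of(anti[i, , drop = FALSE])
    if (nrow(mate) == 0)
      return(data.frame(antisense_pos = p, strand = anti$strand[i],
                        host_cds = host_id, sense_pos = NA_integer_,
                        antisense_peak = a_pk, sense_peak = NA_real_,
                        delta_peak = NA_real_,
                        relationship = NA_character_,
                        stringsAsFactors = FALSE))
    mate <- mate[which.max(mate$plus %||% rep(1, nrow(mate))), , drop = FALSE]
    s_pk <- peak_of(mate)
    d <- abs(a_pk - s_pk)
    rel <- if (d >= anti_min) "anticorrelated"
           else if (d <= corr_max) "correlated" else "intermediate"
    data.frame(antisense_pos = p, strand = anti$strand[i],
               host_cds = host_id, sense_pos = mate$pos,
               antisense_peak = a_pk, sense_peak = s_pk, delta_peak = d,
               relationship = rel, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(antisense_pos = integer(), strand = character(),
                      host_cds = character(), sense_pos = integer(),
                      antisense_peak = numeric(), sense_peak = numeric(),
                      delta_peak = numeric(), relationship = character())
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Replication-direction bias of TSSs
#'
#' A TSS is co-directional when its strand matches the direction of
#' replisome travel on its replichore: plus-strand TSSs on the ascending
#' ori-to-ter arm and minus-strand TSSs on the other arm (circular
#' wrap-around handled).
#'
#' @param records TSS data.frame with \code{pos} and \code{strand}.
#' @param ori,ter replication origin and terminus positions (bp).
#' @param genome_length genome length (bp).
#' @return list with \code{n_codirectional} and \code{n_opposing}.
#' @export
direction_bias <- function(records, ori, ter, genome_length) {
  ## arc from ori ascending (mod L) up to ter = right replichore: the
  ## replisome travels in the + direction there.
  arc <- (records$pos - ori) %% genome_length
  ter_arc <- (ter - ori) %% genome_length
  on_right <- arc > 0 & arc <= ter_arc
  codir <- ifelse(on_right, records$strand == "+", records$strand == "-")
  list(n_codirectional = sum(codir), n_opposing = sum(!codir))
}

#' Sliding-window TSS density
#'
#' Circular sliding-window counts of TSSs per strand.
#'
#' @param records TSS data.frame with \code{pos} and \code{strand}.
#' @param genome_length genome length (bp).
#' @param window window size in bp (default 100000).
#' @param step window step in bp (default \code{window / 10}).
#' @return data.frame with \code{center}, \code{plus}, \code{minus} counts.
#' @export
density_profile <- function(records, genome_length, window = 1e5,
                            step = window / 10) {
  centers <- seq(1, genome_length, by = step)
  count_in <- function(pos, center) {
    d <- abs((pos - center) %% genome_length)
    d <- pmin(d, genome_length - d)
    sum(d <= window / 2)
  }
  plus <- records$pos[records$strand == "+"]
  minus <- records$pos[records$strand == "-"]
  data.frame(center = centers,
             plus = vapply(centers, function(cc) count_in(plus, cc),
                           numeric(1)),
             minus = vapply(centers, function(cc) count_in(minus, cc),
                            numeric(1)))
}
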