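## Readers/writers for on-disk formats and the coordinate-convention boundary.
## Everything in memory is 1-based inclusive; BED/bedGraph on disk are 0-based
## half-open, as usual.

#' Per-position strand-specific 5'-end read counts for one library
#'
#' A thin container: a data.frame with columns \code{pos} (1-based bp),
#' \code{strand} (\code{"+"}/\code{"-"}) and \code{count}, carrying the
#' library id, the genome length and the library's non-rRNA read total as
#' attributes. Positions with zero reads are not stored.
#'
#' @param pos integer vector of 1-based positions.
#' @param strand character vector of \code{"+"}/\code{"-"}, recycled.
#' @param count numeric vector of read counts (>= 0).
#' @param library_id label for the library.
#' @param genome_length genome length in bp.
#' @param total_nonrrna total non-rRNA reads in the library; defaults to
#'   \code{sum(count)}.
#' @return an object of class \code{position_counts}.
#' @export
position_counts <- function(pos, strand, count, library_id = "library",
                            genome_length, total_nonrrna = sum(count)) {
  stopifnot(length(pos) == length(count))
  strand <- rep_len(as.character(strand), length(pos))
  if (length(pos) > 0 && (any(pos < 1) || any(pos > genome_length)))
    stop("positions outside [1, genome_length]")
  if (any(count < 0)) stop("negative counts")
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  df <- data.frame(pos = as.integer(pos), strand = strand, count = count,
                   stringsAsFactors = FALSE)
  df <- df[order(df$strand, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("position_counts", "data.frame"),
            library_id = library_id,
            genome_length = as.integer(genome_length),
            total_nonrrna = total_nonrrna)
}

#' @export
print.position_counts <- function(x, ...) {
  cat(sprintf("<position_counts> library '%s': %d nonzero positions, %.0f reads (non-rRNA total %.0f), genome %d bp\n",
              attr(x, "library_id"), nrow(x), sum(x$count),
              attr(x, "total_nonrrna"), attr(x, "genome_length")))
  invisible(x)
}

#' Look up counts at positions
#'
#' @param x a \code{position_counts} object.
#' @param pos,strand vectors of positions and strands (recycled to match).
#' @return numeric vector of counts (0 where absent).
#' @export
counts_at <- function(x, pos, strand) {
  strand <- rep_len(strand, length(pos))
  key <- paste(x$pos, x$strand)
  m <- match(paste(pos, strand), key)
  out <- x$count[m]
  out[is.na(out)] <- 0
  out
}

#' Read a strand pair of bedGraph files into position counts
#'
#' bedGraph intervals are 0-based half-open; the interval value is applied to
#' every covered base. Overlapping intervals on one strand or negative values
#' are format errors.
#'
#' @param plus_path,minus_path bedGraph files for the plus and minus strand.
#' @param genome_length genome length in bp.
#' @param library_id label for the library.
#' @param total_nonrrna library total; defaults to the sum of the tracks.
#' @return a \code{\link{position_counts}} object.
#' @export
read_bedgraph_pair <- function(plus_path, minus_path, genome_length,
                               library_id = "library", total_nonrrna = NULL) {
  read_one <- function(path, strand) {
    gr <- rtracklayer::import(path, format = "bedGraph")
    if (length(gr) == 0)
      return(data.frame(pos = integer(), strand = character(),
                        count = numeric()))
    if (any(gr$score < 0))
      stop("negative bedGraph value in ", path)
    if (!IRanges::isDisjoint(GenomicRanges::granges(gr)))
      stop("overlapping intervals in ", path)
    if (max(GenomicRanges::end(gr)) > genome_length)
      stop("interval beyond genome end in ", path)
    w <- GenomicRanges::width(gr)
    data.frame(pos = unlist(Map(seq.int, GenomicRanges::start(gr),
                                GenomicRanges::end(gr))),
               strand = strand,
               count = rep(gr$score, w), stringsAsFactors = FALSE)
  }
  df <- rbind(read_one(plus_path, "+"), read_one(minus_path, "-"))
  df <- df[df$count > 0, , drop = FALSE]
  position_counts(df$pos, df$strand, df$count, library_id = library_id,
                  genome_length = genome_length,
                  total_nonrrna = if (is.null(total_nonrrna)) sum(df$count)
                                  else total_nonrrna)
}

#' Write a position-counts object as a strand pair of bedGraph files
#'
#' @param x a \code{\link{position_counts}} object.
#' @param plus_path,minus_path output paths.
#' @param seqname chromosome name to write.
#' @export
write_bedgraph_pair <- function(x, plus_path, minus_path, seqname = "chr") {
  write_one <- function(df, path) {
    gr <- GenomicRanges::GRanges(
      seqnames = seqname,
      ranges = IRanges::IRanges(start = df$pos, width = 1),
      score = df$count)
    GenomeInfoDb::seqlengths(gr) <- attr(x, "genome_length")
    rtracklayer::export(gr, path, format = "bedGraph")
    invisible(NULL)
  }
  write_one(x[x$strand == "+", , drop = FALSE], plus_path)
  write_one(x[x$strand == "-", , drop = FALSE], minus_path)
  invisible(c(plus_path, minus_path))
}

#' Read / write a dense coverage vector as bedGraph
#'
#' Runs of equal coverage are stored as bedGraph intervals (0-based
#' half-open); zero-coverage runs are omitted on write and fill with 0 on
#' read.
#'
#' @param path bedGraph file.
#' @param genome_length genome length in bp.
#' @return numeric vector of per-position coverage.
#' @export
read_bedgraph_vector <- function(path, genome_length) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  out <- numeric(genome_length)
  if (length(gr) == 0) return(out)
  if (max(GenomicRanges::end(gr)) > genome_length)
    stop("interval beyond genome end in ", path)
  for (i in seq_along(gr))
    out[GenomicRanges::start(gr)[i]:GenomicRanges::end(gr)[i]] <- gr$score[i]
  out
}

#' @param coverage numeric vector of per-position coverage.
#' @param seqname chromosome name.
#' @rdname read_bedgraph_vector
#' @export
write_bedgraph_vector <- function(coverage, path, seqname = "chr") {
  r <- rle(coverage)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values != 0
  gr <- GenomicRanges::GRanges(seqname,
          IRanges::IRanges(start = starts[keep], end = ends[keep]),
          score = r$values[keep])
  GenomeInfoDb::seqlengths(gr) <- length(coverage)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Genome annotation container
#'
#' @param cds data.frame with columns \code{id}, \code{start}, \code{end}
#'   (1-based inclusive), \code{strand}.
#' @param operons list of character vectors of CDS ids (coordinate-ordered,
#'   one strand each).
#' @param rnas data.frame with columns \code{id}, \code{type} (tRNA, rRNA or
#'   ncRNA), \code{start}, \code{end}, \code{strand}; may be empty.
#' @param genome_length genome length in bp.
#' @param ori,ter optional replication origin/terminus positions (bp).
#' @return an object of class \code{genome_annotation}.
#' @export
genome_annotation <- function(cds, operons = list(), rnas = NULL,
                              genome_length, ori = NA_integer_,
                              ter = NA_integer_) {
  if (is.null(rnas))
    rnas <- data.frame(id = character(), type = character(),
                       start = integer(), end = integer(),
                       strand = character(), stringsAsFactors = FALSE)
  stopifnot(all(c("id", "start", "end", "strand") %in% names(cds)))
  if (nrow(cds) > 0) {
    if (any(cds$start > cds$end)) stop("CDS with start > end")
    if (anyDuplicated(cds$id)) stop("duplicate CDS ids")
  }
  for (op in operons) {
    s <- cds$strand[match(op, cds$id)]
    if (length(unique(s)) > 1) stop("operon members on mixed strands")
  }
  structure(list(cds = cds, operons = operons, rnas = rnas,
                 genome_length = as.integer(genome_length),
                 ori = ori, ter = ter),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("<genome_annotation> %d CDS, %d operons, %d RNA features, genome %d bp\n",
              nrow(x$cds), length(x$operons), nrow(x$rnas), x$genome_length))
  invisible(x)
}

#' Read a genome annotation from GFF3
#'
#' CDS features become the CDS table; \code{operon} features with member CDSs
#' carrying a matching \code{Parent} attribute become operons; tRNA/rRNA/ncRNA
#' features become typed RNA features.
#'
#' @param path GFF3 file.
#' @param genome_length genome length (bp); if missing, taken from the
#'   \code{##sequence-region} pragma or the rightmost feature end.
#' @return a \code{\link{genome_annotation}}.
#' @export
read_gff3 <- function(path, genome_length = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  typ <- as.character(gr$type)
  ids <- if (!is.null(gr$ID)) as.character(gr$ID) else
    paste0("feat", seq_along(gr))
  take <- function(sel) data.frame(
    id = ids[sel],
    start = GenomicRanges::start(gr)[sel],
    end = GenomicRanges::end(gr)[sel],
    strand = as.character(GenomicRanges::strand(gr))[sel],
    stringsAsFactors = FALSE)
  cds <- take(typ == "CDS")
  rnas <- take(typ %in% c("tRNA", "rRNA", "ncRNA"))
  if (nrow(rnas) > 0) rnas$type <- typ[typ %in% c("tRNA", "rRNA", "ncRNA")]
  else rnas$type <- character(0)
  rnas <- rnas[, c("id", "type", "start", "end", "strand")]
  operons <- list()
  op_sel <- typ == "operon"
  if (any(op_sel)) {
    parent <- gr$Parent
    parent_chr <- vapply(as.list(parent), function(p)
      if (length(p)) as.character(p)[1] else NA_character_, character(1))
    for (i in which(op_sel)) {
      members <- ids[typ == "CDS" & !is.na(parent_chr) & parent_chr == ids[i]]
      mi <- match(members, cds$id)
      operons[[ids[i]]] <- members[order(cds$start[mi])]
    }
  }
  if (is.null(genome_length)) {
    sl <- GenomeInfoDb::seqlengths(gr)
    genome_length <- if (length(sl) && !is.na(sl[1])) sl[1] else
      max(GenomicRanges::end(gr))
  }
  ori <- if (!is.null(gr$ID)) {
    sel <- typ == "region" & !is.na(ids) & ids == "ori"
    if (any(sel)) GenomicRanges::start(gr)[sel][1] else NA_integer_
  } else NA_integer_
  ter <- {
    sel <- typ == "region" & !is.na(ids) & ids == "ter"
    if (any(sel)) GenomicRanges::start(gr)[sel][1] else NA_integer_
  }
  genome_annotation(cds, operons, rnas, genome_length, ori = ori, ter = ter)
}

#' Write a genome annotation as GFF3
#'
#' @param ann a \code{\link{genome_annotation}}.
#' @param path output file.
#' @param seqname chromosome name.
#' @export
write_gff3 <- function(ann, path, seqname = "chr") {
  cds_parent <- rep(NA_character_, nrow(ann$cds))
  for (op in names(ann$operons))
    cds_parent[ann$cds$id %in% ann$operons[[op]]] <- op
  ranges <- list()
  mk <- function(start, end, strand, type, id, parent = NA_character_) {
    gr <- GenomicRanges::GRanges(seqname,
            IRanges::IRanges(start = start, end = end), strand = strand)
    gr$type <- type
    gr$ID <- id
    gr$Parent <- ifelse(is.na(parent), NA_character_, parent)
    gr$phase <- ifelse(type == "CDS", 0L, NA_integer_)
    gr
  }
  out <- mk(ann$cds$start, ann$cds$end, ann$cds$strand, "CDS", ann$cds$id,
            cds_parent)
  if (length(ann$operons) > 0) {
    ostart <- vapply(ann$operons, function(m)
      min(ann$cds$start[ann$cds$id %in% m]), numeric(1))
    oend <- vapply(ann$operons, function(m)
      max(ann$cds$end[ann$cds$id %in% m]), numeric(1))
    ostrand <- vapply(ann$operons, function(m)
      ann$cds$strand[match(m[1], ann$cds$id)], character(1))
    out <- c(out, mk(ostart, oend, ostrand, "operon", names(ann$operons)))
  }
  if (nrow(ann$rnas) > 0)
    out <- c(out, mk(ann$rnas$start, ann$rnas$end, ann$rnas$strand,
                     ann$rnas$type, ann$rnas$id))
  marks <- c(ori = ann$ori, ter = ann$ter)
  marks <- marks[!is.na(marks)]
  if (length(marks) > 0)
    out <- c(out, mk(unname(marks), unname(marks), "*", "region",
                     names(marks)))
  GenomeInfoDb::seqlengths(out) <- ann$genome_length
  rtracklayer::export(out, path, format = "gff3")
  invisible(path)
}

#' Read a single-record FASTA genome
#'
#' Multi-record FASTA is rejected (single-chromosome assumption); bases are
#' upper-cased.
#'
#' @param path FASTA file.
#' @return a single character string of A/C/G/T (and possibly IUPAC codes).
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) != 1)
    stop("expected a single-record FASTA, found ", length(ss), " records")
  toupper(as.character(ss[[1]]))
}

#' Write a genome sequence as FASTA
#'
#' @param genome character string of bases.
#' @param path output file.
#' @param name record name.
#' @export
write_fasta <- function(genome, path, name = "chr") {
  ss <- Biostrings::DNAStringSet(genome)
  names(ss) <- name
  Biostrings::writeXStringSet(ss, path, width = 70)
  invisible(path)
}

#' Write / read a TSS table (TSV)
#'
#' Fixed columns: id, pos, strand, category, theta, the 8 time-point levels
#' (t0..t140), regulated, cluster, assigned_cds. Missing values are written
#' as \code{.}.
#'
#' @param records TSS data.frame.
#' @param path output file.
#' @export
write_tss_table <- function(records, path) {
  level_cols <- paste0("t", seq(0, 140, by = 20))
  cols <- c("id", "pos", "strand", "category", "theta", level_cols,
            "regulated", "cluster", "assigned_cds")
  out <- records
  for (cc in setdiff(cols, names(out))) out[[cc]] <- NA
  out <- out[, cols]
  for (cc in cols) {
    v <- out[[cc]]
    if (is.logical(v)) v <- ifelse(is.na(v), NA, ifelse(v, "TRUE", "FALSE"))
    v <- as.character(v)
    v[is.na(v)] <- "."
    out[[cc]] <- v
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tss_table
#' @export
read_tss_table <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE, na.strings = ".")
  x$pos <- as.integer(x$pos)
  x$theta <- as.numeric(x$theta)
  for (cc in paste0("t", seq(0, 140, by = 20)))
    if (cc %in% names(x)) x[[cc]] <- as.numeric(x[[cc]])
  if ("regulated" %in% names(x)) x$regulated <- as.logical(x$regulated)
  if ("cluster" %in% names(x)) x$cluster <- as.integer(x$cluster)
  x
}

#' Write called TSSs as a BED6 file
#'
#' Rows are 0-based half-open single-base intervals with strand.
#'
#' @param records TSS data.frame with \code{pos}, \code{strand} and
#'   optionally \code{id}.
#' @param path output file.
#' @param seqname chromosome name.
#' @export
write_tss_bed <- function(records, path, seqname = "chr") {
  name <- if ("id" %in% names(records)) records$id else "."
  bed <- data.frame(seqname, records$pos - 1L, records$pos, name, ".",
                    records$strand)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
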