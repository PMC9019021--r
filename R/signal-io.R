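#' Read aligned single-end reads from BED or SAM
#'
#' BED (0-based half-open, via rtracklayer) and plain-text SAM (1-based, via
#' Rsamtools) are both returned as a `GRanges` of read intervals carrying
#' strand. Unmapped SAM records (flag 0x4) are skipped with a tally reported
#' by message and stored in `metadata(reads)$skipped`. Records on contigs not
#' present in `genome`, or extending past a contig end, raise an error naming
#' the offenders. An empty file yields an empty `GRanges`.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"bed"` or `"sam"`.
#' @param genome a [genome_spec()]; optional for SAM (taken from the \@SQ
#'   header), required for BED.
#' @return `GRanges` of reads with seqlengths set.
#' @export
read_reads <- function(path, format = c("auto", "bed", "sam"), genome = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, bed = "bed", sam = "sam",
                     stop("cannot guess format from extension '", ext, "'"))
  }
  if (format == "bed") {
    if (is.null(genome)) stop("BED input requires a genome_spec")
    genome <- genome_spec(genome)
    if (file.size(path) == 0) {
      gr <- GRanges(seqinfo = as_seqinfo(genome))
      metadata(gr)$skipped <- 0L
      return(gr)
    }
    gr <- rtracklayer::import(path, format = "BED")
    validate_reads(gr, genome)
    gr <- GRanges(seqnames = as.character(seqnames(gr)),
                  ranges = IRanges(start(gr), end(gr)),
                  strand = strand(gr),
                  seqinfo = as_seqinfo(genome))
    metadata(gr)$skipped <- 0L
    gr
  } else {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
    on.exit(unlink(bam), add = TRUE)
    res <- Rsamtools::scanBam(
      bam, param = Rsamtools::ScanBamParam(
        what = c("flag", "rname", "pos", "qwidth", "strand")))[[1]]
    unmapped <- bitwAnd(res$flag, 4L) != 0L | is.na(res$pos)
    n_skip <- sum(unmapped)
    if (n_skip > 0)
      message("skipped ", n_skip, " unmapped record(s)")
    keep <- !unmapped
    if (is.null(genome)) {
      hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
      if (length(hdr) == 0) stop("SAM has no @SQ header; supply a genome_spec")
      genome <- genome_spec(hdr)
    } else genome <- genome_spec(genome)
    gr <- GRanges(seqnames = as.character(res$rname[keep]),
                  ranges = IRanges(start = res$pos[keep],
                                   width = res$qwidth[keep]))
    strand(gr) <- as.character(res$strand[keep])
    validate_reads(gr, genome)
    GenomeInfoDb::seqlevels(gr) <- names(genome)
    seqlengths(gr) <- genome
    metadata(gr)$skipped <- n_skip
    gr
  }
}

validate_reads <- function(gr, genome) {
  contig <- as.character(seqnames(gr))
  unknown <- setdiff(unique(contig), names(genome))
  if (length(unknown) > 0)
    stop("unknown contig(s): ", paste(unknown, collapse = ", "))
  over <- end(gr) > genome[contig]
  if (any(over))
    stop(sum(over), " record(s) extend past their contig end (first: ",
         contig[which(over)[1]], ":", start(gr)[which(over)[1]], ")")
  invisible(TRUE)
}

#' Remove duplicate reads
#'
#' Keeps at most one read per (contig, start, strand), preserving the first
#' occurrence in input order — the read-level analogue of `samtools rmdup`
#' for single-end data. Idempotent.
#'
#' @param reads `GRanges` of reads.
#' @return `GRanges` with duplicates removed, original order retained.
#' @export
deduplicate <- function(reads) {
  key <- paste(as.character(seqnames(reads)), start(reads),
               as.character(strand(reads)), sep = "\r")
  reads[!duplicated(key)]
}

#' Build a binned coverage track from read starts
#'
#' Bin value = number of reads whose leftmost coordinate falls in the bin
#' (read-start convention), so the genome-wide sum equals the read count and
#' windowed sums are exact read counts. Optionally reads can be extended to
#' fragments before binning (`extend_to`, default off), in which case every
#' covered bin start is counted.
#'
#' @param reads `GRanges` of reads with seqlengths (or supply `genome`).
#' @param bin_size bin width in bp (>= 1).
#' @param genome optional [genome_spec()] overriding `seqlengths(reads)`.
#' @param extend_to optional fragment length in bp; when set, each read is
#'   extended 3'-wards to this length and contributes to every bin whose
#'   start it covers.
#' @return a `signal_track` (raw counts).
#' @export
coverage_track <- function(reads, bin_size = 100, genome = NULL,
                           extend_to = NULL) {
  stopifnot(bin_size >= 1)
  genome <- if (is.null(genome)) genome_of(reads) else genome_spec(genome)
  nbins <- ceiling(genome / bin_size)
  contig <- as.character(seqnames(reads))
  vals <- lapply(names(genome), function(cn) numeric(nbins[cn]))
  names(vals) <- names(genome)
  if (length(reads) > 0) {
    if (is.null(extend_to)) {
      idx <- (start(reads) - 1) %/% bin_size + 1
      tab <- table(contig, idx)
      for (cn in rownames(tab)) {
        i <- as.integer(colnames(tab))
        vals[[cn]][i] <- vals[[cn]][i] + as.numeric(tab[cn, ])
      }
    } else {
      s <- start(reads)
      e <- pmin(s + extend_to - 1, genome[contig])
      neg <- as.character(strand(reads)) == "-"
      e2 <- end(reads)
      s[neg] <- pmax(e2[neg] - extend_to + 1, 1)
      e[neg] <- e2[neg]
      i1 <- (s - 1) %/% bin_size + 1
      i2 <- (e - 1) %/% bin_size + 1
      for (k in seq_along(s)) {
        cn <- contig[k]
        vals[[cn]][i1[k]:i2[k]] <- vals[[cn]][i1[k]:i2[k]] + 1
      }
    }
  }
  signal_track(vals, bin_size = bin_size, genome = genome,
               normalized = FALSE, total_reads = length(reads))
}

#' Construct a signal track
#'
#' A signal track holds one non-negative numeric vector of binned values per
#' contig (`ceiling(length / bin_size)` bins), plus the bin size, the total
#' mapped read count it was built from, and whether values are CPM-normalized.
#'
#' @param values named list of per-contig numeric vectors.
#' @param bin_size bin width in bp.
#' @param genome a [genome_spec()].
#' @param normalized logical; are values counts-per-million?
#' @param total_reads read count the track was built from.
#' @return object of class `signal_track`.
#' @export
signal_track <- function(values, bin_size, genome, normalized = FALSE,
                         total_reads = NA_integer_) {
  genome <- genome_spec(genome)
  stopifnot(is.list(values), setequal(names(values), names(genome)))
  values <- values[names(genome)]
  nbins <- ceiling(genome / bin_size)
  for (cn in names(genome)) {
    if (length(values[[cn]]) != nbins[cn])
      stop("contig '", cn, "': expected ", nbins[cn], " bins, got ",
           length(values[[cn]]))
    if (any(values[[cn]] < 0)) stop("negative bin values")
  }
  structure(list(values = values, bin_size = bin_size, genome = genome,
                 normalized = isTRUE(normalized),
                 total_reads = total_reads),
            class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  cat("<signal_track> bin_size:", x$bin_size,
      if (x$normalized) "(CPM)" else "(raw)",
      " total_reads:", x$total_reads, "\n")
  for (cn in names(x$values))
    cat("  ", cn, ": ", length(x$values[[cn]]), " bins, sum ",
        format(sum(x$values[[cn]])), "\n", sep = "")
  invisible(x)
}

track_sum <- function(track) sum(vapply(track$values, sum, numeric(1)))

#' CPM-normalize a coverage track
#'
#' Scales every bin by `1e6 / total_reads`, so a whole-genome track sums to
#' one million. Normalizing an already-normalized track is an error
#' (idempotence guard), as is a track built from zero reads.
#'
#' @param track a raw `signal_track`.
#' @return normalized `signal_track`.
#' @export
cpm_normalize <- function(track) {
  stopifnot(inherits(track, "signal_track"))
  if (track$normalized)
    stop("track is already CPM-normalized")
  if (is.na(track$total_reads) || track$total_reads <= 0)
    stop("cannot CPM-normalize a track with zero (or unknown) total reads")
  track$values <- lapply(track$values, function(v) v * 1e6 / track$total_reads)
  track$normalized <- TRUE
  track
}

#' Write / read a signal track as bedGraph
#'
#' The text-standard coverage interchange format. Zero-valued bins are
#' omitted on write and restored as zeros on read; track provenance
#' (bin size, total reads, normalization flag, genome) is carried in
#' leading `#` comment lines so a round trip restores an equal track (values
#' to 6 significant digits). On read, intervals must be disjoint and aligned
#' to the bin grid; overlaps are an error.
#'
#' @param track a `signal_track`.
#' @param path output / input file path.
#' @param bin_size,genome,normalized,total_reads overrides used when reading
#'   a file without dsbscape header comments (e.g. hand-written bedGraph).
#' @return `write_bedgraph`: the path, invisibly. `read_bedgraph`: a
#'   `signal_track`.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "signal_track"))
  meta <- c(
    sprintf("# dsbscape bedGraph bin_size=%d normalized=%d total_reads=%s",
            as.integer(track$bin_size), as.integer(track$normalized),
            ifelse(is.na(track$total_reads), "NA",
                   format(track$total_reads, scientific = FALSE))),
    sprintf("# genome %s", paste(sprintf("%s:%d", names(track$genome),
                                         as.integer(track$genome)),
                                 collapse = ",")),
    "track type=bedGraph name=dsbscape")
  body <- character(0)
  for (cn in names(track$values)) {
    v <- track$values[[cn]]
    nz <- which(v != 0)
    if (length(nz) > 0) {
      s0 <- (nz - 1) * track$bin_size
      e0 <- pmin(nz * track$bin_size, track$genome[cn])
      body <- c(body, sprintf("%s\t%d\t%d\t%s", cn, as.integer(s0),
                              as.integer(e0), formatC(v[nz], digits = 6,
                                                      format = "g")))
    }
  }
  writeLines(c(meta, body), path)
  invisible(path)
}

#' @rdname write_bedgraph
#' @export
read_bedgraph <- function(path, bin_size = NULL, genome = NULL,
                          normalized = NULL, total_reads = NULL) {
  lines <- readLines(path)
  hdr <- grep("^# dsbscape bedGraph", lines, value = TRUE)
  if (length(hdr) == 1) {
    get_num <- function(key) {
      m <- regmatches(hdr, regexec(paste0(key, "=([0-9NA.]+)"), hdr))[[1]][2]
      if (identical(m, "NA")) NA_real_ else as.numeric(m)
    }
    if (is.null(bin_size)) bin_size <- get_num("bin_size")
    if (is.null(normalized)) normalized <- get_num("normalized") == 1
    if (is.null(total_reads)) total_reads <- get_num("total_reads")
    gline <- grep("^# genome ", lines, value = TRUE)
    if (is.null(genome) && length(gline) == 1) {
      parts <- strsplit(sub("^# genome ", "", gline), ",")[[1]]
      kv <- strsplit(parts, ":")
      genome <- genome_spec(setNames(as.numeric(vapply(kv, `[`, "", 2)),
                                     vapply(kv, `[`, "", 1)))
    }
  }
  if (is.null(bin_size) || is.null(genome))
    stop("bin_size and genome must be given for a bedGraph without ",
         "dsbscape header comments")
  if (is.null(normalized)) normalized <- FALSE
  if (is.null(total_reads)) total_reads <- NA_real_

  gr <- rtracklayer::import(path, format = "bedGraph")
  if (length(gr) > 1 &&
      any(IRanges::countOverlaps(gr, gr) > 1))
    stop("overlapping intervals in bedGraph")
  nbins <- ceiling(genome / bin_size)
  vals <- lapply(names(genome), function(cn) numeric(nbins[cn]))
  names(vals) <- names(genome)
  if (length(gr) > 0) {
    contig <- as.character(seqnames(gr))
    unknown <- setdiff(unique(contig), names(genome))
    if (length(unknown) > 0)
      stop("unknown contig(s) in bedGraph: ", paste(unknown, collapse = ", "))
    s0 <- start(gr) - 1
    e0 <- end(gr)
    if (any(s0 %% bin_size != 0) ||
        any(e0 %% bin_size != 0 & e0 != genome[contig]))
      stop("bedGraph intervals must align to the ", bin_size, " bp bin grid")
    for (k in seq_along(gr)) {
      i1 <- s0[k] %/% bin_size + 1
      i2 <- (e0[k] - 1) %/% bin_size + 1
      vals[[contig[k]]][i1:i2] <- S4Vectors::mcols(gr)$score[k]
    }
  }
  signal_track(vals, bin_size = bin_size, genome = genome,
               normalized = normalized, total_reads = total_reads)
}

#' Write reads or a site catalog as BED6
#'
#' Reads are written 0-based half-open with name, score 0 and strand; site
#' catalogs as 1 bp features whose interval start is the cut position, name =
#' site id, score = cleavage score. `read_sites_bed` restores a catalog
#' (cleavage score from the score column; transcription score from a
#' `# transcription` comment line written by `write_sites_bed`).
#'
#' @param reads,sites `GRanges`.
#' @param path file path.
#' @param genome a [genome_spec()] (required to read sites).
#' @return the path (writers, invisibly) or a `GRanges` (reader).
#' @export
write_reads_bed <- function(reads, path) {
  df <- data.frame(as.character(seqnames(reads)), start(reads) - 1,
                   end(reads),
                   if (is.null(names(reads)))
                     sprintf("read_%07d", seq_along(reads)) else names(reads),
                   0L, as.character(strand(reads)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname write_reads_bed
#' @export
write_sites_bed <- function(sites, path) {
  hdr <- sprintf("# transcription %s",
                 paste(formatC(mcols(sites)$transcription_score, digits = 8,
                               format = "g"), collapse = ","))
  df <- data.frame(as.character(seqnames(sites)), start(sites) - 1,
                   start(sites), mcols(sites)$site_id,
                   formatC(mcols(sites)$cleavage_score, digits = 8,
                           format = "g"),
                   ".")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname write_reads_bed
#' @export
read_sites_bed <- function(path, genome) {
  genome <- genome_spec(genome)
  lines <- readLines(path)
  trl <- grep("^# transcription ", lines, value = TRUE)
  tab <- read.table(text = lines[!grepl("^#", lines)], sep = "\t",
                    col.names = c("contig", "start0", "end0", "name",
                                  "score", "strand"))
  gr <- GRanges(tab$contig, IRanges(start = tab$start0 + 1, width = 1),
                seqinfo = as_seqinfo(genome))
  mcols(gr)$site_id <- tab$name
  mcols(gr)$cleavage_score <- as.numeric(tab$score)
  if (length(trl) == 1)
    mcols(gr)$transcription_score <-
      as.numeric(strsplit(sub("^# transcription ", "", trl), ",")[[1]])
  gr
}

#' Write reads as a minimal mapped single-end SAM file
#'
#' Emits \@HD/\@SQ headers from the read seqlengths, a \@CO comment recording
#' any simulation seed, and one mapped record per read (flag 0/16 by strand,
#' MAPQ 60, full-match CIGAR, no sequence). Readable back with
#' [read_reads()].
#'
#' @param reads `GRanges` of reads with seqlengths.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_reads_sam <- function(reads, path) {
  genome <- genome_of(reads)
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(genome), as.integer(genome)))
  seed <- metadata(reads)$seed
  if (!is.null(seed)) hdr <- c(hdr, sprintf("@CO\tdsbscape seed=%d", seed))
  qn <- if (is.null(names(reads))) sprintf("read_%07d", seq_along(reads))
        else names(reads)
  rec <- sprintf("%s\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t*\t*",
                 qn, ifelse(as.character(strand(reads)) == "-", 16L, 0L),
                 as.character(seqnames(reads)), start(reads),
                 GenomicRanges::width(reads))
  writeLines(c(hdr, rec), path)
  invisible(path)
}
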