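#' @import GenomicRanges
#' @import IRanges
#' @importFrom S4Vectors queryHits subjectHits mcols mcols<- DataFrame Rle runValue runLength
#' @importFrom GenomeInfoDb seqlengths seqlengths<- seqlevels seqlevels<- seqnames keepSeqlevels seqinfo Seqinfo
#' @importFrom stats ppois dpois rpois rnorm rlnorm runif setNames
#' @importFrom utils read.table write.table
NULL

# All genomic intervals are held as GRanges. The package-wide convention is
# BED: 0-based half-open on disk, converted to the 1-based closed convention
# of IRanges at the reader boundary and back at the writer boundary.

# Strand-aware fragment extension with silent clipping at chromosome
# edges (the out-of-bound intermediate is intended and immediately trimmed).
.extend_trim <- function(gr, width, fix = "start") {
  suppressWarnings(trim(resize(gr, width, fix = fix)))
}

#' Read a UCSC chrom.sizes genome file
#'
#' Two tab-separated columns: chromosome name and length in bp.
#'
#' @param path Path to a `chrom\tlength` TSV.
#' @return Named integer vector of chromosome lengths.
#' @export
read_genome <- function(path) {
  tab <- read.table(path, sep = "\t", header = FALSE,
                    col.names = c("chrom", "length"),
                    colClasses = c("character", "integer"))
  if (any(tab$length <= 0)) stop("genome file '", path, "': non-positive chromosome length")
  setNames(tab$length, tab$chrom)
}

#' Write a genome map as a chrom.sizes file
#'
#' @param genome Named integer vector of chromosome lengths.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  write.table(data.frame(names(genome),
                         format(as.integer(genome), scientific = FALSE,
                                trim = TRUE)),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read intervals from a BED file
#'
#' Parses BED3/BED6 (0-based, half-open) into a sorted `GRanges`. Track and
#' browser lines and comments are skipped. When a genome map is supplied the
#' chromosomes are validated against it and intervals extending past a
#' chromosome end are clipped (with a message, not an error).
#'
#' @param path Path to a BED file.
#' @param genome Optional named integer vector of chromosome lengths.
#' @return A `GRanges`, sorted by (chrom, start, end), with `name` and
#'   `score` metadata columns when present in the file.
#' @export
read_bed <- function(path, genome = NULL) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    gr <- GRanges()
    if (!is.null(genome)) seqlengths(gr) <- genome
    return(gr)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop("BED parse error at line ", lineno[which(nf < 3L)[1]],
         ": fewer than 3 tab-separated fields")
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end   <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end) | start != floor(start) | end != floor(end))
  if (length(bad)) {
    stop("BED parse error at line ", lineno[bad[1]], ": non-integer coordinate")
  }
  bad <- which(start < 0 | end <= start)
  if (length(bad)) {
    stop("BED parse error at line ", lineno[bad[1]],
         ": requires 0 <= start < end, got [", start[bad[1]], ", ", end[bad[1]], ")")
  }
  nm <- ifelse(nf >= 4L, vapply(fields, function(f) if (length(f) >= 4) f[[4]] else ".", ""), ".")
  sc <- suppressWarnings(as.numeric(
    ifelse(nf >= 5L, vapply(fields, function(f) if (length(f) >= 5) f[[5]] else "0", ""), "0")))
  sc[is.na(sc)] <- 0
  strand <- ifelse(nf >= 6L, vapply(fields, function(f) if (length(f) >= 6) f[[6]] else "*", ""), "*")
  strand[!strand %in% c("+", "-")] <- "*"
  gr <- GRanges(chrom, IRanges(start + 1L, end), strand = strand,
                name = nm, score = sc)
  if (!is.null(genome)) {
    unknown <- setdiff(unique(chrom), names(genome))
    if (length(unknown)) {
      stop("BED validation error: chromosome(s) not in genome map: ",
           paste(unknown, collapse = ", "))
    }
    over <- end(gr) > genome[as.character(seqnames(gr))]
    if (any(over)) {
      message(sum(over), " interval(s) clipped to chromosome bounds")
      end(gr)[over] <- genome[as.character(seqnames(gr))][over]
    }
    seqlevels(gr) <- names(genome)
    seqlengths(gr) <- genome
  }
  sort_intervals(gr)
}

#' Write a GRanges as BED6
#'
#' Coordinates are emitted 0-based half-open. Missing `name`/`score`
#' metadata columns default to `.` and `0`.
#'
#' @param gr A `GRanges`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path) {
  nm <- if (!is.null(mcols(gr)$name)) as.character(mcols(gr)$name) else rep(".", length(gr))
  sc <- if (!is.null(mcols(gr)$score)) mcols(gr)$score else rep(0, length(gr))
  st <- as.character(strand(gr))
  st[st == "*"] <- "."
  df <- data.frame(as.character(seqnames(gr)), start(gr) - 1L, end(gr), nm, sc, st)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Sort intervals by (chrom, start, end)
#'
#' Chromosomes are ordered lexicographically; this is the package's single
#' canonical ordering so downstream indices are stable.
#'
#' @param gr A `GRanges`.
#' @return The sorted `GRanges`.
#' @export
sort_intervals <- function(gr) {
  if (length(gr) == 0L) return(gr)
  ord <- order(as.character(seqnames(gr)), start(gr), end(gr))
  gr[ord]
}

#' Drop intervals on given chromosomes
#'
#' Used to remove peaks on unassembled scaffolds (e.g. chrU / chrUextra in
#' the fly genome) before any downstream counting. Dropping a chromosome
#' absent from the set is a no-op.
#'
#' @param gr A `GRanges`.
#' @param drop Character vector of chromosome names to remove.
#' @return `GRanges` without intervals on `drop` chromosomes; order kept.
#' @export
filter_chromosomes <- function(gr, drop) {
  if (length(drop) == 0L || length(gr) == 0L) return(gr)
  out <- gr[!(as.character(seqnames(gr)) %in% drop)]
  GenomeInfoDb::seqlevels(out) <- setdiff(seqlevels(out), drop)
  out
}

#' Overlapping pairs between two interval sets
#'
#' Reports every pair of intervals (one from each set) whose intersection is
#' at least `min_bp`, plus the number of query intervals with at least one
#' partner. Indices refer to the order of the input sets.
#'
#' @param a,b `GRanges` (query and subject).
#' @param min_bp Minimum intersection length in bp (default 1, i.e. any
#'   shared base).
#' @return A list with `pairs` (two-column integer matrix `a_idx`, `b_idx`)
#'   and `n_a_overlapping`.
#' @export
overlap_pairs <- function(a, b, min_bp = 1L) {
  if (min_bp < 1) stop("min_bp must be >= 1")
  hits <- findOverlaps(a, b, minoverlap = min_bp, ignore.strand = TRUE)
  pairs <- cbind(a_idx = queryHits(hits), b_idx = subjectHits(hits))
  list(pairs = pairs, n_a_overlapping = length(unique(queryHits(hits))))
}

#' Read a bedGraph coverage track
#'
#' @param path Path to a bedGraph file (0-based half-open spans, value).
#' @param genome Named integer vector of chromosome lengths; coverage is
#'   materialised per chromosome over its full length.
#' @return An `RleList` of per-bp values, one element per chromosome.
#' @export
read_bedgraph <- function(path, genome) {
  tab <- read.table(path, sep = "\t", header = FALSE,
                    col.names = c("chrom", "start", "end", "value"))
  covs <- lapply(names(genome), function(chr) {
    v <- numeric(genome[[chr]])
    sub <- tab[tab$chrom == chr, , drop = FALSE]
    if (nrow(sub)) {
      for (i in seq_len(nrow(sub))) {
        v[(sub$start[i] + 1):sub$end[i]] <- sub$value[i]
      }
    }
    Rle(v)
  })
  names(covs) <- names(genome)
  methods::as(covs, "SimpleRleList")
}

#' Write an RleList coverage track as bedGraph
#'
#' Zero-valued runs are omitted, per bedGraph convention.
#'
#' @param cov `RleList` of per-bp values named by chromosome.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(cov, path) {
  rows <- lapply(names(cov), function(chr) {
    r <- cov[[chr]]
    ends <- cumsum(runLength(r))
    starts <- ends - runLength(r)  # 0-based
    vals <- runValue(r)
    keep <- vals != 0
    if (!any(keep)) return(NULL)
    data.frame(chrom = chr, start = starts[keep], end = ends[keep],
               value = vals[keep])
  })
  df <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(df)) df <- data.frame(chrom = character(), start = integer(),
                                    end = integer(), value = numeric())
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
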