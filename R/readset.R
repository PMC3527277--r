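# ReadSet: single-end sequencing reads reduced to their 5' positions.
# The stored total_mapped may exceed the number of stored reads (e.g. after
# restricting to regions) and is the RPM denominator throughout.

#' Construct a ReadSet
#'
#' A ReadSet holds single-end read 5' positions as width-1 `GRanges` with
#' strand, plus the total mapped-read count used as the denominator for
#' reads-per-million (RPM) normalisation. `total_mapped` can exceed the
#' number of stored reads, which is what keeps a subsampled read set on its
#' parent's RPM scale.
#'
#' @param reads Width-1 `GRanges` with strand `+` or `-` (5' positions).
#' @param total_mapped Total mapped reads for RPM normalisation; defaults to
#'   `length(reads)`.
#' @return An object of class `ReadSet`.
#' @export
read_set <- function(reads, total_mapped = length(reads)) {
  stopifnot(methods::is(reads, "GRanges"))
  if (length(reads) && any(width(reads) != 1L)) {
    stop("ReadSet positions must be width-1 (5' positions)")
  }
  if (total_mapped < length(reads)) {
    stop("total_mapped (", total_mapped, ") < number of stored reads (",
         length(reads), ")")
  }
  structure(list(reads = reads, total_mapped = as.numeric(total_mapped)),
            class = "ReadSet")
}

#' @export
print.ReadSet <- function(x, ...) {
  cat("ReadSet:", length(x$reads), "stored reads,",
      format(x$total_mapped, big.mark = ","), "total mapped\n")
  invisible(x)
}

#' @export
length.ReadSet <- function(x) length(x$reads)

#' Write a ReadSet as BED6
#'
#' One line per read: a 1-bp interval at the 5' position, with strand. The
#' total mapped count is recorded on a leading `track` line so the file
#' round-trips.
#'
#' @param rs A `ReadSet`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reads <- function(rs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("track type=reads total_mapped=%d", as.integer(rs$total_mapped)), con)
  gr <- rs$reads
  if (length(gr)) {
    df <- data.frame(as.character(seqnames(gr)), start(gr) - 1L, end(gr),
                     ".", 0L, as.character(strand(gr)))
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  invisible(path)
}

#' Read a ReadSet from BED6
#'
#' @param path Path written by [write_reads()] (or any BED6 of 1-bp reads).
#' @param genome Optional named integer vector of chromosome lengths.
#' @param total_mapped Override for the total mapped count; by default taken
#'   from the `track` line, else the number of reads.
#' @return A `ReadSet`.
#' @export
read_reads <- function(path, genome = NULL, total_mapped = NULL) {
  if (is.null(total_mapped)) {
    first <- readLines(path, n = 1L)
    m <- regmatches(first, regexec("total_mapped=([0-9]+)", first))[[1]]
    if (length(m) == 2L) total_mapped <- as.numeric(m[2])
  }
  gr <- read_bed(path, genome = genome)
  mcols(gr) <- NULL
  if (is.null(total_mapped)) total_mapped <- length(gr)
  read_set(gr, total_mapped)
}
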