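#' Read a FASTA assembly
#'
#' Reads a (possibly gzip-compressed) FASTA file into a named character
#' vector of sequences.  Case is preserved verbatim (soft-masked lowercase
#' runs survive a round-trip through [write_fasta()]); all downstream
#' comparisons are case-insensitive.
#'
#' @param path path to a FASTA file, plain or `.gz`.
#' @param alphabet `"dna"` (default) validates sequence lines against the
#'   IUPAC DNA codes; `"aa"` accepts amino-acid FASTA (no validation).
#' @return named character vector, one element per record, in file order.
#' @details Record IDs are the header tokens up to the first whitespace and
#'   must be unique.  Sequence lines may contain only IUPAC DNA codes
#'   (case-insensitive); a violation is reported with its line number.
#' @export
read_fasta <- function(path, alphabet = c("dna", "aa")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty) == 0L) stop("no records in FASTA file: ", path)
  if (!startsWith(lines[nonempty[1]], ">"))
    stop("malformed FASTA: line ", nonempty[1],
         " does not start a record (expected '>'): ", lines[nonempty[1]])
  hdr <- which(startsWith(lines, ">"))
  ids <- sub("\\s.*$", "", sub("^>", "", lines[hdr]))
  if (any(!nzchar(ids))) {
    bad <- hdr[!nzchar(ids)][1]
    stop("malformed FASTA: empty record ID at line ", bad)
  }
  if (anyDuplicated(ids))
    stop("duplicate sequence ID in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (alphabet == "dna") {
    bad_seq <- setdiff(nonempty, hdr)
    bad_seq <- bad_seq[grepl("[^ACGTRYSWKMBDHVNacgtryswkmbdhvn]",
                             lines[bad_seq])]
    if (length(bad_seq))
      stop("malformed FASTA: non-IUPAC character at line ", bad_seq[1],
           ": ", lines[bad_seq[1]])
  }
  bounds <- c(hdr, length(lines) + 1L)
  seqs <- vapply(seq_along(hdr), function(i) {
    block <- lines[seq(bounds[i] + 1L, bounds[i + 1L] - 1L)]
    paste(block[nzchar(block)], collapse = "")
  }, character(1))
  if (length(seqs) == 0L) stop("no records in FASTA file: ", path)
  setNames(seqs, ids)
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @param width sequence line wrap width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    n <- nchar(s)
    if (n == 0L) next
    starts <- seq(1L, n, by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, n)), con)
  }
  invisible(path)
}

#' Plan search batches for an assembly
#'
#' Assemblies over `split_threshold` total size are split for search speed:
#' each record below `split_threshold` becomes its own intact batch, and each
#' record at or above it is cut into the minimum number of pieces that are
#' each strictly below `batch_ceiling` (equal-sized cuts; the last piece
#' absorbs the remainder), i.e. `N = floor(L / batch_ceiling) + 1` pieces and
#' `N - 1` breakpoints for a record of length `L`.  Assemblies at or below
#' `split_threshold` are kept whole as a single batch.
#'
#' @param assembly named character vector of sequences, or a named numeric
#'   vector of sequence lengths (so plans for multi-Gbp assemblies can be
#'   made without materialising sequence).
#' @param split_threshold total assembly size above which splitting is
#'   triggered (default 1 Gbp).
#' @param batch_ceiling strict upper bound on the size of a piece cut from an
#'   oversized record (default 100 Mbp).
#' @return a batch plan: data frame with columns `batch_index`, `source_id`,
#'   `start`, `end` (0-based half-open original coordinates), one row per
#'   segment.  Empty assembly gives a zero-row plan.
#' @export
plan_batches <- function(assembly, split_threshold = 1e9, batch_ceiling = 1e8) {
  stopifnot(split_threshold > 0, batch_ceiling > 0,
            batch_ceiling < split_threshold)
  lens <- if (is.character(assembly)) nchar(assembly) else as.numeric(assembly)
  ids <- names(assembly)
  if (length(lens) == 0L)
    return(data.frame(batch_index = integer(), source_id = character(),
                      start = numeric(), end = numeric(),
                      stringsAsFactors = FALSE))
  stopifnot(!is.null(ids), !anyDuplicated(ids))
  total <- sum(lens)
  if (total <= split_threshold) {
    return(data.frame(batch_index = 1L, source_id = ids,
                      start = 0, end = lens, stringsAsFactors = FALSE))
  }
  out <- vector("list", length(lens))
  bi <- 0L
  for (i in seq_along(lens)) {
    L <- lens[i]
    if (L < split_threshold) {
      bi <- bi + 1L
      out[[i]] <- data.frame(batch_index = bi, source_id = ids[i],
                             start = 0, end = L, stringsAsFactors = FALSE)
    } else {
      n_pieces <- floor(L / batch_ceiling) + 1
      size <- floor(L / n_pieces)
      starts <- size * (seq_len(n_pieces) - 1)
      ends <- c(starts[-1], L)
      out[[i]] <- data.frame(batch_index = bi + seq_len(n_pieces),
                             source_id = ids[i], start = starts, end = ends,
                             stringsAsFactors = FALSE)
      bi <- bi + as.integer(n_pieces)
    }
  }
  do.call(rbind, out)
}

#' Write a batch plan manifest as TSV
#' @param plan batch plan from [plan_batches()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_batch_manifest <- function(plan, path) {
  write.table(plan, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Reverse complement preserving case (IUPAC-aware)
#' @param x character vector of DNA sequences.
#' @return reverse-complemented sequences.
#' @export
revcomp <- function(x) {
  chartr("ACGTRYSWKMBDHVNacgtryswkmbdhvn",
         "TGCAYRSWMKVHDBNtgcayrswmkvhdbn",
         vapply(x, function(s) paste(rev(strsplit(s, "")[[1]]), collapse = ""),
                character(1), USE.NAMES = FALSE))
}
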