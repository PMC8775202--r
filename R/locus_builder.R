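# Locus construction: expand round-1 core hits by flanks, merge overlaps,
# extract sequence for round-2 annotation.

#' Expand core-domain hits into merged loci
#'
#' Each hit interval is expanded by `flank` bases on both sides (clipped at
#' the sequence bounds); overlapping or touching expanded intervals on the
#' same sequence are merged into a single locus.  Merging has set semantics:
#' the result is independent of hit order.
#'
#' @param hits pre-filtered DomainHit data frame.
#' @param sequence_lengths named numeric vector of source sequence lengths.
#' @param flank flank length in bases (default 7500).
#' @return data frame with columns `locus_id`, `sequence_id`, `start`, `end`
#'   (0-based half-open), `n_seeds`, and a list-column `seed_hits` holding
#'   the contributing hits; sorted by (sequence_id, start).
#' @export
expand_and_merge <- function(hits, sequence_lengths, flank = 7500) {
  stopifnot(flank >= 0)
  if (nrow(hits) == 0L)
    return(data.frame(locus_id = character(), sequence_id = character(),
                      start = numeric(), end = numeric(), n_seeds = integer(),
                      stringsAsFactors = FALSE))
  unknown <- setdiff(unique(hits$sequence_id), names(sequence_lengths))
  if (length(unknown))
    stop("hit references unknown sequence_id: ",
         paste(unknown, collapse = ", "))
  out <- list()
  for (sid in sort(unique(hits$sequence_id))) {
    h <- hits[hits$sequence_id == sid, , drop = FALSE]
    L <- sequence_lengths[[sid]]
    exp_start <- pmax(0, h$genomic_start - flank)
    exp_end <- pmin(L, h$genomic_end + flank)
    ir <- IRanges::IRanges(start = exp_start + 1, end = exp_end)
    red <- IRanges::reduce(ir)          # merges overlapping and adjacent
    ov <- IRanges::findOverlaps(ir, red)
    seeds <- split(seq_len(nrow(h)), S4Vectors::subjectHits(ov))
    out[[sid]] <- data.frame(
      locus_id = sprintf("%s:%d-%d", sid, IRanges::start(red) - 1,
                         IRanges::end(red)),
      sequence_id = sid, start = IRanges::start(red) - 1,
      end = as.numeric(IRanges::end(red)),
      n_seeds = as.integer(lengths(seeds)), stringsAsFactors = FALSE)
    out[[sid]]$seed_hits <- lapply(seeds, function(i) {
      s <- h[i, , drop = FALSE]; rownames(s) <- NULL; s
    })
  }
  loci <- do.call(rbind, out)
  loci <- loci[order(loci$sequence_id, loci$start), ]
  rownames(loci) <- NULL
  loci
}

#' Extract locus sequences from the assembly
#'
#' Fills a `sequence` column with the forward-strand substring of each locus
#' (case preserved).
#'
#' @param loci locus table from [expand_and_merge()].
#' @param assembly named character vector of sequences.
#' @return `loci` with a `sequence` character column added.
#' @export
extract_sequences <- function(loci, assembly) {
  if (nrow(loci) == 0L) { loci$sequence <- character(0); return(loci) }
  missing <- setdiff(unique(loci$sequence_id), names(assembly))
  if (length(missing))
    stop("locus references unknown sequence_id: ",
         paste(missing, collapse = ", "))
  lens <- nchar(assembly)[loci$sequence_id]
  if (any(loci$start < 0 | loci$end > lens | loci$start >= loci$end))
    stop("locus coordinates out of range for assembly")
  loci$sequence <- substring(assembly[loci$sequence_id], loci$start + 1,
                             loci$end)
  loci
}

#' Write loci as BED (0-based half-open)
#' @param loci locus table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_loci_bed <- function(loci, path) {
  bed <- data.frame(loci$sequence_id, format(loci$start, scientific = FALSE,
                                             trim = TRUE),
                    format(loci$end, scientific = FALSE, trim = TRUE),
                    loci$locus_id)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
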