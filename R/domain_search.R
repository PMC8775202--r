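# Round-1/round-2 profile search: six-frame translation + ungapped PSSM
# segment scan, Karlin-Altschul statistics, e-value/length pre-filter, and a
# parser for external RPS-BLAST tabular output.

# Karlin-Altschul lambda for a PSSM under a uniform residue background.
# Solves mean over positions/residues of exp(lambda * s) = 1 for lambda > 0.
ka_lambda <- function(matrix) {
  f <- function(l) mean(exp(l * matrix)) - 1
  hi <- 0.5
  while (f(hi) < 0 && hi < 64) hi <- hi * 2
  if (f(hi) < 0) stop("PSSM has non-negative expected score; lambda undefined")
  uniroot(f, c(1e-6, hi), tol = 1e-9)$root
}

# six-frame translation of one sequence via a genetic-code lookup; returns a
# list of frames, each with strand, frame (0..2 within strand), the peptide
# string and its residue indices in PSSM column order (-1 for stop/ambiguous)
translate_frames <- function(seq) {
  code <- Biostrings::GENETIC_CODE
  aa_idx <- setNames(seq_along(AA_ORDER) - 1L, AA_ORDER)
  fwd <- toupper(seq)
  rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(fwd)))
  out <- list()
  for (strand in c("+", "-")) {
    src <- if (strand == "+") fwd else rc
    L <- nchar(src)
    for (f in 0:2) {
      n_codon <- (L - f) %/% 3
      if (n_codon < 1) next
      starts <- f + 3 * (seq_len(n_codon) - 1) + 1
      aa <- code[substring(src, starts, starts + 2)]
      aa[is.na(aa)] <- "X"          # ambiguous codon
      idx <- aa_idx[aa]
      idx[is.na(idx)] <- -1L        # stop or X: scores the matrix minimum
      out[[length(out) + 1L]] <- list(strand = strand, frame = f,
                                      pep = paste(aa, collapse = ""),
                                      idx = unname(idx))
    }
  }
  out
}

#' Scan sequences with protein-domain profiles
#'
#' Translates every sequence in all six reading frames and scores each frame
#' against each position-specific scoring matrix, reporting maximal-scoring
#' ungapped segments.  Raw segment scores are converted to bit scores and
#' e-values with Karlin-Altschul statistics (per-profile lambda solved from
#' the PSSM under a uniform residue background, K fixed at 0.1, database
#' size = total residues scanned in the call).  Stop codons score the matrix
#' minimum, so segments break at stops.  Coordinates are reported on the
#' forward strand of the original sequence, 0-based half-open.
#'
#' @param seqs named character vector of DNA sequences (an assembly or a set
#'   of extracted loci).
#' @param profiles list of [domain_profile()] objects.
#' @param min_evalue report only hits with e-value at or below this (default
#'   `1e-3`, matching the pipeline pre-filter).
#' @param K Karlin-Altschul K parameter.
#' @return a DomainHit data frame: `sequence_id`, `genomic_start`,
#'   `genomic_end`, `strand`, `frame`, `profile_id`, `profile_start`,
#'   `profile_end`, `bit_score`, `e_value`, `aligned_aa`; sorted by
#'   sequence, position.
#' @export
scan_profiles <- function(seqs, profiles, min_evalue = 1e-3, K = 0.1) {
  validate_profile_set(profiles)
  if (length(seqs) == 0L) return(empty_hits())
  stopifnot(!is.null(names(seqs)))
  frames <- lapply(seqs, translate_frames)
  n_total <- sum(vapply(frames, function(fr)
    sum(vapply(fr, function(x) nchar(x$pep), numeric(1))), numeric(1)))
  if (n_total == 0) return(empty_hits())
  res <- list()
  for (p in profiles) {
    lambda <- ka_lambda(p$matrix)
    m <- p$length
    # minimal raw score whose e-value could pass the cutoff
    min_raw <- (log(K * m * n_total) - log(min_evalue)) / lambda
    for (si in seq_along(seqs)) {
      L_nt <- nchar(seqs[[si]])
      for (fr in frames[[si]]) {
        segs <- scan_pssm_cpp(fr$idx, p$matrix, min_raw)
        if (nrow(segs) == 0L) next
        bits <- (lambda * segs$score - log(K)) / log(2)
        ev <- m * n_total * 2^(-bits)
        keep <- ev <= min_evalue
        if (!any(keep)) next
        segs <- segs[keep, , drop = FALSE]
        bits <- bits[keep]; ev <- ev[keep]
        aa_end <- segs$seq_start + segs$len
        if (fr$strand == "+") {
          gs <- fr$frame + 3 * segs$seq_start
          ge <- fr$frame + 3 * aa_end
        } else {
          gs <- L_nt - (fr$frame + 3 * aa_end)
          ge <- L_nt - (fr$frame + 3 * segs$seq_start)
        }
        res[[length(res) + 1L]] <- data.frame(
          sequence_id = names(seqs)[si], genomic_start = gs, genomic_end = ge,
          strand = fr$strand, frame = fr$frame, profile_id = p$profile_id,
          profile_start = segs$prof_start,
          profile_end = segs$prof_start + segs$len,
          bit_score = round(bits, 2), e_value = ev,
          aligned_aa = substring(fr$pep, segs$seq_start + 1L, aa_end),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(res) == 0L) return(empty_hits())
  hits <- do.call(rbind, res)
  hits <- hits[order(hits$sequence_id, hits$genomic_start, hits$genomic_end), ]
  rownames(hits) <- NULL
  hits
}

#' Pre-filter domain hits by e-value and match length
#'
#' Keeps hits with `e_value <= max_evalue` (inclusive, by convention) whose
#' aligned profile span covers at least `min_match_fraction` of the profile.
#' Input order is preserved; the operation is idempotent.
#'
#' @param hits DomainHit data frame from [scan_profiles()].
#' @param profiles profile set (for profile lengths).
#' @param max_evalue e-value cutoff (default `1e-3`).
#' @param min_match_fraction minimum matched fraction of the profile length
#'   (default 0.3 -- permissive, so frameshift fragments survive for
#'   chaining).
#' @return filtered DomainHit data frame.
#' @export
prefilter_hits <- function(hits, profiles, max_evalue = 1e-3,
                           min_match_fraction = 0.3) {
  stopifnot(max_evalue > 0, min_match_fraction >= 0, min_match_fraction <= 1)
  if (nrow(hits) == 0L) return(hits)
  plen <- setNames(vapply(profiles, `[[`, numeric(1), "length"),
                   vapply(profiles, `[[`, character(1), "profile_id"))
  frac <- (hits$profile_end - hits$profile_start) / plen[hits$profile_id]
  out <- hits[hits$e_value <= max_evalue & frac >= min_match_fraction, ,
              drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Parse RPS-BLAST tabular output into DomainHit records
#'
#' Adapter for an external search run as
#' `rpstblastn -outfmt "6 qseqid sseqid qstart qend sstart send evalue
#' bitscore qframe qseq"`.  External 1-based inclusive coordinates are
#' converted to the package's 0-based half-open convention; a negative query
#' frame denotes the minus strand.
#'
#' @param path tabular output file.
#' @return DomainHit data frame (aligned_aa has alignment gaps removed).
#' @export
parse_rpsblast_hits <- function(path) {
  cols <- c("qseqid", "sseqid", "qstart", "qend", "sstart", "send",
            "evalue", "bitscore", "qframe", "qseq")
  tb <- tryCatch(
    read.table(path, sep = "\t", col.names = cols, stringsAsFactors = FALSE),
    error = function(e) stop("cannot parse RPS-BLAST tabular output ", path,
                             ": ", conditionMessage(e)))
  if (nrow(tb) == 0L) return(empty_hits())
  minus <- tb$qframe < 0
  gs <- pmin(tb$qstart, tb$qend) - 1
  ge <- pmax(tb$qstart, tb$qend)
  data.frame(
    sequence_id = tb$qseqid, genomic_start = gs, genomic_end = ge,
    strand = ifelse(minus, "-", "+"), frame = abs(tb$qframe) - 1L,
    profile_id = tb$sseqid, profile_start = tb$sstart - 1L,
    profile_end = tb$send, bit_score = tb$bitscore, e_value = tb$evalue,
    aligned_aa = gsub("-", "", tb$qseq, fixed = TRUE),
    stringsAsFactors = FALSE)
}
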