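# LTR pair detection: k-mer-seeded local alignment of the windows flanking
# an element's domain block.  LTRs are direct repeats, so the two windows
# are compared in the same orientation regardless of element strand.

#' Do identity/length values qualify as an LTR pair?
#'
#' Thresholds are strict inequalities: identity must exceed `min_identity`
#' and the alignment length must lie strictly between `min_length` and
#' `max_length` (identity exactly 80 or length exactly 100/3000 is
#' rejected).
#'
#' @param identity percent identity of the aligned repeat (0-100).
#' @param length alignment length in columns.
#' @param min_identity,min_length,max_length thresholds (defaults 80, 100,
#'   3000).
#' @return logical.
#' @export
ltr_qualifies <- function(identity, length, min_identity = 80,
                          min_length = 100, max_length = 3000) {
  identity > min_identity & length > min_length & length < max_length
}

# k-mer seed pairs between two sequences; returns data.frame(pos_a, pos_b)
# (0-based), occurrences per k-mer capped to keep low-complexity runs tame
kmer_seeds <- function(a, b, k = 8L, max_occ = 10L) {
  na <- nchar(a); nb <- nchar(b)
  if (na < k || nb < k) return(data.frame(pos_a = integer(), pos_b = integer()))
  ka <- substring(a, 1:(na - k + 1), k:na)
  kb <- substring(b, 1:(nb - k + 1), k:nb)
  common <- intersect(unique(ka), unique(kb))
  if (length(common) == 0L)
    return(data.frame(pos_a = integer(), pos_b = integer()))
  pa <- split(seq_along(ka) - 1L, ka)[common]
  pb <- split(seq_along(kb) - 1L, kb)[common]
  out <- mapply(function(x, y) {
    x <- head(x, max_occ); y <- head(y, max_occ)
    list(pos_a = rep(x, each = length(y)), pos_b = rep(y, length(x)))
  }, pa, pb, SIMPLIFY = FALSE)
  data.frame(pos_a = unlist(lapply(out, `[[`, "pos_a"), use.names = FALSE),
             pos_b = unlist(lapply(out, `[[`, "pos_b"), use.names = FALSE))
}

# Trim chance end-extensions from a local alignment: keep the
# maximal-scoring run of alignment columns under +1 per match, -2 per
# mismatch or gap column (cuts terminal stretches below 60 percent
# identity, i.e. random flank dragged in by the aligner, while leaving
# mismatch clusters inside a real repeat alone).
# Returns column count, match count and how many pattern/subject residues
# were trimmed from each end (NULL when nothing scores positive).
trim_alignment <- function(pat, sub) {
  p <- strsplit(pat, "")[[1]]
  s <- strsplit(sub, "")[[1]]
  is_match <- p == s & p != "-"
  sc <- ifelse(is_match, 1, -1.5)
  best <- 0; run <- 0; run_start <- 1L; b1 <- 0L; b2 <- -1L
  for (i in seq_along(sc)) {
    if (run <= 0) { run <- 0; run_start <- i }
    run <- run + sc[i]
    if (run > best) { best <- run; b1 <- run_start; b2 <- i }
  }
  if (b2 < b1) return(NULL)
  lead <- seq_len(b1 - 1L)
  trail <- if (b2 < length(p)) seq(b2 + 1L, length(p)) else integer(0)
  list(length = b2 - b1 + 1L, matches = sum(is_match[b1:b2]),
       pat_off = sum(p[lead] != "-"), pat_trim = sum(p[trail] != "-"),
       sub_off = sum(s[lead] != "-"), sub_trim = sum(s[trail] != "-"))
}

# total ungapped X-drop extension (matches +1, mismatches -2, drop 12)
# beyond both ends of an aligned pair, along its diagonal
diag_extension <- function(up, down, a, b) {
  u <- strsplit(up, "")[[1]]; d <- strsplit(down, "")[[1]]
  ext <- function(ia, ib, step) {
    run <- 0; best <- 0; n <- 0; total <- 0
    while (ia >= 1 && ia <= length(u) && ib >= 1 && ib <= length(d)) {
      run <- run + if (u[ia] == d[ib]) 1 else -2
      n <- n + 1
      if (run > best) { best <- run; total <- n }
      if (best - run > 12) break
      ia <- ia + step; ib <- ib + step
    }
    total
  }
  ext(a[1], b[1], -1L) + ext(a[2] + 1L, b[2] + 1L, 1L)
}

# group seed pairs into colinear chains: seeds join a chain when their
# diagonal drifts by at most max_drift and the positional gap is at most
# max_gap; returns up to max_chains chains with at least min_support seeds,
# strongest (then leftmost) first
chain_seeds <- function(seeds, max_drift = 50L, max_gap = 400L,
                        min_support = 3L, max_chains = 6L) {
  ord <- order(seeds$pos_a, seeds$pos_b)
  pa <- seeds$pos_a[ord]; pb <- seeds$pos_b[ord]
  diag <- pb - pa
  chains <- list()
  active <- integer(0)           # indices into chains still extendable
  for (i in seq_along(pa)) {
    active <- active[vapply(active, function(ci)
      pa[i] - chains[[ci]]$last_a <= max_gap, logical(1))]
    placed <- FALSE
    for (ci in active) {
      if (abs(diag[i] - chains[[ci]]$last_diag) <= max_drift) {
        ch <- chains[[ci]]
        ch$pos_a <- c(ch$pos_a, pa[i]); ch$pos_b <- c(ch$pos_b, pb[i])
        ch$last_a <- pa[i]; ch$last_diag <- diag[i]
        chains[[ci]] <- ch
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      chains[[length(chains) + 1L]] <- list(pos_a = pa[i], pos_b = pb[i],
                                            last_a = pa[i],
                                            last_diag = diag[i])
      active <- c(active, length(chains))
    }
  }
  support <- vapply(chains, function(ch) length(ch$pos_a), integer(1))
  keep <- which(support >= min_support)
  keep <- keep[order(-support[keep],
                     vapply(chains[keep], function(ch) min(ch$pos_a),
                            numeric(1)))]
  chains[head(keep, max_chains)]
}

#' Detect the LTR pair flanking an element's domain block
#'
#' The window upstream of the first domain and the window downstream of the
#' last domain (each `search_window` bases, clipped to the locus) are
#' compared by local alignment in the same orientation.  Shared 8-mers are
#' binned by alignment diagonal to locate candidate repeat regions; each
#' candidate subregion pair is aligned locally (match 2, mismatch -3, gap
#' open 12, gap extend 4) and the highest-scoring alignment that satisfies
#' the strict thresholds (identity > 80 percent, 100 < length < 3000, see
#' [ltr_qualifies()]) is returned; ties prefer the longer, then leftmost
#' alignment.  Identity is matches / alignment columns over the aligned
#' region; length is the alignment column count.
#'
#' @param element a `retro_element` (domains in locus coordinates).
#' @param locus_sequence the locus DNA string.
#' @param search_window flank window length (default 7500, the locus flank).
#' @param min_identity,min_length,max_length thresholds as in
#'   [ltr_qualifies()].
#' @return a list `(left_start, left_end, right_start, right_end, identity,
#'   length)` in 0-based half-open locus coordinates with identity reported
#'   to 3 decimals, or `NULL` when no qualifying repeat exists (a normal
#'   outcome).
#' @export
find_ltr_pair <- function(element, locus_sequence, search_window = 7500,
                          min_identity = 80, min_length = 100,
                          max_length = 3000) {
  dom <- element$domains
  stopifnot(nrow(dom) >= 1L)
  L <- nchar(locus_sequence)
  bs <- min(dom$genomic_start); be <- max(dom$genomic_end)
  up_off <- max(0, bs - search_window)
  down_off <- be
  up <- toupper(substring(locus_sequence, up_off + 1, bs))
  down <- toupper(substring(locus_sequence, down_off + 1,
                            min(L, be + search_window)))
  if (nchar(up) <= min_length || nchar(down) <= min_length) return(NULL)
  seeds <- kmer_seeds(up, down)
  if (nrow(seeds) == 0L) return(NULL)
  chains <- chain_seeds(seeds)
  if (length(chains) == 0L) return(NULL)
  margin <- 250L
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                 baseOnly = FALSE)
  best <- NULL
  for (ch in chains) {
    a_lo <- max(0L, min(ch$pos_a) - margin)
    a_hi <- min(nchar(up), max(ch$pos_a) + 8L + margin)
    b_lo <- max(0L, min(ch$pos_b) - margin)
    b_hi <- min(nchar(down), max(ch$pos_b) + 8L + margin)
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(substring(up, a_lo + 1, a_hi)),
      Biostrings::DNAString(substring(down, b_lo + 1, b_hi)),
      type = "local", substitutionMatrix = sm,
      gapOpening = 12, gapExtension = 4)
    tr <- trim_alignment(as.character(Biostrings::pattern(pa)),
                         as.character(Biostrings::subject(pa)))
    if (is.null(tr)) next
    len <- tr$length
    identity <- 100 * tr$matches / len
    if (!ltr_qualifies(identity, len, min_identity, min_length, max_length))
      next
    # a qualifying alignment may be a fragment of a longer repeat that was
    # itself rejected: extend ungapped along the diagonal in the full
    # windows and reject when the full repeat reaches max_length
    cand_a <- c(a_lo + IRanges::start(Biostrings::pattern(pa)) - 1 +
                  tr$pat_off,
                a_lo + IRanges::end(Biostrings::pattern(pa)) - tr$pat_trim)
    cand_b <- c(b_lo + IRanges::start(Biostrings::subject(pa)) - 1 +
                  tr$sub_off,
                b_lo + IRanges::end(Biostrings::subject(pa)) - tr$sub_trim)
    full_len <- len + diag_extension(up, down, cand_a, cand_b)
    if (full_len >= max_length) next
    cand <- list(
      left_start = up_off + a_lo + IRanges::start(Biostrings::pattern(pa)) -
        1 + tr$pat_off,
      left_end = up_off + a_lo + IRanges::end(Biostrings::pattern(pa)) -
        tr$pat_trim,
      right_start = down_off + b_lo +
        IRanges::start(Biostrings::subject(pa)) - 1 + tr$sub_off,
      right_end = down_off + b_lo + IRanges::end(Biostrings::subject(pa)) -
        tr$sub_trim,
      identity = round(identity, 3), length = len,
      score = Biostrings::score(pa))
    if (is.null(best) ||
        cand$score > best$score ||
        (cand$score == best$score && cand$length > best$length) ||
        (cand$score == best$score && cand$length == best$length &&
         cand$left_start < best$left_start)) {
      best <- cand
    }
  }
  if (is.null(best)) return(NULL)
  best$score <- NULL
  best
}
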