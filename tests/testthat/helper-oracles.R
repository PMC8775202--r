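# shared fixture builders and independent oracles

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# mutate a fraction of positions by substitution (exact count)
mutate_frac <- function(seq, frac) {
  s <- strsplit(seq, "")[[1]]
  n_mut <- round(frac * length(s))
  if (n_mut > 0) {
    pos <- sample(length(s), n_mut)
    s[pos] <- vapply(s[pos], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  }
  paste(s, collapse = "")
}

aa_order <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# construct a DomainHit row with defaults
make_hit <- function(sequence_id = "s", genomic_start = 0, genomic_end = 300,
                     strand = "+", frame = 0L, profile_id = "toy_gRT",
                     profile_start = 0L, profile_end = 100L,
                     bit_score = 100, e_value = 1e-10, aligned_aa = NULL) {
  if (is.null(aligned_aa))
    aligned_aa <- paste(rep("A", profile_end - profile_start), collapse = "")
  data.frame(sequence_id = sequence_id, genomic_start = genomic_start,
             genomic_end = genomic_end, strand = strand, frame = frame,
             profile_id = profile_id, profile_start = profile_start,
             profile_end = profile_end, bit_score = bit_score,
             e_value = e_value, aligned_aa = aligned_aa,
             stringsAsFactors = FALSE)
}

# can hit b directly follow hit a in one chain? (element orientation)
chainable <- function(a, b, max_gap = 600, max_overlap = 15) {
  gap <- if (a$strand == "+") b$genomic_start - a$genomic_end
         else a$genomic_start - b$genomic_end
  gap <= max_gap && gap >= -3 * max_overlap &&
    b$profile_start >= a$profile_end - max_overlap
}

# exhaustive chaining oracle: minimum number of valid chains over all
# ordered partitions of <= 5 same-profile same-strand hits
min_chain_partition <- function(hits, max_gap = 600, max_overlap = 15) {
  n <- nrow(hits)
  ord <- if (hits$strand[1] == "+") order(hits$genomic_start)
         else order(-hits$genomic_end)
  hits <- hits[ord, ]
  best <- n
  recurse <- function(remaining, chains_open, n_chains) {
    if (length(remaining) == 0L) {
      best <<- min(best, n_chains)
      return(invisible())
    }
    if (n_chains >= best) return(invisible())
    i <- remaining[1]
    rest <- remaining[-1]
    for (ci in seq_along(chains_open)) {
      if (chainable(hits[chains_open[ci], ], hits[i, ], max_gap,
                    max_overlap)) {
        nxt <- chains_open
        nxt[ci] <- i
        recurse(rest, nxt, n_chains)
      }
    }
    recurse(rest, c(chains_open, i), n_chains + 1L)
  }
  recurse(seq_len(n), integer(0), 0L)
  best
}

# independent pairwise qualification for the clustering oracle: same
# definition of identity/coverage, computed directly from an ends-free
# alignment in the test
pair_qualifies <- function(a, b, min_id = 0.8, min_cov = 0.8) {
  submat <- local({
    letters <- c(aa_order, "X", "*")
    m <- matrix(-2, length(letters), length(letters),
                dimnames = list(letters, letters))
    diag(m) <- 2
    m["X", ] <- 0; m[, "X"] <- 0; m["*", "*"] <- 0
    m
  })
  pa <- Biostrings::pairwiseAlignment(Biostrings::AAString(a),
                                      Biostrings::AAString(b),
                                      type = "overlap",
                                      substitutionMatrix = submat,
                                      gapOpening = 6, gapExtension = 1)
  cols <- Biostrings::nchar(pa)
  if (cols == 0L) return(FALSE)
  pat <- Biostrings::pattern(pa); sub <- Biostrings::subject(pa)
  id <- Biostrings::nmatch(pa) / cols
  cov_a <- (IRanges::end(pat) - IRanges::start(pat) + 1) / nchar(a)
  cov_b <- (IRanges::end(sub) - IRanges::start(sub) + 1) / nchar(b)
  id >= min_id && cov_a >= min_cov && cov_b >= min_cov
}

# transitive-closure clustering over all pairs (union-find)
bruteforce_clusters <- function(peptides, min_id = 0.8, min_cov = 0.8) {
  n <- length(peptides)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    if (pair_qualifies(peptides[[i]], peptides[[j]], min_id, min_cov)) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  split(names(peptides), roots)
}

# partition as a canonical set of member-id sets
canonical_partition <- function(groups) {
  unname(lapply(groups, function(g) sort(g)))[
    order(vapply(groups, function(g) sort(g)[1], character(1)))]
}

# build a locus string with planted direct repeats around a stub domain
# block; short distinct sentinels around each copy pin the repeat
# boundaries so expected coordinates are unambiguous
make_ltr_case <- function(ltr_len, identity_frac, pad = 1200, gap = 200,
                          block = 600) {
  ltr <- rand_dna(ltr_len)
  ltr2 <- mutate_frac(ltr, 1 - identity_frac)
  locus <- paste0(rand_dna(pad), "AAA", ltr, "AAA", rand_dna(gap),
                  rand_dna(block), rand_dna(gap), "CCC", ltr2, "CCC",
                  rand_dna(pad))
  bs <- pad + ltr_len + gap + 6
  be <- bs + block
  element <- list(strand = "+",
                  domains = data.frame(genomic_start = bs, genomic_end = be))
  list(locus = locus, element = element, block_start = bs, block_end = be,
       left_start = pad + 3, left_end = pad + 3 + ltr_len,
       right_start = be + gap + 3, right_end = be + gap + 3 + ltr_len)
}

# 1:1 matching of reported elements against the truth table within a
# coordinate tolerance; returns the number of matched truth rows
count_recovered <- function(truth, elements, tol = 30) {
  used <- rep(FALSE, nrow(elements))
  matched <- 0L
  for (i in seq_len(nrow(truth))) {
    cand <- which(!used &
                  elements$sequence_id == truth$sequence_id[i] &
                  elements$strand == truth$strand[i] &
                  abs(elements$block_start - truth$block_start[i]) <= tol &
                  abs(elements$block_end - truth$block_end[i]) <= tol)
    if (length(cand)) {
      used[cand[1]] <- TRUE
      matched <- matched + 1L
    }
  }
  matched
}

# hash every file of a directory tree (relative path -> md5)
hash_tree <- function(dir) {
  files <- sort(list.files(dir, recursive = TRUE, full.names = FALSE))
  h <- tools::md5sum(file.path(dir, files))
  names(h) <- files
  h
}
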