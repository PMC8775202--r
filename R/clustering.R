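# Redundancy reduction: greedy incremental clustering of core-domain
# peptides by identity and bidirectional coverage, representative selection,
# and the cluster TSV.

aa_submat <- function() {
  letters <- c(AA_ORDER, "X", "*")
  m <- matrix(-2, length(letters), length(letters),
              dimnames = list(letters, letters))
  diag(m) <- 2
  m["X", ] <- 0; m[, "X"] <- 0; m["*", "*"] <- 0
  m
}

# ends-free pairwise comparison; identity over aligned columns, coverage of
# the aligned span on each sequence
align_pair <- function(a, b, submat) {
  pa <- Biostrings::pairwiseAlignment(Biostrings::AAString(a),
                                      Biostrings::AAString(b),
                                      type = "overlap",
                                      substitutionMatrix = submat,
                                      gapOpening = 6, gapExtension = 1)
  cols <- Biostrings::nchar(pa)
  if (cols == 0L) return(list(identity = 0, cov_a = 0, cov_b = 0))
  pat <- Biostrings::pattern(pa); sub <- Biostrings::subject(pa)
  list(identity = Biostrings::nmatch(pa) / cols,
       cov_a = (IRanges::end(pat) - IRanges::start(pat) + 1) / nchar(a),
       cov_b = (IRanges::end(sub) - IRanges::start(sub) + 1) / nchar(b))
}

#' Cluster core-domain peptides
#'
#' Greedy incremental clustering in the spirit of MMseqs2 easy-cluster:
#' sequences are visited by decreasing length (ties by id); each sequence
#' joins the first existing cluster whose founder aligns to it with identity
#' at least `min_seq_id` and coverage of at least `min_coverage` on *both*
#' sequences (ends-free global alignment), otherwise it founds a new
#' cluster.  A shared-5-mer prefilter skips hopeless comparisons.
#'
#' @param peptides named character vector of peptides keyed by element id.
#' @param min_seq_id minimum fractional identity (default 0.8).
#' @param min_coverage minimum bidirectional coverage (default 0.8).
#' @return data frame with columns `cluster_id`, `member_id`,
#'   `representative_id` (the cluster founder until
#'   [select_representatives()] re-chooses); clusters partition the input.
#' @export
cluster_core_domains <- function(peptides, min_seq_id = 0.8,
                                 min_coverage = 0.8) {
  stopifnot(length(peptides) > 0, !is.null(names(peptides)))
  if (anyDuplicated(names(peptides)))
    stop("duplicate element_ids in peptide set")
  ord <- order(-nchar(peptides), names(peptides))
  ids <- names(peptides)[ord]
  seqs <- toupper(unname(peptides[ord]))
  submat <- aa_submat()
  k <- 5L
  kindex <- new.env(parent = emptyenv())
  founders <- integer(0)       # index into seqs of each cluster founder
  assignment <- integer(length(seqs))
  seq_kmers <- function(s) {
    n <- nchar(s)
    if (n < k) return(s)
    unique(substring(s, 1:(n - k + 1), k:n))
  }
  for (i in seq_along(seqs)) {
    km <- seq_kmers(seqs[i])
    cand <- sort(unique(unlist(lapply(km, function(x) kindex[[x]]),
                               use.names = FALSE)))
    placed <- FALSE
    for (ci in cand) {
      al <- align_pair(seqs[founders[ci]], seqs[i], submat)
      if (al$identity >= min_seq_id && al$cov_a >= min_coverage &&
          al$cov_b >= min_coverage) {
        assignment[i] <- ci
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      founders <- c(founders, i)
      ci <- length(founders)
      assignment[i] <- ci
      for (x in km) kindex[[x]] <- c(kindex[[x]], ci)
    }
  }
  data.frame(cluster_id = assignment, member_id = ids,
             representative_id = ids[founders[assignment]],
             stringsAsFactors = FALSE)
}

#' Select cluster representatives
#'
#' The representative of each cluster is the member with the most domains in
#' its structure string; ties are broken by highest score, then by
#' lexicographically smallest element id.
#'
#' @param clusters cluster table from [cluster_core_domains()].
#' @param elements data frame with `element_id`, `structure`, `score`.
#' @return the cluster table with `representative_id` updated.
#' @export
select_representatives <- function(clusters, elements) {
  idx <- match(clusters$member_id, elements$element_id)
  if (anyNA(idx)) stop("cluster member missing from element table")
  n_dom <- lengths(strsplit(elements$structure[idx], ".", fixed = TRUE))
  score <- elements$score[idx]
  for (cid in unique(clusters$cluster_id)) {
    sel <- which(clusters$cluster_id == cid)
    best <- sel[order(-n_dom[sel], -score[sel], clusters$member_id[sel])][1]
    clusters$representative_id[sel] <- clusters$member_id[best]
  }
  clusters
}

#' Write the cluster table as TSV
#'
#' Columns: `cluster_id`, `representative_id`, `member_id`,
#' `member_structure`, `member_score`; one row per member, ordered by
#' cluster then member id.
#'
#' @param clusters cluster table (after [select_representatives()]).
#' @param elements element table with `element_id`, `structure`, `score`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cluster_table <- function(clusters, elements, path) {
  idx <- match(clusters$member_id, elements$element_id)
  tb <- data.frame(cluster_id = clusters$cluster_id,
                   representative_id = clusters$representative_id,
                   member_id = clusters$member_id,
                   member_structure = elements$structure[idx],
                   member_score = elements$score[idx],
                   stringsAsFactors = FALSE)
  tb <- tb[order(tb$cluster_id, tb$member_id), ]
  write.table(tb, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cluster table written by [write_cluster_table()]
#' @param path TSV path.
#' @return data frame with the table's columns.
#' @export
read_cluster_table <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
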