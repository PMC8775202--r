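# Round-2 structural annotation: chain frameshift-split fragments, delineate
# tandem elements around their core domains, build structure strings, assess
# ORF intactness, extract domain peptides.

#' Chain frameshift-split domain fragments into assembled domains
#'
#' Hits of one profile on one strand are ordered along the element
#' orientation and partitioned into the minimum number of colinear chains:
#' a fragment may follow another when the genomic gap is at most
#' `max_genomic_gap` (small insertions) and its profile coordinates advance
#' (`profile_start >= previous profile_end - max_profile_overlap`).  Frames
#' are free to differ between chained fragments -- that is the frameshift
#' case.  The minimum chain partition is computed exactly (path cover on
#' the chainability graph), so the result is deterministic and independent
#' of hit input order.  Each chain becomes one assembled domain whose bit
#' score is the sum of its parts and whose e-value is the best of its
#' parts.
#'
#' @param hits round-2 DomainHit data frame for one locus.
#' @param profiles profile set (labels and lengths).
#' @param max_genomic_gap maximum genomic gap between chained fragments in
#'   bases (default 600).
#' @param max_profile_overlap maximum profile-coordinate overlap between
#'   chained fragments in positions (default 15).
#' @return data frame of assembled domains: `domain_label`, `profile_id`,
#'   `strand`, `genomic_start`, `genomic_end` (envelope), `combined_bits`,
#'   `best_evalue`, `profile_coverage`, `interrupted`, `n_parts`, plus a
#'   list-column `parts` of the chained hits in element orientation.
#' @export
chain_fragments <- function(hits, profiles, max_genomic_gap = 600,
                            max_profile_overlap = 15) {
  empty <- data.frame(domain_label = character(), profile_id = character(),
                      strand = character(), genomic_start = numeric(),
                      genomic_end = numeric(), combined_bits = numeric(),
                      best_evalue = numeric(), profile_coverage = numeric(),
                      interrupted = logical(), n_parts = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(hits) == 0L) return(empty)
  labels <- setNames(vapply(profiles, `[[`, character(1), "label"),
                     vapply(profiles, `[[`, character(1), "profile_id"))
  plens <- setNames(vapply(profiles, `[[`, numeric(1), "length"),
                    names(labels))
  out <- list()
  for (key in unique(paste(hits$profile_id, hits$strand))) {
    grp <- hits[paste(hits$profile_id, hits$strand) == key, , drop = FALSE]
    plus <- grp$strand[1] == "+"
    # order along 5'->3' of the element so profile coordinates advance
    grp <- if (plus) grp[order(grp$genomic_start, grp$genomic_end), ,
                         drop = FALSE]
           else grp[order(-grp$genomic_end, -grp$genomic_start), ,
                    drop = FALSE]
    chains <- chain_partition(grp, max_genomic_gap, max_profile_overlap)
    for (ch in chains) {
      pid <- ch$profile_id[1]
      cov_ir <- IRanges::reduce(IRanges::IRanges(ch$profile_start + 1,
                                                 ch$profile_end))
      row <- data.frame(
        domain_label = unname(labels[pid]), profile_id = pid,
        strand = ch$strand[1], genomic_start = min(ch$genomic_start),
        genomic_end = max(ch$genomic_end),
        combined_bits = sum(ch$bit_score), best_evalue = min(ch$e_value),
        profile_coverage = sum(IRanges::width(cov_ir)) / plens[[pid]],
        interrupted = nrow(ch) > 1L, n_parts = nrow(ch),
        stringsAsFactors = FALSE)
      rownames(ch) <- NULL
      row$parts <- list(ch)
      out[[length(out) + 1L]] <- row
    }
  }
  dom <- do.call(rbind, out)
  dom <- dom[order(dom$genomic_start, dom$genomic_end), ]
  rownames(dom) <- NULL
  dom
}

#' Delineate assembled domains into separate elements
#'
#' One element is produced per core assembled domain.  Every non-core domain
#' is assigned to the nearest core domain on the same strand, with the
#' assignment bounded by the midpoints between successive same-strand cores,
#' so tandem elements split their territory.  Elements failing the
#' required-domain filter are dropped with a logged reason.
#'
#' @param locus one row of the locus table (needs `locus_id`, `sequence_id`,
#'   `start`).
#' @param domains assembled-domain table from [chain_fragments()].
#' @param core_label label of the core domain (e.g. `"gRT"`).
#' @param require_additional_domains minimum number of non-core domains an
#'   element must carry to be kept (default 0; set 1-2 to apply the
#'   additional-domain false-positive filter).
#' @return list with `elements` (list of `retro_element` objects, domains in
#'   genomic order) and `dropped` (data frame of dropped elements with
#'   reasons).
#' @export
delineate_elements <- function(locus, domains, core_label,
                               require_additional_domains = 0) {
  dropped <- data.frame(locus_id = character(), structure = character(),
                        reason = character(), stringsAsFactors = FALSE)
  if (nrow(domains) == 0L ||
      !any(domains$domain_label == core_label)) {
    if (nrow(domains) > 0L)
      dropped <- data.frame(locus_id = locus$locus_id, structure = NA,
                            reason = "no core domain in locus",
                            stringsAsFactors = FALSE)
    return(list(elements = list(), dropped = dropped))
  }
  elements <- list()
  for (s in unique(domains$strand[domains$domain_label == core_label])) {
    cores <- which(domains$domain_label == core_label & domains$strand == s)
    cores <- cores[order(domains$genomic_start[cores])]
    others <- which(domains$domain_label != core_label & domains$strand == s)
    # territory boundaries at midpoints between successive cores
    if (length(cores) > 1L) {
      bounds <- (domains$genomic_end[cores[-length(cores)]] +
                 domains$genomic_start[cores[-1]]) / 2
    } else bounds <- numeric(0)
    mid <- (domains$genomic_start[others] + domains$genomic_end[others]) / 2
    assign_to <- findInterval(mid, bounds) + 1L
    for (ci in seq_along(cores)) {
      rows <- c(cores[ci], others[assign_to == ci])
      dom <- domains[rows, , drop = FALSE]
      dom <- dom[order(dom$genomic_start, dom$genomic_end), , drop = FALSE]
      dom <- drop_overlapping(dom)
      rownames(dom) <- NULL
      el <- structure(list(
        element_id = NA_character_, locus_id = locus$locus_id,
        sequence_id = locus$sequence_id, locus_start = locus$start,
        strand = s, domains = dom, structure = NA_character_,
        orf_intact = NA, domain_orf = NULL, ltr = NULL, score = NA_real_),
        class = "retro_element")
      el$structure <- build_structure_string(el)
      elements[[length(elements) + 1L]] <- el
    }
  }
  ord <- order(vapply(elements, function(e) min(e$domains$genomic_start),
                      numeric(1)))
  elements <- elements[ord]
  keep <- vapply(elements, function(e)
    sum(e$domains$domain_label != core_label) >= require_additional_domains,
    logical(1))
  if (any(!keep)) {
    dropped <- rbind(dropped, data.frame(
      locus_id = locus$locus_id,
      structure = vapply(elements[!keep], `[[`, character(1), "structure"),
      reason = sprintf("fewer than %d additional domains",
                       require_additional_domains),
      stringsAsFactors = FALSE))
  }
  list(elements = elements[keep], dropped = dropped)
}

# can hit j directly follow hit i within one chain? (orientation order)
can_chain <- function(a, b, max_genomic_gap, max_profile_overlap) {
  gap <- if (a$strand == "+") b$genomic_start - a$genomic_end
         else a$genomic_start - b$genomic_end
  gap <= max_genomic_gap && gap >= -3 * max_profile_overlap &&
    b$profile_start >= a$profile_end - max_profile_overlap
}

# partition orientation-ordered hits of one (profile, strand) group into the
# minimum number of colinear chains: minimum path cover on the chainability
# DAG via maximum bipartite matching (Kuhn's augmenting paths), which is
# exact and deterministic
chain_partition <- function(grp, max_genomic_gap, max_profile_overlap) {
  n <- nrow(grp)
  if (n == 1L) return(list(grp))
  adj <- lapply(seq_len(n), function(i) {
    js <- seq_len(n)[-seq_len(i)]
    js[vapply(js, function(j) can_chain(grp[i, ], grp[j, ], max_genomic_gap,
                                        max_profile_overlap), logical(1))]
  })
  match_to <- integer(n)          # successor j -> predecessor i (0 = free)
  visited <- logical(n)
  augment <- function(i) {
    for (j in adj[[i]]) {
      if (visited[j]) next
      visited[j] <<- TRUE
      if (match_to[j] == 0L || augment(match_to[j])) {
        match_to[j] <<- i
        return(TRUE)
      }
    }
    FALSE
  }
  for (i in seq_len(n)) {
    visited <- logical(n)
    augment(i)
  }
  succ_of <- integer(n)
  for (j in which(match_to > 0L)) succ_of[match_to[j]] <- j
  # chain heads are hits that are nobody's successor
  heads <- which(match_to == 0L)
  lapply(heads, function(h) {
    idx <- h
    while (succ_of[idx[length(idx)]] > 0L)
      idx <- c(idx, succ_of[idx[length(idx)]])
    grp[idx, , drop = FALSE]
  })
}

# overlapping envelopes within one element keep the stronger domain
# (touching envelopes are fine)
drop_overlapping <- function(dom) {
  repeat {
    if (nrow(dom) < 2L) return(dom)
    ov <- which(dom$genomic_start[-1] < dom$genomic_end[-nrow(dom)])
    if (length(ov) == 0L) return(dom)
    i <- ov[1]
    loser <- if (dom$combined_bits[i] >= dom$combined_bits[i + 1]) i + 1 else i
    dom <- dom[-loser, , drop = FALSE]
  }
}

#' Build the dot-joined structure string of an element
#'
#' Domain labels joined with `"."`, always reading 5'->3' in element
#' orientation (genomic order is reversed for minus-strand elements).
#'
#' @param element a `retro_element`.
#' @return structure string, e.g. `"GAG.Pro.gRT.gRH.INT"`.
#' @export
build_structure_string <- function(element) {
  labs <- element$domains$domain_label
  if (element$strand == "-") labs <- rev(labs)
  paste(labs, collapse = ".")
}

#' Assess ORF intactness of an element
#'
#' A domain is intact when it is not frameshift-chained and the translation
#' of its envelope (in its own frame and orientation) contains no stop
#' codon.  The element is intact when every domain is.
#'
#' @param element a `retro_element`.
#' @return the element with `domain_orf` (logical, per domain in genomic
#'   order) and `orf_intact` filled in.
#' @export
detect_orf_intactness <- function(element) {
  dom <- element$domains
  flags <- vapply(seq_len(nrow(dom)), function(i) {
    if (dom$interrupted[i]) return(FALSE)
    !grepl("[*]", dom$parts[[i]]$aligned_aa[1])
  }, logical(1))
  element$domain_orf <- flags
  element$orf_intact <- all(flags)
  element
}

#' Extract domain peptides from annotated elements
#'
#' For every domain of every element the chained parts are joined in profile
#' order; when successive parts overlap in profile coordinates the overlap
#' is trimmed from the start of the downstream part, splicing frameshifted
#' fragments into one peptide.
#'
#' @param elements list of `retro_element` objects with assigned
#'   `element_id`s.
#' @return named list, one entry per domain label, each a named character
#'   vector of peptides keyed by element id.
#' @export
extract_domain_peptides <- function(elements) {
  out <- list()
  for (el in elements) {
    for (i in seq_len(nrow(el$domains))) {
      d <- el$domains[i, ]
      parts <- d$parts[[1]]
      pep <- parts$aligned_aa[1]
      for (j in seq_len(nrow(parts))[-1]) {
        trim <- max(0L, parts$profile_end[j - 1] - parts$profile_start[j])
        pep <- paste0(pep, substring(parts$aligned_aa[j], trim + 1L))
      }
      lbl <- d$domain_label
      out[[lbl]] <- c(out[[lbl]], setNames(pep, el$element_id))
    }
  }
  out
}

#' @export
print.retro_element <- function(x, ...) {
  cat(sprintf("<retro_element %s %s strand=%s domains=%d score=%s ltr=%s>\n",
              x$element_id %||% "?", x$structure, x$strand,
              nrow(x$domains), format(x$score),
              if (is.null(x$ltr)) "none"
              else sprintf("%.3f/%d", x$ltr$identity, x$ltr$length)))
  invisible(x)
}
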