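# Composite %score and the element identifier grammar
# "{project}_{batch}_{num}|{structure}|{ltr_info}|{score}".

#' Score weights for the composite element score
#'
#' The %score aggregates, on a 0-100 scale, the number of identified
#' domains, the mean profile coverage of the matches, the fraction of
#' domains with intact ORFs, and the LTR identity (0 when no LTR was
#' found).  Weights must be non-negative and sum to 1.
#'
#' @param w_domains,w_coverage,w_orf,w_ltr component weights (defaults 0.4,
#'   0.3, 0.15, 0.15).
#' @param expected_domains expected domain count of a complete element
#'   (default 5, the canonical Ty3/gypsy GAG.Pro.gRT.gRH.INT layout).
#' @return a `score_weights` list.
#' @export
score_weights <- function(w_domains = 0.4, w_coverage = 0.3, w_orf = 0.15,
                          w_ltr = 0.15, expected_domains = 5) {
  w <- c(w_domains, w_coverage, w_orf, w_ltr)
  stopifnot(all(w >= 0), abs(sum(w) - 1) <= 1e-9, expected_domains >= 1)
  structure(list(w_domains = w_domains, w_coverage = w_coverage,
                 w_orf = w_orf, w_ltr = w_ltr,
                 expected_domains = expected_domains),
            class = "score_weights")
}

#' Compute the composite %score of an element
#'
#' `score = 100 * (w_domains * min(1, n_domains / expected_domains) +
#' w_coverage * mean(profile_coverage) + w_orf * fraction_intact +
#' w_ltr * ltr_identity / 100)`, reported with one decimal.  The score is
#' bounded in \[0, 100\] and monotone non-decreasing in every component.
#'
#' @param element an annotated `retro_element` (ORF flags filled, LTR
#'   optional).
#' @param weights a [score_weights()] object.
#' @return numeric score in \[0, 100\].
#' @export
compute_score <- function(element, weights = score_weights()) {
  n <- nrow(element$domains)
  if (is.null(n) || n == 0L) stop("element has no domains; cannot score")
  orf_frac <- if (is.null(element$domain_orf)) 0 else mean(element$domain_orf)
  ltr_term <- if (is.null(element$ltr)) 0 else element$ltr$identity / 100
  s <- 100 * (weights$w_domains * min(1, n / weights$expected_domains) +
              weights$w_coverage * mean(element$domains$profile_coverage) +
              weights$w_orf * orf_frac +
              weights$w_ltr * ltr_term)
  round(s, 1)
}

#' Format the unique element identifier
#'
#' Grammar: `{project}_{batch}_{num}|{structure}|{ltr_info}|{score}` with
#' `num` zero-padded to 4 digits, `ltr_info` either
#' `LTR%{identity:.3f}-{length}` (e.g. `LTR%99.567-232`) or `LTR%none`, and
#' the score printed with one decimal.  The string round-trips through
#' [parse_element_id()].
#'
#' @param project run name; must not contain the `|` delimiter.
#' @param batch batch number (integer).
#' @param num element number within the batch (integer).
#' @param element a scored `retro_element`.
#' @return identifier string.
#' @export
format_element_id <- function(project, batch, num, element) {
  if (grepl("|", project, fixed = TRUE))
    stop("project name must not contain '|' (identifier delimiter)")
  ltr_info <- if (is.null(element$ltr)) "LTR%none"
              else sprintf("LTR%%%.3f-%d", element$ltr$identity,
                           element$ltr$length)
  sprintf("%s_%d_%04d|%s|%s|%.1f", project, as.integer(batch),
          as.integer(num), element$structure, ltr_info, element$score)
}

#' Parse an element identifier
#'
#' @param id identifier produced by [format_element_id()].
#' @return list with `project`, `batch`, `num`, `structure`,
#'   `ltr_identity`/`ltr_length` (NA when `LTR%none`), `score`.
#' @export
parse_element_id <- function(id) {
  re <- "^(.+)_([0-9]+)_([0-9]+)\\|([^|]+)\\|LTR%(none|[0-9]+\\.[0-9]{3}-[0-9]+)\\|([0-9]+(?:\\.[0-9]+)?)$"
  m <- regmatches(id, regexec(re, id))[[1]]
  if (length(m) == 0L) stop("unparseable element identifier: ", id)
  ltr <- m[6]
  if (ltr == "none") {
    ident <- NA_real_; llen <- NA_integer_
  } else {
    p <- strsplit(ltr, "-", fixed = TRUE)[[1]]
    ident <- as.numeric(p[1]); llen <- as.integer(p[2])
  }
  list(project = m[2], batch = as.integer(m[3]), num = as.integer(m[4]),
       structure = m[5], ltr_identity = ident, ltr_length = llen,
       score = as.numeric(m[7]))
}
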