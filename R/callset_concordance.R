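# Matching SV callsets against reference site lists (reciprocal overlap for
# spanned types, breakpoint windows for insertions) and the validation
# arithmetic built on those matches.

#' Match two SV callsets
#'
#' Candidate pairs are restricted to the same `svtype` and chromosome.
#' For DEL/DUP/INV, a query/reference pair matches when the overlap covers
#' at least `ro_threshold` of \emph{both} spans (reciprocal overlap; spans
#' are treated half-open, with length `end - pos`).  For insertions, a pair
#' matches when the breakpoints are within `ins_window` bp.  Matches are
#' then made one-to-one greedily: spanned pairs by descending minimum
#' reciprocal-overlap fraction, insertion pairs by ascending breakpoint
#' distance, ties broken by the smaller reference start.
#'
#' @param query,ref site tables (need `id`, `chrom`, `pos`, `end`,
#'   `svtype`).
#' @param ro_threshold reciprocal-overlap threshold in `(0, 1]`.
#' @param ins_window insertion breakpoint window in bp.
#' @return An object of class `match_result`: list with `pairs`
#'   (data.frame `query_id`, `ref_id`, `score`), `n_query`, `n_ref`,
#'   `n_matched`, `recall` (matched references / reference count) and
#'   `precision` (matched queries / query count).
#' @export
match_callsets <- function(query, ref, ro_threshold = 0.5, ins_window = 500) {
  .check_sites(query)
  .check_sites(ref)
  if (!is.numeric(ro_threshold) || length(ro_threshold) != 1L ||
      is.na(ro_threshold) || ro_threshold <= 0 || ro_threshold > 1)
    .stopf("'ro_threshold' must be in (0, 1]")
  if (!is.numeric(ins_window) || ins_window < 0)
    .stopf("'ins_window' must be non-negative")

  cand <- list()
  for (tp in intersect(unique(query$svtype), unique(ref$svtype))) {
    qi <- which(query$svtype == tp)
    ri <- which(ref$svtype == tp)
    if (!length(qi) || !length(ri)) next
    if (tp %in% c("DEL", "DUP", "INV")) {
      # half-open spans [pos, end): IRanges closed [pos, end-1]
      qlen <- query$end[qi] - query$pos[qi]
      rlen <- ref$end[ri] - ref$pos[ri]
      ok_q <- qlen > 0; ok_r <- rlen > 0
      qi <- qi[ok_q]; ri <- ri[ok_r]; qlen <- qlen[ok_q]; rlen <- rlen[ok_r]
      if (!length(qi) || !length(ri)) next
      qgr <- GenomicRanges::GRanges(query$chrom[qi],
                                    IRanges::IRanges(query$pos[qi],
                                                     query$end[qi] - 1L))
      rgr <- GenomicRanges::GRanges(ref$chrom[ri],
                                    IRanges::IRanges(ref$pos[ri],
                                                     ref$end[ri] - 1L))
      h <- GenomicRanges::findOverlaps(qgr, rgr)
      if (!length(h)) next
      hq <- S4Vectors::queryHits(h)
      hr <- S4Vectors::subjectHits(h)
      ov <- GenomicRanges::width(IRanges::pintersect(qgr[hq], rgr[hr]))
      f_q <- ov / qlen[hq]
      f_r <- ov / rlen[hr]
      keep <- f_q >= ro_threshold & f_r >= ro_threshold
      if (!any(keep)) next
      cand[[tp]] <- data.frame(
        q = qi[hq[keep]], r = ri[hr[keep]],
        score = pmin(f_q, f_r)[keep],
        ref_start = ref$pos[ri[hr[keep]]]
      )
    } else if (tp == "INS") {
      qgr <- GenomicRanges::GRanges(query$chrom[qi],
                                    IRanges::IRanges(query$pos[qi],
                                                     query$pos[qi]))
      rgr <- GenomicRanges::GRanges(ref$chrom[ri],
                                    IRanges::IRanges(ref$pos[ri],
                                                     ref$pos[ri]))
      h <- GenomicRanges::findOverlaps(qgr, rgr, maxgap = ins_window)
      if (!length(h)) next
      hq <- S4Vectors::queryHits(h)
      hr <- S4Vectors::subjectHits(h)
      dist <- abs(query$pos[qi[hq]] - ref$pos[ri[hr]])
      keep <- dist <= ins_window
      if (!any(keep)) next
      # score: closeness, so the same descending-order greedy pass applies
      cand[[tp]] <- data.frame(
        q = qi[hq[keep]], r = ri[hr[keep]],
        score = -dist[keep],
        ref_start = ref$pos[ri[hr[keep]]]
      )
    }
  }

  pairs <- data.frame(query_id = character(), ref_id = character(),
                      score = numeric(), stringsAsFactors = FALSE)
  if (length(cand)) {
    cc <- do.call(rbind, cand)
    cc <- cc[order(-cc$score, cc$ref_start, cc$q), , drop = FALSE]
    used_q <- logical(nrow(query))
    used_r <- logical(nrow(ref))
    keep <- logical(nrow(cc))
    for (i in seq_len(nrow(cc))) {
      if (!used_q[cc$q[i]] && !used_r[cc$r[i]]) {
        keep[i] <- TRUE
        used_q[cc$q[i]] <- TRUE
        used_r[cc$r[i]] <- TRUE
      }
    }
    cc <- cc[keep, , drop = FALSE]
    pairs <- data.frame(query_id = query$id[cc$q], ref_id = ref$id[cc$r],
                        score = cc$score, stringsAsFactors = FALSE)
  }
  structure(
    list(pairs = pairs,
         n_query = nrow(query), n_ref = nrow(ref),
         n_matched = nrow(pairs),
         recall = if (nrow(ref)) nrow(pairs) / nrow(ref) else NA_real_,
         precision = if (nrow(query)) nrow(pairs) / nrow(query) else NA_real_),
    class = "match_result"
  )
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf(
    "match_result: %d/%d queries matched (precision %.3f), recall %.3f over %d reference sites\n",
    x$n_matched, x$n_query, x$precision, x$recall, x$n_ref
  ))
  invisible(x)
}

#' Validation sensitivity percentage
#'
#' The percentage of tested calls confirmed by orthogonal validation,
#' rounded to the nearest integer: `round(100 * n_confirmed / n_tested)`.
#'
#' @param n_tested number of calls put through validation (> 0).
#' @param n_confirmed number confirmed (`<= n_tested`).
#' @return Integer percentage.
#' @examples
#' validation_summary(95, 78)  # 82
#' validation_summary(72, 61)  # 85
#' @export
validation_summary <- function(n_tested, n_confirmed) {
  if (!.is_count(n_tested, positive = TRUE))
    .stopf("'n_tested' must be a positive count")
  if (!.is_count(n_confirmed) || n_confirmed > n_tested)
    .stopf("'n_confirmed' must be a count <= n_tested")
  as.integer(round(100 * n_confirmed / n_tested))
}

#' Genotype concordance percentage
#'
#' Percentage of positions where called and validated genotypes agree,
#' rounded to the nearest integer.  Entries missing in either vector are
#' excluded from numerator and denominator.
#'
#' @param called,validated equal-length genotype vectors over `{0, 1, 2}`
#'   (`NA` for missing).
#' @return Integer percentage.
#' @export
genotype_concordance <- function(called, validated) {
  if (length(called) != length(validated))
    .stopf("genotype vectors must have equal length")
  ok <- !is.na(called) & !is.na(validated)
  if (!any(ok))
    .stopf("no comparable genotypes after excluding missing entries")
  if (!all(c(called[ok], validated[ok]) %in% 0:2))
    .stopf("genotypes must be 0, 1 or 2")
  as.integer(round(100 * mean(called[ok] == validated[ok])))
}
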