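# Per-type high-quality clauses on joint-genotyping site metrics,
# problematic-region masking, and high-confident insertion classification.

#' High-quality clause evaluation
#'
#' Applies the per-type metric clauses used to define high-quality SV calls
#' after graph-based joint genotyping (all comparisons strict):
#' \itemize{
#'   \item DEL: `QD > 12` and (`ABHet > 0.30` or `ABHet < 0`) and
#'     `AC / NUM_MERGED_SVS < 25` and `PASS_AC > 0` and `PASS_ratio > 0.1`.
#'   \item DUP: `QD > 5` and `PASS_AC > 0` and `AC / NUM_MERGED_SVS < 25`.
#'   \item INS, INV: `PASS_AC > 0` and `AC / NUM_MERGED_SVS < 25` and
#'     `PASS_ratio > 0.1` and (`ABHet > 0.25` or `ABHet < 0`) and
#'     `MaxAAS > 4`.
#' }
#' `ABHet` is -1 when a site has no heterozygous calls; that sentinel passes
#' through the `ABHet < 0` arm.  A metric that is missing (`NA`) fails its
#' clause, except `ABHet`, whose absence is treated as the -1 sentinel.
#'
#' @param sites site table (no BND rows: breakends have no clause set and
#'   raise an error; run [prefilter_sites()] first).
#' @return Logical vector, one element per row of `sites`.
#' @examples
#' del <- data.frame(id = "d1", chrom = "chr1", pos = 100L, end = 200L,
#'   svtype = "DEL", qd = 12.5, abhet = -1, ac = 3L, num_merged_svs = 1L,
#'   pass_ac = 1L, pass_ratio = 0.2, maxaas = 10L)
#' is_high_quality(del)
#' @export
is_high_quality <- function(sites) {
  .check_sites(sites, c("svtype"))
  if (nrow(sites) == 0) return(logical())
  if (any(sites$svtype == "BND"))
    .stopf("BND records have no high-quality clause set; prefilter first")
  if (any(!sites$svtype %in% .SV_TYPES))
    .stopf("unknown svtype '%s'", setdiff(sites$svtype, .SV_TYPES)[1])
  g <- function(col) if (col %in% names(sites)) sites[[col]] else rep(NA_real_, nrow(sites))
  gt_ <- function(x, cut) !is.na(x) & x > cut
  lt_ <- function(x, cut) !is.na(x) & x < cut
  qd <- g("qd"); pass_ac <- g("pass_ac"); pass_ratio <- g("pass_ratio")
  maxaas <- g("maxaas")
  ab <- g("abhet"); ab[is.na(ab)] <- -1
  ratio <- g("ac") / g("num_merged_svs")
  ok_ratio <- lt_(ratio, 25)
  ok_passac <- gt_(pass_ac, 0)
  out <- logical(nrow(sites))
  del <- sites$svtype == "DEL"
  dup <- sites$svtype == "DUP"
  insinv <- sites$svtype %in% c("INS", "INV")
  out[del] <- (gt_(qd, 12) & (ab > 0.30 | ab < 0) & ok_ratio & ok_passac &
                 gt_(pass_ratio, 0.1))[del]
  out[dup] <- (gt_(qd, 5) & ok_passac & ok_ratio)[dup]
  out[insinv] <- (ok_passac & ok_ratio & gt_(pass_ratio, 0.1) &
                    (ab > 0.25 | ab < 0) & gt_(maxaas, 4))[insinv]
  out
}

#' Genomic region set
#'
#' A normalized collection of genomic intervals in 0-based half-open (BED)
#' coordinates: sorted and non-overlapping per chromosome after merging.
#'
#' @param chrom,start,end equal-length vectors; `start` 0-based, `end`
#'   exclusive.
#' @return An object of class `region_set` with a data.frame `intervals`
#'   and `merged = TRUE`.
#' @export
region_set <- function(chrom = character(), start = integer(), end = integer()) {
  if (length(chrom) != length(start) || length(start) != length(end))
    .stopf("chrom/start/end must have equal length")
  if (any(end < start)) .stopf("region end < start")
  if (length(chrom) == 0) {
    iv <- data.frame(chrom = character(), start = integer(), end = integer())
    return(structure(list(intervals = iv, merged = TRUE), class = "region_set"))
  }
  gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    chrom, IRanges::IRanges(start + 1L, pmax(end, start + 1L))
  ))
  gr <- GenomicRanges::sort(gr)
  iv <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  structure(list(intervals = iv, merged = TRUE), class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("region_set: %d merged interval(s) on %d chromosome(s)\n",
              nrow(x$intervals), length(unique(x$intervals$chrom))))
  invisible(x)
}

# 1-based closed GRanges view of a region_set.
.region_gr <- function(rs) {
  stopifnot(inherits(rs, "region_set"))
  iv <- rs$intervals
  GenomicRanges::GRanges(iv$chrom, IRanges::IRanges(iv$start + 1L, iv$end))
}

#' Load and merge problematic-region BED masks
#'
#' Reads one or more BED files (0-based half-open) of regions where
#' short-read SV calls are unreliable -- assay blacklists, accessibility
#' masks, assembly gaps, segmental duplications, low-complexity repeats --
#' and returns their merged union.
#'
#' @param bed_paths character vector of BED paths (may be empty).
#' @return A [region_set()].
#' @export
load_region_mask <- function(bed_paths) {
  if (length(bed_paths) == 0) return(region_set())
  grs <- lapply(bed_paths, function(p) {
    if (!file.exists(p)) .stopf("no such BED file: %s", p)
    tryCatch(rtracklayer::import(p, format = "BED"),
             error = function(e) .stopf("malformed BED file '%s': %s",
                                        p, conditionMessage(e)))
  })
  gr <- suppressWarnings(do.call(c, lapply(grs, function(g) {
    GenomicRanges::granges(g)  # strip scores/names before union
  })))
  if (length(gr) == 0) return(region_set())
  region_set(as.character(GenomicRanges::seqnames(gr)),
             GenomicRanges::start(gr) - 1L,
             GenomicRanges::end(gr))
}

#' Flag SVs that reside in problematic regions
#'
#' DEL/DUP/INV records are flagged when their span `[pos, end]` overlaps a
#' masked interval by at least 1 bp; insertions (and breakends) are flagged
#' when their breakpoint position lies inside a masked interval.  The flag
#' is advisory: nothing is removed.
#'
#' @param sites site table.
#' @param mask a [region_set()].
#' @return `sites` with a logical `problematic` column.
#' @export
flag_problematic <- function(sites, mask) {
  .check_sites(sites)
  if (!inherits(mask, "region_set")) .stopf("'mask' must be a region_set")
  if (nrow(sites) == 0) {
    sites$problematic <- logical()
    return(sites)
  }
  if (nrow(mask$intervals) == 0) {
    sites$problematic <- FALSE
    return(sites)
  }
  spanned <- sites$svtype %in% c("DEL", "DUP", "INV")
  q_end <- ifelse(spanned, pmax(sites$end, sites$pos), sites$pos)
  q <- GenomicRanges::GRanges(sites$chrom, IRanges::IRanges(sites$pos, q_end))
  hits <- GenomicRanges::countOverlaps(q, .region_gr(mask))
  sites$problematic <- hits > 0
  sites
}

#' Classify high-confident insertions
#'
#' Deletions, duplications and inversions reach "high-confident" status only
#' through orthogonal evidence review (alignment inspection, wet-lab
#' validation), which is outside this package; insertions cannot be
#' inspected that way, so the rule is purely computational: an insertion is
#' high-confident when it is high-quality and not in a problematic region.
#'
#' @param sites site table with `hq` and `problematic` columns (see
#'   [add_quality_flags()]).
#' @return The subset of insertion rows satisfying `hq & !problematic`.
#' @export
classify_high_confident_insertions <- function(sites) {
  .check_sites(sites, c("svtype", "hq", "problematic"))
  out <- sites[sites$svtype == "INS" & !is.na(sites$hq) & sites$hq &
                 !sites$problematic, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Attach all quality flags
#'
#' Convenience wrapper computing `hq` (via [is_high_quality()]; `NA` for
#' BND), `problematic` (via [flag_problematic()]; `FALSE` when no mask is
#' given) and `high_confident` (insertions passing both) in one pass.
#'
#' @param sites site table.
#' @param mask optional [region_set()].
#' @return `sites` with columns `hq`, `problematic`, `high_confident`.
#' @export
add_quality_flags <- function(sites, mask = NULL) {
  .check_sites(sites)
  hq <- rep(NA, nrow(sites))
  nb <- sites$svtype != "BND"
  if (any(nb)) hq[nb] <- is_high_quality(sites[nb, , drop = FALSE])
  sites$hq <- hq
  if (is.null(mask)) {
    sites$problematic <- rep(FALSE, nrow(sites))
  } else {
    sites <- flag_problematic(sites, mask)
  }
  sites$high_confident <- sites$svtype == "INS" & !is.na(sites$hq) &
    sites$hq & !sites$problematic
  sites
}
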