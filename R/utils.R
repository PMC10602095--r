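# Internal helpers shared across modules.

.SV_TYPES <- c("DEL", "DUP", "INS", "INV", "BND")
.MODELS   <- c("aggregated", "breakpoint", "coverage")

# hg38 autosome lengths; used only to place simulated breakpoints.
.CHROM_LEN <- c(
  chr1 = 248956422, chr2 = 242193529, chr3 = 198295559, chr4 = 190214555,
  chr5 = 181538259, chr6 = 170805979, chr7 = 159345973, chr8 = 145138636,
  chr9 = 138394717, chr10 = 133797422, chr11 = 135086622, chr12 = 133275309,
  chr13 = 114364328, chr14 = 107043718, chr15 = 101991189, chr16 = 90338345,
  chr17 = 83257441, chr18 = 80373285, chr19 = 58617616, chr20 = 64444167,
  chr21 = 46709983, chr22 = 50818468
)

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
.warnf <- function(...) warning(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

.is_count <- function(x, positive = FALSE) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x == floor(x) &&
    (if (positive) x > 0 else x >= 0)
}

# Canonical empty site table: one row per VCF record.
.empty_sites <- function() {
  data.frame(
    id = character(), chrom = character(), pos = integer(), end = integer(),
    svtype = character(), svlen = integer(), model = character(),
    qd = numeric(), abhet = numeric(), ac = integer(), an = integer(),
    num_merged_svs = integer(), pass_ac = integer(), pass_ratio = numeric(),
    maxaas = integer(), stringsAsFactors = FALSE
  )
}

.check_sites <- function(sites, cols = c("id", "chrom", "pos", "end", "svtype")) {
  if (!is.data.frame(sites))
    .stopf("'sites' must be a data.frame (one row per SV record)")
  miss <- setdiff(cols, names(sites))
  if (length(miss))
    .stopf("'sites' is missing required column(s): %s", paste(miss, collapse = ", "))
  invisible(sites)
}

# Sort order used for VCF emission: chromosome (karyotype order), position.
.site_order <- function(sites) {
  ord <- match(sites$chrom, names(.CHROM_LEN))
  ord[is.na(ord)] <- length(.CHROM_LEN) + 1L
  order(ord, sites$pos, sites$id, match(sites$model, .MODELS))
}

#' Genotype dosage matrix
#'
#' Container for a samples-by-variants allele-dosage matrix (0/1/2, `NA` for
#' missing) with an optional parallel matrix of per-call FORMAT/FT pass flags.
#' Rows are samples, columns variants; both must be named.
#'
#' @param dosage integer matrix of allele dosages in `{0,1,2,NA}` with sample
#'   row names and variant column names.
#' @param ft_pass optional logical matrix of the same shape: did the
#'   per-sample genotype call carry `FT == "PASS"`? `NA` where no FT field
#'   was present.
#' @return An object of class `genotype_matrix`.
#' @examples
#' gm <- genotype_matrix(matrix(c(0L, 1L, 2L, 0L), 2, 2,
#'   dimnames = list(c("s1", "s2"), c("v1", "v2"))))
#' allele_counts(gm)
#' @export
genotype_matrix <- function(dosage, ft_pass = NULL) {
  if (!is.matrix(dosage)) .stopf("'dosage' must be a matrix")
  if (nrow(dosage) > 0 && is.null(rownames(dosage)))
    .stopf("'dosage' must have sample row names")
  if (ncol(dosage) > 0 && is.null(colnames(dosage)))
    .stopf("'dosage' must have variant column names")
  if (anyDuplicated(rownames(dosage)))
    .stopf("duplicate sample ids in dosage matrix")
  if (anyDuplicated(colnames(dosage)))
    .stopf("duplicate variant ids in dosage matrix")
  vals <- dosage[!is.na(dosage)]
  if (length(vals) && !all(vals %in% c(0, 1, 2)))
    .stopf("dosages must be 0, 1, 2 or NA")
  storage.mode(dosage) <- "integer"
  if (!is.null(ft_pass)) {
    if (!is.matrix(ft_pass) || !identical(dim(ft_pass), dim(dosage)))
      .stopf("'ft_pass' must be a logical matrix matching 'dosage'")
    storage.mode(ft_pass) <- "logical"
    dimnames(ft_pass) <- dimnames(dosage)
  }
  structure(list(dosage = dosage, ft_pass = ft_pass), class = "genotype_matrix")
}

#' @rdname genotype_matrix
#' @param gm a `genotype_matrix`.
#' @export
dosages <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  gm$dosage
}

#' @rdname genotype_matrix
#' @export
sample_ids <- function(gm) rownames(dosages(gm))

#' @rdname genotype_matrix
#' @export
variant_ids <- function(gm) colnames(dosages(gm))

#' @rdname genotype_matrix
#' @details `allele_counts()` returns, per variant, the sum of non-missing
#'   dosages (the cohort alternate allele count, AC).
#' @export
allele_counts <- function(gm) colSums(dosages(gm), na.rm = TRUE)

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "genotype_matrix: %d samples x %d variants (%.2f%% missing)\n",
    nrow(x$dosage), ncol(x$dosage),
    if (length(x$dosage)) 100 * mean(is.na(x$dosage)) else 0
  ))
  invisible(x)
}

# Subset a genotype matrix by variant ids (keeps all samples).
.gm_subset <- function(gm, ids) {
  genotype_matrix(
    gm$dosage[, ids, drop = FALSE],
    if (!is.null(gm$ft_pass)) gm$ft_pass[, ids, drop = FALSE]
  )
}
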