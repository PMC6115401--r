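#' Species-partitioned PDX read counts
#'
#' Bundles matched genes x samples integer count matrices for reads
#' assigned to the human (graft) and mouse (host) genomes of
#' patient-derived xenograft RNA-seq. Species library sizes (per-sample
#' column totals) are recorded at construction so downstream RPM values
#' stay anchored to the full, pre-filtering libraries.
#'
#' @param human,mouse Non-negative integer matrices of identical shape
#'   with matching gene rownames and sample colnames.
#' @return Object of class `"species_counts"`: list with `human`, `mouse`,
#'   `lib_human`, `lib_mouse`.
#' @export
species_counts <- function(human, mouse) {
  human <- as.matrix(human)
  mouse <- as.matrix(mouse)
  if (!identical(dim(human), dim(mouse)))
    stop("human and mouse count matrices must have the same shape")
  if (is.null(rownames(human)) || is.null(colnames(human)))
    stop("count matrices need gene rownames and sample colnames")
  if (!identical(dimnames(human), dimnames(mouse)))
    stop("human and mouse dimnames must match")
  if (any(human < 0) || any(mouse < 0))
    stop("counts must be non-negative")
  if (any(human != round(human)) || any(mouse != round(mouse)))
    stop("counts must be integers")
  structure(
    list(human = human, mouse = mouse,
         lib_human = colSums(human), lib_mouse = colSums(mouse)),
    class = "species_counts"
  )
}

#' Remove genes with uniformly low counts
#'
#' Keeps genes having at least `min_count` reads in either species in at
#' least one sample; i.e. removes the genes whose human and mouse counts
#' are both below `min_count` in every sample. The original (pre-filter)
#' species library sizes are preserved on the result.
#'
#' @param counts A [species_counts()] object.
#' @param min_count Count threshold (default 5).
#' @return Filtered `"species_counts"` object.
#' @export
filter_low_counts <- function(counts, min_count = 5) {
  stopifnot(inherits(counts, "species_counts"))
  if (min_count < 0) stop("min_count must be >= 0")
  keep <- apply(counts$human >= min_count | counts$mouse >= min_count,
                1L, any)
  if (!any(keep)) message("low-count filter removed every gene")
  out <- counts
  out$human <- counts$human[keep, , drop = FALSE]
  out$mouse <- counts$mouse[keep, , drop = FALSE]
  out
}

#' Per-gene fraction of reads mapped to mouse
#'
#' For each gene and sample the mouse fraction is
#' `mouse / (mouse + human)`; the gene-level value is either the median of
#' the per-sample fractions (default) or the pooled-count fraction across
#' samples. Genes with zero total reads under the chosen aggregation are
#' returned as `NA` (undefined) and should be excluded from summaries.
#'
#' @param counts A [species_counts()] object.
#' @param aggregation `"per_sample_median"` (default) or `"pooled"`.
#' @return Named numeric vector of per-gene mouse fractions in `[0, 1]`
#'   (`NA` where undefined).
#' @export
mouse_fraction <- function(counts,
                           aggregation = c("per_sample_median", "pooled")) {
  stopifnot(inherits(counts, "species_counts"))
  aggregation <- match.arg(aggregation)
  if (aggregation == "pooled") {
    h <- rowSums(counts$human)
    m <- rowSums(counts$mouse)
    tot <- h + m
    out <- ifelse(tot > 0, m / tot, NA_real_)
    names(out) <- rownames(counts$human)
    return(out)
  }
  tot <- counts$human + counts$mouse
  frac <- counts$mouse / tot   # NaN where total 0
  frac[tot == 0] <- NA_real_
  out <- apply(frac, 1L, stats::median, na.rm = TRUE)
  out[is.nan(out)] <- NA_real_
  out
}

#' Species-specific reads-per-million
#'
#' Scales each species' counts by that species' per-sample library size
#' (total reads of that species over all genes, recorded at object
#' construction and therefore computed before any low-count filtering):
#' `rpm = count / library * 1e6`.
#'
#' @param counts A [species_counts()] object.
#' @return List with matrices `human_rpm` and `mouse_rpm`.
#' @export
species_rpm <- function(counts) {
  stopifnot(inherits(counts, "species_counts"))
  if (any(counts$lib_human == 0) || any(counts$lib_mouse == 0))
    stop("zero species library size for sample(s): ",
         paste(names(counts$lib_human)[counts$lib_human == 0 |
                                         counts$lib_mouse == 0],
               collapse = ", "))
  list(human_rpm = sweep(counts$human, 2L, counts$lib_human, "/") * 1e6,
       mouse_rpm = sweep(counts$mouse, 2L, counts$lib_mouse, "/") * 1e6)
}

#' Per-gene log2 fold change of mouse vs human species-specific RPM
#'
#' Computes `log2((mouse_rpm + p) / (human_rpm + p))` per gene and sample,
#' where `p` is `pseudo_reads` converted to RPM within each species'
#' library, then summarizes each gene by the median across samples. The
#' pseudo reads keep genes with zero counts in one species finite.
#'
#' @param counts A [species_counts()] object.
#' @param pseudo_reads Pseudo read count added on the RPM scale
#'   (default 0.5).
#' @return Named numeric vector of per-gene median log2 fold changes, with
#'   the per-sample matrix attached as attribute `per_sample`.
#' @export
rpm_log2fc <- function(counts, pseudo_reads = 0.5) {
  rpm <- species_rpm(counts)
  ph <- pseudo_reads / counts$lib_human * 1e6
  pm <- pseudo_reads / counts$lib_mouse * 1e6
  l2 <- log2(sweep(rpm$mouse_rpm, 2L, pm, "+") /
               sweep(rpm$human_rpm, 2L, ph, "+"))
  out <- apply(l2, 1L, stats::median)
  attr(out, "per_sample") <- l2
  out
}

#' Read-based tumor purity of PDX samples
#'
#' Estimates per-sample tumor purity as the fraction of all reads assigned
#' to the human genome, using the full (pre-filter) species library sizes.
#'
#' @param counts A [species_counts()] object.
#' @return Named numeric vector of human read fractions per sample.
#' @export
purity_from_reads <- function(counts) {
  stopifnot(inherits(counts, "species_counts"))
  tot <- counts$lib_human + counts$lib_mouse
  if (any(tot == 0))
    stop("zero total reads for sample(s): ",
         paste(names(tot)[tot == 0], collapse = ", "))
  counts$lib_human / tot
}

#' Rank-sum contrast of a per-gene statistic between two gene sets
#'
#' Compares the values of a per-gene statistic (e.g. mouse read fraction
#' or RPM log2 fold change) between two gene sets with a two-sided
#' Wilcoxon rank-sum test, optionally removing the overlapping genes from
#' both sets first. Genes without a value (`NA`) are ignored.
#'
#' @param values Named numeric vector of per-gene statistics.
#' @param set_a,set_b Character vectors of gene ids; `set_a` is the
#'   first-named group whose rank sum is reported.
#' @param remove_overlap Remove `intersect(set_a, set_b)` from both sets
#'   before testing (default TRUE).
#' @return A `"rank_test"` with extra fields `median_a` and `median_b`.
#' @export
compare_gene_sets <- function(values, set_a, set_b, remove_overlap = TRUE) {
  if (is.null(names(values))) stop("values must be named by gene id")
  if (remove_overlap) {
    ov <- intersect(set_a, set_b)
    set_a <- setdiff(set_a, ov)
    set_b <- setdiff(set_b, ov)
  }
  va <- values[intersect(names(values), set_a)]
  vb <- values[intersect(names(values), set_b)]
  va <- va[!is.na(va)]
  vb <- vb[!is.na(vb)]
  if (length(va) == 0L || length(vb) == 0L)
    stop("a gene set maps to no values",
         if (remove_overlap) " after overlap removal" else "")
  out <- wilcoxon_rank_sum(va, vb)
  out$median_a <- stats::median(va)
  out$median_b <- stats::median(vb)
  out
}
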