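# Ribosomal DNA profiling: binned CpG methylation with coverage filtering,
# per-read regional methylation with alignment and confidence filters, and
# per-region variant density with quality / allele-frequency filters.
# Reads cannot be assigned to individual rDNA arrays, so all analyses
# operate on a single collapsed repeat unit.

#' rDNA analysis parameters
#'
#' @param bin_size Methylation aggregation bin width in bp.
#' @param min_site_coverage Sites with fewer reads are excluded.
#' @param min_read_ref_coverage Per-read minimum fraction of the reference
#'   unit covered (strict >).
#' @param min_read_identity Per-read minimum alignment identity (strict >).
#' @param confidence_drop_fraction Fraction of least-confident methylation
#'   calls removed (a single global quantile across the sample).
#' @param min_variant_quality Variants below this Phred quality are removed.
#' @param min_allele_frequency Variants below this allele frequency are
#'   excluded from downstream analysis.
#' @return list of class `rdna_params`.
#' @export
rdna_params <- function(bin_size = 200L, min_site_coverage = 100L,
                        min_read_ref_coverage = 0.70,
                        min_read_identity = 0.90,
                        confidence_drop_fraction = 0.10,
                        min_variant_quality = 30,
                        min_allele_frequency = 0.05) {
  stopifnot(bin_size > 0, min_site_coverage >= 0,
            min_read_ref_coverage >= 0, min_read_ref_coverage <= 1,
            min_read_identity >= 0, min_read_identity <= 1,
            confidence_drop_fraction >= 0, confidence_drop_fraction < 1,
            min_allele_frequency >= 0, min_allele_frequency <= 1)
  structure(list(bin_size = as.integer(bin_size),
                 min_site_coverage = as.integer(min_site_coverage),
                 min_read_ref_coverage = min_read_ref_coverage,
                 min_read_identity = min_read_identity,
                 confidence_drop_fraction = confidence_drop_fraction,
                 min_variant_quality = min_variant_quality,
                 min_allele_frequency = min_allele_frequency),
            class = "rdna_params")
}

#' Aggregate a CpG methylation pileup into bins
#'
#' Sites below the coverage threshold are excluded; the bin mean is the
#' pooled ratio of modified to total reads over the retained sites (i.e.
#' coverage-weighted, not a mean of per-site ratios). Bins with no
#' retained site are reported as missing, not zero.
#'
#' @param pileup data.frame with `start, coverage, modified` (bedmethyl
#'   style; 0-based site starts).
#' @param params An [rdna_params()].
#' @param ref_length Optional reference length; when given, all bins over
#'   `[0, ref_length)` are emitted (empty ones with NA mean).
#' @return data.frame(bin_start, bin_end, n_sites, coverage, modified,
#'   mean).
#' @export
bin_methylation <- function(pileup, params = rdna_params(),
                            ref_length = NULL) {
  p <- pileup[pileup$coverage >= params$min_site_coverage, , drop = FALSE]
  bs <- params$bin_size
  bins <- if (!is.null(ref_length)) {
    seq(0L, (as.integer(ref_length) - 1L) %/% bs * bs, by = bs)
  } else if (nrow(p) > 0) {
    seq(0L, max(p$start) %/% bs * bs, by = bs)
  } else {
    integer(0)
  }
  out <- lapply(bins, function(b) {
    pi <- p[p$start >= b & p$start < b + bs, , drop = FALSE]
    cov <- sum(pi$coverage); mod <- sum(pi$modified)
    data.frame(bin_start = b, bin_end = b + bs, n_sites = nrow(pi),
               coverage = cov, modified = mod,
               mean = if (nrow(pi) > 0) mod / cov else NA_real_)
  })
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(bin_start = integer(), bin_end = integer(),
               n_sites = integer(), coverage = numeric(),
               modified = numeric(), mean = numeric())
  rownames(res) <- NULL
  res
}

#' Per-read mean methylation over a region
#'
#' Reads must cover more than `min_read_ref_coverage` of the reference at
#' more than `min_read_identity` identity; the globally least-confident
#' `confidence_drop_fraction` of methylation calls (across all retained
#' reads) is removed; each retained read's mean methylation state over the
#' region's CpGs is returned.
#'
#' @param reads data.frame with `read_id, ref_cov_fraction, identity`.
#' @param calls data.frame with `read_id, pos, conf, state` (state 0/1).
#' @param region c(start, end), 0-based half-open on the reference unit.
#' @param params An [rdna_params()].
#' @return data.frame(read_id, mean, n_calls).
#' @export
per_read_region_methylation <- function(reads, calls, region,
                                        params = rdna_params()) {
  keep_reads <- reads$read_id[
    reads$ref_cov_fraction > params$min_read_ref_coverage &
      reads$identity > params$min_read_identity]
  k <- calls[calls$read_id %in% keep_reads, , drop = FALSE]
  if (nrow(k) > 0 && params$confidence_drop_fraction > 0) {
    n_drop <- floor(params$confidence_drop_fraction * nrow(k))
    if (n_drop > 0) {
      drop_idx <- order(k$conf)[seq_len(n_drop)]
      k <- k[-drop_idx, , drop = FALSE]
    }
  }
  k <- k[k$pos >= region[1] & k$pos < region[2], , drop = FALSE]
  if (nrow(k) == 0) {
    return(data.frame(read_id = character(), mean = numeric(),
                      n_calls = integer(), stringsAsFactors = FALSE))
  }
  agg <- stats::aggregate(state ~ read_id, data = k, FUN = mean)
  cnt <- stats::aggregate(state ~ read_id, data = k, FUN = length)
  res <- data.frame(read_id = agg$read_id, mean = agg$state,
                    n_calls = cnt$state, stringsAsFactors = FALSE)
  res[order(res$read_id), , drop = FALSE]
}

#' Variant density per rDNA region
#'
#' Variants below the quality threshold or the allele-frequency threshold
#' are removed; density is retained variants per kilobase of region.
#'
#' @param variants data.frame with `pos0, quality, af`.
#' @param regions data.frame(region, start, end) such as [rdna_regions()].
#' @param params An [rdna_params()].
#' @return data.frame(region, length_bp, n_variants, density_per_kb).
#' @export
variant_density <- function(variants, regions, params = rdna_params()) {
  if (any(regions$end <= regions$start)) {
    stop("region with non-positive length")
  }
  v <- variants[variants$quality >= params$min_variant_quality &
                  variants$af >= params$min_allele_frequency, ,
                drop = FALSE]
  out <- lapply(seq_len(nrow(regions)), function(i) {
    r <- regions[i, ]
    n <- sum(v$pos0 >= r$start & v$pos0 < r$end)
    data.frame(region = r$region, length_bp = r$end - r$start,
               n_variants = n,
               density_per_kb = n / ((r$end - r$start) / 1000),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
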