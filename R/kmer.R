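# K-mer count tables and copy number estimation.
#
# Copy number of a tandem-repeat feature is estimated as the ratio of the
# median read count of the feature's k-mers to the median read count of
# k-mers from GC-matched background bins on a chosen chromosome, after
# removing unobserved k-mers and outliers and dividing multi-copy k-mers by
# their genomic multiplicity. Distal-junction style copy number instead
# normalises the feature k-mer median to the diploid peak of the genome-wide
# k-mer count spectrum.

#' Canonical (strand-collapsed) k-mer representation
#'
#' @param kmers Character vector of k-mers.
#' @return Lexicographic minimum of each k-mer and its reverse complement.
#' @export
canonical_kmer <- function(kmers) {
  rc <- revcomp(kmers)
  ifelse(kmers <= rc, kmers, rc)
}

extract_kmers <- function(seqs, k) {
  seqs <- as.character(seqs)
  out <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    n <- nchar(s)
    if (n < k) next
    out[[i]] <- substring(s, 1:(n - k + 1L), k:n)
  }
  km <- unlist(out, use.names = FALSE)
  if (is.null(km)) return(character())
  km[!grepl("[^ACGT]", km)]
}

#' Count canonical k-mers in a sequence set
#'
#' @param seqs Named character vector, `DNAStringSet`, or single string.
#' @param k K-mer size (>= 11 for genomic applications; smaller values are
#'   allowed for toy examples).
#' @return A `kmer_count_table`: data.table with columns `kmer` and `mult`
#'   (multiplicity in `seqs`) and `count` (0; fill via simulation or lookup).
#' @export
count_kmers <- function(seqs, k) {
  km <- canonical_kmer(extract_kmers(seqs, k))
  dt <- data.table::data.table(kmer = km)
  tab <- dt[, .(mult = .N), by = kmer]
  tab[, count := 0]
  attr(tab, "k") <- as.integer(k)
  class(tab) <- c("kmer_count_table", class(tab))
  tab[]
}

#' Simulate read k-mer counts over a genome
#'
#' Every canonical k-mer of the supplied sequences receives an observed
#' count drawn from Poisson(depth x multiplicity), i.e. homogeneous
#' per-occurrence coverage. `depth` is the mean coverage of a k-mer that
#' occurs once in the supplied sequence set, so a locus present on both
#' haplotypes of a diploid genome peaks at 2 x depth.
#'
#' @param genome A `diploid_genome`, named character vector, or
#'   `DNAStringSet`.
#' @param k K-mer size (>= 11).
#' @param depth Per-occurrence mean coverage (>= 0).
#' @param seed Optional integer seed.
#' @return A `kmer_count_table` with simulated `count`s and genomic `mult`.
#' @export
simulate_kmer_coverage <- function(genome, k, depth, seed = NULL) {
  if (k < 11) stop("k must be >= 11 for genome-scale k-mer coverage")
  if (depth < 0) stop("depth must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  seqs <- genome_sequences(genome)
  tab <- count_kmers(seqs, k)
  tab[, count := rpois(.N, depth * mult)]
  tab[]
}

genome_sequences <- function(genome) {
  if (inherits(genome, "diploid_genome")) {
    c(genome$sequences$hap1, genome$sequences$hap2)
  } else if (inherits(genome, "DNAStringSet")) {
    setNames(as.character(genome), names(genome))
  } else {
    setNames(as.character(genome), names(genome))
  }
}

#' Build a k-mer count table for a target feature
#'
#' Collects the canonical k-mers of `target`, looks up their observed read
#' counts in `observed` (0 when absent), and records each k-mer's reference
#' multiplicity, counted in `reference` when given and within `target`
#' otherwise. With `exclusive = TRUE`, k-mers occurring in the reference
#' outside the target (reference multiplicity exceeding target multiplicity)
#' are marked with their full reference multiplicity so that the filter can
#' drop or rescale them.
#'
#' @param target Sequence(s) defining the feature or bin set.
#' @param observed A `kmer_count_table` of observed read counts (e.g. from
#'   [simulate_kmer_coverage()]) or NULL for all-zero counts.
#' @param reference Optional sequence set in which multiplicity is counted.
#' @param k K-mer size; defaults to the `k` attribute of `observed`.
#' @return A `kmer_count_table` for the target's k-mers.
#' @export
kmer_table <- function(target, observed = NULL, reference = NULL, k = NULL) {
  if (is.null(k)) k <- attr(observed, "k")
  if (is.null(k)) stop("k must be given when `observed` carries no k")
  tab <- count_kmers(target, k)
  if (!is.null(reference)) {
    ref_tab <- count_kmers(reference, k)
    tab[, mult := NULL]
    tab <- merge(tab, ref_tab[, .(kmer, mult = mult)],
                 by = "kmer", all.x = TRUE)
    tab[is.na(mult), mult := 0L]
  }
  if (!is.null(observed)) {
    tab[, count := NULL]
    tab <- merge(tab, observed[, .(kmer, count)], by = "kmer", all.x = TRUE)
    tab[is.na(count), count := 0]
  }
  attr(tab, "k") <- as.integer(k)
  class(tab) <- c("kmer_count_table", class(tab))
  tab[]
}

#' Parameters for GC-matched bin copy number estimation
#'
#' @param k K-mer size.
#' @param bin_size Background bin width in bp.
#' @param sd_cutoff Outlier cutoff in standard deviations above the mean.
#' @param gc_tolerance Maximum absolute GC-fraction difference between a bin
#'   and the feature.
#' @param background_chromosome Name of the background chromosome.
#' @param ploidy_divisor Divide the median ratio by this (2 when the
#'   background chromosome is haploid in the sample, e.g. after a
#'   chromosome-arm loss in a tumor).
#' @return list of class `conkord_params`.
#' @export
conkord_params <- function(k = 31L, bin_size = 2000L, sd_cutoff = 3,
                           gc_tolerance = 0.02,
                           background_chromosome = NULL,
                           ploidy_divisor = 1) {
  stopifnot(k >= 11, bin_size >= k, sd_cutoff > 0,
            gc_tolerance >= 0, gc_tolerance <= 1, ploidy_divisor > 0)
  structure(list(k = as.integer(k), bin_size = as.integer(bin_size),
                 sd_cutoff = sd_cutoff, gc_tolerance = gc_tolerance,
                 background_chromosome = background_chromosome,
                 ploidy_divisor = ploidy_divisor),
            class = "conkord_params")
}

#' Select background bins GC-matched to a feature
#'
#' Tiles the background chromosome into non-overlapping complete windows of
#' `bin_size` bp and keeps those whose GC fraction is within `gc_tolerance`
#' of the feature's GC fraction.
#'
#' @param reference Named character vector (or `DNAStringSet`) containing the
#'   background chromosome.
#' @param feature Feature sequence (character string).
#' @param params A [conkord_params()] object.
#' @return data.frame with `chrom, start, end, gc, seq`.
#' @export
select_matched_bins <- function(reference, feature, params = conkord_params()) {
  seqs <- genome_sequences(reference)
  chrom <- params$background_chromosome
  if (is.null(chrom)) {
    if (length(seqs) != 1) {
      stop("background_chromosome must name one of the reference sequences")
    }
    chrom <- names(seqs)[1]
    if (is.null(chrom)) chrom <- "background"
  } else if (!chrom %in% names(seqs)) {
    stop("background chromosome '", chrom, "' not found in reference")
  }
  s <- unname(seqs[[if (chrom %in% names(seqs)) chrom else 1L]])
  n_bins <- nchar(s) %/% params$bin_size
  if (n_bins == 0) {
    stop("background chromosome shorter than one bin (", params$bin_size,
         " bp)")
  }
  starts <- (seq_len(n_bins) - 1L) * params$bin_size
  bin_seq <- substring(s, starts + 1L, starts + params$bin_size)
  gc <- vapply(bin_seq, gc_fraction, numeric(1), USE.NAMES = FALSE)
  fgc <- gc_fraction(feature)
  keep <- abs(gc - fgc) <= params$gc_tolerance
  if (!any(keep)) {
    stop("no background bin within gc_tolerance = ", params$gc_tolerance,
         " of the feature GC (", round(fgc, 3),
         "); widen gc_tolerance or choose another background chromosome")
  }
  data.frame(chrom = chrom, start = starts[keep],
             end = starts[keep] + params$bin_size,
             gc = gc[keep], seq = bin_seq[keep], stringsAsFactors = FALSE)
}

#' Filter a k-mer count table before copy number estimation
#'
#' Removes k-mers that were never observed, k-mers whose count exceeds the
#' set mean by more than `sd_cutoff` sample standard deviations (single
#' pass), and k-mers with reference multiplicity 0 (absent from the
#' reference feature/bin set); the counts of k-mers with multiplicity > 1
#' are divided by that multiplicity. When all counts are equal the SD is 0
#' and the outlier rule removes nothing (the inequality is strict).
#'
#' @param table A `kmer_count_table`.
#' @param params A [conkord_params()] object (only `sd_cutoff` is used).
#' @return Filtered `kmer_count_table` with attributes `n_used` and
#'   `n_filtered`.
#' @export
filter_kmer_counts <- function(table, params = conkord_params()) {
  if (nrow(table) == 0) stop("empty k-mer count table")
  k <- attr(table, "k")
  n0 <- nrow(table)
  tab <- table[count > 0 & mult > 0]
  if (nrow(tab) > 0) {
    mu <- mean(tab$count)
    sdev <- if (nrow(tab) > 1) sd(tab$count) else 0
    tab <- tab[count <= mu + params$sd_cutoff * sdev]
  }
  if (nrow(tab) == 0) {
    stop("all k-mers removed by filtering; counts may be absent or aberrant")
  }
  tab <- data.table::copy(tab)
  tab[mult > 1, count := count / mult]
  attr(tab, "k") <- k
  attr(tab, "n_used") <- nrow(tab)
  attr(tab, "n_filtered") <- n0 - nrow(tab)
  class(tab) <- c("kmer_count_table", class(data.table::data.table()))
  tab[]
}

new_copy_number_estimate <- function(value, feature_median, bin_median,
                                     n_used, n_filtered, method) {
  structure(list(value = value, feature_kmer_median = feature_median,
                 bin_kmer_median = bin_median, n_kmers_used = n_used,
                 n_kmers_filtered = n_filtered, method = method),
            class = "copy_number_estimate")
}

#' @export
print.copy_number_estimate <- function(x, ...) {
  cat(sprintf(
    "copy number estimate: %.3f (%s)\n  feature k-mer median: %.1f\n  %s median: %.1f\n  k-mers used: %d (filtered: %d)\n",
    x$value, x$method, x$feature_kmer_median,
    if (x$method == "diploid-peak") "diploid peak" else "bin k-mer",
    x$bin_kmer_median, x$n_kmers_used, x$n_kmers_filtered))
  invisible(x)
}

#' Estimate feature copy number from filtered k-mer tables
#'
#' `value = median(feature counts) / median(bin counts) / ploidy_divisor`.
#' Both tables should have been passed through [filter_kmer_counts()].
#'
#' @param feature_counts,bin_counts Filtered `kmer_count_table`s.
#' @param params A [conkord_params()] object.
#' @return A `copy_number_estimate`.
#' @export
estimate_copy_number <- function(feature_counts, bin_counts,
                                 params = conkord_params()) {
  fm <- median(feature_counts$count)
  bm <- median(bin_counts$count)
  if (bm == 0) stop("bin k-mer median is 0; cannot normalise")
  n_used <- sum(attr(feature_counts, "n_used") %||% nrow(feature_counts),
                attr(bin_counts, "n_used") %||% nrow(bin_counts))
  n_filt <- sum(attr(feature_counts, "n_filtered") %||% 0L,
                attr(bin_counts, "n_filtered") %||% 0L)
  new_copy_number_estimate((fm / bm) / params$ploidy_divisor, fm, bm,
                           n_used, n_filt, "gc-matched-bins")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Estimate copy number by diploid-peak normalisation
#'
#' For features whose k-mers are expected once per copy and shared across
#' copies (distal-junction style), the estimate is
#' `2 x median(feature counts) / diploid_peak`, where the diploid peak is
#' the modal k-mer count of the genome-wide spectrum after excluding counts
#' below `min_peak_count` (which removes the error/low-copy tail).
#'
#' @param dj_counts A `kmer_count_table` (or numeric vector) of feature
#'   k-mer counts.
#' @param genome_spectrum Integer vector of genome-wide k-mer counts (one
#'   entry per distinct k-mer), or a `kmer_count_table`.
#' @param min_peak_count Counts below this are excluded before peak
#'   detection; default depth-agnostic value is a quarter of the spectrum
#'   median.
#' @return A `copy_number_estimate` with method `"diploid-peak"`.
#' @export
estimate_dj_copy_number <- function(dj_counts, genome_spectrum,
                                    min_peak_count = NULL) {
  cnt <- if (inherits(dj_counts, "kmer_count_table")) dj_counts$count
         else as.numeric(dj_counts)
  spec <- if (inherits(genome_spectrum, "kmer_count_table")) {
    genome_spectrum$count
  } else {
    as.numeric(genome_spectrum)
  }
  if (is.null(min_peak_count)) min_peak_count <- median(spec) / 4
  spec <- spec[spec >= min_peak_count]
  if (length(spec) == 0) {
    stop("no spectrum counts at or above min_peak_count = ", min_peak_count,
         "; no detectable diploid peak")
  }
  tab <- tabulate(as.integer(round(spec)))
  peak <- which.max(tab)
  if (tab[peak] == 0 || peak == 0) stop("no detectable diploid peak")
  fm <- median(cnt)
  new_copy_number_estimate(2 * fm / peak, fm, peak, length(cnt), 0L,
                           "diploid-peak")
}
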