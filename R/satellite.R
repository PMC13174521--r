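# Satellite array calling and SV-size periodicity.
#
# Candidate satellite motifs are screened by whether their length is close
# to an integer multiple of the base monomer (different multiple bounds for
# alpha-satellite and HSat1A classes); monomer hits are merged into arrays
# when close enough, small arrays dropped, and array coordinates extended
# by a fixed slop. Somatic SV sizes inside alpha-satellite arrays are
# tested for periodicity at candidate periods, with a largest-near-optimal
# tie-break because every divisor of the true period scores equally well.

#' Parameters for satellite motif filtering and array calling
#'
#' @param base_monomer Base monomer length in bp used by the length filter.
#' @param length_tolerance Maximum relative deviation from `n x
#'   base_monomer`.
#' @param max_n_alpha,max_n_hsat1a Largest allowed monomer multiple per
#'   class.
#' @param max_seq_div Maximum monomer-hit sequence divergence.
#' @param merge_distance Maximum gap (bp, inclusive) between hit clusters
#'   merged into one array.
#' @param min_array Minimum merged core span (bp) to keep an array.
#' @param slop Extension (bp) applied to each side of the core, clipped to
#'   the sequence bounds.
#' @param min_chrom_align_pct Minimum aligned fraction required to assign a
#'   chromosome name.
#' @param kmer_len,kmer_min_occurrences Naive repetitive k-mer prefilter
#'   parameters (k-mers of length `kmer_len` occurring more than
#'   `kmer_min_occurrences` times).
#' @return list of class `satellite_params`.
#' @export
satellite_params <- function(base_monomer = 170L, length_tolerance = 0.02,
                             max_n_alpha = 5L, max_n_hsat1a = 42L,
                             max_seq_div = 0.30, merge_distance = 100000L,
                             min_array = 30000L, slop = 1000000L,
                             min_chrom_align_pct = 0.05,
                             kmer_len = 171L, kmer_min_occurrences = 10L) {
  stopifnot(base_monomer > 0, length_tolerance >= 0, length_tolerance <= 1,
            max_n_alpha >= 1, max_n_hsat1a >= max_n_alpha,
            max_seq_div >= 0, max_seq_div <= 1,
            merge_distance >= 0, min_array >= 0, slop >= 0,
            min_chrom_align_pct >= 0, min_chrom_align_pct <= 1)
  structure(list(base_monomer = as.integer(base_monomer),
                 length_tolerance = length_tolerance,
                 max_n_alpha = as.integer(max_n_alpha),
                 max_n_hsat1a = as.integer(max_n_hsat1a),
                 max_seq_div = max_seq_div,
                 merge_distance = as.integer(merge_distance),
                 min_array = as.integer(min_array),
                 slop = as.integer(slop),
                 min_chrom_align_pct = min_chrom_align_pct,
                 kmer_len = as.integer(kmer_len),
                 kmer_min_occurrences = as.integer(kmer_min_occurrences)),
            class = "satellite_params")
}

#' Does a candidate motif length pass the monomer-multiple filter?
#'
#' A motif passes when some integer `n` between 1 and the class maximum
#' satisfies `|length - n * base_monomer| / (n * base_monomer) <=
#' length_tolerance`. Motifs lacking a monomer annotation always fail.
#'
#' @param length Motif length(s) in bp (vectorised).
#' @param satellite_class `"alpha"` or `"hsat1a"`.
#' @param params A [satellite_params()].
#' @param has_monomer_annotation Logical (vectorised): does a tandem-repeat
#'   monomer annotation support the motif?
#' @return Logical vector.
#' @export
motif_passes_length_filter <- function(length,
                                       satellite_class = c("alpha", "hsat1a"),
                                       params = satellite_params(),
                                       has_monomer_annotation = TRUE) {
  satellite_class <- match.arg(satellite_class)
  if (any(length <= 0)) stop("motif length must be positive")
  n_max <- if (satellite_class == "alpha") params$max_n_alpha
           else params$max_n_hsat1a
  has_monomer_annotation <- rep_len(has_monomer_annotation, length(length))
  vapply(seq_along(length), function(i) {
    if (!has_monomer_annotation[i]) return(FALSE)
    L <- length[i]
    n <- pmax(1L, pmin(n_max, round(L / params$base_monomer)))
    cand <- unique(pmin(n_max, pmax(1L, c(n - 1L, n, n + 1L))))
    any(abs(L - cand * params$base_monomer) /
          (cand * params$base_monomer) <= params$length_tolerance)
  }, TRUE)
}

#' Call satellite arrays from monomer hits
#'
#' Hits above the divergence cutoff are discarded; remaining hits are
#' merged transitively while the gap between clusters is at most
#' `merge_distance`; merged cores shorter than `min_array` are dropped; the
#' slopped interval extends the core by `slop` on each side, clipped to the
#' sequence bounds.
#'
#' @param hits data.frame(chrom, start, end, divergence) of monomer hits
#'   (0-based half-open).
#' @param params A [satellite_params()].
#' @param seqlens Optional named vector of sequence lengths for slop
#'   clipping.
#' @param satellite_class Class label attached to the output regions.
#' @return data.frame(chrom, start, end, slop_start, slop_end, n_monomers,
#'   satellite_class).
#' @export
call_satellite_regions <- function(hits, params = satellite_params(),
                                   seqlens = NULL,
                                   satellite_class = "alpha") {
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), slop_start = integer(),
                      slop_end = integer(), n_monomers = integer(),
                      satellite_class = character(),
                      stringsAsFactors = FALSE)
  if (nrow(hits) == 0) return(empty)
  if (!"divergence" %in% names(hits)) hits$divergence <- 0
  hits <- hits[hits$divergence <= params$max_seq_div, , drop = FALSE]
  if (nrow(hits) == 0) return(empty)
  hits <- hits[order(hits$chrom, hits$start, hits$end), , drop = FALSE]
  out <- list()
  for (chrom in unique(hits$chrom)) {
    hi <- hits[hits$chrom == chrom, , drop = FALSE]
    cs <- hi$start[1]; ce <- hi$end[1]; nmono <- 1L
    flush <- function(cs, ce, nmono) {
      if (ce - cs < params$min_array) return(NULL)
      ss <- max(0L, cs - params$slop)
      se <- ce + params$slop
      if (!is.null(seqlens) && chrom %in% names(seqlens)) {
        se <- min(se, as.integer(seqlens[[chrom]]))
      }
      data.frame(chrom = chrom, start = cs, end = ce,
                 slop_start = ss, slop_end = se, n_monomers = nmono,
                 satellite_class = satellite_class,
                 stringsAsFactors = FALSE)
    }
    for (i in seq_len(nrow(hi))[-1]) {
      if (hi$start[i] - ce <= params$merge_distance) {
        ce <- max(ce, hi$end[i]); nmono <- nmono + 1L
      } else {
        out[[length(out) + 1L]] <- flush(cs, ce, nmono)
        cs <- hi$start[i]; ce <- hi$end[i]; nmono <- 1L
      }
    }
    out[[length(out) + 1L]] <- flush(cs, ce, nmono)
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (length(out) == 0) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Assign a chromosome name from alignment fractions
#'
#' Returns the chromosome with the largest aligned fraction provided it
#' meets the minimum; ties or sub-threshold maxima give `"unassigned"`
#' (a name is never fabricated).
#'
#' @param fractions Named numeric vector: chromosome -> aligned fraction.
#' @param params A [satellite_params()] (uses `min_chrom_align_pct`).
#' @return Chromosome name or `"unassigned"`.
#' @export
assign_region_chromosome <- function(fractions, params = satellite_params()) {
  if (length(fractions) == 0) return("unassigned")
  stopifnot(all(fractions >= 0), all(fractions <= 1))
  top <- max(fractions)
  if (top < params$min_chrom_align_pct) return("unassigned")
  winners <- names(fractions)[fractions == top]
  if (length(winners) != 1) return("unassigned")
  winners
}

#' Estimate the dominant period of SV sizes
#'
#' For each integer candidate period `p`, the deviation score is the mean
#' over sizes of `min(s mod p, p - s mod p) / p`. The estimate is the
#' largest `p` whose score is within `tolerance` of the minimum score: any
#' divisor of the true period also scores 0, so the largest near-optimal
#' period is the non-degenerate answer.
#'
#' @param sv_sizes Integer vector of SV sizes in bp (absolute values used);
#'   sizes of 5 kbp and above are excluded before fitting.
#' @param range Candidate period range `c(min_p, max_p)`.
#' @param tolerance Absolute score tolerance for the tie-break.
#' @param max_size Sizes at or above this are excluded (default 5000).
#' @return list(period, score, scores = data.frame(period, score)).
#' @export
estimate_sv_periodicity <- function(sv_sizes, range = c(50L, 500L),
                                    tolerance = 1e-6, max_size = 5000L) {
  s <- abs(as.numeric(sv_sizes))
  s <- s[s > 0 & s < max_size]
  if (length(s) < 3) {
    stop("at least 3 SV sizes below ", max_size, " bp are required")
  }
  periods <- seq(as.integer(range[1]), as.integer(range[2]))
  scores <- vapply(periods, function(p) {
    r <- s %% p
    mean(pmin(r, p - r)) / p
  }, 1)
  best <- min(scores)
  p_hat <- max(periods[scores <= best + tolerance])
  list(period = p_hat, score = scores[periods == p_hat],
       scores = data.frame(period = periods, score = scores))
}

#' Naive repetitive k-mer prefilter
#'
#' Flags sequences containing k-mers of length `kmer_len` occurring more
#' than `kmer_min_occurrences` times in the sequence set, a cheap screen
#' for tandem-repeat-dense regions on synthetic data.
#'
#' @param seqs Named character vector of sequences.
#' @param params A [satellite_params()].
#' @return data.frame(kmer, count) of over-represented k-mers.
#' @export
repetitive_kmers <- function(seqs, params = satellite_params()) {
  tab <- count_kmers(seqs, params$kmer_len)
  res <- tab[mult > params$kmer_min_occurrences, .(kmer, count = mult)]
  as.data.frame(res)
}
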