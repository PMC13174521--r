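# Chromosome assignment of unplaced contigs.
#
# Each contig is aligned to a panel of haplotype assemblies. Per
# (haplotype, chromosome) the score is the product of the query coverage
# fraction (merged alignment intervals / contig length) and the
# alignment-length-weighted mean gap-compressed identity. A chromosome is
# assigned when almost all haplotypes rank it first and the mean score is
# high enough.

#' Assignment thresholds
#' @param unanimity_min Minimum fraction of haplotypes whose top-scoring
#'   chromosome must equal the panel-wide top chromosome.
#' @param score_min Minimum mean score across haplotypes.
#' @return list of class `assign_params`.
#' @export
assign_params <- function(unanimity_min = 0.95, score_min = 0.60) {
  stopifnot(unanimity_min >= 0, unanimity_min <= 1,
            score_min >= 0, score_min <= 1)
  structure(list(unanimity_min = unanimity_min, score_min = score_min),
            class = "assign_params")
}

#' Score a contig against panel haplotypes and chromosomes
#'
#' @param alignments data.frame with `haplotype, chromosome, qstart, qend,
#'   alen, gci` for one contig (query coordinates 0-based half-open,
#'   `gci` = gap-compressed identity per alignment).
#' @param contig_length Contig length in bp.
#' @return data.frame(haplotype, chromosome, coverage, identity, score).
#' @export
score_contig <- function(alignments, contig_length) {
  if (contig_length <= 0) stop("contig length must be positive")
  a <- alignments
  if (nrow(a) == 0) {
    return(data.frame(haplotype = character(), chromosome = character(),
                      coverage = numeric(), identity = numeric(),
                      score = numeric(), stringsAsFactors = FALSE))
  }
  stopifnot(all(a$gci >= 0), all(a$gci <= 1),
            all(a$qstart >= 0), all(a$qend <= contig_length))
  keys <- unique(a[, c("haplotype", "chromosome")])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    ai <- a[a$haplotype == keys$haplotype[i] &
              a$chromosome == keys$chromosome[i], , drop = FALSE]
    cov_bp <- interval_bp(data.frame(chrom = "q", start = ai$qstart,
                                     end = ai$qend))
    coverage <- cov_bp / contig_length
    identity <- sum(ai$alen * ai$gci) / sum(ai$alen)
    data.frame(haplotype = keys$haplotype[i],
               chromosome = keys$chromosome[i],
               coverage = coverage, identity = identity,
               score = coverage * identity, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Assign a contig to a chromosome from its panel scores
#'
#' Chromosomes are ranked by their mean score across all `haplotypes`
#' (absent cells score 0). A haplotype "agrees" when its own argmax
#' chromosome equals the top-ranked one; haplotypes with no alignments (or
#' tied argmax) do not agree but stay in the denominator. Assignment
#' requires agreement fraction >= `unanimity_min` and top mean score >=
#' `score_min`.
#'
#' @param scores data.frame(haplotype, chromosome, score) from
#'   [score_contig()].
#' @param haplotypes Character vector of all panel haplotypes (defines the
#'   unanimity denominator).
#' @param params An [assign_params()].
#' @return list(chromosome = name or "unassigned", mean_score, unanimity).
#' @export
assign_contig <- function(scores, haplotypes, params = assign_params()) {
  chroms <- unique(scores$chromosome)
  n_hap <- length(haplotypes)
  if (length(chroms) == 0 || n_hap == 0) {
    return(list(chromosome = "unassigned", mean_score = 0, unanimity = 0))
  }
  grid <- matrix(0, nrow = n_hap, ncol = length(chroms),
                 dimnames = list(haplotypes, chroms))
  for (i in seq_len(nrow(scores))) {
    if (scores$haplotype[i] %in% haplotypes) {
      grid[scores$haplotype[i], scores$chromosome[i]] <- scores$score[i]
    }
  }
  mean_scores <- colMeans(grid)
  top <- names(mean_scores)[which.max(mean_scores)]
  agrees <- vapply(haplotypes, function(h) {
    row <- setNames(grid[h, ], colnames(grid))
    if (all(row == 0)) return(FALSE)
    winners <- names(row)[row == max(row)]
    length(winners) == 1 && winners == top
  }, TRUE)
  unanimity <- mean(agrees)
  ok <- unanimity >= params$unanimity_min &&
    mean_scores[[top]] >= params$score_min
  list(chromosome = if (ok) top else "unassigned",
       mean_score = unname(mean_scores[[top]]), unanimity = unanimity)
}

#' Score and assign many contigs from a tabulated alignment set
#'
#' @param alignments data.frame with `contig, haplotype, chromosome,
#'   qstart, qend, alen, gci` (e.g. tabulated from PAF via [read_paf()] and
#'   [gap_compressed_identity()]).
#' @param contig_lengths Named vector of contig lengths.
#' @param haplotypes Panel haplotype names; defaults to those present.
#' @param params An [assign_params()].
#' @return data.frame(contig, chromosome, mean_score, unanimity, status).
#' @export
assign_contigs <- function(alignments, contig_lengths, haplotypes = NULL,
                           params = assign_params()) {
  if (is.null(haplotypes)) haplotypes <- unique(alignments$haplotype)
  out <- lapply(names(contig_lengths), function(ctg) {
    sc <- score_contig(
      alignments[alignments$contig == ctg, , drop = FALSE],
      contig_lengths[[ctg]])
    res <- assign_contig(sc, haplotypes, params)
    data.frame(contig = ctg, chromosome = res$chromosome,
               mean_score = res$mean_score, unanimity = res$unanimity,
               status = if (res$chromosome == "unassigned") "unassigned"
                        else "assigned",
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
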