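# Simulators for read support and methylation pileups.
#
# Read support follows the mapping geometry of a diploid donor-specific
# assembly: reads from each haplotype map to their own haplotype contig, so
# at a somatic site the variant allele fraction among reads covering the
# carrier haplotype equals the cell fraction (not half of it). Short reads
# are additionally mapped per haplotype, mirroring the separate-haplotype
# alignment used for technologies that cannot always be assigned uniquely.

#' Define a sequencing technology profile
#'
#' @param name Technology label.
#' @param depth Mean per-haplotype coverage at a locus.
#' @param base_error Per-read substitution error rate.
#' @param indel_error_by_homopolymer Named numeric vector mapping
#'   homopolymer length to the per-read 1 bp indel error rate; lengths above
#'   the largest name reuse its rate, lengths below the smallest use
#'   `base_error`.
#' @param mappable_in_duplications Can reads be assigned uniquely inside
#'   near-identical somatic duplications?
#' @param tech_class `"short"` or `"long"`.
#' @param per_haplotype Also produce per-haplotype alignments?
#' @return list of class `tech_profile`.
#' @export
tech_profile <- function(name, depth, base_error,
                         indel_error_by_homopolymer = c(`6` = 0.001),
                         mappable_in_duplications = TRUE,
                         tech_class = c("short", "long"),
                         per_haplotype = FALSE) {
  tech_class <- match.arg(tech_class)
  stopifnot(depth > 0, base_error >= 0, base_error <= 1,
            all(indel_error_by_homopolymer >= 0),
            all(indel_error_by_homopolymer <= 1))
  structure(list(name = name, depth = depth, base_error = base_error,
                 indel_error_by_homopolymer = indel_error_by_homopolymer,
                 mappable_in_duplications = mappable_in_duplications,
                 tech_class = tech_class, per_haplotype = per_haplotype),
            class = "tech_profile")
}

#' Default technology panel
#'
#' A short-accurate technology (low error, mapped combined and per
#' haplotype, not mappable in somatic duplications), a HiFi-like long
#' technology, and an ONT-like long technology with elevated homopolymer
#' indel error.
#' @param depth Per-haplotype coverage shared by all three.
#' @return Named list of [tech_profile()]s.
#' @export
default_tech_profiles <- function(depth = 30) {
  list(
    short_accurate = tech_profile(
      "short_accurate", depth, 1e-4,
      indel_error_by_homopolymer = c(`6` = 5e-4, `12` = 2e-3, `20` = 5e-3),
      mappable_in_duplications = FALSE, tech_class = "short",
      per_haplotype = TRUE),
    hifi = tech_profile(
      "hifi", depth, 1e-3,
      indel_error_by_homopolymer = c(`6` = 5e-3, `12` = 0.02, `20` = 0.05),
      mappable_in_duplications = TRUE, tech_class = "long"),
    ont = tech_profile(
      "ont", depth, 5e-3,
      indel_error_by_homopolymer = c(`6` = 0.02, `12` = 0.08, `20` = 0.15),
      mappable_in_duplications = TRUE, tech_class = "long")
  )
}

hp_indel_error <- function(profile, hp_len) {
  tab <- profile$indel_error_by_homopolymer
  lens <- as.numeric(names(tab))
  if (is.na(hp_len) || hp_len < min(lens)) return(profile$base_error)
  tab[[max(which(lens <= hp_len))]]
}

#' Simulate per-variant, per-technology read support tables
#'
#' For every truth variant and technology, tumor alt counts are Binomial in
#' the haplotype coverage with success probability
#' `cf (1 - e) + (1 - cf) e` (halved inside somatic duplications, where
#' reads from both copies pile together), and normal alt counts are
#' Binomial with the error rate alone. Technologies with
#' `per_haplotype = TRUE` additionally emit one row per haplotype.
#'
#' @param truth Truth data.frame from [derive_tumor_genome()] (columns used:
#'   id, hap, type, size, context, cell_fraction; optional
#'   in_somatic_duplication).
#' @param profiles List of [tech_profile()]s.
#' @param genome Optional `diploid_genome` used to annotate homopolymer
#'   tract lengths from the ledger.
#' @param seed Optional integer seed.
#' @return data.frame of `support_record` rows: variant_id, technology,
#'   tech_class, mapping, tumor_alt, tumor_cov, normal_alt, normal_cov,
#'   homopolymer_len, ditr_len, indel_size, in_somatic_duplication, low_mq,
#'   variant_hap.
#' @export
simulate_support_tables <- function(truth, profiles, genome = NULL,
                                    seed = NULL) {
  if (length(profiles) == 0) stop("at least one technology profile required")
  if (!is.null(seed)) set.seed(seed)
  hp_len_of <- function(i) {
    if (truth$context[i] != "homopolymer") return(0L)
    if (is.null(genome)) return(8L)
    led <- genome$ledger
    hit <- led[led$class == "homopolymer" & led$chrom == truth$chrom[i] &
                 led$start - 1L <= truth$pos0[i] &
                 led$end > truth$pos0[i], , drop = FALSE]
    if (nrow(hit) == 0) 0L else as.integer(hit$end[1] - hit$start[1])
  }
  tr_len_of <- function(i) {
    if (truth$context[i] != "tr") return(0L)
    if (is.null(genome)) return(12L)
    led <- genome$ledger
    hit <- led[led$class == "tr" & led$chrom == truth$chrom[i] &
                 led$start - 1L <= truth$pos0[i] &
                 led$end > truth$pos0[i], , drop = FALSE]
    if (nrow(hit) == 0) return(0L)
    if (nchar(sub("unit=", "", hit$info[1])) != 2L) return(0L)
    as.integer(hit$end[1] - hit$start[1])
  }
  in_dup <- if ("in_somatic_duplication" %in% names(truth)) {
    truth$in_somatic_duplication
  } else rep(FALSE, nrow(truth))
  rows <- list()
  for (i in seq_len(nrow(truth))) {
    cf <- truth$cell_fraction[i]
    hp <- hp_len_of(i)
    dtr <- tr_len_of(i)
    isz <- if (truth$type[i] %in% c("ins", "del")) truth$size[i] else 0L
    low_mq <- truth$context[i] == "satellite"
    for (pr in profiles) {
      e <- if (isz == 1L && hp > 0) hp_indel_error(pr, hp) else pr$base_error
      dil <- if (in_dup[i]) 0.5 else 1
      p_alt <- (cf * (1 - e) + (1 - cf) * e) * dil
      emit <- function(mapping, p_t, p_n) {
        ct <- rpois(1, pr$depth); cn <- rpois(1, pr$depth)
        data.frame(
          variant_id = truth$id[i], technology = pr$name,
          tech_class = pr$tech_class, mapping = mapping,
          tumor_alt = rbinom(1, ct, p_t), tumor_cov = ct,
          normal_alt = rbinom(1, cn, p_n), normal_cov = cn,
          homopolymer_len = hp, ditr_len = dtr, indel_size = isz,
          in_somatic_duplication = in_dup[i], low_mq = low_mq,
          variant_hap = truth$hap[i], stringsAsFactors = FALSE)
      }
      rows[[length(rows) + 1L]] <- emit("combined", p_alt, e)
      if (isTRUE(pr$per_haplotype)) {
        for (h in 1:2) {
          on_hap <- h == truth$hap[i]
          rows[[length(rows) + 1L]] <-
            emit(paste0("hap", h), if (on_hap) p_alt else e, e)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# ---- methylation ------------------------------------------------------------

rbetabinom <- function(n, size, mean, dispersion) {
  if (dispersion <= 0 || mean <= 0 || mean >= 1) {
    return(rbinom(n, size, mean))
  }
  s <- (1 - dispersion) / dispersion
  p <- rbeta(n, mean * s, (1 - mean) * s)
  rbinom(n, size, p)
}

#' Simulate a bedmethyl-style CpG methylation pileup
#'
#' CpG sites are located in the supplied sequence; each site inside a
#' profiled region receives `coverage` total reads and a modified count
#' drawn Beta-Binomially around the region mean (dispersion is the
#' intra-class correlation; 0 gives pure Binomial sampling).
#'
#' @param seq Character string (e.g. the rDNA unit sequence) or a
#'   `diploid_genome` (uses its rDNA unit).
#' @param region_profiles data.frame(region, start, end, mean, dispersion,
#'   coverage) with 0-based half-open coordinates on `seq`.
#' @param chrom Sequence name for the output.
#' @param seed Optional integer seed.
#' @return data.frame(chrom, start, end, coverage, modified, region).
#' @export
simulate_methylation <- function(seq, region_profiles, chrom = "rdna_unit",
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (inherits(seq, "diploid_genome")) seq <- seq$rdna_unit
  stopifnot(all(region_profiles$mean >= 0), all(region_profiles$mean <= 1))
  cpg <- as.integer(
    Biostrings::start(Biostrings::matchPattern(
      "CG", Biostrings::DNAString(seq)))) - 1L
  out <- list()
  for (i in seq_len(nrow(region_profiles))) {
    rp <- region_profiles[i, ]
    sites <- cpg[cpg >= rp$start & cpg < rp$end]
    if (length(sites) == 0) next
    mod <- rbetabinom(length(sites), rp$coverage, rp$mean, rp$dispersion)
    out[[length(out) + 1L]] <- data.frame(
      chrom = chrom, start = sites, end = sites + 2L,
      coverage = rp$coverage, modified = mod, region = rp$region,
      stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               coverage = integer(), modified = integer(),
               region = character(), stringsAsFactors = FALSE)
  res <- res[order(res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Simulate per-read methylation call records
#'
#' Draws reads from a mixture of methylation states (e.g. a methylated bulk
#' plus a low-methylation population in a tumor), with per-read reference
#' coverage fraction and identity for alignment filtering and a per-call
#' confidence for quantile filtering.
#'
#' @param n_reads Number of reads.
#' @param cpg_pos Integer vector of CpG positions covered by every read.
#' @param components data.frame(weight, mean, dispersion) of the mixture.
#' @param ref_cov_range,identity_range Uniform sampling ranges of the
#'   per-read reference coverage fraction and identity.
#' @param seed Optional integer seed.
#' @return list(reads = data.frame(read_id, ref_cov_fraction, identity,
#'   component), calls = data.frame(read_id, pos, conf, state)).
#' @export
simulate_methylation_reads <- function(n_reads, cpg_pos,
                                       components = data.frame(
                                         weight = 1, mean = 0.8,
                                         dispersion = 0.05),
                                       ref_cov_range = c(0.6, 1.0),
                                       identity_range = c(0.85, 0.99),
                                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  comp <- sample.int(nrow(components), n_reads, replace = TRUE,
                     prob = components$weight)
  reads <- data.frame(
    read_id = sprintf("read%05d", seq_len(n_reads)),
    ref_cov_fraction = runif(n_reads, ref_cov_range[1], ref_cov_range[2]),
    identity = runif(n_reads, identity_range[1], identity_range[2]),
    component = comp, stringsAsFactors = FALSE)
  calls <- list()
  for (i in seq_len(n_reads)) {
    m <- components$mean[comp[i]]
    d <- components$dispersion[comp[i]]
    p <- if (d <= 0 || m <= 0 || m >= 1) m else {
      s <- (1 - d) / d
      rbeta(1, m * s, (1 - m) * s)
    }
    calls[[i]] <- data.frame(
      read_id = reads$read_id[i], pos = cpg_pos,
      conf = runif(length(cpg_pos), 0.5, 1),
      state = rbinom(length(cpg_pos), 1, p), stringsAsFactors = FALSE)
  }
  list(reads = reads, calls = do.call(rbind, calls))
}
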