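# Rule engines for assembly polishing and truncal somatic classification.
#
# Both engines encode fixed evidence thresholds. The polishing filter keeps
# homozygous, well-supported correction candidates and applies
# technology-specific repeat filters (ONT calls are distrusted in long
# homopolymers / dinucleotide TRs, for 1-2 bp indels and at GQ < 10; HiFi
# calls in those repeats yield to a short-accurate small-indel call). The
# truncal classifier requires tumor-but-not-normal read support across all
# applicable technologies, with relaxed tumor thresholds inside somatic
# duplications and a two-regime rule for per-haplotype short-read
# alignments.

#' Build a polishing candidate record
#'
#' @param technology `"short_accurate"`, `"hifi"`, or `"ont"`.
#' @param genotype `"hom"` or `"het"`.
#' @param gq Genotype quality.
#' @param local_coverage,mean_coverage Read depth at the site and the
#'   assembly-wide mean.
#' @param variant_type `"snv"`, `"ins"`, or `"del"`.
#' @param indel_size Indel size in bp (0 for SNVs).
#' @param homopolymer_len,ditr_len Length of the containing homopolymer /
#'   dinucleotide TR (0 when absent).
#' @param element_small_indel_present Does any short-accurate callset have
#'   a 1-4 bp indel call at the site?
#' @return list of class `polish_candidate`.
#' @export
polish_candidate <- function(technology, genotype = "hom", gq = 30,
                             local_coverage = 30, mean_coverage = 30,
                             variant_type = "snv", indel_size = 0L,
                             homopolymer_len = 0L, ditr_len = 0L,
                             element_small_indel_present = FALSE) {
  structure(list(technology = technology, genotype = genotype, gq = gq,
                 local_coverage = local_coverage,
                 mean_coverage = mean_coverage,
                 variant_type = variant_type,
                 indel_size = as.integer(indel_size),
                 homopolymer_len = as.integer(homopolymer_len),
                 ditr_len = as.integer(ditr_len),
                 element_small_indel_present = element_small_indel_present),
            class = "polish_candidate")
}

#' Evaluate a polishing correction candidate
#'
#' Gates, in order: heterozygous calls are rejected; GQ must exceed 4;
#' local coverage must be below twice the mean. ONT calls are additionally
#' rejected in homopolymers longer than 6 bp, dinucleotide TRs longer than
#' 11 bp, for 1 bp and 2 bp indels, and at GQ below 10. HiFi calls in those
#' repeats are rejected when any short-accurate callset has a 1-4 bp indel
#' at the site.
#'
#' @param c A [polish_candidate()] (or plain list with the same fields).
#' @return list(decision = "accept"|"reject", reason = character).
#' @export
evaluate_polish_candidate <- function(c) {
  if (!c$technology %in% c("short_accurate", "hifi", "ont")) {
    stop("unknown technology: ", c$technology)
  }
  rej <- function(reason) list(decision = "reject", reason = reason)
  if (c$genotype != "hom") return(rej("heterozygous"))
  if (c$gq <= 4) return(rej("gq<=4"))
  if (c$local_coverage >= 2 * c$mean_coverage) return(rej("coverage>=2x_mean"))
  in_repeat <- c$homopolymer_len > 6 || c$ditr_len > 11
  if (c$technology == "ont") {
    if (in_repeat) return(rej("ont_repeat"))
    if (c$variant_type %in% c("ins", "del") && c$indel_size %in% 1:2) {
      return(rej("ont_small_indel"))
    }
    if (c$gq < 10) return(rej("ont_gq<10"))
  }
  if (c$technology == "hifi" && in_repeat &&
      isTRUE(c$element_small_indel_present)) {
    return(rej("hifi_repeat_element_indel"))
  }
  list(decision = "accept", reason = "pass")
}

#' Merge accepted polishing edits across technologies
#'
#' Edits are deduplicated by (chrom, pos0, ref, alt), edits within
#' `exclusion_radius` bp of a somatic SV breakpoint are removed, and
#' conflicting overlapping edits are resolved by technology priority
#' short_accurate > hifi > ont.
#'
#' @param accepted data.frame with `chrom, pos0, ref, alt, technology`
#'   (edits already normalized).
#' @param somatic_sv_positions Optional data.frame(chrom, pos0) of SV
#'   breakpoints.
#' @param exclusion_radius Breakpoint exclusion distance in bp.
#' @return data.frame of final edits.
#' @export
merge_polish_edits <- function(accepted, somatic_sv_positions = NULL,
                               exclusion_radius = 5L) {
  if (nrow(accepted) == 0) return(accepted)
  prio <- c(short_accurate = 1L, hifi = 2L, ont = 3L)
  x <- accepted
  x$.prio <- prio[x$technology]
  if (any(is.na(x$.prio))) stop("unknown technology in edit set")
  x <- x[order(x$chrom, x$pos0, x$.prio), , drop = FALSE]
  x <- x[!duplicated(x[, c("chrom", "pos0", "ref", "alt")]), , drop = FALSE]
  if (!is.null(somatic_sv_positions) && nrow(somatic_sv_positions) > 0) {
    keep <- vapply(seq_len(nrow(x)), function(i) {
      sv <- somatic_sv_positions[somatic_sv_positions$chrom == x$chrom[i], ,
                                 drop = FALSE]
      if (nrow(sv) == 0) return(TRUE)
      span <- c(x$pos0[i], x$pos0[i] + nchar(x$ref[i]) - 1L)
      d <- pmin(abs(sv$pos0 - span[1]), abs(sv$pos0 - span[2]))
      inside <- sv$pos0 >= span[1] & sv$pos0 <= span[2]
      min(ifelse(inside, 0L, d)) > exclusion_radius
    }, TRUE)
    x <- x[keep, , drop = FALSE]
  }
  # resolve overlapping conflicting edits by technology priority
  if (nrow(x) > 1) {
    keep <- rep(TRUE, nrow(x))
    for (chrom in unique(x$chrom)) {
      idx <- which(x$chrom == chrom)
      xi <- x[idx, , drop = FALSE]
      s <- xi$pos0; e <- xi$pos0 + nchar(xi$ref)
      ord <- order(xi$.prio, s)  # winners claim their span first
      claimed_s <- integer(0); claimed_e <- integer(0)
      for (j in ord) {
        clash <- any(s[j] < claimed_e & e[j] > claimed_s)
        if (clash) {
          keep[idx[j]] <- FALSE
        } else {
          claimed_s <- c(claimed_s, s[j]); claimed_e <- c(claimed_e, e[j])
        }
      }
    }
    x <- x[keep, , drop = FALSE]
  }
  x <- x[order(x$chrom, x$pos0), , drop = FALSE]
  x$.prio <- NULL
  rownames(x) <- NULL
  x
}

#' Thresholds for truncal somatic classification
#'
#' Defaults follow the benchmark rule set: support in more than 50% of
#' tumor reads but fewer than 10% of normal reads with coverage above 5
#' (30% tumor inside somatic duplications), and for per-haplotype
#' short-read alignments either (>30% tumor and <10% normal) or (>90%
#' tumor and <70% normal). Long-read evidence is ignored for homopolymers
#' covered by short reads; short-read evidence is ignored for indels over
#' 10 bp or low mapping quality.
#'
#' @param tumor_vaf_min,normal_vaf_max,min_coverage Combined-mapping gates.
#' @param dup_tumor_vaf_min Tumor VAF gate inside somatic duplications.
#' @param hap_tumor_vaf_min,hap_normal_vaf_max First per-haplotype regime.
#' @param hap_alt_tumor_vaf_min,hap_alt_normal_vaf_max Second regime.
#' @param long_read_indel_ignore_size Short-read evidence is ignored for
#'   indels larger than this.
#' @param homopolymer_short_cov_len Homopolymer length above which
#'   short-read coverage supersedes long reads.
#' @return list of class `truncal_thresholds`.
#' @export
truncal_thresholds <- function(tumor_vaf_min = 0.50, normal_vaf_max = 0.10,
                               min_coverage = 5L, dup_tumor_vaf_min = 0.30,
                               hap_tumor_vaf_min = 0.30,
                               hap_normal_vaf_max = 0.10,
                               hap_alt_tumor_vaf_min = 0.90,
                               hap_alt_normal_vaf_max = 0.70,
                               long_read_indel_ignore_size = 10L,
                               homopolymer_short_cov_len = 6L) {
  structure(list(tumor_vaf_min = tumor_vaf_min,
                 normal_vaf_max = normal_vaf_max,
                 min_coverage = as.integer(min_coverage),
                 dup_tumor_vaf_min = dup_tumor_vaf_min,
                 hap_tumor_vaf_min = hap_tumor_vaf_min,
                 hap_normal_vaf_max = hap_normal_vaf_max,
                 hap_alt_tumor_vaf_min = hap_alt_tumor_vaf_min,
                 hap_alt_normal_vaf_max = hap_alt_normal_vaf_max,
                 long_read_indel_ignore_size =
                   as.integer(long_read_indel_ignore_size),
                 homopolymer_short_cov_len =
                   as.integer(homopolymer_short_cov_len)),
            class = "truncal_thresholds")
}

#' Classify a variant as truncal from its read-support record
#'
#' Technology applicability is decided first: long-read evidence is dropped
#' when the variant lies in a homopolymer longer than 6 bp that short reads
#' cover (coverage above the gate), and short-read evidence is dropped for
#' indels larger than 10 bp or flagged low mapping quality. Every
#' applicable combined-mapping technology with coverage above the gate in
#' both samples must then pass its VAF rule (conservative AND); technologies
#' at or below the coverage gate abstain. Per-haplotype short-read rows are
#' evaluated against the two-regime rule. With no applicable evidence the
#' verdict is `insufficient_evidence`.
#'
#' @param record data.frame of support rows for one variant (columns
#'   `technology, tech_class, mapping, tumor_alt, tumor_cov, normal_alt,
#'   normal_cov, homopolymer_len, indel_size, in_somatic_duplication,
#'   low_mq`; per-haplotype rows have mapping `"hap1"`/`"hap2"` and are
#'   restricted to the variant's haplotype via `variant_hap` when present).
#' @param t A [truncal_thresholds()].
#' @return list(label = "truncal"|"not_somatic"|"insufficient_evidence",
#'   verdicts = per-row data.frame with `applicable, votes, pass`).
#' @export
classify_truncal <- function(record, t = truncal_thresholds()) {
  r <- record
  n <- nrow(r)
  if (n == 0) {
    return(list(label = "insufficient_evidence",
                verdicts = data.frame()))
  }
  if (!"variant_hap" %in% names(r)) r$variant_hap <- NA_integer_
  if (!"low_mq" %in% names(r)) r$low_mq <- FALSE
  if (!"in_somatic_duplication" %in% names(r)) {
    r$in_somatic_duplication <- FALSE
  }
  # homopolymer covered by short reads: tract > 6 bp and any short-read
  # combined row with coverage above the gate
  short_combined <- r$tech_class == "short" & r$mapping == "combined"
  hp_short_cov <- any(short_combined &
                        r$homopolymer_len > t$homopolymer_short_cov_len &
                        r$tumor_cov > t$min_coverage &
                        r$normal_cov > t$min_coverage)
  applicable <- rep(TRUE, n)
  applicable[r$tech_class == "long" & hp_short_cov] <- FALSE
  applicable[r$tech_class == "short" &
               (r$indel_size > t$long_read_indel_ignore_size | r$low_mq)] <-
    FALSE
  # per-haplotype rows on the non-carrier haplotype carry no signal
  hap_row <- r$mapping %in% c("hap1", "hap2")
  off_hap <- hap_row & !is.na(r$variant_hap) &
    r$mapping != paste0("hap", r$variant_hap)
  applicable[off_hap] <- FALSE
  votes <- applicable & r$tumor_cov > t$min_coverage &
    r$normal_cov > t$min_coverage
  tv <- r$tumor_alt / pmax(r$tumor_cov, 1)
  nv <- r$normal_alt / pmax(r$normal_cov, 1)
  pass <- rep(NA, n)
  for (i in which(votes)) {
    if (hap_row[i]) {
      pass[i] <- (tv[i] > t$hap_tumor_vaf_min &&
                    nv[i] < t$hap_normal_vaf_max) ||
        (tv[i] > t$hap_alt_tumor_vaf_min && nv[i] < t$hap_alt_normal_vaf_max)
    } else {
      tmin <- if (r$in_somatic_duplication[i]) t$dup_tumor_vaf_min
              else t$tumor_vaf_min
      pass[i] <- tv[i] > tmin && nv[i] < t$normal_vaf_max
    }
  }
  verdicts <- data.frame(technology = r$technology, mapping = r$mapping,
                         applicable = applicable, votes = votes,
                         pass = pass, stringsAsFactors = FALSE)
  label <- if (!any(votes)) "insufficient_evidence"
           else if (all(pass[votes])) "truncal" else "not_somatic"
  list(label = label, verdicts = verdicts)
}

#' Classify every variant in a support table
#'
#' @param support data.frame from [simulate_support_tables()] (or the same
#'   layout read from TSV).
#' @param t A [truncal_thresholds()].
#' @return data.frame(variant_id, label).
#' @export
classify_truncal_table <- function(support, t = truncal_thresholds()) {
  ids <- unique(support$variant_id)
  labels <- vapply(ids, function(id) {
    classify_truncal(support[support$variant_id == id, , drop = FALSE],
                     t)$label
  }, "")
  data.frame(variant_id = ids, label = labels, stringsAsFactors = FALSE)
}

#' Apply polishing edits to assembly sequences
#'
#' A built-in consensus applier for synthetic tests: edits per chromosome
#' are applied with [apply_variants()].
#'
#' @param seqs Named character vector of sequences.
#' @param edits data.frame with `chrom, pos0, ref, alt`.
#' @return Named character vector of edited sequences.
#' @export
apply_polish_edits <- function(seqs, edits) {
  for (chrom in unique(edits$chrom)) {
    ei <- edits[edits$chrom == chrom, , drop = FALSE]
    seqs[[chrom]] <- apply_variants(seqs[[chrom]], ei)$seq
  }
  seqs
}
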