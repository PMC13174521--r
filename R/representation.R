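# Lifting somatic variants from a donor-specific assembly (DSA) to a
# reference and classifying how germline variation changes their
# representation.
#
# The lift map is an explicit list of colinear alignment blocks between DSA
# and reference coordinates (synthetic genomes ship with their true
# alignment, so no external chain file or liftOver binary is involved).
# Representation classification reconstructs the local tumor haplotype and
# reference sequence, re-derives the variant as a reference-based caller
# would see it, and compares type and size against the DSA truth.

#' Build a lift map from alignment blocks
#'
#' @param blocks data.frame with `dsa_chrom, dsa_start, dsa_end, ref_chrom,
#'   ref_start, ref_end` (0-based half-open; equal lengths per block) and
#'   optional `strand` (only "+" is supported).
#' @param min_match Minimum fraction of a query interval that must project
#'   within one colinear block run.
#' @param max_colinear_gap Consecutive blocks whose gap on either side
#'   exceeds this are treated as separate (chain-like) runs, so an interval
#'   spanning them projects to disjoint targets.
#' @return list of class `lift_map`.
#' @export
lift_map <- function(blocks, min_match = 0.1, max_colinear_gap = 10000L) {
  req <- c("dsa_chrom", "dsa_start", "dsa_end", "ref_chrom", "ref_start",
           "ref_end")
  stopifnot(all(req %in% names(blocks)))
  if (!"strand" %in% names(blocks)) blocks$strand <- "+"
  if (any((blocks$dsa_end - blocks$dsa_start) !=
            (blocks$ref_end - blocks$ref_start))) {
    stop("lift map blocks must pair intervals of equal length")
  }
  blocks <- blocks[order(blocks$dsa_chrom, blocks$dsa_start), , drop = FALSE]
  for (chrom in unique(blocks$dsa_chrom)) {
    b <- blocks[blocks$dsa_chrom == chrom, , drop = FALSE]
    if (nrow(b) > 1 && any(b$dsa_start[-1] < b$dsa_end[-nrow(b)])) {
      stop("lift map blocks overlap on the DSA side of ", chrom)
    }
  }
  rownames(blocks) <- NULL
  structure(list(blocks = blocks, min_match = min_match,
                 max_colinear_gap = as.integer(max_colinear_gap)),
            class = "lift_map")
}

#' Lift map between a source sequence and its variant-edited derivative
#'
#' Convenience wrapper around [apply_variants()]: applying `variants` to
#' `src_seq` yields the derived sequence (e.g. a DSA haplotype carrying
#' germline variants on top of the reference) and the exact block
#' alignment between the two coordinate systems.
#'
#' @param src_seq Source (reference) sequence string.
#' @param variants data.frame `pos0, ref, alt` on the source.
#' @param src_chrom,dst_chrom Sequence names of the two sides.
#' @param min_match Passed to [lift_map()].
#' @return list(seq = derived sequence, map = `lift_map` from derived (DSA)
#'   to source (reference) coordinates).
#' @export
lift_map_from_variants <- function(src_seq, variants, src_chrom = "ref",
                                   dst_chrom = "dsa", min_match = 0.1) {
  res <- apply_variants(src_seq, variants)
  blocks <- data.frame(
    dsa_chrom = dst_chrom, dsa_start = res$blocks$dst_start,
    dsa_end = res$blocks$dst_end, ref_chrom = src_chrom,
    ref_start = res$blocks$src_start, ref_end = res$blocks$src_end,
    strand = "+", stringsAsFactors = FALSE)
  keep <- blocks$dsa_end > blocks$dsa_start
  list(seq = res$seq, map = lift_map(blocks[keep, , drop = FALSE],
                                     min_match = min_match))
}

# project a single DSA point through the map; NA when outside all blocks
project_point <- function(map, chrom, pos0) {
  b <- map$blocks
  hit <- which(b$dsa_chrom == chrom & b$dsa_start <= pos0 & b$dsa_end > pos0)
  if (length(hit) == 0) return(NA_integer_)
  i <- hit[1]
  b$ref_start[i] + (pos0 - b$dsa_start[i])
}

#' Lift a DSA interval or variant to reference coordinates
#'
#' The variant interval plus `slop` on each side is projected through the
#' map's blocks. Blocks overlapping the interval are grouped into colinear
#' runs (same reference sequence, monotone reference order); a run
#' qualifies when it covers at least `min_match` of the query interval. No
#' qualifying run gives `unliftable`; two or more disjoint reference
#' targets give `multi_lift`.
#'
#' @param v list or one-row data.frame with `chrom, pos0, ref` (DSA side).
#' @param map A [lift_map()].
#' @param slop Interval slop in bp.
#' @return list(status = "lifted"|"unliftable"|"multi_lift", chrom, start,
#'   end, point = exact projection of `pos0` or NA).
#' @export
lift_variant <- function(v, map, slop = 50L) {
  qs <- max(0L, v$pos0 - slop)
  qe <- v$pos0 + nchar(v$ref) + slop
  qlen <- qe - qs
  b <- map$blocks
  ov <- b[b$dsa_chrom == v$chrom & b$dsa_end > qs & b$dsa_start < qe, ,
          drop = FALSE]
  point <- project_point(map, v$chrom, v$pos0)
  if (nrow(ov) == 0) {
    return(list(status = "unliftable", chrom = NA, start = NA, end = NA,
                point = point))
  }
  ov <- ov[order(ov$dsa_start), , drop = FALSE]
  # group into colinear runs
  run_id <- integer(nrow(ov))
  run <- 1L
  run_id[1] <- run
  gap_max <- map$max_colinear_gap %||% 10000L
  for (i in seq_len(nrow(ov))[-1]) {
    colinear <- ov$ref_chrom[i] == ov$ref_chrom[i - 1] &&
      ov$ref_start[i] >= ov$ref_end[i - 1] &&
      (ov$ref_start[i] - ov$ref_end[i - 1]) <= gap_max &&
      (ov$dsa_start[i] - ov$dsa_end[i - 1]) <= gap_max
    if (!colinear) run <- run + 1L
    run_id[i] <- run
  }
  runs <- lapply(split(seq_len(nrow(ov)), run_id), function(idx) {
    oi <- ov[idx, , drop = FALSE]
    cov <- sum(pmin(oi$dsa_end, qe) - pmax(oi$dsa_start, qs))
    # reference span of the query overlap
    rs <- min(oi$ref_start + pmax(0L, qs - oi$dsa_start))
    re <- max(oi$ref_end - pmax(0L, oi$dsa_end - qe))
    list(chrom = oi$ref_chrom[1], start = rs, end = re,
         cov = cov / qlen)
  })
  ok <- Filter(function(r) r$cov >= map$min_match, runs)
  if (length(ok) == 0) {
    return(list(status = "unliftable", chrom = NA, start = NA, end = NA,
                point = point))
  }
  if (length(ok) >= 2) {
    return(list(status = "multi_lift", chrom = NA, start = NA, end = NA,
                point = point))
  }
  r <- ok[[1]]
  list(status = "lifted", chrom = r$chrom, start = r$start, end = r$end,
       point = point)
}

# ---- variant re-derivation against the reference ----------------------------

# variant rows (pos0, ref, alt) distinguishing x from ref_seq, VCF-style
# anchored, via global pairwise alignment; positions are 0-based on ref_seq
align_diff <- function(x, ref_seq) {
  empty <- data.frame(pos0 = integer(), ref = character(),
                      alt = character(), stringsAsFactors = FALSE)
  if (x == ref_seq) return(empty)
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(x),
    subject = Biostrings::DNAString(ref_seq), type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 2, mismatch = -3),
    gapOpening = 5, gapExtension = 2)
  ap <- strsplit(as.character(Biostrings::pattern(pa)), "")[[1]]
  as_ <- strsplit(as.character(Biostrings::subject(pa)), "")[[1]]
  out <- list()
  rp <- 0L  # consumed reference bases
  i <- 1L
  n <- length(ap)
  while (i <= n) {
    if (ap[i] != "-" && as_[i] != "-") {
      if (ap[i] != as_[i]) {
        out[[length(out) + 1L]] <- data.frame(
          pos0 = rp, ref = as_[i], alt = ap[i], stringsAsFactors = FALSE)
      }
      rp <- rp + 1L
      i <- i + 1L
    } else if (as_[i] == "-") {
      # insertion relative to the reference
      j <- i
      while (j <= n && as_[j] == "-") j <- j + 1L
      ins <- paste(ap[i:(j - 1L)], collapse = "")
      if (rp > 0) {
        anchor <- substr(ref_seq, rp, rp)
        out[[length(out) + 1L]] <- data.frame(
          pos0 = rp - 1L, ref = anchor, alt = paste0(anchor, ins),
          stringsAsFactors = FALSE)
      } else {
        anchor <- substr(ref_seq, 1, 1)
        out[[length(out) + 1L]] <- data.frame(
          pos0 = 0L, ref = anchor, alt = paste0(ins, anchor),
          stringsAsFactors = FALSE)
      }
      i <- j
    } else {
      # deletion relative to the reference
      j <- i
      while (j <= n && ap[j] == "-") j <- j + 1L
      del_len <- j - i
      if (rp > 0) {
        anchor <- substr(ref_seq, rp, rp)
        out[[length(out) + 1L]] <- data.frame(
          pos0 = rp - 1L,
          ref = paste0(anchor, substr(ref_seq, rp + 1L, rp + del_len)),
          alt = anchor, stringsAsFactors = FALSE)
      } else {
        anchor <- substr(ref_seq, del_len + 1L, del_len + 1L)
        out[[length(out) + 1L]] <- data.frame(
          pos0 = 0L, ref = paste0(substr(ref_seq, 1L, del_len), anchor),
          alt = anchor, stringsAsFactors = FALSE)
      }
      rp <- rp + del_len
      i <- j
    }
  }
  if (length(out) == 0) return(empty)
  d <- do.call(rbind, out)
  # normalize every derived variant on the reference window
  for (k in seq_len(nrow(d))) {
    nv <- normalize_variant(ref_seq, d$pos0[k], d$ref[k], d$alt[k])
    d$pos0[k] <- nv$pos0; d$ref[k] <- nv$ref; d$alt[k] <- nv$alt
  }
  d <- unique(d[order(d$pos0), , drop = FALSE])
  rownames(d) <- NULL
  d
}

type_class <- function(type) if (type == "snv") "snv" else "indel"

overlaps_bed <- function(bed, chrom, start, end) {
  if (is.null(bed) || nrow(bed) == 0) return(FALSE)
  any(bed$chrom == chrom & bed$end > start & bed$start < end)
}

#' Classify how a somatic variant's representation changes on the reference
#'
#' Reconstructs the local tumor haplotype (DSA window plus the somatic
#' variant) and the corresponding reference window, re-derives the variant
#' set a reference-based caller would produce (tumor-vs-reference
#' differences minus normal-vs-reference differences, both normalized), and
#' compares the re-derived somatic call against the DSA truth. Classes are
#' assigned with precedence unliftable > multi_lift > in_germline_cnv >
#' reverts_germline > type_changed > size_changed > difficult_region >
#' position_shift_only > unchanged.
#'
#' @param v list/one-row data.frame with `chrom, pos0, ref, alt` (DSA
#'   coordinates; the DSA sequence already carries the germline variants).
#' @param dsa_seqs Named character vector of DSA sequences.
#' @param ref_seqs Named character vector of reference sequences.
#' @param map A [lift_map()] from DSA to reference.
#' @param germline_cnv,difficult Optional BED data.frames (`chrom, start,
#'   end`) on the reference.
#' @param window Context window in bp (also the lift slop).
#' @return list(class, derived = data.frame of the re-derived call(s)).
#' @export
classify_representation <- function(v, dsa_seqs, ref_seqs, map,
                                    germline_cnv = NULL, difficult = NULL,
                                    window = 50L) {
  truth_t <- variant_type(v$ref, v$alt)
  lr <- lift_variant(v, map, slop = window)
  if (lr$status != "lifted") {
    return(list(class = lr$status, derived = NULL))
  }
  if (overlaps_bed(germline_cnv, lr$chrom, lr$start, lr$end)) {
    return(list(class = "in_germline_cnv", derived = NULL))
  }
  dsa <- dsa_seqs[[v$chrom]]
  ws <- max(0L, v$pos0 - window)
  we <- min(nchar(dsa), v$pos0 + nchar(v$ref) + window)
  normal_local <- substr(dsa, ws + 1L, we)
  tl <- apply_variants(normal_local,
                       data.frame(pos0 = v$pos0 - ws, ref = v$ref,
                                  alt = v$alt, stringsAsFactors = FALSE))
  tumor_local <- tl$seq
  ref_seq <- ref_seqs[[lr$chrom]]
  if (is.null(ref_seq) || lr$end > nchar(ref_seq)) {
    stop("reference window unavailable for ", lr$chrom)
  }
  ref_local <- substr(ref_seq, lr$start + 1L, lr$end)
  if (tumor_local == ref_local) {
    return(list(class = "reverts_germline", derived = NULL))
  }
  nd <- align_diff(normal_local, ref_local)
  td <- align_diff(tumor_local, ref_local)
  key <- function(d) paste(d$pos0, d$ref, d$alt)
  derived <- td[!(key(td) %in% key(nd)), , drop = FALSE]
  if (nrow(derived) == 0) {
    return(list(class = "reverts_germline", derived = derived))
  }
  # re-derived call nearest the expected in-window position
  expect <- v$pos0 - ws
  d <- derived[which.min(abs(derived$pos0 - expect)), , drop = FALSE]
  d_t <- variant_type(d$ref, d$alt)
  cls <- if (type_class(d_t$type) != type_class(truth_t$type)) {
    "type_changed"
  } else if (type_class(truth_t$type) == "indel" &&
             d_t$size != truth_t$size) {
    "size_changed"
  } else if (overlaps_bed(difficult, lr$chrom, lr$start, lr$end)) {
    "difficult_region"
  } else {
    # absolute reference position of the re-derived call
    abs_pos <- lr$start + d$pos0
    nv <- normalize_variant(dsa, v$pos0, v$ref, v$alt)
    expect_abs <- project_point(map, v$chrom, nv$pos0)
    same_site <- !is.na(expect_abs) && abs_pos == expect_abs &&
      d$ref == nv$ref && d$alt == nv$alt
    if (same_site) "unchanged" else "position_shift_only"
  }
  list(class = cls, derived = derived)
}

#' Classify representation changes for a variant table
#'
#' @param variants data.frame with `chrom, pos0, ref, alt` (+ optional id).
#' @inheritParams classify_representation
#' @return Input data.frame with added `class` column.
#' @export
classify_representation_table <- function(variants, dsa_seqs, ref_seqs, map,
                                          germline_cnv = NULL,
                                          difficult = NULL, window = 50L) {
  variants$class <- vapply(seq_len(nrow(variants)), function(i) {
    classify_representation(variants[i, , drop = FALSE], dsa_seqs,
                            ref_seqs, map, germline_cnv, difficult,
                            window)$class
  }, "")
  variants
}

#' Build tiered benchmark regions
#'
#' Tier `all`: merged slopped lifted somatic regions minus the exclusion
#' sets (subclonal variants, SV breakpoints +/- 50 bp, assembly errors,
#' complex repeats). Tier `nogermlineinterference` additionally removes
#' regions of variants whose representation class is type_changed,
#' size_changed, or reverts_germline. Tier `nogermlinewithin50bp` removes
#' from `all` any region within `germline_slop` bp of a germline variant.
#'
#' @param variants data.frame with `ref_chrom, ref_start, ref_end` (slopped
#'   lifted intervals) and `class` (representation class).
#' @param exclusions List of BED data.frames (`chrom, start, end`) on the
#'   reference.
#' @param germline data.frame with `chrom, pos0` of germline variants on
#'   the reference.
#' @param germline_slop Distance defining "near a germline variant".
#' @return Named list of three sorted merged BED data.frames.
#' @export
build_benchmark_regions <- function(variants, exclusions = list(),
                                    germline = NULL, germline_slop = 50L) {
  liftable <- variants[!variants$class %in% c("unliftable", "multi_lift"), ,
                       drop = FALSE]
  base <- data.frame(chrom = liftable$ref_chrom, start = liftable$ref_start,
                     end = liftable$ref_end, stringsAsFactors = FALSE)
  tier1 <- merge_intervals(base)
  for (ex in exclusions) {
    if (!is.null(ex) && nrow(ex) > 0) tier1 <- subtract_intervals(tier1, ex)
  }
  interf <- liftable[liftable$class %in%
                       c("type_changed", "size_changed", "reverts_germline"),
                     , drop = FALSE]
  tier2 <- tier1
  if (nrow(interf) > 0) {
    tier2 <- subtract_intervals(
      tier1, data.frame(chrom = interf$ref_chrom, start = interf$ref_start,
                        end = interf$ref_end))
  }
  tier3 <- tier1
  if (!is.null(germline) && nrow(germline) > 0) {
    gb <- data.frame(chrom = germline$chrom,
                     start = pmax(0L, germline$pos0 - germline_slop),
                     end = germline$pos0 + 1L + germline_slop)
    tier3 <- subtract_intervals(tier1, gb)
  }
  list(all = tier1, nogermlineinterference = tier2,
       nogermlinewithin50bp = tier3)
}

# ---- kataegis / omikli ------------------------------------------------------

#' Clustered-mutation detection thresholds
#'
#' The inter-mutation gap and size bounds follow the standard literature
#' definitions of kataegis (long clusters) and omikli (2-5 variant
#' clusters).
#'
#' @param max_gap Maximum gap (bp) between consecutive cluster members.
#' @param kataegis_min Minimum members for kataegis.
#' @param omikli_min,omikli_max Member bounds for omikli.
#' @return list of class `cluster_params`.
#' @export
cluster_params <- function(max_gap = 1000L, kataegis_min = 6L,
                           omikli_min = 2L, omikli_max = 5L) {
  stopifnot(omikli_max < kataegis_min, omikli_min >= 2)
  structure(list(max_gap = as.integer(max_gap),
                 kataegis_min = as.integer(kataegis_min),
                 omikli_min = as.integer(omikli_min),
                 omikli_max = as.integer(omikli_max)),
            class = "cluster_params")
}

#' Detect kataegis and omikli clusters
#'
#' Greedy segmentation: consecutive SNVs on the same haplotype and sequence
#' with gap at most `max_gap` join a run; runs with at least `kataegis_min`
#' members are kataegis, runs with `omikli_min` to `omikli_max` members are
#' omikli, singletons are not clusters.
#'
#' @param variants data.frame with `chrom, pos0, id` and optional `hap`
#'   (reference-projected sets omit it or set a constant) and `type`
#'   (non-SNVs are dropped when present).
#' @param params A [cluster_params()].
#' @param provenance Label stored on each call (`"dsa"` or `"reference"`).
#' @return data.frame(cluster_id, provenance, hap, chrom, start, end, n,
#'   class, members) with `members` a comma-joined id string.
#' @export
detect_clusters <- function(variants, params = cluster_params(),
                            provenance = "dsa") {
  v <- variants
  if ("type" %in% names(v)) v <- v[v$type == "snv", , drop = FALSE]
  if (!"hap" %in% names(v)) v$hap <- 0L
  if (!"id" %in% names(v)) v$id <- sprintf("v%06d", seq_len(nrow(v)))
  out <- list()
  if (nrow(v) > 0) {
    v <- v[order(v$hap, v$chrom, v$pos0), , drop = FALSE]
    groups <- split(v, paste(v$hap, v$chrom))
    for (g in groups) {
      gap_new <- c(TRUE, diff(g$pos0) > params$max_gap)
      run <- cumsum(gap_new)
      for (r in split(g, run)) {
        n <- nrow(r)
        cls <- if (n >= params$kataegis_min) "kataegis"
               else if (n >= params$omikli_min && n <= params$omikli_max)
                 "omikli" else NA
        if (is.na(cls)) next
        out[[length(out) + 1L]] <- data.frame(
          provenance = provenance, hap = r$hap[1], chrom = r$chrom[1],
          start = min(r$pos0), end = max(r$pos0) + 1L, n = n, class = cls,
          members = paste(r$id, collapse = ","), stringsAsFactors = FALSE)
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(provenance = character(), hap = integer(),
               chrom = character(), start = integer(), end = integer(),
               n = integer(), class = character(), members = character(),
               stringsAsFactors = FALSE)
  if (nrow(res)) res$cluster_id <- sprintf("%s_cl%03d", provenance,
                                           seq_len(nrow(res)))
  res
}

#' Attribute reference-projected clusters against DSA truth clusters
#'
#' A reference cluster with no DSA counterpart sharing at least
#' `overlap_min` of its members is "false"; false clusters whose members
#' span both haplotypes are attributed to opposite-haplotype collapse,
#' false clusters containing members with a germline-interaction
#' representation class to germline interaction. DSA clusters with no
#' reference counterpart (e.g. members in unliftable satellite) are
#' "reference_missed".
#'
#' @param dsa_clusters,ref_clusters Outputs of [detect_clusters()] (built
#'   with identical params).
#' @param variant_info data.frame with `id`, `hap`, and optional `class`
#'   (representation class per variant).
#' @param overlap_min Member-overlap fraction defining a counterpart.
#' @return data.frame(side, cluster_id, class, status, cause).
#' @export
compare_cluster_sets <- function(dsa_clusters, ref_clusters, variant_info,
                                 overlap_min = 0.5) {
  germ_classes <- c("type_changed", "size_changed", "reverts_germline",
                    "in_germline_cnv")
  mem <- function(x) strsplit(x, ",", fixed = TRUE)[[1]]
  dsa_members <- lapply(dsa_clusters$members, mem)
  ref_members <- lapply(ref_clusters$members, mem)
  rows <- list()
  for (i in seq_len(nrow(ref_clusters))) {
    m <- ref_members[[i]]
    best <- if (length(dsa_members) == 0) 0 else
      max(vapply(dsa_members,
                 function(dm) length(intersect(m, dm)) / length(m), 1))
    if (best >= overlap_min) {
      status <- "matched"; cause <- NA_character_
    } else {
      status <- "false"
      haps <- unique(variant_info$hap[match(m, variant_info$id)])
      cls <- if ("class" %in% names(variant_info)) {
        variant_info$class[match(m, variant_info$id)]
      } else character(0)
      cause <- if (length(haps[!is.na(haps)]) > 1) "opposite_haplotypes"
               else if (any(cls %in% germ_classes)) "germline_interaction"
               else "other"
    }
    rows[[length(rows) + 1L]] <- data.frame(
      side = "reference", cluster_id = ref_clusters$cluster_id[i],
      class = ref_clusters$class[i], status = status, cause = cause,
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(dsa_clusters))) {
    m <- dsa_members[[i]]
    best <- if (length(ref_members) == 0) 0 else
      max(vapply(ref_members,
                 function(rm) length(intersect(m, rm)) / length(m), 1))
    rows[[length(rows) + 1L]] <- data.frame(
      side = "dsa", cluster_id = dsa_clusters$cluster_id[i],
      class = dsa_clusters$class[i],
      status = if (best >= overlap_min) "matched" else "reference_missed",
      cause = NA_character_, stringsAsFactors = FALSE)
  }
  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(side = character(), cluster_id = character(),
               class = character(), status = character(),
               cause = character(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}
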