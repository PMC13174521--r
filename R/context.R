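# Repeat-context annotation and descriptive statistics of somatic variants:
# enrichment folds by repeat class, SBS96 trinucleotide substitution
# profiles with per-region goodness-of-fit tests, homopolymer 1 bp indel
# rate curves with Wilson intervals, and LINE insertion poly-A tail lengths.

#' Maximal homopolymer run at or abutting a position
#'
#' @param seq Sequence string.
#' @param pos0 0-based position (for anchored indels, the run starting at
#'   `pos0 + 1` is also examined and the longer run wins).
#' @param min_len Minimum run length to report.
#' @return list(base, length, start, end) or NULL.
#' @keywords internal
homopolymer_at <- function(seq, pos0, min_len = 4L) {
  n <- nchar(seq)
  best <- NULL
  for (p in unique(pmin(pmax(c(pos0, pos0 + 1L), 0L), n - 1L))) {
    b <- substr(seq, p + 1L, p + 1L)
    s <- p
    while (s > 0 && substr(seq, s, s) == b) s <- s - 1L
    e <- p + 1L
    while (e < n && substr(seq, e + 1L, e + 1L) == b) e <- e + 1L
    len <- e - s
    if (len >= min_len && (is.null(best) || len > best$length)) {
      best <- list(base = b, length = len, start = s, end = e)
    }
  }
  best
}

# maximal perfect dinucleotide tract covering pos0 or pos0+1; the two
# alternating bases must differ (otherwise it is a homopolymer)
ditr_at <- function(seq, pos0, min_span = 6L) {
  n <- nchar(seq)
  chars <- strsplit(substr(seq, max(1L, pos0 - 60L),
                           min(n, pos0 + 62L)), "")[[1]]
  off <- max(1L, pos0 - 60L) - 1L  # 0-based offset of chars[1]
  m <- length(chars)
  best <- NULL
  for (anchor in c(pos0, pos0 + 1L)) {
    a <- anchor - off  # 1-based index in chars
    if (a < 1 || a > m) next
    s <- a
    while (s - 2 >= 1 && chars[s - 2] == chars[s]) s <- s - 1L
    # extend left one more if the preceding base continues the other phase
    if (s - 1 >= 1 && s + 1 <= m && chars[s - 1] == chars[s + 1]) s <- s - 1L
    e <- a
    while (e + 2 <= m && chars[e + 2] == chars[e]) e <- e + 1L
    if (e + 1 <= m && e - 1 >= 1 && chars[e + 1] == chars[e - 1]) e <- e + 1L
    span <- e - s + 1L
    if (span >= min_span) {
      u <- unique(chars[s:min(s + 1L, e)])
      if (length(u) == 2) {
        if (is.null(best) || span > best$span) {
          best <- list(unit = paste(chars[s:(s + 1L)], collapse = ""),
                       span = span, start = s + off - 1L, end = e + off)
        }
      }
    }
  }
  best
}

#' Annotate a variant with its repeat context
#'
#' Homopolymers and dinucleotide TRs are detected directly from the
#' sequence around the variant (maximal run containing or abutting it);
#' satellite, segmental duplication, VNTR, and STR contexts come from
#' annotation BEDs. Precedence: satellite > segdup > VNTR > STR > diTR >
#' homopolymer > none.
#'
#' @param variants data.frame with `chrom, pos0, ref, alt`.
#' @param seqs Named character vector of sequences.
#' @param annotations Named list of BED data.frames (`satellite`, `segdup`,
#'   `vntr`, `str`), any subset.
#' @param min_homopolymer Minimum homopolymer length to label.
#' @return Input data.frame plus `context, hp_base, hp_len, ditr_len`.
#' @export
annotate_repeat_context <- function(variants, seqs, annotations = list(),
                                    min_homopolymer = 4L) {
  n <- nrow(variants)
  ctx <- character(n); hp_base <- NA_character_
  variants$hp_base <- NA_character_
  variants$hp_len <- 0L
  variants$ditr_len <- 0L
  bed_hit <- function(name, chrom, pos0) {
    bed <- annotations[[name]]
    overlaps_bed(bed, chrom, pos0, pos0 + 1L)
  }
  for (i in seq_len(n)) {
    chrom <- variants$chrom[i]; p <- variants$pos0[i]
    s <- seqs[[chrom]]
    hp <- homopolymer_at(s, p, min_homopolymer)
    dt <- ditr_at(s, p)
    if (!is.null(hp)) {
      variants$hp_base[i] <- hp$base
      variants$hp_len[i] <- hp$length
    }
    if (!is.null(dt)) variants$ditr_len[i] <- dt$span
    ctx[i] <- if (bed_hit("satellite", chrom, p)) "satellite"
      else if (bed_hit("segdup", chrom, p)) "segdup"
      else if (bed_hit("vntr", chrom, p)) "VNTR"
      else if (bed_hit("str", chrom, p)) "STR"
      else if (!is.null(dt)) "diTR"
      else if (!is.null(hp)) "homopolymer"
      else "none"
  }
  variants$context <- ctx
  variants
}

#' Census of maximal homopolymer runs in a genome
#'
#' @param seqs Named character vector of sequences.
#' @param min_len Minimum run length (default 4).
#' @return data.frame(chrom, start, end, base, length).
#' @export
homopolymer_census <- function(seqs, min_len = 4L) {
  out <- list()
  for (chrom in names(seqs)) {
    r <- rle(strsplit(seqs[[chrom]], "")[[1]])
    ends <- cumsum(r$lengths)
    keep <- r$lengths >= min_len & r$values %in% c("A", "C", "G", "T")
    if (!any(keep)) next
    out[[chrom]] <- data.frame(
      chrom = chrom, start = ends[keep] - r$lengths[keep],
      end = ends[keep], base = r$values[keep],
      length = r$lengths[keep], stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               base = character(), length = integer(),
               stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Enrichment of variant density by repeat class
#'
#' `fold = (n_class / bp_class) / (n_total / bp_total)`; classes with no
#' genomic footprint are flagged undefined.
#'
#' @param variants data.frame with a `context` column (and optionally
#'   `type` for per-type tables via prior splitting).
#' @param composition Named numeric vector of bp per repeat class; must
#'   include every class present and a `total` entry (or the sum is used).
#' @return data.frame(context, n, bp, density, fold, defined).
#' @export
enrichment_table <- function(variants, composition) {
  total_bp <- if ("total" %in% names(composition)) composition[["total"]]
              else sum(composition)
  n_total <- nrow(variants)
  classes <- unique(variants$context)
  missing <- setdiff(classes, names(composition))
  if (length(missing)) {
    stop("composition lacks classes: ", paste(missing, collapse = ", "))
  }
  out <- lapply(classes, function(cl) {
    n <- sum(variants$context == cl)
    bp <- composition[[cl]]
    defined <- bp > 0
    dens <- if (defined) n / bp else NA_real_
    fold <- if (defined) dens / (n_total / total_bp) else NA_real_
    data.frame(context = cl, n = n, bp = bp, density = dens, fold = fold,
               defined = defined, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# ---- SBS96 ------------------------------------------------------------------

#' The 96 trinucleotide substitution classes in canonical order
#' @return Character vector like `"A[C>A]A"`.
#' @export
sbs96_classes <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  unlist(lapply(subs, function(s)
    unlist(lapply(bases, function(b5)
      paste0(b5, "[", s, "]", bases)))))
}

comp_base <- c(A = "T", C = "G", G = "C", T = "A")

#' SBS96 class of a single SNV
#'
#' Substitutions are reported on the pyrimidine strand: when the reference
#' base is a purine, the trinucleotide context is reverse-complemented and
#' the alternate base complemented.
#'
#' @param seq Sequence string containing the SNV.
#' @param pos0 0-based SNV position.
#' @param ref,alt Reference and alternate bases.
#' @return Class string like `"T[C>A]T"`, or NA when the context contains
#'   ambiguous bases or lies at a sequence edge.
#' @export
sbs96_class <- function(seq, pos0, ref, alt) {
  n <- nchar(seq)
  if (pos0 < 1 || pos0 >= n - 1) return(NA_character_)
  tri <- substr(seq, pos0, pos0 + 2L)
  if (grepl("[^ACGT]", tri) || !ref %in% names(comp_base) ||
      !alt %in% names(comp_base)) {
    return(NA_character_)
  }
  stopifnot(substr(tri, 2, 2) == ref)
  if (ref %in% c("A", "G")) {
    tri <- revcomp(tri)
    ref <- comp_base[[ref]]
    alt <- comp_base[[alt]]
  }
  paste0(substr(tri, 1, 1), "[", ref, ">", alt, "]", substr(tri, 3, 3))
}

#' SBS96 profile of an SNV set
#'
#' @param snvs data.frame with `chrom, pos0, ref, alt`.
#' @param seqs Named character vector of sequences.
#' @return Named integer vector over [sbs96_classes()]; the `ambiguous`
#'   attribute counts SNVs whose context could not be classified.
#' @export
sbs96_profile <- function(snvs, seqs) {
  cls <- vapply(seq_len(nrow(snvs)), function(i) {
    s <- seqs[[snvs$chrom[i]]]
    cl <- sbs96_class(s, snvs$pos0[i], snvs$ref[i], snvs$alt[i])
    if (is.null(cl)) NA_character_ else cl
  }, "")
  keys <- sbs96_classes()
  counts <- table(factor(cls[!is.na(cls)], levels = keys))
  out <- setNames(as.integer(counts), keys)
  attr(out, "ambiguous") <- sum(is.na(cls))
  out
}

#' Goodness-of-fit of an SBS96 profile against reference proportions
#'
#' Chi-square test of the observed 96-category counts against expected
#' proportions, pooling categories whose expected count falls below 1 into
#' a single category before computing the statistic.
#'
#' @param obs Integer vector of 96 counts.
#' @param props Expected proportions (summing to 1).
#' @return list(statistic, df, p_value).
#' @export
sbs96_test <- function(obs, props) {
  n <- sum(obs)
  if (n == 0) stop("no classified SNVs to test")
  props <- props / sum(props)
  expd <- n * props
  pool <- expd < 1
  if (sum(!pool) < 2 && sum(pool) > 0) {
    # degenerate pooling; keep the two largest separate
    pool[order(expd, decreasing = TRUE)[1:2]] <- FALSE
  }
  o <- c(obs[!pool], if (any(pool)) sum(obs[pool]))
  e <- c(expd[!pool], if (any(pool)) sum(expd[pool]))
  keep <- e > 0
  if (any(!keep & o > 0)) return(list(statistic = Inf,
                                      df = sum(keep) - 1, p_value = 0))
  o <- o[keep]; e <- e[keep]
  stat <- sum((o - e)^2 / e)
  df <- length(o) - 1L
  list(statistic = stat, df = df,
       p_value = pchisq(stat, df, lower.tail = FALSE))
}

#' SBS96 profiles per region with significance against the whole genome
#'
#' Builds the profile of every region and the whole-genome profile, tests
#' each region's profile against the whole-genome proportions
#' (chi-square goodness-of-fit with pooling of sparse categories), and
#' applies Benjamini-Hochberg correction across regions.
#'
#' @param snvs data.frame with `chrom, pos0, ref, alt, region` (region =
#'   repeat-class label; the whole-genome profile pools all rows).
#' @param seqs Named character vector of sequences.
#' @return list(profiles = matrix regions x 96, genome = counts, tests =
#'   data.frame(region, n, statistic, df, p_value, fdr)).
#' @export
sbs96_profile_and_test <- function(snvs, seqs) {
  genome <- sbs96_profile(snvs, seqs)
  props <- genome / sum(genome)
  regions <- unique(snvs$region)
  profs <- list(); tests <- list()
  for (rg in regions) {
    sub <- snvs[snvs$region == rg, , drop = FALSE]
    if (nrow(sub) == 0) {
      warning("region ", rg, " has no SNVs; skipped")
      next
    }
    pr <- sbs96_profile(sub, seqs)
    profs[[rg]] <- pr
    tt <- sbs96_test(pr, props)
    tests[[rg]] <- data.frame(region = rg, n = sum(pr),
                              statistic = tt$statistic, df = tt$df,
                              p_value = tt$p_value, stringsAsFactors = FALSE)
  }
  tests <- do.call(rbind, tests)
  tests$fdr <- p.adjust(tests$p_value, method = "BH")
  rownames(tests) <- NULL
  list(profiles = do.call(rbind, profs), genome = genome, tests = tests)
}

# ---- homopolymer indel rates ------------------------------------------------

#' Wilson score interval for a binomial proportion
#' @param x Successes; `n` trials; `conf` confidence level.
#' @param n,conf See above.
#' @return c(lower, upper).
#' @export
wilson_ci <- function(x, n, conf = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(max(0, centre - half), min(1, centre + half))
}

#' Somatic 1 bp indel rate versus homopolymer length
#'
#' The denominator is the number of genomic homopolymer tracts of each
#' length (per-site semantics); the numerator counts truncal somatic 1 bp
#' insertions/deletions whose context homopolymer has that length. Base
#' classes pool A with T and C with G. Intervals are Wilson 95% CIs.
#'
#' @param variants data.frame of somatic variants with `type, size,
#'   hp_base, hp_len` (e.g. from [annotate_repeat_context()]); only 1 bp
#'   indels in homopolymers are counted.
#' @param census Homopolymer census from [homopolymer_census()].
#' @return data.frame(base_class, length, n_sites, n_1bp_ins, n_1bp_del,
#'   ins_rate, ins_lo, ins_hi, del_rate, del_lo, del_hi).
#' @export
homopolymer_indel_rate <- function(variants, census) {
  census$base_class <- ifelse(census$base %in% c("A", "T"), "A/T", "C/G")
  v <- variants[variants$type %in% c("ins", "del") & variants$size == 1 &
                  !is.na(variants$hp_base) & variants$hp_len > 0, ,
                drop = FALSE]
  v$base_class <- ifelse(v$hp_base %in% c("A", "T"), "A/T", "C/G")
  keys <- unique(census[, c("base_class", "length")])
  keys <- keys[order(keys$base_class, keys$length), , drop = FALSE]
  out <- lapply(seq_len(nrow(keys)), function(i) {
    bc <- keys$base_class[i]; L <- keys$length[i]
    n_sites <- sum(census$base_class == bc & census$length == L)
    vi <- v[v$base_class == bc & v$hp_len == L, , drop = FALSE]
    n_ins <- sum(vi$type == "ins"); n_del <- sum(vi$type == "del")
    ci_i <- wilson_ci(n_ins, n_sites); ci_d <- wilson_ci(n_del, n_sites)
    data.frame(base_class = bc, length = L, n_sites = n_sites,
               n_1bp_ins = n_ins, n_1bp_del = n_del,
               ins_rate = n_ins / n_sites, ins_lo = ci_i[1],
               ins_hi = ci_i[2], del_rate = n_del / n_sites,
               del_lo = ci_d[1], del_hi = ci_d[2],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Poly-A tail length of an insertion sequence
#'
#' Default: length of the maximal uninterrupted terminal A run (the
#' sequence is expected already oriented so the tail is 3'). With tolerance
#' `t`, the longest terminal suffix containing at most `t` non-A bases,
#' each flanked by at least 5 A's on both sides within the suffix.
#'
#' @param seq Insertion sequence string.
#' @param tolerance Number of interruptions allowed.
#' @return Tail length in bp (0 when the sequence does not end in A).
#' @export
polya_tail_length <- function(seq, tolerance = 0L) {
  n <- nchar(seq)
  if (n == 0) stop("empty sequence")
  chars <- strsplit(seq, "")[[1]]
  if (chars[n] != "A") return(0L)
  is_a <- chars == "A"
  if (tolerance == 0) {
    len <- 0L
    while (len < n && is_a[n - len]) len <- len + 1L
    return(len)
  }
  # runs of consecutive A ending/starting at each position
  run_end <- integer(n); run_start <- integer(n)
  for (i in seq_len(n)) {
    run_end[i] <- if (is_a[i]) (if (i > 1) run_end[i - 1] else 0L) + 1L else 0L
  }
  for (i in rev(seq_len(n))) {
    run_start[i] <- if (is_a[i]) (if (i < n) run_start[i + 1] else 0L) + 1L
                    else 0L
  }
  for (start in seq_len(n)) {
    idx <- which(!is_a[start:n]) + start - 1L
    if (length(idx) > tolerance) next
    ok <- all(vapply(idx, function(j) {
      j > start && j < n && run_end[j - 1] >= 5 && (j - 5) >= start &&
        run_start[j + 1] >= 5
    }, TRUE))
    if (ok) return(n - start + 1L)
  }
  0L
}
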