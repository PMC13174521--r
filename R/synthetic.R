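# Synthetic diploid tumor/normal genomes.
#
# The generator emits miniature chromosome mimics carrying the repeat
# structures the downstream analyses assume: centromeric satellite arrays
# built from a 171 bp monomer organised into higher-order repeat (HOR)
# units, acrocentric-mimic arms with a distal-junction-like (DJ) unique
# unit and a scaled-down rDNA tandem array, homopolymer and tandem-repeat
# tracts, and heterozygous germline SNVs. A tumor derivative adds truncal
# and subclonal somatic SNVs, context-biased indels, monomer-multiple
# satellite SVs from an unequal-crossover model, and rDNA unit loss.

#' Synthetic alpha-satellite-like monomer (171 bp)
#'
#' A fixed synthetic monomer used as the default satellite repeat unit. It
#' mirrors the canonical ~171 bp alpha-satellite monomer length and AT-rich
#' composition but is not a biological sequence.
#' @export
alpha_monomer_synthetic <- paste0(
  "AGTGCAAACATTAGGTCAGGGGACTTCCGGCAAATTTCAATAGTACACATAGTTCTAGAGAATTGACTGG",
  "TAATCTTCATGATTGTTATATTATGCGAAGTACTTAATTGAAATCGACCAAGGGGCTAGATGTAAAGATG",
  "CTGTGTTTCAGCTAACAACTAATTATCGGTT")

default_homopolymer_spec <- function() {
  data.frame(
    base = rep(c("A", "T", "C", "G"), times = c(7, 7, 4, 4)),
    length = c(seq(6, 30, by = 4), seq(8, 32, by = 4),
               seq(6, 18, by = 4), seq(8, 20, by = 4)),
    count = rep(c(3L, 3L, 2L, 2L), times = c(7, 7, 4, 4)),
    stringsAsFactors = FALSE
  )
}

default_tr_spec <- function() {
  data.frame(
    unit = c("AT", "AC", "AG", "CT", "ATC", "AATG", "AGGCT"),
    copies = c(8L, 10L, 7L, 12L, 6L, 5L, 8L),
    count = c(4L, 3L, 3L, 2L, 2L, 2L, 2L),
    stringsAsFactors = FALSE
  )
}

#' Configuration for the synthetic normal diploid genome
#'
#' Defaults build a miniature genome mirroring the normal human acrocentric
#' complement: 5 acrocentric-mimic chromosomes, each carrying exactly one
#' DJ-like unique unit per arm per haplotype (10 DJ copies in the diploid
#' genome) and a tandem rDNA-like array, plus autosome mimics with
#' centromeric satellite arrays. All coordinates are 0-based half-open.
#'
#' @param n_autosome_mimics Number of non-acrocentric chromosome mimics.
#' @param n_acrocentric_mimics Number of acrocentric mimics (default 5).
#' @param chrom_length Chromosome length in bp.
#' @param satellite_monomer Monomer sequence (default the synthetic 171 bp
#'   alpha-like monomer).
#' @param hor_order Monomers per HOR unit.
#' @param hor_divergence Per-base substitution rate distinguishing the
#'   monomer slots within a HOR unit.
#' @param array_length Target satellite array length in bp (rounded down to
#'   a whole number of HOR units).
#' @param rdna_unit_length Length of the scaled-down rDNA repeat unit.
#' @param rdna_copies_per_arm rDNA units per acrocentric arm.
#' @param dj_unit_length Length of the DJ-like unique unit.
#' @param homopolymer_spec data.frame(base, length, count) of homopolymer
#'   tracts placed per chromosome.
#' @param tr_spec data.frame(unit, copies, count) of tandem repeat tracts
#'   placed per chromosome.
#' @param germline_het_rate Per-bp probability of a heterozygous germline
#'   SNV.
#' @param seed Integer seed driving all randomness in the build.
#' @return list of class `genome_config`.
#' @export
genome_config <- function(n_autosome_mimics = 3L,
                          n_acrocentric_mimics = 5L,
                          chrom_length = 80000L,
                          satellite_monomer = alpha_monomer_synthetic,
                          hor_order = 6L,
                          hor_divergence = 0.03,
                          array_length = 15000L,
                          rdna_unit_length = 2000L,
                          rdna_copies_per_arm = 8L,
                          dj_unit_length = 3000L,
                          homopolymer_spec = default_homopolymer_spec(),
                          tr_spec = default_tr_spec(),
                          germline_het_rate = 0.001,
                          seed = 1L) {
  stopifnot(n_autosome_mimics >= 0, n_acrocentric_mimics >= 0,
            chrom_length > 0, nchar(satellite_monomer) > 1,
            hor_order >= 1, array_length >= 0,
            rdna_unit_length > 0, rdna_copies_per_arm >= 0,
            dj_unit_length > 0,
            germline_het_rate >= 0, germline_het_rate <= 1)
  structure(list(
    n_autosome_mimics = as.integer(n_autosome_mimics),
    n_acrocentric_mimics = as.integer(n_acrocentric_mimics),
    chrom_length = as.integer(chrom_length),
    satellite_monomer = satellite_monomer,
    hor_order = as.integer(hor_order),
    hor_divergence = hor_divergence,
    array_length = as.integer(array_length),
    rdna_unit_length = as.integer(rdna_unit_length),
    rdna_copies_per_arm = as.integer(rdna_copies_per_arm),
    dj_unit_length = as.integer(dj_unit_length),
    homopolymer_spec = homopolymer_spec,
    tr_spec = tr_spec,
    germline_het_rate = germline_het_rate,
    seed = as.integer(seed)
  ), class = "genome_config")
}

mutate_sequence <- function(seq, rate) {
  n <- nchar(seq)
  k <- rbinom(1, n, rate)
  if (k == 0) return(seq)
  pos <- sample.int(n, k)
  chars <- strsplit(seq, "")[[1]]
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  }
  paste(chars, collapse = "")
}

# HOR unit: hor_order monomer slots, each a slightly diverged copy of the
# base monomer; the array repeats the whole unit.
build_satellite_array <- function(monomer, hor_order, divergence,
                                  array_length) {
  mlen <- nchar(monomer)
  slots <- vapply(seq_len(hor_order), function(i) {
    mutate_sequence(monomer, divergence)
  }, "")
  hor <- paste(slots, collapse = "")
  n_hor <- array_length %/% nchar(hor)
  if (n_hor < 1) n_hor <- 1L
  paste(rep(hor, n_hor), collapse = "")
}

# proportional layout of the scaled-down rDNA unit, mirroring the 45S
# transcription unit followed by the intergenic spacer
rdna_region_layout <- function(unit_length) {
  f <- unit_length / 2000
  data.frame(
    region = c("promoter", "18S", "5.8S", "28S", "IGS"),
    start = as.integer(round(c(0, 100, 450, 550, 1000) * f)),
    end = as.integer(round(c(100, 400, 500, 1000, 2000) * f)),
    stringsAsFactors = FALSE
  )
}

#' Region layout of the synthetic rDNA unit
#'
#' Named subregions (promoter, 18S, 5.8S, 28S, IGS-like) placed
#' proportionally within the scaled-down rDNA repeat unit, in unit-local
#' 0-based half-open coordinates.
#'
#' @param x A `diploid_genome`, `genome_config`, or unit length in bp.
#' @return data.frame(region, start, end).
#' @export
rdna_regions <- function(x) {
  len <- if (inherits(x, "diploid_genome")) x$config$rdna_unit_length
         else if (inherits(x, "genome_config")) x$rdna_unit_length
         else as.integer(x)
  rdna_region_layout(len)
}

#' Build the synthetic normal diploid genome
#'
#' Deterministic given `config$seed`. Both haplotypes share one feature
#' layout, so the feature ledger indexes both haplotype FASTA sets; germline
#' heterozygous SNVs are then placed on one haplotype each at
#' `germline_het_rate` (they do not shift coordinates).
#'
#' @param config A [genome_config()].
#' @return Object of class `diploid_genome`: list with `sequences`
#'   (list hap1/hap2 of named chromosome strings), `reference` (the shared
#'   pre-germline chromosome sequences, a reference-mimic), `ledger`
#'   (feature data.frame: chrom, start, end, class, name, info), `germline`
#'   (data.frame: chrom, pos0, ref, alt, hap), and `config`.
#' @export
build_normal_genome <- function(config = genome_config()) {
  set.seed(config$seed)
  dj_seq <- random_dna(config$dj_unit_length)
  rdna_unit <- random_dna(config$rdna_unit_length, gc = 0.55)
  rdna_layout <- rdna_region_layout(config$rdna_unit_length)
  chroms <- c(
    if (config$n_autosome_mimics > 0)
      paste0("chrA", seq_len(config$n_autosome_mimics)),
    if (config$n_acrocentric_mimics > 0)
      paste0("acro", seq_len(config$n_acrocentric_mimics))
  )
  is_acro <- grepl("^acro", chroms)
  sequences <- character(0)
  ledger <- list()
  for (ci in seq_along(chroms)) {
    chrom <- chroms[ci]
    feats <- list()  # list of (class, name, seq, info, sub = df|NULL)
    if (is_acro[ci]) {
      feats[[length(feats) + 1L]] <-
        list(class = "dj", name = paste0(chrom, "_dj"), seq = dj_seq,
             info = "")
      if (config$rdna_copies_per_arm > 0) {
        sub <- do.call(rbind, lapply(seq_len(config$rdna_copies_per_arm),
          function(u) {
            off <- (u - 1L) * config$rdna_unit_length
            rbind(
              data.frame(class = "rdna_unit", start = off,
                         end = off + config$rdna_unit_length,
                         name = paste0(chrom, "_rdna", u), info = ""),
              data.frame(class = paste0("rdna_", rdna_layout$region),
                         start = off + rdna_layout$start,
                         end = off + rdna_layout$end,
                         name = paste0(chrom, "_rdna", u, "_",
                                       rdna_layout$region), info = "")
            )
          }))
        feats[[length(feats) + 1L]] <-
          list(class = "rdna_array", name = paste0(chrom, "_rdna_array"),
               seq = paste(rep(rdna_unit, config$rdna_copies_per_arm),
                           collapse = ""),
               info = "", sub = sub)
      }
    }
    if (config$array_length > 0) {
      arr <- build_satellite_array(config$satellite_monomer,
                                   config$hor_order,
                                   config$hor_divergence,
                                   config$array_length)
      feats[[length(feats) + 1L]] <-
        list(class = "satellite", name = paste0(chrom, "_sat"),
             seq = arr,
             info = paste0("monomer=", nchar(config$satellite_monomer)))
    }
    hp <- config$homopolymer_spec
    if (!is.null(hp) && nrow(hp) > 0) {
      for (i in seq_len(nrow(hp))) {
        for (j in seq_len(hp$count[i])) {
          feats[[length(feats) + 1L]] <-
            list(class = "homopolymer",
                 name = sprintf("%s_hp_%s%d_%d", chrom, hp$base[i],
                                hp$length[i], j),
                 seq = strrep(hp$base[i], hp$length[i]),
                 info = paste0("base=", hp$base[i]))
        }
      }
    }
    tr <- config$tr_spec
    if (!is.null(tr) && nrow(tr) > 0) {
      for (i in seq_len(nrow(tr))) {
        for (j in seq_len(tr$count[i])) {
          feats[[length(feats) + 1L]] <-
            list(class = "tr",
                 name = sprintf("%s_tr_%s_%d", chrom, tr$unit[i], j),
                 seq = strrep(tr$unit[i], tr$copies[i]),
                 info = paste0("unit=", tr$unit[i]))
        }
      }
    }
    # shuffle the non-structural features so tracts are scattered, keeping
    # dj / rdna / satellite in arm order at the front
    fixed <- which(vapply(feats, function(f)
      f$class %in% c("dj", "rdna_array", "satellite"), TRUE))
    rest <- setdiff(seq_along(feats), fixed)
    feats <- feats[c(fixed, sample(rest))]
    feat_bp <- sum(vapply(feats, function(f) nchar(f$seq), 1))
    n_gaps <- length(feats) + 1L
    spare <- config$chrom_length - feat_bp - n_gaps * 20L
    if (spare < 0) {
      stop("features exceed chromosome length on ", chrom,
           " (need ", feat_bp + n_gaps * 20L, " bp, have ",
           config$chrom_length, ")")
    }
    cuts <- sort(sample.int(spare + 1L, n_gaps - 1L, replace = TRUE) - 1L)
    gap_len <- diff(c(0L, cuts, spare)) + 20L
    pieces <- character(0)
    pos <- 0L
    for (i in seq_along(feats)) {
      g <- random_dna(gap_len[i])
      pieces <- c(pieces, g, feats[[i]]$seq)
      pos <- pos + gap_len[i]
      f <- feats[[i]]
      ledger[[length(ledger) + 1L]] <-
        if (f$class == "rdna_array" && !is.null(f$sub)) {
          data.frame(chrom = chrom, start = pos + f$sub$start,
                     end = pos + f$sub$end, class = f$sub$class,
                     name = f$sub$name, info = f$sub$info,
                     stringsAsFactors = FALSE)
        } else {
          data.frame(chrom = chrom, start = pos,
                     end = pos + nchar(f$seq), class = f$class,
                     name = f$name, info = f$info, stringsAsFactors = FALSE)
        }
      pos <- pos + nchar(f$seq)
    }
    pieces <- c(pieces, random_dna(gap_len[length(gap_len)]))
    sequences[[chrom]] <- paste(pieces, collapse = "")
  }
  ledger <- do.call(rbind, ledger)
  rownames(ledger) <- NULL
  # heterozygous germline SNVs, each on one haplotype
  germline <- list()
  for (chrom in chroms) {
    L <- nchar(sequences[[chrom]])
    n <- rbinom(1, L, config$germline_het_rate)
    if (n == 0) next
    pos0 <- sort(sample.int(L, n)) - 1L
    ref <- substring(sequences[[chrom]], pos0 + 1L, pos0 + 1L)
    alt <- vapply(ref, function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), "", USE.NAMES = FALSE)
    germline[[chrom]] <- data.frame(
      chrom = chrom, pos0 = pos0, ref = ref, alt = alt,
      hap = sample(1:2, n, replace = TRUE), stringsAsFactors = FALSE)
  }
  germline <- if (length(germline)) do.call(rbind, germline) else
    data.frame(chrom = character(), pos0 = integer(), ref = character(),
               alt = character(), hap = integer(), stringsAsFactors = FALSE)
  rownames(germline) <- NULL
  haps <- list(hap1 = sequences, hap2 = sequences)
  for (h in 1:2) {
    gv <- germline[germline$hap == h, , drop = FALSE]
    for (chrom in unique(gv$chrom)) {
      gvc <- gv[gv$chrom == chrom, , drop = FALSE]
      haps[[h]][[chrom]] <-
        apply_variants(haps[[h]][[chrom]], gvc)$seq
    }
  }
  names(haps$hap1) <- paste0(chroms, "_hap1")[match(names(haps$hap1), chroms)]
  names(haps$hap2) <- paste0(chroms, "_hap2")[match(names(haps$hap2), chroms)]
  structure(list(sequences = haps, reference = sequences, ledger = ledger,
                 germline = germline, dj_seq = dj_seq,
                 rdna_unit = rdna_unit, config = config),
            class = "diploid_genome")
}

#' @export
print.diploid_genome <- function(x, ...) {
  lens <- vapply(x$sequences$hap1, nchar, 1)
  cat(sprintf(
    "diploid genome: %d chromosomes x 2 haplotypes (%.2f Mbp diploid)\n",
    length(lens), 2 * sum(lens) / 1e6))
  cat(sprintf("  ledger: %d features (%s)\n", nrow(x$ledger),
              paste(names(sort(table(x$ledger$class), decreasing = TRUE))[1:min(4, length(unique(x$ledger$class)))],
                    collapse = ", ")))
  cat(sprintf("  germline het SNVs: %d\n", nrow(x$germline)))
  invisible(x)
}

# haplotype sequence for a base chromosome name
hap_seq <- function(genome, chrom, hap) {
  genome$sequences[[paste0("hap", hap)]][[paste0(chrom, "_hap", hap)]]
}

#' Chromosome lengths of a diploid genome
#' @param genome A `diploid_genome`.
#' @return Named integer vector over haplotype-suffixed sequence names.
#' @export
genome_seqlens <- function(genome) {
  c(vapply(genome$sequences$hap1, nchar, 1L),
    vapply(genome$sequences$hap2, nchar, 1L))
}

#' Configuration of the somatic mutation process
#'
#' @param snv_rate Per-bp somatic SNV rate per haplotype.
#' @param indel_rate_by_context Named list of rates: `homopolymer` and `tr`
#'   are per-tract probabilities of a slippage indel; `none` is a per-bp
#'   rate outside repeat tracts.
#' @param satellite_sv_model list(n_events, monomer_min, monomer_max):
#'   number of unequal-crossover events in satellite arrays and the uniform
#'   range of monomer counts exchanged; every event size is an exact
#'   multiple of the monomer length.
#' @param rdna_loss_fraction Fraction of rDNA units (per haplotype) deleted
#'   in the tumor.
#' @param subclonal_fraction Fraction of somatic variants assigned a cell
#'   fraction < 1.
#' @param cell_fraction_range Uniform range for subclonal cell fractions.
#' @param seed Integer seed.
#' @return list of class `somatic_config`.
#' @export
somatic_config <- function(snv_rate = 5e-5,
                           indel_rate_by_context = list(
                             homopolymer = 0.05, tr = 0.05, none = 2e-6),
                           satellite_sv_model = list(
                             n_events = 40L, monomer_min = 1L,
                             monomer_max = 20L),
                           rdna_loss_fraction = 0.3,
                           subclonal_fraction = 0.2,
                           cell_fraction_range = c(0.1, 0.6),
                           seed = 1L) {
  stopifnot(snv_rate >= 0, rdna_loss_fraction >= 0, rdna_loss_fraction <= 1,
            subclonal_fraction >= 0, subclonal_fraction <= 1)
  structure(list(snv_rate = snv_rate,
                 indel_rate_by_context = indel_rate_by_context,
                 satellite_sv_model = satellite_sv_model,
                 rdna_loss_fraction = rdna_loss_fraction,
                 subclonal_fraction = subclonal_fraction,
                 cell_fraction_range = cell_fraction_range,
                 seed = as.integer(seed)),
            class = "somatic_config")
}

ledger_context_at <- function(ledger, chrom, pos0) {
  hit <- ledger[ledger$chrom == chrom & ledger$start <= pos0 &
                  ledger$end > pos0, , drop = FALSE]
  if (nrow(hit) == 0) return("none")
  cls <- hit$class
  if (any(cls == "satellite")) return("satellite")
  if (any(grepl("^rdna", cls))) return("rdna")
  if (any(cls == "tr")) return("tr")
  if (any(cls == "homopolymer")) return("homopolymer")
  "none"
}

#' Derive a tumor genome and its somatic truth set from a normal genome
#'
#' Applies somatic SNVs, repeat-context-biased indels, monomer-multiple
#' satellite SVs, and rDNA unit loss to each haplotype. Variants never
#' overlap on a haplotype; every truth record carries the haplotype, cell
#' fraction (1 for truncal), repeat context, and generating mechanism. The
#' tumor sequences differ from the normal sequences exactly by the truth
#' set.
#'
#' @param normal A `diploid_genome` from [build_normal_genome()].
#' @param somatic A [somatic_config()].
#' @return list(tumor = `diploid_genome`, truth = data.frame(id, chrom, hap,
#'   pos0, ref, alt, type, size, cell_fraction, context, mechanism)).
#' @export
derive_tumor_genome <- function(normal, somatic = somatic_config()) {
  set.seed(somatic$seed)
  cfg <- normal$config
  mlen <- nchar(cfg$satellite_monomer)
  chroms <- unique(normal$ledger$chrom)
  if (length(chroms) == 0) {
    chroms <- sub("_hap1$", "", names(normal$sequences$hap1))
  }
  vars <- list()
  add <- function(chrom, hap, pos0, ref, alt, cf, context, mech) {
    vt <- variant_type(ref, alt)
    vars[[length(vars) + 1L]] <<- data.frame(
      chrom = chrom, hap = hap, pos0 = as.integer(pos0), ref = ref,
      alt = alt, type = vt$type, size = vt$size, cell_fraction = cf,
      context = context, mechanism = mech, stringsAsFactors = FALSE)
  }
  bases <- c("A", "C", "G", "T")
  for (chrom in sub("_hap1$", "", names(normal$sequences$hap1))) {
    for (h in 1:2) {
      s <- hap_seq(normal, chrom, h)
      L <- nchar(s)
      # SNVs
      n <- rbinom(1, L, somatic$snv_rate)
      if (n > 0) {
        for (p in sample.int(L, n) - 1L) {
          ref <- substr(s, p + 1L, p + 1L)
          add(chrom, h, p, ref, sample(setdiff(bases, ref), 1), NA,
              ledger_context_at(normal$ledger, chrom, p), "point")
        }
      }
      # context-biased slippage indels in homopolymer / TR tracts
      led <- normal$ledger[normal$ledger$chrom == chrom, , drop = FALSE]
      for (cls in c("homopolymer", "tr")) {
        rate <- somatic$indel_rate_by_context[[cls]]
        if (is.null(rate) || rate <= 0) next
        tracts <- led[led$class == cls, , drop = FALSE]
        if (nrow(tracts) == 0) next
        hitn <- which(runif(nrow(tracts)) < rate)
        for (i in hitn) {
          unit <- if (cls == "homopolymer") {
            sub("base=", "", tracts$info[i])
          } else sub("unit=", "", tracts$info[i])
          ulen <- nchar(unit)
          p <- tracts$start[i] - 1L  # anchor immediately before the tract
          if (p < 0) next
          anchor <- substr(s, p + 1L, p + 1L)
          if (runif(1) < 0.5) {
            add(chrom, h, p, anchor, paste0(anchor, unit), NA, cls,
                "slippage")
          } else {
            del <- substr(s, p + 1L, p + 1L + ulen)
            add(chrom, h, p, del, anchor, NA, cls, "slippage")
          }
        }
      }
      # background indels outside tracts
      rate0 <- somatic$indel_rate_by_context[["none"]]
      if (!is.null(rate0) && rate0 > 0) {
        n0 <- rbinom(1, L, rate0)
        for (p in sample.int(L - 2L, n0)) {
          anchor <- substr(s, p + 1L, p + 1L)
          if (runif(1) < 0.5) {
            add(chrom, h, p, anchor, paste0(anchor, sample(bases, 1)), NA,
                ledger_context_at(normal$ledger, chrom, p), "background")
          } else {
            add(chrom, h, p, substr(s, p + 1L, p + 2L), anchor, NA,
                ledger_context_at(normal$ledger, chrom, p), "background")
          }
        }
      }
    }
  }
  # monomer-multiple unequal-crossover SVs in satellite arrays
  svm <- somatic$satellite_sv_model
  sat <- normal$ledger[normal$ledger$class == "satellite", , drop = FALSE]
  if (!is.null(svm) && svm$n_events > 0 && nrow(sat) > 0) {
    for (e in seq_len(svm$n_events)) {
      i <- sample.int(nrow(sat), 1)
      h <- sample(1:2, 1)
      m <- sample(seq(svm$monomer_min, svm$monomer_max), 1)
      n_mono <- (sat$end[i] - sat$start[i]) %/% mlen
      if (n_mono <= m + 1L) next
      j <- sample.int(n_mono - m - 1L, 1)  # monomer boundary index >= 1
      b <- sat$start[i] + j * mlen         # event at a monomer boundary
      s <- hap_seq(normal, sat$chrom[i], h)
      anchor <- substr(s, b, b)            # base at b-1 (0-based)
      seg <- substr(s, b + 1L, b + m * mlen)
      if (runif(1) < 0.5) {
        add(sat$chrom[i], h, b - 1L, paste0(anchor, seg), anchor, NA,
            "satellite", "unequal_crossover")
      } else {
        add(sat$chrom[i], h, b - 1L, anchor, paste0(anchor, seg), NA,
            "satellite", "unequal_crossover")
      }
    }
  }
  # rDNA unit loss
  if (somatic$rdna_loss_fraction > 0) {
    units <- normal$ledger[normal$ledger$class == "rdna_unit", , drop = FALSE]
    for (h in 1:2) {
      n_lose <- round(somatic$rdna_loss_fraction * nrow(units))
      if (n_lose == 0) next
      lost <- units[sort(sample.int(nrow(units), n_lose)), , drop = FALSE]
      # contiguous lost units merge into one deletion (shared anchor base)
      for (chrom in unique(lost$chrom)) {
        li <- lost[lost$chrom == chrom, , drop = FALSE]
        run <- cumsum(c(TRUE, li$start[-1] != li$end[-nrow(li)]))
        for (r in split(li, run)) {
          p <- min(r$start) - 1L
          if (p < 0) next
          s <- hap_seq(normal, chrom, h)
          anchor <- substr(s, p + 1L, p + 1L)
          add(chrom, h, p, substr(s, p + 1L, max(r$end)), anchor, NA,
              "rdna", "rdna_loss")
        }
      }
    }
  }
  truth <- if (length(vars)) do.call(rbind, vars) else
    data.frame(chrom = character(), hap = integer(), pos0 = integer(),
               ref = character(), alt = character(), type = character(),
               size = integer(), cell_fraction = numeric(),
               context = character(), mechanism = character(),
               stringsAsFactors = FALSE)
  # drop overlapping events on the same haplotype; structural events
  # (satellite crossovers, rDNA loss) take precedence over small variants
  if (nrow(truth) > 1) {
    sv_first <- order(truth$chrom, truth$hap,
                      !truth$mechanism %in% c("rdna_loss",
                                              "unequal_crossover"),
                      truth$pos0)
    truth <- truth[sv_first, , drop = FALSE]
    keep <- rep(TRUE, nrow(truth))
    kept_s <- list(); kept_e <- list()
    for (i in seq_len(nrow(truth))) {
      key <- paste(truth$chrom[i], truth$hap[i])
      s <- truth$pos0[i]; e <- truth$pos0[i] + nchar(truth$ref[i])
      ks <- kept_s[[key]]; ke <- kept_e[[key]]
      if (!is.null(ks) && any(s < ke & e > ks)) {
        keep[i] <- FALSE
      } else {
        kept_s[[key]] <- c(ks, s); kept_e[[key]] <- c(ke, e)
      }
    }
    truth <- truth[keep, , drop = FALSE]
    truth <- truth[order(truth$chrom, truth$hap, truth$pos0), , drop = FALSE]
  }
  # clonality
  if (nrow(truth) > 0) {
    sub <- runif(nrow(truth)) < somatic$subclonal_fraction
    truth$cell_fraction <- ifelse(
      sub, runif(nrow(truth), somatic$cell_fraction_range[1],
                 somatic$cell_fraction_range[2]), 1)
    truth$id <- sprintf("som%04d", seq_len(nrow(truth)))
  } else {
    truth$id <- character(0)
  }
  rownames(truth) <- NULL
  # apply to sequences
  tumor_seqs <- normal$sequences
  maps <- list()
  for (h in 1:2) {
    hv <- truth[truth$hap == h, , drop = FALSE]
    for (chrom in sub("_hap1$", "", names(normal$sequences$hap1))) {
      cv <- hv[hv$chrom == chrom, , drop = FALSE]
      key <- paste0(chrom, "_hap", h)
      res <- apply_variants(normal$sequences[[paste0("hap", h)]][[key]], cv)
      tumor_seqs[[paste0("hap", h)]][[key]] <- res$seq
      maps[[key]] <- res$blocks
    }
  }
  tumor <- structure(list(sequences = tumor_seqs,
                          reference = normal$reference,
                          ledger = normal$ledger,
                          germline = normal$germline,
                          dj_seq = normal$dj_seq,
                          rdna_unit = normal$rdna_unit,
                          config = normal$config, lift_blocks = maps),
                     class = "diploid_genome")
  list(tumor = tumor,
       truth = truth[, c("id", "chrom", "hap", "pos0", "ref", "alt", "type",
                         "size", "cell_fraction", "context", "mechanism")])
}

# ---- output writers ---------------------------------------------------------

#' Write a diploid genome to haplotype-suffixed FASTA files
#' @param genome A `diploid_genome`.
#' @param path Output FASTA path (both haplotypes in one file).
#' @export
write_genome_fasta <- function(genome, path) {
  write_fasta(c(genome$sequences$hap1, genome$sequences$hap2), path)
  invisible(path)
}

#' Write the feature ledger as BED
#' @param genome A `diploid_genome`.
#' @param path Output path.
#' @export
write_ledger_bed <- function(genome, path) {
  led <- genome$ledger
  write_intervals(
    data.frame(chrom = led$chrom, start = led$start, end = led$end,
               name = paste0(led$class, ":", led$name)), path)
}

#' Write a somatic truth set as VCF with HAP / CF / MECH INFO tags
#' @param truth Truth data.frame from [derive_tumor_genome()].
#' @param path Output VCF path.
#' @param genome Optional `diploid_genome` supplying contig lengths.
#' @export
write_truth_vcf <- function(truth, path, genome = NULL) {
  contigs <- NULL
  if (!is.null(genome)) {
    lens <- vapply(genome$sequences$hap1, nchar, 1L)
    contigs <- setNames(as.integer(lens), sub("_hap1$", "", names(lens)))
  }
  x <- truth
  x$info <- sprintf("HAP=%d;CF=%.4f;MECH=%s", x$hap, x$cell_fraction,
                    x$mechanism)
  write_variants(
    x, path, contigs = contigs,
    info_header = c(
      '##INFO=<ID=HAP,Number=1,Type=Integer,Description="Haplotype carrying the variant">',
      '##INFO=<ID=CF,Number=1,Type=Float,Description="Cell fraction (1 = truncal)">',
      '##INFO=<ID=MECH,Number=1,Type=String,Description="Generating mechanism">'))
}
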