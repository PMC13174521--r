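# Polishing candidate filter, edit merging, truncal classification.

# independent brute-force recodings of the published rules ---------------------

polish_oracle <- function(tech, gt, gq, cov, mean_cov, vtype, isz, hp, dtr,
                          elem) {
  if (gt != "hom") return("reject")
  if (!(gq > 4)) return("reject")
  if (!(cov < 2 * mean_cov)) return("reject")
  if (tech == "ont") {
    if (hp > 6) return("reject")
    if (dtr > 11) return("reject")
    if (vtype %in% c("ins", "del") && (isz == 1 || isz == 2)) {
      return("reject")
    }
    if (gq < 10) return("reject")
  }
  if (tech == "hifi") {
    if ((hp > 6 || dtr > 11) && elem) return("reject")
  }
  "accept"
}

truncal_oracle <- function(rows, thr = truncal_thresholds()) {
  # rows: tech_class, mapping, ta, tc, na_, nc, hp, isz, dup, lowmq, vhap
  hp_short <- any(rows$tech_class == "short" & rows$mapping == "combined" &
                    rows$hp > 6 & rows$tc > 5 & rows$nc > 5)
  n_votes <- 0L; all_pass <- TRUE
  for (i in seq_len(nrow(rows))) {
    r <- rows[i, ]
    if (r$tech_class == "long" && hp_short) next
    if (r$tech_class == "short" && (r$isz > 10 || r$lowmq)) next
    if (r$mapping != "combined" && r$mapping != paste0("hap", r$vhap)) next
    if (!(r$tc > 5 && r$nc > 5)) next
    tv <- r$ta / r$tc; nv <- r$na_ / r$nc
    ok <- if (r$mapping == "combined") {
      tmin <- if (r$dup) 0.30 else 0.50
      tv > tmin && nv < 0.10
    } else {
      (tv > 0.30 && nv < 0.10) || (tv > 0.90 && nv < 0.70)
    }
    n_votes <- n_votes + 1L
    if (!ok) all_pass <- FALSE
  }
  if (n_votes == 0) "insufficient_evidence"
  else if (all_pass) "truncal" else "not_somatic"
}

test_that("polishing filter reproduces the documented decisions", {
  expect_equal(
    evaluate_polish_candidate(polish_candidate("ont", gq = 9))$decision,
    "reject")  # ONT needs GQ >= 10
  expect_equal(
    evaluate_polish_candidate(
      polish_candidate("ont", variant_type = "ins", indel_size = 1,
                       gq = 30))$decision, "reject")
  expect_equal(
    evaluate_polish_candidate(
      polish_candidate("hifi", variant_type = "del", indel_size = 1,
                       homopolymer_len = 8,
                       element_small_indel_present = TRUE))$decision,
    "reject")
  expect_equal(
    evaluate_polish_candidate(polish_candidate("short_accurate",
                                               gq = 4))$decision,
    "reject")  # GQ must strictly exceed 4
  expect_equal(
    evaluate_polish_candidate(
      polish_candidate("short_accurate", gq = 40, local_coverage = 36,
                       mean_coverage = 30))$decision, "accept")
  expect_equal(
    evaluate_polish_candidate(
      polish_candidate("hifi", variant_type = "del", indel_size = 1,
                       homopolymer_len = 8,
                       element_small_indel_present = FALSE))$decision,
    "accept")
  expect_error(evaluate_polish_candidate(polish_candidate("nanopore2")),
               "unknown technology")
})

test_that("polishing filter equals the brute-force oracle on a full grid", {
  grid <- expand.grid(
    tech = c("short_accurate", "hifi", "ont"),
    gt = c("hom", "het"),
    gq = c(0, 4, 5, 9, 10, 40),
    cov = c(20, 59, 60, 80),
    vtype = c("snv", "ins", "del"),
    isz = c(0, 1, 2, 3),
    hp = c(0, 6, 7, 12),
    dtr = c(0, 11, 12),
    elem = c(TRUE, FALSE),
    stringsAsFactors = FALSE)
  grid <- grid[!(grid$vtype == "snv" & grid$isz > 0), ]
  grid <- grid[!(grid$vtype != "snv" & grid$isz == 0), ]
  expect_gt(nrow(grid), 1e4)
  got <- vapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    evaluate_polish_candidate(polish_candidate(
      g$tech, genotype = g$gt, gq = g$gq, local_coverage = g$cov,
      mean_coverage = 30, variant_type = g$vtype, indel_size = g$isz,
      homopolymer_len = g$hp, ditr_len = g$dtr,
      element_small_indel_present = g$elem))$decision
  }, "")
  want <- vapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    polish_oracle(g$tech, g$gt, g$gq, g$cov, 30, g$vtype, g$isz, g$hp,
                  g$dtr, g$elem)
  }, "")
  expect_equal(got, want)
})

test_that("edit merging dedups, excludes near-SV edits, and respects priority", {
  ed <- data.frame(
    chrom = "c1", pos0 = c(100L, 100L, 500L, 800L),
    ref = c("A", "A", "T", "G"), alt = c("G", "G", "TA", "C"),
    technology = c("hifi", "ont", "short_accurate", "hifi"),
    stringsAsFactors = FALSE)
  m <- merge_polish_edits(ed)
  expect_equal(nrow(m), 3L)  # identical call from two technologies once
  sv <- data.frame(chrom = "c1", pos0 = 503L)
  m2 <- merge_polish_edits(ed, sv)  # edit 3 bp from a breakpoint removed
  expect_false(500L %in% m2$pos0)
  sv6 <- data.frame(chrom = "c1", pos0 = 506L)
  expect_true(500L %in% merge_polish_edits(ed, sv6)$pos0)
  # conflicting overlapping edits resolve short_accurate > hifi > ont
  conflict <- data.frame(
    chrom = "c1", pos0 = c(200L, 200L), ref = c("AT", "AT"),
    alt = c("A", "ATT"), technology = c("ont", "short_accurate"),
    stringsAsFactors = FALSE)
  mc <- merge_polish_edits(conflict)
  expect_equal(nrow(mc), 1L)
  expect_equal(mc$technology, "short_accurate")
})

test_that("conflict resolution matches a brute-force resolver", {
  prio <- c(short_accurate = 1, hifi = 2, ont = 3)
  resolve_oracle <- function(ed) {
    ed <- ed[order(prio[ed$technology], ed$pos0), ]
    kept <- ed[0, ]
    for (i in seq_len(nrow(ed))) {
      s <- ed$pos0[i]; e <- s + nchar(ed$ref[i])
      ks <- kept$pos0; ke <- kept$pos0 + nchar(kept$ref)
      if (nrow(kept) == 0 || !any(s < ke & e > ks)) {
        kept <- rbind(kept, ed[i, ])
      }
    }
    kept[order(kept$pos0, kept$ref, kept$alt), c("pos0", "ref", "alt")]
  }
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(3:15, 1)
    pos <- sample(0:60, n, replace = TRUE)
    ed <- data.frame(
      chrom = "c1", pos0 = pos,
      ref = strrep("A", sample(1:4, n, replace = TRUE)),
      alt = sample(c("G", "GT", "T"), n, replace = TRUE),
      technology = sample(names(prio), n, replace = TRUE),
      stringsAsFactors = FALSE)
    ed <- ed[!duplicated(ed[, c("chrom", "pos0", "ref", "alt")]), ]
    got <- merge_polish_edits(ed)
    got <- got[order(got$pos0, got$ref, got$alt), c("pos0", "ref", "alt")]
    want <- resolve_oracle(ed)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

mk_row <- function(tech_class = "long", mapping = "combined", ta = 20,
                   tc = 30, na_ = 0, nc = 30, hp = 0, dtr = 0, isz = 0,
                   dup = FALSE, lowmq = FALSE, vhap = 1,
                   tech = "hifi") {
  data.frame(technology = tech, tech_class = tech_class, mapping = mapping,
             tumor_alt = ta, tumor_cov = tc, normal_alt = na_,
             normal_cov = nc, homopolymer_len = hp, ditr_len = dtr,
             indel_size = isz, in_somatic_duplication = dup, low_mq = lowmq,
             variant_hap = vhap, stringsAsFactors = FALSE)
}

test_that("truncal classification reproduces the documented decisions", {
  t <- truncal_thresholds()
  expect_equal(classify_truncal(mk_row(ta = 18, tc = 30, na_ = 1, nc = 28),
                                t)$label, "truncal")
  expect_equal(classify_truncal(
    mk_row(ta = 10, tc = 30, na_ = 0, nc = 25, dup = TRUE), t)$label,
    "truncal")
  expect_equal(classify_truncal(
    mk_row(ta = 10, tc = 30, na_ = 0, nc = 25, dup = FALSE), t)$label,
    "not_somatic")  # 0.33 needs the duplication relaxation
  # per-haplotype short reads, second regime: 0.95 tumor / 0.65 normal
  hap <- mk_row(tech_class = "short", mapping = "hap1", ta = 19, tc = 20,
                na_ = 13, nc = 20, tech = "short_accurate")
  expect_equal(classify_truncal(hap, t)$label, "truncal")
  # coverage gate: every technology at coverage <= 5 abstains
  low <- mk_row(ta = 5, tc = 5, na_ = 0, nc = 5)
  expect_equal(classify_truncal(low, t)$label, "insufficient_evidence")
  expect_equal(classify_truncal(low[0, ], t)$label,
               "insufficient_evidence")
})

test_that("truncal classification equals the truth-table oracle on a grid", {
  t <- truncal_thresholds()
  set.seed(41)
  checked <- 0L
  for (rep in 1:2500) {
    n_rows <- sample(1:4, 1)
    rows <- do.call(rbind, lapply(seq_len(n_rows), function(j) {
      tc <- sample(c(0, 4, 5, 6, 20, 30), 1)
      nc <- sample(c(0, 5, 6, 20, 30), 1)
      cls <- sample(c("short", "long"), 1)
      mk_row(tech_class = cls,
             mapping = sample(if (cls == "short")
               c("combined", "hap1", "hap2") else "combined", 1),
             ta = sample(0:tc, 1), tc = tc, na_ = sample(0:nc, 1), nc = nc,
             hp = sample(c(0, 7, 12), 1), isz = sample(c(0, 1, 11), 1),
             dup = sample(c(TRUE, FALSE), 1),
             lowmq = sample(c(TRUE, FALSE), 1), vhap = sample(1:2, 1),
             tech = if (cls == "short") "short_accurate" else "hifi")
    }))
    rows$in_somatic_duplication <- rows$in_somatic_duplication[1]
    rows$variant_hap <- rows$variant_hap[1]
    got <- classify_truncal(rows, t)$label
    orc <- rows
    names(orc)[names(orc) == "tumor_alt"] <- "ta"
    names(orc)[names(orc) == "tumor_cov"] <- "tc"
    names(orc)[names(orc) == "normal_alt"] <- "na_"
    names(orc)[names(orc) == "normal_cov"] <- "nc"
    names(orc)[names(orc) == "homopolymer_len"] <- "hp"
    names(orc)[names(orc) == "indel_size"] <- "isz"
    names(orc)[names(orc) == "in_somatic_duplication"] <- "dup"
    names(orc)[names(orc) == "low_mq"] <- "lowmq"
    names(orc)[names(orc) == "variant_hap"] <- "vhap"
    want <- truncal_oracle(orc, t)
    expect_equal(got, want)
    checked <- checked + n_rows
  }
  expect_gt(checked, 5000)
})

test_that("raising tumor support never flips truncal to not_somatic", {
  t <- truncal_thresholds()
  set.seed(43)
  for (rep in 1:200) {
    tc <- sample(6:40, 1); nc <- sample(6:40, 1)
    ta <- sample(0:(tc - 1), 1); na_ <- sample(0:nc, 1)
    r1 <- mk_row(ta = ta, tc = tc, na_ = na_, nc = nc)
    r2 <- mk_row(ta = ta + 1, tc = tc, na_ = na_, nc = nc)
    l1 <- classify_truncal(r1, t)$label
    l2 <- classify_truncal(r2, t)$label
    expect_false(l1 == "truncal" && l2 == "not_somatic")
    # and raising normal support never flips not_somatic to truncal
    if (na_ < nc) {
      r3 <- mk_row(ta = ta, tc = tc, na_ = na_ + 1, nc = nc)
      l3 <- classify_truncal(r3, t)$label
      expect_false(l1 == "not_somatic" && l3 == "truncal")
    }
  }
})

test_that("zero-error support tables recover truth labels perfectly", {
  g <- shared_genome()
  tm <- shared_tumor()
  truth <- tm$truth
  truth <- truth[truth$context != "satellite", ]  # low-MQ rows abstain short
  profiles <- list(
    tech_profile("short_accurate", 30, 0, c(`6` = 0),
                 tech_class = "short", per_haplotype = TRUE),
    tech_profile("hifi", 30, 0, c(`6` = 0), tech_class = "long"))
  sup <- simulate_support_tables(truth, profiles, genome = g, seed = 77)
  res <- classify_truncal_table(sup)
  truthy <- truth$cell_fraction == 1
  called <- res$label[match(truth$id, res$variant_id)] == "truncal"
  # sensitivity: every truncal variant is called truncal
  expect_equal(mean(called[truthy]), 1.0)
  # specificity against germline-like sites: both samples carry the allele
  germ <- truth[1:30, ]
  germ$id <- paste0("germ", seq_len(nrow(germ)))
  sup_g <- simulate_support_tables(germ, profiles, genome = g, seed = 78)
  sup_g$normal_alt <- sup_g$tumor_alt  # present in normal reads too
  sup_g$normal_cov <- sup_g$tumor_cov
  res_g <- classify_truncal_table(sup_g)
  expect_true(all(res_g$label != "truncal"))
})
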