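# Repeat-context annotation, enrichment, SBS96, indel-rate curves, poly-A.

test_that("homopolymer and diTR contexts are read off the sequence", {
  seqs <- c(c1 = paste0("GCGC", strrep("A", 7), "GC",
                        strrep("AT", 8), "GGCC"))
  # a 1 bp insertion of A anchored inside the 7 bp A run
  v <- data.frame(chrom = "c1", pos0 = 6L, ref = "A", alt = "AA")
  a <- annotate_repeat_context(v, seqs)
  expect_equal(a$context, "homopolymer")
  expect_equal(a$hp_base, "A")
  expect_equal(a$hp_len, 7L)
  # an SNV in the dinucleotide tract
  v2 <- data.frame(chrom = "c1", pos0 = 15L, ref = substr(seqs, 16, 16),
                   alt = "G")
  a2 <- annotate_repeat_context(v2, seqs)
  expect_equal(a2$context, "diTR")
  expect_equal(a2$ditr_len, 16L)
  # no annotation overlap and no run of 4: class none
  v3 <- data.frame(chrom = "c1", pos0 = 1L, ref = "C", alt = "T")
  expect_equal(annotate_repeat_context(v3, seqs)$context, "none")
  # satellite BED wins over the homopolymer (precedence)
  sat <- data.frame(chrom = "c1", start = 0L, end = 30L)
  a4 <- annotate_repeat_context(v, seqs, annotations = list(satellite = sat))
  expect_equal(a4$context, "satellite")
})

test_that("the homopolymer census finds every maximal run", {
  seqs <- c(c1 = "AAAACCTTTTTTGAAA")
  cen <- homopolymer_census(seqs, min_len = 4L)
  expect_equal(nrow(cen), 2L)
  expect_equal(cen$base, c("A", "T"))
  expect_equal(cen$length, c(4L, 6L))
  expect_equal(cen$start, c(0L, 6L))
  # census bp never exceeds the genome length
  g <- shared_genome()
  cen_g <- homopolymer_census(g$sequences$hap1)
  expect_lte(sum(cen_g$length), sum(nchar(g$sequences$hap1)))
})

test_that("enrichment folds are density ratios with undefined zero classes", {
  v <- data.frame(context = c(rep("sat", 10), rep("none", 90)))
  comp <- c(sat = 1000, none = 99000, total = 100000)
  e <- enrichment_table(v, comp)
  expect_equal(e$fold[e$context == "sat"], 10.0)
  # an empty class present in composition simply never appears; a class
  # with zero genomic footprint is flagged undefined
  v2 <- data.frame(context = c("a", "b"))
  e2 <- enrichment_table(v2, c(a = 100, b = 0, total = 1000))
  expect_false(e2$defined[e2$context == "b"])
  expect_true(is.na(e2$fold[e2$context == "b"]))
})

test_that("uniform variants give folds near 1 for every class", {
  set.seed(61)
  shares <- c(w = 0.40, x = 0.25, y = 0.15, z = 0.12, v = 0.08)
  bp <- shares * 1e6
  ctx <- sample(names(shares), 10000, replace = TRUE, prob = shares)
  e <- enrichment_table(data.frame(context = ctx),
                        c(bp, total = sum(bp)))
  expect_true(all(e$fold > 0.8 & e$fold < 1.25))
})

test_that("SBS96 classes use the pyrimidine strand convention", {
  seqs <- c(c1 = "TAGAT")
  expect_equal(sbs96_class(seqs[["c1"]], 2L, "G", "T"), "T[C>A]T")
  expect_equal(sbs96_class("ACGTA", 2L, "G", "A"), "A[C>T]G")  # revcomp
  expect_equal(sbs96_class("ACTTA", 2L, "T", "G"), "C[T>G]T")  # pyrimidine
  expect_true(is.na(sbs96_class("ANGTA", 2L, "G", "A")))
  expect_equal(length(sbs96_classes()), 96L)
  # strand symmetry: complementing the SNV and context leaves the class
  set.seed(3)
  for (r in 1:20) {
    tri <- random_dna(3)
    ref <- substr(tri, 2, 2)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    a <- sbs96_class(tri, 1L, ref, alt)
    b <- sbs96_class(revcomp(tri), 1L,
                     revcomp(ref), revcomp(alt))
    expect_equal(a, b)
  }
})

test_that("SBS96 profile counts conserve the classified SNV total", {
  g <- shared_genome()
  tm <- shared_tumor()
  snvs <- tm$truth[tm$truth$type == "snv", ]
  snvs$chrom <- paste0(snvs$chrom, "_hap", snvs$hap)
  seqs <- c(g$sequences$hap1, g$sequences$hap2)
  prof <- sbs96_profile(snvs, seqs)
  expect_equal(sum(prof) + attr(prof, "ambiguous"), nrow(snvs))
  snvs$region <- snvs$context
  res <- sbs96_profile_and_test(snvs, seqs)
  expect_true(all(res$tests$p_value >= 0 & res$tests$p_value <= 1))
  expect_true(all(res$tests$fdr >= res$tests$p_value - 1e-12))
})

test_that("the goodness-of-fit test is calibrated and detects real shifts", {
  set.seed(71)
  props <- rep(1 / 96, 96)
  # null draws are not significant at extreme alpha most of the time
  p_null <- replicate(200, {
    obs <- as.integer(rmultinom(1, 500, props))
    sbs96_test(obs, props)$p_value
  })
  expect_gt(mean(p_null > 1e-4), 0.99)
  # a concentrated profile against uniform expectations is detected
  shifted <- c(rep(0L, 95), 500L)
  expect_lt(sbs96_test(shifted, props)$p_value, 1e-10)
})

test_that("Wilson intervals match the hand-computed example", {
  ci <- wilson_ci(5, 100)
  expect_equal(round(ci, 3), c(0.022, 0.112))
  # frozen from the closed form: p=0.05, n=100, z=1.959964
  z <- qnorm(0.975)
  centre <- (0.05 + z^2 / 200) / (1 + z^2 / 100)
  half <- z * sqrt(0.05 * 0.95 / 100 + z^2 / 40000) / (1 + z^2 / 100)
  expect_equal(ci, c(centre - half, centre + half))
  expect_equal(wilson_ci(0, 50)[1], 0)
})

test_that("homopolymer indel rates recover a constructed event rate", {
  # 100 A homopolymers of length 10; 5 carry a somatic 1 bp deletion
  census <- data.frame(chrom = "c", start = seq(0, 99) * 100,
                       end = seq(0, 99) * 100 + 10, base = "A",
                       length = 10L)
  v <- data.frame(type = rep("del", 5), size = 1L, hp_base = "A",
                  hp_len = 10L)
  curve <- homopolymer_indel_rate(v, census)
  row <- curve[curve$base_class == "A/T" & curve$length == 10, ]
  expect_equal(row$n_sites, 100L)
  expect_equal(row$del_rate, 0.05)
  expect_equal(round(c(row$del_lo, row$del_hi), 3), c(0.022, 0.112))
  expect_equal(row$ins_rate, 0)
  # construction-rate recovery within the Wilson interval across seeds
  hits <- 0L
  for (s in 1:20) {
    set.seed(s)
    n_sites <- 400L; rate <- 0.02
    k <- rbinom(1, n_sites, rate)
    cen <- data.frame(chrom = "c", start = seq_len(n_sites),
                      end = seq_len(n_sites) + 12, base = "A",
                      length = 12L)
    vv <- if (k > 0) data.frame(type = rep("ins", k), size = 1L,
                                hp_base = "A", hp_len = 12L) else
      data.frame(type = character(), size = integer(),
                 hp_base = character(), hp_len = integer())
    cr <- homopolymer_indel_rate(vv, cen)
    r <- cr[cr$length == 12, ]
    if (r$ins_lo <= rate && rate <= r$ins_hi) hits <- hits + 1L
  }
  expect_gte(hits, 17L)  # ~95% coverage
})

test_that("poly-A tail lengths tolerate flanked interruptions only", {
  expect_equal(polya_tail_length(paste0("GCGT", strrep("A", 45))), 45L)
  expect_equal(polya_tail_length("GCGTAC"), 0L)
  # AAAAAC AAAAA with tolerance 1: the C is flanked by 5 A's on each side
  s <- paste0("G", strrep("A", 5), "C", strrep("A", 5))
  expect_equal(polya_tail_length(s, tolerance = 1), 11L)
  expect_equal(polya_tail_length(s, tolerance = 0), 5L)
  # an interruption with a short flank does not extend the tail
  s2 <- paste0("G", strrep("A", 3), "C", strrep("A", 5))
  expect_equal(polya_tail_length(s2, tolerance = 1), 5L)
  # two interruptions need tolerance 2 for the full tail
  s3 <- paste0(strrep("A", 5), "C", strrep("A", 5), "G", strrep("A", 6))
  expect_equal(polya_tail_length(s3, tolerance = 0), 6L)
  expect_equal(polya_tail_length(s3, tolerance = 1), 12L)
  expect_equal(polya_tail_length(s3, tolerance = 2), 18L)
  # suffix-scan oracle on random tails
  oracle <- function(seq, tol) {
    ch <- strsplit(seq, "")[[1]]; n <- length(ch)
    if (ch[n] != "A") return(0L)
    for (start in seq_len(n)) {
      suf <- ch[start:n]
      bad <- which(suf != "A")
      if (length(bad) > tol) next
      ok <- TRUE
      for (b in bad) {
        left <- suf[max(1, b - 5):(b - 1)]
        right <- suf[(b + 1):min(length(suf), b + 5)]
        if (b <= 5 || length(left) < 5 || any(left != "A") ||
            length(right) < 5 || any(right != "A") ||
            b + 5 > length(suf)) {
          ok <- FALSE
        }
      }
      if (ok) return(n - start + 1L)
    }
    0L
  }
  set.seed(81)
  for (r in 1:40) {
    seq <- paste0(random_dna(10),
                  paste(sample(c("A", "A", "A", "A", "A", "C", "G"), 40,
                               replace = TRUE), collapse = ""))
    for (tol in 0:2) {
      expect_equal(polya_tail_length(seq, tol), oracle(seq, tol))
    }
  }
})
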