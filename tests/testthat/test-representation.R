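# Lift maps, representation classification, benchmark tiers, clusters.

snv_at <- function(seqs, chrom, pos0, to = NULL) {
  b <- substr(seqs[[chrom]], pos0 + 1, pos0 + 1)
  alt <- if (is.null(to)) setdiff(c("A", "C", "G", "T"), b)[1] else to
  list(chrom = chrom, pos0 = pos0, ref = b, alt = alt)
}

test_that("lifting through blocks is exact, and reverse lift is the identity", {
  set.seed(9)
  ref <- random_dna(3000)
  gl <- data.frame(
    pos0 = c(500L, 1500L),
    ref = c(substr(ref, 501, 501), substr(ref, 1501, 1507)),
    alt = c(paste0(substr(ref, 501, 501), "AACCGG"),
            substr(ref, 1501, 1501)), stringsAsFactors = FALSE)
  lm <- lift_map_from_variants(ref, gl)
  v <- list(chrom = "dsa", pos0 = 2200L, ref = "N")
  lr <- lift_variant(v, lm$map, slop = 50L)
  expect_equal(lr$status, "lifted")
  # net offset: +6 insertion then -6 deletion cancel
  expect_equal(lr$point, 2200L)
  v2 <- list(chrom = "dsa", pos0 = 1000L, ref = "N")
  expect_equal(lift_variant(v2, lm$map, slop = 0L)$point, 1000L - 6L)
  # inverse map restores DSA coordinates for variants inside single blocks
  inv_blocks <- lm$map$blocks
  names(inv_blocks) <- c("ref_chrom", "ref_start", "ref_end", "dsa_chrom",
                         "dsa_start", "dsa_end", "strand")
  inv <- lift_map(inv_blocks)
  back <- lift_variant(list(chrom = "ref", pos0 = lr$point, ref = "N"),
                       inv, slop = 0L)
  expect_equal(back$point, v$pos0)
})

test_that("variants with no block are unliftable; disjoint targets multi-lift", {
  m <- lift_map(data.frame(
    dsa_chrom = "dsa", dsa_start = c(0L, 5000L), dsa_end = c(1000L, 6000L),
    ref_chrom = "ref", ref_start = c(0L, 100000L),
    ref_end = c(1000L, 101000L)))
  v_in_gap <- list(chrom = "dsa", pos0 = 3000L, ref = "A")
  expect_equal(lift_variant(v_in_gap, m)$status, "unliftable")
  v_ok <- list(chrom = "dsa", pos0 = 500L, ref = "A")
  expect_equal(lift_variant(v_ok, m)$status, "lifted")
  # an interval projecting to two far-apart reference loci
  m2 <- lift_map(data.frame(
    dsa_chrom = "dsa", dsa_start = c(0L, 50L), dsa_end = c(50L, 100L),
    ref_chrom = "ref", ref_start = c(0L, 90000L),
    ref_end = c(50L, 90050L)))
  v_span <- list(chrom = "dsa", pos0 = 48L, ref = "AAAA")
  expect_equal(lift_variant(v_span, m2, slop = 30L)$status, "multi_lift")
})

test_that("representation classes follow the documented precedence", {
  set.seed(9)
  ref <- random_dna(5000)
  ins_site <- 2000L; snv_site <- 3000L
  gl <- data.frame(
    pos0 = c(ins_site, snv_site),
    ref = c(substr(ref, ins_site + 1, ins_site + 1),
            substr(ref, snv_site + 1, snv_site + 1)),
    alt = c(paste0(substr(ref, ins_site + 1, ins_site + 1),
                   "CATTAGGACT"), NA), stringsAsFactors = FALSE)
  gl$alt[2] <- setdiff(c("A", "C", "G", "T"), gl$ref[2])[1]
  lm <- lift_map_from_variants(ref, gl)
  refs <- c(ref = ref); dsas <- c(dsa = lm$seq)
  # plain somatic SNV away from germline variation
  v <- snv_at(dsas, "dsa", 500L)
  expect_equal(classify_representation(v, dsas, refs, lm$map)$class,
               "unchanged")
  # somatic SNV that restores the reference base at the germline SNV site
  v2 <- list(chrom = "dsa", pos0 = snv_site + 10L,
             ref = substr(dsas[["dsa"]], snv_site + 11L, snv_site + 11L),
             alt = gl$ref[2])
  expect_equal(classify_representation(v2, dsas, refs, lm$map)$class,
               "reverts_germline")
  # somatic 2 bp deletion inside the germline 10 bp insertion: the
  # reference-based call becomes a net 8 bp insertion (size change)
  p <- ins_site + 4L
  v3 <- list(chrom = "dsa", pos0 = p,
             ref = substr(dsas[["dsa"]], p + 1L, p + 3L),
             alt = substr(dsas[["dsa"]], p + 1L, p + 1L))
  expect_equal(classify_representation(v3, dsas, refs, lm$map)$class,
               "size_changed")
  # somatic SNV inside the germline insertion: no reference base to place
  # it on, so its type changes (appears only via the indel representation)
  v4 <- snv_at(dsas, "dsa", ins_site + 5L)
  expect_equal(classify_representation(v4, dsas, refs, lm$map)$class,
               "type_changed")
  # germline CNV regions win over sequence comparison
  cnv <- data.frame(chrom = "ref", start = 400L, end = 600L)
  expect_equal(classify_representation(v, dsas, refs, lm$map,
                                       germline_cnv = cnv)$class,
               "in_germline_cnv")
  # difficult regions only demote otherwise-unchanged calls
  diff_bed <- data.frame(chrom = "ref", start = 400L, end = 600L)
  expect_equal(classify_representation(v, dsas, refs, lm$map,
                                       difficult = diff_bed)$class,
               "difficult_region")
})

test_that("representation classes partition every somatic variant", {
  set.seed(34)
  ref <- random_dna(20000)
  gpos <- sort(sample(seq(500L, 19000L, by = 600L)))
  gl <- data.frame(pos0 = gpos,
                   ref = substring(ref, gpos + 1L, gpos + 1L),
                   alt = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(gl))) {
    gl$alt[i] <- if (i %% 3 == 0) {
      paste0(gl$ref[i], random_dna(4))          # germline insertions
    } else {
      setdiff(c("A", "C", "G", "T"), gl$ref[i])[1]
    }
  }
  lm <- lift_map_from_variants(ref, gl)
  dsas <- c(dsa = lm$seq); refs <- c(ref = ref)
  set.seed(35)
  sv <- random_variants_on(dsas[["dsa"]], 120, seed = 35)
  sv$chrom <- "dsa"
  classes <- classify_representation_table(sv, dsas, refs, lm$map)$class
  valid <- c("unliftable", "multi_lift", "in_germline_cnv",
             "reverts_germline", "type_changed", "size_changed",
             "position_shift_only", "unchanged", "difficult_region")
  expect_true(all(classes %in% valid))
  expect_equal(length(classes), 120L)
})

test_that("benchmark tiers exclude breakpoints, interference, and germline-near regions", {
  v <- data.frame(
    ref_chrom = "ref",
    ref_start = c(100L, 500L, 900L), ref_end = c(200L, 600L, 1000L),
    class = c("unchanged", "size_changed", "unchanged"),
    stringsAsFactors = FALSE)
  # SV breakpoint 40 bp from the third region: excluded from all tiers
  sv_bed <- data.frame(chrom = "ref", start = 860L, end = 960L)
  germ <- data.frame(chrom = "ref", pos0 = 130L)  # 30 bp inside region 1
  tiers <- build_benchmark_regions(v, exclusions = list(sv_bed),
                                   germline = germ)
  expect_equal(interval_bp(tiers$all), 100 + 100 + 40)
  # size_changed region leaves tier 2
  expect_true(all(subtract_intervals(
    data.frame(chrom = "ref", start = 500L, end = 600L),
    tiers$nogermlineinterference)$end - 0 > 0))
  expect_equal(interval_bp(tiers$nogermlineinterference), 100 + 40)
  # tier 3 removes 50 bp around the germline variant from region 1
  expect_lt(interval_bp(tiers$nogermlinewithin50bp),
            interval_bp(tiers$all))
  expect_equal(interval_bp(tiers$nogermlinewithin50bp),
               (100 - 81) + 100 + 40)
  # with no exclusions and no germline all three tiers coincide
  t0 <- build_benchmark_regions(
    v[v$class == "unchanged", , drop = FALSE])
  expect_equal(t0$all, t0$nogermlineinterference)
  expect_equal(t0$all, t0$nogermlinewithin50bp)
  # unliftable variants contribute to no tier
  t1 <- build_benchmark_regions(
    data.frame(ref_chrom = "ref", ref_start = 0L, ref_end = 100L,
               class = "unliftable"))
  expect_equal(interval_bp(t1$all), 0)
})

# brute-force maximal-run clustering oracle
cluster_oracle <- function(pos, max_gap = 1000, kmin = 6, omin = 2,
                           omax = 5) {
  pos <- sort(pos)
  runs <- split(pos, cumsum(c(TRUE, diff(pos) > max_gap)))
  out <- lapply(runs, function(r) {
    n <- length(r)
    cls <- if (n >= kmin) "kataegis" else if (n >= omin && n <= omax)
      "omikli" else NA_character_
    if (is.na(cls)) return(NULL)
    data.frame(start = min(r), n = n, class = cls)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(out)) data.frame(start = integer(), n = integer(),
                               class = character()) else out
}

test_that("cluster detection handles the documented cases", {
  p <- cluster_params()
  v7 <- data.frame(chrom = "c", pos0 = cumsum(rep(800L, 7)), hap = 1,
                   id = paste0("v", 1:7))
  cl <- detect_clusters(v7, p)
  expect_equal(cl$class, "kataegis")
  expect_equal(cl$n, 7L)
  v3 <- data.frame(chrom = "c", pos0 = c(0L, 400L, 900L), hap = 1,
                   id = paste0("w", 1:3))
  expect_equal(detect_clusters(v3, p)$class, "omikli")
  v1 <- data.frame(chrom = "c", pos0 = 5L, hap = 1, id = "x1")
  expect_equal(nrow(detect_clusters(v1, p)), 0L)
  # gap boundary is inclusive
  v_edge <- data.frame(chrom = "c", pos0 = c(0L, 1000L), hap = 1,
                       id = c("a", "b"))
  expect_equal(nrow(detect_clusters(v_edge, p)), 1L)
  v_out <- data.frame(chrom = "c", pos0 = c(0L, 1001L), hap = 1,
                      id = c("a", "b"))
  expect_equal(nrow(detect_clusters(v_out, p)), 0L)
})

test_that("greedy clustering equals the brute-force oracle at scale", {
  set.seed(55)
  pos <- sort(sample(1:2e7, 10000))
  v <- data.frame(chrom = "c", pos0 = pos, hap = 1,
                  id = sprintf("v%05d", seq_along(pos)))
  got <- detect_clusters(v)
  want <- cluster_oracle(pos)
  expect_equal(nrow(got), nrow(want))
  got <- got[order(got$start), ]
  expect_equal(got$start, want$start)
  expect_equal(got$n, want$n)
  expect_equal(got$class, want$class)
  # member gaps within every cluster respect max_gap
  gaps_ok <- vapply(seq_len(nrow(got)), function(i) {
    mem <- as.integer(sub("v", "", strsplit(got$members[i], ",")[[1]]))
    all(diff(pos[mem]) <= 1000)
  }, TRUE)
  expect_true(all(gaps_ok))
})

test_that("opposite-haplotype collapse creates attributable false omikli", {
  # 3 SNVs with consecutive gaps under 1 kb on the reference, 2 on hap1
  # (too far apart to cluster alone) bridged by 1 on hap2
  v_dsa <- data.frame(chrom = "c", pos0 = c(0L, 800L, 1600L),
                      hap = c(1L, 2L, 1L), id = c("a", "b", "c"))
  dsa_cl <- detect_clusters(v_dsa, provenance = "dsa")
  expect_equal(nrow(dsa_cl), 0L)  # per haplotype nothing clusters
  v_ref <- v_dsa; v_ref$hap <- NULL
  ref_cl <- detect_clusters(v_ref, provenance = "reference")
  expect_equal(ref_cl$class, "omikli")
  info <- data.frame(id = c("a", "b", "c"), hap = c(1L, 2L, 1L))
  att <- compare_cluster_sets(dsa_cl, ref_cl, info)
  ref_rows <- att[att$side == "reference", ]
  expect_equal(ref_rows$status, "false")
  expect_equal(ref_rows$cause, "opposite_haplotypes")
  # a DSA cluster in unliftable satellite has no reference counterpart
  v_k <- data.frame(chrom = "c", pos0 = seq(0L, 5 * 900L, by = 900L),
                    hap = 1L, id = paste0("k", 1:6))
  dsa_k <- detect_clusters(v_k, provenance = "dsa")
  att2 <- compare_cluster_sets(dsa_k, ref_cl[0, ], info)
  expect_equal(att2$status[att2$side == "dsa"], "reference_missed")
  # identical variant sets on both sides: zero false, zero missed
  both <- detect_clusters(v_k, provenance = "reference")
  att3 <- compare_cluster_sets(dsa_k, both,
                               data.frame(id = v_k$id, hap = v_k$hap))
  expect_true(all(att3$status == "matched"))
})
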