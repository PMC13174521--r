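#' @import data.table
#' @importFrom stats rpois rbinom runif rbeta median sd quantile pchisq p.adjust setNames complete.cases
#' @importFrom utils read.table write.table head tail
NULL

# ---- sequence utilities -----------------------------------------------------

#' Generate a random DNA sequence
#'
#' Uses the current RNG state; call [set.seed()] first for reproducibility.
#'
#' @param n Length in bp.
#' @param gc Target GC fraction (sampling probability, not exact composition).
#' @return A single character string of length `n`.
#' @export
random_dna <- function(n, gc = 0.5) {
  if (n <= 0) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Reverse complement of DNA strings
#'
#' @param x Character vector of DNA sequences (ACGT alphabet).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' GC fraction of a sequence
#'
#' @param x A character string or `DNAString`. Ambiguous bases are ignored
#'   in the denominator.
#' @return GC fraction in `[0, 1]`.
#' @export
gc_fraction <- function(x) {
  s <- Biostrings::DNAString(as.character(x))
  f <- Biostrings::letterFrequency(s, letters = c("A", "C", "G", "T"))
  tot <- sum(f)
  if (tot == 0) return(NA_real_)
  unname((f[["C"]] + f[["G"]]) / tot)
}

#' Read FASTA into a named character vector
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write a named character vector of sequences to FASTA
#' @param seqs Named character vector.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
}

# ---- CIGAR / alignment records ----------------------------------------------

parse_cigar <- function(cigar) {
  m <- gregexpr("([0-9]+)([MIDNSHP=X])", cigar)[[1]]
  if (m[1] == -1) stop("malformed CIGAR string: ", cigar)
  toks <- regmatches(cigar, gregexpr("([0-9]+)([MIDNSHP=X])", cigar))[[1]]
  if (sum(nchar(toks)) != nchar(cigar)) stop("malformed CIGAR string: ", cigar)
  data.frame(
    len = as.integer(sub("[MIDNSHP=X]$", "", toks)),
    op = sub("^[0-9]+", "", toks),
    stringsAsFactors = FALSE
  )
}

#' Gap-compressed alignment identity
#'
#' Identity counting every gap run (insertion or deletion) as a single
#' difference event: `matches / (matches + mismatches + gap_openings)`.
#' Requires an extended CIGAR where matches (`=`) and mismatches (`X`) are
#' distinguished; a plain `M` operation is ambiguous and rejected.
#'
#' @param cigar An extended CIGAR string (ops `=`, `X`, `I`, `D`).
#' @return Identity fraction in `[0, 1]`.
#' @export
#' @examples
#' gap_compressed_identity("50=2X1I45=") # 95 / 98
gap_compressed_identity <- function(cigar) {
  ops <- parse_cigar(cigar)
  if (any(ops$op == "M")) {
    stop("CIGAR contains ambiguous 'M'; an extended (=/X) CIGAR is required")
  }
  matches <- sum(ops$len[ops$op == "="])
  mismatches <- sum(ops$len[ops$op == "X"])
  gap_open <- sum(ops$op %in% c("I", "D"))
  denom <- matches + mismatches + gap_open
  if (denom == 0) stop("CIGAR has no aligned bases")
  matches / denom
}

#' Read a PAF alignment file
#'
#' Parses the 12 mandatory PAF columns plus, when present, the `cg:Z` CIGAR
#' tag. No R package on the system reads PAF, so this is a minimal reader for
#' the fields the package consumes.
#'
#' @param path Path to a PAF file.
#' @return A data.frame with columns `qname, qlen, qstart, qend, strand,
#'   tname, tlen, tstart, tend, nmatch, alen, mapq, cigar` (cigar may be NA).
#' @export
read_paf <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) < 12L)
  if (length(bad)) stop("malformed PAF record at line ", bad[1])
  get <- function(i) vapply(parts, `[[`, "", i)
  cg <- vapply(parts, function(p) {
    tags <- p[-(1:12)]
    hit <- grep("^cg:Z:", tags, value = TRUE)
    if (length(hit)) sub("^cg:Z:", "", hit[1]) else NA_character_
  }, "")
  data.frame(
    qname = get(1), qlen = as.integer(get(2)),
    qstart = as.integer(get(3)), qend = as.integer(get(4)),
    strand = get(5),
    tname = get(6), tlen = as.integer(get(7)),
    tstart = as.integer(get(8)), tend = as.integer(get(9)),
    nmatch = as.integer(get(10)), alen = as.integer(get(11)),
    mapq = as.integer(get(12)), cigar = cg,
    stringsAsFactors = FALSE
  )
}

# ---- intervals (0-based half-open) ------------------------------------------

#' Read a BED-like interval file
#'
#' BED 3+ columns, 0-based half-open. Additional columns are kept under the
#' names supplied in `extra_cols`.
#'
#' @param path Path to the file.
#' @param extra_cols Optional character vector naming columns 4, 5, ...
#' @return data.frame with `chrom, start, end` (+ extras).
#' @export
read_intervals <- function(path, extra_cols = NULL) {
  x <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                  comment.char = "#", quote = "")
  if (ncol(x) < 3) stop("BED file must have at least 3 columns")
  names(x)[1:3] <- c("chrom", "start", "end")
  if (!is.null(extra_cols)) {
    k <- min(length(extra_cols), ncol(x) - 3L)
    if (k > 0) names(x)[3 + seq_len(k)] <- extra_cols[seq_len(k)]
  }
  if (any(x$start > x$end)) {
    stop("interval with start > end at row ", which(x$start > x$end)[1])
  }
  x
}

#' Write intervals as BED
#' @param x data.frame with `chrom, start, end` and optional extra columns.
#' @param path Output path.
#' @export
write_intervals <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
}

#' Sort and merge intervals
#'
#' Intervals are 0-based half-open. Overlapping intervals are always merged;
#' abutting intervals (`end == start` of the next) are merged only when
#' `merge_adjacent = TRUE`.
#'
#' @param x data.frame with `chrom, start, end`.
#' @param merge_adjacent Merge book-ended intervals too?
#' @return Sorted, merged data.frame with `chrom, start, end`.
#' @export
merge_intervals <- function(x, merge_adjacent = TRUE) {
  if (nrow(x) == 0) return(x[, c("chrom", "start", "end")])
  x <- x[order(x$chrom, x$start, x$end), , drop = FALSE]
  out <- list()
  for (chrom in unique(x$chrom)) {
    xi <- x[x$chrom == chrom, , drop = FALSE]
    s <- xi$start; e <- xi$end
    cs <- s[1]; ce <- e[1]; res_s <- c(); res_e <- c()
    for (i in seq_along(s)[-1]) {
      joins <- if (merge_adjacent) s[i] <= ce else s[i] < ce
      if (joins) {
        ce <- max(ce, e[i])
      } else {
        res_s <- c(res_s, cs); res_e <- c(res_e, ce)
        cs <- s[i]; ce <- e[i]
      }
    }
    res_s <- c(res_s, cs); res_e <- c(res_e, ce)
    out[[chrom]] <- data.frame(chrom = chrom, start = res_s, end = res_e,
                               stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Subtract one interval set from another
#'
#' @param x,y data.frames with `chrom, start, end` (0-based half-open).
#' @return `x` minus all bases covered by `y`, sorted and merged.
#' @export
subtract_intervals <- function(x, y) {
  x <- merge_intervals(x)
  if (nrow(x) == 0 || nrow(y) == 0) return(x)
  y <- merge_intervals(y)
  out <- list()
  for (i in seq_len(nrow(x))) {
    chrom <- x$chrom[i]; s <- x$start[i]; e <- x$end[i]
    yi <- y[y$chrom == chrom & y$end > s & y$start < e, , drop = FALSE]
    if (nrow(yi) == 0) {
      out[[length(out) + 1L]] <- data.frame(chrom = chrom, start = s, end = e)
      next
    }
    yi <- yi[order(yi$start), , drop = FALSE]
    cur <- s
    for (j in seq_len(nrow(yi))) {
      if (yi$start[j] > cur) {
        out[[length(out) + 1L]] <-
          data.frame(chrom = chrom, start = cur, end = yi$start[j])
      }
      cur <- max(cur, yi$end[j])
    }
    if (cur < e) {
      out[[length(out) + 1L]] <- data.frame(chrom = chrom, start = cur, end = e)
    }
  }
  if (length(out) == 0) {
    return(data.frame(chrom = character(), start = integer(), end = integer()))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Total bp covered by an interval set
#' @param x data.frame with `chrom, start, end`.
#' @return Number of covered bases.
#' @export
interval_bp <- function(x) {
  m <- merge_intervals(x)
  if (nrow(m) == 0) return(0)
  sum(m$end - m$start)
}

# ---- variants ---------------------------------------------------------------

#' Read variants from a VCF file
#'
#' Positions are converted to the package-internal 0-based convention and
#' multiallelic records are split into one row per ALT allele.
#'
#' @param path Path to a VCF (plain or gzipped).
#' @return data.frame with `chrom, pos0, id, ref, alt, qual, filter, info`.
#' @export
read_variants <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v, getINFO = TRUE),
                       stringsAsFactors = FALSE)
  alts <- strsplit(fix$ALT, ",", fixed = TRUE)
  n <- lengths(alts)
  out <- data.frame(
    chrom = rep(fix$CHROM, n),
    pos0 = rep(as.integer(fix$POS), n) - 1L,
    id = rep(fix$ID, n),
    ref = rep(fix$REF, n),
    alt = unlist(alts),
    qual = rep(suppressWarnings(as.numeric(fix$QUAL)), n),
    filter = rep(fix$FILTER, n),
    info = rep(fix$INFO, n),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Write variants to a VCF v4.2 file
#'
#' Converts internal 0-based positions back to 1-based VCF coordinates.
#' `info` may be a character column of pre-formatted INFO strings; missing
#' columns are filled with ".".
#'
#' @param x data.frame with at least `chrom, pos0, ref, alt`.
#' @param path Output path (a `.gz` suffix writes gzipped).
#' @param contigs Optional named integer vector of contig lengths for the
#'   header.
#' @param info_header Optional character vector of extra `##INFO` header lines.
#' @export
write_variants <- function(x, path, contigs = NULL, info_header = NULL) {
  get <- function(col, default) {
    if (col %in% names(x)) as.character(x[[col]]) else rep(default, nrow(x))
  }
  hdr <- c("##fileformat=VCFv4.2", "##source=dsakit")
  if (!is.null(contigs)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(contigs), as.integer(contigs)))
  }
  hdr <- c(hdr, info_header,
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- if (nrow(x) == 0) character() else paste(
    x$chrom, x$pos0 + 1L, get("id", "."), x$ref, x$alt,
    get("qual", "."), get("filter", "PASS"), get("info", "."),
    sep = "\t"
  )
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(c(hdr, body), con)
  invisible(path)
}

#' Normalize a variant (parsimony trim + left alignment)
#'
#' Trims shared suffix/prefix bases and shifts indels as far left as the
#' sequence context allows, the standard normalization applied before any
#' representation comparison.
#'
#' @param chrom_seq Character string: the full sequence of the chromosome.
#' @param pos0 0-based position of the first REF base.
#' @param ref,alt Alleles as written (REF must match `chrom_seq` at `pos0`).
#' @return list(pos0, ref, alt) in normalized form.
#' @export
normalize_variant <- function(chrom_seq, pos0, ref, alt) {
  sub_at <- function(i) substr(chrom_seq, i + 1L, i + 1L)
  stopifnot(substr(chrom_seq, pos0 + 1L, pos0 + nchar(ref)) == ref)
  r <- strsplit(ref, "")[[1]]; a <- strsplit(alt, "")[[1]]
  # right-trim shared bases, refilling from the left reference context so
  # that indels slide left through repeat tracts
  repeat {
    if (length(r) > 0 && length(a) > 0 && r[length(r)] == a[length(a)] &&
        !(length(r) == 1 && length(a) == 1)) {
      r <- r[-length(r)]; a <- a[-length(a)]
      if (length(r) == 0 || length(a) == 0) {
        if (pos0 > 0) {
          pos0 <- pos0 - 1L
          nb <- sub_at(pos0)
          r <- c(nb, r); a <- c(nb, a)
        } else {
          # left sequence edge: re-anchor on the right
          nb <- sub_at(length(r))
          r <- c(r, nb); a <- c(a, nb)
          break
        }
      }
    } else {
      break
    }
  }
  # left-trim shared leading bases while both alleles keep >= 1 base
  while (length(r) > 1 && length(a) > 1 && r[1] == a[1]) {
    r <- r[-1]; a <- a[-1]; pos0 <- pos0 + 1L
  }
  list(pos0 = pos0, ref = paste(r, collapse = ""),
       alt = paste(a, collapse = ""))
}

#' Classify a variant's type and size from its alleles
#' @param ref,alt Allele strings.
#' @return list(type = "snv"|"ins"|"del"|"complex", size = bp changed).
#' @export
variant_type <- function(ref, alt) {
  nr <- nchar(ref); na <- nchar(alt)
  if (nr == 1 && na == 1) return(list(type = "snv", size = 1L))
  if (nr < na && substr(alt, 1, nr) == ref) {
    return(list(type = "ins", size = na - nr))
  }
  if (nr > na && substr(ref, 1, na) == alt) {
    return(list(type = "del", size = nr - na))
  }
  if (nr == na) return(list(type = "complex", size = nr))
  list(type = if (na > nr) "ins" else "del", size = abs(na - nr))
}

# ---- applying variants and lift maps ----------------------------------------

#' Apply variants to a sequence and record the induced alignment map
#'
#' Substitutes each variant's ALT allele for its REF allele, returning the
#' edited sequence together with the block alignment between the source
#' (`src`) and edited (`dst`) coordinate systems. Blocks are broken at
#' indels; SNVs stay inside blocks because they do not shift coordinates.
#'
#' @param seq Character string (source sequence).
#' @param variants data.frame with `pos0, ref, alt` (0-based, non-overlapping
#'   on the source).
#' @return list(seq = edited sequence, blocks = data.frame(src_start, src_end,
#'   dst_start, dst_end)).
#' @export
apply_variants <- function(seq, variants) {
  if (is.null(variants) || nrow(variants) == 0) {
    return(list(seq = seq,
                blocks = data.frame(src_start = 0L, src_end = nchar(seq),
                                    dst_start = 0L, dst_end = nchar(seq))))
  }
  v <- variants[order(variants$pos0), , drop = FALSE]
  ends <- v$pos0 + nchar(v$ref)
  if (any(v$pos0[-1] < ends[-length(ends)])) {
    stop("overlapping variants on the same sequence")
  }
  for (i in seq_len(nrow(v))) {
    obs <- substr(seq, v$pos0[i] + 1L, v$pos0[i] + nchar(v$ref[i]))
    if (obs != v$ref[i]) {
      stop(sprintf("REF mismatch at pos0=%d: expected '%s', found '%s'",
                   v$pos0[i], v$ref[i], obs))
    }
  }
  pieces <- character(2L * nrow(v) + 1L)
  blocks <- list()
  src_cur <- 0L; dst_cur <- 0L
  for (i in seq_len(nrow(v))) {
    gap <- substr(seq, src_cur + 1L, v$pos0[i])
    pieces[2L * i - 1L] <- gap
    pieces[2L * i] <- v$alt[i]
    glen <- v$pos0[i] - src_cur
    nr <- nchar(v$ref[i]); na <- nchar(v$alt[i])
    if (nr == na) {
      # substitution: extend the current block through it
      blocks[[length(blocks) + 1L]] <- c(src_cur, v$pos0[i] + nr,
                                         dst_cur, dst_cur + glen + na)
    } else {
      if (glen > 0 || length(blocks) == 0) {
        blocks[[length(blocks) + 1L]] <- c(src_cur, v$pos0[i],
                                           dst_cur, dst_cur + glen)
      }
    }
    src_cur <- v$pos0[i] + nr
    dst_cur <- dst_cur + glen + na
  }
  pieces[2L * nrow(v) + 1L] <- substr(seq, src_cur + 1L, nchar(seq))
  blocks[[length(blocks) + 1L]] <- c(src_cur, nchar(seq),
                                     dst_cur, dst_cur + nchar(seq) - src_cur)
  b <- do.call(rbind, blocks)
  b <- as.data.frame(b)
  names(b) <- c("src_start", "src_end", "dst_start", "dst_end")
  # coalesce abutting blocks with equal offsets (SNV extensions)
  keep <- rep(TRUE, nrow(b))
  for (i in seq_len(nrow(b))[-1]) {
    j <- max(which(keep[seq_len(i - 1L)]))
    if (b$src_start[i] == b$src_end[j] && b$dst_start[i] == b$dst_end[j] &&
        (b$src_start[i] - b$dst_start[i]) == (b$src_end[j] - b$dst_end[j])) {
      b$src_end[j] <- b$src_end[i]; b$dst_end[j] <- b$dst_end[i]
      keep[i] <- FALSE
    }
  }
  b <- b[keep & (b$src_end > b$src_start | b$dst_end > b$dst_start), ,
         drop = FALSE]
  rownames(b) <- NULL
  list(seq = paste(pieces, collapse = ""), blocks = b)
}
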