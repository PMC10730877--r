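#' 5'-end 4-mer motif profile of a cfDNA fragment set
#'
#' For every counted fragment end, the four reference bases at the 5'
#' terminus are read from the genome (reverse-complemented for ends on the
#' minus template strand) and tallied over all 256 4-mers. cfDNA end-motif
#' composition reflects the nuclease repertoire that cleaved the molecules
#' and shifts systematically in cancer. Fragments on excluded chromosomes
#' (chrY by default) are skipped, as are ends whose 4-mer contains an
#' unidentifiable base (non-ACGT) or falls off the chromosome edge.
#'
#' `ends_mode = "both"` (default) counts both termini of each fragment: the
#' forward-strand 4-mer starting at `start` and the reverse-complement of
#' the four bases ending at `end`. `"five_prime"` counts a single end per
#' fragment, chosen by the fragment's strand field.
#'
#' @param frags a [fragment_set()].
#' @param genome a [Biostrings::DNAStringSet] named by chromosome.
#' @param ends_mode `"both"` or `"five_prime"`.
#' @param k motif length (4).
#' @param exclude_chroms chromosomes to skip entirely.
#' @return an `end_motif_profile`: list with `freq` (named numeric over all
#'   4^k motifs, summing to 1) and `n_counted`.
#' @export
end_motif_profile <- function(frags, genome,
                              ends_mode = c("both", "five_prime"),
                              k = 4L, exclude_chroms = "chrY") {
  ends_mode <- match.arg(ends_mode)
  stopifnot(inherits(frags, "fragment_set"))
  if (!methods::is(genome, "DNAStringSet"))
    genome <- Biostrings::DNAStringSet(genome)
  f <- frags$fragments
  f <- f[!(f$chrom %in% exclude_chroms), , drop = FALSE]
  missing_chrom <- setdiff(unique(f$chrom), names(genome))
  if (length(missing_chrom))
    stop("chromosome(s) absent from genome: ",
         paste(missing_chrom, collapse = ", "), call. = FALSE)
  motifs <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), k)
  counts <- stats::setNames(numeric(length(motifs)), motifs)
  n_counted <- 0L
  for (chrom in unique(f$chrom)) {
    fc <- f[f$chrom == chrom, , drop = FALSE]
    len <- length(genome[[chrom]])
    # 1-based windows on the forward strand for each counted end
    if (ends_mode == "both") {
      fwd_start <- fc$start + 1L
      rev_start <- fc$end - k + 1L
    } else {
      plus <- fc$strand == "+"
      fwd_start <- fc$start[plus] + 1L
      rev_start <- fc$end[!plus] - k + 1L
    }
    fwd_start <- fwd_start[fwd_start >= 1L & fwd_start + k - 1L <= len]
    rev_start <- rev_start[rev_start >= 1L & rev_start + k - 1L <= len]
    seqs <- Biostrings::DNAStringSet()
    if (length(fwd_start))
      seqs <- c(seqs, Biostrings::extractAt(
        genome[[chrom]], IRanges::IRanges(fwd_start, width = k)))
    if (length(rev_start))
      seqs <- c(seqs, Biostrings::reverseComplement(Biostrings::extractAt(
        genome[[chrom]], IRanges::IRanges(rev_start, width = k))))
    if (!length(seqs)) next
    # ends whose 4-mer contains a non-ACGT base match no motif level and
    # drop out of both the counts and n_counted
    cc <- table(factor(as.character(seqs), levels = motifs))
    counts <- counts + as.numeric(cc)
    n_counted <- n_counted + sum(cc)
  }
  if (n_counted == 0L)
    stop("no countable fragment ends (profile undefined)", call. = FALSE)
  structure(list(freq = counts / n_counted, n_counted = as.integer(n_counted)),
            class = "end_motif_profile")
}

#' @export
print.end_motif_profile <- function(x, ...) {
  cat("<end_motif_profile> ", x$n_counted, " ends counted; top motifs: ",
      paste(names(sort(x$freq, decreasing = TRUE))[1:5], collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Window layout for nucleosome-footprint scoring
#'
#' Offsets are in bp relative to the TSS along the direction of
#' transcription, half-open. Defaults: promoter = \[-1000, 1000),
#' background1 = \[-3000, -1000), background2 = \[1000, 3000). These are this
#' package's convention; the footprint contrast is robust to moderate
#' changes in the flanks.
#'
#' @param promoter,background1,background2 length-2 numeric offset intervals.
#' @return a list of the three windows, class `nf_windows`.
#' @export
nf_windows <- function(promoter = c(-1000, 1000),
                       background1 = c(-3000, -1000),
                       background2 = c(1000, 3000)) {
  w <- list(promoter = promoter, background1 = background1,
            background2 = background2)
  for (nm in names(w)) {
    if (length(w[[nm]]) != 2L || w[[nm]][1] >= w[[nm]][2])
      stop("window `", nm, "` must be an increasing length-2 interval",
           call. = FALSE)
  }
  structure(w, class = "nf_windows")
}

# genomic half-open [start0, end0) window for a TSS-relative offset interval
tss_window <- function(tss, strand, offsets) {
  if (strand == "+") c(tss + offsets[1], tss + offsets[2])
  else c(tss - offsets[2] + 1, tss - offsets[1] + 1)
}

#' Nucleosome-footprint (NF) scores at gene promoters
#'
#' Expressed genes leave a nucleosome-depleted region around their TSS, so
#' cfDNA coverage dips at active promoters relative to the flanking
#' background. Per gene, the mean per-bp fragment coverage is computed in a
#' promoter window and two background windows (strand-aware, see
#' [nf_windows()]), each normalized to fragments-per-million so the score is
#' depth-comparable across samples, and
#' \deqn{NF = (background1 + background2)/2 - promoter.}
#' Genes whose windows extend past the chromosome bounds are dropped (a
#' message reports how many).
#'
#' @param frags a [fragment_set()].
#' @param genes data frame with columns `gene_id`, `chrom`, `tss` (0-based
#'   bp of the first transcribed base) and `strand`.
#' @param windows an [nf_windows()] layout.
#' @param chrom_sizes optional named vector of chromosome lengths used for
#'   the bounds check; when `NULL`, only the lower bound (0) is enforced.
#' @return data frame `gene_id`, `promoter_cov`, `bg1_cov`, `bg2_cov`,
#'   `nf_score` (coverage in mean per-bp fragments-per-million units).
#' @export
nf_score <- function(frags, genes, windows = nf_windows(),
                     chrom_sizes = NULL) {
  stopifnot(inherits(frags, "fragment_set"), inherits(windows, "nf_windows"))
  req <- c("gene_id", "chrom", "tss", "strand")
  if (!all(req %in% names(genes)))
    stop("`genes` needs columns ", paste(req, collapse = ", "), call. = FALSE)
  n_frag <- nrow(frags$fragments)
  scale <- if (n_frag > 0L) 1e6 / n_frag else 0

  # genomic windows per gene
  win <- array(NA_real_, dim = c(nrow(genes), 3L, 2L))
  for (j in seq_along(windows))
    for (i in seq_len(nrow(genes)))
      win[i, j, ] <- tss_window(genes$tss[i], genes$strand[i], windows[[j]])
  lo <- apply(win[, , 1, drop = FALSE], 1L, min)
  hi <- apply(win[, , 2, drop = FALSE], 1L, max)
  ok <- lo >= 0
  if (!is.null(chrom_sizes))
    ok <- ok & hi <= unname(chrom_sizes[genes$chrom])
  if (any(!ok))
    message("nf_score: dropped ", sum(!ok),
            " gene(s) with windows outside chromosome bounds")
  genes <- genes[ok, , drop = FALSE]
  win <- win[ok, , , drop = FALSE]
  if (!nrow(genes))
    return(data.frame(gene_id = character(), promoter_cov = numeric(),
                      bg1_cov = numeric(), bg2_cov = numeric(),
                      nf_score = numeric()))

  # coverage Rle per chromosome, padded to span the outermost window
  need_len <- tapply(hi[ok], genes$chrom, max)
  frag_max <- tapply(frags$fragments$end, frags$fragments$chrom, max)
  chroms <- unique(c(names(need_len), names(frag_max)))
  widths <- stats::setNames(rep(0, length(chroms)), chroms)
  widths[names(need_len)] <- pmax(widths[names(need_len)], need_len)
  widths[names(frag_max)] <- pmax(widths[names(frag_max)], frag_max)
  gr <- fragments_granges(frags)
  GenomeInfoDb::seqlevels(gr) <- chroms
  GenomeInfoDb::seqlengths(gr) <- as.integer(widths)
  cov <- GenomicRanges::coverage(gr)

  mean_cov <- matrix(0, nrow(genes), 3L)
  for (chrom in unique(genes$chrom)) {
    idx <- which(genes$chrom == chrom)
    cv <- cov[[chrom]]
    for (j in 1:3) {
      v <- IRanges::Views(cv,
                          start = win[idx, j, 1] + 1L,
                          end = win[idx, j, 2])
      mean_cov[idx, j] <- IRanges::viewMeans(v)
    }
  }
  mean_cov <- mean_cov * scale
  data.frame(gene_id = genes$gene_id,
             promoter_cov = mean_cov[, 1],
             bg1_cov = mean_cov[, 2],
             bg2_cov = mean_cov[, 3],
             nf_score = (mean_cov[, 2] + mean_cov[, 3]) / 2 - mean_cov[, 1],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' hg19 chromosome sizes (chr1-22, X, Y)
#'
#' Lengths in bp of the GRCh37/hg19 primary assembly chromosomes, used for
#' fixed-width genome binning.
#'
#' @return named integer vector.
#' @export
hg19_chrom_sizes <- function() {
  c(chr1 = 249250621L, chr2 = 243199373L, chr3 = 198022430L,
    chr4 = 191154276L, chr5 = 180915260L, chr6 = 171115067L,
    chr7 = 159138663L, chr8 = 146364022L, chr9 = 141213431L,
    chr10 = 135534747L, chr11 = 135006516L, chr12 = 133851895L,
    chr13 = 115169878L, chr14 = 107349540L, chr15 = 102531392L,
    chr16 = 90354753L, chr17 = 81195210L, chr18 = 78077248L,
    chr19 = 59128983L, chr20 = 63025520L, chr21 = 48129895L,
    chr22 = 51304566L, chrX = 155270560L, chrY = 59373566L)
}

#' Tile chromosomes into fixed-width bins
#'
#' Per included chromosome, consecutive half-open bins
#' `[k*bin_size, (k+1)*bin_size)` with a final truncated bin (ceiling
#' convention), in the chromosome order given. With [hg19_chrom_sizes()],
#' 1-Mb bins over chr1-22 + X yield 3053 bins.
#'
#' @param chrom_sizes named vector of chromosome lengths (bp).
#' @param bin_size bin width in bp.
#' @param exclude chromosomes to leave out (default chrY).
#' @return data frame `chrom`, `start`, `end` (0-based half-open).
#' @export
bin_genome <- function(chrom_sizes, bin_size = 1e6, exclude = "chrY") {
  if (!is.numeric(chrom_sizes) || is.null(names(chrom_sizes)) ||
      any(chrom_sizes <= 0))
    stop("`chrom_sizes` must be a named vector of positive lengths",
         call. = FALSE)
  if (bin_size <= 0) stop("`bin_size` must be > 0", call. = FALSE)
  chrom_sizes <- chrom_sizes[!(names(chrom_sizes) %in% exclude)]
  out <- lapply(names(chrom_sizes), function(chrom) {
    len <- chrom_sizes[[chrom]]
    n <- ceiling(len / bin_size)
    start <- (seq_len(n) - 1) * bin_size
    data.frame(chrom = chrom, start = start,
               end = pmin(start + bin_size, len),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Per-bin short-fragment fraction features
#'
#' Assigns each fragment to the bin containing its midpoint and computes,
#' per bin, the fraction of short fragments among short + long
#' (default short = 100-150 bp, long = 151-220 bp, inclusive). Bins with no
#' eligible fragment get `short_frac = 0` and `missing = TRUE`. `zscore`
#' standardizes `short_frac` across non-missing bins within the sample
#' (0 for missing bins; 0 everywhere if the fractions are constant).
#'
#' @param frags a [fragment_set()].
#' @param bins data frame from [bin_genome()].
#' @param short_range,long_range inclusive fragment-length intervals (bp);
#'   must be disjoint.
#' @return `bins` extended with `n_short`, `n_long`, `short_frac`,
#'   `missing`, `zscore`.
#' @export
fragment_bin_features <- function(frags, bins,
                                  short_range = c(100, 150),
                                  long_range = c(151, 220)) {
  stopifnot(inherits(frags, "fragment_set"))
  if (!(short_range[2] < long_range[1] || long_range[2] < short_range[1]))
    stop("`short_range` and `long_range` must be disjoint", call. = FALSE)
  f <- frags$fragments
  len <- f$end - f$start
  cls <- ifelse(len >= short_range[1] & len <= short_range[2], "short",
                ifelse(len >= long_range[1] & len <= long_range[2], "long",
                       NA_character_))
  keep <- !is.na(cls) & f$chrom %in% bins$chrom
  mid <- f$start[keep] + (f$end[keep] - f$start[keep]) %/% 2L
  midg <- GenomicRanges::GRanges(f$chrom[keep],
                                 IRanges::IRanges(mid + 1L, width = 1L))
  bing <- GenomicRanges::GRanges(bins$chrom,
                                 IRanges::IRanges(bins$start + 1L, bins$end))
  hit <- GenomicRanges::findOverlaps(midg, bing, select = "first")
  ok <- !is.na(hit)
  tab <- table(factor(hit[ok], levels = seq_len(nrow(bins))),
               factor(cls[keep][ok], levels = c("short", "long")))
  bins$n_short <- as.integer(tab[, "short"])
  bins$n_long <- as.integer(tab[, "long"])
  tot <- bins$n_short + bins$n_long
  bins$short_frac <- ifelse(tot > 0L, bins$n_short / pmax(tot, 1L), 0)
  bins$missing <- tot == 0L
  z <- rep(0, nrow(bins))
  nm <- !bins$missing
  if (sum(nm) >= 2L && stats::sd(bins$short_frac[nm]) > 0)
    z[nm] <- (bins$short_frac[nm] - mean(bins$short_frac[nm])) /
      stats::sd(bins$short_frac[nm])
  bins$zscore <- z
  bins
}

#' Fragment-size histogram
#'
#' Integer-length counts over a stated range plus the median in-range
#' length. cfDNA from tumors is shifted below the ~166 bp mononucleosomal
#' mode, so the per-sample median is itself a coarse disease signal.
#'
#' @param frags a [fragment_set()].
#' @param range inclusive length interval (bp).
#' @return a `size_histogram`: list with `counts` (named by length) and
#'   `median_size`.
#' @export
size_histogram <- function(frags, range = c(50, 400)) {
  stopifnot(inherits(frags, "fragment_set"), length(range) == 2L,
            range[1] <= range[2])
  len <- fragment_lengths(frags)
  len <- len[len >= range[1] & len <= range[2]]
  if (!length(len))
    stop("no fragments with length in [", range[1], ", ", range[2], "]",
         call. = FALSE)
  lv <- seq.int(range[1], range[2])
  counts <- stats::setNames(tabulate(len - range[1] + 1L,
                                     nbins = length(lv)), lv)
  structure(list(counts = counts, median_size = stats::median(len),
                 range = range),
            class = "size_histogram")
}

#' @export
print.size_histogram <- function(x, ...) {
  cat("<size_histogram> ", sum(x$counts), " fragments in [", x$range[1], ", ",
      x$range[2], "] bp; median ", x$median_size, " bp\n", sep = "")
  invisible(x)
}
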