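#' Filter peaks to the high-confidence set
#'
#' Retains peaks with `q_value < q_max` and `fold_enrichment > fold_min`,
#' both inequalities strict. Defaults (`q < 1e-12`, fold `> 8`) are the
#' thresholds used to call a 5hmC-enriched region highly reliable. Input
#' order is preserved; the operation is idempotent.
#'
#' @param peaks data frame with at least `chrom`, `start`, `end`,
#'   `q_value`, `fold_enrichment`.
#' @param q_max,fold_min positive thresholds.
#' @return the retained subset of `peaks`.
#' @export
filter_high_confidence <- function(peaks, q_max = 1e-12, fold_min = 8) {
  req <- c("chrom", "start", "end", "q_value", "fold_enrichment")
  if (!all(req %in% names(peaks)))
    stop("`peaks` needs columns ", paste(req, collapse = ", "), call. = FALSE)
  if (q_max <= 0 || fold_min <= 0)
    stop("thresholds must be positive", call. = FALSE)
  out <- peaks[peaks$q_value < q_max & peaks$fold_enrichment > fold_min, ,
               drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fragments per kilobase per million mapped (FPKM)
#'
#' `count / ((region_len/1000) * (total_mapped/1e6))` — signal normalized
#' for both region length and library depth.
#'
#' @param count fragments overlapping the region.
#' @param region_len region length in bp, > 0.
#' @param total_mapped total mapped fragments in the library, > 0.
#' @return FPKM value(s); vectorized over `count` and `region_len`.
#' @examples
#' fpkm(100, 2000, 1e7)  # 5
#' @export
fpkm <- function(count, region_len, total_mapped) {
  if (any(region_len <= 0)) stop("`region_len` must be > 0", call. = FALSE)
  if (length(total_mapped) != 1L || total_mapped <= 0)
    stop("`total_mapped` must be a single positive count", call. = FALSE)
  count / ((region_len / 1000) * (total_mapped / 1e6))
}

#' Quantify fragment signal over regions as FPKM
#'
#' Counts, per region, the fragments overlapping it (>= 1 bp by default;
#' `overlap = "midpoint"` counts a fragment iff its midpoint lies inside)
#' and converts to [fpkm()]. Counts are additive over disjoint partitions
#' of a region.
#'
#' @param frags a [fragment_set()].
#' @param regions data frame with `chrom`, `start`, `end` (0-based
#'   half-open) and optionally `region_id`.
#' @param total_mapped library size; defaults to the number of fragments in
#'   `frags`.
#' @param overlap `"any"` or `"midpoint"`.
#' @return `regions` extended with `count` and `fpkm`.
#' @export
quantify_regions <- function(frags, regions, total_mapped = NULL,
                             overlap = c("any", "midpoint")) {
  overlap <- match.arg(overlap)
  stopifnot(inherits(frags, "fragment_set"))
  if (is.null(total_mapped)) total_mapped <- nrow(frags$fragments)
  reg <- GenomicRanges::GRanges(regions$chrom,
                                IRanges::IRanges(regions$start + 1L,
                                                 regions$end))
  qry <- if (overlap == "any") {
    fragments_granges(frags)
  } else {
    f <- frags$fragments
    mid <- f$start + (f$end - f$start) %/% 2L
    GenomicRanges::GRanges(f$chrom, IRanges::IRanges(mid + 1L, width = 1L))
  }
  regions$count <- GenomicRanges::countOverlaps(reg, qry)
  regions$fpkm <- fpkm(regions$count, regions$end - regions$start,
                       total_mapped)
  regions
}

#' Gene-level 5hmC FPKM (promoter + gene body)
#'
#' The region for each gene is the union of its promoter (TSS +/- the
#' flank) and its gene body, merged where they overlap. A fragment is
#' counted once per gene however many sub-intervals it touches; the FPKM
#' length is the total merged width.
#'
#' @param frags a [fragment_set()].
#' @param genes data frame with `gene_id`, `chrom`, `start`, `end` (gene
#'   body, 0-based half-open), `strand`; the TSS is `start` for `+` genes
#'   and `end - 1` for `-` genes.
#' @param promoter_flank bp either side of the TSS (default 1000).
#' @param total_mapped library size; defaults to the fragment count.
#' @param overlap `"any"` or `"midpoint"` (see [quantify_regions()]).
#' @return named numeric vector of FPKM, one entry per gene.
#' @export
quantify_genes <- function(frags, genes, promoter_flank = 1000,
                           total_mapped = NULL,
                           overlap = c("any", "midpoint")) {
  overlap <- match.arg(overlap)
  stopifnot(inherits(frags, "fragment_set"))
  req <- c("gene_id", "chrom", "start", "end", "strand")
  if (!all(req %in% names(genes)))
    stop("`genes` needs columns ", paste(req, collapse = ", "), call. = FALSE)
  if (is.null(total_mapped)) total_mapped <- nrow(frags$fragments)
  tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  prom_lo <- pmax(tss - promoter_flank, 0L)
  prom_hi <- tss + promoter_flank
  mk <- function(lo, hi) GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(lo + 1L, hi))
  parts <- c(mk(genes$start, genes$end), mk(prom_lo, prom_hi))
  grl <- GenomicRanges::reduce(
    S4Vectors::split(parts, rep(genes$gene_id, 2L)))
  grl <- grl[genes$gene_id]  # restore input order
  qry <- if (overlap == "any") {
    fragments_granges(frags)
  } else {
    f <- frags$fragments
    mid <- f$start + (f$end - f$start) %/% 2L
    GenomicRanges::GRanges(f$chrom, IRanges::IRanges(mid + 1L, width = 1L))
  }
  counts <- GenomicRanges::countOverlaps(grl, qry)
  lens <- sum(GenomicRanges::width(grl))
  stats::setNames(fpkm(as.numeric(counts), as.numeric(lens), total_mapped),
                  genes$gene_id)
}

#' Mann-Kendall trend test
#'
#' Nonparametric test for a monotone trend in a sequence:
#' \eqn{S = \sum_{i<j} \mathrm{sign}(x_j - x_i)} (value ties contribute 0),
#' with the tie-corrected normal approximation
#' \eqn{\mathrm{Var}(S) = [n(n-1)(2n+5) - \sum_t t(t-1)(2t+5)]/18} and a
#' continuity-corrected two-sided p. `p_method = "permutation"` instead
#' compares |S| against its permutation distribution — exhaustive for
#' n <= 8, otherwise `n_perm` random shuffles.
#'
#' @param x numeric sequence in its hypothesized order.
#' @param p_method `"normal"` or `"permutation"`.
#' @param n_perm random permutations when exhaustive enumeration is not
#'   feasible.
#' @param seed seed for random permutations.
#' @return list with `S`, `tau` (= S / (n(n-1)/2)), `var_s`, `p`.
#' @export
mann_kendall <- function(x, p_method = c("normal", "permutation"),
                         n_perm = 10000, seed = 1L) {
  p_method <- match.arg(p_method)
  x <- as.numeric(x)
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations", call. = FALSE)
  S <- mk_s(x)
  ties <- table(x)
  ties <- ties[ties > 1L]
  var_s <- (n * (n - 1) * (2 * n + 5) -
              sum(ties * (ties - 1) * (2 * ties + 5))) / 18
  if (p_method == "normal") {
    if (var_s <= 0) {
      p <- 1
    } else {
      z <- (S - sign(S)) / sqrt(var_s)
      p <- 2 * stats::pnorm(-abs(z))
      p <- min(p, 1)
    }
  } else {
    if (n <= 8L) {
      perms <- all_permutations(n)
      s_perm <- apply(perms, 1L, function(idx) mk_s(x[idx]))
    } else {
      s_perm <- withr::with_seed(seed, vapply(
        seq_len(n_perm), function(i) mk_s(sample(x)), numeric(1)))
    }
    p <- mean(abs(s_perm) >= abs(S))
  }
  list(S = S, tau = S / (n * (n - 1) / 2), var_s = var_s, p = p)
}

mk_s <- function(x) {
  n <- length(x)
  s <- 0
  for (i in seq_len(n - 1L))
    s <- s + sum(sign(x[(i + 1L):n] - x[i]))
  as.integer(s)
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub)))
  }))
}

#' Stage trend in per-sample peak counts
#'
#' Tests whether per-sample 5hmC peak counts rise across ordered disease
#' groups (e.g. healthy controls, then stages 0 through IV) with the
#' Mann-Kendall test. Two sequence constructions are reported: per-sample
#' values ordered by group rank with within-group order randomized under
#' `seed` (`"samples"`, the primary result), and the sequence of group
#' medians (`"medians"`).
#'
#' @param counts_by_group named list of numeric vectors, one per group, in
#'   increasing group order (>= 3 groups).
#' @param seed seed for the within-group shuffle.
#' @param p_method passed to [mann_kendall()].
#' @return list with elements `samples` and `medians`, each a
#'   [mann_kendall()] result, plus `sequence` (the sample-level ordering
#'   used).
#' @export
peak_count_trend <- function(counts_by_group, seed = 1L,
                             p_method = c("normal", "permutation")) {
  p_method <- match.arg(p_method)
  if (length(counts_by_group) < 3L)
    stop("need at least 3 ordered groups", call. = FALSE)
  seq_samples <- withr::with_seed(seed, unlist(
    lapply(counts_by_group, function(v)
      if (length(v) > 1L) sample(v) else v),
    use.names = FALSE))
  med <- vapply(counts_by_group, stats::median, numeric(1))
  list(samples = mann_kendall(seq_samples, p_method = p_method, seed = seed),
       medians = mann_kendall(med, p_method = p_method, seed = seed),
       sequence = seq_samples)
}
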