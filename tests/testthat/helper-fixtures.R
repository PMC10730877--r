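# Shared fixtures and independent oracles. Oracles are deliberately naive
# (per-bp loops, exhaustive enumeration) and share no code with the package.

toy_genome <- function(seqs) Biostrings::DNAStringSet(seqs)

toy_frags <- function(chrom, start, end, strand = "+", sample_id = "toy") {
  n <- max(length(chrom), length(start), length(end), length(strand))
  fragment_set(data.frame(chrom = rep_len(chrom, n),
                          start = rep_len(start, n),
                          end = rep_len(end, n),
                          strand = rep_len(strand, n),
                          stringsAsFactors = FALSE),
               sample_id = sample_id)
}

# mean per-bp coverage of [lo, hi) (0-based) by fragments, counted per bp
oracle_mean_coverage <- function(frag_df, chrom, lo, hi) {
  bp <- seq.int(lo, hi - 1L)
  cov <- vapply(bp, function(p) {
    sum(frag_df$chrom == chrom & frag_df$start <= p & frag_df$end > p)
  }, numeric(1))
  mean(cov)
}

# fragments overlapping [lo, hi) (0-based half-open) by >= 1 bp
oracle_overlap_count <- function(frag_df, chrom, lo, hi) {
  sum(frag_df$chrom == chrom & frag_df$start < hi & frag_df$end > lo)
}

# AUC by exhaustive pair counting: wins + half-ties over all (pos, neg)
oracle_auc <- function(scores, y) {
  pos <- scores[y]
  neg <- scores[!y]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# exact two-sided rank-sum p by enumerating all group-1 assignments
oracle_wilcoxon_p <- function(a, b) {
  v <- c(a, b)
  n1 <- length(a)
  r <- rank(v)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(length(v), n1)
  u_all <- apply(combs, 2L, function(idx)
    sum(r[idx]) - n1 * (n1 + 1) / 2)
  p <- min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
  p
}

# Mann-Kendall S by a naive double loop
oracle_mk_s <- function(x) {
  s <- 0
  n <- length(x)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    s <- s + sign(x[j] - x[i])
  s
}

# two-sided permutation p for Mann-Kendall by exhaustive enumeration,
# using an independent iterative permutation generator
oracle_mk_perm_p <- function(x) {
  perms <- list(1L)
  for (m in 2L:length(x)) {
    perms <- unlist(lapply(perms, function(p)
      lapply(seq_len(m), function(k) append(p, m, after = k - 1L))),
      recursive = FALSE)
  }
  s_obs <- oracle_mk_s(x)
  s_all <- vapply(perms, function(p) oracle_mk_s(x[p]), numeric(1))
  mean(abs(s_all) >= abs(s_obs))
}

# small cohort used by unit-level pipeline tests (cached per session)
small_config <- function(depth = 2500L, ...) {
  cohort_config(n_hc = 18L,
                n_escc = c("0" = 4L, I = 4L, II = 4L, III = 4L, IV = 4L),
                n_genes = 40L, n_marker_genes = 10L,
                n_baseline_peaks = 120L, depth = depth, ...)
}

.fixture_env <- new.env(parent = emptyenv())

strong_run <- function() {
  if (is.null(.fixture_env$strong_run)) {
    .fixture_env$strong_run <-
      suppressWarnings(run_pipeline(cohort_config(), seed = 20240101L))
  }
  .fixture_env$strong_run
}
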