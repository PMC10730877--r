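# Seeded synthetic-cohort generator. Produces a small random genome (with a
# decoy chrY so exclusion rules are exercised), a TSS-spaced gene annotation
# with a designated marker-gene subset, a 5hmC peak template, and per-sample
# cfDNA fragment sets whose statistical structure mirrors what the analysis
# assumes: tumor-fraction-driven fragment shortening, 5'-end-motif tilt,
# promoter coverage depletion at marker genes, and stage-increasing 5hmC
# peak counts. Disease effects on end motifs, fragment sizes and promoter
# footprints carry a class-level ("systemic") component on top of the
# tumor-fraction-proportional component, because those signals reflect
# systemic nuclease and chromatin alterations and remain detectable at very
# low tumor burden; the 5hmC gain scales with tumor fraction only, which is
# what makes stage-0 disease hard for the 5hmC analyte alone. Setting every
# tumor fraction to 0 switches all effects off (a pure null cohort).

#' Configuration of the synthetic cfDNA cohort
#'
#' Defaults mirror the study conditions the pipeline is designed for: 71
#' healthy controls and 100 ESCC cases with stage composition
#' 0/I/II/III/IV = 27/23/26/20/4, a monotone stage-to-tumor-fraction map,
#' a healthy fragment-size mode near 166 bp versus a tumor mode near
#' 145 bp, and 5hmC peak counts rising with stage.
#'
#' @param n_hc healthy controls.
#' @param n_escc named integer vector of cases per stage `0, I, II, III, IV`.
#' @param tumor_fraction named numeric, tumor fraction per stage
#'   (non-decreasing).
#' @param n_chrom,chrom_length,gc,chry_length autosome count, length (bp),
#'   GC content, and decoy chrY length.
#' @param n_genes,n_marker_genes genes in the annotation and how many are
#'   disease markers (NF-depleted, 5hmC-gained).
#' @param size_healthy,size_tumor `c(mode, sdlog)` of the discretized
#'   lognormal fragment-size components.
#' @param size_systemic,motif_systemic,nf_systemic class-level effect
#'   weights added to the tumor fraction for ESCC samples (ignored when the
#'   sample's tumor fraction is 0).
#' @param motif_tilt fraction of motif-perturbed fragment placements;
#'   perturbed fragments start at genome positions whose 4-mer begins with
#'   `motif_prefix`.
#' @param motif_prefix 5'-end dinucleotide favored by the tumor nuclease
#'   shift.
#' @param nf_depletion probability that a tumor-affected fragment seated on
#'   a marker promoter is relocated.
#' @param nf_gain multiplier of tumor fraction in the NF effect weight.
#' @param hmc_gain fraction (per unit tumor fraction) of fragments placed
#'   into marker gene bodies.
#' @param n_baseline_peaks,peak_width,extra_peak_rate 5hmC peak template
#'   size, peak width (bp), and expected extra high-confidence tumor peaks
#'   per unit tumor fraction.
#' @param depth fragments per sample.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_hc = 71L,
                          n_escc = c("0" = 27L, I = 23L, II = 26L,
                                     III = 20L, IV = 4L),
                          tumor_fraction = c("0" = 0.01, I = 0.03,
                                             II = 0.06, III = 0.12,
                                             IV = 0.20),
                          n_chrom = 2L, chrom_length = 1e6L, gc = 0.42,
                          chry_length = 2e5L,
                          n_genes = 120L, n_marker_genes = 25L,
                          size_healthy = c(mode = 166, sdlog = 0.15),
                          size_tumor = c(mode = 145, sdlog = 0.15),
                          size_systemic = 0.10, motif_systemic = 0.10,
                          nf_systemic = 0.25,
                          motif_tilt = 0.20, motif_prefix = "CC",
                          nf_depletion = 0.9, nf_gain = 2,
                          hmc_gain = 0.5,
                          n_baseline_peaks = 400L, peak_width = 300L,
                          extra_peak_rate = 1500,
                          depth = 10000L) {
  stages <- c("0", "I", "II", "III", "IV")
  stopifnot(identical(names(n_escc), stages),
            identical(names(tumor_fraction), stages),
            all(diff(tumor_fraction) >= 0),
            all(tumor_fraction >= 0), all(tumor_fraction <= 1),
            n_hc > 0, all(n_escc >= 0), depth > 0, n_genes > 0,
            n_marker_genes <= n_genes)
  structure(as.list(environment()), class = "cohort_config")
}

rand_dna <- function(len, gc) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE, prob = p),
        collapse = "")
}

#' Build the synthetic genome, gene annotation and peak template
#'
#' Random chromosome sequences at the configured GC content plus a decoy
#' chrY; genes with TSS placed at least 5 kb apart on a 5-kb grid away from
#' chromosome edges; a designated marker-gene subset; and a baseline 5hmC
#' peak template. Byte-identical across reruns with the same seed.
#'
#' @param config a [cohort_config()].
#' @param seed RNG seed.
#' @return a `synthetic_genome`: list with `genome`
#'   ([Biostrings::DNAStringSet]), `genes` (data frame with `gene_id`,
#'   `chrom`, `start`, `end`, `strand`, `tss`, `is_marker`),
#'   `peak_template`, `motif_positions` (0-based candidate fragment starts
#'   whose 4-mer begins with the configured prefix), and `chrom_sizes`.
#' @export
make_genome <- function(config, seed = 1L) {
  stopifnot(inherits(config, "cohort_config"))
  if (config$chrom_length < 1e4)
    stop("chromosomes must be at least 10 kb", call. = FALSE)
  withr::with_seed(seed, {
    chroms <- paste0("chr", seq_len(config$n_chrom))
    seqs <- vapply(chroms, function(ch)
      rand_dna(config$chrom_length, config$gc), character(1))
    seqs <- c(seqs, chrY = rand_dna(config$chry_length, config$gc))
    genome <- Biostrings::DNAStringSet(seqs)
    chrom_sizes <- stats::setNames(Biostrings::width(genome), names(genome))

    # TSS candidates on a 5-kb grid, >= 10 kb from either edge
    cand <- do.call(rbind, lapply(chroms, function(ch) {
      pos <- seq(10000L, config$chrom_length - 10000L, by = 5000L)
      data.frame(chrom = ch, tss = pos, stringsAsFactors = FALSE)
    }))
    if (nrow(cand) < config$n_genes)
      stop("genes do not fit the 5-kb TSS spacing on this genome",
           call. = FALSE)
    cand <- cand[sort(sample(nrow(cand), config$n_genes)), , drop = FALSE]
    strand <- sample(c("+", "-"), config$n_genes, replace = TRUE)
    body_len <- sample(2000:8000, config$n_genes, replace = TRUE)
    start <- ifelse(strand == "+", cand$tss, cand$tss + 1L - body_len)
    end <- ifelse(strand == "+", cand$tss + body_len, cand$tss + 1L)
    genes <- data.frame(
      gene_id = sprintf("g%03d", seq_len(config$n_genes)),
      chrom = cand$chrom, start = pmax(start, 0L), end = end,
      strand = strand, tss = cand$tss,
      is_marker = FALSE, stringsAsFactors = FALSE)
    genes$is_marker[sample(config$n_genes, config$n_marker_genes)] <- TRUE

    # candidate starts whose forward 4-mer begins with the motif prefix
    motif_positions <- lapply(chroms, function(ch) {
      m <- Biostrings::matchPattern(config$motif_prefix, genome[[ch]])
      pos <- BiocGenerics::start(m) - 1L
      pos[pos + 600L <= chrom_sizes[[ch]]]
    })
    names(motif_positions) <- chroms

    tmpl <- data.frame(
      chrom = sample(chroms, config$n_baseline_peaks, replace = TRUE),
      stringsAsFactors = FALSE)
    tmpl$start <- vapply(tmpl$chrom, function(ch)
      sample.int(chrom_sizes[[ch]] - config$peak_width, 1L) - 1L, integer(1))
    tmpl$end <- tmpl$start + config$peak_width
    tmpl <- tmpl[order(tmpl$chrom, tmpl$start), , drop = FALSE]
    rownames(tmpl) <- NULL

    structure(list(genome = genome, genes = genes, peak_template = tmpl,
                   motif_positions = motif_positions,
                   chrom_sizes = chrom_sizes, config = config),
              class = "synthetic_genome")
  })
}

# effect weights for one sample; all zero when f == 0
effect_weights <- function(config, f) {
  active <- as.numeric(f > 0)
  list(size = active * min(1, config$size_systemic + f),
       motif = active * min(1, config$motif_systemic + f) *
         config$motif_tilt,
       nf = active * min(1, config$nf_systemic + config$nf_gain * f),
       hmc = min(1, config$hmc_gain * f))
}

#' Simulate one plasma sample
#'
#' Draws `depth` fragments as a mixture of a healthy and a tumor component
#' governed by the stage's tumor fraction (see the file-level notes on the
#' systemic components), a per-sample 5hmC peak table (baseline template
#' peaks plus Poisson-distributed tumor peaks whose statistics pass the
#' high-confidence filter), and QC metrics drawn to pass the gates.
#'
#' @param genome_art a [make_genome()] result.
#' @param stage `"HC"` or one of `"0", "I", "II", "III", "IV"`.
#' @param seed RNG seed.
#' @param sample_id sample identifier.
#' @param tumor_fraction optional override of the stage's tumor fraction.
#' @return a `synthetic_sample`: list with `sample_id`, `label`, `stage`,
#'   `tumor_fraction`, `frags` ([fragment_set()]), `peaks`, and `qc`
#'   (list of wgs and hmc [qc_metrics()]).
#' @export
simulate_sample <- function(genome_art, stage, seed = 1L,
                            sample_id = "sample", tumor_fraction = NULL) {
  stopifnot(inherits(genome_art, "synthetic_genome"))
  config <- genome_art$config
  stages <- c("0", "I", "II", "III", "IV")
  if (!(stage %in% c("HC", stages)))
    stop("unknown stage: ", stage, call. = FALSE)
  f <- if (!is.null(tumor_fraction)) tumor_fraction
  else if (stage == "HC") 0 else unname(config$tumor_fraction[stage])
  w <- effect_weights(config, f)
  sizes_par <- function(p) {
    sdlog <- p[["sdlog"]]
    c(meanlog = log(p[["mode"]]) + sdlog^2, sdlog = sdlog)
  }
  ph <- sizes_par(config$size_healthy)
  pt <- sizes_par(config$size_tumor)
  csz <- genome_art$chrom_sizes
  markers <- genome_art$genes[genome_art$genes$is_marker, , drop = FALSE]

  withr::with_seed(seed, {
    n <- config$depth
    len <- ifelse(stats::runif(n) < w$size,
                  stats::rlnorm(n, pt["meanlog"], pt["sdlog"]),
                  stats::rlnorm(n, ph["meanlog"], ph["sdlog"]))
    len <- as.integer(pmin(pmax(round(len), 60L), 500L))
    chrom <- sample(names(csz), n, replace = TRUE, prob = csz)
    start <- as.integer(floor(stats::runif(n) *
                                (unname(csz[chrom]) - len)))

    u <- stats::runif(n)
    on_auto <- chrom != "chrY"
    # 5hmC gain: relocate into a marker gene body (downstream of promoter)
    hmc_idx <- which(u < w$hmc & on_auto)
    if (length(hmc_idx) && nrow(markers)) {
      gi <- sample.int(nrow(markers), length(hmc_idx), replace = TRUE)
      lo <- pmin(markers$tss[gi] + 1000L, markers$end[gi] - 1L)
      hi <- pmax(markers$end[gi] - len[hmc_idx], lo + 1L)
      chrom[hmc_idx] <- markers$chrom[gi]
      start[hmc_idx] <- lo + floor(stats::runif(length(hmc_idx)) * (hi - lo))
    }
    # motif tilt: seat the fragment start on a perturbed-prefix position
    mot_idx <- which(u >= w$hmc & u < w$hmc + w$motif & on_auto)
    if (length(mot_idx)) {
      for (ch in unique(chrom[mot_idx])) {
        ii <- mot_idx[chrom[mot_idx] == ch]
        pos <- genome_art$motif_positions[[ch]]
        if (length(pos))
          start[ii] <- sample(pos, length(ii), replace = TRUE)
      }
    }
    # NF depletion: relocate tumor-affected fragments off marker promoters
    if (w$nf > 0 && nrow(markers)) {
      fr_gr <- GenomicRanges::GRanges(chrom,
                                      IRanges::IRanges(start + 1L,
                                                       start + len))
      pr_gr <- GenomicRanges::GRanges(
        markers$chrom,
        IRanges::IRanges(pmax(markers$tss - 1000L, 0L) + 1L,
                         markers$tss + 1000L))
      hit <- unique(S4Vectors::queryHits(
        GenomicRanges::findOverlaps(fr_gr, pr_gr)))
      move <- hit[stats::runif(length(hit)) < w$nf * config$nf_depletion]
      if (length(move))
        start[move] <- as.integer(floor(
          stats::runif(length(move)) * (unname(csz[chrom[move]]) -
                                          len[move])))
    }

    frag_df <- data.frame(chrom = chrom, start = start, end = start + len,
                          strand = sample(c("+", "-"), n, replace = TRUE),
                          stringsAsFactors = FALSE)
    qc <- list(
      wgs = qc_metrics("wgs",
                       duplicate_rate = stats::runif(1, 0.05, 0.12),
                       mapping_rate = stats::runif(1, 0.96, 0.995)),
      hmc = qc_metrics("hmc",
                       duplicate_rate = stats::runif(1, 0.35, 0.60),
                       enrichment_fold = stats::runif(1, 100, 150)))
    frags <- fragment_set(frag_df, sample_id = sample_id, qc = qc)

    # per-sample peak table: jittered baseline template + tumor extras
    tmpl <- genome_art$peak_template
    keep <- stats::runif(nrow(tmpl)) < 0.9
    base <- tmpl[keep, , drop = FALSE]
    base$q_value <- 10^(-stats::runif(nrow(base), 8, 20))
    base$fold_enrichment <- stats::runif(nrow(base), 4, 15)
    n_extra <- stats::rpois(1L, config$extra_peak_rate * f)
    if (n_extra > 0) {
      chroms <- setdiff(names(csz), "chrY")
      ech <- sample(chroms, n_extra, replace = TRUE)
      est <- vapply(ech, function(ch)
        sample.int(csz[[ch]] - config$peak_width, 1L) - 1L, integer(1))
      extra <- data.frame(chrom = ech, start = est,
                          end = est + config$peak_width,
                          q_value = 10^(-stats::runif(n_extra, 13, 25)),
                          fold_enrichment = stats::runif(n_extra, 9, 20),
                          stringsAsFactors = FALSE)
      peaks <- rbind(base, extra)
    } else peaks <- base
    peaks <- peaks[order(peaks$chrom, peaks$start), , drop = FALSE]
    rownames(peaks) <- NULL

    structure(list(sample_id = sample_id,
                   label = if (stage == "HC") "HC" else "ESCC",
                   stage = if (stage == "HC") NA_character_ else stage,
                   tumor_fraction = f, frags = frags, peaks = peaks,
                   qc = qc),
              class = "synthetic_sample")
  })
}

# derive a stable 31-bit per-sample seed from the master seed
derive_seed <- function(master, i) {
  as.integer((as.numeric(master) * 1000003 + 7919 * as.numeric(i)) %%
               2147483647)
}

#' Simulate a full two-class cohort
#'
#' Builds the genome artifacts, then one [simulate_sample()] per subject
#' with a per-sample seed derived from the master seed by stable hashing,
#' so the whole cohort is byte-identical across reruns.
#'
#' @param config a [cohort_config()].
#' @param seed master seed.
#' @return a `synthetic_cohort`: list with `genome` (the
#'   [make_genome()] artifacts), `samples` (list of `synthetic_sample`),
#'   and `truth` (data frame `sample_id`, `label`, `stage`,
#'   `tumor_fraction`).
#' @export
simulate_cohort <- function(config = cohort_config(), seed = 1L) {
  stopifnot(inherits(config, "cohort_config"))
  genome_art <- make_genome(config, seed = derive_seed(seed, 0L))
  plan <- data.frame(
    stage = c(rep("HC", config$n_hc),
              rep(names(config$n_escc), config$n_escc)),
    stringsAsFactors = FALSE)
  plan$sample_id <- sprintf("%s_%03d",
                            ifelse(plan$stage == "HC", "HC", "ES"),
                            seq_len(nrow(plan)))
  samples <- lapply(seq_len(nrow(plan)), function(i)
    simulate_sample(genome_art, plan$stage[i],
                    seed = derive_seed(seed, i),
                    sample_id = plan$sample_id[i]))
  truth <- data.frame(
    sample_id = plan$sample_id,
    label = vapply(samples, `[[`, character(1), "label"),
    stage = vapply(samples, `[[`, character(1), "stage"),
    tumor_fraction = vapply(samples, `[[`, numeric(1), "tumor_fraction"),
    stringsAsFactors = FALSE)
  structure(list(genome = genome_art, samples = samples, truth = truth,
                 config = config, seed = seed),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> ", nrow(x$truth), " samples (",
      sum(x$truth$label == "HC"), " HC, ",
      sum(x$truth$label == "ESCC"), " ESCC), depth ",
      x$config$depth, " fragments/sample\n", sep = "")
  invisible(x)
}
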