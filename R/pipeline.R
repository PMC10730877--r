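# End-to-end orchestration: QC -> feature extraction -> marker selection ->
# per-analyte SVM training -> logistic integration -> ROC evaluation, with
# every threshold and seed recorded in a run manifest.

#' Extract the four analyte feature matrices from a cohort
#'
#' Per QC-passing sample: the 256 5'-end 4-mer motif frequencies
#' (`motif:AAAA`, ...), per-gene NF scores (`nf:<gene>`), per-bin
#' short-fragment fractions (`fragbin:<chrom>:<start>-<end>`), gene-level
#' 5hmC FPKM (`hmc:<gene>`), plus the per-sample count of high-confidence
#' 5hmC peaks and the per-sample median fragment size.
#'
#' @param cohort a [simulate_cohort()] result (or a compatible list with
#'   `samples` and `genome` elements).
#' @param bin_size fragment-feature bin width in bp.
#' @param short_range,long_range fragment-length classes for the bin
#'   features (see [fragment_bin_features()]).
#' @return list with matrices `motif`, `nf`, `fragment`, `hmc` (rows =
#'   samples), vector `peak_counts`, and vector `median_size`.
#' @export
extract_features <- function(cohort, bin_size = 1e5,
                             short_range = c(100, 150),
                             long_range = c(151, 220)) {
  art <- cohort$genome
  genes <- art$genes
  bins <- bin_genome(art$chrom_sizes, bin_size = bin_size, exclude = "chrY")
  bin_names <- sprintf("fragbin:%s:%d-%d", bins$chrom, bins$start, bins$end)
  ids <- vapply(cohort$samples, `[[`, character(1), "sample_id")
  per_sample <- lapply(cohort$samples, function(s) {
    prof <- end_motif_profile(s$frags, art$genome)
    nf <- nf_score(s$frags, genes, chrom_sizes = art$chrom_sizes)
    fb <- fragment_bin_features(s$frags, bins, short_range, long_range)
    hmc <- quantify_genes(s$frags, genes)
    hist <- size_histogram(s$frags)
    list(motif = prof$freq,
         nf = stats::setNames(nf$nf_score, nf$gene_id),
         fragment = stats::setNames(fb$short_frac, bin_names),
         hmc = hmc,
         peak_count = nrow(filter_high_confidence(s$peaks)),
         median_size = hist$median_size)
  })
  bind <- function(field, prefix) {
    m <- do.call(rbind, lapply(per_sample, `[[`, field))
    rownames(m) <- ids
    colnames(m) <- paste0(prefix, colnames(m))
    m
  }
  mot <- bind("motif", "motif:")
  nf <- bind("nf", "nf:")
  frag <- do.call(rbind, lapply(per_sample, `[[`, "fragment"))
  rownames(frag) <- ids
  hmc <- bind("hmc", "hmc:")
  list(motif = mot, nf = nf, fragment = frag, hmc = hmc,
       peak_counts = stats::setNames(
         vapply(per_sample, `[[`, numeric(1), "peak_count"), ids),
       median_size = stats::setNames(
         vapply(per_sample, `[[`, numeric(1), "median_size"), ids))
}

#' Run the full multi-analyte pipeline on a (synthetic) cohort
#'
#' Executes, in order: cohort simulation, QC gating, feature extraction,
#' stratified train/test split, analyte-specific marker selection on the
#' training set, per-analyte SVM training, logistic integration (refit on
#' the training analyte scores), and ROC evaluation on the held-out test
#' set. Any stage failure halts with an error naming the stage; the
#' partial manifest is attached to the condition as `manifest`.
#'
#' @param config a [cohort_config()].
#' @param seed master seed; every stage seed is derived from it.
#' @param train_frac training fraction for [split_cohort()].
#' @param bin_size fragment-feature bin width.
#' @return a `pipeline_run`: list with `manifest`, `features`, `split`,
#'   `selection`, `models`, `integration`, and `evaluation`.
#' @export
run_pipeline <- function(config = cohort_config(), seed = 1L,
                         train_frac = 2 / 3, bin_size = 1e5) {
  manifest <- list(
    seed = seed, train_frac = train_frac, bin_size = bin_size,
    thresholds = list(qc_wgs = c(duplicate = 0.15, mapping = 0.95),
                      qc_hmc = c(duplicate = 0.65, enrichment = 95),
                      peak = c(q_max = 1e-12, fold_min = 8),
                      wilcoxon = c(motif = 0.05, nf = 0.001, hmc = 0.001),
                      zero_fraction = 0.10),
    stages = character(0))
  stage <- function(name, expr) {
    res <- tryCatch(force(expr), error = function(e) {
      err <- simpleError(paste0("pipeline failed at stage `", name, "`: ",
                                conditionMessage(e)))
      err$manifest <- manifest
      stop(err)
    })
    manifest$stages[[name]] <<- "pass"
    res
  }

  cohort <- stage("simulate", simulate_cohort(config, seed = seed))
  truth <- cohort$truth

  qc_res <- stage("qc", {
    qtab <- do.call(rbind, lapply(cohort$samples, function(s) {
      data.frame(sample_id = s$sample_id,
                 wgs_pass = qc_gate(s$qc$wgs)$pass,
                 hmc_pass = qc_gate(s$qc$hmc)$pass,
                 stringsAsFactors = FALSE)
    }))
    qtab$pass <- qtab$wgs_pass & qtab$hmc_pass
    qtab
  })
  manifest$qc <- c(total = nrow(qc_res), pass = sum(qc_res$pass),
                   fail = sum(!qc_res$pass))
  keep <- qc_res$sample_id[qc_res$pass]
  cohort$samples <- cohort$samples[match(keep, qc_res$sample_id)]
  truth <- truth[truth$sample_id %in% keep, , drop = FALSE]

  features <- stage("features",
                    extract_features(cohort, bin_size = bin_size))

  split <- stage("split",
                 split_cohort(truth$sample_id, truth$label, truth$stage,
                              train_frac = train_frac,
                              seed = derive_seed(seed, 101L)))
  tr <- split$train; te <- split$test
  lab <- stats::setNames(truth$label, truth$sample_id)

  analytes <- c("motif", "nf", "fragment", "hmc")
  selection <- stage("selection", {
    stats::setNames(lapply(analytes, function(a)
      select_markers(features[[a]][tr, , drop = FALSE], lab[tr],
                     analyte = a, seed = derive_seed(seed, 202L))),
      analytes)
  })
  manifest$n_selected <- vapply(selection, function(s)
    length(s$retained), integer(1))

  models <- stage("train", {
    stats::setNames(lapply(analytes, function(a)
      train_omic_svm(features[[a]][tr, selection[[a]]$retained,
                                   drop = FALSE],
                     lab[tr], seed = derive_seed(seed, 303L))),
      analytes)
  })

  integration <- stage("integrate", {
    score_mat <- function(ids) {
      m <- vapply(analytes, function(a)
        predict(models[[a]], features[[a]][ids, , drop = FALSE]),
        numeric(length(ids)))
      colnames(m) <- analytes
      as.data.frame(m)
    }
    s_tr <- score_mat(tr)
    model <- refit_integration(s_tr, lab[tr])
    int_tr <- integrate_logistic(s_tr$nf, s_tr$fragment, s_tr$motif,
                                 s_tr$hmc, model)
    cutoff <- choose_cutoff(int_tr, lab[tr], rule = "accuracy")
    list(model = model, cutoff = cutoff, scores_train = s_tr,
         score_fun = score_mat)
  })

  evaluation <- stage("evaluate", {
    s_te <- integration$score_fun(te)
    int_te <- integrate_logistic(s_te$nf, s_te$fragment, s_te$motif,
                                 s_te$hmc, integration$model)
    per_analyte <- stats::setNames(lapply(analytes, function(a)
      roc_auc(s_te[[a]], lab[te], cutoff = models[[a]]$cutoff)),
      analytes)
    integrated <- roc_auc(int_te, lab[te], cutoff = integration$cutoff)
    stg <- stats::setNames(truth$stage, truth$sample_id)[te]
    stage_acc <- function(scores, cutoff) {
      pred <- scores >= cutoff
      pos <- lab[te] == "ESCC"
      vapply(c("0", "I", "II", "III", "IV"), function(s) {
        i <- which(pos & !is.na(stg) & stg == s)
        if (!length(i)) NA_real_ else mean(pred[i])
      }, numeric(1))
    }
    list(per_analyte = per_analyte, integrated = integrated,
         scores_test = cbind(s_te, integrated = int_te,
                             label = lab[te], stage = stg),
         stage_accuracy = rbind(
           integrated = stage_acc(int_te, integration$cutoff),
           hmc = stage_acc(s_te$hmc, models$hmc$cutoff)))
  })

  manifest$auc <- c(vapply(evaluation$per_analyte, `[[`, numeric(1), "auc"),
                    integrated = evaluation$integrated$auc)
  structure(list(manifest = manifest, truth = truth, features = features,
                 split = split, selection = selection, models = models,
                 integration = integration, evaluation = evaluation),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("<pipeline_run> stages: ",
      paste(names(x$manifest$stages), collapse = " -> "), "\n", sep = "")
  cat("  samples: ", x$manifest$qc[["pass"]], "/", x$manifest$qc[["total"]],
      " QC-pass; train ", length(x$split$train), ", test ",
      length(x$split$test), "\n", sep = "")
  cat("  AUC:", paste(sprintf("%s %.3f", names(x$manifest$auc),
                              x$manifest$auc), collapse = ", "), "\n")
  invisible(x)
}
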