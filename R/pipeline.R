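#' Default pipeline configuration
#'
#' A desk-scale configuration exercising every stage: simulate a cohort,
#' fit the codec, train the combined MLP+CNN denoiser, generate a synthetic
#' cohort of the training size, decode it, and evaluate quality and privacy.
#'
#' @param seed master seed; stage seeds are derived from it.
#' @return nested configuration list (YAML-serialisable).
#' @export
default_pipeline_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    test_fraction = 0.25,
    cohort = list(n_samples = 600, n_genes = 64, snps_per_gene = c(5, 30),
                  rank_range = c(2, 4), n_causal = 20, effect_size = 2,
                  prevalence = 0.4, ploidy_mode = "genotype"),
    codec = list(depth = 3, threshold = 0.99),
    diffusion = list(T = 200, beta_start = 1e-4, beta_end = 0.02,
                     arch = "unet_mlp_cnn", steps = 1500, batch_size = 16,
                     lr = 1e-3, base_channels = 16),
    generate = list(n = 450),
    evaluate = list(metric = "l2")
  )
}

stage_file <- function(out_dir, name) file.path(out_dir, name)

#' Run the full pipeline
#'
#' Executes simulate, embed, train, generate, decode and evaluate in order,
#' halting on the first error, and writes a run manifest with the config
#' hash, seeds and a checksum for every produced file. Deterministic stages
#' are pure functions of (inputs, config, seed): rerunning with the same
#' manifest reproduces their outputs bit for bit.
#'
#' @param config configuration list (see [default_pipeline_config()]) or
#'   path to a YAML file with the same structure.
#' @param out_dir output directory, created if needed.
#' @param stages subset of stages to run, in pipeline order.
#' @return the manifest list, invisibly; also written as `manifest.json`.
#' @export
run_pipeline <- function(config, out_dir,
                         stages = c("simulate", "embed", "train", "generate",
                                    "decode", "evaluate")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  manifest <- list(config = config,
                   config_hash = config_hash(config),
                   seed = seed, stages = stages, files = list(),
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  note <- function(name, path) {
    manifest$files[[name]] <<- list(path = path,
                                    md5 = unname(tools::md5sum(path)))
  }

  if ("simulate" %in% stages) {
    cc <- do.call(cohort_config, c(config$cohort, list(seed = seed)))
    cohort <- simulate_cohort(cc)
    write_genotypes(cohort$genotypes, stage_file(out_dir, "cohort.tsv"), "tsv")
    write_gene_bed(cohort$map, stage_file(out_dir, "genes.bed"))
    saveRDS(cohort, stage_file(out_dir, "cohort.rds"))
    note("cohort_tsv", stage_file(out_dir, "cohort.tsv"))
    note("genes_bed", stage_file(out_dir, "genes.bed"))
    if (!is.null(cohort$oracle))
      manifest$bayes_accuracy <- cohort$oracle$bayes_accuracy
  }

  if (any(c("embed", "train", "generate", "decode", "evaluate") %in% stages)) {
    cohort <- readRDS(stage_file(out_dir, "cohort.rds"))
  }

  if ("embed" %in% stages) {
    n <- nrow(cohort$genotypes$values)
    split <- with_local_seed(seed + 1L, {
      test_idx <- stratified_subsample(cohort$genotypes$labels,
                                       config$test_fraction, seed + 1L)
      list(test = test_idx, train = setdiff(seq_len(n), test_idx))
    })
    train_gm <- subset_genotypes(cohort$genotypes, split$train)
    test_gm <- subset_genotypes(cohort$genotypes, split$test)
    codec <- fit_gene_codec(train_gm, cohort$map,
                            depth = config$codec$depth,
                            threshold = config$codec$threshold)
    saveRDS(list(codec = codec, split = split), stage_file(out_dir, "codec.rds"))
    emb_train <- encode_genotypes(train_gm, codec)
    emb_test <- encode_genotypes(test_gm, codec)
    saveRDS(list(train = emb_train, test = emb_test),
            stage_file(out_dir, "embeddings.rds"))
    round_trip <- genotype_mismatch(train_gm,
                                    decode_embedding(emb_train, codec))
    manifest$codec_mismatch_pct <- 100 * round_trip
    save_codec(codec, stage_file(out_dir, "codec_archive.rds"))
    note("codec", stage_file(out_dir, "codec_archive.rds"))
  }

  if (any(c("train", "generate", "decode", "evaluate") %in% stages)) {
    cs <- readRDS(stage_file(out_dir, "codec.rds"))
    embs <- readRDS(stage_file(out_dir, "embeddings.rds"))
  }

  if ("train" %in% stages) {
    dcfg <- config$diffusion
    sched <- noise_schedule(dcfg$T, dcfg$beta_start, dcfg$beta_end)
    model <- denoiser(dcfg$arch, G_pad = cs$codec$G_pad,
                      n_classes = length(unique(embs$train$labels)),
                      depth = config$codec$depth,
                      base_channels = dcfg$base_channels %||% 16,
                      seed = seed + 2L)
    fit <- train_denoiser(model, embs$train, sched, steps = dcfg$steps,
                          batch_size = dcfg$batch_size, lr = dcfg$lr,
                          seed = seed + 3L)
    save_denoiser(fit$model, stage_file(out_dir, "model.rds"),
                  codec_fingerprint = manifest$files$codec$md5)
    write.table(fit$log, stage_file(out_dir, "training_log.csv"),
                sep = ",", row.names = FALSE, quote = FALSE)
    note("model", stage_file(out_dir, "model.rds"))
    note("training_log", stage_file(out_dir, "training_log.csv"))
    saveRDS(sched, stage_file(out_dir, "schedule.rds"))
  }

  if (any(c("generate", "decode", "evaluate") %in% stages)) {
    model <- load_denoiser(stage_file(out_dir, "model.rds"))
    sched <- readRDS(stage_file(out_dir, "schedule.rds"))
  }

  if ("generate" %in% stages) {
    classes <- sort(unique(embs$train$labels))
    per_class <- table(factor(embs$train$labels, levels = classes))
    n_gen <- config$generate$n %||% sum(per_class)
    y <- rep(classes, round(n_gen * as.numeric(per_class) / sum(per_class)))
    syn <- sample_embeddings(model, length(y), y, sched,
                             embs$train$clamp_mask, seed = seed + 4L)
    saveRDS(syn, stage_file(out_dir, "synthetic_embedding.rds"))
  }

  if (any(c("decode", "evaluate") %in% stages)) {
    syn <- readRDS(stage_file(out_dir, "synthetic_embedding.rds"))
  }

  if ("decode" %in% stages) {
    syn_gm <- decode_embedding(syn, cs$codec)
    write_genotypes(syn_gm, stage_file(out_dir, "synthetic_cohort.tsv"), "tsv")
    note("synthetic_cohort", stage_file(out_dir, "synthetic_cohort.tsv"))
  }

  if ("evaluate" %in% stages) {
    metric <- config$evaluate$metric %||% "l2"
    nnaa <- adversarial_accuracy(embs$train, syn, metric, seed = seed + 5L)
    pl <- privacy_loss(embs$train, embs$test, syn, metric, seed = seed + 5L)
    dup <- duplicate_audit(embs$train, syn)
    spec <- classifier_spec("mlp", n_classes = length(unique(embs$train$labels)),
                            seed = seed + 6L)
    grid <- recovery_experiment(embs$train, embs$test,
                                list(diffusion = syn), list(mlp = spec))
    report <- list(nnaa = unclass(nnaa),
                   privacy_loss = pl$privacy_loss,
                   privacy_loss_mean_aa = pl$privacy_loss_mean_aa,
                   duplicates = list(n = dup$n_duplicates,
                                     min_l2 = dup$l2$min,
                                     min_l1 = dup$l1$min,
                                     min_cosine = dup$cosine$min),
                   recovery = grid)
    jsonlite::write_json(report, stage_file(out_dir, "evaluation.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    note("evaluation", stage_file(out_dir, "evaluation.json"))
    manifest$evaluation <- report
  }

  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  jsonlite::write_json(manifest, stage_file(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       force = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(config), tmp)
  unname(tools::md5sum(tmp))
}

#' Subset a genotype matrix by sample index
#' @param x a [genotype_matrix()].
#' @param idx sample indices to keep.
#' @return a [genotype_matrix()].
#' @export
subset_genotypes <- function(x, idx) {
  genotype_matrix(x$values[idx, , drop = FALSE], x$sample_ids[idx],
                  x$variants, labels = x$labels[idx],
                  ploidy_mode = x$ploidy_mode)
}
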