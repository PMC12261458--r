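#' Train-synthetic-test-real recovery grid
#'
#' For every (generator, classifier) cell: train the classifier on the real
#' training embeddings (accuracy `a_r` on the held-out real test set), train
#' the same classifier on the synthetic set (`a_s` on the same test set),
#' and report the recovery rate `R = a_s / a_r`. All accuracies are
#' evaluated on real held-out data only.
#'
#' @param real_train,real_test [gene_embedding()]s of real data with labels.
#' @param syn_sets named list of [gene_embedding()]s, one per generator,
#'   label-conditionally generated.
#' @param specs named list of [classifier_spec()]s.
#' @return data.frame with columns classifier, generator, a_r, a_s,
#'   recovery (and recovery_pct on the usual x100 scale).
#' @export
recovery_experiment <- function(real_train, real_test, syn_sets, specs) {
  gd_assert(length(syn_sets) >= 1 && length(specs) >= 1,
            "need at least one synthetic set and one classifier spec")
  if (is.null(names(syn_sets))) names(syn_sets) <- paste0("gen", seq_along(syn_sets))
  if (is.null(names(specs))) names(specs) <- vapply(specs, `[[`, "", "architecture")
  classes <- sort(unique(real_train$labels))
  for (nm in names(syn_sets)) {
    missing <- setdiff(classes, unique(syn_sets[[nm]]$labels))
    gd_assert(length(missing) == 0,
              "synthetic set '", nm, "' lacks class(es) ",
              paste(missing, collapse = ", "))
  }
  rows <- list()
  for (cn in names(specs)) {
    spec <- specs[[cn]]
    real_model <- train_classifier(spec, real_train, real_train$labels)
    a_r <- accuracy(real_model, real_test, real_test$labels)
    for (gn in names(syn_sets)) {
      syn_model <- train_classifier(spec, syn_sets[[gn]], syn_sets[[gn]]$labels)
      a_s <- accuracy(syn_model, real_test, real_test$labels)
      rows[[length(rows) + 1]] <- data.frame(
        classifier = cn, generator = gn, a_r = a_r, a_s = a_s,
        recovery = recovery_rate(a_r, a_s),
        recovery_pct = recovery_rate(a_r, a_s, percent = TRUE),
        seed = spec$seed)
    }
  }
  do.call(rbind, rows)
}

subset_embedding <- function(emb, idx) {
  gene_embedding(emb$tensor[idx, , , drop = FALSE], emb$clamp_mask,
                 labels = emb$labels[idx], sample_ids = emb$sample_ids[idx])
}

bind_embeddings <- function(a, b) {
  gd_assert(all(a$clamp_mask == b$clamp_mask), "clamp masks differ")
  n_a <- dim(a$tensor)[1]
  n_b <- dim(b$tensor)[1]
  tensor <- array(0, c(n_a + n_b, dim(a$tensor)[2], 8))
  tensor[seq_len(n_a), , ] <- a$tensor
  tensor[n_a + seq_len(n_b), , ] <- b$tensor
  gene_embedding(tensor, a$clamp_mask,
                 labels = c(a$labels, b$labels),
                 sample_ids = c(a$sample_ids, b$sample_ids))
}

stratified_subsample <- function(labels, fraction, seed) {
  with_local_seed(seed, {
    idx <- unlist(lapply(split(seq_along(labels), labels), function(ix) {
      k <- max(1L, round(fraction * length(ix)))
      sample(ix, k)
    }))
    sort(idx)
  })
}

#' Data-augmentation experiment
#'
#' Emulates the small-cohort setting: for each fraction `f`, a stratified
#' `f`-subsample of the real training set is used alone, and topped up with
#' synthetic samples to the full training-set size; both classifiers are
#' evaluated on the real held-out test set.
#'
#' @param real_train,real_test labelled [gene_embedding()]s.
#' @param fractions vector of real-data fractions in `(0, 1]`.
#' @param syn_set synthetic [gene_embedding()], large enough to top up.
#' @param spec a [classifier_spec()].
#' @param seed subsampling seed.
#' @return data.frame with fraction, n_real, n_syn, acc_real_only,
#'   acc_augmented.
#' @export
augmentation_experiment <- function(real_train, real_test, fractions,
                                    syn_set, spec, seed = 1L) {
  gd_assert(all(fractions > 0 & fractions <= 1), "fractions must lie in (0,1]")
  n_full <- dim(real_train$tensor)[1]
  rows <- list()
  for (f in fractions) {
    idx <- stratified_subsample(real_train$labels, f, seed)
    tab <- table(real_train$labels[idx])
    gd_assert(all(tab >= 2),
              "fraction ", f, " leaves fewer than 2 samples in a class")
    sub <- subset_embedding(real_train, idx)
    m_plain <- train_classifier(spec, sub, sub$labels)
    acc_plain <- accuracy(m_plain, real_test, real_test$labels)
    n_top <- n_full - length(idx)
    if (n_top > 0) {
      gd_assert(dim(syn_set$tensor)[1] >= n_top,
                "synthetic set too small to top up to the full training size")
      top_idx <- with_local_seed(seed + 1L,
                                 sample.int(dim(syn_set$tensor)[1], n_top))
      aug <- bind_embeddings(sub, subset_embedding(syn_set, top_idx))
    } else {
      aug <- sub
    }
    m_aug <- train_classifier(spec, aug, aug$labels)
    acc_aug <- accuracy(m_aug, real_test, real_test$labels)
    rows[[length(rows) + 1]] <- data.frame(
      fraction = f, n_real = length(idx), n_syn = max(0, n_top),
      acc_real_only = acc_plain, acc_augmented = acc_aug)
  }
  do.call(rbind, rows)
}
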