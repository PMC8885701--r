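#' Minibatch sampling plan
#'
#' @param batch_size Number of indices per minibatch (default 512).
#' @param batches_per_epoch Minibatches per epoch (default 100).
#' @param mode `"pooled"` draws each batch from the whole cohort without
#'   regard to subpopulation membership; `"balanced"` fills each batch with
#'   an equal share from every subpopulation.
#' @param seed Integer seed for the sampler stream.
#' @return A `batch_plan` list.
#' @export
batch_plan <- function(batch_size = 512L, batches_per_epoch = 100L,
                       mode = c("pooled", "balanced"), seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(batch_size >= 1, batches_per_epoch >= 1)
  structure(list(batch_size = as.integer(batch_size),
                 batches_per_epoch = as.integer(batches_per_epoch),
                 mode = mode, seed = as.integer(seed)),
            class = "batch_plan")
}

# chunk a queue of indices into batches, reshuffling the source whenever the
# queue runs dry (so within an epoch a small pool is resampled)
chunk_queue <- function(pool, count, n_batches) {
  out <- vector("list", n_batches)
  queue <- integer(0)
  for (b in seq_len(n_batches)) {
    while (length(queue) < count) {
      queue <- c(queue, pool[sample.int(length(pool))])
    }
    out[[b]] <- queue[seq_len(count)]
    queue <- queue[-seq_len(count)]
  }
  out
}

#' Pooled minibatch indices for one epoch
#'
#' Batches are consecutive chunks of repeatedly reshuffled row permutations,
#' the standard SGD regime: within-batch group composition is random and
#' converges in the long run to the cohort's group fractions.
#'
#' @param cohort A cohort.
#' @param plan A [batch_plan()] with `mode = "pooled"`.
#' @param epoch Epoch number (each epoch gets an independent substream).
#' @return List of `batches_per_epoch` integer index vectors of length
#'   `batch_size`.
#' @export
pooled_batches <- function(cohort, plan, epoch = 1L) {
  stopifnot(inherits(plan, "batch_plan"), plan$mode == "pooled")
  n <- nrow(cohort)
  if (plan$batch_size > n) {
    abort("configuration error: batch_size exceeds cohort size",
          class = "groupdro_config_error")
  }
  withr::with_seed(
    derive_seed(plan$seed, "pooled", epoch),
    chunk_queue(seq_len(n), plan$batch_size, plan$batches_per_epoch)
  )
}

#' Subpopulation-balanced minibatch indices for one epoch
#'
#' Every batch holds `floor(batch_size / K)` indices from each group, the
#' remainder going one each to the first `batch_size %% K` groups in
#' vocabulary order. Groups smaller than their per-epoch demand are resampled
#' (reshuffled with replacement across passes) so minority groups sustain
#' their share of every batch.
#'
#' @inheritParams pooled_batches
#' @param plan A [batch_plan()] with `mode = "balanced"`.
#' @return List of integer index vectors.
#' @export
balanced_batches <- function(cohort, plan, epoch = 1L) {
  stopifnot(inherits(plan, "batch_plan"), plan$mode == "balanced")
  lv <- group_levels(cohort)
  K <- length(lv)
  if (plan$batch_size < K) {
    abort("configuration error: batch_size < number of groups",
          class = "groupdro_config_error")
  }
  codes <- group_codes(cohort$group, lv)
  pools <- lapply(seq_len(K), function(k) which(codes == k))
  if (any(lengths(pools) == 0)) {
    abort(paste0("configuration error: empty group(s): ",
                 paste(lv[lengths(pools) == 0], collapse = ", ")),
          class = "groupdro_config_error")
  }
  counts <- rep(plan$batch_size %/% K, K)
  extra <- plan$batch_size %% K
  if (extra > 0) counts[seq_len(extra)] <- counts[seq_len(extra)] + 1L
  withr::with_seed(derive_seed(plan$seed, "balanced", epoch), {
    per_group <- lapply(seq_len(K), function(k) {
      chunk_queue(pools[[k]], counts[k], plan$batches_per_epoch)
    })
    lapply(seq_len(plan$batches_per_epoch), function(b) {
      unlist(lapply(per_group, `[[`, b), use.names = FALSE)
    })
  })
}

# dispatch on plan mode
make_batches <- function(cohort, plan, epoch) {
  if (plan$mode == "balanced") balanced_batches(cohort, plan, epoch)
  else pooled_batches(cohort, plan, epoch)
}
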