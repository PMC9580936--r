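#' Build the reference side of the pipeline
#'
#' Dereplicates an aligned reference, builds the pairwise sampling plan,
#' trains the distance-preserving latent space, and trains the convolutional
#' encoder on the gap-stripped reference sequences. The result is the
#' reusable "reference component": it is built once and then applied to any
#' number of samples.
#'
#' @param ref An `aligned_ref` tibble (filtered/trimmed as desired).
#' @param n,m Sampling-plan nearest-neighbor and total-partner counts; see
#'   [build_sampling_plan()]. Defaults scale with the reference size
#'   (`min(300, N/4)` and `min(500, N/2)` rounded) so small references stay
#'   valid.
#' @param embed_config An [embedding_config()].
#' @param enc_config An [encoder_config()]; its `input_length` must cover the
#'   gap-stripped reference sequences.
#' @return A list of class `latent_pipeline` with `ref` (dereplicated),
#'   `plan`, `space`, `model`.
#' @export
build_reference_space <- function(ref,
                                  n = NULL, m = NULL,
                                  embed_config = embedding_config(),
                                  enc_config = encoder_config()) {
  derep <- dereplicate_reference(ref)
  N <- nrow(derep)
  if (is.null(n)) n <- max(2L, min(300L, as.integer(N / 4)))
  if (is.null(m)) m <- max(n + 1L, min(500L, as.integer(N / 2)))
  plan <- build_sampling_plan(derep, n = n, m = m)
  space <- train_embedding(derep, plan, embed_config)
  model <- train_encoder(degap(derep$aligned_seq), space, enc_config)
  structure(
    list(ref = derep, plan = plan, space = space, model = model),
    class = "latent_pipeline"
  )
}

#' @export
print.latent_pipeline <- function(x, ...) {
  cat("<latent_pipeline> ", nrow(x$ref), " dereplicated references, ",
      ncol(x$space$coords), "-dim latent space, encoder ",
      if (x$model$trained) "trained" else "untrained", "\n", sep = "")
  invisible(x)
}

#' Denoise a sample with a built pipeline
#'
#' @param pipeline A `latent_pipeline` from [build_reference_space()].
#' @param reads A `read_set` (or character vector of reads).
#' @param params A [denoise_params()].
#' @param min_unique Dereplication minimum copy count (default 2: singletons
#'   removed).
#' @return An annotated `asv_tbl`.
#' @export
pipeline_denoise <- function(pipeline, reads, params = denoise_params(),
                             min_unique = 2) {
  tbl <- dereplicate_reads(reads, min_unique = min_unique)
  denoise_sample(tbl, pipeline$model, pipeline$ref, pipeline$space, params)
}
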