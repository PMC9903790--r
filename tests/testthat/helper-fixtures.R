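# hand-built segmentation objects for testing downstream operations
# without fitting a model
fake_seg <- function(bins, calls, max_post = NULL, n_states = max(calls)) {
  B <- length(calls)
  if (is.null(max_post)) max_post <- rep(1, B)
  post <- matrix((1 - max_post) / max(n_states - 1, 1), B, n_states)
  post[cbind(seq_len(B), calls)] <- max_post
  structure(list(state_call = as.integer(calls),
                 posterior = post,
                 max_posterior = max_post,
                 loglik = NA_real_,
                 n_states = n_states,
                 bins = bins),
            class = "segmentation")
}
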