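#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, then restores the
#' previous RNG state, so seeded package operations do not disturb the
#' caller's random stream. A `NULL` seed evaluates `code` unseeded.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# clamp numeric data into [0, 1]
clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

# stable per-pixel softmax over the channel (3rd) dimension of an H x W x C
# array; returns an array of the same shape whose channels sum to 1
softmax_hwc <- function(logits) {
  d <- dim(logits)
  M <- matrix(logits, ncol = d[3])
  mx <- do.call(pmax, lapply(seq_len(d[3]), function(j) M[, j]))
  E <- exp(M - mx)
  array(E / rowSums(E), dim = d)
}

# cross-entropy loss and logit gradient for one image.
# probs: H x W x C softmax output; labels: H x W integer matrix in 0..C-1
ce_loss_grad <- function(probs, labels, grad = TRUE) {
  d <- dim(probs)
  np <- d[1] * d[2]
  P <- matrix(probs, ncol = d[3])
  ix <- cbind(seq_len(np), as.integer(labels) + 1L)
  loss <- -mean(log(pmax(P[ix], 1e-12)))
  if (!grad) return(list(loss = loss))
  G <- P
  G[ix] <- G[ix] - 1
  list(loss = loss, dlogits = array(G / np, dim = d))
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}
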