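#' Cosine similarity of two feature vectors
#'
#' The inner product divided by the product of the Euclidean norms.  For
#' two full +/-1 vectors of length n differing in exactly k positions the
#' cosine is (n - 2k)/n, so achievable values lie on a grid of step 2/n.
#'
#' @param u,v Numeric vectors of equal length; each must have at least
#'   one nonzero entry.
#' @return A scalar in \[-1, 1\].
#' @export
vector_cosine <- function(u, v) {
  if (length(u) != length(v)) stop("`u` and `v` must have equal length")
  nu <- sqrt(sum(u * u))
  nv <- sqrt(sum(v * v))
  if (nu == 0 || nv == 0) {
    stop("cosine similarity is undefined for a zero vector")
  }
  sum(u * v) / (nu * nv)
}

#' Sample the symbol bank of binary feature vectors
#'
#' Draws `n_stimuli + n_responses` feature vectors (7 + 6 by default) of
#' length `vector_length`, each entry an independent fair draw from
#' \{-1, +1\}.  A candidate bank is accepted only if every pairwise cosine
#' among all vectors (stimulus-stimulus, response-response and
#' stimulus-response pairs alike) respects the similarity cap; otherwise
#' the whole bank is redrawn, so accepted banks are i.i.d. fair-coin
#' vectors conditioned on the acceptance region.
#'
#' @param n_stimuli,n_responses Number of stimulus and response vectors.
#' @param vector_length Features per vector (default 30).
#' @param max_cos Similarity cap (default 0.4).
#' @param cap_mode `"signed"` (default) accepts banks with all pairwise
#'   cosines `<= max_cos`, permitting strongly negative similarities,
#'   which is the literal reading of the cap; `"absolute"` additionally
#'   requires `cos >= -max_cos`, for sensitivity analyses.
#' @param max_attempts Number of full-bank redraws before giving up.
#'
#' @return An object of class `symbol_bank`: a list with matrices
#'   `stimulus` (`n_stimuli x vector_length`) and `response`
#'   (`n_responses x vector_length`), plus the generation settings.
#' @examples
#' set.seed(1)
#' bank <- sample_symbol_bank()
#' dim(bank$stimulus)  # 7 30
#' max_pairwise_cosine(bank)
#' @export
sample_symbol_bank <- function(n_stimuli = 7L, n_responses = 6L,
                               vector_length = 30L, max_cos = 0.4,
                               cap_mode = c("signed", "absolute"),
                               max_attempts = 10000L) {
  cap_mode <- match.arg(cap_mode)
  stopifnot(max_attempts >= 1L, n_stimuli >= 1L, n_responses >= 1L,
            vector_length >= 1L)
  n_total <- n_stimuli + n_responses
  for (attempt in seq_len(max_attempts)) {
    V <- matrix(sample(c(-1, 1), n_total * vector_length, replace = TRUE),
                nrow = n_total, ncol = vector_length)
    cosines <- tcrossprod(V) / vector_length
    off <- cosines[upper.tri(cosines)]
    ok <- all(off <= max_cos)
    if (cap_mode == "absolute") ok <- ok && all(off >= -max_cos)
    if (ok) {
      return(structure(
        list(stimulus = V[seq_len(n_stimuli), , drop = FALSE],
             response = V[n_stimuli + seq_len(n_responses), , drop = FALSE],
             vector_length = as.integer(vector_length),
             max_cos = max_cos, cap_mode = cap_mode),
        class = "symbol_bank"
      ))
    }
  }
  stop(sprintf(
    "failed to sample a symbol bank satisfying the cosine cap %.3g within %d attempts",
    max_cos, max_attempts))
}

#' @export
print.symbol_bank <- function(x, ...) {
  cat(sprintf(
    "<symbol_bank> %d stimulus + %d response vectors of length %d (cos cap %.2f, %s)\n",
    nrow(x$stimulus), nrow(x$response), x$vector_length, x$max_cos,
    x$cap_mode))
  invisible(x)
}

#' Maximum pairwise cosine within a symbol bank
#'
#' @param bank A [sample_symbol_bank()] object.
#' @return The largest cosine over all distinct pairs of bank vectors.
#' @export
max_pairwise_cosine <- function(bank) {
  V <- rbind(bank$stimulus, bank$response)
  cosines <- tcrossprod(V) / ncol(V)
  max(cosines[upper.tri(cosines)])
}

#' Write / read a symbol bank as a plain-text sidecar
#'
#' One vector per row, entries space-separated, stimulus vectors first.
#' The round trip is exact (entries are integers -1/+1).
#'
#' @param bank A `symbol_bank`.
#' @param path File path.
#' @return `write_symbol_bank()` returns `path` invisibly;
#'   `read_symbol_bank()` returns a `symbol_bank`.
#' @param n_stimuli Number of leading rows that are stimulus vectors
#'   (needed on read; default 7).
#' @export
write_symbol_bank <- function(bank, path) {
  V <- rbind(bank$stimulus, bank$response)
  utils::write.table(V, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_symbol_bank
#' @export
read_symbol_bank <- function(path, n_stimuli = 7L) {
  V <- as.matrix(utils::read.table(path))
  dimnames(V) <- NULL
  structure(
    list(stimulus = V[seq_len(n_stimuli), , drop = FALSE],
         response = V[-seq_len(n_stimuli), , drop = FALSE],
         vector_length = ncol(V), max_cos = NA_real_, cap_mode = NA_character_),
    class = "symbol_bank"
  )
}
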