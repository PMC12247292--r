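#' Derive a reproducible stream seed from a master seed
#'
#' Every stochastic stage of the package draws its randomness from a stream
#' keyed by (master seed, stage name, replicate index), so that replicates
#' are independent and any stage can be re-run in isolation with identical
#' output.
#'
#' @param master integer master seed.
#' @param stage character stage name, e.g. \code{"founders"}.
#' @param index integer replicate or round index (default 1).
#' @return An integer seed in \code{[1, 2^31 - 2]}.
#' @examples
#' deriveSeed(42, "founders", 3)
#' @export
deriveSeed <- function(master, stage, index = 1L) {
  stopifnot(is.numeric(master), length(master) == 1L)
  m <- 2147483647 # 2^31 - 1, prime
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% m
  s <- (abs(as.numeric(master)) %% m)
  s <- (s * 48271) %% m
  s <- (s + h * 9349 + as.numeric(index) * 2147) %% m
  as.integer(s %% (m - 2)) + 1L
}

# Compact string key per row of a 0/1 matrix: loci are packed 30 per word
# into doubles (exact for < 2^53), words joined with ",". Used to deduplicate
# haplotypes and to test library membership in O(1) per row.
.keyOf <- function(X) {
  w <- ncol(X)
  if (w == 0L) return(rep("", nrow(X)))
  K <- ceiling(w / 30)
  codes <- vapply(seq_len(K), function(k) {
    idx <- ((k - 1L) * 30L + 1L):min(k * 30L, w)
    as.numeric(X[, idx, drop = FALSE] %*% 2^(seq_along(idx) - 1))
  }, numeric(nrow(X)))
  if (is.null(dim(codes))) codes <- matrix(codes, nrow = nrow(X))
  do.call(paste, c(as.data.frame(codes), sep = ","))
}

# interleave individual indices into haplotype row indices (2 rows per ind)
.hapRows <- function(ind) as.vector(rbind(2L * ind - 1L, 2L * ind))
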