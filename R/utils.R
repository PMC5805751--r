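#' @useDynLib repgenr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rmultinom runif cor quantile setNames dnbinom
#' @importFrom utils write.csv read.csv head modifyList
NULL

NT <- c("A", "C", "G", "T")

# encode a nucleotide string as 0-based integers (N and anything else -> -1)
nt_int <- function(s) {
  v <- match(strsplit(toupper(s), "", fixed = TRUE)[[1]], NT) - 1L
  v[is.na(v)] <- -1L
  v
}

int_nt <- function(v) {
  out <- rep("N", length(v))
  ok <- v >= 0L
  out[ok] <- NT[v[ok] + 1L]
  paste(out, collapse = "")
}

revcomp <- function(s) {
  chartr("ACGTacgtN", "TGCAtgcaN", paste(rev(strsplit(s, "", fixed = TRUE)[[1]]),
                                         collapse = ""))
}

logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(x - m)))
}

# normalize a non-negative vector/matrix row to a probability vector;
# all-zero rows are returned untouched as NA-flag (caller decides)
norm1 <- function(x) {
  s <- sum(x)
  if (s <= 0) return(x)
  x / s
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
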