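#' Germline segment with palindromic extension
#'
#' A germline V, D or J template together with the short palindromic
#' (P-nucleotide) extension appended at its recombination-facing end(s).
#' Deletion counts below zero consume palindromic bases: deletion \code{-k}
#' retains \code{k} P-nucleotides.  V segments are extended at their 3' end
#' only, J segments at their 5' end only, and D segments at both ends.
#'
#' @param name segment label (free-form allele name).
#' @param seg_class one of \code{"V"}, \code{"D"}, \code{"J"}.
#' @param seq nucleotide string over \code{A,C,G,T}.
#' @param max_p maximum number of P-nucleotides modeled (extension length).
#' @param family optional family label (e.g. \code{"J1"}/\code{"J2"} for TRB).
#' @param is_reverse_complement flag for reversed-D templates.
#' @param cdr3_anchor optional 0-based position, in \code{seq}, of the first
#'   base of the conserved CDR3 anchor codon (V cysteine, J phenylalanine or
#'   tryptophan); used by the productivity filter.
#' @return an object of class \code{germline_segment} with fields \code{seq}
#'   and \code{extended_seq}; \code{ext5}/\code{ext3} give the extension
#'   lengths actually applied at each end.
#' @export
germline_segment <- function(name, seg_class, seq, max_p = 4L, family = "",
                             is_reverse_complement = FALSE,
                             cdr3_anchor = NA_integer_) {
  seg_class <- match.arg(seg_class, c("V", "D", "J"))
  seq <- toupper(seq)
  if (nchar(seq) == 0L) stopf("empty germline sequence for %s", name)
  if (grepl("[^ACGT]", seq)) stopf("germline %s contains non-ACGT bases", name)
  seg <- structure(list(name = name, seg_class = seg_class, family = family,
                        seq = seq, extended_seq = seq, ext5 = 0L, ext3 = 0L,
                        is_reverse_complement = is_reverse_complement,
                        cdr3_anchor = as.integer(cdr3_anchor)),
                   class = "germline_segment")
  extend_palindrome(seg, max_p)
}

#' Apply the P-nucleotide extension to a germline segment
#'
#' The reverse complement of the terminal \code{max_p} bases is appended in
#' mirrored orientation at every recombination-facing end, so that truncating
#' the extended sequence at deletion \code{-k} always ends in a perfect
#' reverse-complement mirror of length \code{k}.
#'
#' @param segment a \code{germline_segment}.
#' @param max_p extension length, \code{0 <= max_p <= nchar(segment$seq)}.
#' @return the segment with \code{extended_seq}, \code{ext5}, \code{ext3} set.
#' @export
extend_palindrome <- function(segment, max_p) {
  max_p <- as.integer(max_p)
  if (max_p < 0L) stopf("max_p must be >= 0")
  if (max_p > nchar(segment$seq))
    stopf("max_p (%d) exceeds length of %s", max_p, segment$name)
  core <- segment$seq
  n <- nchar(core)
  p3 <- if (max_p > 0L) revcomp(substr(core, n - max_p + 1L, n)) else ""
  p5 <- if (max_p > 0L) revcomp(substr(core, 1L, max_p)) else ""
  segment$extended_seq <- switch(segment$seg_class,
    V = paste0(core, p3),
    J = paste0(p5, core),
    D = paste0(p5, core, p3))
  segment$ext3 <- if (segment$seg_class %in% c("V", "D")) max_p else 0L
  segment$ext5 <- if (segment$seg_class %in% c("J", "D")) max_p else 0L
  segment
}

#' @export
print.germline_segment <- function(x, ...) {
  cat(sprintf("<germline %s %s, %d nt (+%d/+%d P)%s>\n", x$seg_class, x$name,
              nchar(x$seq), x$ext5, x$ext3,
              if (x$is_reverse_complement) " [revcomp]" else ""))
  invisible(x)
}

#' Read a germline segment library from FASTA
#'
#' One record per allele.  The segment class is taken from the
#' \code{seg_class} argument, or guessed from the first \code{V}/\code{D}/
#' \code{J} character in each record name when \code{seg_class = NULL}.
#' Optional per-record metadata can be embedded in the description line as
#' \code{family=...} and \code{anchor=...} (0-based) tokens.
#'
#' @param path FASTA file.
#' @param seg_class \code{"V"}, \code{"D"}, \code{"J"} or NULL to guess.
#' @param max_p palindromic extension length.
#' @return list of \code{germline_segment}.
#' @export
read_germline_fasta <- function(path, seg_class = NULL, max_p = 4L) {
  recs <- read_sequences(path)
  lapply(seq_along(recs$id), function(i) {
    nm <- recs$id[i]
    desc <- recs$desc[i]
    cls <- seg_class
    if (is.null(cls)) {
      hit <- regmatches(nm, regexpr("[VDJ]", nm))
      if (length(hit) == 0L) stopf("cannot guess segment class of '%s'", nm)
      cls <- hit
    }
    fam <- sub(".*family=([^ ]+).*", "\\1", desc)
    if (identical(fam, desc)) fam <- ""
    anc <- suppressWarnings(as.integer(sub(".*anchor=([0-9]+).*", "\\1", desc)))
    germline_segment(nm, cls, recs$seq[i], max_p = max_p, family = fam,
                     cdr3_anchor = if (is.na(anc)) NA_integer_ else anc)
  })
}

# split a flat segment list into V/D/J sub-lists
split_germline <- function(segs) {
  cls <- vapply(segs, `[[`, "", "seg_class")
  list(V = segs[cls == "V"], D = segs[cls == "D"], J = segs[cls == "J"])
}
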