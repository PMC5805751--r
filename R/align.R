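# Ungapped diagonal scan: best-scoring local window on every diagonal.
# Returns a data.frame of candidate placements (0-based half-open read and
# segment coordinates).  N bases score as mismatches.
diag_windows <- function(rint, sint, s_match = 5, s_mism = -14,
                         min_score = -Inf) {
  L <- length(rint); M <- length(sint)
  offs <- (-(L - 1L)):(M - 1L)
  n <- length(offs)
  offset <- integer(n); score <- numeric(n)
  rs <- integer(n); re <- integer(n); nm <- integer(n); nx <- integer(n)
  mm <- character(n)
  k <- 0L
  for (off in offs) {
    p0 <- max(0L, -off); p1 <- min(L - 1L, M - 1L - off)
    if (p1 < p0) next
    p <- p0:p1
    mt <- rint[p + 1L] >= 0L & rint[p + 1L] == sint[p + off + 1L]
    sc <- ifelse(mt, s_match, s_mism)
    # best-scoring contiguous window via prefix sums:
    # max_e [ S(e) - min_{s<e} S(s) ]
    S <- cumsum(sc)
    pre <- c(0, S[-length(S)])
    val <- S - cummin(pre)
    best <- max(val)
    if (best < min_score) next
    be <- which.max(val)
    bs <- which.min(pre[seq_len(be)])
    w <- bs:be
    k <- k + 1L
    offset[k] <- off; score[k] <- best
    rs[k] <- p[bs]; re[k] <- p[be] + 1L
    nm[k] <- sum(mt[w]); nx[k] <- sum(!mt[w])
    mm[k] <- paste(p[w][!mt[w]], collapse = ";")
  }
  if (k == 0L) return(NULL)
  i <- seq_len(k)
  data.frame(offset = offset[i], score_ungapped = score[i],
             read_start = rs[i], read_end = re[i],
             seg_start = rs[i] + offset[i], seg_end = re[i] + offset[i],
             n_match = nm[i], n_mismatch = nx[i], mismatches = mm[i],
             stringsAsFactors = FALSE)
}

#' Align a read against all germline templates
#'
#' Pre-alignment step of the analysis pipeline: each read is aligned to all
#' V, D and J germline templates (extended with P-nucleotides; D templates
#' additionally in reverse complement) with the Smith-Waterman algorithm,
#' and only placements scoring above the per-class thresholds are kept.
#' The reported \code{score} is the true Smith-Waterman local score (gaps
#' allowed at heavy penalty); coordinates and mismatch maps come from the
#' best ungapped diagonal window, which is what scenario enumeration
#' consumes.  V candidates are anchored toward the read 5' end, J toward
#' the 3' end, and D is searched between the best V and best J placements.
#'
#' @param read nucleotide string over A,C,G,T,N.
#' @param germline a \code{recomb_model} or a list with V/D/J segment lists.
#' @param params a \code{\link{prune_config}} supplying scores/thresholds.
#' @param min_read_len reads shorter than this are rejected.
#' @return list of data.frames (\code{V}, \code{D}, \code{J}), possibly
#'   empty; each row one candidate placement with score, coordinates,
#'   mismatch positions and the offset of its diagonal.
#' @export
align_all <- function(read, germline, params = prune_config(),
                      min_read_len = 15L) {
  if (!nzchar(read)) stopf("empty read")
  if (nchar(read) < min_read_len) {
    message(sprintf("read shorter than %d nt: skipped", min_read_len))
    return(list(V = NULL, D = NULL, J = NULL))
  }
  gl <- if (inherits(germline, "recomb_model")) germline$germline else germline
  rint <- nt_int(read)
  L <- length(rint)
  thr <- c(V = params$thr_v, D = params$thr_d, J = params$thr_j)
  res <- list(V = NULL, D = NULL, J = NULL)
  one_class <- function(segs, cls, window = NULL) {
    rows <- list()
    for (s in segs) {
      sint <- nt_int(s$extended_seq)
      dw <- diag_windows(rint, sint, params$s_match, params$s_mism,
                         min_score = thr[cls] - 15)
      if (is.null(dw)) next
      if (!is.null(window))
        dw <- dw[dw$read_start >= window[1] & dw$read_end <= window[2], ,
                 drop = FALSE]
      if (!nrow(dw)) next
      sw <- cpp_sw_score(rint, sint, params$s_match, params$s_mism,
                         params$s_gap)
      # the Smith-Waterman score (gaps allowed) is reported for the best
      # placement; other diagonals carry their own ungapped window score
      dw$score <- dw$score_ungapped
      if (is.null(window)) {
        top <- which.max(dw$score_ungapped)
        dw$score[top] <- max(dw$score_ungapped[top], sw)
      }
      dw <- dw[dw$score >= thr[cls], , drop = FALSE]
      if (!nrow(dw)) next
      dw$segment <- s$name
      dw$seg_class <- cls
      dw$is_reverse_complement <- s$is_reverse_complement
      rows[[length(rows) + 1L]] <- dw
    }
    if (!length(rows)) return(NULL)
    df <- do.call(rbind, rows)
    df[order(-df$score, df$segment, df$offset), , drop = FALSE]
  }
  res$V <- one_class(gl$V, "V")
  res$J <- one_class(gl$J, "J")
  if (length(gl$D)) {
    win <- c(0L, L)
    if (!is.null(res$V)) win[1] <- res$V$read_end[1]
    if (!is.null(res$J)) win[2] <- res$J$read_start[1]
    dtempl <- c(gl$D, lapply(gl$D, function(s) {
      rc <- germline_segment(paste0(s$name, "_rc"), "D", revcomp(s$seq),
                             max_p = s$ext5, is_reverse_complement = TRUE)
      rc
    }))
    if (win[2] > win[1]) res$D <- one_class(dtempl, "D", window = win)
  }
  res
}

#' Deletion values consistent with an alignment placement
#'
#' Given a candidate placement on a fixed diagonal, returns the interval of
#' deletion values that keep the retained germline portion inside the read
#' and inside the configured event-space ranges; negative values are allowed
#' only while palindromic bases remain.
#'
#' @param alignment one row of an \code{\link{align_all}} data.frame.
#' @param model a \code{recomb_model} (supplies ranges and segment lengths).
#' @return for V or J, an integer vector of feasible deletion values (may be
#'   empty); for D, a list with \code{dl} and \code{dr} vectors.
#' @export
feasible_deletions <- function(alignment, model) {
  cls <- alignment$seg_class
  off <- alignment$offset
  L <- nchar(alignment$read %||% "") # optional
  segs <- model$germline[[cls]]
  s <- segs[[match(sub("_rc$", "", alignment$segment),
                   sub("_rc$", "", vapply(segs, `[[`, "", "name")))]]
  Lc <- nchar(s$seq)
  if (cls == "V") {
    rng <- model$del_range$V[1]:model$del_range$V[2]
    # boundary x = Lc - d - off must satisfy 1 <= x and x <= read_end bound
    ok <- (Lc - rng - off) >= 1L & rng <= Lc - 1L
    return(rng[ok])
  }
  if (cls == "J") {
    rng <- model$del_range$J[1]:model$del_range$J[2]
    ok <- (model$max_p + rng - off) >= 0L & rng <= Lc - 1L
    return(rng[ok])
  }
  dl <- model$del_range$Dl[1]:model$del_range$Dl[2]
  dr <- model$del_range$Dr[1]:model$del_range$Dr[2]
  list(dl = dl[model$max_p + dl - off >= 0L & dl <= Lc],
       dr = dr[dr <= Lc])
}

#' Write an alignment dump CSV
#'
#' @param alignments named list of \code{\link{align_all}} outputs keyed by
#'   read id.
#' @param path output CSV.
#' @return path, invisibly.
#' @export
write_alignment_csv <- function(alignments, path) {
  rows <- list()
  for (id in names(alignments)) {
    al <- alignments[[id]]
    for (cls in c("V", "D", "J")) {
      df <- al[[cls]]
      if (is.null(df)) next
      rows[[length(rows) + 1L]] <- data.frame(
        read_id = id, seg_class = cls, segment = df$segment,
        score = df$score, read_start = df$read_start,
        read_end = df$read_end, seg_start = df$seg_start,
        seg_end = df$seg_end, mismatches = df$mismatches,
        stringsAsFactors = FALSE)
    }
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
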