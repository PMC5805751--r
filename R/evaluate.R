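#' Kullback-Leibler divergence between two recombination models
#'
#' Exact chain-rule computation over the conditional probability tables (no
#' Monte Carlo): \code{D(theta1 || theta2) = sum_E P(E, theta1) log2[P(E,
#' theta1) / P(E, theta2)]} over all scenarios E, decomposed into additive
#' per-feature contributions.  Each conditional term is weighted by the
#' theta1-marginal of its conditioners; the insertion-nucleotide chains are
#' handled exactly by propagating the theta1 distribution of the chain state
#' (starting from the distribution of the conditioning germline boundary
#' base) and weighting step k by \code{P1(len >= k)}.  Reported in bits.
#'
#' @param model_a theta1 (the reference measure).
#' @param model_b theta2.
#' @return object of class \code{kl_report}: \code{total_bits} and named
#'   \code{per_event_bits}; when theta2 is zero where theta1 is positive the
#'   total is +Inf and the offending cells are attached as attribute
#'   \code{zero_cells}.
#' @export
kl_divergence <- function(model_a, model_b) {
  if (model_a$chain != model_b$chain)
    stopf("models have different chain types")
  bad <- list()
  kl_vec <- function(p, q, what) {
    i <- p > 0
    if (any(i & q <= 0)) {
      bad[[what]] <<- which(i & q <= 0)
      return(Inf)
    }
    sum(p[i] * log2(p[i] / q[i]))
  }
  kl_rows <- function(wt, P, Q, what) {
    tot <- 0
    for (i in seq_len(nrow(P))) {
      if (wt[i] <= 0) next
      tot <- tot + wt[i] * kl_vec(P[i, ], Q[i, ], paste0(what, ":", i))
    }
    tot
  }
  # exact insertion-chain divergence
  kl_chain <- function(plen, p0, T1, T2, what) {
    tot <- 0
    state <- p0
    for (k in seq_len(length(plen) - 1L)) {
      wk <- sum(plen[(k + 1L):length(plen)])  # P1(len >= k)
      if (wk <= 0) break
      step <- 0
      for (b in 1:4) {
        if (state[b] <= 0) next
        step <- step + state[b] * kl_vec(T1[b, ], T2[b, ],
                                         paste0(what, ":", NT[b]))
      }
      tot <- tot + wk * step
      state <- as.numeric(state %*% T1)
    }
    tot
  }
  boundary_base_dist <- function(model, side) {
    # distribution of the chain-conditioning germline base under the model
    d <- rep(0, 4)
    if (side == "V") {
      segs <- model$germline$V
      pv <- if (model$chain == "VDJ") model$gene$p_v else rowSums(model$gene$p_vj)
      for (v in seq_along(segs)) {
        Lc <- nchar(segs[[v]]$seq)
        for (k in seq_len(ncol(model$del_v))) {
          pr <- pv[v] * model$del_v[v, k]
          if (pr <= 0) next
          del <- as.integer(colnames(model$del_v)[k])
          b <- match(substr(segs[[v]]$extended_seq, Lc - del, Lc - del), NT)
          d[b] <- d[b] + pr
        }
      }
    } else {
      segs <- model$germline$J
      pj <- if (model$chain == "VDJ") colSums(model$gene$p_dj)
            else colSums(model$gene$p_vj)
      for (j in seq_along(segs)) {
        for (k in seq_len(ncol(model$del_j))) {
          pr <- pj[j] * model$del_j[j, k]
          if (pr <= 0) next
          del <- as.integer(colnames(model$del_j)[k])
          b <- match(substr(segs[[j]]$extended_seq, model$max_p + del + 1L,
                            model$max_p + del + 1L), NT)
          d[b] <- d[b] + pr
        }
      }
    }
    d / sum(d)
  }

  per <- c()
  if (model_a$chain == "VJ") {
    per["gene_usage"] <- kl_vec(as.numeric(model_a$gene$p_vj),
                                as.numeric(model_b$gene$p_vj), "p_vj")
    pv <- rowSums(model_a$gene$p_vj)
    pj <- colSums(model_a$gene$p_vj)
    per["del_v"] <- kl_rows(pv, model_a$del_v, model_b$del_v, "del_v")
    per["del_j"] <- kl_rows(pj, model_a$del_j, model_b$del_j, "del_j")
    per["ins_vj_len"] <- kl_vec(model_a$ins_vj, model_b$ins_vj, "ins_vj")
    per["ins_vj_nt"] <- kl_chain(model_a$ins_vj,
                                 boundary_base_dist(model_a, "V"),
                                 model_a$mk_vj, model_b$mk_vj, "mk_vj")
  } else {
    per["gene_v"] <- kl_vec(model_a$gene$p_v, model_b$gene$p_v, "p_v")
    per["gene_dj"] <- kl_vec(as.numeric(model_a$gene$p_dj),
                             as.numeric(model_b$gene$p_dj), "p_dj")
    pv <- model_a$gene$p_v
    pd <- rowSums(model_a$gene$p_dj)
    pj <- colSums(model_a$gene$p_dj)
    per["del_v"] <- kl_rows(pv, model_a$del_v, model_b$del_v, "del_v")
    per["del_j"] <- kl_rows(pj, model_a$del_j, model_b$del_j, "del_j")
    dd <- 0
    for (g in seq_len(dim(model_a$del_d)[1]))
      dd <- dd + (if (pd[g] > 0)
        pd[g] * kl_vec(as.numeric(model_a$del_d[g, , ]),
                       as.numeric(model_b$del_d[g, , ]),
                       paste0("del_d:", g)) else 0)
    per["del_d"] <- dd
    per["ins_vd_len"] <- kl_vec(model_a$ins_vd, model_b$ins_vd, "ins_vd")
    per["ins_dj_len"] <- kl_vec(model_a$ins_dj, model_b$ins_dj, "ins_dj")
    per["ins_vd_nt"] <- kl_chain(model_a$ins_vd,
                                 boundary_base_dist(model_a, "V"),
                                 model_a$mk_vd, model_b$mk_vd, "mk_vd")
    per["ins_dj_nt"] <- kl_chain(model_a$ins_dj,
                                 boundary_base_dist(model_a, "J"),
                                 model_a$mk_dj, model_b$mk_dj, "mk_dj")
  }
  out <- structure(list(total_bits = sum(per), per_event_bits = per),
                   class = "kl_report")
  if (length(bad)) attr(out, "zero_cells") <- bad
  out
}

#' @export
print.kl_report <- function(x, ...) {
  cat(sprintf("<kl_report: %.4f bits>\n", x$total_bits))
  print(round(x$per_event_bits, 5))
  invisible(x)
}

#' True-scenario rank statistics on annotated synthetic reads
#'
#' Compares annotations against the generator's ground truth: distribution
#' of the rank of the true scenario in the likelihood-ranked list, top-1
#' (maximum-likelihood) exact-scenario accuracy, per-feature accuracy of
#' the top-1 scenario, and the number of top scenarios needed to include
#' the truth with a given confidence across reads.  Scenario identity is
#' exact match on all fields (gene names, all deletions, insertion
#' strings); an equivalent scenario with different labels counts as a
#' mismatch.  Failed reads count as incorrect and carry infinite rank.
#'
#' @param truth truth data.frame from \code{\link{generate_batch}}.
#' @param summary annotation summary from \code{\link{annotate_batch}} run
#'   with this truth.
#' @param conf confidence levels for the scenario-coverage number.
#' @return list: \code{ranks}, \code{top1_accuracy}, \code{feature_accuracy},
#'   \code{n_conf} (named: smallest k such that the true scenario lies in
#'   the top k for a fraction conf of reads), \code{n_failed}.
#' @export
rank_stats <- function(truth, summary,
                       conf = c(0.5, 0.75, 0.9, 0.95)) {
  ix <- match(summary$read_id, truth$read_id)
  if (anyNA(ix)) stopf("truth/annotation read id mismatch")
  tr <- truth[ix, ]
  ranks <- summary$truth_rank
  ranks[is.na(ranks) | summary$failed] <- Inf
  same <- function(a, b) !is.na(a) & !is.na(b) & a == b
  vdj <- "top_d" %in% names(summary) && any(!is.na(summary$top_d))
  f_v <- same(summary$top_v, tr$v)
  f_j <- same(summary$top_j, tr$j)
  if (vdj) {
    f_d <- same(summary$top_d, tr$d)
    f_del <- same(summary$top_del_v, tr$del_v) &
      same(summary$top_del_j, tr$del_j) &
      same(summary$top_del_d_l, tr$del_d_l) &
      same(summary$top_del_d_r, tr$del_d_r)
    f_ins <- same(summary$top_ins_vd, tr$ins_vd) &
      same(summary$top_ins_dj, tr$ins_dj)
    f_all <- f_v & f_d & f_j & f_del & f_ins
  } else {
    f_del <- same(summary$top_del_v, tr$del_v) &
      same(summary$top_del_j, tr$del_j)
    f_ins <- same(summary$top_ins_vj, tr$ins_vj)
    f_all <- f_v & f_j & f_del & f_ins
  }
  nconf <- vapply(conf, function(f) {
    as.numeric(stats::quantile(ranks, f, type = 1, names = FALSE))
  }, 0)
  names(nconf) <- paste0("N_", conf)
  out <- list(ranks = ranks,
              top1_accuracy = mean(f_all),
              feature_accuracy = c(
                scenario = mean(f_all), v_gene = mean(f_v),
                d_gene = if (vdj) mean(f_d) else NA_real_,
                j_gene = mean(f_j), deletions = mean(f_del),
                insertions = mean(f_ins),
                failed = mean(summary$failed)),
              n_conf = nconf,
              n_failed = sum(summary$failed))
  out
}

#' Frequency of reads compatible with tandem (double) D usage
#'
#' For each read, searches the window between the best V and best J
#' alignments for two non-overlapping D placements of at least
#' \code{min_len} aligned and matching nucleotides (both D orientations
#' considered).  The frequency is meant to be compared between real data
#' and a single-D synthetic control, where chance alignments set the
#' baseline.
#'
#' @param reads named character vector.
#' @param model a \code{recomb_model} with D segments.
#' @param min_len minimum matched length per D placement (default 10).
#' @param params a \code{\link{prune_config}}.
#' @return list: \code{frequency}, per-read logical \code{flags},
#'   \code{n_eval} (reads with V and J anchors), \code{n_excluded}.
#' @export
tandem_d_frequency <- function(reads, model, min_len = 10L,
                               params = prune_config()) {
  gl <- model$germline
  if (!length(gl$D)) stopf("model has no D segments")
  dtempl <- c(gl$D, lapply(gl$D, function(s)
    germline_segment(paste0(s$name, "_rc"), "D", revcomp(s$seq),
                     max_p = s$ext5, is_reverse_complement = TRUE)))
  flags <- logical(length(reads))
  excluded <- logical(length(reads))
  for (i in seq_along(reads)) {
    rint <- nt_int(reads[[i]])
    al <- align_all(reads[[i]], model, params = params)
    if (is.null(al$V) || is.null(al$J)) { excluded[i] <- TRUE; next }
    win <- c(al$V$read_end[1], al$J$read_start[1])
    if (win[2] - win[1] < 2L * min_len) next
    hits <- list()
    for (s in dtempl) {
      dw <- diag_windows(rint, nt_int(s$extended_seq), 5, -14,
                         min_score = 5 * min_len - 28)
      if (is.null(dw)) next
      dw <- dw[dw$read_start >= win[1] & dw$read_end <= win[2] &
               dw$n_match >= min_len, , drop = FALSE]
      if (nrow(dw)) hits[[length(hits) + 1L]] <- dw
    }
    if (length(hits) < 1L) next
    h <- do.call(rbind, hits)
    # any two non-overlapping placements?
    if (nrow(h) >= 2L) {
      h <- h[order(h$read_start), , drop = FALSE]
      for (p in seq_len(nrow(h) - 1L)) {
        if (any(h$read_start[(p + 1L):nrow(h)] >= h$read_end[p])) {
          flags[i] <- TRUE
          break
        }
      }
    }
  }
  list(frequency = mean(flags[!excluded]), flags = flags,
       n_eval = sum(!excluded), n_excluded = sum(excluded))
}
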