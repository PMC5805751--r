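#' Pruning and scoring configuration for scenario enumeration
#'
#' @param prune_ratio branches whose optimistic probability bound falls below
#'   \code{prune_ratio} times the best complete scenario found so far are
#'   discarded (0 disables pruning entirely).
#' @param floor likelihood floor: reads with \code{P_read} below it are
#'   reported as failed rather than annotated.
#' @param k_top number of ranked scenarios retained per read.
#' @param thr_v,thr_j,thr_d alignment-score thresholds per segment class.
#' @param s_match,s_mism,s_gap alignment scores (gap applies to the
#'   Smith-Waterman scoring in \code{\link{align_all}}; scenario enumeration
#'   itself is gapless).
#' @param mm_budget log-likelihood budget (nats) used to cap the number of
#'   mismatches considered for a single segment placement.
#' @return a named list.
#' @export
prune_config <- function(prune_ratio = 1e-4, floor = 1e-40, k_top = 100L,
                         thr_v = 35, thr_j = 25, thr_d = 15,
                         s_match = 5, s_mism = -14, s_gap = -50,
                         mm_budget = 45) {
  list(prune_ratio = prune_ratio, floor = floor, k_top = as.integer(k_top),
       thr_v = thr_v, thr_j = thr_j, thr_d = thr_d, s_match = s_match,
       s_mism = s_mism, s_gap = s_gap, mm_budget = mm_budget)
}

cpp_opts <- function(prune, exact = FALSE, want_stats = FALSE, truth = NULL,
                     k_top = NULL) {
  list(exact = exact, thr_v = prune$thr_v, thr_j = prune$thr_j,
       s_match = prune$s_match, s_mism = prune$s_mism,
       prune_ratio = prune$prune_ratio, floor_lp = log(prune$floor),
       mm_budget = prune$mm_budget,
       k_top = as.integer(k_top %||% prune$k_top),
       want_stats = want_stats, truth = truth)
}

# truth row (R-side, gene names + named fields) -> numeric vector for C++
truth_vec <- function(truth_row, model) {
  t <- truth_row
  vi <- match(t$v, vapply(model$germline$V, `[[`, "", "name")) - 1L
  ji <- match(t$j, vapply(model$germline$J, `[[`, "", "name")) - 1L
  if (model$chain == "VDJ") {
    di <- match(t$d, vapply(model$germline$D, `[[`, "", "name")) - 1L
    as.numeric(c(vi, di, ji, t$del_v, t$del_d_l, t$del_d_r, t$del_j,
                 t$x, t$a, t$y))
  } else {
    as.numeric(c(vi, -1, ji, t$del_v, 0, 0, t$del_j, t$x, t$x, t$y))
  }
}

#' Enumerate recombination scenarios for one read
#'
#' Lists scenarios consistent with the read (gene choices, deletions
#' including P-nucleotides, insertions, mismatches explained as errors or
#' hypermutations), ranked by decreasing \code{P_scenario = P_recomb x
#' P_err}.  Enumeration explores a fixed event-tree order with
#' branch-and-bound pruning; \code{P_read} is the sum over enumerated
#' scenarios and \code{truncated_mass_bound} an upper bound on what pruning
#' discarded.
#'
#' @param read nucleotide string.
#' @param model a \code{recomb_model}.
#' @param alignments optional result of \code{\link{align_all}} used to
#'   restrict the candidate V/J gene sets (genes absent from it are not
#'   considered); by default the enumerator performs its own candidate
#'   search with the same score thresholds.
#' @param hm_model optional \code{pwm_model}; overrides the model's error
#'   component with context-dependent hypermutation probabilities.
#' @param prune a \code{\link{prune_config}}.
#' @param read_id id stored in the result.
#' @param truth optional named list/row with the true scenario (fields
#'   \code{v,d,j,del_v,del_d_l,del_d_r,del_j,x,a,y}); when given, the rank of
#'   the true scenario among all enumerated scenarios is reported.
#' @return an object of class \code{annotation_result}: ranked scenario
#'   data frame, \code{log_p_read}, \code{n_scenarios}, \code{failed} flag,
#'   \code{truncated_mass_bound}, and rank/likelihood of the truth if given.
#' @export
enumerate_scenarios <- function(read, model, alignments = NULL,
                                hm_model = NULL, prune = prune_config(),
                                read_id = "read", truth = NULL) {
  if (!nzchar(read)) stopf("empty read")
  if (!is.null(hm_model)) model$err <- list(kind = "pwm", pwm = hm_model)
  if (!is.null(alignments)) model <- restrict_model(model, alignments)
  cm <- compile_model(model)
  tv <- if (is.null(truth)) NULL else truth_vec(truth, model)
  res <- cpp_annotate(nt_int(read), cm, cpp_opts(prune, truth = tv))
  build_annotation(res, read, model, read_id)
}

restrict_model <- function(model, alignments) {
  keepv <- unique(alignments$V$segment)
  keepj <- unique(alignments$J$segment)
  vn <- vapply(model$germline$V, `[[`, "", "name")
  jn <- vapply(model$germline$J, `[[`, "", "name")
  if (length(keepv)) {
    drop <- !(vn %in% keepv)
    if (model$chain == "VDJ") model$gene$p_v[drop] <- 0
    else model$gene$p_vj[drop, ] <- 0
    model$del_v[drop, ] <- 0   # structurally removes the gene's rows
  }
  if (length(keepj)) {
    drop <- !(jn %in% keepj)
    if (model$chain == "VDJ") model$gene$p_dj[, drop] <- 0
    else model$gene$p_vj[, drop] <- 0
    model$del_j[drop, ] <- 0
  }
  model
}

build_annotation <- function(res, read, model, read_id) {
  sc <- res$scenarios
  df <- NULL
  if (!is.null(sc) && nrow(sc) > 0) {
    vn <- vapply(model$germline$V, `[[`, "", "name")
    jn <- vapply(model$germline$J, `[[`, "", "name")
    df <- data.frame(rank = sc[, "rank"],
                     v = vn[sc[, "v"]], stringsAsFactors = FALSE)
    if (model$chain == "VDJ") {
      dn <- vapply(model$germline$D, `[[`, "", "name")
      df$d <- dn[sc[, "d"]]
    }
    df$j <- jn[sc[, "j"]]
    df$del_v <- sc[, "del_v"]
    if (model$chain == "VDJ") {
      df$del_d_l <- sc[, "del_d_l"]
      df$del_d_r <- sc[, "del_d_r"]
    }
    df$del_j <- sc[, "del_j"]
    x <- sc[, "x"]; a <- sc[, "a"]; b <- sc[, "b"]; y <- sc[, "y"]
    if (model$chain == "VDJ") {
      df$ins_vd <- substr(rep(read, nrow(sc)), x + 1, a)
      df$ins_dj <- substr(rep(read, nrow(sc)), b + 1, y)
    } else {
      df$ins_vj <- substr(rep(read, nrow(sc)), x + 1, y)
    }
    df$x <- x; df$a <- a; df$b <- b; df$y <- y
    df$n_mismatch <- sc[, "mm"]
    df$logp <- sc[, "logp"]
    df$log_p_recomb <- sc[, "logprecomb"]
    df$posterior <- exp(df$logp - res$log_pread)
  }
  structure(list(read_id = read_id, read = read,
                 scenarios = df,
                 log_p_read = res$log_pread,
                 p_read = exp(res$log_pread),
                 n_scenarios = res$n_scenarios,
                 failed = res$failed,
                 truncated_mass_bound = res$pruned_bound,
                 truth_logp = res$truth_logp,
                 truth_rank = if (is.na(res$truth_logp)) Inf
                              else res$rank_above + 1),
            class = "annotation_result")
}

#' @export
print.annotation_result <- function(x, ...) {
  cat(sprintf("<annotation %s: log P_read = %.3f, %d scenario(s)%s>\n",
              x$read_id, x$log_p_read, x$n_scenarios,
              if (x$failed) " [FAILED]" else ""))
  if (!is.null(x$scenarios)) print(utils::head(x$scenarios, 5), ...)
  invisible(x)
}

#' Generation probability of a nucleotide sequence
#'
#' \code{P_gen}: the summed recombination probability \code{P_recomb} of all
#' scenarios reconstructing the sequence exactly (no error factor).  The
#' sequence is interpreted, like reads, as a 3'-anchored window of the
#' recombined product.
#'
#' @param sequence nucleotide string (assumed error-free).
#' @param model a \code{recomb_model}.
#' @param prune a \code{\link{prune_config}}; by default pruning is disabled
#'   so the sum is exact over the enumerable scenario space.
#' @return probability (0 with a warning when unalignable).
#' @export
pgen <- function(sequence, model, prune = prune_config(prune_ratio = 0)) {
  cm <- compile_model(model)
  res <- cpp_annotate(nt_int(sequence), cm,
                      cpp_opts(prune, exact = TRUE, k_top = 0L))
  if (res$n_scenarios == 0) {
    warning("sequence cannot be reconstructed by the model; Pgen = 0")
    return(0)
  }
  exp(res$log_pread)
}

#' Approximate generation probability of a (hyper)mutated read
#'
#' Because the unmutated ancestral sequence of a mutated read is uncertain,
#' \code{P_gen} is estimated as the geometric mean of the generation
#' probabilities of the candidate ancestral sequences, weighted by their
#' posterior probabilities \code{P_gen x P_err / P_read}; the ancestors and
#' their weights are read off the enumerated scenario list.  The maximum a
#' posteriori ancestor is available as an alternative estimator.
#'
#' @param read nucleotide string.
#' @param model a \code{recomb_model}.
#' @param hm_model optional \code{pwm_model} hypermutation model (otherwise
#'   the model's own error component is used).
#' @param prune a \code{\link{prune_config}}; \code{k_top} bounds the number
#'   of scenarios from which ancestors are collected.
#' @param method \code{"geometric"} (posterior-weighted geometric mean) or
#'   \code{"map"} (Pgen of the most likely ancestral sequence).
#' @return list with \code{p_gen}, \code{log_p_gen}, the ancestor table and
#'   the annotation result.
#' @export
pgen_mutated <- function(read, model, hm_model = NULL,
                         prune = prune_config(k_top = 500L),
                         method = c("geometric", "map")) {
  method <- match.arg(method)
  ann <- enumerate_scenarios(read, model, hm_model = hm_model, prune = prune)
  if (ann$failed || is.null(ann$scenarios))
    return(list(p_gen = NA_real_, log_p_gen = NA_real_, failed = TRUE,
                ancestors = NULL, annotation = ann))
  sc <- ann$scenarios
  anc <- vapply(seq_len(nrow(sc)), function(i)
    scenario_ancestor(ann$read, model, sc[i, ])$ancestor, "")
  ag <- split(seq_len(nrow(sc)), anc)
  w <- vapply(ag, function(ix) sum(exp(sc$logp[ix] - ann$log_p_read)), 0)
  lg <- vapply(ag, function(ix) logsumexp(sc$log_p_recomb[ix]), 0)
  w <- w / sum(w)  # renormalize over retained scenarios
  lpg <- if (method == "geometric") sum(w * lg) else lg[which.max(w)]
  list(p_gen = exp(lpg), log_p_gen = lpg, failed = FALSE,
       ancestors = data.frame(ancestor = names(ag), weight = unname(w),
                              log_p_gen = unname(lg)),
       annotation = ann)
}

# rebuild the ancestral (pre-error) window of a read under one scenario row
scenario_ancestor <- function(read, model, row) {
  x <- row$x; a <- row$a; b <- row$b; y <- row$y
  L <- nchar(read)
  vi <- match(row$v, vapply(model$germline$V, `[[`, "", "name"))
  ji <- match(row$j, vapply(model$germline$J, `[[`, "", "name"))
  V <- model$germline$V[[vi]]; J <- model$germline$J[[ji]]
  Lv <- nchar(V$seq)
  voff <- Lv - row$del_v - x
  vpart <- substr(V$extended_seq, voff + 1, voff + x)
  jpart <- substr(J$extended_seq, model$max_p + row$del_j + 1,
                  model$max_p + nchar(J$seq))
  if (model$chain == "VDJ") {
    di <- match(row$d, vapply(model$germline$D, `[[`, "", "name"))
    D <- model$germline$D[[di]]
    dpart <- substr(D$extended_seq, model$max_p + row$del_d_l + 1,
                    model$max_p + nchar(D$seq) - row$del_d_r)
    anc <- paste0(vpart, substr(read, x + 1, a), dpart,
                  substr(read, b + 1, y), jpart)
  } else {
    anc <- paste0(vpart, substr(read, x + 1, y), jpart)
  }
  mm <- which(strsplit(anc, "")[[1]] != strsplit(read, "")[[1]] &
              strsplit(read, "")[[1]] != "N") - 1L
  covered <- c(seq_len(x) - 1L,
               if (model$chain == "VDJ" && b > a) a:(b - 1L),
               if (y < L) y:(L - 1L))
  list(ancestor = anc, mismatches = intersect(mm, covered),
       covered = covered)
}

#' Number of top scenarios needed to cover a likelihood fraction
#'
#' Smallest k such that the top-k ranked scenarios carry at least a fraction
#' \code{f} of the total read likelihood \code{P_read}.
#'
#' @param result an \code{annotation_result}.
#' @param f fraction in (0, 1].
#' @return integer k (NA when the retained ranked list is too short).
#' @export
rank_coverage <- function(result, f) {
  stopifnot(f > 0, f <= 1)
  if (is.null(result$scenarios)) return(NA_integer_)
  cs <- cumsum(exp(result$scenarios$logp - result$log_p_read))
  k <- which(cs >= f - 1e-12)[1]
  if (is.na(k)) {
    warning("ranked list too short to cover requested fraction")
    return(NA_integer_)
  }
  as.integer(k)
}

#' Annotate a batch of reads
#'
#' @param reads named character vector of reads.
#' @param model a \code{recomb_model}.
#' @param hm_model optional hypermutation \code{pwm_model}.
#' @param prune a \code{\link{prune_config}}.
#' @param truth optional data.frame of true scenarios keyed by \code{read_id}
#'   (as produced by \code{\link{generate_batch}}); adds true-scenario rank
#'   columns to the summary.
#' @param keep_results keep the full per-read \code{annotation_result}s.
#' @return list with \code{summary} data.frame (read_id, log_p_read,
#'   n_scenarios, failed, top-1 scenario fields, and rank columns when truth
#'   is given) and optionally \code{results}.
#' @export
annotate_batch <- function(reads, model, hm_model = NULL,
                           prune = prune_config(), truth = NULL,
                           keep_results = FALSE) {
  if (!is.null(hm_model)) model$err <- list(kind = "pwm", pwm = hm_model)
  cm <- compile_model(model)
  ids <- names(reads) %||% paste0("read", seq_along(reads))
  if (!is.null(truth)) {
    ti <- match(ids, truth$read_id)
    if (anyNA(ti)) stopf("truth table is missing read ids")
  }
  out <- vector("list", length(reads))
  results <- if (keep_results) vector("list", length(reads)) else NULL
  for (i in seq_along(reads)) {
    tv <- NULL
    if (!is.null(truth)) {
      tr <- truth[ti[i], ]
      # reads whose junction was cut by the window have no visible truth
      if (!isTRUE(tr$junction_lost)) tv <- truth_vec(tr, model)
    }
    res <- cpp_annotate(nt_int(reads[[i]]), cm, cpp_opts(prune, truth = tv))
    ann <- build_annotation(res, reads[[i]], model, ids[i])
    top <- if (!is.null(ann$scenarios) && nrow(ann$scenarios))
      ann$scenarios[1, ] else NULL
    row <- data.frame(read_id = ids[i], log_p_read = ann$log_p_read,
                      n_scenarios = ann$n_scenarios, failed = ann$failed,
                      stringsAsFactors = FALSE)
    for (f in c("v", "d", "j", "del_v", "del_d_l", "del_d_r", "del_j",
                "ins_vd", "ins_dj", "ins_vj")) {
      if (!is.null(top) && f %in% names(top)) row[[paste0("top_", f)]] <- top[[f]]
      else if (f %in% c("v", "d", "j", "ins_vd", "ins_dj", "ins_vj"))
        row[[paste0("top_", f)]] <- NA_character_
      else row[[paste0("top_", f)]] <- NA_real_
    }
    if (!is.null(truth)) {
      row$truth_logp <- ann$truth_logp
      row$truth_rank <- ann$truth_rank
    }
    out[[i]] <- row
    if (keep_results) results[[i]] <- ann
  }
  list(summary = do.call(rbind, out), results = results)
}
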