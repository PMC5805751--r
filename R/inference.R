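#' Expectation step: posterior-weighted sufficient statistics
#'
#' Annotates every read and accumulates, for each enumerated scenario, its
#' posterior weight \code{P_scenario / P_read} into the count table cell of
#' every event value it realizes; failed reads contribute nothing.  Also
#' accumulates weighted error events and opportunities, the total
#' log-likelihood \code{sum(log P_read)} and the pseudo-log-likelihood
#' \code{sum_reads sum_scenarios w log P_scenario}.
#'
#' @param reads named character vector.
#' @param model a \code{recomb_model} (normalized).
#' @param prune a \code{\link{prune_config}}.
#' @return object of class \code{suff_stats}.
#' @export
e_step <- function(reads, model, prune = prune_config()) {
  cm <- compile_model(model)
  opts <- cpp_opts(prune, want_stats = TRUE, k_top = 0L)
  nV <- length(model$germline$V)
  nJ <- length(model$germline$J)
  nD <- length(model$germline$D)
  zero_like <- function(x) { x[] <- 0; x }
  acc <- list(loglik = 0, pseudo_ll = 0, n_used = 0L, n_failed = 0L,
              err_events = 0, err_opps = 0,
              del_v = zero_like(model$del_v), del_j = zero_like(model$del_j))
  if (model$chain == "VDJ") {
    acc$gene_v <- zero_like(model$gene$p_v)
    acc$gene_dj <- zero_like(model$gene$p_dj)
    acc$del_d <- zero_like(model$del_d)
    acc$ins_vd <- zero_like(model$ins_vd)
    acc$ins_dj <- zero_like(model$ins_dj)
    acc$mk_vd <- zero_like(model$mk_vd)
    acc$mk_dj <- zero_like(model$mk_dj)
  } else {
    acc$gene_vj <- zero_like(model$gene$p_vj)
    acc$ins_vj <- zero_like(model$ins_vj)
    acc$mk_vj <- zero_like(model$mk_vj)
  }
  ndl <- dim(model$del_d)[2]; ndr <- dim(model$del_d)[3]
  for (i in seq_along(reads)) {
    res <- cpp_annotate(nt_int(reads[[i]]), cm, opts)
    if (isTRUE(res$failed)) { acc$n_failed <- acc$n_failed + 1L; next }
    st <- res$stats
    acc$n_used <- acc$n_used + 1L
    acc$loglik <- acc$loglik + res$log_pread
    acc$pseudo_ll <- acc$pseudo_ll + st$wlogp
    acc$err_events <- acc$err_events + st$err_events
    acc$err_opps <- acc$err_opps + st$err_opps
    acc$del_v <- acc$del_v + matrix(st$cdelV, nrow = nV)
    acc$del_j <- acc$del_j + matrix(st$cdelJ, nrow = nJ)
    if (model$chain == "VDJ") {
      acc$gene_v <- acc$gene_v + st$cV
      acc$gene_dj <- acc$gene_dj + matrix(st$cDJ, nrow = nD)
      # C layout (g*ndl + dli)*ndr + dri -> R array [g, dl, dr]
      acc$del_d <- acc$del_d +
        aperm(array(st$cdelD, dim = c(ndr, ndl, nD)), c(3, 2, 1))
      acc$ins_vd <- acc$ins_vd + st$cinsVD
      acc$ins_dj <- acc$ins_dj + st$cinsDJ
      acc$mk_vd <- acc$mk_vd + matrix(st$cTvd, 4, 4, byrow = TRUE)
      acc$mk_dj <- acc$mk_dj + matrix(st$cTdj, 4, 4, byrow = TRUE)
    } else {
      acc$gene_vj <- acc$gene_vj + matrix(st$cVJ, nrow = nV)
      acc$ins_vj <- acc$ins_vj + st$cinsVJ
      acc$mk_vj <- acc$mk_vj + matrix(st$cTvj, 4, 4, byrow = TRUE)
    }
  }
  if (acc$n_used == 0L) stopf("no read could be analyzed")
  structure(acc, class = "suff_stats")
}

#' Maximization step: re-normalize counts into a model
#'
#' Each conditional probability table row becomes its normalized count row
#' (rows with zero total keep their previous values, with a message);
#' structurally masked cells receive no counts and therefore stay exactly 0.
#' The uniform error rate becomes \code{err_events / err_opportunities}.
#'
#' @param stats a \code{suff_stats}.
#' @param model the model whose shapes (and fallback rows) to use.
#' @param smoothing pseudocount added to every cell of the structurally
#'   allowed support (cells the previous model gives positive probability);
#'   keeps never-enumerated but possible events at a tiny non-zero
#'   probability so divergences against the truth stay finite.  Masked /
#'   impossible cells receive none and stay exactly 0.
#' @return updated \code{recomb_model}.
#' @export
m_step <- function(stats, model, smoothing = 1e-6) {
  norm_rows <- function(cnt, old) {
    cnt <- cnt + smoothing * (old > 0)
    for (i in seq_len(nrow(cnt))) {
      s <- sum(cnt[i, ])
      if (s > 0) cnt[i, ] <- cnt[i, ] / s
      else cnt[i, ] <- old[i, ]
    }
    cnt
  }
  norm_vec <- function(cnt, old) {
    cnt <- cnt + smoothing * (old > 0)
    if (sum(cnt) > 0) cnt / sum(cnt) else old
  }
  model$del_v <- norm_rows(stats$del_v, model$del_v)
  model$del_j <- norm_rows(stats$del_j, model$del_j)
  if (model$chain == "VDJ") {
    model$gene$p_v <- norm_vec(stats$gene_v, model$gene$p_v)
    model$gene$p_dj <- norm_vec(stats$gene_dj, model$gene$p_dj)
    for (g in seq_len(dim(model$del_d)[1])) {
      cg <- stats$del_d[g, , ] + smoothing * (model$del_d[g, , ] > 0)
      s <- sum(cg)
      if (s > 0) model$del_d[g, , ] <- cg / s
    }
    model$ins_vd <- norm_vec(stats$ins_vd, model$ins_vd)
    model$ins_dj <- norm_vec(stats$ins_dj, model$ins_dj)
    model$mk_vd <- norm_rows(stats$mk_vd, model$mk_vd)
    model$mk_dj <- norm_rows(stats$mk_dj, model$mk_dj)
  } else {
    model$gene$p_vj <- norm_vec(stats$gene_vj, model$gene$p_vj)
    model$ins_vj <- norm_vec(stats$ins_vj, model$ins_vj)
    model$mk_vj <- norm_rows(stats$mk_vj, model$mk_vj)
  }
  if (model$err$kind == "uniform" && stats$err_opps > 0)
    model$err$rate <- max(stats$err_events / stats$err_opps, 1e-8)
  model
}

#' Learn model parameters by sparse expectation-maximization
#'
#' Alternates \code{\link{e_step}} and \code{\link{m_step}} until the mean
#' log-likelihood per read improves by less than \code{tol} or
#' \code{max_iter} is reached.  The first iteration runs with a coarser
#' pruning ratio (candidate placements are identical across iterations, so
#' the enumeration support is fixed by the score thresholds while pruning
#' sharpens as the model concentrates).  A decrease of the total
#' log-likelihood beyond the pruning-noise tolerance is a contract violation
#' and raises an error.
#'
#' @param reads named character vector.
#' @param init_model starting \code{recomb_model} (e.g. uniform from
#'   \code{\link{build_model}}).
#' @param max_iter maximum EM iterations (default 20).
#' @param tol absolute convergence tolerance on log-likelihood per read
#'   (default 1e-3).
#' @param prune a \code{\link{prune_config}}.
#' @param verbose print per-iteration progress.
#' @return list with \code{model} and \code{trajectory} (data.frame of
#'   iteration, loglik, pseudo_ll, err_rate).
#' @export
em_learn <- function(reads, init_model, max_iter = 20L, tol = 1e-3,
                     prune = prune_config(), verbose = FALSE) {
  model <- init_model
  traj <- NULL
  prev <- -Inf
  for (it in seq_len(max_iter)) {
    pr <- prune
    if (it == 1L) pr$prune_ratio <- max(prune$prune_ratio, 1e-2)
    st <- e_step(reads, model, pr)
    ll <- st$loglik / st$n_used
    traj <- rbind(traj, data.frame(
      iter = it, loglik = st$loglik, loglik_per_read = ll,
      pseudo_ll = st$pseudo_ll, n_used = st$n_used,
      n_failed = st$n_failed,
      err_rate = if (model$err$kind == "uniform") model$err$rate else NA_real_))
    if (verbose)
      message(sprintf("EM iter %d: loglik/read = %.4f (%d reads)", it, ll,
                      st$n_used))
    if (it > 2L && ll < prev - max(1e-5 * abs(prev), 1e-8))
      stopf("EM contract violation: log-likelihood decreased (%.6f -> %.6f)",
            prev, ll)
    converged <- it > 1L && (ll - prev) < tol && ll >= prev - tol
    model <- m_step(st, model)
    if (converged) break
    prev <- ll
  }
  list(model = model, trajectory = traj)
}

#' Select out-of-frame (non-productive) synthetic reads
#'
#' Emulates the restriction to unique non-productive sequences used when
#' learning recombination statistics free of functional selection: keeps
#' reads whose true rearrangement has a CDR3 length not divisible by three,
#' a stop codon in the junction, or a destroyed anchor.
#'
#' @param truth truth data.frame from \code{\link{generate_batch}}.
#' @return character vector of read ids.
#' @export
filter_out_of_frame <- function(truth) {
  truth$read_id[!vapply(truth$productive, isTRUE, TRUE)]
}
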