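#' Additive context PWM hypermutation model
#'
#' The per-site mutation probability depends on its (2m+1)-mer context
#' through a logistic link: \code{P_mut / (1 - P_mut) = mu * exp(sum_i
#' e_i(pi_i))}.  The PWM is stored in a fixed gauge with \code{sum_sigma
#' e_i(sigma) = 0} at every position, which makes \code{mu} the geometric
#' mean of the mutation odds over all possible contexts and the
#' serialization unique; any constant shift of \code{e} is absorbed into
#' \code{mu} on construction.
#'
#' @param m context half-width (default 3, i.e. 7-mers).
#' @param e (2m+1) x 4 matrix of additive contributions (columns A,C,G,T);
#'   default all zero.
#' @param mu overall rate scale (> 0).
#' @param renormalize impose the zero-sum gauge (default TRUE).
#' @return object of class \code{pwm_model}.
#' @export
pwm_model <- function(m = 3L, e = NULL, mu = 1e-3, renormalize = TRUE) {
  m <- as.integer(m)
  stopifnot(m >= 0, mu > 0)
  if (is.null(e)) e <- matrix(0, 2 * m + 1, 4)
  stopifnot(nrow(e) == 2 * m + 1, ncol(e) == 4)
  dimnames(e) <- list(as.character(-m:m), NT)
  if (renormalize) {
    shift <- rowMeans(e)
    e <- e - shift
    mu <- mu * exp(sum(shift))
  }
  structure(list(m = m, e = e, mu = mu), class = "pwm_model")
}

#' @export
print.pwm_model <- function(x, ...) {
  cat(sprintf("<pwm_model %d-mer, mu = %.4g>\n", 2 * x$m + 1, x$mu))
  invisible(x)
}

#' Context-dependent mutation probability
#'
#' \code{P_mut = x / (1 + x)} with \code{x = mu * exp(sum_i e_i(pi_i))}.
#' Contexts containing N fall back to the overall rate \code{mu / (1 + mu)}.
#'
#' @param context character vector of (2m+1)-mers (the candidate site at the
#'   center).
#' @param pwm a \code{pwm_model}.
#' @return numeric vector of probabilities.
#' @export
mut_prob <- function(context, pwm) {
  vapply(context, function(ctx) {
    b <- strsplit(toupper(ctx), "")[[1]]
    if (length(b) != 2 * pwm$m + 1)
      stopf("context must have length %d", 2 * pwm$m + 1)
    ix <- match(b, NT)
    if (anyNA(ix)) return(pwm$mu / (1 + pwm$mu))
    x <- pwm$mu * exp(sum(pwm$e[cbind(seq_along(b), ix)]))
    x / (1 + x)
  }, 0, USE.NAMES = FALSE)
}

#' Fit a context PWM by weighted logistic regression
#'
#' Maximizes the weighted Bernoulli likelihood of mutation indicators given
#' contexts under the logistic-link additive model.  The optimization is an
#' iteratively reweighted least-squares logistic fit on one-hot context
#' features (reference base A per position), after which the zero-sum gauge
#' is re-imposed.  Deterministic given its inputs.
#'
#' @param counts data.frame with columns \code{context} ((2m+1)-mers),
#'   \code{mutated} (0/1) and \code{weight} (posterior weights from the
#'   expectation step).
#' @param m context half-width.
#' @param init optional initial \code{pwm_model} (used only for its shape /
#'   as fallback when no mutated context is present).
#' @return fitted \code{pwm_model}.
#' @export
fit_pwm <- function(counts, m = 3L, init = NULL) {
  m <- as.integer(m)
  w <- counts$weight
  y <- as.numeric(counts$mutated)
  if (sum(w[y > 0]) <= 0) {
    warning("no mutated contexts; returning floor-rate model")
    return(pwm_model(m = m, mu = 1e-8))
  }
  # aggregate identical (context, mutated) rows
  key <- paste(counts$context, y)
  agg <- rowsum(w, key)
  parts <- strsplit(rownames(agg), " ", fixed = TRUE)
  ctx <- vapply(parts, `[[`, "", 1L)
  y <- as.numeric(vapply(parts, `[[`, "", 2L))
  w <- as.numeric(agg)
  bmat <- do.call(rbind, strsplit(ctx, ""))
  X <- matrix(0, length(ctx), (2 * m + 1) * 3)
  cn <- character((2 * m + 1) * 3)
  k <- 0L
  for (i in seq_len(2 * m + 1)) {
    for (bb in c("C", "G", "T")) {
      k <- k + 1L
      X[, k] <- as.numeric(bmat[, i] == bb)
      cn[k] <- paste0(i, bb)
    }
  }
  fit <- suppressWarnings(
    stats::glm.fit(cbind(1, X), y, weights = w,
                   family = stats::quasibinomial()))
  cf <- fit$coefficients
  cf[is.na(cf)] <- 0
  e <- matrix(0, 2 * m + 1, 4)
  for (i in seq_len(2 * m + 1)) {
    e[i, 2:4] <- cf[1 + ((i - 1) * 3 + 1:3)]
  }
  pwm_model(m = m, e = e, mu = exp(cf[1]))
}

#' Non-additive n-mer mutability table
#'
#' Assigns an empirical mutation rate to every possible n-mer context
#' (4^n rows); contexts observed with less total weight than
#' \code{coverage_threshold} are flagged inestimable.
#'
#' @param counts data.frame with \code{context}, \code{mutated},
#'   \code{weight}.
#' @param n odd n-mer length (default 5; the table then has 1024 rows).
#' @param coverage_threshold minimum weighted coverage (default 100).
#' @return object of class \code{nmer_table}: data.frame \code{context},
#'   \code{rate}, \code{coverage}, \code{estimable}.
#' @export
fit_nmer <- function(counts, n = 5L, coverage_threshold = 100) {
  n <- as.integer(n)
  if (n %% 2L == 0L) stopf("n must be odd")
  all_ctx <- do.call(paste0, rev(expand.grid(rep(list(NT), n),
                                             stringsAsFactors = FALSE)))
  all_ctx <- sort(all_ctx)
  m <- (nchar(counts$context[1]) - n) %/% 2L
  ctx <- if (m > 0) substr(counts$context, m + 1L, m + n) else counts$context
  cov <- rowsum(counts$weight, ctx)
  mut <- rowsum(counts$weight * as.numeric(counts$mutated), ctx)
  coverage <- setNames(rep(0, length(all_ctx)), all_ctx)
  mutw <- coverage
  coverage[rownames(cov)] <- cov
  mutw[rownames(mut)] <- mut
  df <- data.frame(context = all_ctx, rate = ifelse(coverage > 0,
                                                    mutw / coverage, NA_real_),
                   coverage = unname(coverage),
                   estimable = unname(coverage >= coverage_threshold),
                   stringsAsFactors = FALSE)
  structure(list(n = n, coverage_threshold = coverage_threshold, table = df),
            class = "nmer_table")
}

# ---------------------------------------------------------------------------
# posterior-weighted mutation statistics from annotation results

#' Posterior-weighted (context, mutated) counts from annotations
#'
#' For every retained scenario of every read, each germline-covered position
#' with a fully defined (2m+1)-mer ancestral context contributes its
#' scenario-posterior weight, with the mutation indicator set when the read
#' differs from the scenario's ancestral base.  Contexts straddling the
#' junction use the scenario's reconstructed ancestral sequence; sites whose
#' context extends beyond the ancestral window are excluded.
#'
#' @param results list of \code{annotation_result} (from
#'   \code{\link{annotate_batch}} with \code{keep_results = TRUE}).
#' @param model the \code{recomb_model} used for annotation.
#' @param m context half-width.
#' @param classes which segment classes to collect (default V, D and J).
#' @return data.frame \code{context}, \code{mutated}, \code{weight},
#'   \code{class}, \code{gene}, \code{gpos} (0-based germline position).
#' @export
shm_context_counts <- function(results, model, m = 3L, classes = c("V", "D", "J")) {
  out <- list()
  for (res in results) {
    if (res$failed || is.null(res$scenarios)) next
    sc <- res$scenarios
    w <- exp(sc$logp - res$log_p_read)
    w <- w / sum(w)
    for (i in seq_len(nrow(sc))) {
      pieces <- scenario_ancestor(res$read, model, sc[i, ])
      anc <- strsplit(pieces$ancestor, "")[[1]]
      rd <- strsplit(res$read, "")[[1]]
      x <- sc$x[i]; a <- sc$a[i]; b <- sc$b[i]; y <- sc$y[i]
      L <- length(rd)
      segs <- list(V = if (x >= 1) 0:(x - 1L),
                   D = if (model$chain == "VDJ" && b > a) a:(b - 1L),
                   J = if (y <= L - 1L) y:(L - 1L))
      for (cls in classes) {
        pos <- segs[[cls]]
        if (is.null(pos)) next
        pos <- pos[pos - m >= 0L & pos + m <= L - 1L & rd[pos + 1L] != "N"]
        if (!length(pos)) next
        ctx <- vapply(pos, function(p)
          paste(anc[(p - m):(p + m) + 1L], collapse = ""), "")
        gpos <- switch(cls,
          V = pos + (nchar(model$germline$V[[match(sc$v[i],
                vapply(model$germline$V, `[[`, "", "name"))]]$seq) -
                sc$del_v[i] - x),
          D = pos - a + model$max_p + sc$del_d_l[i],
          J = pos - y + model$max_p + sc$del_j[i])
        out[[length(out) + 1L]] <- data.frame(
          context = ctx, mutated = as.numeric(anc[pos + 1L] != rd[pos + 1L]),
          weight = w[i], class = cls,
          gene = switch(cls, V = sc$v[i], D = sc$d[i], J = sc$j[i]),
          gpos = gpos, read_id = res$read_id, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

#' Observed versus PWM-predicted mutability along a gene
#'
#' Posterior-weighted observed mutation frequency per germline position of
#' one gene, against the PWM prediction from the germline context, with
#' their Pearson correlation.
#'
#' @param counts output of \code{\link{shm_context_counts}}.
#' @param gene gene name.
#' @param pwm a \code{pwm_model}.
#' @return data.frame \code{gpos}, \code{observed}, \code{predicted},
#'   \code{coverage}, with attribute \code{pearson}.
#' @export
posterior_mutation_profile <- function(counts, gene, pwm) {
  g <- counts[counts$gene == gene, ]
  if (!nrow(g)) return(data.frame(gpos = integer(), observed = numeric(),
                                  predicted = numeric(), coverage = numeric()))
  cov <- rowsum(g$weight, g$gpos)
  mut <- rowsum(g$weight * g$mutated, g$gpos)
  # prediction from the modal context observed at that position
  pred <- vapply(rownames(cov), function(p) {
    sub <- g[g$gpos == as.integer(p), ]
    ctx <- sub$context[which.max(sub$weight)]
    mut_prob(ctx, pwm)
  }, 0)
  df <- data.frame(gpos = as.integer(rownames(cov)),
                   observed = as.numeric(mut / cov),
                   predicted = unname(pred), coverage = as.numeric(cov))
  r <- if (nrow(df) > 2 && stats::sd(df$observed) > 0 &&
           stats::sd(df$predicted) > 0)
    stats::cor(df$observed, df$predicted) else NA_real_
  attr(df, "pearson") <- r
  df
}

#' Hypermutation co-localization index g(r)
#'
#' Radial enrichment of pairs of hypermutations at genomic distance r:
#' \code{g(r) = (1/N_r) sum_{V,(i,j) in C_V(r)} f(i,j,V) / (f(i,V) f(j,V))}
#' where \code{f(i,V)} and \code{f(i,j,V)} are posterior-weighted mutation
#' frequencies at single positions and position pairs of gene V, and
#' \code{C_V(r)} keeps pairs observed with enough coverage.  Independent
#' per-site mutations give g(r) ~ 1.
#'
#' @param counts output of \code{\link{shm_context_counts}} (V class rows
#'   are used).
#' @param min_pair_count minimum weighted coverage for a pair of positions.
#' @param r_max maximum distance.
#' @return data.frame \code{r}, \code{g}, \code{n_pairs}.
#' @export
colocalization <- function(counts, min_pair_count = 20, r_max = 25L) {
  cv <- counts[counts$class == "V", ]
  if (!nrow(cv)) return(data.frame(r = integer(), g = numeric(),
                                   n_pairs = integer()))
  res <- list()
  for (r in 1:r_max) {
    num <- 0; np <- 0L
    for (gene in unique(cv$gene)) {
      g <- cv[cv$gene == gene, ]
      # per read x position: posterior-weighted mutation call
      tab <- rowsum(cbind(w = g$weight, mw = g$weight * g$mutated),
                    paste(g$read_id, g$gpos))
      key <- do.call(rbind, strsplit(rownames(tab), " "))
      df <- data.frame(read = key[, 1], gpos = as.integer(key[, 2]),
                       w = tab[, "w"], mw = tab[, "mw"])
      pos <- sort(unique(df$gpos))
      f1c <- rowsum(cbind(df$w, df$mw), df$gpos)
      f1 <- setNames(f1c[, 2] / f1c[, 1], rownames(f1c))
      cov1 <- setNames(f1c[, 1], rownames(f1c))
      for (i in pos) {
        j <- i + r
        if (!(j %in% pos)) next
        di <- df[df$gpos == i, ]; dj <- df[df$gpos == j, ]
        common <- intersect(di$read, dj$read)
        if (!length(common)) next
        di <- di[match(common, di$read), ]; dj <- dj[match(common, dj$read), ]
        wpair <- pmin(di$w, dj$w)
        if (sum(wpair) < min_pair_count) next
        fij <- sum(di$mw / di$w * dj$mw / dj$w * wpair) / sum(wpair)
        fi <- f1[as.character(i)]; fj <- f1[as.character(j)]
        if (is.na(fi) || is.na(fj) || fi <= 0 || fj <= 0) next
        num <- num + fij / (fi * fj)
        np <- np + 1L
      }
    }
    if (np > 0L)
      res[[length(res) + 1L]] <- data.frame(r = r, g = num / np, n_pairs = np)
  }
  if (!length(res)) return(data.frame(r = integer(), g = numeric(),
                                      n_pairs = integer()))
  do.call(rbind, res)
}
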