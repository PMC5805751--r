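#' Build a V(D)J recombination model
#'
#' Constructs the Bayesian-network generative model of recombination: joint
#' gene usage, gene-conditional deletion profiles (negative values =
#' P-nucleotides), junctional insertion-length distributions and dinucleotide
#' Markov chains for inserted nucleotide identity, plus a sequencing-error /
#' hypermutation model.  For VJ chains (e.g. TRA) gene usage is the joint
#' \code{P(V,J)}; for VDJ chains (TRB/IGH) it is factorized as
#' \code{P(V,D,J) = P(V) P(D,J)}.  All conditional probability tables are
#' initialized uniform over their structurally allowed support and can be
#' overwritten afterwards (or learned with \code{\link{em_learn}}).
#'
#' @param structure_config list with elements \code{chain} ("VJ" or "VDJ"),
#'   and optionally \code{max_p} (palindromic extension, default 4),
#'   \code{del_range} (list V/J/Dl/Dr of c(min,max), default c(-4, 16)),
#'   \code{ins_max} (default 40), \code{forbidden_dj} (character vector of
#'   \code{"Dname:Jfamily"} pairs declared structurally impossible, e.g. the
#'   TRB rule that D2 cannot recombine with J1-family genes),
#'   \code{err_rate} (uniform per-base error probability, default 1e-3), and
#'   \code{dependencies} (optional named list parent -> children used only to
#'   validate that the declared event graph is acyclic).
#' @param germline list of \code{germline_segment} (or a list with V/D/J
#'   components).  D segments are required for VDJ and forbidden for VJ.
#' @return an object of class \code{recomb_model}.
#' @export
build_model <- function(structure_config, germline) {
  cfg <- structure_config
  chain <- match.arg(cfg$chain, c("VJ", "VDJ"))
  max_p <- as.integer(cfg$max_p %||% 4L)
  if (!is.null(cfg$dependencies)) check_acyclic(cfg$dependencies)

  if (!is.null(names(germline)) && all(c("V", "J") %in% names(germline)))
    gl <- germline
  else gl <- split_germline(germline)
  if (length(gl$V) == 0L || length(gl$J) == 0L)
    stopf("germline must contain at least one V and one J segment")
  if (chain == "VJ" && length(gl$D) > 0L)
    stopf("D genes supplied for a VJ chain model")
  if (chain == "VDJ" && length(gl$D) == 0L)
    stopf("VDJ chain requires D germline segments")
  # re-extend to the model's max_p
  gl <- lapply(gl, function(l) lapply(l, extend_palindrome, max_p = max_p))

  dr <- cfg$del_range %||% list()
  del_range <- list(V = as.integer(dr$V %||% c(-max_p, 16L)),
                    J = as.integer(dr$J %||% c(-max_p, 16L)),
                    Dl = as.integer(dr$Dl %||% c(-max_p, 16L)),
                    Dr = as.integer(dr$Dr %||% c(-max_p, 16L)))
  for (nm in names(del_range)) {
    rg <- del_range[[nm]]
    if (length(rg) != 2L || rg[1] > rg[2]) stopf("bad del_range for %s", nm)
    if (-rg[1] > max_p)
      stopf("del_range %s allows %d P-nucleotides but max_p is %d",
            nm, -rg[1], max_p)
  }
  ins_max <- as.integer(cfg$ins_max %||% 40L)

  nV <- length(gl$V); nD <- length(gl$D); nJ <- length(gl$J)
  vn <- vapply(gl$V, `[[`, "", "name")
  dn <- vapply(gl$D, `[[`, "", "name")
  jn <- vapply(gl$J, `[[`, "", "name")

  model <- structure(list(
    chain = chain, max_p = max_p, germline = gl,
    del_range = del_range, ins_max = ins_max,
    dj_chain_dir = "rev", ins_first = "conditioned"), class = "recomb_model")

  # gene usage
  if (chain == "VJ") {
    model$gene <- list(kind = "vj",
                       p_vj = matrix(1 / (nV * nJ), nV, nJ,
                                     dimnames = list(vn, jn)))
  } else {
    mask <- matrix(FALSE, nD, nJ, dimnames = list(dn, jn))
    for (tok in cfg$forbidden_dj %||% character()) {
      parts <- strsplit(tok, ":", fixed = TRUE)[[1]]
      if (length(parts) != 2L) stopf("bad forbidden_dj entry '%s'", tok)
      di <- match(parts[1], dn)
      if (is.na(di)) stopf("forbidden_dj names unknown D gene '%s'", parts[1])
      jf <- vapply(gl$J, `[[`, "", "family")
      hit <- jf == parts[2] | jn == parts[2]
      if (!any(hit)) stopf("forbidden_dj names unknown J family '%s'", parts[2])
      mask[di, hit] <- TRUE
    }
    p_dj <- matrix(1, nD, nJ, dimnames = list(dn, jn))
    p_dj[mask] <- 0
    model$gene <- list(kind = "factorized",
                       p_v = setNames(rep(1 / nV, nV), vn),
                       p_dj = p_dj / sum(p_dj), mask_dj = mask)
  }

  # deletion CPTs, uniform over per-gene valid support (retained length >= 0,
  # at least one core base retained for V/J)
  model$del_v <- uniform_del_cpt(gl$V, del_range$V, min_keep = 1L)
  model$del_j <- uniform_del_cpt(gl$J, del_range$J, min_keep = 1L)
  if (chain == "VDJ") {
    ndl <- del_range$Dl[2] - del_range$Dl[1] + 1L
    ndr <- del_range$Dr[2] - del_range$Dr[1] + 1L
    arr <- array(0, dim = c(nD, ndl, ndr),
                 dimnames = list(dn, del_range$Dl[1]:del_range$Dl[2],
                                 del_range$Dr[1]:del_range$Dr[2]))
    for (g in seq_len(nD)) {
      Lc <- nchar(gl$D[[g]]$seq)
      for (dl in del_range$Dl[1]:del_range$Dl[2])
        for (drr in del_range$Dr[1]:del_range$Dr[2])
          if (Lc - dl - drr >= 0L)
            arr[g, as.character(dl), as.character(drr)] <- 1
      arr[g, , ] <- arr[g, , ] / sum(arr[g, , ])
    }
    model$del_d <- arr
  }

  # insertions
  unif_ins <- rep(1 / (ins_max + 1), ins_max + 1)
  names(unif_ins) <- 0:ins_max
  unif_mk <- matrix(0.25, 4, 4, dimnames = list(NT, NT))
  if (chain == "VJ") {
    model$ins_vj <- unif_ins
    model$mk_vj <- unif_mk
  } else {
    model$ins_vd <- unif_ins
    model$ins_dj <- unif_ins
    model$mk_vd <- unif_mk
    model$mk_dj <- unif_mk
  }

  model$err <- list(kind = "uniform", rate = cfg$err_rate %||% 1e-3)
  validate_model(model)
  model
}

check_acyclic <- function(deps) {
  nodes <- unique(c(names(deps), unlist(deps)))
  indeg <- setNames(rep(0L, length(nodes)), nodes)
  for (ch in unlist(deps)) indeg[ch] <- indeg[ch] + 1L
  q <- nodes[indeg == 0L]
  seen <- 0L
  while (length(q)) {
    n <- q[1]; q <- q[-1]; seen <- seen + 1L
    for (ch in deps[[n]] %||% character()) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) q <- c(q, ch)
    }
  }
  if (seen < length(nodes)) stopf("cyclic dependency declaration")
  invisible(TRUE)
}

uniform_del_cpt <- function(segs, rng, min_keep = 1L) {
  vals <- rng[1]:rng[2]
  m <- matrix(0, length(segs), length(vals),
              dimnames = list(vapply(segs, `[[`, "", "name"), vals))
  for (i in seq_along(segs)) {
    ok <- vals <= nchar(segs[[i]]$seq) - min_keep
    m[i, ok] <- 1 / sum(ok)
  }
  m
}

#' Validate a recombination model
#'
#' Checks that every conditional probability table row sums to one within
#' \code{tol}, that all probabilities lie in \code{[0, 1]}, and that declared
#' structural zeros carry exactly zero mass.
#'
#' @param model a \code{recomb_model}.
#' @param tol row-sum tolerance (default 1e-10).
#' @return the model, invisibly; errors on violation.
#' @export
validate_model <- function(model, tol = 1e-10) {
  chk_rows <- function(m, what) {
    if (any(m < 0 | m > 1 + tol)) stopf("%s has entries outside [0,1]", what)
    bad <- abs(rowSums(m) - 1) > tol
    if (any(bad)) stopf("%s rows not normalized: %s", what,
                        paste(rownames(m)[bad] %||% which(bad), collapse = ", "))
  }
  if (model$chain == "VJ") {
    if (abs(sum(model$gene$p_vj) - 1) > tol) stopf("P(V,J) does not sum to 1")
    chk_rows(model$mk_vj, "VJ insertion Markov chain")
    if (abs(sum(model$ins_vj) - 1) > tol) stopf("P(insVJ) does not sum to 1")
  } else {
    if (abs(sum(model$gene$p_v) - 1) > tol) stopf("P(V) does not sum to 1")
    if (abs(sum(model$gene$p_dj) - 1) > tol) stopf("P(D,J) does not sum to 1")
    if (any(model$gene$p_dj[model$gene$mask_dj] != 0))
      stopf("masked D-J pairs carry non-zero probability")
    for (g in seq_len(dim(model$del_d)[1]))
      if (abs(sum(model$del_d[g, , ]) - 1) > tol)
        stopf("P(delDl,delDr|D=%s) does not sum to 1",
              dimnames(model$del_d)[[1]][g])
    if (abs(sum(model$ins_vd) - 1) > tol) stopf("P(insVD) does not sum to 1")
    if (abs(sum(model$ins_dj) - 1) > tol) stopf("P(insDJ) does not sum to 1")
    chk_rows(model$mk_vd, "VD insertion Markov chain")
    chk_rows(model$mk_dj, "DJ insertion Markov chain")
  }
  chk_rows(model$del_v, "P(delV|V)")
  chk_rows(model$del_j, "P(delJ|J)")
  if (model$err$kind == "uniform" &&
      (model$err$rate < 0 || model$err$rate > 1))
    stopf("error rate outside [0,1]")
  invisible(model)
}

#' @export
print.recomb_model <- function(x, ...) {
  nd <- length(x$germline$D)
  cat(sprintf("<recomb_model %s: %d V / %s%d J; del [%d,%d], ins <= %d, err %s>\n",
              x$chain, length(x$germline$V),
              if (nd) sprintf("%d D / ", nd) else "", length(x$germline$J),
              x$del_range$V[1], x$del_range$V[2], x$ins_max,
              if (x$err$kind == "uniform") format(x$err$rate) else x$err$kind))
  invisible(x)
}

# ---------------------------------------------------------------------------

#' Probability of a fully specified recombination scenario
#'
#' Evaluates the Bayesian-network factorization directly: for VJ chains
#' \code{P(V,J) P(delV|V) P(delJ|J) P(insVJ) prod P(n_i | n_{i-1})}, and for
#' VDJ chains
#' \code{P(V) P(D,J) P(delV|V) P(delDl,delDr|D) P(delJ|J) P(insVD) P(insDJ)}
#' times both insertion Markov chains.  The first inserted nucleotide of the
#' V-side chain is conditioned on the last retained V base; the D-J chain
#' runs 3' to 5' from the J side, conditioned on the first retained J base.
#' Structurally forbidden gene pairs return exactly 0; event values outside
#' the configured ranges raise an error.
#'
#' @param model a \code{recomb_model}.
#' @param scenario list with \code{v}, \code{j} (and \code{d} for VDJ) gene
#'   names or indices; deletions \code{del_v}, \code{del_j} (and
#'   \code{del_d_l}, \code{del_d_r}); insertion strings \code{ins_vj} or
#'   \code{ins_vd}, \code{ins_dj}.
#' @return the scenario probability \code{P_recomb} (linear scale).
#' @export
scenario_prob <- function(model, scenario) {
  s <- scenario
  gidx <- function(x, segs, what) {
    if (is.character(x)) {
      i <- match(x, vapply(segs, `[[`, "", "name"))
      if (is.na(i)) stopf("unknown %s gene '%s'", what, x)
      i
    } else {
      i <- as.integer(x)
      if (i < 1L || i > length(segs)) stopf("%s index out of range", what)
      i
    }
  }
  in_rng <- function(v, rng, what) {
    if (v < rng[1] || v > rng[2]) stopf("%s=%d outside range [%d,%d]",
                                        what, v, rng[1], rng[2])
    v
  }
  chain_lp <- function(ins, mk, ctx, reverse = FALSE) {
    if (nchar(ins) == 0L) return(0)
    b <- strsplit(ins, "", fixed = TRUE)[[1]]
    if (reverse) b <- rev(b)   # generate from the J side, 3' -> 5'
    lp <- log(mk[ctx, b[1]])
    if (length(b) > 1L)
      for (k in 2:length(b)) lp <- lp + log(mk[b[k - 1L], b[k]])
    lp
  }
  vi <- gidx(s$v, model$germline$V, "V")
  ji <- gidx(s$j, model$germline$J, "J")
  dv <- in_rng(as.integer(s$del_v), model$del_range$V, "del_v")
  dj <- in_rng(as.integer(s$del_j), model$del_range$J, "del_j")
  V <- model$germline$V[[vi]]; J <- model$germline$J[[ji]]
  Lv <- nchar(V$seq); Lj <- nchar(J$seq)
  if (Lv - dv < 1L || Lj - dj < 1L) return(0)
  vbase <- substr(V$extended_seq, Lv - dv, Lv - dv)
  jbase <- substr(J$extended_seq, model$max_p + dj + 1L, model$max_p + dj + 1L)

  if (model$chain == "VJ") {
    ins <- toupper(s$ins_vj %||% "")
    if (nchar(ins) > model$ins_max) stopf("ins_vj longer than ins_max")
    lp <- log(model$gene$p_vj[vi, ji]) +
      log(model$del_v[vi, as.character(dv)]) +
      log(model$del_j[ji, as.character(dj)]) +
      log(model$ins_vj[[nchar(ins) + 1L]]) +
      chain_lp(ins, model$mk_vj, vbase)
    return(if (is.finite(lp)) exp(unname(lp)) else 0)
  }
  di <- gidx(s$d, model$germline$D, "D")
  dl <- in_rng(as.integer(s$del_d_l), model$del_range$Dl, "del_d_l")
  drr <- in_rng(as.integer(s$del_d_r), model$del_range$Dr, "del_d_r")
  D <- model$germline$D[[di]]
  if (nchar(D$seq) - dl - drr < 0L) return(0)
  iv <- toupper(s$ins_vd %||% ""); id <- toupper(s$ins_dj %||% "")
  if (nchar(iv) > model$ins_max || nchar(id) > model$ins_max)
    stopf("insertion longer than ins_max")
  lp <- log(model$gene$p_v[vi]) + log(model$gene$p_dj[di, ji]) +
    log(model$del_v[vi, as.character(dv)]) +
    log(model$del_j[ji, as.character(dj)]) +
    log(model$del_d[di, as.character(dl), as.character(drr)]) +
    log(model$ins_vd[[nchar(iv) + 1L]]) + log(model$ins_dj[[nchar(id) + 1L]]) +
    chain_lp(iv, model$mk_vd, vbase) +
    chain_lp(id, model$mk_dj, jbase, reverse = TRUE)
  if (is.finite(lp)) exp(unname(lp)) else 0
}

# ---------------------------------------------------------------------------
# flatten a model into the representation consumed by the C++ enumerator

compile_model <- function(model) {
  gl <- model$germline
  seg_ints <- function(l) lapply(l, function(s) nt_int(s$extended_seq))
  cores <- function(l) vapply(l, function(s) nchar(s$seq), 0L)
  nV <- length(gl$V); nJ <- length(gl$J); nD <- length(gl$D)
  safe_log <- function(x) {
    x[x < 0] <- 0
    suppressWarnings(log(x))
  }
  cm <- list(
    chain = if (model$chain == "VDJ") 1L else 0L,
    maxp = model$max_p,
    Vext = seg_ints(gl$V), Vcore = cores(gl$V),
    Jext = seg_ints(gl$J), Jcore = cores(gl$J),
    Dext = seg_ints(gl$D %||% list()), Dcore = cores(gl$D %||% list()),
    dv0 = model$del_range$V[1], dv1 = model$del_range$V[2],
    dj0 = model$del_range$J[1], dj1 = model$del_range$J[2],
    dl0 = model$del_range$Dl[1], dl1 = model$del_range$Dl[2],
    dr0 = model$del_range$Dr[1], dr1 = model$del_range$Dr[2],
    insmax = model$ins_max)
  cm$lpdelV <- safe_log(matrix(model$del_v, nrow = nV))
  cm$lpdelJ <- safe_log(matrix(model$del_j, nrow = nJ))
  if (model$chain == "VDJ") {
    cm$lpV <- safe_log(unname(model$gene$p_v))
    cm$lpDJ <- safe_log(matrix(model$gene$p_dj, nrow = nD))
    # [g, dl, dr] flattened as (g*ndl + dli)*ndr + dri  (C order)
    cm$lpdelD <- safe_log(as.numeric(aperm(model$del_d, c(3, 2, 1))))
    cm$lpinsVD <- safe_log(unname(model$ins_vd))
    cm$lpinsDJ <- safe_log(unname(model$ins_dj))
    cm$lpinsVJ <- numeric(model$ins_max + 1)
    cm$lTvd <- safe_log(as.numeric(t(model$mk_vd)))  # prev*4 + next
    cm$lTdj <- safe_log(as.numeric(t(model$mk_dj)))
    cm$lTvj <- numeric(16)
    cm$lpVJ <- matrix(0, 1, 1)
  } else {
    cm$lpVJ <- safe_log(matrix(model$gene$p_vj, nrow = nV))
    cm$lpV <- numeric(nV)
    cm$lpDJ <- matrix(0, 1, 1)
    cm$lpdelD <- numeric(1)
    cm$lpinsVJ <- safe_log(unname(model$ins_vj))
    cm$lpinsVD <- numeric(model$ins_max + 1)
    cm$lpinsDJ <- numeric(model$ins_max + 1)
    cm$lTvj <- safe_log(as.numeric(t(model$mk_vj)))
    cm$lTvd <- numeric(16)
    cm$lTdj <- numeric(16)
  }
  if (model$err$kind == "uniform") {
    cm$err_kind <- 0L
    cm$err_rate <- model$err$rate
  } else {
    pw <- model$err$pwm
    cm$err_kind <- 1L
    cm$err_rate <- 0
    cm$pwm_m <- pw$m
    cm$pwm_mu <- pw$mu
    cm$pwm_e <- as.numeric(t(pw$e))  # pos*4 + base
  }
  cm
}
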