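#' Sample one recombination scenario from the model
#'
#' Ancestral sampling in the Bayesian-network order: genes, deletions,
#' insertion lengths, then inserted nucleotide identities from the
#' dinucleotide Markov chains (the V-side chain runs 5'->3' conditioned on
#' the last retained V base; the D-J chain runs 3'->5' from the first
#' retained J base).  Structural zeros are never sampled.
#'
#' @param model a \code{recomb_model}.
#' @return scenario list (gene names, deletions, insertion strings).
#' @export
sample_scenario <- function(model) {
  draw <- function(p) sample.int(length(p), 1L, prob = p)
  gl <- model$germline
  vn <- vapply(gl$V, `[[`, "", "name")
  jn <- vapply(gl$J, `[[`, "", "name")
  chain_sample <- function(len, mk, ctx, reverse = FALSE) {
    if (len == 0L) return("")
    out <- character(len)
    prev <- ctx
    for (k in seq_len(len)) {
      prev <- NT[draw(mk[prev, ])]
      out[k] <- prev
    }
    if (reverse) out <- rev(out)
    paste(out, collapse = "")
  }
  if (model$chain == "VJ") {
    ix <- draw(as.numeric(model$gene$p_vj))
    vi <- (ix - 1L) %% nrow(model$gene$p_vj) + 1L
    ji <- (ix - 1L) %/% nrow(model$gene$p_vj) + 1L
  } else {
    vi <- draw(model$gene$p_v)
    ix <- draw(as.numeric(model$gene$p_dj))
    di <- (ix - 1L) %% nrow(model$gene$p_dj) + 1L
    ji <- (ix - 1L) %/% nrow(model$gene$p_dj) + 1L
  }
  dv <- model$del_range$V[1] - 1L + draw(model$del_v[vi, ])
  dj <- model$del_range$J[1] - 1L + draw(model$del_j[ji, ])
  V <- gl$V[[vi]]; J <- gl$J[[ji]]
  vbase <- substr(V$extended_seq, nchar(V$seq) - dv, nchar(V$seq) - dv)
  jbase <- substr(J$extended_seq, model$max_p + dj + 1L, model$max_p + dj + 1L)
  if (model$chain == "VJ") {
    len <- draw(model$ins_vj) - 1L
    return(list(v = vn[vi], j = jn[ji], del_v = dv, del_j = dj,
                ins_vj = chain_sample(len, model$mk_vj, vbase)))
  }
  dn <- vapply(gl$D, `[[`, "", "name")
  pdd <- model$del_d[di, , ]
  ix <- draw(as.numeric(pdd))
  dl <- model$del_range$Dl[1] - 1L + (ix - 1L) %% nrow(pdd) + 1L
  drr <- model$del_range$Dr[1] - 1L + (ix - 1L) %/% nrow(pdd) + 1L
  lvd <- draw(model$ins_vd) - 1L
  ldj <- draw(model$ins_dj) - 1L
  list(v = vn[vi], d = dn[di], j = jn[ji],
       del_v = dv, del_d_l = dl, del_d_r = drr, del_j = dj,
       ins_vd = chain_sample(lvd, model$mk_vd, vbase),
       ins_dj = chain_sample(ldj, model$mk_dj, jbase, reverse = TRUE))
}

# retained segment pieces of a scenario (strings)
scenario_pieces <- function(scen, model) {
  gl <- model$germline
  vi <- match(scen$v, vapply(gl$V, `[[`, "", "name"))
  ji <- match(scen$j, vapply(gl$J, `[[`, "", "name"))
  V <- gl$V[[vi]]; J <- gl$J[[ji]]
  vpart <- substr(V$extended_seq, 1L, nchar(V$seq) - scen$del_v)
  jpart <- substr(J$extended_seq, model$max_p + scen$del_j + 1L,
                  model$max_p + nchar(J$seq))
  if (model$chain == "VDJ") {
    di <- match(scen$d, vapply(gl$D, `[[`, "", "name"))
    D <- gl$D[[di]]
    dpart <- substr(D$extended_seq, model$max_p + scen$del_d_l + 1L,
                    model$max_p + nchar(D$seq) - scen$del_d_r)
    list(v = vpart, ivd = scen$ins_vd, d = dpart, idj = scen$ins_dj,
         j = jpart, vi = vi, di = di, ji = ji)
  } else {
    list(v = vpart, ivj = scen$ins_vj, j = jpart, vi = vi, ji = ji)
  }
}

#' Realize a sequencing read from a scenario
#'
#' Builds the recombined ancestral sequence, applies per-base errors
#' (uniform rate) or context-dependent hypermutations (PWM model) to the
#' germline-covered positions -- the mutated base is drawn uniformly from
#' the three alternatives -- and truncates to the requested read length,
#' anchored by default at the 3' (J) end as in junction-centric short-read
#' protocols.
#'
#' @param scenario output of \code{\link{sample_scenario}}.
#' @param model a \code{recomb_model}.
#' @param hm_model optional \code{pwm_model}; when supplied hypermutation
#'   probabilities follow the PWM instead of the uniform error rate.
#' @param read_len read length (NULL keeps the full sequence).
#' @param anchor \code{"3p"} (default) or \code{"5p"}.
#' @return list: \code{read}, \code{truth} (one-row data.frame with scenario
#'   fields, visible window coordinates x/a/b/y, mutation positions, the
#'   ancestral window, productivity and truncation flags).
#' @export
realize_read <- function(scenario, model, hm_model = NULL, read_len = NULL,
                         anchor = c("3p", "5p")) {
  anchor <- match.arg(anchor)
  pc <- scenario_pieces(scenario, model)
  if (model$chain == "VDJ") {
    parts <- c(pc$v, pc$ivd, pc$d, pc$idj, pc$j)
  } else {
    parts <- c(pc$v, pc$ivj, pc$j)
  }
  anc <- paste(parts, collapse = "")
  n <- nchar(anc)
  lens <- nchar(parts)
  bnd <- cumsum(lens)  # end positions of V, insVD, D, insDJ, J (or V,ins,J)
  covered <- c(seq_len(lens[1]),
               if (model$chain == "VDJ" && lens[3] > 0)
                 (bnd[2] + 1L):bnd[3],
               if (model$chain == "VDJ") (bnd[4] + 1L):bnd[5]
               else (bnd[2] + 1L):bnd[3])
  av <- strsplit(anc, "")[[1]]
  # mutation probability per covered position
  if (is.null(hm_model) && model$err$kind == "pwm") hm_model <- model$err$pwm
  if (is.null(hm_model)) {
    pm <- rep(model$err$rate, length(covered))
  } else {
    m <- hm_model$m
    pm <- vapply(covered, function(p) {
      if (p - m < 1L || p + m > n) return(hm_model$mu / (1 + hm_model$mu))
      mut_prob(paste(av[(p - m):(p + m)], collapse = ""), hm_model)
    }, 0)
  }
  flip <- covered[runif(length(covered)) < pm]
  seqv <- av
  for (p in flip) seqv[p] <- sample(setdiff(NT, av[p]), 1L)
  full <- paste(seqv, collapse = "")

  short <- FALSE
  offset <- 0L
  if (!is.null(read_len) && read_len < n) {
    if (anchor == "3p") {
      offset <- n - read_len
      read <- substr(full, offset + 1L, n)
    } else read <- substr(full, 1L, read_len)
  } else {
    read <- full
    short <- !is.null(read_len) && read_len > n
  }
  # visible window coordinates (0-based, on the read)
  x <- lens[1] - offset
  if (model$chain == "VDJ") {
    a <- bnd[2] - offset; b <- bnd[3] - offset; y <- bnd[4] - offset
  } else {
    a <- b <- y <- bnd[2] - offset
  }
  junction_lost <- x < 1L
  mut_vis <- flip - offset
  mut_vis <- mut_vis[mut_vis >= 1L]
  truth <- data.frame(
    v = scenario$v, d = scenario$d %||% NA_character_, j = scenario$j,
    del_v = scenario$del_v,
    del_d_l = scenario$del_d_l %||% NA_integer_,
    del_d_r = scenario$del_d_r %||% NA_integer_,
    del_j = scenario$del_j,
    ins_vd = scenario$ins_vd %||% NA_character_,
    ins_dj = scenario$ins_dj %||% NA_character_,
    ins_vj = scenario$ins_vj %||% NA_character_,
    x = x, a = a, b = b, y = y,
    n_mut = length(flip), mut_pos = paste(mut_vis - 1L, collapse = ";"),
    anc_window = substr(anc, offset + 1L, n),
    anc_len = n, short = short, junction_lost = junction_lost,
    productive = is_productive(scenario, model),
    stringsAsFactors = FALSE)
  list(read = read, truth = truth)
}

#' Productivity of a recombination scenario
#'
#' A rearrangement is productive when both CDR3 anchors (the conserved V
#' cysteine and J phenylalanine/tryptophan codons, annotated on the germline
#' segments) survive deletion, the CDR3 nucleotide length is a multiple of
#' three, and the junction contains no stop codon in the anchor reading
#' frame.  Scenarios with destroyed anchors are non-productive.
#'
#' @param scenario scenario list.
#' @param model a \code{recomb_model} with anchor-annotated germline.
#' @return logical.
#' @export
is_productive <- function(scenario, model) {
  gl <- model$germline
  vi <- match(scenario$v, vapply(gl$V, `[[`, "", "name"))
  ji <- match(scenario$j, vapply(gl$J, `[[`, "", "name"))
  va <- gl$V[[vi]]$cdr3_anchor
  ja <- gl$J[[ji]]$cdr3_anchor
  if (is.na(va) || is.na(ja)) return(NA)
  retv <- nchar(gl$V[[vi]]$seq) - scenario$del_v
  if (retv < va + 3L) return(FALSE)            # V anchor deleted
  if (scenario$del_j > ja) return(FALSE)       # J anchor deleted
  pc <- scenario_pieces(scenario, model)
  anc <- if (model$chain == "VDJ")
    paste0(pc$v, pc$ivd, pc$d, pc$idj, pc$j) else paste0(pc$v, pc$ivj, pc$j)
  jstart <- nchar(anc) - nchar(pc$j)           # 0-based start of retained J
  cdr3 <- substr(anc, va + 1L, jstart + ja - scenario$del_j + 3L)
  if (nchar(cdr3) %% 3L != 0L) return(FALSE)
  codons <- substring(cdr3, seq(1L, nchar(cdr3) - 2L, 3L),
                      seq(3L, nchar(cdr3), 3L))
  !any(codons %in% c("TAA", "TAG", "TGA"))
}

#' Generate a synthetic repertoire batch with ground truth
#'
#' Reproducible for a fixed seed.  Optional rejection filters keep only
#' out-of-frame (non-productive) rearrangements, or match a target CDR3
#' nucleotide-length histogram.
#'
#' @param model a \code{recomb_model}.
#' @param n number of reads.
#' @param seed integer seed; all randomness derives from it.
#' @param read_len read length (default 60); NULL keeps full sequences.
#' @param hm_model optional hypermutation \code{pwm_model}.
#' @param out_of_frame_only keep only non-productive rearrangements.
#' @param cdr3_length_match optional table/named vector of target CDR3
#'   length frequencies to match by rejection sampling.
#' @param max_tries abort when the filter acceptance rate falls below
#'   roughly \code{1 / max_tries_per_read} (diagnostic error).
#' @return list with \code{reads} (named character), \code{truth}
#'   (data.frame, one row per read).
#' @export
generate_batch <- function(model, n, seed = 1L, read_len = 60L,
                           hm_model = NULL, out_of_frame_only = FALSE,
                           cdr3_length_match = NULL, max_tries = 1000L) {
  stopifnot(n >= 1)
  set.seed(as.integer(seed))
  want_len <- NULL
  if (!is.null(cdr3_length_match)) {
    p <- cdr3_length_match / sum(cdr3_length_match)
    want_len <- sample(as.integer(names(p)), n, replace = TRUE, prob = p)
  }
  reads <- character(n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (tr in seq_len(max_tries)) {
      scen <- sample_scenario(model)
      if (out_of_frame_only && isTRUE(is_productive(scen, model))) next
      if (!is.null(want_len)) {
        cl <- cdr3_length(scen, model)
        if (is.na(cl) || cl != want_len[i]) next
      }
      rr <- realize_read(scen, model, hm_model = hm_model,
                         read_len = read_len)
      ok <- TRUE
      break
    }
    if (!ok) stopf("filter acceptance rate below 1/%d; aborting", max_tries)
    reads[i] <- rr$read
    truth[[i]] <- cbind(read_id = sprintf("read%06d", i), rr$truth)
  }
  names(reads) <- sprintf("read%06d", seq_len(n))
  list(reads = reads, truth = do.call(rbind, truth))
}

#' CDR3 nucleotide length of a scenario
#'
#' Distance from the first base of the conserved V cysteine codon to the
#' last base of the J anchor codon, NA when an anchor was deleted.
#'
#' @param scenario scenario list.
#' @param model a \code{recomb_model}.
#' @return integer length or NA.
#' @export
cdr3_length <- function(scenario, model) {
  gl <- model$germline
  vi <- match(scenario$v, vapply(gl$V, `[[`, "", "name"))
  ji <- match(scenario$j, vapply(gl$J, `[[`, "", "name"))
  va <- gl$V[[vi]]$cdr3_anchor
  ja <- gl$J[[ji]]$cdr3_anchor
  if (is.na(va) || is.na(ja)) return(NA_integer_)
  retv <- nchar(gl$V[[vi]]$seq) - scenario$del_v
  if (retv < va + 3L || scenario$del_j > ja) return(NA_integer_)
  mid <- if (model$chain == "VDJ")
    nchar(scenario$ins_vd) + nchar(scenario$ins_dj) +
      (nchar(gl$D[[match(scenario$d,
                         vapply(gl$D, `[[`, "", "name"))]]$seq) -
       scenario$del_d_l - scenario$del_d_r)
  else nchar(scenario$ins_vj)
  as.integer((retv - va) + mid + (ja - scenario$del_j + 3L))
}
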