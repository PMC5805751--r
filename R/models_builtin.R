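#' Bundled synthetic germline libraries
#'
#' Small synthetic germline sets shipped with the package so that every
#' analysis runs without downloads: a TRB-like VDJ locus (8 V, 2 D, 6 J
#' with J1/J2 families), an IGH-like VDJ locus (10 V, 5 D, 6 J, longer
#' segments and D genes), and two miniature toy loci sized for exhaustive
#' enumeration oracles.  These are synthetic stand-ins for IMGT-style
#' exports: V genes are divergent copies of a common ancestor, anchors are
#' planted at fixed positions.
#'
#' @param name one of \code{"trb"}, \code{"igh"}, \code{"toy_vj"},
#'   \code{"toy_vdj"}.
#' @param max_p palindromic extension length.
#' @return list of \code{germline_segment}.
#' @export
builtin_germline <- function(name = c("trb", "igh", "toy_vj", "toy_vdj"),
                             max_p = 4L) {
  name <- match.arg(name)
  f <- c(trb = "trb_synthetic_germline.fa", igh = "igh_synthetic_germline.fa",
         toy_vj = "toy_vj_germline.fa", toy_vdj = "toy_vdj_germline.fa")[name]
  path <- system.file("extdata", f, package = "repgenr", mustWork = TRUE)
  read_germline_fasta(path, max_p = max_p)
}

# negative-binomial-shaped profile over a deletion range, zeroed outside
# each gene's support and renormalized per row
shape_del_rows <- function(cpt, rng, size, mu) {
  vals <- rng[1]:rng[2]
  w <- stats::dnbinom(vals - rng[1], size = size, mu = mu)
  for (i in seq_len(nrow(cpt))) {
    row <- w * (cpt[i, ] > 0)
    cpt[i, ] <- row / sum(row)
  }
  cpt
}

shape_ins <- function(ins_max, size, mu) {
  w <- stats::dnbinom(0:ins_max, size = size, mu = mu)
  w / sum(w)
}

# mild composition/stacking bias for inserted nucleotides
biased_markov <- function(base = c(0.22, 0.28, 0.28, 0.22), stack = 0.25) {
  T <- matrix(base, 4, 4, byrow = TRUE, dimnames = list(NT, NT))
  diag(T) <- diag(T) * (1 + stack)
  T / rowSums(T)
}

#' TRB-like recombination model with realistic event statistics
#'
#' VDJ model on the bundled TRB-like germline: Zipf-like V usage, D-J joint
#' usage with the structural exclusion of D2 with J1-family genes, deletion
#' profiles peaked at small positive values with a P-nucleotide tail
#' (range -4..16), insertion lengths with mean ~4.6 nt, and a mildly
#' biased insertion dinucleotide chain.
#'
#' @param err_rate uniform per-base error probability (default 1e-3; the
#'   scenario-degeneracy experiments use 5e-3).
#' @param germline optional germline override.
#' @return a \code{recomb_model}.
#' @export
model_trb_like <- function(err_rate = 1e-3, germline = NULL) {
  gl <- germline %||% builtin_germline("trb")
  m <- build_model(list(chain = "VDJ", max_p = 4L,
                        del_range = list(V = c(-4L, 16L), J = c(-4L, 16L),
                                         Dl = c(-4L, 16L), Dr = c(-4L, 16L)),
                        ins_max = 40L,
                        forbidden_dj = "TRBD2:J1",
                        err_rate = err_rate), gl)
  nV <- length(m$germline$V)
  m$gene$p_v <- norm1(1 / seq_len(nV)^0.7)
  names(m$gene$p_v) <- vapply(m$germline$V, `[[`, "", "name")
  dj <- outer(c(0.55, 0.45), norm1(1 / seq_len(length(m$germline$J))^0.4))
  dj[m$gene$mask_dj] <- 0
  m$gene$p_dj[] <- dj / sum(dj)
  m$del_v <- shape_del_rows(m$del_v, m$del_range$V, size = 2.5, mu = 5.5)
  m$del_j <- shape_del_rows(m$del_j, m$del_range$J, size = 2.5, mu = 6.0)
  for (g in seq_along(m$germline$D)) {
    wl <- stats::dnbinom(0:(dim(m$del_d)[2] - 1), size = 2.0, mu = 7.0)
    wr <- stats::dnbinom(0:(dim(m$del_d)[3] - 1), size = 2.0, mu = 7.0)
    jt <- outer(wl, wr) * (m$del_d[g, , ] > 0)
    m$del_d[g, , ] <- jt / sum(jt)
  }
  m$ins_vd <- setNames(shape_ins(m$ins_max, size = 2.2, mu = 4.6),
                       names(m$ins_vd))
  m$ins_dj <- setNames(shape_ins(m$ins_max, size = 2.2, mu = 4.6),
                       names(m$ins_dj))
  m$mk_vd <- biased_markov()
  m$mk_dj <- biased_markov(base = c(0.24, 0.27, 0.26, 0.23))
  validate_model(m)
  m
}

#' IGH-like recombination model
#'
#' Like \code{\link{model_trb_like}} but on the IGH-like germline (longer V
#' and D segments, no D-J exclusion) with more junctional insertions (mean
#' ~7.5 nt per junction), matching the broader IGH insertion profile.
#'
#' @inheritParams model_trb_like
#' @return a \code{recomb_model}.
#' @export
model_igh_like <- function(err_rate = 1e-3, germline = NULL) {
  gl <- germline %||% builtin_germline("igh")
  m <- build_model(list(chain = "VDJ", max_p = 4L,
                        del_range = list(V = c(-4L, 16L), J = c(-4L, 16L),
                                         Dl = c(-4L, 16L), Dr = c(-4L, 16L)),
                        ins_max = 40L, err_rate = err_rate), gl)
  nV <- length(m$germline$V)
  m$gene$p_v <- norm1(1 / seq_len(nV)^0.6)
  names(m$gene$p_v) <- vapply(m$germline$V, `[[`, "", "name")
  dj <- outer(norm1(c(0.8, 1.2, 1.0, 0.9, 1.1)),
              norm1(1 / seq_len(length(m$germline$J))^0.5))
  m$gene$p_dj[] <- dj / sum(dj)
  m$del_v <- shape_del_rows(m$del_v, m$del_range$V, size = 2.2, mu = 5.0)
  m$del_j <- shape_del_rows(m$del_j, m$del_range$J, size = 2.2, mu = 5.5)
  for (g in seq_along(m$germline$D)) {
    wl <- stats::dnbinom(0:(dim(m$del_d)[2] - 1), size = 2.0, mu = 6.0)
    wr <- stats::dnbinom(0:(dim(m$del_d)[3] - 1), size = 2.0, mu = 6.0)
    jt <- outer(wl, wr) * (m$del_d[g, , ] > 0)
    m$del_d[g, , ] <- jt / sum(jt)
  }
  m$ins_vd <- setNames(shape_ins(m$ins_max, size = 1.6, mu = 7.5),
                       names(m$ins_vd))
  m$ins_dj <- setNames(shape_ins(m$ins_max, size = 1.6, mu = 7.5),
                       names(m$ins_dj))
  m$mk_vd <- biased_markov()
  m$mk_dj <- biased_markov(base = c(0.24, 0.27, 0.26, 0.23))
  validate_model(m)
  m
}

#' Reduced TRB-like model for scaled-down learning experiments
#'
#' Same event statistics as \code{\link{model_trb_like}} but on a reduced
#' germline (4 V, 2 D, 4 J), cutting the parameter count so that synthetic
#' learning experiments run at desk scale.
#'
#' @inheritParams model_trb_like
#' @return a \code{recomb_model}.
#' @export
model_trb_small <- function(err_rate = 1e-3) {
  gl <- builtin_germline("trb")
  nm <- vapply(gl, `[[`, "", "name")
  keep <- nm %in% c("TRBV1", "TRBV2", "TRBV3", "TRBV4", "TRBD1", "TRBD2",
                    "TRBJ1-1", "TRBJ1-2", "TRBJ2-1", "TRBJ2-2")
  model_trb_like(err_rate = err_rate, germline = gl[keep])
}

#' Hotspot-motif-like hypermutation PWM
#'
#' A fixed 7-mer additive PWM emulating the qualitative structure of known
#' somatic hypermutation hotspots (WRC/WA-like enrichment of A/T upstream,
#' depletion of C/G around the site) with overall rate \code{mu}.  Used as
#' the generating model in synthetic hypermutation experiments.
#'
#' @param mu overall mutation odds scale (default 0.02).
#' @return a \code{pwm_model}.
#' @export
shm_pwm_default <- function(mu = 0.02) {
  e <- rbind(
    c( 0.15, -0.20, -0.15,  0.20),   # -3
    c( 0.45, -0.35, -0.40,  0.30),   # -2  (W)
    c( 0.55, -0.30,  0.35, -0.60),   # -1  (R)
    c(-0.25,  0.60, -0.45,  0.10),   #  0  mutated site (C-biased)
    c( 0.20,  0.25, -0.35, -0.10),   # +1  (Y-ish)
    c( 0.25, -0.15, -0.25,  0.15),   # +2
    c( 0.10, -0.10, -0.05,  0.05))   # +3
  pwm_model(m = 3L, e = e, mu = mu)
}
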