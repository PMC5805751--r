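# Micro toy models sized so that brute-force oracles can enumerate the whole
# scenario space.  CPTs are deliberately non-uniform so that oracle
# comparisons exercise every factor.

micro_vj_model <- function(err_rate = 0.02) {
  gl <- list(
    germline_segment("UV1", "V", "ACGTACGTAC", max_p = 1),
    germline_segment("UV2", "V", "TTGACCGTTG", max_p = 1),
    germline_segment("UJ1", "J", "GGATCCAA", max_p = 1),
    germline_segment("UJ2", "J", "CATGGTGA", max_p = 1))
  m <- build_model(list(chain = "VJ", max_p = 1L,
                        del_range = list(V = c(-1L, 2L), J = c(-1L, 2L)),
                        ins_max = 3L, err_rate = err_rate), gl)
  m$gene$p_vj[] <- matrix(c(0.4, 0.2, 0.25, 0.15), 2, 2)
  m$del_v[] <- matrix(rep(c(0.1, 0.4, 0.3, 0.2), each = 2), 2, 4)
  m$del_j[] <- matrix(rep(c(0.2, 0.35, 0.3, 0.15), each = 2), 2, 4)
  m$ins_vj[] <- c(0.4, 0.3, 0.2, 0.1)
  m$mk_vj[] <- matrix(c(0.4, 0.2, 0.2, 0.2,
                        0.1, 0.5, 0.2, 0.2,
                        0.25, 0.25, 0.3, 0.2,
                        0.2, 0.3, 0.1, 0.4), 4, 4, byrow = TRUE)
  validate_model(m)
  m
}

micro_vdj_model <- function(err_rate = 0.02) {
  gl <- list(
    germline_segment("MV1", "V", "ACGTACGT", max_p = 1),
    germline_segment("MV2", "V", "TTGACCGT", max_p = 1),
    germline_segment("MD1", "D", "GGCA", max_p = 1),
    germline_segment("MD2", "D", "GTTC", max_p = 1),
    germline_segment("MJ1", "J", "GGATCC", max_p = 1, family = "J1"),
    germline_segment("MJ2", "J", "CATGGT", max_p = 1, family = "J2"))
  m <- build_model(list(chain = "VDJ", max_p = 1L,
                        del_range = list(V = c(-1L, 2L), J = c(-1L, 2L),
                                         Dl = c(-1L, 1L), Dr = c(-1L, 1L)),
                        ins_max = 2L, forbidden_dj = "MD2:J1",
                        err_rate = err_rate), gl)
  m$gene$p_v[] <- c(0.6, 0.4)
  dj <- matrix(c(0.3, 0, 0.3, 0.4), 2, 2)  # MD2 x MJ1 masked
  m$gene$p_dj[] <- dj / sum(dj)
  m$del_v[] <- matrix(rep(c(0.1, 0.4, 0.3, 0.2), each = 2), 2, 4)
  m$del_j[] <- matrix(rep(c(0.2, 0.35, 0.3, 0.15), each = 2), 2, 4)
  for (g in 1:2) {
    jt <- outer(c(0.25, 0.45, 0.3), c(0.3, 0.45, 0.25)) *
      (m$del_d[g, , ] > 0)
    m$del_d[g, , ] <- jt / sum(jt)
  }
  m$ins_vd[] <- c(0.5, 0.3, 0.2)
  m$ins_dj[] <- c(0.45, 0.35, 0.2)
  m$mk_vd[] <- matrix(c(0.4, 0.2, 0.2, 0.2,
                        0.1, 0.5, 0.2, 0.2,
                        0.25, 0.25, 0.3, 0.2,
                        0.2, 0.3, 0.1, 0.4), 4, 4, byrow = TRUE)
  m$mk_dj[] <- matrix(c(0.3, 0.3, 0.2, 0.2,
                        0.2, 0.4, 0.2, 0.2,
                        0.2, 0.2, 0.4, 0.2,
                        0.15, 0.25, 0.2, 0.4), 4, 4, byrow = TRUE)
  validate_model(m)
  m
}

# exhaustive enumeration settings: no pruning, no thresholds, no caps
exhaustive_cfg <- function(k_top = 100000L) {
  prune_config(prune_ratio = 0, floor = 1e-300, k_top = k_top,
               thr_v = -1e18, thr_j = -1e18, mm_budget = 1e6)
}
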