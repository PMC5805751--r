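# Brute-force oracles, written independently of the enumeration engine:
# plain R loops over every event combination, reconstructing strings and
# recomputing probabilities through scenario_prob().

seg_names <- function(model, cls) vapply(model$germline[[cls]], `[[`, "", "name")

# every scenario consistent with `read` (3'-anchored window convention),
# with its p_recomb and p_err
oracle_enumerate <- function(read, model) {
  L <- nchar(read)
  r <- model$err$rate
  maxp <- model$max_p
  out <- list()
  mm_count <- function(a, b) {
    if (nchar(a) == 0) return(0L)
    va <- strsplit(a, "")[[1]]; vb <- strsplit(b, "")[[1]]
    sum(va != vb & va != "N")
  }
  for (vi in seq_along(model$germline$V)) {
    V <- model$germline$V[[vi]]
    Lv <- nchar(V$seq)
    for (delv in model$del_range$V[1]:model$del_range$V[2]) {
      retv <- Lv - delv
      if (retv < 1) next
      vfull <- substr(V$extended_seq, 1, retv)
      for (x in 1:min(retv, L - 1)) {
        vvis <- substr(vfull, retv - x + 1, retv)
        mm_v <- mm_count(substr(read, 1, x), vvis)
        for (ji in seq_along(model$germline$J)) {
          J <- model$germline$J[[ji]]
          Lj <- nchar(J$seq)
          for (delj in model$del_range$J[1]:model$del_range$J[2]) {
            retj <- Lj - delj
            if (retj < 1) next
            y <- L - retj
            if (y < x || y > L - 1) next
            jvis <- substr(J$extended_seq, maxp + delj + 1, maxp + Lj)
            mm_j <- mm_count(substr(read, y + 1, L), jvis)
            if (model$chain == "VJ") {
              if (y - x > model$ins_max) next
              scen <- list(v = V$name, j = J$name, del_v = delv,
                           del_j = delj, ins_vj = substr(read, x + 1, y))
              pr <- scenario_prob(model, scen)
              if (pr == 0) next
              mm <- mm_v + mm_j
              cov <- x + (L - y)
              pe <- (r / 3)^mm * (1 - r)^(cov - mm)
              out[[length(out) + 1L]] <- c(scen,
                list(x = x, a = y, b = y, y = y, mm = mm,
                     p_recomb = pr, p_err = pe, p = pr * pe))
              next
            }
            for (di in seq_along(model$germline$D)) {
              D <- model$germline$D[[di]]
              Ld <- nchar(D$seq)
              for (dl in model$del_range$Dl[1]:model$del_range$Dl[2]) {
                for (dr in model$del_range$Dr[1]:model$del_range$Dr[2]) {
                  len <- Ld - dl - dr
                  if (len < 0) next
                  dpart <- substr(D$extended_seq, maxp + dl + 1,
                                  maxp + Ld - dr)
                  if (y - len < x) next
                  for (a in x:(y - len)) {
                    b <- a + len
                    if (a - x > model$ins_max || y - b > model$ins_max) next
                    scen <- list(v = V$name, d = D$name, j = J$name,
                                 del_v = delv, del_d_l = dl, del_d_r = dr,
                                 del_j = delj,
                                 ins_vd = substr(read, x + 1, a),
                                 ins_dj = substr(read, b + 1, y))
                    pr <- scenario_prob(model, scen)
                    if (pr == 0) next
                    mm_d <- mm_count(substr(read, a + 1, b), dpart)
                    mm <- mm_v + mm_d + mm_j
                    cov <- x + len + (L - y)
                    pe <- (r / 3)^mm * (1 - r)^(cov - mm)
                    out[[length(out) + 1L]] <- c(scen,
                      list(x = x, a = a, b = b, y = y, mm = mm,
                           p_recomb = pr, p_err = pe, p = pr * pe))
                  }
                }
              }
            }
          }
        }
      }
    }
  }
  out
}

# full generative space of a VJ micro model: every (event, insertion
# content) combination with its probability and recombined sequence
oracle_vj_space <- function(model) {
  stopifnot(model$chain == "VJ")
  strs <- function(len) {
    if (len == 0) return("")
    do.call(paste0, rev(expand.grid(rep(list(c("A", "C", "G", "T")), len),
                                    stringsAsFactors = FALSE)))
  }
  out <- list()
  for (vi in seq_along(model$germline$V)) {
    V <- model$germline$V[[vi]]
    Lv <- nchar(V$seq)
    for (delv in model$del_range$V[1]:model$del_range$V[2]) {
      if (Lv - delv < 1) next
      vpart <- substr(V$extended_seq, 1, Lv - delv)
      for (ji in seq_along(model$germline$J)) {
        J <- model$germline$J[[ji]]
        for (delj in model$del_range$J[1]:model$del_range$J[2]) {
          if (nchar(J$seq) - delj < 1) next
          jpart <- substr(J$extended_seq, model$max_p + delj + 1,
                          model$max_p + nchar(J$seq))
          for (len in 0:model$ins_max) {
            for (ins in strs(len)) {
              scen <- list(v = V$name, j = J$name, del_v = delv,
                           del_j = delj, ins_vj = ins)
              p <- scenario_prob(model, scen)
              if (p == 0) next
              out[[length(out) + 1L]] <- list(
                scen = scen, p = p, seq = paste0(vpart, ins, jpart))
            }
          }
        }
      }
    }
  }
  out
}

# textbook Smith-Waterman DP, linear gap penalty
r_sw_score <- function(a, b, s_match = 5, s_mism = -14, s_gap = -50) {
  va <- nt_int_test(a); vb <- nt_int_test(b)
  n <- length(va); m <- length(vb)
  H <- matrix(0, n + 1, m + 1)
  for (i in 1:n) for (j in 1:m) {
    sub <- if (va[i] >= 0 && va[i] == vb[j]) s_match else s_mism
    H[i + 1, j + 1] <- max(0, H[i, j] + sub, H[i, j + 1] + s_gap,
                           H[i + 1, j] + s_gap)
  }
  max(H)
}

nt_int_test <- function(s) {
  v <- match(strsplit(toupper(s), "")[[1]], c("A", "C", "G", "T")) - 1L
  v[is.na(v)] <- -1L
  v
}
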