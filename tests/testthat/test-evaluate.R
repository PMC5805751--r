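test_that("KL divergence basics", {
  m <- micro_vdj_model()
  kl <- kl_divergence(m, m)
  expect_equal(kl$total_bits, 0, tolerance = 1e-12)
  expect_equal(sum(kl$per_event_bits), kl$total_bits, tolerance = 1e-12)

  # hand evaluation on a single 2-value event
  gl <- list(germline_segment("V1", "V", "ACGTACGTCC", max_p = 0),
             germline_segment("J1", "J", "GGATCCAA", max_p = 0))
  base <- list(chain = "VJ", max_p = 0,
               del_range = list(V = c(0, 1), J = c(0, 0)), ins_max = 0,
               err_rate = 1e-3)
  a <- build_model(base, gl); b <- build_model(base, gl)
  a$del_v[] <- matrix(c(0.5, 0.5), 1)
  b$del_v[] <- matrix(c(0.25, 0.75), 1)
  kl2 <- kl_divergence(a, b)
  expect_equal(kl2$total_bits, 0.5 * log2(2) + 0.5 * log2(2 / 3),
               tolerance = 1e-10)

  # asymmetry
  expect_false(isTRUE(all.equal(kl_divergence(a, b)$total_bits,
                                kl_divergence(b, a)$total_bits)))

  # zero where the reference is positive -> +Inf with offenders listed
  c2 <- b; c2$del_v[] <- matrix(c(1, 0), 1)
  klz <- kl_divergence(a, c2)
  expect_identical(klz$total_bits, Inf)
  expect_true(length(attr(klz, "zero_cells")) > 0)
})

test_that("chain-rule KL equals the brute-force scenario sum", {
  m1 <- micro_vj_model()
  m2 <- micro_vj_model()
  # perturb every table of m2
  m2$gene$p_vj[] <- norm1(m2$gene$p_vj + 0.05)
  m2$del_v[] <- t(apply(m2$del_v + 0.03, 1, norm1))
  m2$del_j[] <- t(apply(m2$del_j + 0.06, 1, norm1))
  m2$ins_vj[] <- norm1(m2$ins_vj + c(0.05, 0, 0.1, 0))
  m2$mk_vj[] <- t(apply(m2$mk_vj + 0.08, 1, norm1))
  sp1 <- oracle_vj_space(m1)
  brute <- 0
  for (s in sp1) {
    p2 <- scenario_prob(m2, s$scen)
    brute <- brute + s$p * log2(s$p / p2)
  }
  kl <- kl_divergence(m1, m2)
  expect_equal(kl$total_bits, brute, tolerance = 1e-8)
})

test_that("rank statistics on a deterministic toy give rank 1", {
  gl <- list(germline_segment("V1", "V", "ACGTACGTCC", max_p = 0),
             germline_segment("J1", "J", "GGATCCAA", max_p = 0))
  m <- build_model(list(chain = "VJ", max_p = 0,
                        del_range = list(V = c(0, 0), J = c(0, 0)),
                        ins_max = 0, err_rate = 1e-3), gl)
  b <- generate_batch(m, 10, seed = 3, read_len = NULL)
  ab <- annotate_batch(b$reads, m, truth = b$truth,
                       prune = exhaustive_cfg())
  rs <- rank_stats(b$truth, ab$summary)
  expect_equal(rs$top1_accuracy, 1)
  expect_true(all(rs$ranks == 1))
  expect_equal(unname(rs$n_conf["N_0.95"]), 1)
  expect_equal(length(rs$ranks), 10)
})

test_that("tandem D detection flags a hand-built double-D read", {
  m <- model_igh_like()
  V <- m$germline$V[[1]]$seq
  J <- m$germline$J[[1]]$seq
  d1 <- substr(m$germline$D[[3]]$seq, 1, 12)
  d2 <- substr(m$germline$D[[5]]$seq, 1, 12)
  read <- paste0(substr(V, nchar(V) - 59, nchar(V)), "ACG", d1, "TT", d2,
                 "CA", J)
  plain <- paste0(substr(V, nchar(V) - 59, nchar(V)), "ACGTT", J)
  td <- tandem_d_frequency(c(a = read, b = plain), m, min_len = 10)
  expect_true(td$flags[1])
  expect_false(td$flags[2])
  expect_equal(td$n_eval, 2)
})

test_that("single-D synthetic batches act as their own control", {
  m <- model_igh_like()
  b1 <- generate_batch(m, 30, seed = 51, read_len = 130)
  b2 <- generate_batch(m, 30, seed = 52, read_len = 130)
  t1 <- tandem_d_frequency(b1$reads, m)
  t2 <- tandem_d_frequency(b2$reads, m)
  # both are single-D by construction; frequencies are comparable baselines
  expect_lt(abs(t1$frequency - t2$frequency), 0.25)
})
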