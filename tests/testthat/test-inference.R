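test_that("posterior weights land in the right count cells", {
  # forced single scenario: every realized cell receives weight exactly 1
  gl <- list(germline_segment("V1", "V", "ACGTACGTCC", max_p = 0),
             germline_segment("J1", "J", "GGATCCAA", max_p = 0))
  m <- build_model(list(chain = "VJ", max_p = 0,
                        del_range = list(V = c(0, 0), J = c(0, 0)),
                        ins_max = 0, err_rate = 1e-3), gl)
  st <- e_step(c(r1 = "ACGTACGTCCGGATCCAA"), m, exhaustive_cfg(k_top = 0))
  expect_equal(unname(st$gene_vj[1, 1]), 1, tolerance = 1e-12)
  expect_equal(unname(st$del_v[1, "0"]), 1, tolerance = 1e-12)
  expect_equal(unname(st$ins_vj[["0"]]), 1, tolerance = 1e-12)
  expect_equal(st$err_events, 0, tolerance = 1e-12)
  expect_equal(st$err_opps, 18, tolerance = 1e-12)
})

test_that("e_step counts equal exhaustive posterior expectations", {
  m <- micro_vj_model()
  set.seed(41)
  rr <- realize_read(sample_scenario(m), m)
  st <- e_step(setNames(rr$read, "r"), m, exhaustive_cfg(k_top = 0))
  orc <- oracle_enumerate(rr$read, m)
  p <- vapply(orc, `[[`, 0, "p")
  w <- p / sum(p)
  # oracle posterior marginals
  vs <- vapply(orc, `[[`, "", "v")
  for (v in unique(vs))
    expect_equal(unname(rowSums(st$gene_vj)[v]), sum(w[vs == v]),
                 tolerance = 1e-8)
  dels <- vapply(orc, `[[`, 0, "del_v")
  for (d in unique(dels)) {
    vi <- match(vs[dels == d][1], seg_names(m, "V"))
    got <- sum(st$del_v[, as.character(d)])
    expect_equal(got, sum(w[dels == d]), tolerance = 1e-8)
  }
  ins <- vapply(orc, function(s) nchar(s$ins_vj), 0)
  for (l in unique(ins))
    expect_equal(unname(st$ins_vj[[as.character(l)]]), sum(w[ins == l]),
                 tolerance = 1e-8)
  mm <- vapply(orc, `[[`, 0, "mm")
  expect_equal(st$err_events, sum(w * mm), tolerance = 1e-8)
  expect_equal(st$pseudo_ll, sum(w * log(p)), tolerance = 1e-6)
})

test_that("symmetric scenarios split posterior weight equally", {
  # palindromic-free junction where two deletions explain the read equally
  gl <- list(germline_segment("V1", "V", "ACGTACGTAA", max_p = 0),
             germline_segment("J1", "J", "GGATCCAA", max_p = 0))
  m <- build_model(list(chain = "VJ", max_p = 0,
                        del_range = list(V = c(0, 1), J = c(0, 0)),
                        ins_max = 1, err_rate = 1e-6), gl)
  # read with full V: (delV=0, ins 0) vs (delV=1, ins "A"): make them
  # equally likely by tuning P(ins) against the markov factor
  m$ins_vj[] <- c(0.5, 0.5)
  m$mk_vj[] <- matrix(0.25, 4, 4)
  m$del_v[] <- matrix(c(0.5, 0.5), 1)
  read <- "ACGTACGTAAGGATCCAA"
  st <- e_step(setNames(read, "r"), m, exhaustive_cfg(k_top = 0))
  # P(delV=0)P(ins=0) = .25 vs P(delV=1)P(ins=1)P(A) = .5*.5*.25
  w0 <- 0.25; w1 <- 0.0625
  expect_equal(unname(st$del_v[1, "0"]), w0 / (w0 + w1), tolerance = 1e-6)
  expect_equal(unname(st$del_v[1, "1"]), w1 / (w0 + w1), tolerance = 1e-6)
})

test_that("m_step normalizes, smooths support only, and updates error rate", {
  m <- micro_vdj_model()
  st <- e_step(setNames(realize_read(sample_scenario(m), m)$read, "r"), m,
               exhaustive_cfg(k_top = 0))
  st$gene_v[] <- c(3, 1)
  st$err_events <- 10; st$err_opps <- 10000
  m2 <- m_step(st, m, smoothing = 0)
  expect_equal(unname(m2$gene$p_v), c(0.75, 0.25), tolerance = 1e-12)
  expect_equal(m2$err$rate, 1e-3, tolerance = 1e-12)
  # masked D-J cells stay exactly zero even with smoothing
  m3 <- m_step(st, m, smoothing = 1e-6)
  jfam <- vapply(m3$germline$J, `[[`, "", "family")
  expect_identical(unname(m3$gene$p_dj["MD2", jfam == "J1"]), 0)
  validate_model(m3)
})

test_that("EM is order-invariant and monotone on a small batch", {
  m <- micro_vdj_model()
  set.seed(57)
  b <- generate_batch(m, 40, seed = 57, read_len = NULL)
  init <- build_model(list(chain = "VDJ", max_p = 1,
                           del_range = list(V = c(-1, 2), J = c(-1, 2),
                                            Dl = c(-1, 1), Dr = c(-1, 1)),
                           ins_max = 2, forbidden_dj = "MD2:J1",
                           err_rate = 1e-2),
                      lapply(m$germline, identity))
  pr <- prune_config(prune_ratio = 1e-6, thr_v = 10, thr_j = 10)
  fit <- em_learn(b$reads, init, max_iter = 3, tol = 1e-6, prune = pr)
  ll <- fit$trajectory$loglik
  expect_true(all(diff(ll[-1]) > -1e-5 * abs(ll[-1][-1]) - 1e-8))
  # shuffling reads changes nothing
  set.seed(99)
  sh <- sample(seq_along(b$reads))
  fit2 <- em_learn(b$reads[sh], init, max_iter = 3, tol = 1e-6, prune = pr)
  expect_equal(fit2$model$del_v, fit$model$del_v, tolerance = 1e-10)
  expect_equal(fit2$model$gene$p_dj, fit$model$gene$p_dj, tolerance = 1e-10)
})

test_that("EM near the truth stays near the truth", {
  m <- micro_vdj_model()
  set.seed(73)
  b <- generate_batch(m, 150, seed = 73, read_len = NULL)
  st <- e_step(b$reads, m, prune_config(prune_ratio = 1e-6, thr_v = 10,
                                        thr_j = 10))
  m2 <- m_step(st, m)
  # one EM step from the generating model moves each CPT by little
  # (fixed point up to sampling noise)
  tv <- function(p, q) sum(abs(p - q)) / 2
  expect_lt(tv(m2$gene$p_v, m$gene$p_v), 0.1)
  expect_lt(tv(as.numeric(m2$ins_vd), as.numeric(m$ins_vd)), 0.15)
})

test_that("out-of-frame filter keeps only non-productive truths", {
  m <- model_trb_like()
  b <- generate_batch(m, 60, seed = 3, read_len = 60, out_of_frame_only = TRUE)
  expect_true(all(!b$truth$productive))
  ids <- filter_out_of_frame(b$truth)
  expect_setequal(ids, b$truth$read_id)
})
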