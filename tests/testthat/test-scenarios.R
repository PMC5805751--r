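test_that("single forced scenario has closed-form likelihood", {
  # one V, one J, deletions pinned to 0, no insertions: the exact
  # concatenation admits exactly one scenario with P_read = (1-p)^L
  p <- 0.01
  gl <- list(germline_segment("V1", "V", "ACGTACGTCC", max_p = 0),
             germline_segment("J1", "J", "GGATCCAA", max_p = 0))
  m <- build_model(list(chain = "VJ", max_p = 0,
                        del_range = list(V = c(0, 0), J = c(0, 0)),
                        ins_max = 0, err_rate = p), gl)
  read <- "ACGTACGTCCGGATCCAA"
  ann <- enumerate_scenarios(read, m, prune = exhaustive_cfg())
  expect_equal(ann$n_scenarios, 1)
  expect_equal(ann$p_read, (1 - p)^nchar(read), tolerance = 1e-12)
  expect_equal(ann$scenarios$log_p_recomb[1], 0, tolerance = 1e-12)
})

test_that("templated junction bases yield competing scenarios", {
  gl <- list(germline_segment("V1", "V", "ACGTACGTCG", max_p = 1),
             germline_segment("J1", "J", "GGATCCAA", max_p = 1))
  m <- build_model(list(chain = "VJ", max_p = 1,
                        del_range = list(V = c(-1, 2), J = c(0, 2)),
                        ins_max = 2, err_rate = 1e-3), gl)
  # read carrying the full V: explainable as (delV=0, ins "G"+junction) or
  # (delV=1, insertion supplies the templated G), etc.
  read <- paste0("ACGTACGTCG", "G", "GGATCCAA")
  ann <- enumerate_scenarios(read, m, prune = exhaustive_cfg())
  sc <- ann$scenarios
  a <- sc[sc$del_v == 0 & sc$ins_vj == "G", ]
  b <- sc[sc$del_v == 1 & sc$ins_vj == "GG", ]
  expect_equal(nrow(a), 1)
  expect_equal(nrow(b), 1)
  expect_true(all(is.finite(c(a$log_p_recomb, b$log_p_recomb))))
})

test_that("enumeration equals the exhaustive oracle (VJ and VDJ micro)", {
  set.seed(101)
  for (maker in list(micro_vj_model, micro_vdj_model)) {
    m <- maker()
    for (k in 1:2) {
      scen <- sample_scenario(m)
      rr <- realize_read(scen, m, read_len = NULL)  # untruncated
      orc <- oracle_enumerate(rr$read, m)
      p_orc <- sum(vapply(orc, `[[`, 0, "p"))
      ann <- enumerate_scenarios(rr$read, m, prune = exhaustive_cfg())
      expect_equal(ann$n_scenarios, length(orc))
      expect_equal(ann$log_p_read, log(p_orc), tolerance = 1e-10)
      expect_equal(max(ann$scenarios$logp),
                   log(max(vapply(orc, `[[`, 0, "p"))), tolerance = 1e-10)
    }
  }
})

test_that("pruned enumeration loses at most the truncated mass bound", {
  m <- micro_vdj_model()
  set.seed(7)
  for (k in 1:5) {
    rr <- realize_read(sample_scenario(m), m)
    full <- enumerate_scenarios(rr$read, m, prune = exhaustive_cfg())
    pruned <- enumerate_scenarios(rr$read, m,
      prune = prune_config(prune_ratio = 1e-3, thr_v = -1e18, thr_j = -1e18,
                           mm_budget = 1e6))
    expect_lte(pruned$p_read, full$p_read * (1 + 1e-9))
    eps <- pruned$truncated_mass_bound
    expect_gte(pruned$p_read, full$p_read - eps)
    # posterior weights over the ranked list sum to <= 1
    expect_lte(sum(pruned$scenarios$posterior), 1 + 1e-9)
  }
})

test_that("ranking is deterministic and tie-broken stably", {
  m <- micro_vdj_model()
  set.seed(17)
  rr <- realize_read(sample_scenario(m), m)
  a <- enumerate_scenarios(rr$read, m, prune = exhaustive_cfg())
  b <- enumerate_scenarios(rr$read, m, prune = exhaustive_cfg())
  expect_identical(a$scenarios, b$scenarios)
  expect_true(all(diff(a$scenarios$logp) <= 1e-12))
})

test_that("pgen of the deterministic toy and sum over sequences", {
  # deterministic point-mass model -> unique sequence with pgen 1
  gl <- list(germline_segment("V1", "V", "ACGTACGTCC", max_p = 0),
             germline_segment("J1", "J", "GGATCCAA", max_p = 0))
  m <- build_model(list(chain = "VJ", max_p = 0,
                        del_range = list(V = c(0, 0), J = c(0, 0)),
                        ins_max = 0, err_rate = 1e-3), gl)
  expect_equal(pgen("ACGTACGTCCGGATCCAA", m), 1, tolerance = 1e-10)
  expect_warning(p0 <- pgen("TTTTTTTTTTTTTTTTTT", m), "Pgen = 0")
  expect_equal(p0, 0)

  # micro VJ: sum of pgen over all reachable windows of the minimal length
  m2 <- micro_vj_model()
  sp <- oracle_vj_space(m2)
  L <- min(vapply(sp, function(x) nchar(x$seq), 0))
  win <- vapply(sp, function(x) substring(x$seq, nchar(x$seq) - L + 1), "")
  probs <- vapply(sp, `[[`, 0, "p")
  agg <- rowsum(probs, win)
  expect_equal(sum(agg), 1, tolerance = 1e-8)
  for (s in sample(rownames(agg), 25)) {
    expect_equal(pgen(s, m2), unname(agg[s, 1]), tolerance = 1e-8)
  }
})

test_that("degenerate sequences have pgen equal to the scenario sum", {
  gl <- list(germline_segment("V1", "V", "ACGTACGTCG", max_p = 1),
             germline_segment("J1", "J", "GGATCCAA", max_p = 1))
  m <- build_model(list(chain = "VJ", max_p = 1,
                        del_range = list(V = c(-1, 2), J = c(0, 2)),
                        ins_max = 2, err_rate = 1e-3), gl)
  read <- paste0("ACGTACGTCG", "G", "GGATCCAA")
  ann <- enumerate_scenarios(read, m, prune = exhaustive_cfg())
  clean <- ann$scenarios[ann$scenarios$n_mismatch == 0, ]
  expect_gt(nrow(clean), 1)  # same sequence generated in different ways
  pg <- pgen(read, m)
  expect_equal(pg, sum(exp(clean$log_p_recomb)), tolerance = 1e-10)
  expect_gt(pg, max(exp(clean$log_p_recomb)))
})

test_that("pgen_mutated reduces to pgen on unmutated reads", {
  m <- micro_vdj_model(err_rate = 1e-9)
  set.seed(23)
  rr <- realize_read(sample_scenario(m), m)
  est <- pgen_mutated(rr$read, m, prune = prune_config(
    prune_ratio = 1e-4, thr_v = -1e18, thr_j = -1e18, k_top = 5000))
  expect_false(est$failed)
  expect_equal(nrow(est$ancestors), 1)  # single plausible ancestor
  expect_equal(est$p_gen, pgen(rr$read, m), tolerance = 1e-6)
})

test_that("rank_coverage partial sums", {
  fake <- structure(list(
    scenarios = data.frame(logp = log(c(0.4, 0.3, 0.2, 0.1))),
    log_p_read = log(1)), class = "annotation_result")
  expect_equal(rank_coverage(fake, 0.75), 3L)
  expect_equal(rank_coverage(fake, 1), 4L)
  one <- structure(list(scenarios = data.frame(logp = log(0.9)),
                        log_p_read = log(0.9)), class = "annotation_result")
  expect_equal(rank_coverage(one, 0.5), 1L)
  expect_equal(rank_coverage(one, 1), 1L)
})
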