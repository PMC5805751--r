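# local helpers --------------------------------------------------------------
scenario_pieces_test <- function(scen, model) {
  gl <- model$germline
  vi <- match(scen$v, vapply(gl$V, `[[`, "", "name"))
  di <- match(scen$d, vapply(gl$D, `[[`, "", "name"))
  lens <- c(nchar(gl$V[[vi]]$seq) - scen$del_v, nchar(scen$ins_vd),
            nchar(gl$D[[di]]$seq) - scen$del_d_l - scen$del_d_r,
            nchar(scen$ins_dj))
  lens
}

site_probs_test <- function(anc, lens, pw) {
  n <- length(anc)
  covered <- c(seq_len(lens[1]),
               if (lens[3] > 0) (sum(lens[1:2]) + 1):sum(lens[1:3]),
               (sum(lens[1:4]) + 1):n)
  vapply(covered, function(p) {
    if (p - pw$m < 1 || p + pw$m > n) return(pw$mu / (1 + pw$mu))
    mut_prob(paste(anc[(p - pw$m):(p + pw$m)], collapse = ""), pw)
  }, 0)
}

test_that("mut_prob follows the logistic link", {
  pw <- pwm_model(m = 3, mu = 1e-3)
  expect_equal(mut_prob("ACGTACG", pw), 1e-3 / (1 + 1e-3), tolerance = 1e-12)
  pw2 <- pwm_model(m = 3, mu = 1e-12)
  expect_lt(mut_prob("ACGTACG", pw2), 1e-11)
  # context with N falls back to the overall rate
  expect_equal(mut_prob("ACGNACG", pw), 1e-3 / (1 + 1e-3), tolerance = 1e-12)
})

test_that("zero-sum gauge makes mu the geometric mean of the odds", {
  set.seed(61)
  for (m in 1:2) {
    e <- matrix(rnorm((2 * m + 1) * 4, sd = 0.6), 2 * m + 1, 4)
    pw <- pwm_model(m = m, e = e, mu = 0.01)  # gauge imposed here
    expect_equal(rowSums(pw$e), rep(0, 2 * m + 1), tolerance = 1e-12,
                 ignore_attr = TRUE)
    ctxs <- do.call(paste0, rev(expand.grid(
      rep(list(c("A", "C", "G", "T")), 2 * m + 1),
      stringsAsFactors = FALSE)))
    p <- mut_prob(ctxs, pw)
    odds <- p / (1 - p)
    expect_equal(exp(mean(log(odds))), pw$mu, tolerance = 1e-10)
    # predictions invariant under a constant shift absorbed into mu
    pw2 <- pwm_model(m = m, e = e + 0.37, mu = 0.01 * exp(-(2 * m + 1) * 4 *
                                                          0.37 / 4))
    expect_equal(mut_prob(ctxs[1:16], pw2), mut_prob(ctxs[1:16], pw),
                 tolerance = 1e-9)
  }
})

test_that("fit_pwm identifies the null and matches an independent maximizer", {
  set.seed(67)
  ctxs <- do.call(paste0, rev(expand.grid(rep(list(c("A", "C", "G", "T")), 3),
                                          stringsAsFactors = FALSE)))
  # context-independent mutations at rate q
  q <- 0.05
  n <- 4000
  cc <- sample(ctxs, n, replace = TRUE)
  counts <- data.frame(context = cc, mutated = as.numeric(runif(n) < q),
                       weight = 1)
  f <- fit_pwm(counts, m = 1)
  expect_lt(max(abs(f$e)), 0.15)
  expect_equal(f$mu / (1 + f$mu), q, tolerance = 0.3)

  # structured data: compare against optim() on an independently written
  # weighted Bernoulli objective
  truth <- pwm_model(m = 1, e = matrix(c(0.5, -0.5, 0, 0,
                                         -0.3, 0.3, -0.2, 0.2,
                                         0, 0, 0.4, -0.4), 3, 4,
                                       byrow = TRUE), mu = 0.05)
  pm <- mut_prob(cc, truth)
  counts2 <- data.frame(context = cc, mutated = as.numeric(runif(n) < pm),
                        weight = 1)
  f2 <- fit_pwm(counts2, m = 1)
  obj <- function(theta) {
    e <- matrix(theta[-1], 3, 4)
    pw <- list(m = 1, e = e, mu = exp(theta[1]))
    class(pw) <- "pwm_model"
    dimnames(pw$e) <- list(as.character(-1:1), c("A", "C", "G", "T"))
    p <- mut_prob(counts2$context, pw)
    -sum(counts2$weight * ifelse(counts2$mutated > 0, log(p), log(1 - p)))
  }
  o <- stats::optim(c(log(0.05), rep(0, 12)), obj, method = "BFGS",
                    control = list(maxit = 300, reltol = 1e-12))
  # compare fitted probabilities (gauge-invariant) on all contexts
  pw_o <- pwm_model(m = 1, e = matrix(o$par[-1], 3, 4), mu = exp(o$par[1]))
  expect_equal(mut_prob(ctxs, f2), mut_prob(ctxs, pw_o), tolerance = 1e-3)
})

test_that("fit_nmer builds the full 1024-row 5-mer table", {
  counts <- data.frame(context = c(rep("ACGTA", 100), rep("CCGTT", 10)),
                       mutated = c(rep(1, 7), rep(0, 93), rep(1, 1),
                                   rep(0, 9)),
                       weight = 1)
  tb <- fit_nmer(counts, n = 5, coverage_threshold = 50)
  expect_equal(nrow(tb$table), 1024)
  row <- tb$table[tb$table$context == "ACGTA", ]
  expect_equal(row$rate, 0.07, tolerance = 1e-12)
  expect_true(row$estimable)
  row2 <- tb$table[tb$table$context == "CCGTT", ]
  expect_false(row2$estimable)
  expect_equal(sum(tb$table$coverage), 110)
})

test_that("per-read mutation counts match the independent-site model", {
  # Poisson-binomial check on a fixed scenario: mean and variance of the
  # number of mutations across realizations match sum(p) and sum(p(1-p))
  m <- model_igh_like(1e-3)
  pw <- shm_pwm_default(mu = 0.05)
  set.seed(83)
  scen <- sample_scenario(m)
  n <- 250
  counts <- vapply(seq_len(n), function(i)
    realize_read(scen, m, hm_model = pw, read_len = NULL)$truth$n_mut, 0)
  rr <- realize_read(scen, m, hm_model = pw, read_len = NULL)
  anc <- strsplit(rr$truth$anc_window, "")[[1]]
  # recompute per-site probabilities independently
  pieces <- scenario_pieces_test(scen, m)
  pm <- site_probs_test(anc, pieces, pw)
  mu_hat <- mean(counts); v <- sum(pm * (1 - pm))
  expect_equal(mu_hat, sum(pm), tolerance = 4 * sqrt(v / n) + 1e-9)
  expect_equal(stats::var(counts), v, tolerance = 0.5 * v + 0.5)
})

test_that("colocalization is ~1 for independent sites and matches a hand toy", {
  # hand-built counts with perfectly co-occurring mutations at distance 3
  mk <- function(read, pos, mut) data.frame(
    context = "AAAAAAA", mutated = as.numeric(mut), weight = 1, class = "V",
    gene = "V1", gpos = pos, read_id = read)
  toy <- rbind(mk("r1", c(5, 8), c(1, 1)), mk("r2", c(5, 8), c(0, 0)),
               mk("r3", c(5, 8), c(1, 1)), mk("r4", c(5, 8), c(0, 0)))
  g <- colocalization(toy, min_pair_count = 2, r_max = 5)
  # f(5)=f(8)=1/2, f(5,8)=1/2 -> g(3) = (1/2)/(1/4) = 2
  expect_equal(g$g[g$r == 3], 2, tolerance = 1e-9)

  # single-mutation reads: no pairs ever co-mutate
  toy2 <- rbind(mk("r1", c(2, 6), c(1, 0)), mk("r2", c(2, 6), c(0, 1)),
                mk("r3", c(2, 6), c(1, 0)), mk("r4", c(2, 6), c(0, 1)))
  g2 <- colocalization(toy2, min_pair_count = 2, r_max = 6)
  expect_true(all(g2$g[g2$r == 4] == 0))
})

test_that("independent simulated hypermutations give g(r) near 1", {
  m <- model_igh_like(1e-3)
  pw <- shm_pwm_default(mu = 0.06)
  b <- generate_batch(m, 80, seed = 19, read_len = 130, hm_model = pw)
  ab <- annotate_batch(b$reads, m, hm_model = pw, keep_results = TRUE,
                       prune = prune_config(k_top = 20))
  cnt <- shm_context_counts(ab$results[!vapply(ab$results, `[[`, TRUE,
                                               "failed")], m, m = 3,
                            classes = "V")
  g <- colocalization(cnt, min_pair_count = 10, r_max = 12)
  expect_gt(nrow(g), 3)
  expect_lt(abs(mean(g$g) - 1), 0.35)
})

test_that("posterior mutation profile correlates with the generating PWM", {
  m <- model_igh_like(1e-3)
  pw <- shm_pwm_default(mu = 0.08)
  b <- generate_batch(m, 100, seed = 29, read_len = 130, hm_model = pw)
  ab <- annotate_batch(b$reads, m, hm_model = pw, keep_results = TRUE,
                       prune = prune_config(k_top = 20))
  cnt <- shm_context_counts(ab$results[!vapply(ab$results, `[[`, TRUE,
                                               "failed")], m, m = 3,
                            classes = "V")
  gene <- names(sort(table(cnt$gene), decreasing = TRUE))[1]
  prof <- posterior_mutation_profile(cnt, gene, pw)
  expect_gt(nrow(prof), 20)
  expect_gt(attr(prof, "pearson"), 0.4)  # self-consistency, small n
})

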