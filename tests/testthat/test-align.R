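test_that("perfect and near-perfect V matches score as expected", {
  m <- model_igh_like()
  v1 <- m$germline$V[[1]]
  read <- substr(v1$seq, 1, 40)
  al <- align_all(read, m)
  expect_equal(al$V$segment[1], v1$name)
  expect_equal(al$V$score[1], 200)  # 40 matches x 5
  # one mismatch: 39 x 5 - 14 = 181, position recorded
  rv <- strsplit(read, "")[[1]]
  rv[20] <- setdiff(c("A", "C", "G", "T"), rv[20])[1]
  al2 <- align_all(paste(rv, collapse = ""), m)
  expect_equal(al2$V$score[1], 181)
  expect_true("19" %in% strsplit(al2$V$mismatches[1], ";")[[1]])
})

test_that("Smith-Waterman scores match an independent DP oracle", {
  set.seed(71)
  gl <- list(germline_segment("G1", "V", paste(sample(c("A","C","G","T"), 20,
                                                      TRUE), collapse = "")),
             germline_segment("G2", "V", paste(sample(c("A","C","G","T"), 20,
                                                      TRUE), collapse = "")),
             germline_segment("G3", "V", paste(sample(c("A","C","G","T"), 20,
                                                      TRUE), collapse = "")))
  for (i in 1:200) {
    read <- paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = "")
    g <- gl[[sample(3, 1)]]
    got <- repgenr:::cpp_sw_score(repgenr:::nt_int(read),
                                  repgenr:::nt_int(g$extended_seq), 5, -14, -50)
    expect_equal(got, r_sw_score(read, g$extended_seq), tolerance = 1e-12)
  }
})

test_that("alignment is deterministic and threshold-monotone", {
  m <- model_trb_like()
  set.seed(5)
  b <- generate_batch(m, 5, seed = 5, read_len = 60)
  for (rd in b$reads) {
    a1 <- align_all(rd, m)
    a2 <- align_all(rd, m)
    expect_identical(a1, a2)
    lo <- align_all(rd, m, params = prune_config(thr_v = 20, thr_j = 15))
    hi <- align_all(rd, m, params = prune_config(thr_v = 60, thr_j = 40))
    for (cls in c("V", "J")) {
      lo_set <- paste(lo[[cls]]$segment, lo[[cls]]$offset)
      hi_set <- paste(hi[[cls]]$segment, hi[[cls]]$offset)
      expect_true(all(hi_set %in% lo_set))
    }
  }
})

test_that("true segments are candidates for clean reads", {
  m <- model_trb_like(err_rate = 1e-9)
  b <- generate_batch(m, 10, seed = 9, read_len = 60)
  for (i in seq_len(10)) {
    if (b$truth$junction_lost[i] || b$truth$x[i] < 10) next
    al <- align_all(b$reads[[i]], m)
    expect_true(b$truth$v[i] %in% al$V$segment)
    expect_true(b$truth$j[i] %in% al$J$segment)
  }
})

test_that("feasible deletions agree with substring reconstruction", {
  m <- micro_vj_model()
  set.seed(31)
  for (rep in 1:100) {
    vi <- sample(2, 1)
    V <- m$germline$V[[vi]]
    Lc <- nchar(V$seq)
    off <- sample(0:3, 1)
    al <- data.frame(seg_class = "V", segment = V$name, offset = off)
    al$read <- paste(rep("A", 12), collapse = "")
    got <- feasible_deletions(al, m)
    # brute force: deletion d is feasible iff the boundary lands inside the
    # read (x >= 1) and at least one core base is retained
    rng <- m$del_range$V[1]:m$del_range$V[2]
    want <- rng[(Lc - rng - off) >= 1 & rng <= Lc - 1]
    expect_equal(got, want)
  }
})

test_that("alignment dump CSV has the documented columns", {
  m <- model_trb_like()
  b <- generate_batch(m, 2, seed = 2, read_len = 60)
  al <- lapply(b$reads, align_all, germline = m)
  f <- withr::local_tempfile(fileext = ".csv")
  write_alignment_csv(al, f)
  df <- utils::read.csv(f)
  expect_true(all(c("read_id", "seg_class", "segment", "score", "read_start",
                    "read_end", "seg_start", "seg_end", "mismatches")
                  %in% names(df)))
  expect_true(all(df$read_id %in% names(b$reads)))
})
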