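#' Read sequences from FASTA or FASTQ
#'
#' Accepts plain or gzipped files; the format is sniffed from the first
#' non-empty character (\code{>} FASTA, \code{@} FASTQ).  Sequences are
#' uppercased and \code{U} is converted to \code{T}.  Duplicate ids are made
#' unique by appending \code{.1}, \code{.2}, ... with a warning.
#'
#' @param path input file.
#' @return list with character vectors \code{id}, \code{desc}, \code{seq}.
#' @export
read_sequences <- function(path) {
  if (!file.exists(path)) stopf("input file '%s' does not exist", path)
  con <- gzfile(path, "rt")
  first <- readLines(con, n = 1L, warn = FALSE)
  close(con)
  if (!length(first) || !nzchar(first)) stopf("'%s' is empty", path)
  first <- substr(first, 1L, 1L)
  fmt <- if (first == ">") "fasta" else if (first == "@") "fastq"
         else stopf("'%s' is neither FASTA nor FASTQ (starts with '%s')",
                    path, first)
  if (fmt == "fastq") {
    ln <- readLines(path, warn = FALSE)
    ln <- ln[nzchar(ln)]
    if (length(ln) %% 4L != 0L) {
      last <- ln[max(which(startsWith(ln, "@")))]
      stopf("truncated FASTQ record near '%s' (line %d)", last, length(ln))
    }
  }
  set <- Biostrings::readBStringSet(path, format = fmt)
  seqs <- chartr("u", "t", tolower(as.character(set)))
  seqs <- toupper(seqs)
  full <- names(set)
  id <- sub("[ \t].*$", "", full)
  desc <- ifelse(grepl("[ \t]", full), sub("^[^ \t]+[ \t]+", "", full), "")
  if (anyDuplicated(id)) {
    warning("duplicated sequence ids made unique")
    id <- make.unique(id, sep = ".")
  }
  list(id = id, desc = desc, seq = unname(seqs))
}

write_fasta <- function(ids, seqs, path) {
  writeLines(paste0(">", ids, "\n", seqs), path)
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# model file: human-readable text with @structure / @germline / @cpt /
# @error (/ @shm) sections.  Numbers are printed with %.17g so that
# write -> read -> write is bit-identical.

fmtg <- function(x) sprintf("%.17g", x)

#' Write a recombination model to a text file
#'
#' @param model a \code{recomb_model}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_model <- function(model, path) {
  ln <- c("@structure",
          paste("chain", model$chain),
          paste("max_p", model$max_p),
          paste("del_v", model$del_range$V[1], model$del_range$V[2]),
          paste("del_j", model$del_range$J[1], model$del_range$J[2]),
          paste("del_dl", model$del_range$Dl[1], model$del_range$Dl[2]),
          paste("del_dr", model$del_range$Dr[1], model$del_range$Dr[2]),
          paste("ins_max", model$ins_max),
          paste("dj_chain", model$dj_chain_dir),
          paste("ins_first", model$ins_first),
          paste("gene_kind", model$gene$kind))
  ln <- c(ln, "@germline")
  for (cls in c("V", "D", "J"))
    for (s in model$germline[[cls]])
      ln <- c(ln, paste(cls, s$name,
                        if (nzchar(s$family)) s$family else ".",
                        if (is.na(s$cdr3_anchor)) "." else s$cdr3_anchor,
                        s$seq))
  ln <- c(ln, "@cpt")
  tbl <- function(label, m) {
    c(paste("table", label, nrow(m), ncol(m)),
      vapply(seq_len(nrow(m)), function(i)
        paste(c(rownames(m)[i] %||% i, fmtg(m[i, ])), collapse = " "), ""))
  }
  vec <- function(label, v)
    c(paste("vector", label, length(v)), paste(fmtg(v), collapse = " "))
  if (model$chain == "VJ") {
    ln <- c(ln, tbl("p_vj", model$gene$p_vj),
            tbl("del_v", model$del_v), tbl("del_j", model$del_j),
            vec("ins_vj", model$ins_vj), tbl("mk_vj", model$mk_vj))
  } else {
    ln <- c(ln, vec("p_v", model$gene$p_v), tbl("p_dj", model$gene$p_dj),
            tbl("mask_dj", model$gene$mask_dj * 1),
            tbl("del_v", model$del_v), tbl("del_j", model$del_j))
    nD <- dim(model$del_d)[1]
    for (g in seq_len(nD))
      ln <- c(ln, tbl(paste0("del_d:", dimnames(model$del_d)[[1]][g]),
                      model$del_d[g, , , drop = TRUE]))
    ln <- c(ln, vec("ins_vd", model$ins_vd), vec("ins_dj", model$ins_dj),
            tbl("mk_vd", model$mk_vd), tbl("mk_dj", model$mk_dj))
  }
  if (model$err$kind == "uniform") {
    ln <- c(ln, "@error", paste("uniform", fmtg(model$err$rate)))
  } else {
    pw <- model$err$pwm
    ln <- c(ln, "@shm", paste("m", pw$m), paste("mu", fmtg(pw$mu)))
    for (i in seq_len(nrow(pw$e)))
      ln <- c(ln, paste(c(rownames(pw$e)[i], fmtg(pw$e[i, ])), collapse = " "))
  }
  writeLines(ln, path)
  invisible(path)
}

#' Read a recombination model from a text file
#'
#' Inverse of \code{\link{write_model}}; the parsed model is validated
#' (CPT rows must sum to one within 1e-6) and round-trips bit-exactly.
#'
#' @param path model file.
#' @return a \code{recomb_model}.
#' @export
read_model <- function(path) {
  ln <- readLines(path)
  ln <- ln[nzchar(trimws(ln))]
  sec <- cumsum(startsWith(ln, "@"))
  secname <- startsWith(ln, "@")
  kv <- function(lines) {
    sp <- strsplit(lines, " +")
    setNames(lapply(sp, `[`, -1L), vapply(sp, `[[`, "", 1L))
  }
  get_sec <- function(nm) ln[sec == match(paste0("@", nm), ln[secname]) & !secname]

  st <- kv(get_sec("structure"))
  chain <- st$chain[1]
  max_p <- as.integer(st$max_p[1])

  glin <- get_sec("germline")
  segs <- lapply(strsplit(glin, " +"), function(f) {
    germline_segment(f[2], f[1], f[5], max_p = max_p,
                     family = if (f[3] == ".") "" else f[3],
                     cdr3_anchor = if (f[4] == ".") NA_integer_
                                   else as.integer(f[4]))
  })
  cfg <- list(chain = chain, max_p = max_p,
              del_range = list(V = as.integer(st$del_v),
                               J = as.integer(st$del_j),
                               Dl = as.integer(st$del_dl),
                               Dr = as.integer(st$del_dr)),
              ins_max = as.integer(st$ins_max[1]))
  model <- build_model(cfg, segs)

  cl <- get_sec("cpt")
  i <- 1L
  tabs <- list()
  while (i <= length(cl)) {
    hdr <- strsplit(cl[i], " +")[[1]]
    if (hdr[1] == "table") {
      nr <- as.integer(hdr[3]); nc <- as.integer(hdr[4])
      rows <- strsplit(cl[i + seq_len(nr)], " +")
      m <- do.call(rbind, lapply(rows, function(r) as.numeric(r[-1L])))
      rownames(m) <- vapply(rows, `[[`, "", 1L)
      if (ncol(m) != nc) stopf("malformed table %s in %s", hdr[2], path)
      tabs[[hdr[2]]] <- m
      i <- i + nr + 1L
    } else if (hdr[1] == "vector") {
      n <- as.integer(hdr[3])
      v <- as.numeric(strsplit(cl[i + 1L], " +")[[1]])
      if (length(v) != n) stopf("malformed vector %s in %s", hdr[2], path)
      tabs[[hdr[2]]] <- v
      i <- i + 2L
    } else stopf("unexpected line in @cpt: %s", cl[i])
  }
  put_tbl <- function(tpl, m) {
    if (!all(dim(tpl) == dim(m))) stopf("CPT dimension mismatch in %s", path)
    dimnames(m) <- dimnames(tpl)
    m
  }
  if (chain == "VJ") {
    model$gene$p_vj <- put_tbl(model$gene$p_vj, tabs$p_vj)
    model$ins_vj <- setNames(tabs$ins_vj, names(model$ins_vj))
    model$mk_vj <- put_tbl(model$mk_vj, tabs$mk_vj)
  } else {
    model$gene$p_v <- setNames(as.numeric(tabs$p_v), names(model$gene$p_v))
    model$gene$p_dj <- put_tbl(model$gene$p_dj, tabs$p_dj)
    model$gene$mask_dj <- put_tbl(model$gene$mask_dj, tabs$mask_dj) > 0
    for (g in seq_len(dim(model$del_d)[1])) {
      nm <- paste0("del_d:", dimnames(model$del_d)[[1]][g])
      model$del_d[g, , ] <- put_tbl(model$del_d[g, , , drop = TRUE], tabs[[nm]])
    }
    model$ins_vd <- setNames(tabs$ins_vd, names(model$ins_vd))
    model$ins_dj <- setNames(tabs$ins_dj, names(model$ins_dj))
    model$mk_vd <- put_tbl(model$mk_vd, tabs$mk_vd)
    model$mk_dj <- put_tbl(model$mk_dj, tabs$mk_dj)
  }
  model$del_v <- put_tbl(model$del_v, tabs$del_v)
  model$del_j <- put_tbl(model$del_j, tabs$del_j)

  if (any(ln == "@error")) {
    er <- strsplit(get_sec("error")[1], " +")[[1]]
    model$err <- list(kind = "uniform", rate = as.numeric(er[2]))
  } else if (any(ln == "@shm")) {
    sl <- get_sec("shm")
    skv <- kv(sl[1:2])
    m <- as.integer(skv$m[1])
    rows <- strsplit(sl[-(1:2)], " +")
    e <- do.call(rbind, lapply(rows, function(r) as.numeric(r[-1L])))
    rownames(e) <- vapply(rows, `[[`, "", 1L)
    colnames(e) <- NT
    model$err <- list(kind = "pwm",
                      pwm = pwm_model(m = m, e = e, mu = as.numeric(skv$mu[1]),
                                      renormalize = FALSE))
  } else stopf("model file lacks @error/@shm section")
  tryCatch(validate_model(model, tol = 1e-6),
           error = function(e) stopf("invalid model file %s: %s", path,
                                     conditionMessage(e)))
  model
}
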