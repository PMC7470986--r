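#' Save a model library to a text file
#'
#' The package's own versioned plain-text model format: one block per
#' model, one line per position, all probabilities printed with 17
#' significant digits so that save/load round-trips are bit-exact.
#'
#' @param models A [profile_hmm] or list of them.
#' @param path Output path.
#' @export
save_library <- function(models, path) {
  if (inherits(models, "profile_hmm")) models <- list(models)
  fmt <- function(x) paste(sprintf("%.17g", x), collapse = " ")
  con <- file(path, "w")
  on.exit(close(con))
  for (hmm in models) {
    writeLines(c(
      "RRESCAN-HMM 1",
      paste("NAME", hmm$name),
      paste("CLASS", if (is.na(hmm$class_tag)) "-" else hmm$class_tag),
      paste("M", hmm$M),
      paste("BACKGROUND", fmt(hmm$background)),
      paste("GUMBEL", if (is.na(hmm$gumbel_mu)) "-" else
        fmt(c(hmm$gumbel_mu, hmm$gumbel_lambda))),
      paste("TRUSTED", if (is.na(hmm$trusted_cutoff)) "-" else
        fmt(hmm$trusted_cutoff))
    ), con)
    for (j in seq_len(hmm$M)) {
      writeLines(paste("MATCH", j, fmt(hmm$match_emissions[j, ])), con)
    }
    for (j in seq_len(hmm$M + 1)) {
      writeLines(paste("INSERT", j - 1, fmt(hmm$insert_emissions[j, ])), con)
    }
    for (j in seq_len(hmm$M)) {
      writeLines(paste("TRANS", j, fmt(hmm$transitions[j, ])), con)
    }
    writeLines("END", con)
  }
  invisible(path)
}

#' Load a model library
#'
#' Reads the package's own text format and, for interoperability with
#' published model files, HMMER3 ASCII (`HMMER3/f` files as written by
#' `hmmbuild`, with emissions stored as negative natural logs and `*` for
#' probability zero).  Imported HMMER models are renormalised so that all
#' [profile_hmm] invariants hold.
#'
#' @param path Path to a model file (either format; multiple models per
#'   file are supported).
#' @return A list of [profile_hmm] objects.
#' @export
load_library <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  first <- lines[nzchar(trimws(lines))][1]
  if (grepl("^RRESCAN-HMM", first)) {
    load_rrescan_format(lines)
  } else if (grepl("^HMMER3", first)) {
    load_hmmer3_ascii(lines)
  } else {
    stop("unrecognised model file header at line 1: '", first, "'",
         call. = FALSE)
  }
}

load_rrescan_format <- function(lines) {
  models <- list()
  i <- 1
  n <- length(lines)
  get_field <- function(line, key, lineno) {
    if (!startsWith(line, key)) {
      stop("model format error at line ", lineno, ": expected ", key,
           call. = FALSE)
    }
    trimws(sub(key, "", line, fixed = TRUE))
  }
  nums <- function(x) as.numeric(strsplit(trimws(x), "\\s+")[[1]])
  while (i <= n) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1; next }
    get_field(lines[i], "RRESCAN-HMM", i)
    name <- get_field(lines[i + 1], "NAME", i + 1)
    cls <- get_field(lines[i + 2], "CLASS", i + 2)
    M <- as.integer(get_field(lines[i + 3], "M", i + 3))
    bg <- nums(get_field(lines[i + 4], "BACKGROUND", i + 4))
    gum <- get_field(lines[i + 5], "GUMBEL", i + 5)
    tru <- get_field(lines[i + 6], "TRUSTED", i + 6)
    i <- i + 7
    need <- 2 * M + (M + 1) + 1
    if (i + need - 1 > n) stop("truncated model file: missing position blocks",
                               call. = FALSE)
    emis <- matrix(NA_real_, M, 20)
    for (j in seq_len(M)) {
      emis[j, ] <- nums(sub("^MATCH\\s+\\d+", "", lines[i])); i <- i + 1
    }
    ins <- matrix(NA_real_, M + 1, 20)
    for (j in seq_len(M + 1)) {
      ins[j, ] <- nums(sub("^INSERT\\s+\\d+", "", lines[i])); i <- i + 1
    }
    trans <- matrix(NA_real_, M, 7)
    for (j in seq_len(M)) {
      trans[j, ] <- nums(sub("^TRANS\\s+\\d+", "", lines[i])); i <- i + 1
    }
    if (i > n || trimws(lines[i]) != "END") {
      stop("truncated model file: missing END for model '", name, "'",
           call. = FALSE)
    }
    i <- i + 1
    gv <- if (gum == "-") c(NA_real_, NA_real_) else nums(gum)
    models[[length(models) + 1]] <- profile_hmm(
      name = name, match_emissions = emis, transitions = trans,
      insert_emissions = ins, background = bg,
      class_tag = if (cls == "-") NA_character_ else cls,
      gumbel_mu = gv[1], gumbel_lambda = gv[2],
      trusted_cutoff = if (tru == "-") NA_real_ else as.numeric(tru)
    )
  }
  models
}

# negative-natural-log value, '*' meaning probability zero
nlog_to_prob <- function(x) {
  p <- ifelse(x == "*", 0, exp(-suppressWarnings(as.numeric(x))))
  p[is.na(p)] <- 0
  p
}

renorm <- function(x) {
  s <- sum(x)
  if (s <= 0) rep(1 / length(x), length(x)) else x / s
}

load_hmmer3_ascii <- function(lines) {
  models <- list()
  breaks <- grep("^//", lines)
  if (length(breaks) == 0) breaks <- length(lines)
  starts <- c(1, utils::head(breaks, -1) + 1)
  toks <- function(x) strsplit(trimws(x), "\\s+")[[1]]
  for (b in seq_along(breaks)) {
    rec <- lines[starts[b]:breaks[b]]
    if (!any(grepl("^HMMER3", rec))) next
    name_line <- rec[grepl("^NAME\\s", rec)]
    name <- if (length(name_line)) toks(name_line[1])[2] else "imported"
    leng_line <- rec[grepl("^LENG\\s", rec)]
    if (length(leng_line) == 0) stop("HMMER3 file missing LENG line", call. = FALSE)
    M <- as.integer(toks(leng_line[1])[2])
    tc_line <- rec[grepl("^TC\\s", rec)]
    trusted <- if (length(tc_line)) as.numeric(toks(tc_line[1])[2]) else NA_real_

    hmm_at <- grep("^HMM\\s", rec)
    if (length(hmm_at) == 0) stop("HMMER3 file missing HMM section", call. = FALSE)
    body <- rec[(hmm_at[1] + 2):length(rec)]  # skip transition-name header
    body <- body[nzchar(trimws(body)) & !grepl("^//", body)]

    bg <- uniform_background()
    k <- 1
    if (grepl("^\\s*COMPO", body[1])) {
      bg <- stats::setNames(renorm(nlog_to_prob(toks(body[1])[2:21])), AA20)
      k <- 4  # skip COMPO, insert-0 emissions and begin-transition lines
    } else {
      k <- 3  # node-0 insert emissions + begin transitions
    }
    emis <- matrix(NA_real_, M, 20)
    ins <- matrix(1 / 20, M + 1, 20)
    trans <- matrix(NA_real_, M, 7)
    for (j in seq_len(M)) {
      mt <- toks(body[k])
      if (length(mt) < 21 || suppressWarnings(as.integer(mt[1])) != j) {
        stop("HMMER3 parse error: expected match line for position ", j,
             call. = FALSE)
      }
      emis[j, ] <- renorm(nlog_to_prob(mt[2:21]))
      it <- toks(body[k + 1])
      ins[j + 1, ] <- renorm(nlog_to_prob(it[1:20]))
      tt <- nlog_to_prob(toks(body[k + 2])[1:7])
      trans[j, ] <- c(renorm(tt[1:3]), renorm(tt[4:5]), renorm(tt[6:7]))
      k <- k + 3
    }
    models[[length(models) + 1]] <- profile_hmm(
      name = name, match_emissions = emis, transitions = trans,
      insert_emissions = ins, background = renorm(bg),
      trusted_cutoff = trusted
    )
  }
  if (length(models) == 0) stop("no HMMER3 models found", call. = FALSE)
  models
}
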