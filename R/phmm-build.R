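#' Construct a profile hidden Markov model
#'
#' The scoring object at the core of the package: per-position match and
#' insert emission distributions over the 20 canonical amino acids, seven
#' transition probabilities per position (M->M, M->I, M->D, I->M, I->I,
#' D->M, D->D), a background distribution, optional Gumbel calibration
#' parameters for E-values, an optional per-model trusted bit-score
#' cutoff, and an optional RiPP-class tag.
#'
#' @param name Model name.
#' @param match_emissions M x 20 matrix of match emission probabilities
#'   (rows sum to 1).
#' @param transitions M x 7 matrix; row j holds the probabilities of
#'   leaving position j, columns `MM, MI, MD, IM, II, DM, DD`.  The
#'   `MM/MI/MD`, `IM/II` and `DM/DD` groups each sum to 1.
#' @param insert_emissions Optional (M+1) x 20 matrix; defaults to the
#'   background at every position (inserts then score 0 bits).
#' @param background Length-20 probability vector; default uniform.
#' @param class_tag Optional RiPP-class label (e.g. `"lasso_discrete"`).
#' @param gumbel_mu,gumbel_lambda Optional E-value calibration.
#' @param trusted_cutoff Optional trusted bit-score cutoff.
#' @return Object of class `profile_hmm`.
#' @export
profile_hmm <- function(name, match_emissions, transitions,
                        insert_emissions = NULL, background = NULL,
                        class_tag = NA_character_,
                        gumbel_mu = NA_real_, gumbel_lambda = NA_real_,
                        trusted_cutoff = NA_real_) {
  match_emissions <- as.matrix(match_emissions)
  transitions <- as.matrix(transitions)
  M <- nrow(match_emissions)
  background <- validate_background(background)
  if (is.null(insert_emissions)) {
    insert_emissions <- matrix(background, nrow = M + 1, ncol = 20, byrow = TRUE)
  }
  colnames(match_emissions) <- AA20
  colnames(insert_emissions) <- AA20
  colnames(transitions) <- c("MM", "MI", "MD", "IM", "II", "DM", "DD")
  hmm <- structure(
    list(name = name, class_tag = class_tag, M = M,
         match_emissions = match_emissions,
         insert_emissions = insert_emissions,
         transitions = transitions,
         background = background,
         gumbel_mu = gumbel_mu, gumbel_lambda = gumbel_lambda,
         trusted_cutoff = trusted_cutoff),
    class = "profile_hmm"
  )
  validate_phmm(hmm)
}

validate_phmm <- function(hmm, tol = 1e-9) {
  stopifnot(hmm$M >= 1,
            nrow(hmm$match_emissions) == hmm$M,
            ncol(hmm$match_emissions) == 20,
            nrow(hmm$transitions) == hmm$M,
            ncol(hmm$transitions) == 7,
            nrow(hmm$insert_emissions) == hmm$M + 1)
  if (any(abs(rowSums(hmm$match_emissions) - 1) > tol)) {
    stop("match emission rows must sum to 1", call. = FALSE)
  }
  if (any(abs(rowSums(hmm$insert_emissions) - 1) > tol)) {
    stop("insert emission rows must sum to 1", call. = FALSE)
  }
  tr <- hmm$transitions
  if (any(abs(rowSums(tr[, 1:3, drop = FALSE]) - 1) > tol) ||
      any(abs(rowSums(tr[, 4:5, drop = FALSE]) - 1) > tol) ||
      any(abs(rowSums(tr[, 6:7, drop = FALSE]) - 1) > tol)) {
    stop("transition groups (MM/MI/MD, IM/II, DM/DD) must each sum to 1",
         call. = FALSE)
  }
  if (abs(sum(hmm$background) - 1) > 1e-6) stop("background must sum to 1")
  hmm
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat("<profile_hmm> ", x$name, ": ", x$M, " match states",
      if (!is.na(x$class_tag)) paste0(" [", x$class_tag, "]"), "\n", sep = "")
  if (!is.na(x$gumbel_mu)) {
    cat("  calibrated: mu=", signif(x$gumbel_mu, 4),
        " lambda=", signif(x$gumbel_lambda, 4), "\n", sep = "")
  }
  invisible(x)
}

#' Position-based (Henikoff) sequence weights
#'
#' For each alignment column with r distinct residues, a sequence carrying
#' a residue shared by s rows receives 1/(r*s); gap rows receive nothing.
#' Per-sequence sums are normalised to average 1.
#'
#' @param aln An [rre_alignment].
#' @return Numeric weights, one per row, mean 1.
#' @export
henikoff_weights <- function(aln) {
  m <- alignment_matrix(aln)
  n <- nrow(m)
  w <- numeric(n)
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    res <- col[col != "-"]
    if (length(res) == 0) next
    counts <- table(res)
    r <- length(counts)
    contrib <- 1 / (r * as.numeric(counts[col]))
    contrib[col == "-"] <- 0
    contrib[is.na(contrib)] <- 0
    w <- w + contrib
  }
  if (sum(w) == 0) return(rep(1, n))
  w * n / sum(w)
}

#' Build a profile HMM from a multiple sequence alignment
#'
#' Columns whose weighted gap fraction is below 0.5 become match states.
#' Emissions are weighted residue counts smoothed with
#' background-proportional pseudocounts of strength `alpha`:
#' `e(a) = (c_a + alpha * f_a) / (n + alpha)`.  Transitions are estimated
#' from the state paths implied by the match-column assignment, smoothed
#' the same way with a uniform prior over each state's options.  Sequence
#' weights are position-based (Henikoff) by default.
#'
#' @param aln An [rre_alignment] with at least 2 rows (or a single-row
#'   alignment when `allow_single = TRUE`, used to seed iterative
#'   enrichment from one sequence).
#' @param name Model name.
#' @param alpha Pseudocount strength (default 1).
#' @param background Background distribution (default uniform).
#' @param weighting `"henikoff"` or `"none"`.
#' @param gap_threshold Weighted gap fraction above which a column becomes
#'   an insert column.
#' @param class_tag Optional class label carried on the model.
#' @param allow_single Permit a 1-row alignment.
#' @return A [profile_hmm].
#' @export
build_phmm <- function(aln, name = "model", alpha = 1, background = NULL,
                       weighting = c("henikoff", "none"), gap_threshold = 0.5,
                       class_tag = NA_character_, allow_single = FALSE) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(aln, "rre_alignment"))
  n <- nrow(aln$rows)
  if (n < 2 && !allow_single) stop("model building needs >= 2 aligned rows")
  background <- validate_background(background)
  m <- alignment_matrix(aln)
  w <- if (weighting == "henikoff" && n > 1) henikoff_weights(aln) else rep(1, n)

  gap_frac <- vapply(seq_len(ncol(m)), function(j) {
    sum(w[m[, j] == "-"]) / sum(w)
  }, numeric(1))
  match_cols <- which(gap_frac < gap_threshold)
  M <- length(match_cols)
  if (M == 0) stop("degenerate alignment: no column qualifies as a match column")

  # --- emissions ---
  emis <- matrix(0, nrow = M, ncol = 20, dimnames = list(NULL, AA20))
  for (k in seq_len(M)) {
    col <- m[, match_cols[k]]
    for (i in seq_len(n)) {
      a <- col[i]
      if (a != "-" && a != "X") emis[k, a] <- emis[k, a] + w[i]
    }
    tot <- sum(emis[k, ])
    emis[k, ] <- (emis[k, ] + alpha * background) / (tot + alpha)
  }

  # --- transitions from implied state paths ---
  # state at match position k for row i: M (residue) or D (gap); numbers of
  # insert-column residues between match cols k and k+1 give I visits.
  col_is_match <- logical(ncol(m))
  col_is_match[match_cols] <- TRUE
  cnt <- array(0, dim = c(M, 7),
               dimnames = list(NULL, c("MM", "MI", "MD", "IM", "II", "DM", "DD")))
  for (i in seq_len(n)) {
    row <- m[i, ]
    st <- ifelse(row[match_cols] == "-", "D", "M")
    ins <- integer(M)
    for (k in seq_len(M)) {
      from <- match_cols[k] + 1
      to <- if (k < M) match_cols[k + 1] - 1 else ncol(m)
      if (k < M && to >= from) {
        ins[k] <- sum(row[from:to] != "-" & !col_is_match[from:to])
      }
    }
    for (k in seq_len(M - 1)) {
      a <- st[k]; b <- st[k + 1]; ni <- ins[k]
      if (ni > 0) {
        # a -> I, (ni-1) self loops, I -> b
        if (a == "M") cnt[k, "MI"] <- cnt[k, "MI"] + w[i]
        # delete->insert transitions are not modelled; fold them into D->M
        if (a == "D") cnt[k, "DM"] <- cnt[k, "DM"] + w[i]
        cnt[k, "II"] <- cnt[k, "II"] + w[i] * (ni - 1)
        cnt[k, "IM"] <- cnt[k, "IM"] + w[i]
      } else {
        key <- paste0(a, b)
        if (key %in% colnames(cnt)) cnt[k, key] <- cnt[k, key] + w[i]
      }
    }
  }
  trans <- matrix(0, nrow = M, ncol = 7,
                  dimnames = list(NULL, colnames(cnt)))
  for (k in seq_len(M)) {
    grp <- list(c("MM", "MI", "MD"), c("IM", "II"), c("DM", "DD"))
    for (g in grp) {
      tot <- sum(cnt[k, g])
      prior <- 1 / length(g)
      trans[k, g] <- if (tot + alpha == 0) {
        prior
      } else {
        (cnt[k, g] + alpha * prior) / (tot + alpha)
      }
    }
  }

  profile_hmm(name = name, match_emissions = emis, transitions = trans,
              background = background, class_tag = class_tag)
}

#' Consensus sequence of a model
#'
#' The residue of maximal match-emission probability at each position.
#'
#' @param hmm A [profile_hmm].
#' @return A single string of length `hmm$M`.
#' @export
phmm_consensus <- function(hmm) {
  paste(AA20[apply(hmm$match_emissions, 1, which.max)], collapse = "")
}
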