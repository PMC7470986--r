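# Independent brute-force oracles.  These enumerate explicitly and stay
# independent of the dynamic-programming code paths they check.

# Explicit enumeration of every legal local state path through a profile
# HMM for a given sequence, scored in bits.  Entry B->Mj costs log2(1/M);
# exit after any match is free; insert emissions score 0 bits
# (background).  Accumulates the path maximum (Viterbi) and the
# probability-domain path sum (forward) without any dynamic programming.
enum_both <- function(hmm, sequence) {
  idx <- match(strsplit(sequence, "")[[1]], rrescan:::AA20)
  L <- length(idx)
  M <- hmm$M
  lod <- log2(sweep(hmm$match_emissions, 2, hmm$background, "/"))
  ltr <- suppressWarnings(log2(hmm$transitions))
  entry <- log2(1 / M)
  vit <- -Inf
  psum <- 0

  # state: "M" (just emitted match j using residue i), "I" (insert at j,
  # last residue consumed i), "D" (delete at j, last residue consumed i)
  walk <- function(state, i, j, acc) {
    if (!is.finite(acc)) return()
    if (state == "M") {
      if (acc > vit) vit <<- acc          # exit here
      psum <<- psum + 2^acc
      if (j < M) {
        if (i < L) {
          walk("M", i + 1, j + 1, acc + ltr[j, "MM"] + lod[j + 1, idx[i + 1]])
          walk("I", i + 1, j, acc + ltr[j, "MI"])
        }
        walk("D", i, j + 1, acc + ltr[j, "MD"])
      }
    } else if (state == "I") {
      if (i < L) {
        walk("I", i + 1, j, acc + ltr[j, "II"])
        if (j < M) {
          walk("M", i + 1, j + 1, acc + ltr[j, "IM"] + lod[j + 1, idx[i + 1]])
        }
      }
    } else if (state == "D") {
      if (j < M) {
        if (i < L) {
          walk("M", i + 1, j + 1, acc + ltr[j, "DM"] + lod[j + 1, idx[i + 1]])
        }
        walk("D", i, j + 1, acc + ltr[j, "DD"])
      }
    }
  }
  for (i0 in seq_len(L)) {
    for (j0 in seq_len(M)) {
      walk("M", i0, j0, entry + lod[j0, idx[i0]])
    }
  }
  list(viterbi = unname(vit),
       forward = if (psum == 0) -Inf else unname(log2(psum)))
}

enum_viterbi <- function(hmm, sequence) enum_both(hmm, sequence)$viterbi

enum_forward <- function(hmm, sequence) enum_both(hmm, sequence)$forward

# Random profile HMM with emissions supported on a 3-letter reduced
# alphabet (A/C/D) and uniform 1/20 background.
random_3letter_hmm <- function(M, seed) {
  withr::with_seed(seed, {
    emis <- matrix(0, M, 20)
    for (j in seq_len(M)) {
      g <- stats::rgamma(3, shape = 1)
      emis[j, 1:3] <- g / sum(g)
    }
    trans <- t(vapply(seq_len(M), function(j) {
      m3 <- stats::rgamma(3, 1); m3 <- m3 / sum(m3)
      i2 <- stats::rgamma(2, 1); i2 <- i2 / sum(i2)
      d2 <- stats::rgamma(2, 1); d2 <- d2 / sum(d2)
      c(m3, i2, d2)
    }, numeric(7)))
    profile_hmm(sprintf("rand_M%d_s%d", M, seed), emis, trans)
  })
}

# Point-mass model: emits exactly `consensus`, deterministic M->M path.
point_mass_hmm <- function(consensus, name = "pointmass") {
  chars <- strsplit(consensus, "")[[1]]
  M <- length(chars)
  emis <- matrix(0, M, 20)
  emis[cbind(seq_len(M), match(chars, rrescan:::AA20))] <- 1
  trans <- matrix(rep(c(1, 0, 0, 1, 0, 1, 0), each = M), nrow = M)
  profile_hmm(name, emis, trans)
}

# Exhaustive global affine-gap alignment score (BLOSUM62; a gap of length
# k costs gap_open + k * gap_extend), by recursion over alignment states.
enum_global_score <- function(a, b, gap_open = 11, gap_extend = 1) {
  sm <- rrescan:::blosum62()
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  na <- length(ca); nb <- length(cb)
  best <- -Inf
  rec <- function(i, j, acc, state) {
    if (i > na && j > nb) {
      best <<- max(best, acc)
      return()
    }
    if (i <= na && j <= nb) {
      rec(i + 1, j + 1, acc + sm[ca[i], cb[j]], "M")
    }
    if (i <= na) {
      cost <- if (state == "A") gap_extend else gap_open + gap_extend
      rec(i + 1, j, acc - cost, "A")
    }
    if (j <= nb) {
      cost <- if (state == "B") gap_extend else gap_open + gap_extend
      rec(i, j + 1, acc - cost, "B")
    }
  }
  rec(1, 1, 0, "M")
  best
}

# Exhaustive local profile-profile alignment over column score matrix S
# with affine gaps (open/extend in bits): enumerate all start cells and
# paths, track best score.
enum_pp_score <- function(S, gap_open = 3, gap_extend = 0.3) {
  n <- nrow(S); m <- ncol(S)
  best <- 0
  rec <- function(i, j, acc, state) {
    best <<- max(best, acc)
    if (i < n && j < m) rec(i + 1, j + 1, acc + S[i + 1, j + 1], "M")
    if (i < n) {
      cost <- if (state == "A") gap_extend else gap_open + gap_extend
      rec(i + 1, j, acc - cost, "A")
    }
    if (j < m) {
      cost <- if (state == "B") gap_extend else gap_open + gap_extend
      rec(i, j + 1, acc - cost, "B")
    }
  }
  for (i0 in seq_len(n)) for (j0 in seq_len(m)) rec(i0, j0, S[i0, j0], "M")
  best
}

# Mutate a fraction of positions of a sequence to different residues.
mutate_seq <- function(s, n_mut, seed) {
  withr::with_seed(seed, {
    chars <- strsplit(s, "")[[1]]
    pos <- sample(seq_along(chars), n_mut)
    for (p in pos) {
      chars[p] <- sample(setdiff(rrescan:::AA20, chars[p]), 1)
    }
    paste(chars, collapse = "")
  })
}

# Planted 12-sequence identity structure: 3 groups of 4; members share
# ~85% identity within a group and ~40% across groups (groups derive from
# a common ancestor).
planted_cluster_fixture <- function(seed = 101, len = 80) {
  withr::with_seed(seed, {
    ancestor <- paste(sample(rrescan:::AA20, len, replace = TRUE),
                      collapse = "")
    groups <- lapply(1:3, function(g) {
      cons <- mutate_seq(ancestor, round(0.45 * len), seed + 10 * g)
      vapply(1:4, function(k) {
        mutate_seq(cons, round(0.07 * len), seed + 10 * g + k)
      }, character(1))
    })
    tibble::tibble(
      id = sprintf("g%d_m%d", rep(1:3, each = 4), rep(1:4, 3)),
      sequence = unlist(groups),
      group = rep(1:3, each = 4)
    )
  })
}
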