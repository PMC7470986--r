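#' Generate a synthetic protein family
#'
#' Deterministic stand-in for a curated RRE family: a generator profile
#' is built by perturbing a random consensus with per-column Dirichlet
#' noise, and members are sampled from it with known generator
#' coordinates.  The `divergence` knob sets both the Dirichlet base
#' mixture (towards uniform) and the indel rate; at `divergence = 0` the
#' generator is deterministic and every member equals the consensus,
#' and mean within-family identity decreases as divergence grows.
#' Defaults emulate an RRE-like family: ~90 match columns (discrete RREs
#' are <100 residues) at a moderate divergence giving within-family
#' identities spanning roughly 30-80%.
#'
#' @param m Number of match columns.
#' @param n_members Members to sample.
#' @param divergence Non-negative divergence knob (default 0.4,
#'   "moderate").
#' @param seed RNG seed; everything is a pure function of the spec and
#'   seed.
#' @param name Family/generator name.
#' @param class_tag Optional class tag carried on the generator.
#' @param concentration Dirichlet concentration for column noise.
#' @return List with `generator` (a [profile_hmm]), `members` (protein
#'   tibble with `aligned` rows in generator coordinates), `msa` (an
#'   [rre_alignment] of all members over the match columns), and `truth`
#'   (per-member id, length and matched-column count).
#' @export
make_family <- function(m = 90, n_members = 200, divergence = 0.4, seed = 1,
                        name = "family", class_tag = NA_character_,
                        concentration = 50) {
  stopifnot(divergence >= 0, m >= 1, n_members >= 1)
  d <- min(divergence, 0.95)
  generator <- with_seed(seed, {
    consensus <- sample(AA20, m, replace = TRUE)
    emis <- matrix(0, nrow = m, ncol = 20, dimnames = list(NULL, AA20))
    for (j in seq_len(m)) {
      point <- as.numeric(AA20 == consensus[j])
      if (d == 0) {
        emis[j, ] <- point
      } else {
        base <- (1 - d) * point + d / 20
        g <- stats::rgamma(20, shape = concentration * base)
        emis[j, ] <- g / sum(g)
      }
    }
    dt <- 0.025 * d
    trans <- matrix(rep(c(1 - 2 * dt, dt, dt, 0.7, 0.3, 0.7, 0.3), each = m),
                    nrow = m)
    profile_hmm(name = name, match_emissions = emis, transitions = trans,
                class_tag = class_tag)
  })
  members <- sample_from_phmm(generator, n_members, seed = seed + 1,
                              prefix = paste0(name, "_"))
  msa <- rre_alignment(members$id, members$aligned)
  truth <- tibble::tibble(
    id = members$id,
    length = nchar(members$sequence),
    n_match = nchar(gsub("-", "", members$aligned, fixed = TRUE))
  )
  list(generator = generator, members = members, msa = msa, truth = truth,
       spec = list(m = m, n_members = n_members, divergence = divergence,
                   seed = seed, name = name))
}

#' Build a detection model from family members
#'
#' Convenience wrapper: a profile HMM built from the first `n_seed`
#' member rows of a [make_family()] alignment (the generator-coordinate
#' seed alignment).
#'
#' @param family A [make_family()] result.
#' @param n_seed Number of seed rows (the published models use 5-20).
#' @param name Model name (defaults to the family name).
#' @param class_tag Class tag for the model.
#' @param config An [rre_config] (pseudocounts, background).
#' @return A [profile_hmm].
#' @export
family_model <- function(family, n_seed = 20, name = NULL,
                         class_tag = NA_character_, config = rre_config()) {
  rows <- family$msa$rows[seq_len(min(n_seed, nrow(family$msa$rows))), ]
  build_phmm(rre_alignment(rows$id, rows$aligned),
             name = name %||% family$spec$name,
             alpha = config$pseudocount, background = config$background,
             class_tag = class_tag)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate background decoy sequences
#'
#' I.i.d. residues from the background distribution with lengths from
#' `length_dist`; deterministic given `seed`.
#'
#' @param n Number of decoys (0 gives an empty table).
#' @param length_dist Fixed length, vector of lengths to sample, or a
#'   function `n -> lengths` (default: uniform on 70-130).
#' @param background Residue distribution (default uniform).
#' @param seed RNG seed.
#' @param prefix Id prefix.
#' @return Protein tibble.
#' @export
make_decoys <- function(n, length_dist = NULL, background = NULL, seed = 1,
                        prefix = "decoy") {
  background <- validate_background(background)
  if (n == 0) {
    return(tibble::tibble(id = character(0), description = character(0),
                          sequence = character(0)))
  }
  with_seed(seed, {
    lens <- if (is.null(length_dist)) {
      sample(70:130, n, replace = TRUE)
    } else {
      sample_lengths(length_dist, n, 100L)
    }
    tibble::tibble(
      id = sprintf("%s%04d", prefix, seq_len(n)),
      description = "background decoy",
      sequence = vapply(lens, function(L) {
        paste(sample(AA20, L, replace = TRUE, prob = background),
              collapse = "")
      }, character(1))
    )
  })
}

#' Generate helix-turn-helix-like decoys and their filter model
#'
#' A regulator-like generator profile (distinct from any RRE fixture
#' family), `n` sampled decoys, and a [regulator_model_set] whose single
#' model is built from the samples with its trusted cutoff set at the
#' 1st percentile of the samples' own scores — so every generated decoy
#' scores at or above the cutoff against its own model.
#'
#' @param n Number of decoys.
#' @param seed RNG seed.
#' @param m Generator length (HTH domains are short).
#' @return List with `proteins`, `regulator_set`, `model`, `generator`.
#' @export
make_hth_decoys <- function(n, seed = 1, m = 60) {
  fam <- make_family(m = m, n_members = max(n, 25), divergence = 0.25,
                     seed = seed + 7000, name = "HTH_like",
                     class_tag = "regulator")
  model <- family_model(fam, n_seed = 20, name = "HTH_like",
                        class_tag = "regulator")
  proteins <- fam$members[seq_len(n), c("id", "description", "sequence")]
  scores <- vapply(fam$members$sequence, function(s) {
    viterbi_raw(model, s)$score
  }, numeric(1), USE.NAMES = FALSE)
  model$trusted_cutoff <- unname(stats::quantile(scores, 0.01, type = 1))
  list(proteins = proteins,
       regulator_set = regulator_model_set(
         list(model), notes = "synthetic HTH-like regulator fixture"),
       model = model, generator = fam$generator)
}

#' Embed a domain inside a background host protein
#'
#' A background host sequence of `host_length` residues with the domain
#' substring written over positions `position .. position + len - 1`
#' (1-based; `position = 1` is an N-terminal fusion).  Truth coordinates
#' record the exact span.
#'
#' @param host_length Host length (must be >= the domain length).
#' @param domain_seq Domain sequence to embed.
#' @param position 1-based start, or `NULL` for a seeded random position.
#' @param seed RNG seed.
#' @param background Host residue distribution.
#' @param id Record id.
#' @return One-row tibble: `id`, `description`, `sequence`,
#'   `domain_from`, `domain_to`.
#' @export
embed_domain <- function(host_length, domain_seq, position = NULL, seed = 1,
                         background = NULL, id = "fusion") {
  dlen <- nchar(domain_seq)
  if (host_length < dlen) {
    stop("host_length (", host_length, ") is shorter than the domain (",
         dlen, ")")
  }
  background <- validate_background(background)
  with_seed(seed, {
    host <- sample(AA20, host_length, replace = TRUE, prob = background)
    pos <- position %||% sample(seq_len(host_length - dlen + 1), 1)
    stopifnot(pos >= 1, pos + dlen - 1 <= host_length)
    host[pos:(pos + dlen - 1)] <- seq_chars(domain_seq)
    tibble::tibble(
      id = id, description = "domain fusion fixture",
      sequence = paste(host, collapse = ""),
      domain_from = as.integer(pos), domain_to = as.integer(pos + dlen - 1)
    )
  })
}

#' Build a toy biosynthetic gene cluster locus
#'
#' Assembles a [bgc_locus] from an ordered gene plan over the roles
#' `precursor` (<150 aa), `rre` (discrete RRE-family sample), `rre_fused`
#' (RRE embedded in a larger host), `rsam`, `transporter`,
#' `regulator_hth` and `random`, together with a truth table and the
#' family models needed to annotate it.  Everything is a pure function
#' of the plan and seed.
#'
#' @param plan Character vector of roles, in gene order.
#' @param seed RNG seed.
#' @param locus_id Locus id.
#' @param generators Optional list with `rre`, `rsam`, `hth`
#'   [make_family()] results to reuse across loci.
#' @return List with `locus` (a [bgc_locus]), `truth` (per-gene role and
#'   embedded-domain coordinates), `models` (named list of profile HMMs
#'   for rre/rsam/hth), `generators`.
#' @export
make_toy_locus <- function(plan, seed = 1, locus_id = "toy_locus",
                           generators = NULL) {
  roles <- c("precursor", "rre", "rre_fused", "rsam", "transporter",
             "regulator_hth", "random")
  stopifnot(length(plan) >= 1, all(plan %in% roles))
  if (is.null(generators)) {
    generators <- list(
      rre = make_family(m = 90, n_members = 30, divergence = 0.3,
                        seed = seed + 100, name = "rre_fam"),
      rsam = make_family(m = 180, n_members = 30, divergence = 0.2,
                         seed = seed + 200, name = "rSAM"),
      hth = make_family(m = 60, n_members = 30, divergence = 0.25,
                        seed = seed + 300, name = "HTH_like")
    )
  }
  models <- list(
    rre = family_model(generators$rre, name = "rre_fam", class_tag = "rre"),
    rsam = family_model(generators$rsam, name = "rSAM", class_tag = "rsam"),
    hth = family_model(generators$hth, name = "HTH_like",
                       class_tag = "regulator")
  )
  genes <- list()
  truth <- list()
  with_seed(seed, {
    for (i in seq_along(plan)) {
      role <- plan[i]
      gid <- sprintf("g%02d_%s", i, role)
      dfrom <- NA_integer_; dto <- NA_integer_
      s <- switch(
        role,
        precursor = paste(sample(AA20, sample(30:80, 1), replace = TRUE),
                          collapse = ""),
        rre = sample_from_phmm(generators$rre$generator, 1,
                               seed = seed + 1000 + i)$sequence,
        rre_fused = {
          dom <- sample_from_phmm(generators$rre$generator, 1,
                                  seed = seed + 1000 + i)$sequence
          emb <- embed_domain(nchar(dom) + 160, dom, seed = seed + 2000 + i,
                              id = gid)
          dfrom <- emb$domain_from; dto <- emb$domain_to
          emb$sequence
        },
        rsam = sample_from_phmm(generators$rsam$generator, 1,
                                seed = seed + 3000 + i)$sequence,
        transporter = paste(sample(AA20, 220, replace = TRUE), collapse = ""),
        regulator_hth = sample_from_phmm(generators$hth$generator, 1,
                                         seed = seed + 4000 + i)$sequence,
        random = paste(sample(AA20, sample(150:250, 1), replace = TRUE),
                       collapse = "")
      )
      strand <- if (i %% 3 == 0) "-" else "+"
      genes[[i]] <- tibble::tibble(id = gid, strand = strand, translation = s)
      truth[[i]] <- tibble::tibble(gene_index = i, id = gid, role = role,
                                   domain_from = dfrom, domain_to = dto)
    }
  })
  locus <- bgc_locus(locus_id, dplyr::bind_rows(genes))
  list(locus = locus, truth = dplyr::bind_rows(truth), models = models,
       generators = generators)
}
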