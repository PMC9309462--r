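# Diploid three-way local-ancestry HMM.
#
# Hidden state at SNP m is the ordered pair of haplotype ancestries (a, b),
# K^2 states. Between adjacent SNPs at distance d bp each haplotype switches
# ancestry with probability s = 1 - exp(-g * r * d) (g admixture
# generations, r per-bp recombination rate); on a switch the new ancestry
# is drawn from the prior pi, so the per-haplotype transition matrix is
# A = (1 - s) I + s 1 pi', and the diploid transition is the Kronecker
# product A (x) A (haplotypes switch independently; no phasing needed).
# Emission at SNP m in state (a, b): the two alleles are independent
# Bernoulli(f_am) and Bernoulli(f_bm) draws, so
#   P(g=0) = (1-f_a)(1-f_b), P(g=1) = f_a + f_b - 2 f_a f_b, P(g=2) = f_a f_b,
# and a missing genotype emits 1 in every state.

#' Build a local-ancestry HMM
#'
#' @param panel a `ref_panel` giving per-SNP emission frequencies f_km.
#' @param map optional `snp_map` (defaults to the panel's map).
#' @param priors ancestry mixture proportions pi (named or in panel label
#'   order); default 0.30 wild boar, 0.66 European domestic, 0.04 Asian
#'   domestic. Must be positive; normalised to sum to 1.
#' @param g admixture generations (default 25).
#' @param r per-bp per-generation recombination rate (default 1e-8).
#' @return object of class `ancestry_hmm`.
#' @export
build_hmm <- function(panel, map = NULL,
                      priors = c(WB = 0.30, EUR_DP = 0.66, ASIA_DP = 0.04),
                      g = 25, r = 1e-8) {
  map <- map %||% panel$map
  K <- ncol(panel$freq)
  if (!is.null(names(priors))) {
    priors <- priors[panel$labels]
    if (anyNA(priors)) stop("priors must be named for every panel label")
  }
  if (length(priors) != K) stop("priors must have length ", K)
  if (any(priors <= 0)) stop("ancestry priors must be strictly positive")
  stopifnot(g >= 1, r >= 0)
  priors <- priors / sum(priors)
  # ordered diploid states s = (a-1)*K + b
  a_of <- rep(seq_len(K), each = K)
  b_of <- rep(seq_len(K), times = K)
  structure(list(panel = panel, map = map, K = K,
                 priors = stats::setNames(as.numeric(priors), panel$labels),
                 g = g, r = r, a_of = a_of, b_of = b_of,
                 pi2 = priors[a_of] * priors[b_of]),
            class = "ancestry_hmm")
}

#' Per-haplotype ancestry switch probability between adjacent SNPs
#' @param hmm an `ancestry_hmm`.
#' @param d distance in bp (vectorised).
#' @return `1 - exp(-g * r * d)`.
#' @export
switch_prob <- function(hmm, d) 1 - exp(-hmm$g * hmm$r * d)

hap_transition <- function(hmm, s) {
  K <- hmm$K
  (1 - s) * diag(K) + s * matrix(hmm$priors, K, K, byrow = TRUE)
}

# list of K^2 x K^2 diploid transition matrices for one chromosome's gaps
chrom_transitions <- function(hmm, pos) {
  lapply(diff(pos), function(d) {
    A <- hap_transition(hmm, switch_prob(hmm, d))
    kronecker(A, A)
  })
}

# genotype emission table for one chromosome: list(P0, P1, P2), each M x K^2
emission_tables <- function(hmm, rows) {
  fa <- hmm$panel$freq[rows, hmm$a_of, drop = FALSE]
  fb <- hmm$panel$freq[rows, hmm$b_of, drop = FALSE]
  list(P0 = (1 - fa) * (1 - fb), P1 = fa + fb - 2 * fa * fb, P2 = fa * fb)
}

emission_at <- function(tab, m, gcol, n_states) {
  # gcol: genotypes of all individuals at SNP m (NA = missing emits 1)
  E <- matrix(1, length(gcol), n_states)
  for (gv in 0:2) {
    sel <- which(!is.na(gcol) & gcol == gv)
    if (length(sel))
      E[sel, ] <- matrix(tab[[gv + 1L]][m, ], length(sel), n_states,
                         byrow = TRUE)
  }
  E
}

#' Posterior local-ancestry dosages by forward-backward decoding
#'
#' Runs the scaled forward–backward algorithm per chromosome, batched
#' across individuals, and returns per-SNP posterior ancestry dosages in
#' `[0, 2]` per ancestry (dosage / 2 is the allelic ancestry proportion).
#' Dosages sum to 2 over ancestries at every SNP. Individuals with no
#' observed genotypes get prior-marginal posteriors with a warning.
#'
#' @param hmm an `ancestry_hmm`.
#' @param gm a `genotype_matrix` on the same SNPs as the HMM.
#' @return a `lai_field`: list with `dosage` (individuals x SNPs x
#'   ancestries array), `loglik` per individual, `map`, `labels`, `ids`.
#' @export
posterior_dosages <- function(hmm, gm) {
  check_hmm_gm(hmm, gm)
  n <- nrow(gm$geno); S <- hmm$K^2; K <- hmm$K
  if (any(all_missing <- rowSums(!is.na(gm$geno)) == 0L))
    warning("individual(s) with no observed genotypes get uniform ",
            "(prior) posteriors: ",
            paste(gm$ids[all_missing], collapse = ", "))
  cnt <- sapply(seq_len(K), function(k)
    (hmm$a_of == k) + (hmm$b_of == k))  # S x K
  dos <- array(NA_real_, dim = c(n, nrow(hmm$map), K),
               dimnames = list(gm$ids, hmm$map$id, hmm$panel$labels))
  loglik <- numeric(n)
  for (ch in unique(hmm$map$chrom)) {
    rows <- which(hmm$map$chrom == ch)
    M <- length(rows)
    Tr <- chrom_transitions(hmm, hmm$map$pos[rows])
    tab <- emission_tables(hmm, rows)
    G <- gm$geno[, rows, drop = FALSE]
    alphas <- vector("list", M)
    logc <- matrix(0, n, M)
    E <- emission_at(tab, 1L, G[, 1L], S)
    a <- sweep(E, 2, hmm$pi2, "*")
    cs <- rowSums(a); a <- a / cs; logc[, 1L] <- log(cs)
    alphas[[1L]] <- a
    if (M > 1L) for (m in 2:M) {
      E <- emission_at(tab, m, G[, m], S)
      a <- (a %*% Tr[[m - 1L]]) * E
      cs <- rowSums(a); a <- a / cs; logc[, m] <- log(cs)
      alphas[[m]] <- a
    }
    loglik <- loglik + rowSums(logc)
    b <- matrix(1, n, S)
    post <- alphas[[M]] * b
    dos[, rows[M], ] <- (post / rowSums(post)) %*% cnt
    if (M > 1L) for (m in (M - 1L):1L) {
      E <- emission_at(tab, m + 1L, G[, m + 1L], S)
      b <- ((E * b) %*% t(Tr[[m]])) / exp(logc[, m + 1L])
      post <- alphas[[m]] * b
      dos[, rows[m], ] <- (post / rowSums(post)) %*% cnt
    }
  }
  structure(list(dosage = dos, map = hmm$map, labels = hmm$panel$labels,
                 ids = gm$ids, loglik = loglik, source = "hmm"),
            class = "lai_field")
}

check_hmm_gm <- function(hmm, gm) {
  if (!identical(gm$map$id, hmm$map$id) ||
      !identical(gm$map$pos, hmm$map$pos))
    stop("genotype matrix SNPs do not match the HMM's SNP map")
  if (nrow(gm$geno) < 1L) stop("empty genotype matrix")
  invisible(TRUE)
}

#' Maximum a posteriori ancestry tracts (Viterbi decoding)
#'
#' Decodes the most probable ordered diploid state path per chromosome and
#' merges consecutive same-ancestry runs per haplotype slot into tracts.
#' Haplotype slot labels (1/2) are arbitrary within a chromosome (the model
#' is unphased); the diploid (unordered) ancestry at each SNP is what is
#' identifiable.
#'
#' @param hmm an `ancestry_hmm`.
#' @param gm a `genotype_matrix` on the HMM's SNPs.
#' @return list with `tracts` (data frame: individual, haplotype, chrom,
#'   start, end in 0-based half-open bp of flanking SNPs, ancestry),
#'   `path_loglik` per individual, and `states` (individuals x SNPs matrix
#'   of state indices).
#' @export
viterbi_tracts <- function(hmm, gm) {
  check_hmm_gm(hmm, gm)
  n <- nrow(gm$geno); S <- hmm$K^2
  states <- matrix(NA_integer_, n, nrow(hmm$map),
                   dimnames = list(gm$ids, hmm$map$id))
  path_ll <- numeric(n)
  for (ch in unique(hmm$map$chrom)) {
    rows <- which(hmm$map$chrom == ch)
    M <- length(rows)
    logT <- lapply(chrom_transitions(hmm, hmm$map$pos[rows]), log)
    tab <- emission_tables(hmm, rows)
    G <- gm$geno[, rows, drop = FALSE]
    psi <- array(1L, dim = c(n, S, M))
    delta <- log(emission_at(tab, 1L, G[, 1L], S)) +
      matrix(log(hmm$pi2), n, S, byrow = TRUE)
    if (M > 1L) for (m in 2:M) {
      newd <- matrix(-Inf, n, S)
      for (s in seq_len(S)) {
        cand <- delta + matrix(logT[[m - 1L]][, s], n, S, byrow = TRUE)
        psi[, s, m] <- max.col(cand, ties.method = "first")
        newd[, s] <- cand[cbind(seq_len(n), psi[, s, m])]
      }
      delta <- newd + log(emission_at(tab, m, G[, m], S))
    }
    last <- max.col(delta, ties.method = "first")
    path_ll <- path_ll + delta[cbind(seq_len(n), last)]
    sp <- matrix(NA_integer_, n, M)
    sp[, M] <- last
    if (M > 1L) for (m in (M - 1L):1L)
      sp[, m] <- psi[cbind(seq_len(n), sp[, m + 1L], m + 1L)]
    states[, rows] <- sp
  }
  tracts <- states_to_tracts(states, hmm, gm$ids)
  list(tracts = tracts, path_loglik = path_ll, states = states)
}

states_to_tracts <- function(states, hmm, ids) {
  out <- list()
  for (i in seq_len(nrow(states))) {
    for (ch in unique(hmm$map$chrom)) {
      rows <- which(hmm$map$chrom == ch)
      pos <- hmm$map$pos[rows]
      for (slot in 1:2) {
        anc <- if (slot == 1) hmm$a_of[states[i, rows]]
          else hmm$b_of[states[i, rows]]
        runs <- rle(anc)
        ends <- cumsum(runs$lengths)
        starts <- c(1L, ends[-length(ends)] + 1L)
        out[[length(out) + 1L]] <- data.frame(
          individual = ids[i], haplotype = slot, chrom = ch,
          start = pos[starts] - 1L, end = pos[ends],
          ancestry = hmm$panel$labels[runs$values],
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' Hard local-ancestry dosages from the Viterbi path
#'
#' Converts the maximum a posteriori state path into a `lai_field` of hard
#' ancestry dosages (0/1/2 per ancestry; allelic proportions 0, 0.5 or 1),
#' the discrete form of local-ancestry output that the junction karyotype
#' rule was designed around.
#'
#' @param hmm an `ancestry_hmm`.
#' @param gm a `genotype_matrix` on the HMM's SNPs.
#' @return a `lai_field` with integer dosages.
#' @export
viterbi_field <- function(hmm, gm) {
  vt <- viterbi_tracts(hmm, gm)
  n <- nrow(vt$states); M <- ncol(vt$states); K <- hmm$K
  dos <- array(0, dim = c(n, M, K),
               dimnames = list(gm$ids, hmm$map$id, hmm$panel$labels))
  for (k in seq_len(K))
    dos[, , k] <- (matrix(hmm$a_of[vt$states], n, M) == k) +
      (matrix(hmm$b_of[vt$states], n, M) == k)
  structure(list(dosage = dos, map = hmm$map, labels = hmm$panel$labels,
                 ids = gm$ids, loglik = vt$path_loglik, source = "viterbi"),
            class = "lai_field")
}

#' Log likelihood of a fixed ordered state path
#'
#' Used to verify Viterbi optimality against, e.g., the true simulated path.
#'
#' @param hmm an `ancestry_hmm`.
#' @param geno genotype vector on the HMM's SNPs.
#' @param path integer vector of ordered state indices per SNP
#'   (s = (a-1)*K + b).
#' @return log joint probability of the path and the genotypes.
#' @export
path_loglik <- function(hmm, geno, path) {
  stopifnot(length(geno) == nrow(hmm$map), length(path) == nrow(hmm$map))
  ll <- 0
  for (ch in unique(hmm$map$chrom)) {
    rows <- which(hmm$map$chrom == ch)
    Tr <- chrom_transitions(hmm, hmm$map$pos[rows])
    tab <- emission_tables(hmm, rows)
    ll <- ll + log(hmm$pi2[path[rows[1]]])
    for (j in seq_along(rows)) {
      m <- rows[j]
      if (j > 1) ll <- ll + log(Tr[[j - 1L]][path[rows[j - 1L]], path[m]])
      if (!is.na(geno[m]))
        ll <- ll + log(tab[[geno[m] + 1L]][j, path[m]])
    }
  }
  ll
}

#' Genome-wide mean wild-ancestry proportion per individual from dosages
#' @param field a `lai_field`.
#' @param label ancestry component, default `"WB"`.
#' @return named vector: mean dosage / 2 across SNPs per individual.
#' @export
global_from_dosages <- function(field, label = "WB") {
  stats::setNames(rowMeans(field$dosage[, , label, drop = FALSE]) / 2,
                  field$ids)
}

#' Write per-ancestry dosage matrices as TSV (SNPs x individuals)
#' @param field a `lai_field`.
#' @param dir output directory.
#' @param prefix filename prefix.
#' @export
write_dosages <- function(field, dir, prefix = "dosage") {
  for (k in field$labels) {
    d <- t(field$dosage[, , k])
    df <- data.frame(snp = field$map$id, chrom = field$map$chrom,
                     pos = field$map$pos, d, check.names = FALSE)
    utils::write.table(df, file.path(dir, paste0(prefix, "_", k, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
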