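# Supervised global-ancestry estimation.
#
# Likelihood: each of the 2M allele draws of an individual comes from the
# mixture sum_k q_k f_km (alt) or sum_k q_k (1 - f_km) (ref), with panel
# frequencies f_km fixed. The log likelihood
#   l(q) = sum_m [ g_m log(sum_k q_k f_km) + (2 - g_m) log(sum_k q_k (1 - f_km)) ]
# is concave in q on the simplex and maximised by EM: allele-level
# responsibilities in the E step, renormalised allele counts in the M step.

em_q <- function(g, F, W = NULL, tol = 1e-6, max_iter = 2000L, q0 = NULL) {
  # g: length-M alt counts (no NA); F: M x K clamped panel frequencies;
  # W: optional M x B resampling-weight matrix (B replicates share F);
  # q0: optional warm start (e.g. the full-data estimate for bootstrap).
  # Plain EM converges geometrically slowly near simplex vertices (the
  # common case: nearly pure animals), so each cycle takes a SQUAREM
  # extrapolation step with a fall-back to the plain double EM step
  # whenever extrapolation would decrease the log likelihood — keeping the
  # recorded likelihood trace monotone.
  M <- length(g); K <- ncol(F)
  B <- if (is.null(W)) 1L else ncol(W)
  if (is.null(W)) W <- matrix(1, M, 1L)
  denom <- 2 * colSums(W)
  Wg <- g * W; Wh <- (2 - g) * W
  clampP <- function(P) pmin(pmax(P, 1e-12), 1 - 1e-12)
  emstep <- function(Q, act) {
    P <- clampP(F %*% Q)
    Qn <- (crossprod(F, Wg[, act, drop = FALSE] / P) +
             crossprod(1 - F, Wh[, act, drop = FALSE] / (1 - P))) * Q
    Qn <- sweep(Qn, 2, denom[act], "/")
    # the exact M-step lands on the simplex; renormalise to stop
    # floating-point drift from compounding
    sweep(Qn, 2, colSums(Qn), "/")
  }
  loglik <- function(Q, act) {
    P <- clampP(F %*% Q)
    colSums(Wg[, act, drop = FALSE] * log(P) +
              Wh[, act, drop = FALSE] * log1p(-P))
  }
  Qout <- matrix(if (is.null(q0)) 1 / K else pmax(q0, 1e-8), K, B)
  Qout <- sweep(Qout, 2, colSums(Qout), "/")
  ll_out <- rep(-Inf, B)
  trace <- numeric(0)
  active <- seq_len(B)  # replicates still iterating (each to its own tol)
  iter <- 0L
  while (length(active) && iter < max_iter) {
    iter <- iter + 1L
    Q <- Qout[, active, drop = FALSE]
    Q1 <- emstep(Q, active)
    Q2 <- emstep(Q1, active)
    R <- Q1 - Q
    V <- (Q2 - Q1) - R
    alpha <- -sqrt(colSums(R^2)) / pmax(sqrt(colSums(V^2)), 1e-30)
    alpha <- pmin(alpha, -1)  # alpha = -1 reproduces the plain EM step
    Qs <- Q - sweep(R, 2, 2 * alpha, "*") + sweep(V, 2, alpha^2, "*")
    # floor the projection well above zero: the multiplicative EM update
    # makes q_k ~ 0 a near-fixed point even when the gradient points inward
    Qs[Qs < 1e-6] <- 1e-6
    Qs <- sweep(Qs, 2, colSums(Qs), "/")
    Q3 <- emstep(Qs, active)   # stabilising EM step after extrapolation
    ll3 <- loglik(Q3, active)
    ll2 <- loglik(Q2, active)
    use2 <- !is.finite(ll3) | ll3 < ll2
    Qnew <- Q3; Qnew[, use2] <- Q2[, use2]
    ll_new <- ifelse(use2, ll2, ll3)
    # converge on the EM fixed-point residual |EM(Q) - Q| (proportional to
    # the scaled gradient): with weakly diverged panels the surface is flat
    # and both likelihood changes and accelerated-step sizes can look tiny
    # far from the optimum
    delta <- apply(abs(Q1 - Q), 2, max)
    done <- delta < tol
    if (any(done)) {
      # KKT check: a residually-stationary column whose near-zero component
      # the EM still wants to grow sits at a spurious boundary fixed point;
      # restart that component (guarded so the likelihood never decreases)
      di <- which(done)
      probe <- emstep(Qnew[, di, drop = FALSE], active[di])
      growth <- probe / pmax(Qnew[, di, drop = FALSE], 1e-300)
      viol <- (Qnew[, di, drop = FALSE] < 1e-5) & (growth > 1 + 1e-7)
      for (j in which(colSums(viol) > 0)) {
        col <- di[j]
        for (bump in c(1e-3, 1e-5)) {
          qb <- Qnew[, col]
          qb[viol[, j]] <- pmax(qb[viol[, j]], bump)
          qb <- qb / sum(qb)
          llb <- loglik(matrix(qb, ncol = 1), active[col])
          if (llb >= ll_new[col]) {
            Qnew[, col] <- qb
            ll_new[col] <- llb
            done[col] <- FALSE
            break
          }
        }
      }
    }
    Qout[, active] <- Qnew
    ll_out[active] <- ll_new
    if (B == 1L) trace <- c(trace, ll_new)
    active <- active[!done]
  }
  list(Q = Qout, loglik = ll_out, trace = trace, iterations = iter,
       converged = length(active) == 0L)
}

#' Estimate global ancestry proportions of one individual
#'
#' Maximises the supervised admixture likelihood over the simplex by EM
#' against fixed reference-panel frequencies. Missing genotypes are
#' skipped. The log likelihood is non-decreasing across iterations (the
#' returned `trace` lets callers assert this).
#'
#' @param geno integer vector of alt-allele counts (0/1/2, NA missing), in
#'   the panel's SNP order, or a 1-row `genotype_matrix`.
#' @param panel a `ref_panel`.
#' @param tol convergence tolerance on the EM fixed-point residual
#'   (max absolute single-step change in q).
#' @param max_iter maximum EM iterations.
#' @return list with `q` (named proportions summing to 1), `loglik`,
#'   `trace`, `iterations`, `converged`, `n_snps` used.
#' @export
estimate_q <- function(geno, panel, tol = 1e-6, max_iter = 2000L) {
  if (inherits(geno, "genotype_matrix")) geno <- drop(geno$geno[1, ])
  if (length(geno) != nrow(panel$freq))
    stop("genotype vector length does not match panel")
  obs <- which(!is.na(geno))
  if (!length(obs))
    stop("no overlap between observed genotypes and panel SNPs")
  if (length(obs) < 100L)
    warning("only ", length(obs), " informative SNPs; estimates unstable")
  K <- ncol(panel$freq)
  if (K == 1L)
    return(list(q = stats::setNames(1, panel$labels), loglik = NA_real_,
                trace = numeric(0), iterations = 0L, converged = TRUE,
                n_snps = length(obs)))
  fit <- em_q(geno[obs], panel$freq[obs, , drop = FALSE],
              tol = tol, max_iter = max_iter)
  list(q = stats::setNames(drop(fit$Q), panel$labels),
       loglik = fit$loglik[1], trace = fit$trace,
       iterations = fit$iterations, converged = fit$converged,
       n_snps = length(obs))
}

#' Bootstrap standard errors and confidence intervals for q
#'
#' SNPs are resampled with replacement `n_boot` times (as resampling
#' weights, so every replicate reuses the same panel matrix); the SE per
#' ancestry component is the standard deviation of replicate estimates and
#' the 95% CI is `q_hat +/- 1.96 * SE`, truncated to `[0, 1]`.
#'
#' @param geno genotype vector (or 1-row `genotype_matrix`).
#' @param panel a `ref_panel`.
#' @param n_boot bootstrap replicates, default 200.
#' @param seed optional integer seed.
#' @param tol,max_iter EM controls.
#' @return list with `q`, `se`, `ci_lower`, `ci_upper` (truncated),
#'   `ci_lower_raw`, `ci_upper_raw` (untruncated), all named by population.
#' @export
bootstrap_q <- function(geno, panel, n_boot = 200L, seed = NULL,
                        tol = 1e-6, max_iter = 2000L) {
  stopifnot(n_boot >= 2)
  if (!is.null(seed)) set.seed(seed)
  if (inherits(geno, "genotype_matrix")) geno <- drop(geno$geno[1, ])
  obs <- which(!is.na(geno))
  if (!length(obs)) stop("no overlap between observed genotypes and panel SNPs")
  g <- geno[obs]; F <- panel$freq[obs, , drop = FALSE]
  M <- length(obs)
  point <- em_q(g, F, tol = tol, max_iter = max_iter)
  W <- matrix(0, M, n_boot)
  for (b in seq_len(n_boot))
    W[, b] <- tabulate(sample.int(M, M, replace = TRUE), M)
  boot <- em_q(g, F, W = W, tol = tol, max_iter = max_iter,
               q0 = drop(point$Q))
  qhat <- stats::setNames(drop(point$Q), panel$labels)
  se <- stats::setNames(apply(boot$Q, 1, stats::sd), panel$labels)
  lo <- qhat - 1.96 * se; hi <- qhat + 1.96 * se
  list(q = qhat, se = se,
       ci_lower = pmax(lo, 0), ci_upper = pmin(hi, 1),
       ci_lower_raw = lo, ci_upper_raw = hi, n_boot = n_boot)
}

#' Classify an individual from its wild boar ancestry CI
#'
#' `unadmixed` if the upper 95% CI bound of the wild boar component reaches
#' 0.99 (the CI "overlaps 0.99"); otherwise `recent_hybrid_candidate` if the
#' point estimate of wild ancestry is below 0.60 (flagged PCA outliers
#' carried >40% domestic ancestry); otherwise `admixed`.
#'
#' @param q_wb point estimate of the wild boar ancestry proportion.
#' @param ci_upper_wb upper bound of its truncated 95% CI.
#' @return one of `"unadmixed"`, `"admixed"`, `"recent_hybrid_candidate"`.
#' @export
classify_admixture <- function(q_wb, ci_upper_wb) {
  stopifnot(length(q_wb) == 1, length(ci_upper_wb) == 1)
  if (ci_upper_wb >= 0.99) "unadmixed"
  else if (q_wb < 0.60) "recent_hybrid_candidate"
  else "admixed"
}

#' Global ancestry table for a cohort
#'
#' Runs [estimate_q()] and [bootstrap_q()] per individual and applies
#' [classify_admixture()], returning the Q-matrix in tabular form.
#'
#' @param gm a `genotype_matrix`.
#' @param panel a `ref_panel`.
#' @param n_boot bootstrap replicates (0 skips SEs and classification
#'   becomes NA).
#' @param seed integer seed (per-individual seeds derived by offset).
#' @param wild_label which panel component counts as wild boar.
#' @return data frame, one row per individual: q, SE, CI and class.
#' @export
ancestry_q_table <- function(gm, panel, n_boot = 200L, seed = 1L,
                             wild_label = "WB") {
  K <- length(panel$labels)
  rows <- vector("list", nrow(gm$geno))
  for (i in seq_len(nrow(gm$geno))) {
    g <- gm$geno[i, ]
    if (n_boot >= 2) {
      b <- bootstrap_q(g, panel, n_boot = n_boot, seed = seed + i)
      cls <- classify_admixture(b$q[[wild_label]], b$ci_upper[[wild_label]])
      rows[[i]] <- data.frame(
        id = gm$ids[i], t(b$q), t(b$se), t(b$ci_lower), t(b$ci_upper),
        class = cls, stringsAsFactors = FALSE)
      names(rows[[i]]) <- c("id", paste0("q_", panel$labels),
                            paste0("se_", panel$labels),
                            paste0("ci_lo_", panel$labels),
                            paste0("ci_hi_", panel$labels), "class")
    } else {
      e <- estimate_q(g, panel)
      rows[[i]] <- data.frame(id = gm$ids[i], t(e$q),
                              class = NA_character_, stringsAsFactors = FALSE)
      names(rows[[i]]) <- c("id", paste0("q_", panel$labels), "class")
    }
  }
  do.call(rbind, rows)
}
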