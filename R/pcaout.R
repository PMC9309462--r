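#' Principal component analysis of genotypes
#'
#' Genotypes are centred at 2*p and scaled by sqrt(2*p*(1-p)) per SNP
#' (p = observed alt allele frequency; missing cells imputed to the column
#' mean, i.e. zero after centring), then decomposed by SVD of the
#' standardised matrix. Monomorphic columns are dropped. Sign convention:
#' each component is flipped so that its largest-magnitude score is
#' positive.
#'
#' @param gm a `genotype_matrix`.
#' @param n_components number of components to return.
#' @return object of class `pc_scores`: list with `scores` (individuals x
#'   components), `explained` (variance fractions, non-increasing) and `ids`.
#' @export
pca_genotypes <- function(gm, n_components = 10L) {
  g <- gm$geno
  if (nrow(g) < 2L || ncol(g) < 2L)
    stop("PCA needs at least 2 individuals and 2 SNPs")
  p <- colMeans(g, na.rm = TRUE) / 2
  v <- apply(g, 2, stats::var, na.rm = TRUE)
  poly <- !is.na(p) & p > 0 & p < 1 & !is.na(v) & v > 0
  if (!any(poly)) stop("constant genotype matrix: no polymorphic SNPs")
  g <- g[, poly, drop = FALSE]; p <- p[poly]
  x <- sweep(g, 2, 2 * p, "-")
  x[is.na(x)] <- 0
  x <- sweep(x, 2, sqrt(2 * p * (1 - p)), "/")
  n_components <- min(n_components, nrow(x) - 1L, ncol(x))
  sv <- svd(x, nu = n_components, nv = 0)
  scores <- sv$u %*% diag(sv$d[seq_len(n_components)], n_components)
  for (c in seq_len(n_components))
    if (scores[which.max(abs(scores[, c])), c] < 0)
      scores[, c] <- -scores[, c]
  colnames(scores) <- paste0("PC", seq_len(n_components))
  rownames(scores) <- gm$ids
  explained <- (sv$d^2 / sum(sv$d^2))[seq_len(n_components)]
  structure(list(scores = scores, explained = explained, ids = gm$ids),
            class = "pc_scores")
}

#' Flag outlier individuals by model-based clustering of PC1/PC2
#'
#' Fits Gaussian mixture models with 1..`max_clusters` components to the
#' first two principal components using `mclust` (BIC model selection over
#' its covariance families). The majority component is the one with the
#' largest mixing weight (ties broken toward the lower component index).
#' An individual is an outlier if its maximum-posterior component is not
#' the majority component, or — when `density_quantile > 0` — if its
#' mixture density falls below that quantile of the densities of
#' majority-component members (an optional backstop, off by default, for
#' stragglers absorbed into the majority component).
#'
#' @param scores a `pc_scores` object (components 1 and 2 are used).
#' @param max_clusters maximum number of mixture components.
#' @param density_quantile low-density quantile for within-cluster
#'   outliers; the default 0 disables the density rule (cluster membership
#'   alone decides, as in the source workflow).
#' @return data frame with id, cluster, posterior membership probability
#'   and `is_outlier`.
#' @importFrom mclust Mclust mclustBIC
#' @export
detect_outliers <- function(scores, max_clusters = 9L,
                            density_quantile = 0) {
  x <- scores$scores[, 1:2, drop = FALSE]
  if (nrow(x) < 10L)
    stop("too few individuals (", nrow(x), ") to fit a mixture model")
  fit <- Mclust(x, G = 1:max_clusters, verbose = FALSE)
  if (is.null(fit)) stop("mixture model fit failed")
  major <- which.max(fit$parameters$pro)  # ties: which.max takes lowest index
  dens <- mclust::dens(fit$modelName, data = x,
                       parameters = fit$parameters)
  in_major <- fit$classification == major
  # with a single selected component every point is "majority" and the
  # density rule is disabled, so k = 1 always yields zero outliers
  thr <- if (fit$G > 1L && density_quantile > 0 && any(in_major))
    stats::quantile(dens[in_major], density_quantile) else -Inf
  post <- apply(fit$z, 1, max)
  out <- data.frame(id = scores$ids,
                    cluster = fit$classification,
                    posterior = post,
                    is_outlier = !in_major | dens < thr,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "n_clusters") <- fit$G
  attr(out, "majority") <- major
  out
}
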