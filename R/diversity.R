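#' Per-sample OTU richness
#'
#' @param x a `count_table`.
#' @return named integer vector: taxa with count > 0 per sample.
#' @export
richness <- function(x) {
  stopifnot(inherits(x, "count_table"))
  colSums(x$counts > 0)
}

#' Bray-Curtis dissimilarity between samples
#'
#' d(j,k) = sum|x_ij - x_ik| / sum(x_ij + x_ik), computed on counts (the
#' rarefied table in the pipeline) or on relative abundances.
#'
#' @param x a `count_table`.
#' @param relative divide each sample by its total first.
#' @return a `dist` over samples.
#' @export
bray_curtis <- function(x, relative = FALSE) {
  stopifnot(inherits(x, "count_table"))
  m <- t(x$counts)
  if (relative) m <- m / rowSums(m)
  vegan::vegdist(m, method = "bray")
}

#' Principal coordinate analysis
#'
#' Classical metric scaling (Gower-centered -D^2/2 eigendecomposition).
#' Coordinates are returned for positive eigenvalues only; negative
#' eigenvalue mass is reported in the result and logged.
#'
#' @param d a `dist` or symmetric matrix.
#' @param k maximum number of axes to keep.
#' @return list of class `pcoa_ord`: `coords` (samples x axes), `eig`
#'   (positive eigenvalues, descending), `prop_explained`, `negative_mass`.
#' @export
pcoa <- function(d, k = NULL) {
  m <- as.matrix(d)
  if (!isSymmetric(unname(m), tol = 1e-8)) abort("distance matrix is not symmetric")
  n <- nrow(m)
  if (is.null(k)) k <- n - 1L
  cs <- stats::cmdscale(stats::as.dist(m), k = min(k, n - 1L), eig = TRUE)
  pos <- cs$eig > sqrt(.Machine$double.eps) * max(abs(cs$eig))
  eig <- cs$eig[pos]
  coords <- cs$points[, seq_len(min(sum(pos), ncol(cs$points))), drop = FALSE]
  colnames(coords) <- paste0("PCoA", seq_len(ncol(coords)))
  neg <- sum(abs(cs$eig[cs$eig < 0]))
  if (neg > 0)
    log_msg("pcoa: dropping negative eigenvalue mass %.3g (%.1f%% of total)",
            neg, 100 * neg / sum(abs(cs$eig)))
  structure(list(coords = coords, eig = eig,
                 prop_explained = eig / sum(abs(cs$eig)),
                 negative_mass = neg),
            class = "pcoa_ord")
}

#' PERMANOVA on a distance matrix
#'
#' Pseudo-F from the distance partition with free label permutation;
#' p = (1 + #{F_perm >= F_obs}) / (1 + n_perm).
#'
#' @param d a `dist` or symmetric matrix over samples.
#' @param grouping factor-like, one level per sample.
#' @param n_perm number of permutations (999 by default).
#' @param seed integer seed.
#' @param strata optional blocking factor restricting permutations
#'   (off by default).
#' @return list: pseudo_F, R2, p, df.
#' @export
permanova <- function(d, grouping, n_perm = 999L, seed = 1L, strata = NULL) {
  d <- stats::as.dist(as.matrix(d))
  g <- factor(grouping)
  if (any(table(g) < 2L)) abort("every group needs >= 2 samples")
  set.seed(seed)
  perm <- if (is.null(strata)) n_perm else
    permute::how(blocks = strata, nperm = n_perm)
  fit <- vegan::adonis2(d ~ g, permutations = perm)
  list(pseudo_F = fit$F[1L], R2 = fit$R2[1L], p = fit$`Pr(>F)`[1L],
       df = c(between = fit$Df[1L], within = fit$Df[2L]))
}

#' Two-group and four-group comparison statistics
#'
#' Two groups: t-test (Welch by default, Student optional). Three or more
#' groups: one-way ANOVA plus pairwise least-significant-difference (LSD)
#' comparisons with a compact letter display (pooled-variance pairwise t at
#' alpha, no multiplicity correction, as LSD is defined).
#'
#' @param values numeric response.
#' @param groups factor-like grouping.
#' @param var_equal use pooled variance in the 2-group t-test.
#' @param alpha significance level for LSD letters.
#' @return list with the test type, statistic, p, group means, and for
#'   ANOVA the pairwise p matrix and letters.
#' @export
group_tests <- function(values, groups, var_equal = FALSE, alpha = 0.05) {
  g <- factor(groups)
  stopifnot(length(values) == length(g))
  means <- tapply(values, g, mean)
  if (nlevels(g) == 2L) {
    tt <- stats::t.test(values ~ g, var.equal = var_equal)
    return(list(type = "t", statistic = unname(tt$statistic),
                p = tt$p.value, means = means))
  }
  fit <- stats::aov(values ~ g)
  an <- summary(fit)[[1L]]
  mse <- an$`Mean Sq`[2L]
  dfres <- an$Df[2L]
  lev <- levels(g)
  n <- table(g)
  pmat <- matrix(NA_real_, nlevels(g), nlevels(g), dimnames = list(lev, lev))
  for (i in seq_len(nlevels(g) - 1L)) for (j in (i + 1L):nlevels(g)) {
    se <- sqrt(mse * (1 / n[i] + 1 / n[j]))
    tstat <- (means[i] - means[j]) / se
    pmat[i, j] <- pmat[j, i] <- 2 * stats::pt(-abs(tstat), dfres)
  }
  list(type = "anova_lsd", statistic = an$`F value`[1L],
       p = an$`Pr(>F)`[1L], means = means, pairwise_p = pmat,
       letters = cld_letters(pmat, means, alpha))
}

# compact letter display by insert-and-absorb: groups ordered by
# descending mean; any pair with p >= alpha may share a letter
cld_letters <- function(pmat, means, alpha = 0.05) {
  lev <- names(sort(means, decreasing = TRUE))
  sets <- list()
  for (gname in lev) {
    placed <- FALSE
    for (k in seq_along(sets)) {
      ok <- all(vapply(sets[[k]], function(o)
        is.na(pmat[gname, o]) || pmat[gname, o] >= alpha, logical(1)))
      if (ok) { sets[[k]] <- c(sets[[k]], gname); placed <- TRUE }
    }
    if (!placed) sets[[length(sets) + 1L]] <- gname
  }
  # drop sets fully contained in another
  keep <- rep(TRUE, length(sets))
  for (i in seq_along(sets)) for (j in seq_along(sets))
    if (i != j && keep[j] && all(sets[[i]] %in% sets[[j]])) keep[i] <- FALSE
  sets <- sets[keep]
  out <- stats::setNames(rep("", length(means)), names(means))
  for (k in seq_along(sets))
    for (gname in sets[[k]]) out[gname] <- paste0(out[gname], letters[k])
  out[lev]
}
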