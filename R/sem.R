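#' Specify a recursive path model over observed variables
#'
#' Directed edges (cause -> effect) over named observed variables. Free
#' parameters are one coefficient per edge, the full covariance block of
#' the exogenous variables, and one residual variance per endogenous
#' variable. The graph must be acyclic and the model cannot have more free
#' parameters than distinct covariance moments.
#'
#' @param variables character vector of variable names.
#' @param edges two-column matrix or data.frame (from, to).
#' @return list of class `path_model`: variables, edges, exogenous,
#'   endogenous, df.
#' @export
path_model <- function(variables, edges) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  names(edges) <- c("from", "to")
  stopifnot(all(unlist(edges) %in% variables))
  if (any(edges$from == edges$to)) abort("self-loop in path model")
  if (anyDuplicated(paste(edges$from, edges$to))) abort("duplicate path")
  # acyclicity by repeated sink removal
  rem <- edges; vs <- variables
  while (length(vs)) {
    sinks <- setdiff(vs, rem$from)
    if (!length(sinks)) abort("path model is cyclic")
    vs <- setdiff(vs, sinks)
    rem <- rem[!(rem$to %in% sinks), , drop = FALSE]
  }
  p <- length(variables)
  endo <- unique(edges$to)
  exo <- setdiff(variables, endo)
  n_free <- nrow(edges) + length(exo) * (length(exo) + 1) / 2 + length(endo)
  df <- p * (p + 1) / 2 - n_free
  if (df < 0) abort("model has negative degrees of freedom (%d)", df)
  structure(list(variables = variables, edges = edges, exogenous = exo,
                 endogenous = endo, df = df),
            class = "path_model")
}

# pack/unpack parameter vector: edge coefs, exo (co)variances, endo resid vars
sem_matrices <- function(theta, model) {
  p <- length(model$variables)
  v <- model$variables
  B <- matrix(0, p, p, dimnames = list(v, v))
  ne <- nrow(model$edges)
  B[cbind(match(model$edges$to, v), match(model$edges$from, v))] <-
    theta[seq_len(ne)]
  Psi <- matrix(0, p, p, dimnames = list(v, v))
  k <- ne
  exo <- model$exogenous
  for (i in seq_along(exo)) for (j in seq_len(i)) {
    k <- k + 1L
    Psi[exo[i], exo[j]] <- Psi[exo[j], exo[i]] <- theta[k]
  }
  for (e in model$endogenous) {
    k <- k + 1L
    Psi[e, e] <- theta[k]
  }
  list(B = B, Psi = Psi)
}

sem_implied <- function(theta, model) {
  m <- sem_matrices(theta, model)
  IB <- solve(diag(length(model$variables)) - m$B)
  IB %*% m$Psi %*% t(IB)
}

sem_fml <- function(theta, model, S, logdetS) {
  Sigma <- sem_implied(theta, model)
  ch <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  inv <- chol2inv(ch)
  val <- 2 * sum(log(diag(ch))) + sum(inv * S) - logdetS - nrow(S)
  if (!is.finite(val)) 1e10 else val
}

#' Fit a path model by maximum likelihood
#'
#' Minimizes the ML discrepancy F = log|Sigma(theta)| + tr(S Sigma^-1) -
#' log|S| - p. Starting values come from per-equation OLS (exact ML for
#' recursive models with uncorrelated errors), polished by bounded
#' quasi-Newton with seeded random restarts. Reports chi-square =
#' (n-1) F at the optimum, GFI, RMSEA, standardized coefficients (via
#' model-implied variances), asymptotic SEs and z-based p-values, and
#' total effects.
#'
#' @param data numeric matrix or data.frame, n observations x p variables
#'   (columns named as in the model).
#' @param model a `path_model`.
#' @param n_restarts jittered restarts around the OLS start (default 10).
#' @param seed integer seed for the restarts.
#' @return list of class `sem_fit`: estimates data.frame (from, to, est,
#'   std, se, z, p), chi_square, df, p_value, GFI, RMSEA, F_ml, n,
#'   B (unstandardized), B_std, Psi, implied, total_effects.
#' @export
fit_sem <- function(data, model, n_restarts = 10L, seed = 1L) {
  data <- as.matrix(data[, model$variables, drop = FALSE])
  n <- nrow(data); p <- ncol(data)
  if (n <= p) abort("need more observations than variables")
  # fit on z-scored variables for numerical conditioning (F_ML and all fit
  # indices are invariant to affine rescaling); rescale estimates after
  sds0 <- apply(data, 2L, stats::sd)
  if (any(sds0 <= 0)) abort("constant variable in SEM data")
  data <- scale(data)
  S <- stats::cov(data)
  chS <- tryCatch(chol(S), error = function(e)
    abort("sample covariance is not positive definite"))
  logdetS <- 2 * sum(log(diag(chS)))
  v <- model$variables
  # OLS starting values
  ne <- nrow(model$edges)
  theta0 <- numeric(0)
  coef0 <- numeric(ne)
  resid0 <- stats::setNames(numeric(length(model$endogenous)),
                            model$endogenous)
  for (e in model$endogenous) {
    parents <- model$edges$from[model$edges$to == e]
    fit <- stats::lm.fit(cbind(1, data[, parents, drop = FALSE]), data[, e])
    coef0[model$edges$to == e] <-
      fit$coefficients[-1L][match(model$edges$from[model$edges$to == e],
                                  parents)]
    resid0[e] <- sum(fit$residuals^2) / (n - 1)
  }
  exo <- model$exogenous
  exo0 <- numeric(0)
  for (i in seq_along(exo)) for (j in seq_len(i))
    exo0 <- c(exo0, S[exo[i], exo[j]])
  theta0 <- c(coef0, exo0, resid0)
  # bounds: variances positive, covariances and coefficients free
  is_var <- c(rep(FALSE, ne),
              unlist(lapply(seq_along(exo), function(i)
                c(rep(FALSE, i - 1L), TRUE))),
              rep(TRUE, length(model$endogenous)))
  lower <- ifelse(is_var, 1e-10, -Inf)
  obj <- function(th) sem_fml(th, model, S, logdetS)
  best <- stats::optim(theta0, obj, method = "L-BFGS-B", lower = lower,
                       control = list(maxit = 1000, factr = 1e4))
  set.seed(seed)
  for (r in seq_len(n_restarts)) {
    th <- theta0 * (1 + stats::rnorm(length(theta0), 0, 0.1)) +
      stats::rnorm(length(theta0), 0, 0.01)
    th[is_var] <- pmax(th[is_var], 1e-8)
    cand <- tryCatch(stats::optim(th, obj, method = "L-BFGS-B", lower = lower,
                                  control = list(maxit = 1000, factr = 1e4)),
                     error = function(e) NULL)
    if (!is.null(cand) && cand$value < best$value) best <- cand
  }
  theta <- best$par
  if (any(theta[is_var] <= 2e-10))
    warning("Heywood case: residual variance at boundary")
  Fml <- max(best$value, 0)
  mats <- sem_matrices(theta, model)
  Sigma <- sem_implied(theta, model)
  invS <- solve(Sigma, S)
  chi <- (n - 1) * Fml
  dfm <- model$df
  gfi <- 1 - sum(diag(crossprod(invS - diag(p)))) / sum(diag(crossprod(invS)))
  rmsea <- if (dfm == 0) 0 else sqrt(max((chi - dfm) / (dfm * (n - 1)), 0))
  # standardized coefficients from model-implied variances
  sds <- sqrt(diag(Sigma))
  B_std <- mats$B * outer(1 / sds, sds)
  # asymptotic SEs from the numerical Hessian of F_ml
  H <- tryCatch(stats::optimHess(theta, obj), error = function(e) NULL)
  se <- rep(NA_real_, length(theta))
  if (!is.null(H)) {
    acov <- tryCatch(2 / (n - 1) * solve(H), error = function(e) NULL)
    if (!is.null(acov)) {
      dg <- diag(acov)
      se[dg > 0] <- sqrt(dg[dg > 0])
    }
  }
  # back to the original units: b_orig = b_z * sd(to) / sd(from)
  fac <- sds0[model$edges$to] / sds0[model$edges$from]
  est <- theta[seq_len(ne)] * fac
  se_e <- se[seq_len(ne)] * fac
  z <- est / se_e
  idx <- cbind(match(model$edges$to, v), match(model$edges$from, v))
  estimates <- data.frame(from = model$edges$from, to = model$edges$to,
                          est = est, std = B_std[idx], se = se_e, z = z,
                          p = 2 * stats::pnorm(-abs(z)),
                          stringsAsFactors = FALSE)
  rownames(estimates) <- NULL
  tot <- solve(diag(p) - B_std) - diag(p)
  dimnames(tot) <- list(v, v)
  structure(list(estimates = estimates, chi_square = chi, df = dfm,
                 p_value = if (dfm > 0) stats::pchisq(chi, dfm,
                                                      lower.tail = FALSE)
                           else NA_real_,
                 GFI = gfi, RMSEA = rmsea, F_ml = Fml, n = n,
                 B = mats$B * outer(sds0, 1 / sds0), B_std = B_std,
                 Psi = mats$Psi * outer(sds0, sds0),
                 implied = Sigma * outer(sds0, sds0), total_effects = tot,
                 convergence = best$convergence),
            class = "sem_fit")
}

#' @export
print.sem_fit <- function(x, ...) {
  cat(sprintf("sem_fit: chi2 = %.4g (df = %d), GFI = %.3f, RMSEA = %.3f, n = %d\n",
              x$chi_square, x$df, x$GFI, x$RMSEA, x$n))
  print(x$estimates, digits = 3)
  invisible(x)
}

#' Total effects of each cause on each outcome
#'
#' (I - B)^-1 - I on the standardized coefficient matrix: entry [effect,
#' cause] sums the products of standardized path coefficients over every
#' directed path from cause to effect.
#'
#' @param fit a `sem_fit`.
#' @param outcome optional outcome name; returns that column slice.
#' @return matrix (or named vector for one outcome) of total effects.
#' @export
total_effects <- function(fit, outcome = NULL) {
  te <- fit$total_effects
  if (is.null(outcome)) te else te[outcome, ]
}

#' Assemble the five-variable study path model
#'
#' Per cultivar class: community structure (PCoA1 of Bray-Curtis on the
#' count table), keystone relative abundance, KBS relative abundance, soil
#' PC1 and yield, with the hypothesized paths soil -> community -> keystone
#' -> KBS and all four predictors into yield.
#'
#' @param x a `count_table` restricted to the class's samples.
#' @param net a `co_network` after [zi_pi()].
#' @param kbs_result a `kbs_result`.
#' @param meta `sample_metadata` covering the samples.
#' @param edges optional custom edge data.frame (from, to) overriding the
#'   default topology.
#' @return list: `data` (samples x 5 matrix) and `model` (a `path_model`).
#' @export
build_study_model <- function(x, net, kbs_result, meta, edges = NULL) {
  ids <- sample_ids(x)
  meta <- meta[match(ids, meta$sample_id), , drop = FALSE]
  if (anyNA(meta$sample_id)) abort("metadata does not cover all samples")
  ord <- pcoa(bray_curtis(x))
  rel <- prop.table(x$counts, 2L)
  keystone_taxa <- intersect(net$nodes$taxon_id[net$nodes$keystone],
                             rownames(rel))
  keystone_ab <- if (length(keystone_taxa))
    colSums(rel[keystone_taxa, , drop = FALSE]) else numeric(length(ids))
  kbs_ab <- kbs_abundance(kbs_result, x)$per_sample
  dat <- cbind(soil = soil_pc1(meta[, soil_vars()]),
               community = ord$coords[ids, "PCoA1"],
               keystone = keystone_ab[ids],
               kbs = kbs_ab[ids],
               yield = meta$yield)
  rownames(dat) <- ids
  if (is.null(edges))
    edges <- data.frame(
      from = c("soil", "community", "keystone", "soil",
               "community", "keystone", "kbs"),
      to = c("community", "keystone", "kbs", "yield",
             "yield", "yield", "yield"),
      stringsAsFactors = FALSE)
  # a constant column (e.g. an empty KBS set) carries no information and
  # would make the sample covariance singular: drop it and its paths
  keep <- apply(dat, 2L, stats::sd) > 1e-12
  dropped <- colnames(dat)[!keep]
  dat2 <- dat[, keep, drop = FALSE]
  # collinear pairs (e.g. KBS set identical to the keystone set) would make
  # the covariance singular: keep the first of each near-duplicate pair
  r <- stats::cor(dat2)
  for (j in seq_len(ncol(dat2))[-1L])
    if (any(abs(r[j, seq_len(j - 1L)]) > 0.999))
      dropped <- c(dropped, colnames(dat2)[j])
  if (length(dropped)) {
    log_msg("build_study_model: dropping degenerate variable(s): %s",
            paste(dropped, collapse = ", "))
    keep2 <- setdiff(colnames(dat), dropped)
    edges <- edges[edges$from %in% keep2 & edges$to %in% keep2, , drop = FALSE]
    dat <- dat[, keep2, drop = FALSE]
  }
  list(data = dat, model = path_model(colnames(dat), edges))
}
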