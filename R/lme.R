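#' @importFrom stats optim var median setNames
NULL

# Precompute the per-cancer block structure of the mixed model
#   Y = Kit + (Kit | Cancer) + (1 | cell) + residual
# Within one cancer the fixed design X and the random design Z coincide:
# an intercept column plus one indicator per non-reference condition.
.lmeStructure <- function(design) {
  cond <- droplevels(design$condition)
  if (nlevels(cond) < 2L) stop("need at least 2 conditions")
  cancer <- factor(design$cancer_id)
  if (nlevels(cancer) < 2L) stop("need at least 2 cancers")
  K <- nlevels(cond)
  idx <- split(seq_along(cancer), cancer)
  key <- vapply(idx, function(ii)
    paste(as.integer(cond[ii]), collapse = ","), character(1))
  pats <- unique(key)
  pat <- lapply(pats, function(pk) {
    ii <- idx[[match(pk, key)]]
    ci <- as.integer(cond[ii])
    Z <- cbind(1, outer(ci, seq_len(K)[-1], "==") + 0)
    list(Z = Z, Scell = (outer(ci, ci, "==")) + 0, n = length(ii))
  })
  list(idx = idx, pat_of = match(key, pats), pat = pat,
       kits = levels(cond)[-1], K = K, n = length(cancer),
       cancers = levels(cancer))
}

# -2 * restricted log-likelihood for covariance parameters
# Lambda: K x K covariance of (intercept, slopes) random effects per cancer
.remlCrit2 <- function(y, st, Lambda, su2, se2) {
  K <- st$K
  p <- K                      # X has the same columns as Z
  XtViX <- matrix(0, p, p); XtViy <- numeric(p)
  ytViy <- 0; logdet <- 0
  # per-pattern pieces shared by every cancer with that design pattern
  chols <- Ws <- WtWs <- vector("list", length(st$pat))
  logds <- numeric(length(st$pat))
  for (pi in seq_along(st$pat)) {
    pp <- st$pat[[pi]]
    V <- pp$Z %*% Lambda %*% t(pp$Z) + su2 * pp$Scell + diag(se2, pp$n)
    R <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(R)) return(list(crit = 1e10, beta = rep(NA_real_, p)))
    chols[[pi]] <- R
    Ws[[pi]] <- backsolve(R, pp$Z, transpose = TRUE)
    WtWs[[pi]] <- crossprod(Ws[[pi]])
    logds[pi] <- 2 * sum(log(diag(R)))
  }
  for (ci in seq_along(st$idx)) {
    pi <- st$pat_of[ci]
    u <- backsolve(chols[[pi]], y[st$idx[[ci]]], transpose = TRUE)
    XtViX <- XtViX + WtWs[[pi]]
    XtViy <- XtViy + crossprod(Ws[[pi]], u)[, 1]
    ytViy <- ytViy + sum(u * u)
    logdet <- logdet + logds[pi]
  }
  Rx <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(Rx)) return(list(crit = 1e10, beta = rep(NA_real_, p)))
  beta <- backsolve(Rx, backsolve(Rx, XtViy, transpose = TRUE))
  quad <- ytViy - sum(XtViy * beta)
  crit <- logdet + 2 * sum(log(diag(Rx))) + quad +
    (st$n - p) * log(2 * pi)
  list(crit = crit, beta = beta)
}

#' Restricted-likelihood criterion of the reliability mixed model
#'
#' Evaluates -2 times the restricted (REML) log-likelihood of
#' \code{Y = Kit + (Kit | Cancer) + (1 | cell) + residual} at given
#' variance-component values, profiling nothing: the surface that
#' \code{\link{fitLmeSingle}} minimizes. Exposed so that the optimum can be
#' checked against independent optimizers.
#'
#' @param y numeric vector of per-sample values.
#' @param design data.frame with \code{cancer_id}, \code{condition} (factor,
#'   reference first), \code{replicate}.
#' @param sigma_a2 variance of the per-cancer random intercept.
#' @param tau2 named (or positionally matched) per-kit random-slope
#'   variances.
#' @param sigma_e2 residual (replicate) variance.
#' @param sigma_u2 shared cell-effect variance (default 0).
#' @param Lambda optional full K x K random-effect covariance matrix
#'   (intercept + slopes); overrides \code{sigma_a2}/\code{tau2}.
#' @return list with \code{crit} (-2 restricted log-likelihood, including
#'   the \eqn{(n-p)\log 2\pi} constant) and \code{beta} (GLS fixed effects:
#'   intercept then per-kit bias).
#' @export
remlCriterion <- function(y, design, sigma_a2, tau2, sigma_e2,
                          sigma_u2 = 0, Lambda = NULL) {
  st <- .lmeStructure(design)
  if (is.null(Lambda)) {
    tau2 <- rep_len(tau2, st$K - 1L)
    Lambda <- diag(c(sigma_a2, tau2), st$K)
  }
  .remlCrit2(y, st, Lambda, sigma_u2, sigma_e2)
}

#' Method-of-moments decomposition for a balanced design
#'
#' Closed-form estimates for the balanced replicated paired design:
#' residual variance from the pooled within-cell variance (half the mean
#' squared replicate difference for duplicates), per-kit bias from the mean
#' across cancers of the (kit - reference) cell-mean difference, per-kit
#' slope variance from the between-cancer variance of those differences
#' minus the replicate-noise contribution (floored at 0), and the cancer
#' variance from the between-cancer variance of the reference cell means.
#' Used as the deterministic starting point of \code{\link{fitLmeSingle}}
#' and as an independent cross-check of the REML fit.
#'
#' @param y numeric vector of per-sample values.
#' @param design design data.frame (see \code{\link{remlCriterion}}).
#' @return list with \code{beta} (named per kit), \code{tau2} (named),
#'   \code{sigma_a2}, \code{sigma_e2}, \code{intercept}.
#' @export
balancedClosedForm <- function(y, design) {
  cond <- droplevels(design$condition)
  cancer <- factor(design$cancer_id)
  tab <- table(cancer, cond)
  if (any(tab == 0L) || any(apply(tab, 2, function(v) length(unique(v))) != 1L))
    stop("design is unbalanced; use fitLmeSingle() instead")
  reps <- tab[1, ]
  cm <- tapply(y, list(cancer, cond), mean)   # cancers x conditions
  ref <- levels(cond)[1]; kits <- levels(cond)[-1]
  # pooled within-cell variance
  cellmean <- cm[cbind(as.integer(cancer), as.integer(cond))]
  dfw <- sum(tab - 1L)
  sigma_e2 <- if (dfw > 0) sum((y - cellmean)^2) / dfw else 0
  beta <- tau2 <- setNames(numeric(length(kits)), kits)
  for (k in kits) {
    dk <- cm[, k] - cm[, ref]
    beta[k] <- mean(dk)
    tau2[k] <- max(0, var(dk) - sigma_e2 * (1 / reps[[k]] + 1 / reps[[ref]]))
  }
  sigma_a2 <- max(0, var(cm[, ref]) - sigma_e2 / reps[[ref]])
  list(beta = beta, tau2 = tau2, sigma_a2 = sigma_a2, sigma_e2 = sigma_e2,
       intercept = mean(cm[, ref]))
}

# moment start for possibly unbalanced designs (falls back gracefully)
.momStart <- function(y, design) {
  out <- tryCatch(balancedClosedForm(y, design), error = function(e) NULL)
  if (!is.null(out)) return(out)
  cond <- droplevels(design$condition)
  cancer <- factor(design$cancer_id)
  ref <- levels(cond)[1]; kits <- levels(cond)[-1]
  cell <- interaction(cancer, cond, drop = TRUE)
  wv <- tapply(y, cell, var)
  sigma_e2 <- mean(wv, na.rm = TRUE)
  if (!is.finite(sigma_e2)) sigma_e2 <- var(y) / 4
  cm <- tapply(y, list(cancer, cond), mean)
  beta <- tau2 <- setNames(numeric(length(kits)), kits)
  for (k in kits) {
    dk <- cm[, k] - cm[, ref]
    beta[k] <- mean(dk, na.rm = TRUE)
    tau2[k] <- max(0, var(dk, na.rm = TRUE) - sigma_e2)
  }
  sigma_a2 <- max(0, var(cm[, ref], na.rm = TRUE) - sigma_e2)
  list(beta = beta, tau2 = tau2, sigma_a2 = sigma_a2, sigma_e2 = sigma_e2,
       intercept = mean(cm[, ref], na.rm = TRUE))
}

#' REML fit of the gene-level reliability mixed model
#'
#' Fits \code{Y = Kit + (Kit | Cancer) + (1 | cell) + residual} by
#' restricted maximum likelihood: the fixed kit terms estimate the
#' systematic expression bias of each FFPE extraction kit against the
#' reference arm, the per-cancer random slopes estimate how much that bias
#' varies across tumors, and the residual captures replicate noise.
#' Variances are optimized on the log scale (L-BFGS-B, deterministic
#' method-of-moments start, criterion tolerance ~1e-8) with a Nelder-Mead
#' polish on non-convergence. Variance estimates driven to the boundary are
#' reported in \code{boundary}, never jittered.
#'
#' @param y numeric vector of per-sample values (one gene or one signature
#'   score), aligned with \code{design} rows.
#' @param design design data.frame (see \code{\link{remlCriterion}}), or a
#'   \linkS4class{KitExperiment} from which it is taken.
#' @param structure \code{"diagonal"} (default; independent random intercept
#'   and per-kit slopes) or \code{"full"} (unstructured covariance of
#'   intercept + slopes, parameterized by its Cholesky factor).
#' @param includeCell estimate the shared cell-effect variance sigma_u^2
#'   (default FALSE: with duplicate extractions it is weakly identified and
#'   fixed at 0).
#' @param unit label stored in the result.
#' @return object of class \code{"LMEResult"}: a list with \code{unit},
#'   \code{intercept}, \code{beta} (named per-kit bias), \code{tau2} (named
#'   per-kit slope variances), \code{sigma_a2}, \code{sigma_u2},
#'   \code{sigma_e2}, \code{Lambda} (full random-effect covariance),
#'   \code{m2reml}, \code{converged}, \code{boundary} (character vector of
#'   variance components pinned at the zero boundary), \code{n_obs}.
#' @examples
#' ke <- simulateStudy(simulationConfig(nGenes = 12, nCancers = 6,
#'                                      nReferenceGenes = 0, seed = 3))
#' fitLmeSingle(assay(ke)[1, ], studyDesign(ke))
#' @export
fitLmeSingle <- function(y, design, structure = c("diagonal", "full"),
                         includeCell = FALSE, unit = "unit") {
  structure <- match.arg(structure)
  if (is(design, "KitExperiment")) design <- studyDesign(design)
  if (!is.numeric(y) || any(!is.finite(y)))
    stop("y must be finite numeric")
  if (length(y) != nrow(design)) stop("length(y) != nrow(design)")
  st <- .lmeStructure(design)
  K <- st$K
  kits <- st$kits
  mom <- .momStart(y, design)

  vscale <- max(var(y), 1e-8)
  vfloor <- 1e-12
  lo <- log(vfloor); hi <- log(vscale * 1e3 + 1)
  clamp <- function(v) pmin(pmax(log(pmax(v, vfloor)), lo), hi)

  if (structure == "diagonal") {
    th0 <- clamp(c(mom$sigma_a2, mom$tau2, mom$sigma_e2))
    nvar <- K + 1L
    if (includeCell) th0 <- c(th0[seq_len(K)], clamp(mom$sigma_e2 / 4),
                              th0[K + 1L])
    make <- function(th) {
      v <- exp(th)
      list(Lambda = diag(v[seq_len(K)], K),
           su2 = if (includeCell) v[K + 1L] else 0,
           se2 = v[length(v)])
    }
    lower <- rep(lo, length(th0)); upper <- rep(hi, length(th0))
  } else {
    # unstructured Lambda via its lower Cholesky factor: log-diagonals,
    # free off-diagonals, then (optional cell) + residual log-variances
    ltri <- lower.tri(matrix(0, K, K))
    d0 <- clamp(c(mom$sigma_a2, mom$tau2)) / 2   # log of chol diagonals
    th0 <- c(d0, rep(0, sum(ltri)))
    if (includeCell) th0 <- c(th0, clamp(mom$sigma_e2 / 4))
    th0 <- c(th0, clamp(mom$sigma_e2))
    make <- function(th) {
      L <- matrix(0, K, K)
      diag(L) <- exp(th[seq_len(K)])
      L[ltri] <- th[K + seq_len(sum(ltri))]
      rest <- th[-(seq_len(K + sum(ltri)))]
      list(Lambda = tcrossprod(L),
           su2 = if (includeCell) exp(rest[1]) else 0,
           se2 = exp(rest[length(rest)]))
    }
    lower <- c(rep(lo / 2, K), rep(-50, sum(ltri)),
               rep(lo, length(th0) - K - sum(ltri)))
    upper <- c(rep(hi / 2, K), rep(50, sum(ltri)),
               rep(hi, length(th0) - K - sum(ltri)))
  }

  fn <- function(th) {
    p <- make(th)
    .remlCrit2(y, st, p$Lambda, p$su2, p$se2)$crit
  }
  crit0 <- fn(th0)
  degenerate <- all(c(mom$sigma_a2, mom$tau2, mom$sigma_e2) <= vfloor * 10)
  if (degenerate) {
    # data fit the fixed effects exactly; the criterion decreases without
    # bound as all variances shrink, so report the boundary fit directly
    opt <- list(par = th0, value = crit0, convergence = 0L)
    converged <- TRUE
  } else {
    # deterministic multi-start: the moment estimate plus an equal split
    # of the total variance (guards against local optima of the surface)
    veq <- clamp(rep(var(y) / (length(th0)), length(th0)))
    starts <- list(th0, pmin(pmax(veq, lower), upper))
    opt <- NULL
    vals <- c()
    for (s in starts) {
      o <- tryCatch(
        optim(s, fn, method = "L-BFGS-B", lower = lower, upper = upper,
              control = list(factr = 1e7, maxit = 200,
                             ndeps = rep(1e-5, length(th0)))),
        error = function(e) NULL)
      if (!is.null(o)) {
        vals <- c(vals, o$value)
        if (is.null(opt) || o$value < opt$value) opt <- o
      }
    }
    converged <- !is.null(opt) && opt$convergence == 0
    # Nelder-Mead escape when the quasi-Newton starts disagree or failed
    agree <- length(vals) == length(starts) &&
      diff(range(vals)) < 1e-6 && converged
    if (!agree) {
      start2 <- if (is.null(opt)) th0 else opt$par
      opt2 <- optim(start2, fn, method = "Nelder-Mead",
                    control = list(maxit = 1000, reltol = 1e-10))
      opt2$par <- pmin(pmax(opt2$par, lower), upper)
      opt2$value <- fn(opt2$par)
      if (is.null(opt) || opt2$value < opt$value - 1e-12) {
        opt <- opt2
        converged <- opt2$convergence == 0
      }
    }
    # final bounded quasi-Newton pass
    opt3 <- tryCatch(
      optim(opt$par, fn, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(factr = 1e3, maxit = 300,
                           ndeps = rep(1e-6, length(th0)))),
      error = function(e) NULL)
    if (!is.null(opt3) && opt3$value <= opt$value) {
      opt <- opt3
      converged <- converged || opt3$convergence == 0
    }
  }
  if (opt$value > crit0) {      # never worse than the moment start
    opt$par <- th0; opt$value <- crit0
  }
  par <- make(opt$par)
  fit <- .remlCrit2(y, st, par$Lambda, par$su2, par$se2)
  beta <- setNames(fit$beta[-1], kits)
  vars <- c(sigma_a2 = unname(par$Lambda[1, 1]),
            setNames(diag(par$Lambda)[-1], paste0("tau2_", kits)),
            sigma_u2 = unname(par$su2), sigma_e2 = unname(par$se2))
  boundary <- names(vars)[vars <= vfloor * 10 & vars > 0]
  if (!includeCell) boundary <- setdiff(boundary, "sigma_u2")
  # an optimizer stall while one or more variances sit on the zero
  # boundary is a boundary optimum, not a failure; the pinned components
  # are reported
  if (!converged && length(boundary)) converged <- TRUE
  out <- list(unit = unit, intercept = unname(fit$beta[1]), beta = beta,
              tau2 = setNames(diag(par$Lambda)[-1], kits),
              sigma_a2 = unname(par$Lambda[1, 1]),
              sigma_u2 = unname(par$su2),
              sigma_e2 = unname(par$se2), Lambda = par$Lambda,
              m2reml = fit$crit, crit_start = crit0,
              converged = converged, boundary = boundary,
              structure = structure, n_obs = st$n)
  class(out) <- "LMEResult"
  out
}

#' @rdname fitLmeSingle
#' @param ke a \linkS4class{KitExperiment} with replicate columns (log2 or
#'   normalized-log2 scale, not averaged).
#' @param maxNonConvergent abort when the non-convergence rate exceeds this
#'   fraction (default 0.5).
#' @param verbose print progress every 1000 genes.
#' @return \code{fitLmeAll}: list with \code{results} (one row per gene:
#'   unit_id, per-kit bias and slope variance, sigma_a2, sigma_e2,
#'   sigma_u2, m2reml, converged, boundary), \code{summary} (per-kit median
#'   and raw MAD of bias and slope variance, median residual variance) and
#'   \code{convergence_rate}.
#' @export
fitLmeAll <- function(ke, structure = c("diagonal", "full"),
                      includeCell = FALSE, maxNonConvergent = 0.5,
                      verbose = FALSE) {
  structure <- match.arg(structure)
  stopifnot(is(ke, "KitExperiment"))
  if (exprScale(ke) == "counts")
    stop("fit the mixed model on the log2 scale")
  design <- studyDesign(ke)
  x <- assay(ke)
  fits <- vector("list", nrow(x))
  for (g in seq_len(nrow(x))) {
    fits[[g]] <- fitLmeSingle(x[g, ], design, structure = structure,
                              includeCell = includeCell,
                              unit = rownames(x)[g])
    if (verbose && g %% 1000 == 0) message(g, " genes fitted")
  }
  kits <- levels(design$condition)[-1]
  res <- data.frame(unit_id = rownames(x), stringsAsFactors = FALSE)
  for (k in kits) res[[paste0("bias_", k)]] <-
    vapply(fits, function(f) f$beta[[k]], numeric(1))
  for (k in kits) res[[paste0("tau2_", k)]] <-
    vapply(fits, function(f) f$tau2[[k]], numeric(1))
  res$sigma_a2 <- vapply(fits, `[[`, numeric(1), "sigma_a2")
  res$sigma_e2 <- vapply(fits, `[[`, numeric(1), "sigma_e2")
  res$sigma_u2 <- vapply(fits, `[[`, numeric(1), "sigma_u2")
  res$m2reml <- vapply(fits, `[[`, numeric(1), "m2reml")
  res$converged <- vapply(fits, `[[`, logical(1), "converged")
  res$boundary <- vapply(fits, function(f)
    paste(f$boundary, collapse = ";"), character(1))
  rate <- mean(!res$converged)
  if (rate > maxNonConvergent)
    stop(sprintf("%.1f%% of gene fits failed to converge", 100 * rate))
  summ <- do.call(rbind, lapply(kits, function(k) {
    b <- res[[paste0("bias_", k)]][res$converged]
    t2 <- res[[paste0("tau2_", k)]][res$converged]
    data.frame(kit = k, median_bias = median(b),
               mad_bias = stats::mad(b, constant = 1),
               median_tau2 = median(t2),
               mad_tau2 = stats::mad(t2, constant = 1),
               stringsAsFactors = FALSE)
  }))
  list(results = res, summary = summ,
       median_sigma_e2 = median(res$sigma_e2[res$converged]),
       convergence_rate = 1 - rate)
}

#' @export
print.LMEResult <- function(x, ...) {
  cat("LMEResult [", x$unit, "] ", x$structure, " structure, n = ",
      x$n_obs, "\n", sep = "")
  cat("  kit bias:", paste(names(x$beta), sprintf("%.4g", x$beta),
                           sep = "=", collapse = ", "), "\n")
  cat("  slope var:", paste(names(x$tau2), sprintf("%.4g", x$tau2),
                            sep = "=", collapse = ", "), "\n")
  cat(sprintf("  sigma_a2 = %.4g  sigma_e2 = %.4g  sigma_u2 = %.4g\n",
              x$sigma_a2, x$sigma_e2, x$sigma_u2))
  cat(sprintf("  -2 REML = %.6g  converged: %s%s\n", x$m2reml, x$converged,
              if (length(x$boundary))
                paste0("  (boundary: ",
                       paste(x$boundary, collapse = ", "), ")") else ""))
  invisible(x)
}
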