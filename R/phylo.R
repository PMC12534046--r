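#' Parse a Newick tree
#'
#' Reads a Newick string or `.nwk` file via \pkg{ape}. Trees without branch
#' lengths (or with missing lengths) get a configurable default length with
#' a warning; duplicate tip labels are an error since tips must identify
#' species uniquely.
#'
#' @param x Newick text or a path to a Newick file.
#' @param default_length branch length substituted where none is given.
#' @return an \pkg{ape} `phylo` object.
#' @export
parse_newick <- function(x, default_length = 1) {
  tree <- if (length(x) == 1 && file.exists(x) && !grepl("\\(", x))
    ape::read.tree(x) else ape::read.tree(text = x)
  if (is.null(tree)) stop("failed to parse Newick input")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; defaulting all to ", default_length)
    tree$edge.length <- rep(default_length, nrow(tree$edge))
  } else if (anyNA(tree$edge.length)) {
    warning("missing branch lengths defaulted to ", default_length)
    tree$edge.length[is.na(tree$edge.length)] <- default_length
  }
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  tree
}

#' Prune a tree to a set of species
#'
#' Returns the induced subtree on the requested tips; unary internal nodes
#' are collapsed with their branch lengths summed, so root-to-tip and
#' patristic distances among the kept species are preserved.
#'
#' @param tree a `phylo` object.
#' @param species character vector of tip labels to keep.
#' @return the pruned `phylo` object.
#' @export
prune_to <- function(tree, species) {
  keep <- intersect(tree$tip.label, species)
  if (!length(keep))
    stop("none of the requested species are in the tree: ",
         paste(utils::head(setdiff(species, tree$tip.label), 10),
               collapse = ", "))
  if (length(keep) == length(tree$tip.label)) return(tree)
  ape::keep.tip(tree, keep)
}

#' Phylogenetic covariance matrix under Pagel's lambda
#'
#' Under Brownian motion the covariance of a trait between two species is
#' the shared branch length from the root to their most recent common
#' ancestor; the diagonal holds root-to-tip lengths. Pagel's lambda
#' multiplies the off-diagonal entries: lambda = 0 removes all phylogenetic
#' dependence, lambda = 1 keeps the full Brownian structure.
#'
#' @param tree a `phylo` object with branch lengths.
#' @param lambda value in \[0, 1\].
#' @return covariance matrix over tips (tip labels as dimnames).
#' @export
phylo_covariance <- function(tree, lambda = 1) {
  stopifnot(lambda >= 0, lambda <= 1)
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  C <- ape::vcv.phylo(tree)
  off <- row(C) != col(C)
  C[off] <- C[off] * lambda
  C
}

# Profile log-likelihood machinery: for fixed lambda the GLS estimates have
# a closed form; lambda is the only parameter needing numeric optimization.
.gls_at_lambda <- function(X, y, C, lambda) {
  Cl <- C
  off <- row(Cl) != col(Cl)
  Cl[off] <- Cl[off] * lambda
  L <- tryCatch(chol(Cl), error = function(e)
    stop("phylogenetic covariance singular at lambda = ", lambda))
  Xw <- backsolve(L, X, transpose = TRUE)
  yw <- backsolve(L, y, transpose = TRUE)
  fit <- stats::lm.fit(Xw, yw)
  n <- length(y)
  rss <- sum(fit$residuals^2)
  sigma2_ml <- rss / n
  loglik <- -0.5 * (n * log(2 * pi * sigma2_ml) +
                      2 * sum(log(diag(L))) + n)
  list(coef = fit$coefficients, rss = rss, loglik = loglik, Xw = Xw, yw = yw)
}

#' Phylogenetic generalized least squares with Pagel's lambda
#'
#' Fits `y ~ x` by generalized least squares whose error covariance is the
#' phylogenetic covariance scaled by Pagel's lambda. Lambda is estimated by
#' maximum likelihood over \[0, 1\] (golden-section search with boundary
#' checks, tolerance 1e-6) unless supplied. The slope's p-value comes from
#' its t-statistic on n - 2 degrees of freedom; the adjusted R-squared is
#' computed in the GLS metric against the intercept-only model at the same
#' lambda.
#'
#' Species present in the trait vectors but absent from the tree are dropped
#' with a message; tip order is immaterial since traits are matched by name.
#'
#' @param x,y named numeric vectors (names = species / tip labels). Unnamed
#'   vectors are taken in `tree$tip.label` order.
#' @param tree a `phylo` object with branch lengths.
#' @param lambda fix lambda instead of estimating it.
#' @return object of class `pgls_fit`: list with `beta`, `intercept`,
#'   `se_beta`, `p_beta`, `r2_adj`, `lambda`, `loglik`, `n_species`,
#'   `n_dropped`.
#' @export
pgls_fit <- function(x, y, tree, lambda = NULL) {
  if (is.null(names(x))) names(x) <- tree$tip.label[seq_along(x)]
  if (is.null(names(y))) names(y) <- tree$tip.label[seq_along(y)]
  common <- intersect(intersect(names(x), names(y)), tree$tip.label)
  n_dropped <- length(union(names(x), names(y))) - length(common)
  if (length(common) < 3) stop("PGLS needs at least 3 species shared ",
                               "between traits and tree")
  if (n_dropped > 0)
    message(n_dropped, " species dropped (absent from tree or traits)")
  tree <- prune_to(tree, common)
  ord <- tree$tip.label
  xv <- x[ord]; yv <- y[ord]
  if (stats::sd(xv) == 0) stop("constant predictor x: slope undefined")
  n <- length(ord)
  C <- ape::vcv.phylo(tree)
  X <- cbind(`(Intercept)` = 1, x = xv)

  if (is.null(lambda)) {
    obj <- function(l) .gls_at_lambda(X, yv, C, l)$loglik
    opt <- stats::optimize(obj, interval = c(0, 1), maximum = TRUE,
                           tol = 1e-6)
    cand <- c(opt$maximum, 0, 1)
    ll <- c(opt$objective, obj(0), obj(1))
    lambda_hat <- cand[which.max(ll)]
    estimated <- TRUE
  } else {
    stopifnot(lambda >= 0, lambda <= 1)
    lambda_hat <- lambda
    estimated <- FALSE
  }
  g <- .gls_at_lambda(X, yv, C, lambda_hat)
  df <- n - 2
  sigma2 <- g$rss / df
  XtX_inv <- chol2inv(chol(crossprod(g$Xw)))
  se <- sqrt(sigma2 * diag(XtX_inv))
  t_beta <- g$coef[2] / se[2]
  p_beta <- 2 * stats::pt(-abs(t_beta), df)
  g0 <- .gls_at_lambda(X[, 1, drop = FALSE], yv, C, lambda_hat)
  r2 <- 1 - g$rss / g0$rss
  r2_adj <- 1 - (1 - r2) * (n - 1) / df

  structure(list(beta = unname(g$coef[2]),
                 intercept = unname(g$coef[1]),
                 se_beta = unname(se[2]), t_beta = unname(t_beta),
                 p_beta = unname(p_beta), r2_adj = r2_adj,
                 lambda = lambda_hat, lambda_estimated = estimated,
                 loglik = g$loglik, n_species = n, n_dropped = n_dropped),
            class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat(sprintf(
    "<pgls_fit> beta = %.4g (SE %.3g), p = %.3g, adj. R2 = %.3f, lambda%s = %.4f, n = %d\n",
    x$beta, x$se_beta, x$p_beta, x$r2_adj,
    if (x$lambda_estimated) " (ML)" else " (fixed)", x$lambda, x$n_species))
  invisible(x)
}
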