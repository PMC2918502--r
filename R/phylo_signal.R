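#' Read a phylogeny from a Newick file
#'
#' Thin wrapper around [ape::read.tree()] with the validation the
#' downstream fits rely on: tip labels must be unique, and the string must
#' parse to a rooted topology.
#'
#' @param path Path to a Newick file (or use `text` for a literal string).
#' @param text Optional Newick string instead of a file.
#' @return An [ape::read.tree()] `phylo` object.
#' @export
read_newick_tree <- function(path = NULL, text = NULL) {
  tr <- tryCatch(
    if (is.null(text)) ape::read.tree(path) else ape::read.tree(text = text),
    error = function(e) stop("Newick parse error: ", conditionMessage(e)),
    warning = function(w) stop("Newick parse error: ", conditionMessage(w))
  )
  if (is.null(tr)) stop("Newick parse error: no tree could be read")
  if (inherits(tr, "multiPhylo")) tr <- tr[[1]]
  if (anyDuplicated(tr$tip.label))
    stop("duplicate tip label(s): ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  tr
}

#' Write a phylogeny to a Newick file
#' @param tree A `phylo` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Apply a branch-length hypothesis
#'
#' `"equal"` sets every branch length to 1. `"proportional"` assigns node
#' heights proportional to (number of descendant tips - 1), producing an
#' ultrametric tree of unit depth (Grafen's rho = 1 method). `"as-given"`
#' leaves the tree untouched.
#'
#' @param tree A `phylo` object.
#' @param scheme One of `"equal"`, `"proportional"`, `"as-given"`.
#' @return The transformed `phylo`, with attribute `scheme`.
#' @export
apply_branch_scheme <- function(tree, scheme = c("equal", "proportional", "as-given")) {
  scheme <- match.arg(scheme)
  if (scheme == "equal") {
    tree$edge.length <- rep(1, nrow(tree$edge))
  } else if (scheme == "proportional") {
    if (ape::Ntip(tree) < 2)
      stop("proportional branch lengths are undefined for a single-tip tree")
    tree <- ape::compute.brlen(tree, method = "Grafen", power = 1)
  }
  attr(tree, "scheme") <- scheme
  tree
}

#' Phylogenetic covariance matrix
#'
#' Entry (i, j) is the depth (from the root) of the most recent common
#' ancestor of tips i and j; the diagonal holds root-to-tip distances.
#' This is the trait covariance implied by Brownian motion on the tree.
#'
#' @param tree A `phylo` with positive branch lengths.
#' @return Symmetric positive semi-definite matrix over tips.
#' @export
phylo_covariance <- function(tree) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length <= 0))
    stop("all branch lengths must be positive; apply a branch scheme first")
  ape::vcv.phylo(tree)
}

.lambda_cov <- function(C, lambda) {
  Cl <- C * lambda
  diag(Cl) <- diag(C)
  Cl
}

#' Profiled log-likelihood of Pagel's lambda
#'
#' Multiplies the off-diagonal elements of the phylogenetic covariance by
#' `lambda`, profiles out the mean (GLS estimate) and the scale (ML
#' estimate, divisor n) and returns the resulting multivariate-normal
#' log-likelihood. Evaluated through the Cholesky factor of the
#' transformed covariance, never an explicit inverse.
#'
#' @param y Named (or C-ordered) trait values, one per tip.
#' @param C Covariance matrix from [phylo_covariance()].
#' @param lambda Multiplier in \[0, 1\].
#' @return Log-likelihood, with attributes `mu` and `sigma2` (the
#'   profiled estimates).
#' @export
lambda_loglik <- function(y, C, lambda) {
  if (!is.null(names(y)) && !is.null(rownames(C))) {
    if (!setequal(names(y), rownames(C)))
      stop("trait names do not match covariance tips")
    y <- y[rownames(C)]
  }
  n <- length(y)
  if (n != nrow(C)) stop("length(y) must equal nrow(C)")
  if (anyNA(y) || !all(is.finite(y))) stop("trait values must be finite")
  R <- tryCatch(chol(.lambda_cov(C, lambda)),
                error = function(e) stop("transformed covariance is singular at lambda = ",
                                         lambda))
  logdet <- 2 * sum(log(diag(R)))
  one <- rep(1, n)
  z1 <- backsolve(R, one, transpose = TRUE)
  zy <- backsolve(R, y, transpose = TRUE)
  mu <- sum(z1 * zy) / sum(z1 * z1)
  zr <- zy - mu * z1
  sigma2 <- sum(zr * zr) / n
  ll <- -0.5 * (n * log(2 * pi) + n * log(sigma2) + logdet + n)
  structure(ll, mu = mu, sigma2 = sigma2)
}

#' Likelihood-ratio statistic and p-value
#'
#' @param lnl_hat Log-likelihood at the maximum-likelihood estimate.
#' @param lnl_ref Log-likelihood of the constrained model.
#' @param df Degrees of freedom of the test (default 1).
#' @return List with `stat` (2 * (lnl_hat - lnl_ref)) and `p` from the
#'   chi-square reference distribution.
#' @export
lr_test <- function(lnl_hat, lnl_ref, df = 1) {
  stat <- 2 * (lnl_hat - lnl_ref)
  list(stat = stat, p = stats::pchisq(max(stat, 0), df = df, lower.tail = FALSE))
}

#' Maximum-likelihood fit of Pagel's lambda
#'
#' Estimates the multiplier of the off-diagonal phylogenetic covariances
#' by bounded 1-D maximum likelihood on \[0, 1\] (tolerance 1e-6; the
#' interior optimum is compared against both endpoints), with
#' likelihood-ratio tests against lambda = 1 (Brownian motion) and
#' lambda = 0 (phylogenetic independence), each on 1 df. When the
#' estimate sits on a bound the chi-square p-value is still reported, with
#' a `boundary` flag (the plain chi-square reference is conservative
#' there).
#'
#' @param y Named trait values, one per tip of `tree`.
#' @param tree A `phylo` object.
#' @param scheme Branch-length hypothesis passed to
#'   [apply_branch_scheme()]; default `"as-given"`.
#' @param tol Optimiser tolerance, default 1e-6.
#' @return A `lambda_fit` object with components `lambda`, `lnL`, `lnL1`,
#'   `lnL0`, `LR1`, `LR0`, `p1`, `p0`, `mu`, `sigma2`, `scheme`, `n`,
#'   `boundary`. Has `print`, `summary`, `coef` and `logLik` methods.
#' @export
fit_lambda <- function(y, tree, scheme = c("as-given", "equal", "proportional"),
                       tol = 1e-6) {
  scheme <- match.arg(scheme)
  if (ape::Ntip(tree) < 4) stop("fit_lambda needs at least 4 tips")
  tree <- apply_branch_scheme(tree, scheme)
  C <- phylo_covariance(tree)
  if (!is.null(names(y))) y <- y[rownames(C)]
  if (anyNA(y)) stop("trait values missing for some tips")
  f <- function(lam) as.numeric(lambda_loglik(y, C, lam))
  opt <- stats::optimize(f, c(0, 1), maximum = TRUE, tol = tol)
  if (!is.finite(opt$objective))
    stop("lambda optimiser failed to converge: non-finite likelihood at lambda = ",
         opt$maximum)
  ll0 <- f(0); ll1 <- f(1)
  cand_lam <- c(opt$maximum, 0, 1)
  cand_ll <- c(opt$objective, ll0, ll1)
  best <- which.max(cand_ll)
  lambda_hat <- cand_lam[best]
  ll_hat <- lambda_loglik(y, C, lambda_hat)
  t1 <- lr_test(as.numeric(ll_hat), ll1)
  t0 <- lr_test(as.numeric(ll_hat), ll0)
  structure(list(
    lambda = lambda_hat, lnL = as.numeric(ll_hat), lnL1 = ll1, lnL0 = ll0,
    LR1 = t1$stat, LR0 = t0$stat, p1 = t1$p, p0 = t0$p,
    mu = attr(ll_hat, "mu"), sigma2 = attr(ll_hat, "sigma2"),
    scheme = scheme, n = length(y),
    boundary = lambda_hat < tol || lambda_hat > 1 - tol,
    call = match.call()
  ), class = "lambda_fit")
}

#' @export
print.lambda_fit <- function(x, digits = 4, ...) {
  cat("Pagel's lambda fit (", x$n, " tips, ", x$scheme, " branch lengths)\n",
      sep = "")
  cat(sprintf("  lambda = %.3f   lnL = %.2f   lnL1 = %.2f   lnL0 = %.2f\n",
              x$lambda, x$lnL, x$lnL1, x$lnL0))
  cat(sprintf("  LR vs 1: %.2f (p = %.3g)   LR vs 0: %.2f (p = %.3g)\n",
              x$LR1, x$p1, x$LR0, x$p0))
  if (x$boundary)
    cat("  note: estimate at a bound; chi-square p-values are conservative\n")
  invisible(x)
}

#' @export
summary.lambda_fit <- function(object, ...) object

#' @export
coef.lambda_fit <- function(object, ...) {
  c(lambda = object$lambda, mu = object$mu, sigma2 = object$sigma2)
}

#' @export
logLik.lambda_fit <- function(object, ...) {
  structure(object$lnL, df = 3, nobs = object$n, class = "logLik")
}

#' Tabulate lambda fits across traits and schemes
#'
#' @param fits Named list of `lambda_fit` objects (names become the trait
#'   column).
#' @param path Optional CSV output path.
#' @return Data frame with columns trait, scheme, lambda, lnL_lambda,
#'   lnL1, lnL0, LR1, LR0, p1, p0.
#' @export
lambda_table <- function(fits, path = NULL) {
  d <- do.call(rbind, lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    data.frame(trait = nm, scheme = f$scheme, lambda = f$lambda,
               lnL_lambda = f$lnL, lnL1 = f$lnL1, lnL0 = f$lnL0,
               LR1 = f$LR1, LR0 = f$LR0, p1 = f$p1, p0 = f$p0)
  }))
  rownames(d) <- NULL
  if (!is.null(path)) utils::write.csv(d, path, row.names = FALSE)
  d
}
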