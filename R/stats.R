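#' Sequential (Type-I) ANOVA over an ordered factor battery
#'
#' Tests the effect of the first factor (microhabitat, by convention) while
#' controlling for the remaining factors by entering them sequentially:
#' the sums of squares are the Type-I decomposition in the stated order, and
#' each factor's F is tested against the residual mean square. Nested factors
#' (species within microhabitat, individual within species, ...) are handled
#' naturally: aliased levels are absorbed, and the factor's degrees of freedom
#' are those actually estimable.
#'
#' @param data data.frame of wingbeat records
#' @param response name of the response column
#' @param factors character vector of factor column names in the order they
#'   should enter the model
#' @return data.frame of class \code{anova_table}: one row per factor plus a
#'   Residuals row, columns term, df, sum_sq, mean_sq, F, p
#' @export
sequential_anova <- function(data, response,
                             factors = c("microhabitat", "species",
                                         "individual", "flight",
                                         "wingbeat_index")) {
  stopifnot(response %in% names(data), all(factors %in% names(data)))
  y <- data[[response]]
  if (any(!is.finite(y))) stop("non-finite response values")
  d <- data.frame(.y = y)
  for (f in factors) d[[f]] <- factor(data[[f]])
  fml <- stats::as.formula(paste(".y ~", paste(factors, collapse = " + ")))
  fit <- stats::lm(fml, data = d)
  if (stats::df.residual(fit) < 1)
    stop("factors are fully confounded with the observations ",
         "(zero residual degrees of freedom)")
  a <- suppressWarnings(stats::anova(fit))  # perfect fits are legitimate here
  out <- data.frame(term = rownames(a), df = a$Df, sum_sq = a$`Sum Sq`,
                    mean_sq = a$`Mean Sq`, F = a$`F value`, p = a$`Pr(>F)`)
  if (stats::var(y) == 0) {
    out$sum_sq <- 0; out$mean_sq <- 0
    out$F[-nrow(out)] <- 0
    out$p[-nrow(out)] <- 1
  }
  attr(out, "total_ss") <- sum(out$sum_sq)
  class(out) <- c("anova_table", "data.frame")
  out
}

#' MANOVA with Wilks' lambda
#'
#' Multivariate test of a group effect across several responses at once:
#' Wilks' lambda = det(W) / det(W + B) (W, B the within- and between-group
#' cross-product matrices) with Rao's F approximation for the p-value.
#'
#' @param data data.frame
#' @param responses character vector of response column names
#' @param group name of the grouping column
#' @return list with \code{lambda}, \code{F}, \code{df1}, \code{df2},
#'   \code{p} and \code{n}
#' @export
manova_wilks <- function(data, responses, group) {
  stopifnot(all(responses %in% names(data)), group %in% names(data))
  Y <- as.matrix(data[responses])
  g <- factor(data[[group]])
  n <- nrow(Y); p <- ncol(Y); k <- nlevels(g)
  if (k < 2) stop("need at least two groups")
  if (n <= p + k - 1)
    stop("too few observations (", n, ") for ", p, " responses")
  gm <- colMeans(Y)
  W <- matrix(0, p, p); B <- matrix(0, p, p)
  for (lev in levels(g)) {
    Yk <- Y[g == lev, , drop = FALSE]
    mk <- colMeans(Yk)
    Ck <- sweep(Yk, 2, mk)
    W <- W + crossprod(Ck)
    B <- B + nrow(Yk) * tcrossprod(mk - gm)
  }
  detW <- det(W); detT <- det(W + B)
  if (!is.finite(detW) || detW <= 0 || detT <= 0)
    stop("singular within-group covariance; reduce the response set")
  lambda <- detW / detT
  # Rao's F approximation
  df1 <- p * (k - 1)
  tden <- p^2 + (k - 1)^2 - 5
  tt <- if (tden > 0) sqrt((p^2 * (k - 1)^2 - 4) / tden) else 1
  df2 <- ((n - 1) - (p + k) / 2) * tt - (p * (k - 1) - 2) / 2
  lam_t <- lambda^(1 / tt)
  Fstat <- ((1 - lam_t) / lam_t) * (df2 / df1)
  list(lambda = lambda, F = Fstat, df1 = df1, df2 = df2,
       p = stats::pf(Fstat, df1, df2, lower.tail = FALSE), n = n)
}

# one-way F statistic; x: values, g: factor. Vectorized over columns of x.
.oneway_F <- function(X, g) {
  X <- cbind(X)
  n <- nrow(X); k <- nlevels(g)
  gm <- colMeans(X)
  ssb <- 0; ssw <- 0
  for (lev in levels(g)) {
    idx <- g == lev
    m <- colMeans(X[idx, , drop = FALSE])
    ssb <- ssb + sum(idx) * (m - gm)^2
    ssw <- ssw + colSums(sweep(X[idx, , drop = FALSE], 2, m)^2)
  }
  as.numeric((ssb / (k - 1)) / (ssw / (n - k)))
}

#' Phylogenetic ANOVA by Brownian-motion simulation
#'
#' Tests a group difference in species mean traits while controlling for
#' phylogenetic relatedness: the observed one-way ANOVA F on the species means
#' is compared with the null distribution of F obtained by simulating trait
#' evolution under Brownian motion on the supplied tree (rate estimated from
#' the observed tip data by GLS), following the simulation approach of
#' Garland-style phylogenetic ANOVA. The p-value is the proportion of
#' simulated F at least as large as the observed one, with the +1 correction.
#'
#' @param species_means named numeric vector of per-species trait means
#'   (names = tree tips)
#' @param groups named factor/character of group membership per species
#' @param tree \code{phylo} tree whose tips match the species names
#' @param n_sim number of Brownian-motion simulations (>= 100)
#' @param seed RNG seed
#' @return object of class \code{phylo_anova}: list with \code{F_obs},
#'   \code{F_sim}, \code{p}, \code{sigma2}, \code{n_sim}, \code{tree}
#' @export
phylogenetic_anova <- function(species_means, groups, tree, n_sim = 10000,
                               seed = NULL) {
  if (n_sim < 100) stop("n_sim must be at least 100")
  sp <- names(species_means)
  if (is.null(sp) || !setequal(sp, tree$tip.label))
    stop("species names do not match the tree tips: ",
         paste(setdiff(tree$tip.label, sp), collapse = ", "))
  g <- factor(unlist(groups)[sp])
  if (nlevels(g) < 2) stop("need at least two groups")
  x <- as.numeric(species_means[sp])
  n <- length(x)
  C <- ape::vcv(tree)[sp, sp]
  Ci <- solve(C)
  one <- rep(1, n)
  mu <- as.numeric((one %*% Ci %*% x) / (one %*% Ci %*% one))
  sigma2 <- as.numeric(t(x - mu) %*% Ci %*% (x - mu)) / n
  F_obs <- .oneway_F(x, g)
  if (!is.null(seed)) set.seed(seed)
  Lc <- t(chol(C))
  Z <- matrix(stats::rnorm(n * n_sim), n, n_sim)
  X_sim <- mu + sqrt(sigma2) * (Lc %*% Z)
  F_sim <- .oneway_F(X_sim, g)
  p <- (1 + sum(F_sim >= F_obs)) / (n_sim + 1)
  structure(list(F_obs = F_obs, F_sim = F_sim, p = p, sigma2 = sigma2,
                 n_sim = n_sim, tree = tree),
            class = "phylo_anova")
}

#' @export
print.phylo_anova <- function(x, ...) {
  cat("Phylogenetic ANOVA (Brownian-motion simulation null)\n")
  cat("  observed F:", signif(x$F_obs, 4), " phylogenetic p:",
      signif(x$p, 4), " (", x$n_sim, "simulations )\n")
  invisible(x)
}

#' Simple linear regression
#'
#' Ordinary least-squares fit of y on x with the fit statistics reported in
#' regression tables: slope, intercept, R^2, F and its two-sided p-value.
#'
#' @param x,y numeric vectors (n >= 3, x non-constant)
#' @return list with slope, intercept, r_squared, F, p, n, residual_sd
#' @export
linear_regression <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("regression needs at least 3 paired observations")
  if (stats::var(x) == 0) stop("x is constant; slope undefined")
  fit <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(fit))  # exact lines are legitimate inputs
  co <- stats::coef(fit)
  fstat <- sm$fstatistic
  p <- if (is.null(fstat)) NA_real_ else
    stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
  list(slope = unname(co[2]), intercept = unname(co[1]),
       r_squared = sm$r.squared,
       F = if (is.null(fstat)) NA_real_ else unname(fstat[1]),
       p = unname(p), n = n, residual_sd = sm$sigma)
}

#' Pearson correlation with two-sided t-based p-value
#'
#' @param x,y numeric vectors (n >= 3, both non-constant)
#' @return list with \code{r}, \code{p}, \code{n}
#' @export
pearson_correlation <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("correlation needs at least 3 paired observations")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("constant input; correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Wilcoxon rank-sum test
#'
#' Exact two-sided p-value for small samples without ties (combined n <= 25),
#' normal approximation with tie correction otherwise.
#'
#' @param group_a,group_b numeric vectors
#' @return list with \code{W} (rank-sum statistic of group a), \code{p},
#'   \code{exact} (logical)
#' @export
wilcoxon_rank_sum <- function(group_a, group_b) {
  if (length(group_a) == 0 || length(group_b) == 0)
    stop("both groups must be non-empty")
  ties <- any(duplicated(c(group_a, group_b)))
  exact <- (length(group_a) + length(group_b)) <= 25 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(group_a, group_b, exact = exact, correct = TRUE))
  list(W = unname(wt$statistic), p = min(1, wt$p.value), exact = exact)
}

#' Percent difference of two group means
#'
#' The percentage by which \code{mean_a} exceeds \code{mean_b}:
#' 100 (a - b) / b, optionally rounded to the reporting precision.
#'
#' @param mean_a,mean_b group means (b nonzero)
#' @param digits rounding digits (NULL for unrounded)
#' @return percent difference
#' @export
percent_difference <- function(mean_a, mean_b, digits = NULL) {
  if (mean_b == 0) stop("baseline mean is zero; percent difference undefined")
  pd <- 100 * (mean_a - mean_b) / mean_b
  if (!is.null(digits)) pd <- round(pd, digits)
  pd
}
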