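# Independent oracles used across the suite.  Each deliberately uses a
# different algorithm from the implementation it checks.

# Wright's recursive coancestry: f(i,i) = (1 + f(s,d))/2,
# f(i,j) = (f(s,j) + f(d,j))/2 recursing on the younger animal.
# Returns the additive relationship matrix A = 2f (diagonal 1 + F).
wright_A <- function(ped) {
  id <- as.character(ped$id)
  sire <- match(as.character(ped$sire), id)
  dam <- match(as.character(ped$dam), id)
  n <- length(id)
  depth <- integer(n)
  repeat {
    new <- pmax(ifelse(is.na(sire), 0L, depth[sire] + 1L),
                ifelse(is.na(dam), 0L, depth[dam] + 1L))
    if (identical(new, depth)) break
    depth <- new
  }
  memo <- new.env(hash = TRUE)
  f <- function(i, j) {
    if (i > j) { tmp <- i; i <- j; j <- tmp }
    key <- paste(i, j)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    val <- if (i == j) {
      s <- sire[i]; d <- dam[i]
      0.5 * (1 + if (is.na(s) || is.na(d)) 0 else f(s, d))
    } else {
      # recurse on the deeper (younger) of the pair
      if (depth[i] > depth[j]) { tmp <- i; i2 <- j; j2 <- tmp } else {
        i2 <- i; j2 <- j }
      s <- sire[j2]; d <- dam[j2]
      0.5 * ((if (is.na(s)) 0 else f(i2, s)) +
               (if (is.na(d)) 0 else f(i2, d)))
    }
    memo[[key]] <- val
    val
  }
  A <- matrix(0, n, n, dimnames = list(id, id))
  for (i in seq_len(n)) for (j in i:n) {
    v <- 2 * f(i, j)
    if (i == j) v <- v else A[j, i] <- v
    A[i, j] <- v
  }
  A
}

# Gene-dropping Monte Carlo estimate of A: unique founder alleles are
# dropped through the pedigree; relationship = 2 * P(random alleles IBD),
# diagonal = 1 + P(the animal's two alleles IBD).  Returns estimate and
# per-entry standard errors.
gene_drop_A <- function(ped, n_drops = 1e5, seed = 1) {
  set.seed(seed)
  id <- as.character(ped$id)
  sire <- match(as.character(ped$sire), id)
  dam <- match(as.character(ped$dam), id)
  n <- length(id)
  depth <- integer(n)
  repeat {
    new <- pmax(ifelse(is.na(sire), 0L, depth[sire] + 1L),
                ifelse(is.na(dam), 0L, depth[dam] + 1L))
    if (identical(new, depth)) break
    depth <- new
  }
  ord <- order(depth)
  # allele labels: constant across drops; IBD is judged within a drop
  a1 <- matrix(0L, n, n_drops)
  a2 <- matrix(0L, n, n_drops)
  label <- 0L
  for (i in ord) {
    s <- sire[i]; d <- dam[i]
    if (is.na(s)) {
      label <- label + 1L
      a1[i, ] <- label
    } else {
      pick <- stats::runif(n_drops) < 0.5
      a1[i, ] <- ifelse(pick, a1[s, ], a2[s, ])
    }
    if (is.na(d)) {
      label <- label + 1L
      a2[i, ] <- label
    } else {
      pick <- stats::runif(n_drops) < 0.5
      a2[i, ] <- ifelse(pick, a1[d, ], a2[d, ])
    }
  }
  ibd_self <- a1 == a2  # animals x drops indicator of autozygosity
  A_hat <- matrix(0, n, n, dimnames = list(id, id))
  A_se <- matrix(0, n, n, dimnames = list(id, id))
  for (i in seq_len(n)) for (j in i:n) {
    v <- if (i == j) {
      1 + (a1[i, ] == a2[i, ])
    } else {
      0.5 * ((a1[i, ] == a1[j, ]) + (a1[i, ] == a2[j, ]) +
               (a2[i, ] == a1[j, ]) + (a2[i, ] == a2[j, ]))
    }
    A_hat[i, j] <- A_hat[j, i] <- mean(v)
    A_se[i, j] <- A_se[j, i] <- stats::sd(v) / sqrt(n_drops)
  }
  list(A = A_hat, se = A_se, ibd_self = ibd_self)
}

# Dense-matrix restricted log-likelihood at variance ratio delta, with
# sigma_a2 profiled out; same constant convention as the package.
dense_reml_loglik <- function(y, X, A, delta) {
  n <- length(y)
  p <- ncol(X)
  V0 <- A + delta * diag(n)
  Vi <- solve(V0)
  XtViX <- t(X) %*% Vi %*% X
  beta <- solve(XtViX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  rss <- drop(t(r) %*% Vi %*% r)
  sa <- rss / (n - p)
  -0.5 * ((n - p) * log(2 * pi) + (n - p) * log(sa) +
            as.numeric(determinant(V0)$modulus) +
            as.numeric(determinant(XtViX)$modulus) + (n - p))
}

# Dense GLS of y on [1, x] with covariance known up to scale: the scale is
# re-estimated from the weighted residuals (the F-test convention).
dense_gls <- function(y, x, V) {
  n <- length(y)
  X <- cbind(1, x)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  beta <- solve(XtViX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  s2 <- drop(t(r) %*% Vi %*% r) / (n - 2)
  covb <- s2 * solve(XtViX)
  list(beta = beta[2], se = sqrt(covb[2, 2]),
       f = (beta[2] / sqrt(covb[2, 2]))^2,
       p = stats::pf((beta[2] / sqrt(covb[2, 2]))^2, 1, n - 2,
                     lower.tail = FALSE))
}
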